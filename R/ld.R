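#' Pairwise signed r and r2 between SNPs on the same chromosome
#'
#' For each same-chromosome pair within `max_dist_bp`, the signed gametic
#' correlation r = (p_AB - p_A p_B) / sqrt(p_A (1-p_A) p_B (1-p_B)) is
#' computed over the gametes complete at both markers, with allele
#' orientation fixed to the alt-allele dosage at both markers (this equals
#' the Pearson correlation of the two 0/1 gamete columns). Pairs
#' monomorphic in the sample (r undefined) are skipped and counted.
#'
#' @param haps a `hap_set` (see [panel_haplotypes()]).
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @return data.frame (`ld_pairs`) with columns `id_i`, `id_j`, `dist_bp`,
#'   `r`, `r2`; attribute `n_monomorphic_skipped`.
#' @export
pairwise_ld <- function(haps, max_dist_bp = 1e6) {
  mk <- haps$markers
  out <- vector("list", 0L)
  skipped <- 0L
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    if (length(idx) < 2L) next
    pos <- mk$pos[idx]
    h <- haps$haplotypes[, idx, drop = FALSE]
    r <- suppressWarnings(stats::cor(h, use = "pairwise.complete.obs"))
    dd <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(dd) & dd <= max_dist_bp, arr.ind = TRUE)
    if (!nrow(sel)) next
    rv <- r[sel]
    ok <- !is.na(rv)
    skipped <- skipped + sum(!ok)
    sel <- sel[ok, , drop = FALSE]; rv <- rv[ok]
    out[[length(out) + 1L]] <- data.frame(
      id_i = mk$id[idx[sel[, 1L]]], id_j = mk$id[idx[sel[, 2L]]],
      dist_bp = dd[sel], r = rv, r2 = rv^2,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(id_i = character(0), id_j = character(0),
                         dist_bp = numeric(0), r = numeric(0),
                         r2 = numeric(0))
  attr(res, "n_monomorphic_skipped") <- skipped
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Hill-Weir expected r2 under drift-recombination equilibrium
#'
#' E\[r2\](C) = (10+C) / ((2+C)(11+C)) *
#'   (1 + (3+C)(12+12C+C^2) / (n (2+C)(11+C)))
#' with C the population recombination parameter of the pair and n the
#' number of sampled gametes. Decreases monotonically from its value at
#' C = 0 to the sampling floor 1/n.
#'
#' @param C nonnegative recombination parameter (vectorized).
#' @param n number of gametes.
#' @export
hill_weir_r2 <- function(C, n) {
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir r2 decay curve to observed pairs
#'
#' Least-squares fit of observed r2 against E\[r2\](C) with C = rho * d
#' (d = physical distance in bp) and rho >= 0 the single free parameter.
#' The residual sum of squares is minimized in log10(rho) by a dense grid
#' scan (covering the multi-start range 1e-12 .. 1e-2 per bp) followed by
#' golden-section refinement in the bracketing interval.
#'
#' @param pairs an `ld_pairs` table ([pairwise_ld()]); needs >= 50 pairs
#'   spanning more than one distance.
#' @param n_gametes sample size entering the expectation.
#' @return A `decay_fit`: list with `rho_per_bp`, `n_gametes`, `sse`,
#'   `n_pairs`.
#' @export
hill_weir_fit <- function(pairs, n_gametes) {
  d <- pairs$dist_bp; r2 <- pairs$r2
  ok <- is.finite(d) & is.finite(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (length(d) < 50L) stop("need >= 50 informative pairs, got ", length(d))
  if (length(unique(d)) < 2L)
    stop("degenerate fit: all pairs at a single distance")
  sse <- function(log10rho) {
    C <- 10^log10rho * d
    sum((r2 - hill_weir_r2(C, n_gametes))^2)
  }
  grid <- seq(-12, -2, length.out = 121L)
  vals <- vapply(grid, sse, numeric(1L))
  if (!any(is.finite(vals))) stop("Hill-Weir fit failed at all starts")
  b <- which.min(vals)
  lo <- grid[max(1L, b - 1L)]; hi <- grid[min(length(grid), b + 1L)]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  ## a flat profile up to the lower grid edge means no decay is detectable
  rho <- if (b == 1L && vals[1L] <= opt$objective) 10^grid[1L]
         else 10^opt$minimum
  structure(list(rho_per_bp = rho, n_gametes = as.integer(n_gametes),
                 sse = min(vals[b], opt$objective),
                 n_pairs = length(d)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir fit: rho = %.4g /bp (n = %d gametes, %d pairs)\n",
              x$rho_per_bp, x$n_gametes, x$n_pairs))
  invisible(x)
}

#' Physical LD decay distance of a fitted curve
#'
#' Root of E\[r2\](rho d) = threshold on (0, 10 Mb\]; the curve decreases
#' monotonically so the root is unique. When the curve starts at or below
#' the threshold the distance is 0 (flag `below_threshold`); when the
#' sampling asymptote 1/n (or the curve at 10 Mb) stays above the threshold
#' the distance is not reached (flag `reached = FALSE`, distance NA).
#'
#' @param fit a `decay_fit`.
#' @param threshold r2 threshold (default 0.2).
#' @param max_bp search cap (default 10 Mb).
#' @return list with `distance_bp`, `reached`, `below_threshold`.
#' @export
decay_distance <- function(fit, threshold = 0.2, max_bp = 1e7) {
  n <- fit$n_gametes; rho <- fit$rho_per_bp
  e0 <- hill_weir_r2(0, n)
  if (e0 <= threshold)
    return(list(distance_bp = 0, reached = TRUE, below_threshold = TRUE))
  if (1 / n >= threshold || rho <= 0 ||
      hill_weir_r2(rho * max_bp, n) > threshold)
    return(list(distance_bp = NA_real_, reached = FALSE,
                below_threshold = FALSE))
  root <- stats::uniroot(function(dd) hill_weir_r2(rho * dd, n) - threshold,
                         lower = 1e-9, upper = max_bp, tol = 1e-6)
  list(distance_bp = root$root, reached = TRUE, below_threshold = FALSE)
}

#' Draw a gamete sample under an l-populations x g-gametes scheme
#'
#' Draws `l` populations, then `g` gametes per population uniformly without
#' replacement, and pools them into a `hap_set`. With `seed = NULL` the
#' current RNG stream is used (callers such as [sampling_scheme_ld()] manage
#' their own seed).
#'
#' @param panel phased [pop_panel()].
#' @param l number of populations.
#' @param g gametes per population.
#' @param seed optional integer seed.
#' @return A `hap_set` of the pooled gametes.
#' @export
sample_gametes <- function(panel, l, g, seed = NULL) {
  if (!is.null(seed)) return(local_seed(seed, sample_gametes(panel, l, g)))
  pops <- unique(panel_populations(panel))
  if (l > length(pops)) stop("cannot draw ", l, " populations")
  chosen <- if (l == length(pops)) pops else sample(pops, l)
  all_h <- panel_haplotypes(panel)
  rows <- unlist(lapply(chosen, function(pp) {
    cand <- which(all_h$populations == pp)
    if (length(cand) < g) stop("population ", pp, " has only ",
                               length(cand), " gametes; need ", g)
    sample(cand, g)
  }), use.names = FALSE)
  structure(list(markers = all_h$markers,
                 haplotypes = all_h$haplotypes[rows, , drop = FALSE],
                 populations = all_h$populations[rows]),
            class = "hap_set")
}

## decay distance of one gamete sample (0 when below threshold, NA when
## not reached)
decay_of_haps <- function(haps, n_gametes, max_dist_bp = 1e6,
                          threshold = 0.2) {
  pr <- pairwise_ld(haps, max_dist_bp)
  fit <- hill_weir_fit(pr, n_gametes)
  dd <- decay_distance(fit, threshold)
  if (!dd$reached) NA_real_ else dd$distance_bp
}

#' LD decay distance over a grid of sampling schemes (l populations x g
#' gametes)
#'
#' Per repeat and cell, l populations are drawn, then g gametes per
#' population uniformly without replacement; the pooled gametes give an LD
#' pair table, a Hill-Weir fit with n = g*l, and a decay distance. Cells
#' with g*l < 12 (or with a population too small for g) are skipped.
#'
#' @param panel phased [pop_panel()].
#' @param l_values,g_values grid of numbers of populations / gametes per
#'   population.
#' @param repeats random samples per cell (default 10).
#' @param max_dist_bp,threshold LD decay settings.
#' @param seed integer seed.
#' @return data.frame with one row per computed cell: `g`, `l`,
#'   `mean_decay_bp` (over repeats that reached the threshold),
#'   `n_reached`, `repeats`.
#' @export
sampling_scheme_ld <- function(panel, l_values, g_values, repeats = 10L,
                               max_dist_bp = 1e6, threshold = 0.2,
                               seed = NULL) {
  pops <- panel_populations(panel)
  min_g <- min(table(pops)) * 2L
  rows <- list()
  local_seed(seed, {
    for (g in sort(g_values)) for (l in sort(l_values)) {
      if (g * l < 12L) next
      if (g > min_g) next                       # population too small; skip
      dvals <- vapply(seq_len(repeats), function(i)
        decay_of_haps(sample_gametes(panel, l, g), g * l, max_dist_bp,
                      threshold), numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        g = g, l = l, mean_decay_bp = mean(dvals, na.rm = TRUE),
        n_reached = sum(!is.na(dvals)), repeats = repeats)
    }
  })
  do.call(rbind, rows)
}

#' Effect of sample size on LD decay distance within one population
#'
#' Per size and repeat, that many individuals are drawn without replacement
#' within the population and the decay distance computed from their
#' gametes. When the size equals the population size the draw is exhaustive
#' and the estimate deterministic.
#'
#' @param panel phased [pop_panel()].
#' @param pop population label.
#' @param sizes individual counts (output is sorted ascending).
#' @param repeats random draws per size.
#' @param max_dist_bp,threshold LD decay settings.
#' @param seed integer seed.
#' @return data.frame with `size`, `mean_decay_bp`, `var_decay_bp`,
#'   `n_reached`.
#' @export
sample_size_ld <- function(panel, pop, sizes, repeats = 10L,
                           max_dist_bp = 1e6, threshold = 0.2,
                           seed = NULL) {
  pops <- panel_populations(panel)
  cand <- which(pops == pop)
  if (max(sizes) > length(cand))
    stop("population ", pop, " has ", length(cand), " individuals")
  rows <- local_seed(seed, lapply(sort(sizes), function(sz) {
    dvals <- vapply(seq_len(repeats), function(i) {
      sub <- subset_samples(panel, sort(sample(cand, sz)))
      decay_of_haps(panel_haplotypes(sub), 2L * sz, max_dist_bp, threshold)
    }, numeric(1L))
    data.frame(size = sz, mean_decay_bp = mean(dvals, na.rm = TRUE),
               var_decay_bp = stats::var(dvals[!is.na(dvals)]),
               n_reached = sum(!is.na(dvals)))
  }))
  do.call(rbind, rows)
}

#' Interchromosomal (admixture-induced) LD for a sampling scheme
#'
#' Per repeat: `n_individuals` are drawn from `l` populations (equal
#' numbers per population), polymorphic SNPs are binned by sample MAF in
#' steps of `maf_bin_width`, `snps_per_bin_per_chrom` SNPs are drawn per
#' bin per chromosome (underfilled bins skipped), and the fraction of
#' cross-chromosome pairs with r2 > `r2_threshold` is recorded.
#'
#' @param panel phased [pop_panel()] with >= 2 chromosomes.
#' @param l number of populations sampled from.
#' @param n_individuals total sample size (must be a multiple of l).
#' @param maf_bin_width,snps_per_bin_per_chrom,r2_threshold binning and
#'   threshold settings.
#' @param repeats random samples.
#' @param seed integer seed.
#' @return data.frame with one row per repeat: `l`, `repeat_`, `fraction`,
#'   `n_pairs`.
#' @export
interchromosomal_ld <- function(panel, l, n_individuals = 24L,
                                maf_bin_width = 0.05,
                                snps_per_bin_per_chrom = 100L,
                                r2_threshold = 0.2, repeats = 10L,
                                seed = NULL) {
  if (length(unique(panel$markers$chrom)) < 2L)
    stop("need >= 2 chromosomes")
  if (n_individuals %% l != 0L)
    stop("n_individuals must be a multiple of l")
  n_per <- n_individuals %/% l
  pops_all <- panel_populations(panel)
  upops <- unique(pops_all)
  if (l > length(upops)) stop("cannot draw ", l, " populations")
  local_seed(seed, {
    rows <- lapply(seq_len(repeats), function(rep_i) {
      chosen <- if (l == length(upops)) upops else sample(upops, l)
      idx <- unlist(lapply(chosen, function(pp) {
        cand <- which(pops_all == pp)
        if (length(cand) < n_per)
          stop("population ", pp, " has fewer than ", n_per, " individuals")
        sample(cand, n_per)
      }), use.names = FALSE)
      sub <- subset_samples(panel, sort(idx))
      p <- colMeans(sub$genotypes, na.rm = TRUE) / 2
      maf <- pmin(p, 1 - p)
      poly <- !is.nan(maf) & maf > 0
      bin <- ceiling(maf / maf_bin_width)        # (0, w], (w, 2w], ...
      keep <- logical(n_markers(sub))
      for (ch in unique(sub$markers$chrom)) for (b in unique(bin[poly])) {
        snps <- which(poly & sub$markers$chrom == ch & bin == b)
        if (length(snps) >= snps_per_bin_per_chrom)
          keep[sample(snps, snps_per_bin_per_chrom)] <- TRUE
      }
      if (sum(keep) < 2L ||
          length(unique(sub$markers$chrom[keep])) < 2L)
        stop("fewer than 2 chromosomes with sampled SNPs")
      h <- panel_haplotypes(subset_markers(sub, keep))
      chs <- h$markers$chrom
      uch <- unique(chs)
      tot <- 0L; hit <- 0L
      for (i in seq_len(length(uch) - 1L)) for (j in (i + 1L):length(uch)) {
        r <- suppressWarnings(stats::cor(
          h$haplotypes[, chs == uch[i], drop = FALSE],
          h$haplotypes[, chs == uch[j], drop = FALSE],
          use = "pairwise.complete.obs"))
        r2v <- r[is.finite(r)]^2
        tot <- tot + length(r2v)
        hit <- hit + sum(r2v > r2_threshold)
      }
      data.frame(l = l, repeat_ = rep_i, fraction = hit / tot,
                 n_pairs = tot)
    })
    do.call(rbind, rows)
  })
}

#' Compare interchromosomal LD across sampling schemes
#'
#' Runs [interchromosomal_ld()] for each l and compares every l > 1 against
#' l = 1 by a two-sided Wilcoxon rank-sum test with Bonferroni correction
#' over the number of l > 1 comparisons.
#'
#' @inheritParams interchromosomal_ld
#' @param l_values numbers of populations (must include 1).
#' @return list with `fractions` (data.frame over all l and repeats) and
#'   `comparisons` (data.frame l, p_value, p_bonferroni).
#' @export
interchromosomal_ld_experiment <- function(panel, l_values,
                                           n_individuals = 24L,
                                           maf_bin_width = 0.05,
                                           snps_per_bin_per_chrom = 100L,
                                           r2_threshold = 0.2,
                                           repeats = 10L, seed = NULL) {
  stopifnot(1L %in% l_values)
  frac <- do.call(rbind, lapply(sort(l_values), function(l)
    interchromosomal_ld(panel, l, n_individuals, maf_bin_width,
                        snps_per_bin_per_chrom, r2_threshold, repeats,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, paste0("l", l)))))
  base <- frac$fraction[frac$l == 1L]
  ls <- setdiff(sort(unique(frac$l)), 1L)
  comp <- do.call(rbind, lapply(ls, function(l) {
    w <- stats::wilcox.test(frac$fraction[frac$l == l], base,
                            exact = FALSE)
    data.frame(l = l, p_value = w$p.value,
               p_bonferroni = min(1, w$p.value * length(ls)))
  }))
  list(fractions = frac, comparisons = comp)
}
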