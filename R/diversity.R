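#' Proportion of polymorphic markers
#'
#' Fraction of markers at which at least two alleles are observed among the
#' non-missing calls (a marker with any heterozygote, or with both
#' homozygote classes, is polymorphic).
#'
#' @param panel a [pop_panel()].
#' @export
proportion_polymorphic <- function(panel) {
  g <- panel$genotypes
  if (ncol(g) < 1L) stop("panel has no markers")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.nan(p) & p > 0 & p < 1
  mean(poly)
}

#' Per-marker nucleotide diversity
#'
#' For a marker with k callable gametes and alt-allele frequency p,
#' pi = k/(k-1) * 2 p (1 - p): the probability that two gametes drawn
#' without replacement differ, i.e. the mean pairwise difference over all
#' gamete pairs. Monomorphic markers contribute 0; markers with fewer than
#' 2 callable gametes are excluded from the mean.
#'
#' @param panel a [pop_panel()].
#' @return list with `per_marker` (vector, NA where excluded), `mean`, and
#'   `n_excluded`.
#' @export
nucleotide_diversity <- function(panel) {
  g <- panel$genotypes
  k <- 2 * colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / k
  pi <- ifelse(k >= 2, k / (k - 1) * 2 * p * (1 - p), NA_real_)
  excl <- sum(k < 2)
  if (all(is.na(pi))) stop("no marker with >= 2 callable gametes")
  list(per_marker = pi, mean = mean(pi, na.rm = TRUE), n_excluded = excl)
}

#' Sliding-window specification for haplotype heterozygosity
#'
#' @param width_bp window span in bp (default 100 kb).
#' @param min_snps minimum SNPs per window (default 5); windows with fewer
#'   are skipped.
#' @export
window_spec <- function(width_bp = 1e5, min_snps = 5L) {
  stopifnot(width_bp > 0, min_snps >= 2L)
  structure(list(width_bp = as.numeric(width_bp),
                 min_snps = as.integer(min_snps)),
            class = "window_spec")
}

#' Sliding-window haplotype heterozygosity
#'
#' One window is anchored at every SNP position s and spans
#' \[s, s + width_bp) on the same chromosome (steps of one SNP). Within a
#' window, the haplotype classes are the distinct allele strings over the
#' window's SNPs among the k gametes with complete calls there;
#' H = k/(k-1) * (1 - sum of squared class frequencies).
#'
#' @param haps a `hap_set` (see [panel_haplotypes()]).
#' @param spec a [window_spec()].
#' @return list with `per_window` data.frame (chrom, start, n_snps, k, H)
#'   and `mean`.
#' @export
haplotype_heterozygosity <- function(haps, spec = window_spec()) {
  mk <- haps$markers
  H <- numeric(0); chroms <- character(0); starts <- integer(0)
  nsnp <- integer(0); kk <- integer(0)
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    pos <- mk$pos[idx]
    hi <- haps$haplotypes[, idx, drop = FALSE]
    ends <- findInterval(pos + spec$width_bp - 1e-9, pos)  # last SNP in window
    for (s in seq_along(idx)) {
      cols <- s:ends[s]
      if (length(cols) < spec$min_snps) next
      sub <- hi[, cols, drop = FALSE]
      complete <- rowSums(is.na(sub)) == 0L
      k <- sum(complete)
      if (k < 2L) next
      cls <- do.call(paste0, as.data.frame(sub[complete, , drop = FALSE]))
      x <- tabulate(factor(cls)) / k
      H <- c(H, k / (k - 1) * (1 - sum(x^2)))
      chroms <- c(chroms, ch); starts <- c(starts, pos[s])
      nsnp <- c(nsnp, length(cols)); kk <- c(kk, k)
    }
  }
  if (!length(H)) stop("no window retained (min_snps too strict?)")
  list(per_window = data.frame(chrom = chroms, start = starts,
                               n_snps = nsnp, k = kk, H = H),
       mean = mean(H))
}

## Weir-Cockerham (1984) multi-locus within-population f on a dosage matrix
## (individuals x markers, one population)
wc_fis_from_geno <- function(g) {
  n <- colSums(!is.na(g))
  ok <- n >= 2
  g <- g[, ok, drop = FALSE]; n <- n[ok]
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  hbar <- colMeans(g == 1L, na.rm = TRUE)
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
  cc <- hbar / 2
  denom <- sum(b + cc)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  sum(b) / denom
}

#' Weir-Cockerham within-population inbreeding coefficient with permutation
#' test
#'
#' Multi-locus f for a single population: the ratio of summed locus-wise
#' between-individual (b) to b + within-individual (c) variance components
#' of the Weir-Cockerham (1984) estimator. Significance is assessed under
#' the Hardy-Weinberg null by re-pairing the population's 2n gametes into n
#' genotypes uniformly at random; the two-sided p-value uses +1 smoothing.
#'
#' @param panel a [pop_panel()] holding a single population (callers loop
#'   over populations).
#' @param n_perms number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `fis`, `p_value`, `n_perms`.
#' @export
fis <- function(panel, n_perms = 1000L, seed = NULL) {
  stopifnot(n_perms >= 1L)
  if (length(unique(panel_populations(panel))) != 1L)
    stop("fis expects a single-population panel")
  g <- panel$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  if (all(is.nan(p) | p == 0 | p == 1))
    stop("all loci monomorphic; f undefined")
  f_obs <- wc_fis_from_geno(g)
  n <- nrow(g)

  f_perm <- local_seed(seed, {
    ## allele matrix (2n x L): real gametes when phased; otherwise each
    ## heterozygote's alleles are assigned to the two gamete slots at
    ## random (a fixed orientation would fabricate across-locus
    ## association among the constructed gametes and distort the null)
    if (panel$phased) {
      al <- panel$haplotypes
      miss <- is.na(g)
      if (any(miss)) {
        mi <- which(miss, arr.ind = TRUE)
        al[cbind(2L * mi[, 1L] - 1L, mi[, 2L])] <- NA_integer_
        al[cbind(2L * mi[, 1L], mi[, 2L])] <- NA_integer_
      }
    } else {
      flip <- matrix(stats::runif(length(g)) < 0.5, n, ncol(g))
      a1 <- ifelse(g == 2L, 1L, ifelse(g == 1L & flip, 1L, 0L))
      a2 <- g - a1
      a1[is.na(g)] <- NA_integer_; a2[is.na(g)] <- NA_integer_
      al <- matrix(NA_integer_, 2L * n, ncol(g))
      al[seq(1L, 2L * n, 2L), ] <- a1
      al[seq(2L, 2L * n, 2L), ] <- a2
    }
    vapply(seq_len(n_perms), function(i) {
      ord <- sample.int(2L * n)
      gp <- al[ord[seq(1L, 2L * n, 2L)], , drop = FALSE] +
            al[ord[seq(2L, 2L * n, 2L)], , drop = FALSE]
      wc_fis_from_geno(gp)
    }, numeric(1L))
  })
  f_perm <- f_perm[is.finite(f_perm)]
  ge <- sum(f_perm >= f_obs); le <- sum(f_perm <= f_obs)
  p_val <- min(1, 2 * min((ge + 1) / (length(f_perm) + 1),
                          (le + 1) / (length(f_perm) + 1)))
  list(fis = f_obs, p_value = p_val, n_perms = as.integer(n_perms))
}

#' Per-population diversity summary
#'
#' PP, mean per-marker nucleotide diversity, mean window haplotype
#' heterozygosity (phased panels) and Weir-Cockerham f with permutation
#' p-value, per population.
#'
#' @param panel a [pop_panel()].
#' @param spec a [window_spec()] for H (ignored when the panel is unphased).
#' @param n_perms permutations for the f test.
#' @param seed integer seed.
#' @return data.frame with one row per population.
#' @export
diversity_summary <- function(panel, spec = window_spec(),
                              n_perms = 1000L, seed = NULL) {
  pops <- panel_populations(panel)
  res <- lapply(sort(unique(pops)), function(pp) {
    sub <- subset_samples(panel, which(pops == pp))
    pi <- nucleotide_diversity(sub)
    hm <- if (panel$phased)
      haplotype_heterozygosity(panel_haplotypes(sub), spec)$mean
    else NA_real_
    fz <- fis(sub, n_perms = n_perms,
              seed = if (is.null(seed)) NULL else derive_seed(seed, pp))
    data.frame(population = pp, n = n_individuals(sub),
               PP = proportion_polymorphic(sub), pi = pi$mean, H = hm,
               Fis = fz$fis, Fis_p = fz$p_value)
  })
  do.call(rbind, res)
}

#' Weir-Cockerham multi-population differentiation (theta / F_ST)
#'
#' Ratio-of-sums Weir-Cockerham (1984) estimator over all loci: per locus
#' the among-population (a), between-individual (b) and within-individual
#' (c) components are computed from population sizes, allele frequencies
#' and heterozygote frequencies; theta = sum(a) / sum(a + b + c).
#'
#' @param panel a [pop_panel()] with >= 2 populations.
#' @return Scalar theta estimate.
#' @export
wc_fst <- function(panel) {
  pops <- panel_populations(panel)
  upops <- unique(pops)
  r <- length(upops)
  if (r < 2L) stop("need >= 2 populations")
  g <- panel$genotypes
  L <- ncol(g)
  n_i <- matrix(0, r, L); p_i <- matrix(0, r, L); h_i <- matrix(0, r, L)
  for (k in seq_len(r)) {
    sub <- g[pops == upops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(sub))
    p_i[k, ] <- colSums(sub, na.rm = TRUE) / (2 * n_i[k, ])
    h_i[k, ] <- colSums(sub == 1L, na.rm = TRUE) / n_i[k, ]
  }
  ok <- colSums(n_i >= 1) == r & colSums(is.nan(p_i)) == 0
  n_i <- n_i[, ok, drop = FALSE]; p_i <- p_i[, ok, drop = FALSE]
  h_i <- h_i[, ok, drop = FALSE]
  nsum <- colSums(n_i)
  nbar <- nsum / r
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * sweep(p_i, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  fin <- is.finite(a) & is.finite(b) & is.finite(cc)
  sum(a[fin]) / sum(a[fin] + b[fin] + cc[fin])
}
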