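#' Persistence of linkage phase between two populations
#'
#' Marker pairs on the same chromosome, within `max_dist_bp` and
#' polymorphic in BOTH populations, are binned by physical distance in
#' half-open bins ((k-1) bin_bp, k bin_bp\]. Per bin: the Pearson
#' correlation of the two populations' signed r values, and PEP, the
#' proportion of pairs with equal sign of r (pairs with r = 0 in either
#' population are excluded from PEP; their count is reported). Both hap
#' sets must share the marker list and allele orientation (intersect the
#' panels first).
#'
#' @param hapsA,hapsB `hap_set` objects over identical markers.
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @param bin_bp bin width (default 10 kb).
#' @return A `phase_persistence`: list with `bins` data.frame (`bin_start`,
#'   `bin_end`, `corr_r`, `pep`, `n_pairs`, `n_zero_excluded`), and pooled
#'   summaries `overall_corr_r` / `overall_pep` over all pairs <= 1 Mb.
#' @export
phase_persistence <- function(hapsA, hapsB, max_dist_bp = 1e6,
                              bin_bp = 1e4) {
  if (!identical(hapsA$markers[c("chrom", "pos", "ref", "alt")],
                 hapsB$markers[c("chrom", "pos", "ref", "alt")]))
    stop("marker lists differ between the two populations")
  mk <- hapsA$markers
  rA <- numeric(0); rB <- numeric(0); dd <- numeric(0)
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    if (length(idx) < 2L) next
    pos <- mk$pos[idx]
    cA <- suppressWarnings(stats::cor(hapsA$haplotypes[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cB <- suppressWarnings(stats::cor(hapsB$haplotypes[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    dmat <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(dmat) & dmat <= max_dist_bp, arr.ind = TRUE)
    if (!nrow(sel)) next
    a <- cA[sel]; b <- cB[sel]
    ok <- is.finite(a) & is.finite(b)        # polymorphic in both
    rA <- c(rA, a[ok]); rB <- c(rB, b[ok]); dd <- c(dd, dmat[sel][ok])
  }
  if (!length(dd)) stop("no marker pairs polymorphic in both populations")
  bin <- ceiling(dd / bin_bp)
  n_bins <- ceiling(max_dist_bp / bin_bp)
  bins <- lapply(seq_len(n_bins), function(k) {
    inb <- bin == k
    n <- sum(inb)
    if (n == 0L)
      return(data.frame(bin_start = (k - 1) * bin_bp, bin_end = k * bin_bp,
                        corr_r = NA_real_, pep = NA_real_, n_pairs = 0L,
                        n_zero_excluded = 0L))
    a <- rA[inb]; b <- rB[inb]
    cr <- if (n >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0)
      stats::cor(a, b) else NA_real_
    nz <- a != 0 & b != 0
    pep <- if (any(nz)) mean(a[nz] * b[nz] > 0) else NA_real_
    data.frame(bin_start = (k - 1) * bin_bp, bin_end = k * bin_bp,
               corr_r = cr, pep = pep, n_pairs = n,
               n_zero_excluded = sum(!nz))
  })
  nz_all <- rA != 0 & rB != 0
  structure(list(bins = do.call(rbind, bins),
                 overall_corr_r = stats::cor(rA, rB),
                 overall_pep = mean(rA[nz_all] * rB[nz_all] > 0),
                 n_pairs = length(dd)),
            class = "phase_persistence")
}

#' @export
print.phase_persistence <- function(x, ...) {
  cat(sprintf(
    "phase persistence: %d pairs; overall corr(r) = %.3f, PEP = %.3f\n",
    x$n_pairs, x$overall_corr_r, x$overall_pep))
  invisible(x)
}

#' Split-half linkage-phase persistence within one population
#'
#' Per repeat, the population's individuals are split uniformly into two
#' halves (sizes differing by at most 1) and [phase_persistence()] is
#' computed between the halves' gametes; per-bin statistics are averaged
#' over repeats.
#'
#' @param panel phased [pop_panel()].
#' @param pop population label (>= 8 individuals).
#' @param repeats number of random splits (default 100).
#' @param max_dist_bp,bin_bp see [phase_persistence()].
#' @param seed integer seed.
#' @return list with `per_bin` data.frame (mean `corr_r` and `pep` per bin
#'   over repeats, with mean pair counts) and `overall` data.frame of the
#'   pooled statistics per repeat.
#' @export
split_half_persistence <- function(panel, pop, repeats = 100L,
                                   max_dist_bp = 1e6, bin_bp = 1e4,
                                   seed = NULL) {
  pops <- panel_populations(panel)
  cand <- which(pops == pop)
  if (length(cand) < 8L)
    stop("population ", pop, " has fewer than 8 individuals")
  n_half <- length(cand) %/% 2L
  res <- local_seed(seed, lapply(seq_len(repeats), function(i) {
    ord <- sample(cand)
    h1 <- panel_haplotypes(subset_samples(panel, sort(ord[seq_len(n_half)])))
    h2 <- panel_haplotypes(subset_samples(panel, sort(ord[(n_half + 1L):
                                                          length(ord)])))
    phase_persistence(h1, h2, max_dist_bp, bin_bp)
  }))
  bins0 <- res[[1L]]$bins[, c("bin_start", "bin_end")]
  corr_mat <- vapply(res, function(x) x$bins$corr_r,
                     numeric(nrow(bins0)))
  pep_mat <- vapply(res, function(x) x$bins$pep, numeric(nrow(bins0)))
  np_mat <- vapply(res, function(x) as.numeric(x$bins$n_pairs),
                   numeric(nrow(bins0)))
  per_bin <- cbind(bins0,
                   corr_r = rowMeans(corr_mat, na.rm = TRUE),
                   pep = rowMeans(pep_mat, na.rm = TRUE),
                   mean_n_pairs = rowMeans(np_mat))
  overall <- data.frame(
    repeat_ = seq_len(repeats),
    corr_r = vapply(res, `[[`, numeric(1L), "overall_corr_r"),
    pep = vapply(res, `[[`, numeric(1L), "overall_pep"))
  list(per_bin = per_bin, overall = overall)
}
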