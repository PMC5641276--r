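#' One-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style decomposition on squared distances:
#' SS_total = (1/N) sum_\{i<j\} d2_ij, SS_within the analogous per-population
#' sums, sigma2 components from the mean squares with
#' n0 = (N - sum N_p^2 / N) / (P - 1), Phi_ST = sigma2_among / total. The
#' permutation p-value shuffles individuals among populations (sizes fixed)
#' and counts permutations with Phi >= observed, with +1 smoothing.
#' A negative among component is clamped to 0 before percentages.
#'
#' @param dist symmetric distance matrix (class `dist` or square matrix)
#'   over individuals; distances are squared internally (modified Rogers'
#'   distances from [mrd()] are the package-wide convention).
#' @param partition character/factor of population labels, one per
#'   individual, in matrix order.
#' @param n_perms permutations (0 skips the test).
#' @param seed integer seed.
#' @return An `amova_result` list: sums of squares, df, variance components,
#'   percentages, `phi_st`, `p_value`.
#' @export
amova <- function(dist, partition, n_perms = 1000L, seed = NULL) {
  d <- as.matrix(dist)
  N <- nrow(d)
  partition <- as.character(partition)
  stopifnot(length(partition) == N, isSymmetric(unname(d)))
  sizes <- table(partition)
  P <- length(sizes)
  if (P < 2L) stop("need >= 2 populations")
  if (any(sizes < 2L))
    stop("population(s) of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- d^2

  ss_parts <- function(labels) {
    ssw <- 0
    for (pp in unique(labels)) {
      idx <- which(labels == pp)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  ss_total <- sum(d2) / (2 * N)
  ss_within <- ss_parts(partition)
  ss_among <- ss_total - ss_within
  df_among <- P - 1L
  df_within <- N - P
  sigma_w <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- (ss_among / df_among - sigma_w) / n0
  phi <- sigma_a / (sigma_a + sigma_w)

  sigma_a_cl <- max(sigma_a, 0)
  tot <- sigma_a_cl + sigma_w
  pct_among <- 100 * sigma_a_cl / tot
  pct_within <- 100 * sigma_w / tot

  p_value <- NA_real_
  if (n_perms > 0L) {
    phi_perm <- local_seed(seed, vapply(seq_len(n_perms), function(i) {
      lab <- sample(partition)
      ssw <- ss_parts(lab)
      ssa <- ss_total - ssw
      sw <- ssw / df_within
      sa <- (ssa / df_among - sw) / n0
      sa / (sa + sw)
    }, numeric(1L)))
    p_value <- (sum(phi_perm >= phi) + 1) / (n_perms + 1)
  }

  structure(list(ss_among = ss_among, ss_within = ss_within,
                 ss_total = ss_total,
                 df_among = df_among, df_within = df_within,
                 sigma2_among = sigma_a_cl, sigma2_within = sigma_w,
                 sigma2_among_raw = sigma_a,
                 pct_among = pct_among, pct_within = pct_within,
                 phi_st = phi, p_value = p_value,
                 n_perms = as.integer(n_perms)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: among %.1f%% / within %.1f%%; Phi_ST = %.4f",
              x$pct_among, x$pct_within, x$phi_st))
  if (!is.na(x$p_value)) cat(sprintf(" (p = %.4g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Proportion of total molecular variance captured by groups of l populations
#'
#' Per repeat, the panel's populations are shuffled and chunked into
#' ceiling(P/l) groups (the last group holds the remainder when P is not a
#' multiple of l). For each group, the captured proportion is the
#' mean-squared-deviation ratio
#' (SS_total(group)/df_total(group)) / (SS_total(all)/df_total(all)), where
#' SS_total is the AMOVA total sum of squares over the stated individuals
#' and df_total = N - 1. All group values are pooled into the distribution
#' for that l.
#'
#' @param dist distance matrix over the panel's individuals (see [amova()]).
#' @param partition population labels per individual.
#' @param l_values group sizes to evaluate (within \[1, P\]).
#' @param n_repeats random repeats per l.
#' @param seed integer seed.
#' @return A `capture_curve`: list with `l_values`, `distributions` (list of
#'   pooled proportions per l), `summary` data.frame (l, mean, quartiles).
#' @export
variance_captured <- function(dist, partition, l_values, n_repeats = 100L,
                              seed = NULL) {
  d2 <- as.matrix(dist)^2
  partition <- as.character(partition)
  N <- nrow(d2)
  pops <- unique(partition)
  P <- length(pops)
  stopifnot(all(l_values >= 1L), all(l_values <= P))
  idx_of <- split(seq_len(N), partition)
  msd <- function(idx) {
    n <- length(idx)
    (sum(d2[idx, idx]) / (2 * n)) / (n - 1)
  }
  msd_all <- msd(seq_len(N))

  distributions <- local_seed(seed, lapply(l_values, function(l) {
    unlist(lapply(seq_len(n_repeats), function(rep) {
      ord <- sample(pops)
      groups <- split(ord, ceiling(seq_along(ord) / l))
      vapply(groups, function(gr) {
        idx <- unlist(idx_of[gr], use.names = FALSE)
        msd(idx) / msd_all
      }, numeric(1L))
    }), use.names = FALSE)
  }))
  names(distributions) <- l_values
  summ <- data.frame(
    l = l_values,
    mean = vapply(distributions, mean, numeric(1L)),
    q25 = vapply(distributions, stats::quantile, numeric(1L), probs = 0.25),
    median = vapply(distributions, stats::median, numeric(1L)),
    q75 = vapply(distributions, stats::quantile, numeric(1L), probs = 0.75))
  structure(list(l_values = l_values, distributions = distributions,
                 n_repeats = as.integer(n_repeats), summary = summ),
            class = "capture_curve")
}

#' @export
print.capture_curve <- function(x, ...) {
  cat("variance captured by groups of l populations:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
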