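#' Expected folded site-frequency spectrum under neutrality
#'
#' Under the standard neutral coalescent with infinite-sites mutation, the
#' expected proportion of SNPs with derived-allele count i in a sample of g
#' gametes is proportional to 1/i (normalized by the harmonic number
#' H(g-1)). Folding sums classes i and g-i for i < g/2 and keeps the g/2
#' class as is.
#'
#' @param g number of gametes sampled per SNP (>= 2).
#' @return A `folded_sfs` object: list with `g`, `proportions` (classes
#'   i = 1 .. floor(g/2)), `monomorphic_mass` (0 here), `n_reps`, `n_snps`.
#' @export
expected_neutral_sfs <- function(g) {
  g <- as.integer(g)
  if (g < 2L) stop("g must be >= 2")
  i <- seq_len(g - 1L)
  f <- (1 / i) / sum(1 / i)
  folded <- fold_spectrum(f, g)
  structure(list(g = g, proportions = folded, monomorphic_mass = 0,
                 n_reps = NA_integer_, n_snps = NA_integer_),
            class = "folded_sfs")
}

## fold an unfolded spectrum f[1..g-1] into classes 1..floor(g/2)
fold_spectrum <- function(f, g) {
  half <- g %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (2L * i == g) f[i] else f[i] + f[g - i]
  }
  names(out) <- seq_len(half)
  out
}

#' Folded SFS of a panel via repeated gamete subsampling
#'
#' Per SNP and repeat, g = floor(2 n c) gametes are sampled uniformly
#' without replacement among the gametes with non-missing calls (a
#' SNP-repeat with fewer than g callable gametes is skipped) and the minor
#' allele is counted within the drawn sample. The alt-allele count of such a
#' draw is hypergeometric, which is how the draw is realized. With
#' `method = "mass"` every draw contributes mass 1/(SNPs x repeats) to its
#' minor-count class; with `method = "round"` each SNP's mean minor count
#' over repeats is rounded to the nearest class and the SNP contributes
#' mass 1 there.
#'
#' @param panel a [pop_panel()].
#' @param call_rate_c minimum call rate c defining g = floor(2 n c).
#' @param n_reps number of random samples per SNP.
#' @param seed integer seed.
#' @param method `"mass"` (default) or `"round"`; see above.
#' @return A `folded_sfs` (monomorphic-in-sample draws are reported as
#'   `monomorphic_mass`; proportions plus that mass sum to 1).
#' @export
folded_sfs <- function(panel, call_rate_c = 0.9, n_reps = 1000L, seed = NULL,
                       method = c("mass", "round")) {
  method <- match.arg(method)
  stopifnot(call_rate_c > 0, call_rate_c <= 1, n_reps >= 1L)
  n <- n_individuals(panel)
  g <- floor(2 * n * call_rate_c)
  if (g < 2L) stop("g = floor(2 n c) must be >= 2")
  geno <- panel$genotypes
  k <- 2L * colSums(!is.na(geno))        # callable gametes per SNP
  a <- colSums(geno, na.rm = TRUE)       # alt-allele count among callable
  usable <- k >= g
  if (!any(usable)) stop("no SNP has ", g, " callable gametes")
  k <- k[usable]; a <- a[usable]
  m <- length(k)
  half <- g %/% 2L

  counts <- local_seed(seed, {
    ## alt count of a without-replacement draw of g from k gametes
    x <- stats::rhyper(m * n_reps, m = rep(a, each = n_reps),
                       n = rep(k - a, each = n_reps), k = g)
    matrix(x, nrow = n_reps)             # repeats x SNPs
  })
  minor <- pmin(counts, g - counts)

  if (method == "mass") {
    tab <- tabulate(minor + 1L, nbins = half + 1L) / (m * n_reps)
    mono <- tab[1L]
    props <- tab[-1L]
  } else {
    cls <- round(colMeans(minor))
    tab <- tabulate(cls + 1L, nbins = half + 1L) / m
    mono <- tab[1L]
    props <- tab[-1L]
  }
  names(props) <- seq_len(half)
  structure(list(g = g, proportions = props, monomorphic_mass = mono,
                 n_reps = as.integer(n_reps), n_snps = m),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("folded SFS: g =", x$g, "(", length(x$proportions), "classes )\n")
  print(round(x$proportions, 4))
  if (x$monomorphic_mass > 0)
    cat("monomorphic-in-sample mass:", round(x$monomorphic_mass, 4), "\n")
  invisible(x)
}

#' Total-variation distance between two folded spectra
#'
#' Spectra are compared on the polymorphic classes after renormalization
#' (the observed spectrum may carry monomorphic-in-sample mass).
#'
#' @param a,b `folded_sfs` objects with equal g.
#' @export
sfs_tv_distance <- function(a, b) {
  stopifnot(inherits(a, "folded_sfs"), inherits(b, "folded_sfs"),
            a$g == b$g)
  pa <- a$proportions / sum(a$proportions)
  pb <- b$proportions / sum(b$proportions)
  sum(abs(pa - pb)) / 2
}

#' Mean minor-allele frequency of a panel
#'
#' Computed from per-SNP allele frequencies over non-missing calls;
#' monomorphic SNPs contribute 0.
#'
#' @param panel a [pop_panel()].
#' @export
mean_maf <- function(panel) {
  p <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  p <- p[!is.nan(p)]
  mean(pmin(p, 1 - p))
}
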