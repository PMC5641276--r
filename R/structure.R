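#' Modified Rogers' distance between individuals
#'
#' For individuals x, y over the m markers where both have non-missing
#' calls: MRD = sqrt( (1/(2m)) sum_markers sum_alleles (p_xa - p_ya)^2 )
#' with within-individual allele frequencies in \{0, 1/2, 1\}. For
#' bi-allelic markers this reduces to sqrt( mean( ((d_x - d_y)/2)^2 ) )
#' over the shared markers; MRD is in \[0, 1\] and is a metric on genotype
#' vectors.
#'
#' @param panel a [pop_panel()] with >= 2 individuals.
#' @return Symmetric matrix of distances with sample IDs as dimnames.
#' @export
mrd <- function(panel) {
  g <- panel$genotypes
  if (nrow(g) < 2L) stop("need >= 2 individuals")
  X <- g / 2
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Mn <- M * 1
  E <- (X0^2) %*% t(Mn)          # E_ij = sum_k x_ik^2 [j callable]
  G2 <- X0 %*% t(X0)
  S <- E + t(E) - 2 * G2         # sum over shared markers of (x-y)^2
  mshare <- Mn %*% t(Mn)
  if (any(mshare[upper.tri(mshare)] == 0)) {
    w <- which(mshare == 0 & upper.tri(mshare), arr.ind = TRUE)[1L, ]
    stop("no shared markers between ", rownames(g)[w[1L]], " and ",
         rownames(g)[w[2L]])
  }
  D <- sqrt(pmax(S, 0) / mshare)
  diag(D) <- 0
  dimnames(D) <- list(rownames(g), rownames(g))
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classical Q-matrix agglomeration with deterministic tie-breaking (ties
#' resolved toward the lowest node-creation index) and negative branch
#' lengths clamped to 0 with the deficit transferred to the sister branch,
#' preserving the joined pair's path length.
#'
#' @param dist symmetric distance matrix with labels.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dist) {
  D <- as.matrix(dist)
  if (!all(is.finite(D))) stop("non-finite distances")
  labs <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 labels")
  node <- labs                      # newick fragment per active node
  active <- seq_len(n)
  born <- seq_len(n)                # creation order for tie-breaking
  nk <- function(x, len) sprintf("%s:%.10g", x, len)

  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    best <- NULL; bestQ <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * Dm[i, j] - R[i] - R[j]
      if (q < bestQ - 1e-12) {
        bestQ <- q; best <- c(i, j)
      } else if (q <= bestQ + 1e-12) {   # tie: lowest creation index wins
        bi <- born[active[i]]; bj <- born[active[j]]
        ci <- born[active[best[1L]]]; cj <- born[active[best[2L]]]
        if (bi < ci || (bi == ci && bj < cj)) best <- c(i, j)
      }
    }
    i <- best[1L]; j <- best[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    newlab <- sprintf("(%s,%s)", nk(node[ai], li), nk(node[aj], lj))
    ## distances of the new node u to remaining nodes
    rest <- active[-c(i, j)]
    du <- (D[ai, rest] + D[aj, rest] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, rest] <- du; D[rest, u] <- du
    node <- c(node, newlab)
    born <- c(born, max(born) + 1L)
    active <- c(rest, u)
  }
  a <- active[1L]; b <- active[2L]; cc <- active[3L]
  la <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
  lb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
  lc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
  newick <- sprintf("(%s,%s,%s);", nk(node[a], max(la, 0)),
                    nk(node[b], max(lb, 0)), nk(node[cc], max(lc, 0)))
  ape::read.tree(text = newick)
}

#' Principal coordinate analysis (Gower)
#'
#' Double-centering of -1/2 d^2, eigendecomposition, coordinates scaled by
#' the square roots of the nonnegative eigenvalues. Axes of negative
#' eigenvalues are omitted but the eigenvalues are reported. Axis signs are
#' fixed so the largest-magnitude loading on each axis is positive.
#'
#' @param dist symmetric distance matrix with labels.
#' @param k number of axes to return (<= N - 1).
#' @return A `coordinates` object: list with `labels`, `axes`
#'   (individuals x k'), `eigenvalues` (all), `negative_eigenvalues`.
#' @export
pcoa <- function(dist, k = 3L) {
  D <- as.matrix(dist)
  N <- nrow(D)
  stopifnot(k >= 1L, k <= N - 1L)
  labs <- rownames(D) %||% paste0("i", seq_len(N))
  B <- -0.5 * D^2                       # Gower double centering: J A J
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  kk <- min(k, length(pos))
  axes <- eg$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(kk)]]), kk)
  for (a in seq_len(ncol(axes))) {
    mx <- which.max(abs(axes[, a]))
    if (axes[mx, a] < 0) axes[, a] <- -axes[, a]
  }
  rownames(axes) <- labs
  structure(list(labels = labs, axes = axes,
                 eigenvalues = ev,
                 negative_eigenvalues = ev[ev < -tol]),
            class = "coordinates")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles; the p-value is
#' one-sided (>= observed) from simultaneous row/column permutations of the
#' second matrix, with +1 smoothing.
#'
#' @param d1,d2 distance matrices over the same labels.
#' @param n_perms permutations.
#' @param seed integer seed.
#' @return list with `r`, `p_value`, `n_perms`.
#' @export
mantel_test <- function(d1, d2, n_perms = 1000L, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  stopifnot(identical(dim(m1), dim(m2)))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)))
    m2 <- m2[rownames(m1), rownames(m1)]
  v1 <- upper_tri_vals(m1)
  if (stats::sd(v1) == 0 || stats::sd(upper_tri_vals(m2)) == 0)
    stop("zero-variance distance triangle")
  r_obs <- stats::cor(v1, upper_tri_vals(m2))
  r_perm <- local_seed(seed, vapply(seq_len(n_perms), function(i) {
    ord <- sample.int(nrow(m2))
    stats::cor(v1, upper_tri_vals(m2[ord, ord]))
  }, numeric(1L)))
  list(r = r_obs,
       p_value = (sum(r_perm >= r_obs) + 1) / (n_perms + 1),
       n_perms = as.integer(n_perms))
}

#' Procrustes comparison of two coordinate sets
#'
#' Optimal translation, scaling and rotation (reflections allowed) of the
#' second configuration onto the first, minimizing the residual sum of
#' squares ss of the standard (symmetric) Procrustes statistic
#' ss = 1 - (sum of singular values of X'Y)^2 / (tr X'X tr Y'Y).
#' Returns the correlation-like statistic sqrt(1 - ss).
#'
#' @param c1,c2 `coordinates` objects (see [pcoa()]) over the same labels.
#' @param k number of leading axes compared.
#' @return list with `statistic` and `ss`.
#' @export
procrustes_fit <- function(c1, c2, k = 3L) {
  stopifnot(k >= 1L, ncol(c1$axes) >= k, ncol(c2$axes) >= k)
  X <- c1$axes[, seq_len(k), drop = FALSE]
  Y <- c2$axes[c1$labels, seq_len(k), drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  tx <- sum(X^2); ty <- sum(Y^2)
  if (tx <= 0 || ty <= 0) stop("degenerate (zero-spread) configuration")
  sv <- svd(crossprod(X, Y))$d
  ss <- 1 - sum(sv)^2 / (tx * ty)
  list(statistic = sqrt(max(0, 1 - ss)), ss = ss)
}

#' Sliding-window LD pruning
#'
#' Within each window of `window_snps` SNPs (advanced by `step_snps`), pairs
#' of surviving markers are scanned greedily in position order; when
#' r^2 > `r2_threshold` the member with the lower minor-allele frequency is
#' removed (tie: the later position). A marker removed in one window stays
#' removed.
#'
#' @param haps a `hap_set` with sorted markers.
#' @param window_snps,step_snps,r2_threshold pruning parameters (defaults:
#'   50-SNP windows, steps of 5 SNPs, r^2 threshold 0.8).
#' @return The pruned `hap_set`, with attribute `removed` (marker ids).
#' @export
ld_prune <- function(haps, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.8) {
  mk <- haps$markers
  keep <- rep(TRUE, nrow(mk))
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    h <- haps$haplotypes[, idx, drop = FALSE]
    nn <- length(idx)
    p <- colMeans(h, na.rm = TRUE)
    maf <- pmin(p, 1 - p)
    r2 <- suppressWarnings(
      stats::cor(h, use = "pairwise.complete.obs"))^2
    alive <- rep(TRUE, nn)
    starts <- seq(1L, max(1L, nn - 1L), by = step_snps)
    for (s in starts) {
      w <- s:min(s + window_snps - 1L, nn)
      for (i in w) {
        if (!alive[i]) next
        for (j in w[w > i]) {
          if (!alive[j]) next
          v <- r2[i, j]
          if (!is.na(v) && v > r2_threshold) {
            drop <- if (maf[i] < maf[j]) i
                    else if (maf[j] < maf[i]) j
                    else j                      # tie: later position
            alive[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
    keep[idx] <- alive
  }
  out <- structure(list(markers = mk[keep, , drop = FALSE],
                        haplotypes = haps$haplotypes[, keep, drop = FALSE],
                        populations = haps$populations),
                   class = "hap_set")
  attr(out, "removed") <- mk$id[!keep]
  out
}
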