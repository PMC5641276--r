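test_that("modified Rogers' distance hits its closed-form anchors", {
  ## identical genotypes
  g <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 2, 3, byrow = TRUE)
  expect_equal(mrd(toy_panel(g))[1, 2], 0)
  ## opposite homozygotes at every marker
  g2 <- rbind(rep(0L, 4), rep(2L, 4))
  expect_equal(mrd(toy_panel(g2))[1, 2], 1)
  ## het vs homozygote at a single shared marker: sqrt(0.5/2)
  g3 <- rbind(1L, 2L)
  expect_equal(mrd(toy_panel(g3))[1, 2], 0.5)
  ## missing cells restrict to shared markers
  g4 <- rbind(c(0L, NA, 2L), c(0L, 1L, 0L))
  expect_equal(mrd(toy_panel(g4))[1, 2], sqrt(1 / 2))
  g5 <- rbind(c(NA, NA), c(0L, 1L))
  expect_error(mrd(toy_panel(g5)), "no shared markers")
})

test_that("mrd agrees with a per-pair loop oracle and obeys the triangle
           inequality", {
  set.seed(13)
  g <- matrix(sample(c(0:2, NA), 8 * 20, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 8, 20)
  D <- mrd(toy_panel(g))
  for (i in 1:7) for (j in (i + 1):8) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    oracle <- sqrt(mean(((g[i, ok] - g[j, ok]) / 2)^2))
    expect_equal(D[i, j], oracle)
  }
  for (t in 1:50) {
    ijk <- sample(8, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("neighbor joining solves three taxa exactly and recovers additive
           trees", {
  d <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d["x", "y"] <- d["y", "x"] <- 5
  d["x", "z"] <- d["z", "x"] <- 9
  d["y", "z"] <- d["z", "y"] <- 10
  tr <- neighbor_joining(d)
  ## three-point solution: lx = 2, ly = 3, lz = 7
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("x", "y", "z")]), c(2, 3, 7))

  ## random additive tree: topology recovered exactly (RF distance 0)
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (rep in 1:5) {
    true <- ape::rtree(8, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.5, 2)
    dd <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(dd)
    expect_equal(phangorn::RF.dist(est, true), 0)
    ## and the classical reference implementation agrees on topology
    expect_equal(phangorn::RF.dist(est, ape::nj(as.dist(dd))), 0)
  }
})

test_that("neighbor joining is deterministic under complete ties", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  t1 <- ape::write.tree(neighbor_joining(d))
  t2 <- ape::write.tree(neighbor_joining(d))
  expect_identical(t1, t2)
})

test_that("negative branch lengths are clamped with length transferred", {
  ## distances violating the four-point condition force a negative branch
  d <- matrix(c(0, 2, 2, 2.9,
                2, 0, 2.9, 2,
                2, 2.9, 0, 2,
                2.9, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("principal coordinates embed Euclidean configurations exactly", {
  ## points on a line: first axis reproduces spacing
  x <- c(0, 1, 3, 6, 10)
  d <- as.matrix(dist(x))
  pc <- pcoa(d, k = 2)
  expect_equal(dim(pc$axes)[2], 1L)   # only one positive eigenvalue
  expect_equal(as.numeric(dist(pc$axes[, 1])), as.numeric(dist(x)))

  ## 3-D points: k = 3 embedding reproduces all pairwise distances
  set.seed(21)
  pts <- matrix(rnorm(30), 10)
  d3 <- as.matrix(dist(pts))
  pc3 <- pcoa(d3, k = 3)
  expect_lt(max(abs(as.matrix(dist(pc3$axes)) - d3)), 1e-9)
  expect_true(all(diff(pc3$eigenvalues) <= 1e-9))

  ## duplicated individuals land on identical coordinates
  dd <- as.matrix(dist(rbind(pts, pts[1, ])))
  pcd <- pcoa(dd, k = 3)
  expect_lt(max(abs(pcd$axes[1, ] - pcd$axes[11, ])), 1e-9)
})

test_that("pcoa eigenvalues tie out against the AMOVA total sum of squares", {
  p <- study_panel()$panel
  sub <- subset_samples(p, 1:48)
  d <- mrd(sub)
  pc <- pcoa(d, k = 3)
  ss_tot <- amova(d, panel_populations(sub), n_perms = 0)$ss_total
  expect_equal(sum(pc$eigenvalues[pc$eigenvalues > 0]), ss_tot,
               tolerance = 1e-8)
})

test_that("nearest neighbors are overwhelmingly same-population", {
  p <- study_panel()$panel
  D <- mrd(p)
  diag(D) <- Inf
  pops <- panel_populations(p)
  nn <- apply(D, 1L, which.min)
  expect_gte(mean(pops[nn] == pops), 0.95)
})

test_that("mantel statistic and null are well behaved", {
  set.seed(41)
  pts <- matrix(rnorm(30), 15)
  d1 <- as.matrix(dist(pts))
  expect_equal(mantel_test(d1, d1, n_perms = 19, seed = 1L)$r, 1)
  ## affine invariance
  expect_equal(mantel_test(d1, 3 * d1 + 2, n_perms = 19, seed = 1L)$r, 1)
  expect_error(mantel_test(d1, matrix(1, 15, 15) - diag(15)),
               "zero-variance")
  ## independent matrices: r near 0, p not extreme
  d2 <- as.matrix(dist(matrix(rnorm(30), 15)))
  mt <- mantel_test(d1, d2, n_perms = 99, seed = 2L)
  expect_lt(abs(mt$r), 0.5)
  expect_identical(mt$p_value,
                   mantel_test(d1, d2, n_perms = 99, seed = 2L)$p_value)
})

test_that("mantel agrees with the reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(43)
  d1 <- as.matrix(dist(matrix(rnorm(36), 12)))
  d2 <- as.matrix(dist(matrix(rnorm(36), 12)))
  ours <- mantel_test(d1, d2, n_perms = 199, seed = 3L)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 199)
  expect_equal(ours$r, unname(ref$statistic))
})

test_that("procrustes statistic is 1 under similarity transforms", {
  set.seed(51)
  X <- matrix(rnorm(24), 8)
  cx <- structure(list(labels = paste0("i", 1:8), axes = X,
                       eigenvalues = rep(1, 3)), class = "coordinates")
  rownames(cx$axes) <- cx$labels
  th <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mk <- function(Y) {
    rownames(Y) <- cx$labels
    structure(list(labels = cx$labels, axes = Y,
                   eigenvalues = rep(1, 3)), class = "coordinates")
  }
  ## rotation + scale + shift
  expect_equal(procrustes_fit(cx, mk(2.5 * X %*% R + 7), 3)$statistic, 1)
  ## reflection is allowed
  refl <- diag(c(-1, 1, 1))
  expect_equal(procrustes_fit(cx, mk(X %*% refl), 3)$statistic, 1)
  ## degradation is monotone in noise
  stats <- vapply(c(0.05, 0.3, 1), function(s) {
    set.seed(7)
    procrustes_fit(cx, mk(X + matrix(rnorm(24, sd = s), 8)), 3)$statistic
  }, numeric(1))
  expect_true(all(diff(stats) < 0))
  expect_error(procrustes_fit(cx, mk(matrix(0, 8, 3)), 3), "degenerate")
})

test_that("procrustes statistic matches the reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(53)
  X <- matrix(rnorm(30), 10); Y <- X + matrix(rnorm(30, sd = 0.4), 10)
  rn <- paste0("i", 1:10); rownames(X) <- rownames(Y) <- rn
  cx <- structure(list(labels = rn, axes = X, eigenvalues = rep(1, 3)),
                  class = "coordinates")
  cy <- structure(list(labels = rn, axes = Y, eigenvalues = rep(1, 3)),
                  class = "coordinates")
  ours <- procrustes_fit(cx, cy, 3)
  ref <- vegan::protest(X, Y, permutations = 9)
  expect_equal(ours$statistic, sqrt(1 - ref$ss), tolerance = 1e-10)
})

test_that("LD pruning removes duplicates and follows the greedy trace", {
  set.seed(61)
  base <- matrix(rbinom(40 * 10, 1, 0.5), 40, 10)
  ## duplicate column: exactly one of the pair survives
  h <- cbind(base[, 1], base)
  hs <- toy_haps(h)
  pruned <- ld_prune(hs, window_snps = 50, step_snps = 5,
                     r2_threshold = 0.8)
  expect_equal(ncol(pruned$haplotypes), ncol(h) - 1L)
  expect_length(attr(pruned, "removed"), 1L)

  ## independent markers are untouched
  set.seed(62)
  ind <- matrix(rbinom(200 * 8, 1, 0.5), 200, 8)
  keep <- ld_prune(toy_haps(ind), r2_threshold = 0.999)
  expect_equal(ncol(keep$haplotypes), 8L)

  ## 60-SNP toy with two engineered high-LD pairs: the lower-MAF member of
  ## each pair goes (ties resolved toward the later position)
  set.seed(63)
  m <- matrix(rbinom(60 * 56, 1, 0.5), 60)
  a <- rbinom(60, 1, 0.5)
  b <- a; b[1] <- 1 - b[1]              # near-duplicate, maf differs
  cc <- rbinom(60, 1, 0.3)
  h60 <- cbind(m[, 1:10], a, b, m[, 11:40], cc, cc, m[, 41:56])
  colnames(h60) <- NULL
  hs60 <- toy_haps(h60)
  pr60 <- ld_prune(hs60, r2_threshold = 0.8)
  removed <- attr(pr60, "removed")
  expect_length(removed, 2L)
  maf_a <- min(mean(a), 1 - mean(a)); maf_b <- min(mean(b), 1 - mean(b))
  want_first <- if (maf_a < maf_b) 11L else 12L   # a at column 11, b at 12
  expect_setequal(match(removed, hs60$markers$id),
                  c(want_first, 44L))   # duplicated cc pair: later one goes
})
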