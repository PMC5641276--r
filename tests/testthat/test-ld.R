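test_that("pairwise r reproduces haplotype-count anchors", {
  ## perfect coupling AB,AB,ab,ab
  h <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  pr <- pairwise_ld(toy_haps(h))
  expect_equal(pr$r, 1)
  expect_equal(pr$r2, 1)
  ## the four gamete classes equally: independence
  h2 <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(pairwise_ld(toy_haps(h2))$r, 0)
  ## counts AB=3, Ab=1, aB=1, ab=3: D = 1/8, r2 = 0.25
  h3 <- rbind(matrix(1, 3, 2), c(1, 0), c(0, 1), matrix(0, 3, 2))
  pr3 <- pairwise_ld(toy_haps(h3))
  expect_equal(pr3$r, 0.5)
  expect_equal(pr3$r2, 0.25)
})

test_that("r matches brute-force haplotype counting on random gamete sets", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(8:20, 1)
    h <- matrix(rbinom(2 * n, 1, runif(1, 0.2, 0.8)), n, 2)
    if (sample(c(TRUE, FALSE), 1)) h[sample(n, 1), sample(2, 1)] <- NA
    pr <- pairwise_ld(toy_haps(h))
    oracle <- r_bruteforce(h[, 1], h[, 2])
    if (!is.finite(oracle)) {
      expect_equal(nrow(pr), 0L)
    } else {
      expect_lt(abs(pr$r - oracle), 1e-12)
      expect_lt(abs(pr$r2 - oracle^2), 1e-12)
    }
  }
})

test_that("allele swaps flip the sign of r but never r2", {
  set.seed(73)
  h <- matrix(rbinom(40, 1, 0.5), 20, 2)
  r0 <- pairwise_ld(toy_haps(h))$r
  h1 <- h; h1[, 1] <- 1 - h1[, 1]
  expect_equal(pairwise_ld(toy_haps(h1))$r, -r0)
  h2 <- 1 - h
  expect_equal(pairwise_ld(toy_haps(h2))$r, r0)
})

test_that("pair tables respect the distance cap and chromosome boundaries", {
  set.seed(74)
  h <- matrix(rbinom(20 * 6, 1, 0.5), 20, 6)
  hs <- toy_haps(h, pos = c(100L, 200L, 1500L, 100L, 250L, 5000L),
                 chrom = rep(c("chr01", "chr02"), each = 3))
  hs$markers$id <- sprintf("%s_%d", hs$markers$chrom, hs$markers$pos)
  pr <- pairwise_ld(hs, max_dist_bp = 1000)
  ## only within-chromosome pairs within 1 kb
  expect_setequal(paste(pr$id_i, pr$id_j),
                  c("chr01_100 chr01_200", "chr02_100 chr02_250"))
  expect_equal(sort(pr$dist_bp), c(100, 150))
})

test_that("the expected r2 curve has its closed-form anchor and asymptote", {
  for (n in c(4, 24, 48, 70)) {
    expect_equal(hill_weir_r2(0, n), (10 / 22) * (1 + 36 / (22 * n)))
    expect_equal(hill_weir_r2(1e9, n), 1 / n, tolerance = 1e-6)
  }
  ## monotone decreasing in C
  C <- seq(0, 100, by = 0.5)
  expect_true(all(diff(hill_weir_r2(C, 48)) < 0))
})

test_that("fitting noise-free curves recovers the generating parameter", {
  d <- seq(500, 1e6, length.out = 400)
  for (rho in c(1e-5, 1e-4)) for (n in c(24, 48)) {
    tab <- data.frame(dist_bp = d, r2 = hill_weir_r2(rho * d, n))
    fit <- hill_weir_fit(tab, n)
    expect_lt(abs(fit$rho_per_bp - rho) / rho, 1e-6)
  }
})

test_that("degenerate pair tables are rejected", {
  d <- rep(1000, 100)
  tab <- data.frame(dist_bp = d, r2 = runif(100))
  expect_error(hill_weir_fit(tab, 48), "single distance")
  small <- data.frame(dist_bp = 1:10, r2 = runif(10))
  expect_error(hill_weir_fit(small, 48), ">= 50")
})

test_that("decay distances respect thresholds, asymptotes and scaling", {
  fit <- structure(list(rho_per_bp = 1e-4, n_gametes = 48L),
                   class = "decay_fit")
  ## curve at origin below threshold: distance 0, flagged
  lo <- decay_distance(fit, threshold = 0.5)
  expect_equal(lo$distance_bp, 0)
  expect_true(lo$below_threshold)
  ## n = 4: asymptote 1/4 > 0.2 is never crossed
  f4 <- structure(list(rho_per_bp = 1e-4, n_gametes = 4L),
                  class = "decay_fit")
  expect_false(decay_distance(f4, 0.2)$reached)
  ## doubling rho halves the distance (C depends on rho * d only)
  f1 <- decay_distance(fit, 0.2)$distance_bp
  fit2 <- structure(list(rho_per_bp = 2e-4, n_gametes = 48L),
                    class = "decay_fit")
  f2 <- decay_distance(fit2, 0.2)$distance_bp
  expect_equal(f1 / f2, 2, tolerance = 1e-4)
  ## the root actually solves the curve equation
  expect_equal(hill_weir_r2(1e-4 * f1, 48), 0.2, tolerance = 1e-6)
})

test_that("sampling-scheme grids are deterministic and complete", {
  p <- ldphase_panel()$panel
  g1 <- sampling_scheme_ld(p, l_values = c(1L, 2L), g_values = c(12L, 24L),
                           repeats = 3L, seed = 5L)
  g2 <- sampling_scheme_ld(p, l_values = c(1L, 2L), g_values = c(12L, 24L),
                           repeats = 3L, seed = 5L)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 4L)
  expect_true(all(g1$mean_decay_bp > 0))
  ## cells under the g*l floor are not computed
  g3 <- sampling_scheme_ld(p, l_values = 1L, g_values = c(8L, 16L),
                           repeats = 2L, seed = 1L)
  expect_equal(g3$g, 16L)
})

test_that("within-population LD exceeds across-population LD at matched
           sample size", {
  p <- ldphase_panel()$panel
  set.seed(3)
  r2_within <- local({
    h <- sample_gametes(p, 1L, 40L)
    mean(pairwise_ld(h)$r2)
  })
  r2_across <- local({
    h <- sample_gametes(p, 10L, 4L)
    mean(pairwise_ld(h)$r2)
  })
  expect_gt(r2_within, r2_across)
})

test_that("sample-size runs are sorted, and exhaustive draws are
           deterministic", {
  p <- ldphase_panel()$panel
  res <- sample_size_ld(p, "P01", sizes = c(48L, 10L), repeats = 3L,
                        seed = 2L)
  expect_equal(res$size, c(10L, 48L))
  ## all 48 individuals drawn each repeat: zero variance
  expect_equal(res$var_decay_bp[res$size == 48L], 0)
  expect_error(sample_size_ld(p, "P01", sizes = 60L, repeats = 2L),
               "has 48")
})

test_that("interchromosomal LD is reproducible and low in panmixia", {
  sim <- simulate_panel(sim_config(n_pops = 1L, n_ind_per_pop = 40L,
                                   n_chrom = 4L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 300L,
                                   split_generations = 0L,
                                   missing_rate = 0, seed = 88L))
  ic <- interchromosomal_ld(sim$panel, l = 1L, n_individuals = 24L,
                            snps_per_bin_per_chrom = 10L, repeats = 4L,
                            seed = 6L)
  ic2 <- interchromosomal_ld(sim$panel, l = 1L, n_individuals = 24L,
                             snps_per_bin_per_chrom = 10L, repeats = 4L,
                             seed = 6L)
  expect_identical(ic, ic2)
  expect_true(all(ic$fraction < 0.05))
  expect_error(interchromosomal_ld(sim$panel, l = 5L, n_individuals = 24L),
               "multiple")
})
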