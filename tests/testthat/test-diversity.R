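test_that("proportion of polymorphic markers counts segregating sites", {
  n <- 6L
  fixed0 <- matrix(0L, n, 4L)
  expect_equal(proportion_polymorphic(toy_panel(fixed0)), 0)
  seg <- matrix(rep(c(0L, 1L, 2L), each = 2L), n, 4L)
  expect_equal(proportion_polymorphic(toy_panel(seg)), 1)
  ## 10 markers, 3 fixed (two at 0, one at 2)
  g <- matrix(1L, n, 10L)
  g[, 1:2] <- 0L; g[, 3] <- 2L
  expect_equal(proportion_polymorphic(toy_panel(g)), 0.7)
})

test_that("nucleotide diversity equals the gamete-pair mismatch average", {
  ## fixed marker
  expect_equal(nucleotide_diversity(toy_panel(matrix(2L, 4, 1)))$mean, 0)
  ## 4 gametes at p = 0.5: (4/3) * 2 * 0.25 = 2/3
  p <- toy_panel(matrix(c(2L, 0L), 2, 1))
  expect_equal(nucleotide_diversity(p)$mean, 2 / 3)

  ## brute-force oracle: average difference over all gamete pairs,
  ## on 100 random small markers
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:8, 1L)
    g <- matrix(sample(0:2, n, replace = TRUE), n, 1L)
    gam <- c(rbind(ifelse(g >= 1, 1L, 0L), ifelse(g == 2, 1L, 0L)))
    prs <- utils::combn(length(gam), 2L)
    oracle <- mean(gam[prs[1L, ]] != gam[prs[2L, ]])
    expect_equal(nucleotide_diversity(toy_panel(g))$per_marker[[1L]], oracle)
  }

  ## markers with < 2 callable gametes are excluded, not fatal
  g <- cbind(c(0L, 1L, 2L), c(NA, NA, NA))
  nd <- nucleotide_diversity(toy_panel(g))
  expect_equal(nd$n_excluded, 1L)
  expect_true(is.na(nd$per_marker[2L]))
})

test_that("window haplotype heterozygosity matches direct enumeration", {
  ## all gametes identical in the window -> 0
  h0 <- toy_haps(matrix(1L, 6, 5), pos = c(10, 20, 30, 40, 50))
  expect_equal(haplotype_heterozygosity(h0, window_spec(1e5, 5L))$mean, 0)

  ## k distinct gametes -> (k/(k-1)) (1 - 1/k) = 1
  hd <- toy_haps(diag(1L, 5, 5), pos = c(10, 20, 30, 40, 50))
  expect_equal(haplotype_heterozygosity(hd, window_spec(1e5, 5L))$mean, 1)

  ## classes {3,2,1} among 6 gametes: (6/5)(1 - 14/36) = 11/15
  h <- rbind(c(0, 0, 0, 0, 0), c(0, 0, 0, 0, 0), c(0, 0, 0, 0, 0),
             c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1))
  ht <- toy_haps(h, pos = c(10, 20, 30, 40, 50))
  expect_equal(haplotype_heterozygosity(ht, window_spec(100, 5L))$mean,
               11 / 15)

  ## windows with fewer than min_snps are skipped; none left errors
  sparse <- toy_haps(h, pos = c(10, 2000, 4000, 6000, 8000))
  expect_error(haplotype_heterozygosity(sparse, window_spec(100, 5L)),
               "no window")

  ## gametes with incomplete calls drop out of the window's class count
  hm <- h; hm[1L, 3L] <- NA
  htm <- toy_haps(hm, pos = c(10, 20, 30, 40, 50))
  ## remaining 5 gametes: classes {2,2,1} -> (5/4)(1 - 9/25) = 4/5
  expect_equal(haplotype_heterozygosity(htm, window_spec(100, 5L))$mean,
               4 / 5)
})

test_that("inbreeding coefficient hits its algebraic extremes", {
  ## every individual heterozygous at p = 0.5 loci -> f = -1
  het <- toy_panel(matrix(1L, 10, 5))
  expect_equal(fis(het, n_perms = 9L, seed = 1L)$fis, -1)
  ## all homozygotes at p = 0.5 -> f = 1
  hom <- toy_panel(matrix(rep(c(0L, 2L), each = 5), 10, 5))
  expect_equal(fis(hom, n_perms = 9L, seed = 1L)$fis, 1)
  expect_error(fis(toy_panel(matrix(0L, 5, 4))), "monomorphic")
})

test_that("random-mating populations show no spurious inbreeding", {
  ## equilibrium random-mating draws (no drift, so loci are independent)
  ok <- vapply(1:20, function(i) {
    sim <- simulate_panel(sim_config(n_pops = 1L, n_ind_per_pop = 100L,
                                     n_chrom = 2L, chrom_length_bp = 1e6,
                                     n_snps_per_chrom = 250L,
                                     split_generations = 0L,
                                     within_pop_Ne = 100L,
                                     missing_rate = 0,
                                     seed = 3000L + i))
    fz <- fis(sim$panel, n_perms = 99L, seed = i)
    abs(fz$fis) < 0.02 && fz$p_value > 0.05
  }, logical(1L))
  expect_gte(mean(ok), 0.85)
})

test_that("pooled panels are at least as diverse as within-population ones", {
  p <- study_panel()$panel
  pops <- panel_populations(p)
  pi_within <- vapply(unique(pops), function(pp)
    nucleotide_diversity(subset_samples(p, which(pops == pp)))$mean,
    numeric(1L))
  pi_all <- nucleotide_diversity(p)$mean
  expect_gte(pi_all, mean(pi_within))
  h_within <- vapply(unique(pops)[1:3], function(pp)
    haplotype_heterozygosity(panel_haplotypes(p, pp))$mean, numeric(1L))
  h_all <- haplotype_heterozygosity(panel_haplotypes(p))$mean
  expect_gte(h_all, mean(h_within))
})

test_that("diversity_summary reports one coherent row per population", {
  sim <- simulate_panel(sim_config(n_pops = 3L, n_ind_per_pop = 12L,
                                   n_chrom = 1L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 200L,
                                   missing_rate = 0.02, seed = 55L))
  ds <- diversity_summary(sim$panel, n_perms = 49L, seed = 4L)
  expect_equal(nrow(ds), 3L)
  expect_true(all(ds$PP >= 0 & ds$PP <= 1))
  expect_true(all(ds$pi >= 0 & ds$pi <= 1))
  expect_true(all(ds$H >= 0 & ds$H <= 1))
  expect_true(all(abs(ds$Fis) <= 1))
})

test_that("multi-population theta is near zero without divergence", {
  sim <- simulate_panel(sim_config(n_pops = 4L, n_ind_per_pop = 20L,
                                   n_chrom = 1L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 400L,
                                   split_generations = 0L,
                                   missing_rate = 0, seed = 66L))
  expect_lt(abs(wc_fst(sim$panel)), 0.02)
})
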