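test_that("same seed gives a bit-identical panel", {
  cfg <- sim_config(n_pops = 3L, n_ind_per_pop = 10L, n_chrom = 2L,
                    chrom_length_bp = 1e6, n_snps_per_chrom = 100L,
                    missing_rate = 0.05, seed = 17L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$genotypes, b$panel$genotypes)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$panel$markers, b$panel$markers)
  expect_identical(a$truth, b$truth)
})

test_that("panel invariants hold: phase consistency, sorting, segregation", {
  p <- study_panel()$panel
  expect_silent(validate_panel(p))
  ## every retained site segregates
  f <- colMeans(p$genotypes, na.rm = TRUE) / 2
  expect_true(all(f > 0 & f < 1))
  ## positions strictly increasing within chromosomes
  for (ch in unique(p$markers$chrom))
    expect_true(all(diff(p$markers$pos[p$markers$chrom == ch]) > 0))
})

test_that("apply_missingness hits its rate and composes with filtering", {
  sim <- simulate_panel(sim_config(n_pops = 2L, n_ind_per_pop = 25L,
                                   n_chrom = 2L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 1000L,
                                   missing_rate = 0, seed = 4L))
  p <- sim$panel
  expect_identical(apply_missingness(p, 0)$genotypes, p$genotypes)
  m <- apply_missingness(p, 0.1, seed = 6L)
  ncell <- length(m$genotypes)
  expect_gt(ncell, 2e4)
  obs <- mean(is.na(m$genotypes))
  se <- sqrt(0.1 * 0.9 / ncell)
  expect_lt(abs(obs - 0.1), 3 * se)
  ## gametes masked in step with genotypes
  expect_silent(validate_panel(m))
  ## near-total missingness exercises the empty-panel error path
  m99 <- apply_missingness(p, 0.999, seed = 7L)
  expect_error(filter_panel(m99, 0.9, 0.9), "no markers left")
})

test_that("no divergence means no among-population variance", {
  sim <- simulate_panel(sim_config(n_pops = 4L, n_ind_per_pop = 15L,
                                   n_chrom = 2L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 300L,
                                   split_generations = 0L,
                                   missing_rate = 0, seed = 11L))
  am <- amova(mrd(sim$panel), panel_populations(sim$panel), n_perms = 0)
  expect_lt(am$pct_among, 2)
})

test_that("ascertainment enriches intermediate allele frequencies", {
  base <- sim_config(n_pops = 4L, n_ind_per_pop = 20L, n_chrom = 2L,
                     chrom_length_bp = 1e6, n_snps_per_chrom = 500L,
                     missing_rate = 0, seed = 23L)
  asc <- base; asc$ascertainment_maf <- 0.1
  expect_gt(mean_maf(simulate_panel(asc)$panel),
            mean_maf(simulate_panel(base)$panel))
})

test_that("selfing produces a significantly positive inbreeding coefficient", {
  sim <- simulate_panel(sim_config(n_pops = 1L, n_ind_per_pop = 30L,
                                   n_chrom = 2L, chrom_length_bp = 1e6,
                                   n_snps_per_chrom = 300L,
                                   selfing_rate = 0.8, missing_rate = 0,
                                   seed = 29L))
  fz <- fis(sim$panel, n_perms = 199L, seed = 1L)
  expect_gt(fz$fis, 0.2)
  expect_lt(fz$p_value, 0.05)
})

test_that("realized Weir-Cockerham F_ST tracks the drift expectation", {
  reps <- 8L
  ests <- vapply(seq_len(reps), function(i) {
    sim <- simulate_panel(sim_config(n_pops = 8L, n_ind_per_pop = 20L,
                                     n_chrom = 2L, chrom_length_bp = 1e6,
                                     n_snps_per_chrom = 400L,
                                     missing_rate = 0, seed = 500L + i))
    wc_fst(sim$panel)
  }, numeric(1L))
  truth <- 1 - (1 - 1 / 100)^17
  se <- stats::sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - truth), 3 * se + 0.01)
})

test_that("LD decay distance shrinks as the recombination rate grows", {
  dd <- vapply(c(2e-8, 1e-7, 5e-7), function(rr) {
    sim <- simulate_panel(sim_config(
      n_pops = 1L, n_ind_per_pop = 40L, n_chrom = 2L,
      chrom_length_bp = 2e6, n_snps_per_chrom = 400L,
      ancestral_Ne = 100L, ancestral_generations = 120L,
      within_pop_Ne = 50L, recomb_rate_per_bp = rr,
      missing_rate = 0, seed = 77L))
    h <- panel_haplotypes(sim$panel)
    fit <- hill_weir_fit(pairwise_ld(h), nrow(h$haplotypes))
    decay_distance(fit)$distance_bp
  }, numeric(1L))
  expect_true(all(diff(dd) < 0))
})

test_that("ascertainment that removes every site is reported", {
  cfg <- sim_config(n_pops = 1L, n_ind_per_pop = 10L, n_chrom = 1L,
                    chrom_length_bp = 1e5, n_snps_per_chrom = 20L,
                    ancestral_Ne = 5000L, ascertainment_maf = 0.5,
                    missing_rate = 0, seed = 2L)
  expect_error(simulate_panel(cfg), "ascertainment")
})
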