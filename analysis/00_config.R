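# Shared study conditions for the analysis scripts.
#
# Three synthetic panels stand in for the landrace datasets:
#  * STUDY   - 10 populations x 24 individuals, calibrated so that the
#              individual-level AMOVA gives Phi_ST ~ 0.27 (drift F ~ 0.157
#              after 17 generations at Ne = 50); 2000 SNPs on 5 chromosomes.
#  * LDPHASE - same differentiation, but with 150 burn-in generations of the
#              ancestral pool (Ne = 100) so populations share ancestral LD,
#              48 individuals per population and dense markers; used for LD
#              decay, sample-size and linkage-phase analyses.
#  * NEUTRAL - a single no-divergence population drawn straight from
#              neutral standing variation; used for the site frequency
#              spectrum, with an ascertained twin.

library(popldiv)

MASTER_SEED <- 104729L   # fixed for the whole analysis

cfg_study <- function() sim_config(seed = derive_seed(MASTER_SEED, "study"))

cfg_ldphase <- function() sim_config(
  n_pops = 10L, n_ind_per_pop = 48L, n_chrom = 3L, chrom_length_bp = 2e6,
  n_snps_per_chrom = 800L, ancestral_Ne = 100L, ancestral_generations = 150L,
  split_generations = 17L, within_pop_Ne = 50L, recomb_rate_per_bp = 1e-7,
  missing_rate = 0.02, seed = derive_seed(MASTER_SEED, "ldphase"))

cfg_neutral <- function(ascertainment_maf = 0) sim_config(
  n_pops = 1L, n_ind_per_pop = 25L, n_chrom = 5L, chrom_length_bp = 5e6,
  n_snps_per_chrom = 2000L, ancestral_Ne = 1000L, split_generations = 0L,
  within_pop_Ne = 50L, missing_rate = 0.02,
  ascertainment_maf = ascertainment_maf,
  seed = derive_seed(MASTER_SEED, "neutral"))

cfg_diverged <- function() sim_config(
  split_generations = 60L, seed = derive_seed(MASTER_SEED, "diverged"))

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
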