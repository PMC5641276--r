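# Persistence of linkage phase: correlation of signed r and the proportion
# of equal phase (PEP) per 10-kb distance bin, between populations and for
# split halves within a population.

source("analysis/00_config.R")

ldp <- simulate_panel(cfg_ldphase())$panel
pops <- sort(unique(panel_populations(ldp)))[1:5]   # 10 population pairs

## pairwise population comparisons, pooled per bin
pair_rows <- list()
for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
  ph <- phase_persistence(panel_haplotypes(ldp, pops[i]),
                          panel_haplotypes(ldp, pops[j]))
  pair_rows[[length(pair_rows) + 1L]] <-
    cbind(pop_a = pops[i], pop_b = pops[j], ph$bins)
}
all_pairs <- do.call(rbind, pair_rows)
write_tsv(all_pairs, results_path("06_phase_between_pairs.tsv"))

per_bin <- aggregate(cbind(corr_r, pep) ~ bin_start,
                     all_pairs[all_pairs$n_pairs > 2, ], mean)
write_tsv(per_bin, results_path("06_phase_between_mean.tsv"))
near <- per_bin[1L, ]; far <- per_bin[nrow(per_bin), ]
cat(sprintf("between populations: corr(r) %.3f -> %.3f, PEP %.3f -> %.3f from the nearest to the farthest bin\n",
            near$corr_r, far$corr_r, near$pep, far$pep))

## split-half control within each of three populations
sh_rows <- lapply(pops[1:3], function(pp) {
  sh <- split_half_persistence(ldp, pp, repeats = 25L,
                               seed = derive_seed(MASTER_SEED,
                                                  paste0("split_", pp)))
  cbind(population = pp, sh$per_bin)
})
sh_tab <- do.call(rbind, sh_rows)
write_tsv(sh_tab, results_path("06_phase_split_half.tsv"))
first <- sh_tab[sh_tab$bin_start == 0, ]
cat(sprintf("split-half first bin: corr(r) %.3f, PEP %.3f (mean over %d populations)\n",
            mean(first$corr_r), mean(first$pep), nrow(first)))

# What we find: within populations linkage phases are almost perfectly
# consistent at all distances; between populations agreement is high for
# tightly linked pairs and decays toward zero near 1 Mb - the window over
# which marker effects could transfer between populations shrinks
# accordingly.
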