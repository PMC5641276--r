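#' Configuration of the structured-population generator
#'
#' Defaults emulate a panel of open-pollinated landraces: 10 isolated
#' populations of 24 genotyped individuals drifting at effective size 50 for
#' 17 generations after splitting from a common ancestral pool. The drift
#' model gives an identity-by-descent coefficient F = 1 - (1 - 1/(2 Ne))^t
#' (about 0.157 at the defaults), and a two-level AMOVA on individual-level
#' squared modified Rogers' distances then has expectation
#' Phi_ST = 2F/(1+F), about 0.27 — the differentiation regime the panel is
#' calibrated to. 2000 SNPs on 5 chromosomes of 5 Mb with recombination at
#' 1e-8 per bp give within-population LD decaying over hundreds of kb; 2%
#' missing calls.
#'
#' @param n_pops number of populations.
#' @param n_ind_per_pop diploid individuals drawn per population
#'   (<= `within_pop_Ne`).
#' @param n_chrom,chrom_length_bp,n_snps_per_chrom genome layout; SNP
#'   positions are uniform without ties on each chromosome.
#' @param ancestral_Ne diploid size of the ancestral pool; standing variation
#'   is drawn with allele frequencies from a density proportional to 1/x
#'   truncated to \[1/(2 Ne), 1 - 1/(2 Ne)\] (neutral-like spectrum).
#' @param ancestral_generations optional burn-in: generations of random
#'   mating of the ancestral pool (at `ancestral_Ne`, with recombination)
#'   before the split. 0 (the default) leaves the pool in linkage
#'   equilibrium; a positive value builds shared ancestral LD, which is the
#'   truth model for linkage-phase persistence between populations.
#' @param split_generations generations t of isolated random mating after
#'   the split.
#' @param within_pop_Ne diploid effective size of each population after the
#'   split.
#' @param recomb_rate_per_bp per-generation crossover probability per bp
#'   (crossovers per gamete per chromosome are Poisson with rate
#'   `recomb_rate_per_bp * chrom_length_bp`, positions uniform).
#' @param missing_rate fraction of genotype calls set missing, i.i.d.
#' @param selfing_rate probability that an offspring is produced by selfing.
#' @param ascertainment_maf minimal minor-allele frequency in a discovery
#'   subset of 8 individuals drawn across populations (0 disables); emulates
#'   array-style SNP ascertainment enriching intermediate frequencies.
#' @param seed integer seed; same seed, bit-identical panel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 10L, n_ind_per_pop = 24L, n_chrom = 5L,
                       chrom_length_bp = 5e6, n_snps_per_chrom = 400L,
                       ancestral_Ne = 1000L, ancestral_generations = 0L,
                       split_generations = 17L, within_pop_Ne = 50L,
                       recomb_rate_per_bp = 1e-8, missing_rate = 0.02,
                       selfing_rate = 0, ascertainment_maf = 0,
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops),
              n_ind_per_pop = as.integer(n_ind_per_pop),
              n_chrom = as.integer(n_chrom),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              ancestral_Ne = as.integer(ancestral_Ne),
              ancestral_generations = as.integer(ancestral_generations),
              split_generations = as.integer(split_generations),
              within_pop_Ne = as.integer(within_pop_Ne),
              recomb_rate_per_bp = as.numeric(recomb_rate_per_bp),
              missing_rate = as.numeric(missing_rate),
              selfing_rate = as.numeric(selfing_rate),
              ascertainment_maf = as.numeric(ascertainment_maf),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pops >= 1L, n_ind_per_pop >= 1L, n_chrom >= 1L,
              n_snps_per_chrom >= 1L, ancestral_Ne >= 2L,
              within_pop_Ne >= 2L, split_generations >= 0L,
              ancestral_generations >= 0L,
              chrom_length_bp >= n_snps_per_chrom,
              recomb_rate_per_bp >= 0,
              missing_rate >= 0, missing_rate < 1,
              selfing_rate >= 0, selfing_rate <= 1,
              ascertainment_maf >= 0, ascertainment_maf <= 0.5,
              n_ind_per_pop <= within_pop_Ne)
  })
  structure(cfg, class = "sim_config")
}

## one generation of random mating: h is gametes x markers (2N rows, rows
## 2i-1/2i form individual i); returns the offspring gamete matrix
wf_generation <- function(h, chrom_idx, chrom_pos, lambda, selfing_rate) {
  N <- nrow(h) %/% 2L
  nC <- length(chrom_idx)
  p1 <- sample.int(N, N, replace = TRUE)
  p2 <- sample.int(N, N, replace = TRUE)
  if (selfing_rate > 0) {
    s <- stats::runif(N) < selfing_rate
    p2[s] <- p1[s]
  }
  par_of_gamete <- as.vector(rbind(p1, p2))      # length 2N
  k <- matrix(stats::rpois(2L * N * nC, lambda), 2L * N, nC)
  start <- matrix(sample.int(2L, 2L * N * nC, replace = TRUE) - 1L, 2L * N, nC)
  nh <- matrix(0L, 2L * N, ncol(h))
  for (r in seq_len(2L * N)) {
    p <- par_of_gamete[r]
    for (cc in seq_len(nC)) {
      idx <- chrom_idx[[cc]]
      if (k[r, cc] == 0L) {
        nh[r, idx] <- h[2L * p - 1L + start[r, cc], idx]
      } else {
        cx <- sort(stats::runif(k[r, cc], 0, attr(chrom_pos, "len")[cc]))
        phase <- (findInterval(chrom_pos[[cc]], cx) + start[r, cc]) %% 2L
        nh[r, idx] <- ifelse(phase == 0L, h[2L * p - 1L, idx],
                             h[2L * p, idx])
      }
    }
  }
  nh
}

evolve_pop <- function(h, n_gen, chrom_idx, chrom_pos, lambda, selfing_rate) {
  for (g in seq_len(n_gen))
    h <- wf_generation(h, chrom_idx, chrom_pos, lambda, selfing_rate)
  h
}

#' Simulate a structured random-mating panel with known truth
#'
#' Forward Wright-Fisher model: (1) standing variation drawn in an ancestral
#' pool (optionally burnt in to build ancestral LD), (2) split into isolated
#' populations, (3) t generations of random mating with recombination and
#' optional selfing, (4) diploid individuals sampled, phased output, then
#' missingness and optional discovery-panel ascertainment applied and fixed
#' sites removed.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a phased [pop_panel()]) and `truth`
#'   (realized settings incl. `expected_fst` = 1 - (1 - 1/(2 Ne))^t and the
#'   per-chromosome recombination map).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    nC <- cfg$n_chrom
    chrom_names <- sprintf("chr%02d", seq_len(nC))
    chrom_pos <- lapply(seq_len(nC), function(cc)
      sort(sample.int(cfg$chrom_length_bp, cfg$n_snps_per_chrom)))
    attr(chrom_pos, "len") <- rep(cfg$chrom_length_bp, nC)
    L <- nC * cfg$n_snps_per_chrom
    chrom_idx <- split(seq_len(L), rep(seq_len(nC),
                                       each = cfg$n_snps_per_chrom))
    lambda <- cfg$recomb_rate_per_bp * cfg$chrom_length_bp

    ## ancestral standing variation, density ~ 1/x on [1/(2Ne), 1-1/(2Ne)]
    xmin <- 1 / (2 * cfg$ancestral_Ne); xmax <- 1 - xmin
    x <- xmin * (xmax / xmin)^stats::runif(L)
    gA <- 2L * cfg$ancestral_Ne
    pool <- matrix(stats::rbinom(gA * L, 1L, rep(x, each = gA)), gA, L)
    if (cfg$ancestral_generations > 0L)
      pool <- evolve_pop(pool, cfg$ancestral_generations, chrom_idx,
                         chrom_pos, lambda, 0)

    ## split and drift
    gP <- 2L * cfg$within_pop_Ne
    pops <- lapply(seq_len(cfg$n_pops), function(p) {
      founders <- pool[sample.int(gA, gP, replace = gP > gA), , drop = FALSE]
      evolve_pop(founders, cfg$split_generations, chrom_idx, chrom_pos,
                 lambda, cfg$selfing_rate)
    })

    ## draw individuals
    hap_rows <- vector("list", cfg$n_pops)
    for (p in seq_len(cfg$n_pops)) {
      ind <- sort(sample.int(cfg$within_pop_Ne, cfg$n_ind_per_pop))
      hap_rows[[p]] <- pops[[p]][as.vector(rbind(2L * ind - 1L, 2L * ind)), ,
                                 drop = FALSE]
    }
    haps <- do.call(rbind, hap_rows)
    n_tot <- cfg$n_pops * cfg$n_ind_per_pop
    pop_lab <- rep(sprintf("P%02d", seq_len(cfg$n_pops)),
                   each = cfg$n_ind_per_pop)
    sample_id <- sprintf("%s_I%02d", pop_lab,
                         rep(seq_len(cfg$n_ind_per_pop), cfg$n_pops))
    geno <- haps[seq(1L, 2L * n_tot, 2L), , drop = FALSE] +
            haps[seq(2L, 2L * n_tot, 2L), , drop = FALSE]
    rownames(geno) <- sample_id

    markers <- data.frame(
      chrom = rep(chrom_names, each = cfg$n_snps_per_chrom),
      pos = unlist(chrom_pos),
      id = sprintf("%s_%d", rep(chrom_names, each = cfg$n_snps_per_chrom),
                   unlist(chrom_pos)),
      ref = "A", alt = "T", stringsAsFactors = FALSE)

    panel <- pop_panel(markers, geno,
                       stats::setNames(pop_lab, sample_id),
                       phased = TRUE, haplotypes = haps)

    if (cfg$missing_rate > 0)
      panel <- apply_missingness_(panel, cfg$missing_rate)

    if (cfg$ascertainment_maf > 0) {
      ## discovery subset: 8 individuals spread across populations
      ## (round-robin over shuffled population members)
      by_pop <- lapply(split(seq_len(n_tot), pop_lab),
                       function(v) if (length(v) > 1L) sample(v) else v)
      take <- integer(0)
      i <- 1L
      while (length(take) < min(8L, n_tot)) {
        cand <- unlist(lapply(by_pop, function(v)
          if (length(v) >= i) v[i] else NULL), use.names = FALSE)
        if (length(cand) > 1L) cand <- sample(cand)
        take <- c(take, cand)
        i <- i + 1L
      }
      take <- take[seq_len(min(8L, n_tot))]
      sub <- panel$genotypes[take, , drop = FALSE]
      p_hat <- colMeans(sub, na.rm = TRUE) / 2
      maf <- pmin(p_hat, 1 - p_hat)
      maf[is.nan(maf)] <- 0
      keep <- !is.na(maf) & maf >= cfg$ascertainment_maf
      if (!any(keep))
        stop("all sites lost to ascertainment; lower ascertainment_maf")
      panel <- subset_markers(panel, keep)
    }

    ## drop sites fixed in the drawn panel
    p_hat <- colMeans(panel$genotypes, na.rm = TRUE) / 2
    seg <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
    if (!any(seg)) stop("no segregating sites in simulated panel")
    panel <- subset_markers(panel, seg)

    Fdrift <- 1 - (1 - 1 / (2 * cfg$within_pop_Ne))^cfg$split_generations
    truth <- list(
      expected_fst = Fdrift,
      expected_phi_st = 2 * Fdrift / (1 + Fdrift),
      split_generations = cfg$split_generations,
      within_pop_Ne = cfg$within_pop_Ne,
      recomb_map = lapply(seq_len(nC), function(cc)
        list(chrom = chrom_names[cc], length_bp = cfg$chrom_length_bp,
             rate_per_bp = cfg$recomb_rate_per_bp)),
      seed = cfg$seed, config = unclass(cfg))
    list(panel = panel, truth = truth)
  })
}

## unseeded core so simulate_panel can call it inside its own seed scope
apply_missingness_ <- function(panel, rate) {
  g <- panel$genotypes
  miss <- matrix(stats::runif(length(g)) < rate, nrow(g), ncol(g))
  g[miss] <- NA_integer_
  panel$genotypes <- g
  if (panel$phased) {
    mi <- which(miss, arr.ind = TRUE)
    if (nrow(mi)) {
      panel$haplotypes[cbind(2L * mi[, 1L] - 1L, mi[, 2L])] <- NA_integer_
      panel$haplotypes[cbind(2L * mi[, 1L], mi[, 2L])] <- NA_integer_
    }
  }
  validate_panel(panel)
  panel
}

#' Set genotype calls missing at random
#'
#' @param panel a [pop_panel()].
#' @param rate per-call missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return The panel with calls (and, for phased panels, the corresponding
#'   gametes) masked.
#' @export
apply_missingness <- function(panel, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  local_seed(seed, apply_missingness_(panel, rate))
}
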