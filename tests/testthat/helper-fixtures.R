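# Shared fixtures: panels are simulated once per session and cached, so the
# heavier acceptance checks and the module tests draw on the same objects.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# calibrated study panel: 10 populations x 24 individuals, Phi_ST ~ 0.27
study_panel <- function() fixture("study", function()
  simulate_panel(sim_config(seed = 42L)))

# LD / linkage-phase experiment panel: ancestral burn-in creates shared
# ancestral LD; 48 individuals per population for split-half and
# sample-size designs; dense markers for 10-kb distance bins
ldphase_panel <- function() fixture("ldphase", function()
  simulate_panel(sim_config(
    n_pops = 10L, n_ind_per_pop = 48L, n_chrom = 3L,
    chrom_length_bp = 2e6, n_snps_per_chrom = 800L,
    ancestral_Ne = 100L, ancestral_generations = 150L,
    split_generations = 17L, within_pop_Ne = 50L,
    recomb_rate_per_bp = 1e-7, missing_rate = 0.02, seed = 21L)))

# no-divergence panel drawn straight from neutral standing variation
neutral_panel <- function() fixture("neutral", function()
  simulate_panel(sim_config(
    n_pops = 1L, n_ind_per_pop = 25L, n_chrom = 5L,
    chrom_length_bp = 5e6, n_snps_per_chrom = 2000L,
    ancestral_Ne = 1000L, split_generations = 0L,
    within_pop_Ne = 50L, missing_rate = 0.02, seed = 101L)))

# hand-built tiny panel; geno is individuals x markers, one chromosome
toy_panel <- function(geno, pos = NULL, pops = NULL, phased = FALSE,
                      haps = NULL, chrom = "chr01") {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("S%02d", seq_len(n))
  if (is.null(pops)) pops <- rep("POP1", n)
  markers <- data.frame(chrom = chrom, pos = as.integer(pos),
                        id = sprintf("%s_%d", chrom, pos),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  pop_panel(markers, geno, stats::setNames(pops, rownames(geno)),
            phased = phased, haplotypes = haps)
}

# hap_set straight from a gametes x markers matrix
toy_haps <- function(h, pos = NULL, chrom = "chr01", pops = NULL) {
  h <- as.matrix(h)
  if (is.null(pos)) pos <- seq_len(ncol(h)) * 100L
  structure(list(
    markers = data.frame(chrom = chrom, pos = as.integer(pos),
                         id = sprintf("%s_%d", chrom, pos),
                         ref = "A", alt = "T", stringsAsFactors = FALSE),
    haplotypes = h,
    populations = pops %||% rep("POP1", nrow(h))), class = "hap_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: signed r by explicit haplotype counting
r_bruteforce <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pA <- sum(x) / n; pB <- sum(y) / n
  pAB <- sum(x == 1 & y == 1) / n
  (pAB - pA * pB) / sqrt(pA * (1 - pA) * pB * (1 - pB))
}
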