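#' Apply call-rate and bi-allelic filters to a panel
#'
#' Markers are filtered first against `min_marker_call_rate`, then samples
#' against `min_sample_call_rate` computed on the marker-filtered matrix
#' (array QC convention: marker quality first, then individual call rates).
#'
#' @param panel a [pop_panel()].
#' @param min_marker_call_rate,min_sample_call_rate fractions in \[0, 1\];
#'   a marker/sample is kept when its call rate is >= the threshold.
#' @param biallelic_only drop markers with fewer than 2 observed alleles?
#'   (Disabled by default; panels read by [read_panel()] are already
#'   bi-allelic by record, this drops markers monomorphic in the data.)
#' @param log_path optional JSON-lines log receiving the removal counts.
#' @return The filtered panel, with an attribute `removed` carrying
#'   `n_markers` and `n_samples` removed.
#' @export
filter_panel <- function(panel, min_marker_call_rate = 0.9,
                         min_sample_call_rate = 0.9,
                         biallelic_only = FALSE, log_path = NULL) {
  stopifnot(min_marker_call_rate >= 0, min_marker_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1)
  g <- panel$genotypes
  m_rate <- colMeans(!is.na(g))
  keep_m <- m_rate >= min_marker_call_rate
  if (biallelic_only) {
    poly <- apply(g, 2L, function(col) {
      col <- col[!is.na(col)]
      length(col) > 0L && (any(col == 1L) || (any(col == 0L) & any(col == 2L)))
    })
    keep_m <- keep_m & poly
  }
  if (!any(keep_m)) stop("no markers left after filtering")
  p2 <- subset_markers(panel, keep_m)
  s_rate <- rowMeans(!is.na(p2$genotypes))
  keep_s <- s_rate >= min_sample_call_rate
  if (!any(keep_s)) stop("no samples left after filtering")
  out <- subset_samples(p2, keep_s)
  removed <- c(n_markers = sum(!keep_m), n_samples = sum(!keep_s))
  log_event(log_path, "filter_panel",
            markers_removed = removed[["n_markers"]],
            samples_removed = removed[["n_samples"]],
            markers_kept = n_markers(out), samples_kept = n_individuals(out))
  attr(out, "removed") <- removed
  out
}

#' Restrict two panels to their overlapping markers
#'
#' Markers match on (chrom, pos) with a compatible allele pair; a ref/alt
#' swap is accepted and the second panel's dosages are recoded d -> 2 - d
#' (haplotype alleles a -> 1 - a). Matching positions with incompatible
#' allele pairs are dropped and logged, not an error. Strand is not
#' reconciled beyond the ref/alt swap.
#'
#' @param a,b two [pop_panel()] objects.
#' @param log_path optional JSON-lines log.
#' @return list of the two reduced panels (`a`, `b`) with identical marker
#'   order.
#' @export
intersect_panels <- function(a, b, log_path = NULL) {
  key_a <- paste(a$markers$chrom, a$markers$pos)
  key_b <- paste(b$markers$chrom, b$markers$pos)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  ra <- a$markers$ref[ia]; aa <- a$markers$alt[ia]
  rb <- b$markers$ref[ib]; ab <- b$markers$alt[ib]
  same <- ra == rb & aa == ab
  swap <- ra == ab & aa == rb
  dropped <- sum(!(same | swap))
  if (dropped)
    log_event(log_path, "intersect_panels_incompatible_alleles",
              n_dropped = dropped,
              positions = common[!(same | swap)])
  keep <- same | swap
  if (!any(keep)) stop("empty intersection")
  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]
  pa <- subset_markers(a, ia)
  pb <- subset_markers(b, ib)
  if (any(swap)) {
    sw <- which(swap)
    pb$genotypes[, sw] <- 2L - pb$genotypes[, sw]
    if (pb$phased) pb$haplotypes[, sw] <- 1L - pb$haplotypes[, sw]
    pb$markers$ref[sw] <- pa$markers$ref[sw]
    pb$markers$alt[sw] <- pa$markers$alt[sw]
    validate_panel(pb)
  }
  log_event(log_path, "intersect_panels", n_common = n_markers(pa),
            n_swapped = sum(swap))
  list(a = pa, b = pb)
}

#' Sample individuals under a within- or across-population design
#'
#' `within(pop, n)`: n individuals uniformly without replacement from one
#' population. `across(n)`: n distinct populations drawn uniformly, then one
#' individual uniformly from each (every individual originates from a
#' different population).
#'
#' @param panel a [pop_panel()].
#' @param design result of [design_within()] or [design_across()].
#' @param seed integer seed; same seed, same sample.
#' @return The sub-panel of drawn individuals.
#' @export
sample_individuals <- function(panel, design, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  pops <- panel_populations(panel)
  idx <- local_seed(seed, {
    if (design$type == "within") {
      cand <- which(pops == design$pop)
      if (!length(cand)) stop("population not in panel: ", design$pop)
      if (design$n > length(cand))
        stop("population ", design$pop, " has ", length(cand),
             " individuals; cannot draw ", design$n)
      sort(sample(cand, design$n))
    } else {
      u <- unique(pops)
      if (design$n > length(u))
        stop("cannot draw ", design$n, " populations from ", length(u))
      chosen <- sample(u, design$n)
      sort(vapply(chosen, function(p) {
        cand <- which(pops == p)
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, integer(1L)))
    }
  })
  subset_samples(panel, idx)
}

#' @rdname sample_individuals
#' @param pop population label.
#' @param n number of individuals (within) or populations (across).
#' @export
design_within <- function(pop, n)
  structure(list(type = "within", pop = pop, n = as.integer(n)),
            class = "sampling_design")

#' @rdname sample_individuals
#' @export
design_across <- function(n)
  structure(list(type = "across", n = as.integer(n)),
            class = "sampling_design")
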