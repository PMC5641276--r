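#' Genotype panel of one or more populations
#'
#' The universal input object of the package: an individuals x markers matrix
#' of alt-allele dosages in \{0, 1, 2\} (NA = missing call), an ordered marker
#' map, a sample-to-population assignment, and (for phased data) the
#' underlying gametes.
#'
#' @param markers data.frame with columns `chrom`, `pos` (1-based physical
#'   position in bp), `id`, `ref`, `alt`. Markers must be sorted by
#'   (chrom, pos) with no duplicate positions within a chromosome.
#' @param genotypes integer matrix, individuals x markers, entries 0/1/2/NA.
#'   Row names are sample IDs.
#' @param populations named character vector mapping every sample ID to its
#'   population label.
#' @param phased logical; TRUE when `haplotypes` carries resolved gametes.
#' @param haplotypes optional (2 x individuals) x markers binary matrix of
#'   gametes; rows 2i-1 and 2i belong to individual i. Required when
#'   `phased = TRUE`; per-cell sums must equal the dosage wherever
#'   non-missing.
#'
#' @return An object of class `pop_panel`.
#' @export
pop_panel <- function(markers, genotypes, populations, phased = FALSE,
                      haplotypes = NULL) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  obj <- structure(
    list(markers = markers, genotypes = genotypes,
         populations = populations, phased = isTRUE(phased),
         haplotypes = haplotypes),
    class = "pop_panel")
  validate_panel(obj)
  obj
}

#' @rdname pop_panel
#' @param x a `pop_panel`.
#' @export
validate_panel <- function(x) {
  mk <- x$markers; g <- x$genotypes
  if (ncol(g) != nrow(mk))
    stop("genotype columns (", ncol(g), ") != markers (", nrow(mk), ")")
  if (nrow(g) < 1L) stop("panel has no individuals")
  if (any(mk$pos < 1L)) stop("marker positions must be >= 1")
  if (any(mk$ref == mk$alt)) stop("ref and alt alleles must differ")
  ord <- order(mk$chrom, mk$pos)
  if (!identical(ord, seq_len(nrow(mk))))
    stop("markers must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(mk$chrom, mk$pos)))
    stop("duplicate marker positions within a chromosome")
  bad <- setdiff(rownames(g), names(x$populations))
  if (length(bad))
    stop("sample(s) missing from population map: ",
         paste(bad, collapse = ", "))
  rng <- range(g, na.rm = TRUE)
  if (!all(is.na(g)) && (rng[1] < 0L || rng[2] > 2L))
    stop("dosages must be in {0,1,2} or NA")
  if (x$phased) {
    h <- x$haplotypes
    if (is.null(h)) stop("phased panel requires haplotypes")
    if (nrow(h) != 2L * nrow(g) || ncol(h) != ncol(g))
      stop("haplotype matrix must be (2 x individuals) x markers")
    hs <- h[seq(1L, nrow(h), 2L), , drop = FALSE] +
          h[seq(2L, nrow(h), 2L), , drop = FALSE]
    ok <- is.na(g) | (!is.na(hs) & hs == g)
    if (!all(ok)) stop("haplotype pair sums disagree with dosages")
  }
  invisible(x)
}

#' @export
print.pop_panel <- function(x, ...) {
  cat("pop_panel:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "markers;",
      length(unique(x$populations[rownames(x$genotypes)])), "populations;",
      if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' Number of individuals / markers in a panel
#' @param panel a `pop_panel`.
#' @export
n_individuals <- function(panel) nrow(panel$genotypes)

#' @rdname n_individuals
#' @export
n_markers <- function(panel) ncol(panel$genotypes)

#' Population labels of the panel's samples, in sample order
#' @param panel a `pop_panel`.
#' @export
panel_populations <- function(panel)
  unname(panel$populations[rownames(panel$genotypes)])

#' Subset a panel by markers or individuals
#'
#' Keeps genotypes, haplotypes, the marker map and the population map
#' consistent; `idx` is an integer or logical index in the current marker /
#' sample order.
#'
#' @param panel a [pop_panel()].
#' @param idx indices of markers (`subset_markers`) or individuals
#'   (`subset_samples`) to keep.
#' @return The reduced panel.
#' @export
subset_markers <- function(panel, idx) {
  idx <- if (is.logical(idx)) which(idx) else as.integer(idx)
  h <- if (panel$phased) panel$haplotypes[, idx, drop = FALSE] else NULL
  pop_panel(panel$markers[idx, , drop = FALSE],
            panel$genotypes[, idx, drop = FALSE],
            panel$populations, phased = panel$phased, haplotypes = h)
}

#' @rdname subset_markers
#' @export
subset_samples <- function(panel, idx) {
  idx <- if (is.logical(idx)) which(idx) else as.integer(idx)
  h <- NULL
  if (panel$phased) {
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    h <- panel$haplotypes[hrows, , drop = FALSE]
  }
  g <- panel$genotypes[idx, , drop = FALSE]
  pop_panel(panel$markers, g,
            panel$populations[rownames(g)],
            phased = panel$phased, haplotypes = h)
}

#' Extract the gametes of a phased panel
#'
#' Builds the gametes x markers binary matrix used by all LD and
#' linkage-phase statistics. A missing genotype call masks both of the
#' individual's gametes at that marker.
#'
#' @param panel a phased `pop_panel`.
#' @param populations optional character vector restricting to gametes whose
#'   individual belongs to one of these populations.
#' @return An object of class `hap_set`: list with `markers`, `haplotypes`
#'   (gametes x markers, 0/1/NA) and `populations` (per-gamete source label).
#' @export
panel_haplotypes <- function(panel, populations = NULL) {
  if (!panel$phased) stop("panel is not phased; gametes unavailable")
  keep <- seq_len(n_individuals(panel))
  pops <- panel_populations(panel)
  if (!is.null(populations)) keep <- which(pops %in% populations)
  if (!length(keep)) stop("no individuals in requested populations")
  hrows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  h <- panel$haplotypes[hrows, , drop = FALSE]
  ## mask gametes at missing genotype cells
  miss <- is.na(panel$genotypes[keep, , drop = FALSE])
  if (any(miss)) {
    mi <- which(miss, arr.ind = TRUE)
    h[cbind(2L * mi[, 1L] - 1L, mi[, 2L])] <- NA_integer_
    h[cbind(2L * mi[, 1L], mi[, 2L])] <- NA_integer_
  }
  structure(list(markers = panel$markers, haplotypes = h,
                 populations = rep(pops[keep], each = 2L)),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat("hap_set:", nrow(x$haplotypes), "gametes x", ncol(x$haplotypes),
      "markers\n")
  invisible(x)
}
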