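#' Read a genotype panel from VCF plus a population map
#'
#' Consumes bi-allelic SNP records (GT field only). The panel is flagged
#' phased when every non-missing GT uses the `|` separator; gametes are then
#' extracted from the GT strings.
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzipped).
#' @param popmap_path path to a TSV with columns `sample_id`, `population`
#'   listing every sample of the VCF.
#' @return A [pop_panel()].
#' @export
read_panel <- function(vcf_path, popmap_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
  if (any(multi)) {
    i <- which(multi)[1L]
    stop("non-bi-allelic SNP record at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no genotype columns")
  popmap <- read_popmap(popmap_path)
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(popmap))
  if (length(missing_samples))
    stop("sample(s) in VCF missing from popmap: ",
         paste(missing_samples, collapse = ", "))

  gt[gt == "."] <- NA
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE))
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  h1 <- matrix(as.integer(a1), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(a2), nrow(gt), ncol(gt))
  geno <- t(h1 + h2)  # individuals x markers
  rownames(geno) <- samples

  markers <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE)

  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  haps <- NULL
  if (phased) {
    n <- length(samples)
    haps <- matrix(NA_integer_, 2L * n, nrow(markers))
    haps[seq(1L, 2L * n, 2L), ] <- t(h1)[, ord, drop = FALSE]
    haps[seq(2L, 2L * n, 2L), ] <- t(h2)[, ord, drop = FALSE]
  }
  pop_panel(markers, geno, popmap, phased = phased, haplotypes = haps)
}

#' @rdname read_panel
#' @export
read_popmap <- function(popmap_path) {
  pm <- utils::read.table(popmap_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(pm)))
    stop("popmap must have columns sample_id, population")
  stats::setNames(pm$population, pm$sample_id)
}

#' Write a panel as VCF plus population map
#'
#' Emits a minimal VCF 4.2 body (GT only) and a two-column TSV popmap; a
#' read/write/read round trip preserves dosages, phase and positions exactly.
#'
#' @param panel a [pop_panel()].
#' @param vcf_path,popmap_path output paths.
#' @export
write_panel <- function(panel, vcf_path, popmap_path) {
  mk <- panel$markers
  n <- n_individuals(panel)
  samples <- rownames(panel$genotypes)
  sep <- if (panel$phased) "|" else "/"
  if (panel$phased) {
    h1 <- t(panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE])
    h2 <- t(panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE])
  } else {
    g <- t(panel$genotypes)                       # markers x individuals
    h1 <- ifelse(g == 2L, 1L, ifelse(g == 1L, 0L, 0L))
    h2 <- ifelse(g >= 1L, 1L, 0L)
  }
  gt <- matrix(paste0(h1, sep, h2), nrow(mk), n)
  gt[is.na(t(panel$genotypes))] <- paste0(".", sep, ".")

  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popldiv",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)

  pops <- panel$populations[samples]
  utils::write.table(
    data.frame(sample_id = samples, population = unname(pops)),
    popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}
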