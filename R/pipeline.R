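#' Run an end-to-end analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order (panel acquisition ->
#' statistics), writing per-stage TSV/JSON outputs plus a manifest
#' recording the package version, a stable hash of the configuration and
#' the per-stage seeds (derived from the master seed by hashing the stage
#' name, so adding a stage does not perturb the others). Reruns under the
#' same configuration are bit-identical. Analysis parameters are validated
#' against the stages' preconditions before any computation starts; any
#' stage error aborts with the stage name, earlier outputs preserved.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `simulate` (arguments for [sim_config()]) or `input`
#'   (list `vcf`, `popmap`), optional `filter`
#'   (`min_marker_call_rate`, `min_sample_call_rate`), `analyses`
#'   (subset of "diversity", "sfs", "amova", "structure", "ld", "phase"),
#'   optional `params` (per-analysis parameter overrides), `out_dir`,
#'   `seed` (master seed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$seed))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  master <- as.integer(config$seed)
  analyses <- config$analyses %||% character(0)
  known <- c("diversity", "sfs", "amova", "structure", "ld", "phase")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  pr <- config$params %||% list()
  stage_seed <- function(name) derive_seed(master, name)
  run_stage <- function(name, expr) {
    log_event(log_path, "stage_start", stage = name)
    res <- tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    log_event(log_path, "stage_done", stage = name)
    res
  }

  outputs <- character(0)

  ## ---- panel acquisition -------------------------------------------------
  panel <- run_stage("panel", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% stage_seed("simulate")
      sim <- simulate_panel(do.call(sim_config, args))
      write_panel(sim$panel, file.path(out_dir, "panel.vcf"),
                  file.path(out_dir, "panel_popmap.tsv"))
      jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "panel.vcf", "panel_popmap.tsv", "truth.json")
      sim$panel
    } else if (!is.null(config$input)) {
      read_panel(config$input$vcf, config$input$popmap)
    } else stop("config needs either 'simulate' or 'input'")
  })
  if (!is.null(config$filter)) {
    panel <- run_stage("filter", filter_panel(
      panel,
      min_marker_call_rate = config$filter$min_marker_call_rate %||% 0.9,
      min_sample_call_rate = config$filter$min_sample_call_rate %||% 0.9,
      log_path = log_path))
  }

  ## ---- pre-flight validation against stage preconditions -----------------
  if (any(c("ld", "phase") %in% analyses) && !panel$phased)
    stop("pre-flight: analyses ", paste(intersect(c("ld", "phase"),
         analyses), collapse = ", "), " require a phased panel")
  if ("phase" %in% analyses &&
      length(unique(panel_populations(panel))) < 2L)
    stop("pre-flight: phase analysis needs >= 2 populations")
  n_perms <- as.integer(pr$n_perms %||% 1000L)
  stopifnot(n_perms >= 1L)

  emit <- function(df, fname) {
    utils::write.table(df, file.path(out_dir, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, fname)
  }

  dist_cache <- NULL
  get_mrd <- function() {
    if (is.null(dist_cache)) dist_cache <<- mrd(panel)
    dist_cache
  }

  for (an in analyses) {
    run_stage(an, switch(an,
      diversity = {
        ds <- diversity_summary(panel, window_spec(
          width_bp = pr$h_window_bp %||% 1e5,
          min_snps = pr$h_min_snps %||% 5L),
          n_perms = n_perms, seed = stage_seed("diversity"))
        emit(ds, "diversity.tsv")
      },
      sfs = {
        obs <- folded_sfs(panel, call_rate_c = pr$sfs_call_rate %||% 0.9,
                          n_reps = pr$sfs_reps %||% 1000L,
                          seed = stage_seed("sfs"))
        exp_sfs <- expected_neutral_sfs(obs$g)
        emit(data.frame(class_index = seq_along(obs$proportions),
                        proportion = obs$proportions,
                        expected_neutral_proportion = exp_sfs$proportions),
             "sfs.tsv")
      },
      amova = {
        am <- amova(get_mrd(), panel_populations(panel), n_perms = n_perms,
                    seed = stage_seed("amova"))
        jsonlite::write_json(unclass(am), file.path(out_dir, "amova.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, "amova.json")
        P <- length(unique(panel_populations(panel)))
        lv <- pr$capture_l_values %||% seq_len(min(5L, P))
        cc <- variance_captured(get_mrd(), panel_populations(panel),
                                l_values = lv,
                                n_repeats = pr$capture_repeats %||% 100L,
                                seed = stage_seed("capture"))
        emit(cc$summary, "capture_curve.tsv")
      },
      structure = {
        pc <- pcoa(get_mrd(), k = pr$pcoa_axes %||% 3L)
        emit(data.frame(sample = pc$labels, pc$axes), "pcoa.tsv")
        tr <- neighbor_joining(get_mrd())
        ape::write.tree(tr, file.path(out_dir, "njt.nwk"))
        outputs <- c(outputs, "njt.nwk")
      },
      ld = {
        pops <- sort(unique(panel_populations(panel)))
        rows <- lapply(pops, function(pp) {
          h <- panel_haplotypes(panel, pp)
          prs <- pairwise_ld(h, pr$ld_max_dist_bp %||% 1e6)
          fit <- hill_weir_fit(prs, nrow(h$haplotypes))
          dd <- decay_distance(fit, pr$ld_threshold %||% 0.2)
          data.frame(population = pp, mean_r2 = mean(prs$r2),
                     rho_per_bp = fit$rho_per_bp,
                     decay_bp = dd$distance_bp, reached = dd$reached)
        })
        emit(do.call(rbind, rows), "ld_decay.tsv")
      },
      phase = {
        pops <- sort(unique(panel_populations(panel)))
        pa <- pr$phase_pops %||% pops[1:2]
        ph <- phase_persistence(panel_haplotypes(panel, pa[1L]),
                                panel_haplotypes(panel, pa[2L]),
                                max_dist_bp = pr$ld_max_dist_bp %||% 1e6,
                                bin_bp = pr$phase_bin_bp %||% 1e4)
        emit(ph$bins, "phase_bins.tsv")
      }))
  }

  manifest <- list(
    package = "popldiv",
    version = as.character(utils::packageVersion("popldiv")),
    config = config,
    config_hash = derive_seed(0L, jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   digits = NA)),
    master_seed = master,
    stage_seeds = stats::setNames(
      lapply(c("simulate", "diversity", "sfs", "amova", "capture",
               "structure", "ld", "phase"), stage_seed),
      c("simulate", "diversity", "sfs", "amova", "capture", "structure",
        "ld", "phase")),
    outputs = unique(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
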