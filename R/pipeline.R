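#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end pipeline (segmentation
#' thresholds, SBNT analysis windows, statistics options, simulation sizes
#' and the RNG seed) into one object that round-trips losslessly through
#' JSON, so a report can always state exactly which settings produced it.
#'
#' @param quant A [quant_config].
#' @param sbnt List of SBNT analysis parameters.
#' @param stats List of statistics options.
#' @param n_subjects Cohort size for simulated runs.
#' @param n_phantom_subjects Number of subjects run as full voxel phantoms
#'   (the rest are simulated at the index level).
#' @param phantom_grid Grid shape for those phantoms.
#' @param phantom_spacing Voxel spacing (mm) for those phantoms.
#' @param seed Integer RNG seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(quant = quant_config(),
                            sbnt = list(cutoff = 2.5,
                                        window_start_frac = 0.3,
                                        search_start_frac = 0.5,
                                        slope_ratio = 2,
                                        flow_range = c(0.3, 0.5)),
                            stats = list(linkage = "average",
                                         k_branches = 3,
                                         icc_model = "ICC(2,1)",
                                         ci_method = "delong"),
                            n_subjects = 30L,
                            n_phantom_subjects = 2L,
                            phantom_grid = c(48L, 48L, 48L),
                            phantom_spacing = c(3, 3, 3),
                            seed = 1L) {
  stopifnot(inherits(quant, "quant_config"))
  structure(
    list(quant = quant, sbnt = sbnt, stats = stats,
         n_subjects = as.integer(n_subjects),
         n_phantom_subjects = as.integer(n_phantom_subjects),
         phantom_grid = as.integer(phantom_grid),
         phantom_spacing = as.numeric(phantom_spacing),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path JSON path.
#' @return `read_pipeline_config()` returns a [pipeline_config];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$quant <- unclass(out$quant)
  out
}

#' @rdname write_pipeline_config
#' @param config A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    quant = do.call(quant_config, j$quant),
    sbnt = j$sbnt,
    stats = j$stats,
    n_subjects = j$n_subjects,
    n_phantom_subjects = j$n_phantom_subjects,
    phantom_grid = j$phantom_grid,
    phantom_spacing = j$phantom_spacing,
    seed = j$seed
  )
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_pipeline_config(config, f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline
#'
#' Executes simulation (or file input) -> quantification -> indices -> SBNT
#' -> statistics and writes a versioned report directory. Without `inputs`,
#' a cohort is simulated at the index level, the first
#' `n_phantom_subjects` subjects are additionally run as full voxel
#' phantoms through segmentation and densitometry, and each subject's dN2
#' is re-measured from a simulated washout curve whose true slope is the
#' subject's latent dN2. With `inputs` (a data.frame with `subject_id`,
#' `insp_path`, `exp_path` and optionally `sbnt_path`, `levels`), volumes
#' are read from disk; subjects with missing files are skipped and counted.
#'
#' Every stage logs its parameters to `pipeline.log` in the output
#' directory, and the report embeds the MD5 hash of the configuration that
#' produced it.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory.
#' @param inputs Optional per-subject file table (see Details).
#' @return The report list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  log_line("config", "hash=", config_hash(config),
           " seed=", config$seed)

  n_skipped <- 0L
  if (is.null(inputs)) {
    log_line("simulate", "index-level cohort, n=", config$n_subjects,
             ", phantom subjects=", config$n_phantom_subjects)
    cs <- cohort_spec(n_subjects = config$n_subjects, seed = config$seed)
    table <- generate_cohort(cs)

    # full voxel phantoms for a few subjects: quantify and record indices
    nph <- min(config$n_phantom_subjects, config$n_subjects)
    if (nph > 0L) {
      phantom_rows <- lapply(seq_len(nph), function(i) {
        ps <- phantom_spec(grid_shape = config$phantom_grid,
                           spacing = config$phantom_spacing,
                           trapped_fraction = table$trapped_fraction[i],
                           seed = config$seed + i)
        ph <- generate_phantom(ps)
        mask <- suppressWarnings(segment_lung(ph$expiratory, config$quant))
        levels <- default_levels(mask)
        es <- summarize_volume(ph$expiratory, mask, levels, config$quant)
        is <- summarize_volume(ph$inspiratory, mask, levels, config$quant)
        cbind(subject_id = table$subject_id[i], indices_table(es, is))
      })
      phantoms <- do.call(rbind, phantom_rows)
      utils::write.csv(phantoms, file.path(out_dir, "indices_phantom.csv"),
                       row.names = FALSE)
      log_line("quantify", "phantom indices written for ", nph, " subjects")
    }

    # re-measure dN2 from simulated washout curves
    log_line("sbnt", "windows: phase III from ",
             config$sbnt$window_start_frac, " VC; breakpoint search from ",
             config$sbnt$search_start_frac, " VC; cutoff ",
             config$sbnt$cutoff, " %N2/L")
    cs_link <- cs$dn2_intercept + cs$dn2_gain * table$trapped_fraction
    dn2_meas <- vapply(seq_len(nrow(table)), function(i) {
      sim <- generate_sbnt_curve(sbnt_spec(phase3_slope = cs_link[i],
                                           seed = config$seed + 1000L + i))
      analyze_curve(sim$curve, cutoff = config$sbnt$cutoff,
                    search_start_frac = config$sbnt$search_start_frac,
                    slope_ratio = config$sbnt$slope_ratio,
                    window_start_frac = config$sbnt$window_start_frac)$dn2
    }, numeric(1))
    table$dn2 <- dn2_meas
    table$obstructed <- classify_obstruction(dn2_meas, config$sbnt$cutoff)
  } else {
    log_line("input", "reading ", nrow(inputs), " subjects from disk")
    rows <- list()
    for (i in seq_len(nrow(inputs))) {
      sid <- inputs$subject_id[i]
      if (!file.exists(inputs$insp_path[i]) ||
          !file.exists(inputs$exp_path[i])) {
        n_skipped <- n_skipped + 1L
        log_line("input", "subject ", sid, " skipped: missing volume file")
        next
      }
      insp <- read_ct_volume(inputs$insp_path[i])
      expv <- read_ct_volume(inputs$exp_path[i])
      mask <- suppressWarnings(segment_lung(expv, config$quant))
      levels <- if ("levels" %in% names(inputs)) {
        as.integer(strsplit(as.character(inputs$levels[i]), ";")[[1]])
      } else {
        default_levels(mask)
      }
      es <- summarize_volume(expv, mask, levels, config$quant)
      is <- summarize_volume(insp, mask, levels, config$quant)
      idx <- indices_table(es, is)
      dn2 <- NA_real_
      if ("sbnt_path" %in% names(inputs) &&
          file.exists(inputs$sbnt_path[i])) {
        curve <- read_sbnt_curve(inputs$sbnt_path[i])
        dn2 <- analyze_curve(curve, cutoff = config$sbnt$cutoff)$dn2
      }
      row <- data.frame(subject_id = sid, dn2 = dn2)
      for (lv in seq_len(nrow(idx))) {
        tag <- if (idx$level_id[lv] == "mean") "mean" else
          paste0("l", idx$level_id[lv])
        vals <- idx[lv, setdiff(names(idx), "level_id")]
        names(vals) <- paste0(names(vals), "_", tag)
        row <- cbind(row, vals)
      }
      rows[[length(rows) + 1L]] <- row
    }
    if (!length(rows)) stop("input stage failed: no readable subjects",
                            call. = FALSE)
    table <- do.call(rbind, rows)
    table$obstructed <- classify_obstruction(table$dn2, config$sbnt$cutoff)
    class(table) <- c("cohort_table", "data.frame")
  }

  write_cohort(table, file.path(out_dir, "cohort.csv"))

  if (nrow(table) >= 5L) {
    log_line("stats", "linkage=", config$stats$linkage,
             " k_branches=", config$stats$k_branches)
    report <- run_comparison(table, k_branches = config$stats$k_branches,
                             cutoff = config$sbnt$cutoff,
                             linkage = config$stats$linkage)
    write_report(report, out_dir)
  } else {
    log_line("stats", "skipped: fewer than 5 subjects")
    report <- NULL
  }

  meta <- list(package_version = as.character(utils::packageVersion("airtrapr")),
               config = unclass_config(config),
               config_hash = config_hash(config),
               n_subjects = nrow(table),
               n_skipped = n_skipped,
               prevalence = mean(table$dn2 > config$sbnt$cutoff,
                                 na.rm = TRUE),
               top_criterion = report$top_criterion %||% NA)
  jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("done", "report written to ", out_dir)
  invisible(report)
}
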