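#' Full cohort comparison of CT criteria against dN2
#'
#' Mirrors the study workflow: report the prevalence of small airway
#' obstruction (dN2 > cutoff), correlate every criterion with dN2
#' (Spearman), cluster dN2 with the criteria in a 1 - |rho| dendrogram,
#' then run ROC analysis on the branches closest to dN2 and rank them by
#' AUC.
#'
#' @param table A cohort table (see [generate_cohort()] / [read_cohort()]).
#' @param criteria Criterion column names; defaults to the nine mean-level
#'   criteria.
#' @param k_branches Number of dendrogram branches closest to dN2 carried
#'   into ROC analysis.
#' @param cutoff dN2 cutoff (\%N2/L) defining obstruction.
#' @param linkage Dendrogram linkage.
#' @return An object of class `airtrap_report`: list with `n_subjects`,
#'   `prevalence`, `spearman` (data.frame), `dendrogram`, `branches`,
#'   `roc` (list of [roc_analysis()] results ranked by AUC, or a
#'   single-class message) and `top_criterion`.
#' @examples
#' rep <- run_comparison(generate_cohort(cohort_spec(n_subjects = 30)))
#' rep$top_criterion
#' @export
run_comparison <- function(table,
                           criteria = paste0(airtrap_criteria()$criterion,
                                             "_mean"),
                           k_branches = 3L, cutoff = 2.5,
                           linkage = "average") {
  stopifnot(is.data.frame(table), "dn2" %in% names(table))
  missing_cols <- setdiff(criteria, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks criteria: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obstructed <- table$dn2 > cutoff
  n <- nrow(table)
  prevalence <- mean(obstructed)

  sp <- do.call(rbind, lapply(criteria, function(cn) {
    s <- spearman_vs_dn2(table, cn)
    data.frame(criterion = cn, rho = s$rho, p_value = s$p_value, n = s$n)
  }))

  dend <- build_dendrogram(table, c("dn2", criteria), linkage = linkage)
  branches <- names(dend$closest_to_dn2)[
    seq_len(min(k_branches, length(dend$closest_to_dn2)))]

  if (all(obstructed) || !any(obstructed)) {
    roc <- NULL
    roc_note <- "single-class labels: ROC analysis skipped"
    top <- NA_character_
  } else {
    roc <- lapply(branches, function(cn) {
      roc_analysis(table[[cn]], obstructed)
    })
    names(roc) <- branches
    roc <- roc[order(-vapply(roc, `[[`, numeric(1), "auc"))]
    roc_note <- NULL
    top <- names(roc)[1]
  }

  structure(
    list(n_subjects = n, prevalence = prevalence, cutoff = cutoff,
         spearman = sp, dendrogram = dend, branches = branches,
         roc = roc, roc_note = roc_note, top_criterion = top),
    class = "airtrap_report"
  )
}

#' @export
print.airtrap_report <- function(x, ...) {
  cat(sprintf("<airtrap_report> %d subjects; obstruction prevalence %.1f%% ",
              x$n_subjects, 100 * x$prevalence))
  cat(sprintf("(dN2 > %.1f %%N2/L)\n", x$cutoff))
  cat("Spearman rho vs dN2:\n")
  sp <- x$spearman[order(-abs(x$spearman$rho)), ]
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %-24s rho = %+.3f  (p = %.2g)\n", sp$criterion[i],
                sp$rho[i], sp$p_value[i]))
  }
  cat("Branches closest to dN2:", paste(x$branches, collapse = ", "), "\n")
  if (is.null(x$roc)) {
    cat(x$roc_note, "\n")
  } else {
    cat("ROC (ranked by AUC):\n")
    for (cn in names(x$roc)) {
      r <- x$roc[[cn]]
      cat(sprintf(
        "  %-24s AUC %.3f (%.3f-%.3f), thr %.4g: sens %.2f spec %.2f\n",
        cn, r$auc, r$auc_ci[1], r$auc_ci[2], r$best_threshold,
        r$sensitivity, r$specificity))
    }
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Writes the Spearman table as CSV, the dendrogram as Newick + JSON, the
#' ROC curves as CSV and a JSON summary.
#'
#' @param report An `airtrap_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "airtrap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$spearman, file.path(dir, "spearman.csv"),
                   row.names = FALSE)
  write_dendrogram(report$dendrogram,
                   newick_path = file.path(dir, "dendrogram.nwk"),
                   json_path = file.path(dir, "dendrogram.json"))
  summary <- list(
    n_subjects = report$n_subjects,
    prevalence = report$prevalence,
    cutoff = report$cutoff,
    branches = report$branches,
    top_criterion = report$top_criterion
  )
  if (!is.null(report$roc)) {
    for (cn in names(report$roc)) {
      utils::write.csv(report$roc[[cn]]$curve,
                       file.path(dir, paste0("roc_", cn, ".csv")),
                       row.names = FALSE)
    }
    summary$roc <- lapply(report$roc, function(r) {
      list(auc = r$auc, auc_ci = r$auc_ci, threshold = r$best_threshold,
           sensitivity = r$sensitivity, specificity = r$specificity,
           direction = r$direction)
    })
  } else {
    summary$roc_note <- report$roc_note
  }
  jsonlite::write_json(summary, file.path(dir, "roc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
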