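#' Paired expiratory/inspiratory air-trapping indices
#'
#' From matched expiratory and inspiratory density summaries of the same
#' level, computes the three paired criteria E/I, E-I and (E-I)/I on each of
#' the three density bases (MLD, LAA -850..-1024 and LAA -850..-910),
#' i.e. the nine air-trapping criteria. Ratios are taken on raw signed
#' values: on the MLD basis both E and I are negative HU, so E/I is a
#' positive ratio slightly below 1 in normal lungs (e.g. -780/-860 = 0.907)
#' and (E-I)/I = E/I - 1 holds identically. E-I carries HU on the MLD basis
#' and percentage points on the LAA bases.
#'
#' If the inspiratory value of an LAA basis is 0, the ratio and relative
#' difference are undefined: they are returned as `NA` with a warning while
#' the difference is still reported.
#'
#' @param exp_summary,insp_summary One-row `density_summary` data.frames
#'   (from [summarize_level()] or one row of [summarize_volume()]) sharing
#'   the same `level_id`.
#' @return A one-row data.frame of class `air_trapping_indices` with columns
#'   `level_id` and, for each basis `b` in `mld`, `laa_full`, `laa_narrow`:
#'   `e_<b>`, `i_<b>`, `e_over_i_<b>`, `e_minus_i_<b>`, `rel_diff_<b>`.
#' @examples
#' e <- airtrapr:::density_summary("1", -780, 10, 8, 100)
#' i <- airtrapr:::density_summary("1", -860, 31, 25, 100)
#' compute_indices(e, i)$e_over_i_mld
#' @export
compute_indices <- function(exp_summary, insp_summary) {
  stopifnot(nrow(exp_summary) == 1L, nrow(insp_summary) == 1L)
  if (!identical(as.character(exp_summary$level_id),
                 as.character(insp_summary$level_id))) {
    stop("summaries do not share a level_id", call. = FALSE)
  }
  cols <- c(mld = "mld", laa_full = "laa_full_pct",
            laa_narrow = "laa_narrow_pct")
  out <- data.frame(level_id = exp_summary$level_id)
  for (b in names(cols)) {
    e <- exp_summary[[cols[[b]]]]
    i <- insp_summary[[cols[[b]]]]
    out[[paste0("e_", b)]] <- e
    out[[paste0("i_", b)]] <- i
    if (i == 0) {
      warning("inspiratory ", b, " is 0: ratio and relative difference ",
              "undefined at level ", out$level_id, call. = FALSE)
      out[[paste0("e_over_i_", b)]] <- NA_real_
      out[[paste0("e_minus_i_", b)]] <- e - i
      out[[paste0("rel_diff_", b)]] <- NA_real_
    } else {
      out[[paste0("e_over_i_", b)]] <- e / i
      out[[paste0("e_minus_i_", b)]] <- e - i
      out[[paste0("rel_diff_", b)]] <- (e - i) / i
    }
  }
  class(out) <- c("air_trapping_indices", "data.frame")
  out
}

#' Indices for every level of a paired summary table
#'
#' Applies [compute_indices()] row-wise to matched multi-level summaries
#' (such as two [summarize_volume()] outputs), giving one row per level plus
#' the across-level mean.
#'
#' @param exp_summaries,insp_summaries `density_summary` data.frames with
#'   identical `level_id` sequences.
#' @return An `air_trapping_indices` data.frame, one row per level.
#' @export
indices_table <- function(exp_summaries, insp_summaries) {
  stopifnot(nrow(exp_summaries) == nrow(insp_summaries))
  rows <- lapply(seq_len(nrow(exp_summaries)), function(r) {
    compute_indices(exp_summaries[r, , drop = FALSE],
                    insp_summaries[r, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("air_trapping_indices", "data.frame")
  out
}
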