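#' Single-breath nitrogen washout curve
#'
#' Container for an SBNT trace: exhaled N2 concentration (and optionally
#' flow) sampled against cumulative expired volume after a full inspiration
#' of 100\% oxygen.
#'
#' @param expired_volume Monotone increasing expired volumes (L), within
#'   `[0, vital_capacity]`.
#' @param n2 N2 concentration (\%) per sample.
#' @param flow Optional expiratory flow (L/s) per sample.
#' @param vital_capacity Vital capacity (L).
#' @return An object of class `sbnt_curve`.
#' @export
sbnt_curve <- function(expired_volume, n2, flow = NULL, vital_capacity) {
  stopifnot(is.numeric(expired_volume), is.numeric(n2),
            length(expired_volume) == length(n2),
            is_scalar_num(vital_capacity), vital_capacity > 0)
  if (!is.null(flow)) stopifnot(length(flow) == length(n2))
  if (is.unsorted(expired_volume, strictly = FALSE)) {
    stop("`expired_volume` must be monotone increasing", call. = FALSE)
  }
  if (min(expired_volume) < 0 ||
      max(expired_volume) > vital_capacity + 1e-9) {
    stop("expired volumes must lie in [0, vital_capacity]", call. = FALSE)
  }
  structure(list(expired_volume = expired_volume, n2 = n2, flow = flow,
                 vital_capacity = vital_capacity),
            class = "sbnt_curve")
}

#' @export
print.sbnt_curve <- function(x, ...) {
  cat(sprintf("<sbnt_curve> %d samples over %.2f of %.2f L VC%s\n",
              length(x$n2), max(x$expired_volume), x$vital_capacity,
              if (is.null(x$flow)) " (no flow trace)" else ""))
  invisible(x)
}

#' Check expiratory flow against the protocol window
#'
#' The SBNT protocol asks for a steady 0.3-0.5 L/s expiration. The check is
#' restricted to mid-expiration (25\%-75\% of expired VC), where flow control
#' matters for the plateau, and passes when at least 90\% of those samples
#' fall inside `[lo, hi]`.
#'
#' @param curve An [sbnt_curve].
#' @param lo,hi Acceptable flow bounds (L/s).
#' @param min_fraction Required fraction of in-range mid-expiration samples.
#' @return A list with `ok` (logical, `NA` when no flow trace is present)
#'   and `fraction` in range.
#' @export
validate_flow <- function(curve, lo = 0.3, hi = 0.5, min_fraction = 0.9) {
  stopifnot(inherits(curve, "sbnt_curve"))
  if (is.null(curve$flow)) {
    return(list(ok = NA, fraction = NA_real_, note = "not assessed"))
  }
  vc <- curve$vital_capacity
  mid <- curve$expired_volume >= 0.25 * vc & curve$expired_volume <= 0.75 * vc
  f <- curve$flow[mid]
  frac <- mean(f >= lo & f <= hi)
  list(ok = frac >= min_fraction, fraction = frac)
}

# Continuous two-segment least squares with break at b over (v, y):
# y ~ a + s1 * min(v, b) + s2 * max(v - b, 0). Returns coefficients and SSE.
two_segment_fit <- function(v, y, b) {
  X <- cbind(1, pmin(v, b), pmax(v - b, 0))
  fit <- stats::.lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

#' Detect the closing volume (phase IV onset)
#'
#' Finds the phase III/IV breakpoint as the sample position minimising the
#' total squared error of a continuous two-segment linear fit over the
#' search window (the second half of expired VC by default), then accepts a
#' phase IV only if the terminal segment is convincingly steeper than the
#' plateau: terminal slope > `slope_ratio` x plateau slope. Otherwise the
#' curve is treated as phase III to the end and the closing volume is 0.
#'
#' @param curve An [sbnt_curve] spanning at least 60\% of VC.
#' @param search_start_frac Start of the breakpoint search window as a
#'   fraction of VC expired.
#' @param slope_ratio Required ratio of terminal to plateau slope.
#' @param min_points Minimum samples required in the search window.
#' @return A list with `closing_volume` (L), `breakpoint` (L expired),
#'   `slope_phase3`, `slope_phase4` and `sse` of the accepted fit.
#' @export
detect_closing_volume <- function(curve, search_start_frac = 0.5,
                                  slope_ratio = 2, min_points = 10L) {
  stopifnot(inherits(curve, "sbnt_curve"))
  v <- curve$expired_volume
  y <- curve$n2
  vc <- curve$vital_capacity
  if (max(v) < 0.6 * vc) {
    stop("curve spans less than 60% of vital capacity", call. = FALSE)
  }
  win <- v >= search_start_frac * vc
  if (sum(win) < min_points) {
    stop("fewer than ", min_points, " samples in the breakpoint search ",
         "window", call. = FALSE)
  }
  vw <- v[win]
  yw <- y[win]
  m <- length(vw)
  # candidate breakpoints at interior sample positions, >= 4 points per side
  cand <- seq.int(4L, m - 4L)
  if (length(cand) == 0L) {
    stop("too few samples to place a breakpoint", call. = FALSE)
  }
  fits <- lapply(cand, function(j) two_segment_fit(vw, yw, vw[j]))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  best <- which.min(sse)
  cf <- fits[[best]]$coef
  s3 <- cf[2]
  s4 <- cf[3] # slope of the terminal segment
  bp <- vw[cand[best]]
  if (s4 > slope_ratio * max(s3, 0)) {
    cv <- vc - bp
  } else {
    cv <- 0
    bp <- vc
  }
  list(closing_volume = cv, breakpoint = bp, slope_phase3 = unname(s3),
       slope_phase4 = unname(s4), sse = sse[best])
}

#' Fit the phase III nitrogen slope (dN2)
#'
#' Ordinary least-squares slope of N2 versus expired volume over the
#' alveolar plateau window, which runs from 30\% of VC expired to the phase
#' III/IV breakpoint.
#'
#' @param curve An [sbnt_curve].
#' @param closing_volume Closing volume in litres (0 when no phase IV); the
#'   breakpoint is `vital_capacity - closing_volume`.
#' @param window_start_frac Start of the plateau window as a fraction of VC.
#' @param min_window_l Minimum admissible window length (L).
#' @return A list with `dn2` (\%N2/L), `interval` (the fitted volume window),
#'   `r2` and `n` samples used.
#' @export
fit_phase3 <- function(curve, closing_volume = 0, window_start_frac = 0.3,
                       min_window_l = 0.5) {
  stopifnot(inherits(curve, "sbnt_curve"), closing_volume >= 0)
  vc <- curve$vital_capacity
  lo <- window_start_frac * vc
  hi <- vc - closing_volume
  if (hi - lo < min_window_l) {
    stop("phase III too short: window [", signif(lo, 3), ", ",
         signif(hi, 3), "] L is under ", min_window_l, " L", call. = FALSE)
  }
  sel <- curve$expired_volume >= lo & curve$expired_volume <= hi
  if (sum(sel) < 3L) stop("phase III too short: fewer than 3 samples",
                          call. = FALSE)
  v <- curve$expired_volume[sel]
  y <- curve$n2[sel]
  fit <- stats::lm.fit(cbind(1, v), y)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(dn2 = slope, interval = c(lo, hi), r2 = r2, n = sum(sel))
}

#' Classify small airway obstruction from dN2
#'
#' Positive when dN2 strictly exceeds the cutoff (the standard 2.5 \%N2/L);
#' the boundary value itself is classified negative.
#'
#' @param dn2 Phase III slope (\%N2/L), finite.
#' @param cutoff Decision threshold (\%N2/L).
#' @return Logical.
#' @export
classify_obstruction <- function(dn2, cutoff = 2.5) {
  stopifnot(is.numeric(dn2), all(is.finite(dn2)))
  dn2 > cutoff
}

#' Analyze an SBNT curve end to end
#'
#' Runs the full pipeline: flow quality control, closing-volume detection,
#' phase III slope fit, and obstruction classification.
#'
#' @param curve An [sbnt_curve].
#' @param cutoff dN2 cutoff for obstruction (\%N2/L).
#' @param search_start_frac,slope_ratio Passed to [detect_closing_volume()].
#' @param window_start_frac Passed to [fit_phase3()].
#' @param flow_range Acceptable flow bounds (L/s) for [validate_flow()].
#' @return An object of class `sbnt_result`: list with `dn2`,
#'   `closing_volume`, `phase3_interval`, `fit_r2`, `flow_ok`, `flow_fraction`
#'   and `obstructed`.
#' @examples
#' sim <- generate_sbnt_curve(sbnt_spec(phase3_slope = 3))
#' analyze_curve(sim$curve)$obstructed
#' @export
analyze_curve <- function(curve, cutoff = 2.5, search_start_frac = 0.5,
                          slope_ratio = 2, window_start_frac = 0.3,
                          flow_range = c(0.3, 0.5)) {
  stopifnot(inherits(curve, "sbnt_curve"))
  fl <- validate_flow(curve, flow_range[1], flow_range[2])
  cv <- detect_closing_volume(curve, search_start_frac, slope_ratio)
  p3 <- fit_phase3(curve, cv$closing_volume, window_start_frac)
  structure(
    list(dn2 = p3$dn2,
         closing_volume = cv$closing_volume,
         phase3_interval = p3$interval,
         fit_r2 = p3$r2,
         flow_ok = fl$ok,
         flow_fraction = fl$fraction,
         obstructed = classify_obstruction(p3$dn2, cutoff)),
    class = "sbnt_result"
  )
}

#' @export
print.sbnt_result <- function(x, ...) {
  cat(sprintf(
    "<sbnt_result> dN2 = %.3f %%N2/L (R2 %.3f), CV = %.2f L, %s\n",
    x$dn2, x$fit_r2, x$closing_volume,
    if (isTRUE(x$obstructed)) "obstructed" else "not obstructed"
  ))
  invisible(x)
}

#' Read or write an SBNT curve as CSV
#'
#' Column convention: `expired_volume_L`, `n2_pct`, optional `flow_Lps`.
#'
#' @param path CSV path.
#' @param vital_capacity VC in litres; defaults to the maximum expired
#'   volume in the file.
#' @return `read_sbnt_curve()` returns an [sbnt_curve]; `write_sbnt_curve()`
#'   returns `path` invisibly.
#' @export
read_sbnt_curve <- function(path, vital_capacity = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("expired_volume_L", "n2_pct")
  if (!all(need %in% names(tab))) {
    stop("SBNT CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sbnt_curve(tab$expired_volume_L, tab$n2_pct,
             flow = tab[["flow_Lps"]],
             vital_capacity = vital_capacity %||% max(tab$expired_volume_L))
}

#' @rdname read_sbnt_curve
#' @param curve An [sbnt_curve].
#' @export
write_sbnt_curve <- function(curve, path) {
  tab <- data.frame(expired_volume_L = curve$expired_volume,
                    n2_pct = curve$n2)
  if (!is.null(curve$flow)) tab$flow_Lps <- curve$flow
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
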