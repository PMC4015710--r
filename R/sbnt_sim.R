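#' Specification of a simulated single-breath nitrogen washout curve
#'
#' Describes the canonical four-phase N2-vs-expired-volume curve: phase I
#' (dead space, ~0 %N2), phase II (sigmoid bronchial/alveolar transition),
#' phase III (linear alveolar plateau whose slope is dN2) and phase IV
#' (steeper linear rise after small airways in dependent lung zones close;
#' its length, measured from end-expiration, is the closing volume).
#'
#' @param vital_capacity Vital capacity in litres.
#' @param phase1_end,phase2_end Expired volumes (L) ending phases I and II.
#' @param closing_volume Length of phase IV in litres, measured backwards
#'   from end-expiration; the phase III/IV breakpoint sits at
#'   `vital_capacity - closing_volume`. Use 0 for no phase IV.
#' @param phase3_slope Alveolar plateau slope (dN2) in \%N2 per litre.
#' @param phase4_slope Slope of phase IV in \%N2 per litre; defaults to a
#'   clearly steeper `3 * phase3_slope + 6`. Must be at least `phase3_slope`.
#' @param n2_at_phase3_start N2 concentration (\%) where the plateau begins.
#' @param noise_sd Gaussian measurement noise on N2 (\%N2).
#' @param sample_step Volume sampling step in litres.
#' @param mean_flow,flow_noise_sd Expiratory flow trace (L/s), recorded for
#'   quality control.
#' @param seed Integer RNG seed.
#' @return An object of class `sbnt_spec`.
#' @seealso [generate_sbnt_curve()]
#' @export
sbnt_spec <- function(vital_capacity = 4,
                      phase1_end = 0.15,
                      phase2_end = 0.8,
                      closing_volume = 0.8,
                      phase3_slope = 2.5,
                      phase4_slope = 3 * phase3_slope + 6,
                      n2_at_phase3_start = 25,
                      noise_sd = 0.05,
                      sample_step = 0.01,
                      mean_flow = 0.4,
                      flow_noise_sd = 0.01,
                      seed = 1L) {
  stopifnot(is_scalar_num(vital_capacity), is_scalar_num(closing_volume))
  if (!(0 < phase1_end && phase1_end < phase2_end &&
        phase2_end < vital_capacity - closing_volume &&
        vital_capacity - closing_volume <= vital_capacity)) {
    stop("need 0 < phase1_end < phase2_end < VC - closing_volume <= VC",
         call. = FALSE)
  }
  if (closing_volume < 0) stop("`closing_volume` must be >= 0", call. = FALSE)
  if (phase3_slope < 0 || phase4_slope < phase3_slope) {
    stop("need phase4_slope >= phase3_slope >= 0", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, sample_step > 0)
  phase_lengths <- c(phase1_end, phase2_end - phase1_end,
                     vital_capacity - closing_volume - phase2_end)
  if (closing_volume > 0) phase_lengths <- c(phase_lengths, closing_volume)
  if (sample_step >= min(phase_lengths)) {
    stop("`sample_step` too coarse to resolve the shortest phase",
         call. = FALSE)
  }
  structure(
    list(vital_capacity = vital_capacity, phase1_end = phase1_end,
         phase2_end = phase2_end, closing_volume = closing_volume,
         phase3_slope = phase3_slope, phase4_slope = phase4_slope,
         n2_at_phase3_start = n2_at_phase3_start, noise_sd = noise_sd,
         sample_step = sample_step, mean_flow = mean_flow,
         flow_noise_sd = flow_noise_sd, seed = as.integer(seed)),
    class = "sbnt_spec"
  )
}

# Noiseless N2 concentration at expired volumes v for a given spec.
sbnt_baseline <- function(spec, v) {
  p1 <- spec$phase1_end
  p2 <- spec$phase2_end
  vb <- spec$vital_capacity - spec$closing_volume
  n2_start <- spec$n2_at_phase3_start
  y <- numeric(length(v))

  # phase II: logistic rise rescaled to hit 0 at p1 and n2_start at p2
  # exactly, so phase III starts continuously
  in2 <- v > p1 & v < p2
  if (any(in2)) {
    m <- (p1 + p2) / 2
    s <- (p2 - p1) / 10
    lg <- function(x) stats::plogis((x - m) / s)
    y[in2] <- n2_start * (lg(v[in2]) - lg(p1)) / (lg(p2) - lg(p1))
  }
  in3 <- v >= p2 & v <= vb
  y[in3] <- n2_start + spec$phase3_slope * (v[in3] - p2)
  in4 <- v > vb
  y[in4] <- n2_start + spec$phase3_slope * (vb - p2) +
    spec$phase4_slope * (v[in4] - vb)
  y
}

#' Simulate a single-breath nitrogen washout curve
#'
#' Samples the four-phase curve described by an [sbnt_spec] on a regular
#' volume grid, adds Gaussian measurement noise, and returns the curve
#' together with its ground truth (the plateau slope and closing volume the
#' curve was built from).
#'
#' @param spec An [sbnt_spec].
#' @return A list with elements `curve` (an [sbnt_curve]), `dn2` and
#'   `closing_volume` (the generating truths).
#' @examples
#' sim <- generate_sbnt_curve(sbnt_spec(phase3_slope = 3, noise_sd = 0))
#' sim$dn2
#' @export
generate_sbnt_curve <- function(spec) {
  stopifnot(inherits(spec, "sbnt_spec"))
  v <- seq(0, spec$vital_capacity, by = spec$sample_step)
  base <- sbnt_baseline(spec, v)
  out <- with_seed(spec$seed, {
    n2 <- base + stats::rnorm(length(v), 0, spec$noise_sd)
    flow <- spec$mean_flow + stats::rnorm(length(v), 0, spec$flow_noise_sd)
    list(n2 = n2, flow = flow)
  })
  list(
    curve = sbnt_curve(expired_volume = v, n2 = out$n2, flow = out$flow,
                       vital_capacity = spec$vital_capacity),
    dn2 = spec$phase3_slope,
    closing_volume = spec$closing_volume
  )
}

#' Simulate paired measurements from two readers
#'
#' Produces two measurement series that share per-subject values but differ
#' by independent reader noise (and optionally a systematic per-reader bias),
#' the data-generating model under which the two-way random-effects ICC has a
#' closed form: `subject_sd^2 / (subject_sd^2 + error_sd^2 + bias variance)`.
#'
#' @param true_values Numeric vector of per-subject true values.
#' @param subject_sd Additional between-subject spread added on top of
#'   `true_values` (0 keeps them as-is).
#' @param error_sd Length-2 (or scalar) reader measurement noise SD.
#' @param reader_bias Length-2 systematic offsets added to each reader.
#' @param seed Integer RNG seed.
#' @return A list with numeric vectors `reader_a` and `reader_b`.
#' @export
generate_reader_pair <- function(true_values, subject_sd = 0,
                                 error_sd = c(0, 0), reader_bias = c(0, 0),
                                 seed = 1L) {
  stopifnot(is.numeric(true_values), subject_sd >= 0, all(error_sd >= 0))
  error_sd <- rep_len(error_sd, 2L)
  reader_bias <- rep_len(reader_bias, 2L)
  n <- length(true_values)
  with_seed(seed, {
    s <- true_values + stats::rnorm(n, 0, subject_sd)
    list(
      reader_a = s + reader_bias[1] + stats::rnorm(n, 0, error_sd[1]),
      reader_b = s + reader_bias[2] + stats::rnorm(n, 0, error_sd[2])
    )
  })
}
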