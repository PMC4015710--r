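# Index-level cohort simulation: each subject carries a latent trapped
# fraction; densitometric summaries follow the same two-Gaussian mixture
# closed forms as the voxel phantom, so the nine paired criteria are exact
# affine functions of the latent fraction before measurement noise.

#' The nine paired air-trapping criteria
#'
#' Names the nine expiratory/inspiratory criteria (E/I, E-I and (E-I)/I on
#' the MLD, LAA -850..-1024 and LAA -850..-910 bases) together with the sign
#' of their expected association with the trapped fraction (and hence with
#' dN2) under the trapping model: trapped lung keeps low expiratory
#' attenuation, so every criterion rises with trapping except E-I on the MLD
#' basis, which shrinks towards 0.
#'
#' @return A data.frame with columns `criterion` and `expected_sign`.
#' @export
airtrap_criteria <- function() {
  bases <- c("mld", "laa_full", "laa_narrow")
  kinds <- c("e_over_i", "e_minus_i", "rel_diff")
  crit <- as.vector(outer(kinds, bases, paste, sep = "_"))
  sign <- ifelse(crit == "e_minus_i_mld", -1, 1)
  data.frame(criterion = crit, expected_sign = sign)
}

#' Specification of a simulated cohort
#'
#' Describes a cohort in which each subject has a latent trapped fraction
#' drawn uniformly from `trapped_fraction_range`, dN2 is a noisy increasing
#' affine function of that fraction, and the nine CT criteria are noisy
#' affine functions of it through the mixture-model densitometry. Per-index
#' measurement noise is expressed relative to each index's latent SD; the
#' defaults deliberately give `e_over_i_mld` the strongest link so the
#' statistics layer has a known ranking to recover.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param trapped_fraction_range Length-2 range the latent fraction is drawn
#'   from.
#' @param dn2_intercept,dn2_gain Affine link from trapped fraction to dN2
#'   (\%N2/L); the gain must be positive, inducing the positive dN2-criterion
#'   correlations.
#' @param dn2_noise_sd Gaussian noise on dN2 (\%N2/L).
#' @param index_noise_sd Named vector of per-criterion noise levels, each a
#'   multiple of that criterion's latent SD; unnamed scalar applies to all.
#' @param level_multipliers Length-4 multipliers applied to the latent
#'   fraction at anatomical levels 1-4 (cranial to caudal), emulating the
#'   gravity-dependent cranio-caudal trapping gradient.
#' @param hu_model HU distributions used for the closed-form densitometry;
#'   defaults mirror [phantom_spec()] defaults.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 50L,
                        trapped_fraction_range = c(0.05, 0.95),
                        dn2_intercept = 0.5,
                        dn2_gain = 4,
                        dn2_noise_sd = 0.3,
                        index_noise_sd = c(e_over_i_mld = 0.2),
                        level_multipliers = c(0.7, 0.9, 1.1, 1.3),
                        hu_model = list(
                          insp_mean = -880, insp_sd = 20,
                          exp_mean = -750, exp_sd = 20,
                          trap_mean = -880, trap_sd = 15,
                          laa_full = c(-1024, -850),
                          laa_narrow = c(-910, -850)
                        ),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  stopifnot(length(trapped_fraction_range) == 2L,
            trapped_fraction_range[1] >= 0, trapped_fraction_range[2] <= 1,
            trapped_fraction_range[1] < trapped_fraction_range[2])
  if (dn2_gain <= 0) stop("`dn2_gain` must be positive", call. = FALSE)
  stopifnot(dn2_noise_sd >= 0, length(level_multipliers) == 4L,
            all(level_multipliers > 0))
  crit <- airtrap_criteria()$criterion
  noise <- rep(1.4, length(crit))
  names(noise) <- crit
  if (length(index_noise_sd)) {
    if (is.null(names(index_noise_sd))) {
      noise[] <- index_noise_sd[1]
    } else {
      bad <- setdiff(names(index_noise_sd), crit)
      if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "),
                            call. = FALSE)
      noise[names(index_noise_sd)] <- index_noise_sd
    }
  }
  if (any(noise < 0)) stop("index noise must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = n_subjects,
         trapped_fraction_range = trapped_fraction_range,
         dn2_intercept = dn2_intercept, dn2_gain = dn2_gain,
         dn2_noise_sd = dn2_noise_sd, index_noise_sd = noise,
         level_multipliers = level_multipliers, hu_model = hu_model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# P(lo <= X <= hi) for X ~ N(mean, sd)
gauss_range_prob <- function(lo, hi, mean, sd) {
  stats::pnorm((hi - mean) / sd) - stats::pnorm((lo - mean) / sd)
}

# Closed-form expiratory and inspiratory density summaries for trapped
# fraction f (vectorised over f). Mirrors what densitometry measures on a
# phantom with the same HU model.
mixture_summaries <- function(f, hu) {
  p_full <- c(
    normal = gauss_range_prob(hu$laa_full[1], hu$laa_full[2], hu$exp_mean,
                              hu$exp_sd),
    trap = gauss_range_prob(hu$laa_full[1], hu$laa_full[2], hu$trap_mean,
                            hu$trap_sd),
    insp = gauss_range_prob(hu$laa_full[1], hu$laa_full[2], hu$insp_mean,
                            hu$insp_sd)
  )
  p_narrow <- c(
    normal = gauss_range_prob(hu$laa_narrow[1], hu$laa_narrow[2], hu$exp_mean,
                              hu$exp_sd),
    trap = gauss_range_prob(hu$laa_narrow[1], hu$laa_narrow[2], hu$trap_mean,
                            hu$trap_sd),
    insp = gauss_range_prob(hu$laa_narrow[1], hu$laa_narrow[2], hu$insp_mean,
                            hu$insp_sd)
  )
  list(
    e = list(
      mld = (1 - f) * hu$exp_mean + f * hu$trap_mean,
      laa_full = 100 * ((1 - f) * p_full["normal"] + f * p_full["trap"]),
      laa_narrow = 100 * ((1 - f) * p_narrow["normal"] + f * p_narrow["trap"])
    ),
    i = list(
      mld = rep(hu$insp_mean, length(f)),
      laa_full = rep(100 * p_full[["insp"]], length(f)),
      laa_narrow = rep(100 * p_narrow[["insp"]], length(f))
    )
  )
}

# Noiseless criterion values for trapped fraction f: named list of length 9,
# each a vector along f.
criterion_signals <- function(f, hu) {
  s <- mixture_summaries(f, hu)
  out <- list()
  for (b in c("mld", "laa_full", "laa_narrow")) {
    e <- as.numeric(s$e[[b]])
    i <- as.numeric(s$i[[b]])
    out[[paste0("e_over_i_", b)]] <- e / i
    out[[paste0("e_minus_i_", b)]] <- e - i
    out[[paste0("rel_diff_", b)]] <- (e - i) / i
  }
  out
}

#' Simulate a cohort table
#'
#' Generates one row per subject: a latent trapped fraction, a noisy dN2
#' linked to it by an increasing affine map, the resulting obstruction label
#' (dN2 > 2.5 \%N2/L), and the nine paired air-trapping criteria at
#' anatomical levels 1-4 and their mean, each as the exact mixture-model
#' value plus independent measurement noise.
#'
#' @param spec A [cohort_spec].
#' @return A data.frame of class `cohort_table` with columns `subject_id`,
#'   `trapped_fraction`, `dn2`, `obstructed` and `<criterion>_<l1..l4|mean>`
#'   for each of the nine criteria.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_subjects = 10))
#' mean(tab$obstructed)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  hu <- spec$hu_model
  rng <- spec$trapped_fraction_range
  crit <- airtrap_criteria()$criterion

  # latent SD of each criterion induced by the fraction distribution: all
  # criteria are affine in f, so it is |signal(1) - signal(0)| * sd(f)
  sd_f <- diff(rng) / sqrt(12)
  s0 <- criterion_signals(0, hu)
  s1 <- criterion_signals(1, hu)
  latent_sd <- vapply(crit, function(cn) abs(s1[[cn]] - s0[[cn]]) * sd_f,
                      numeric(1))

  with_seed(spec$seed, {
    f <- stats::runif(n, rng[1], rng[2])
    dn2 <- spec$dn2_intercept + spec$dn2_gain * f +
      stats::rnorm(n, 0, spec$dn2_noise_sd)
    tab <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      trapped_fraction = f,
      dn2 = dn2,
      obstructed = dn2 > 2.5
    )
    tags <- c(paste0("l", 1:4), "mean")
    f_levels <- cbind(
      vapply(spec$level_multipliers, function(m) clamp(f * m, 0, 1),
             numeric(n))
    )
    f_levels <- cbind(f_levels, rowMeans(f_levels))
    for (j in seq_along(tags)) {
      sig <- criterion_signals(f_levels[, j], hu)
      for (cn in crit) {
        noise_sd <- spec$index_noise_sd[[cn]] * latent_sd[[cn]]
        tab[[paste0(cn, "_", tags[j])]] <- sig[[cn]] +
          stats::rnorm(n, 0, noise_sd)
      }
    }
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Read or write a cohort table as CSV
#'
#' @param path CSV path.
#' @return `read_cohort()` returns a `cohort_table` data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "dn2") %in% names(tab))) {
    stop("cohort CSV must have at least subject_id and dn2 columns",
         call. = FALSE)
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicated subject_id in cohort table", call. = FALSE)
  }
  if (!"obstructed" %in% names(tab)) tab$obstructed <- tab$dn2 > 2.5
  tab$obstructed <- as.logical(tab$obstructed)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @rdname read_cohort
#' @param table A cohort table.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
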