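# Segmentation and densitometry: exact small cases, distributional oracles,
# and the algebraic properties of MLD/LAA%.

test_that("a clean low-attenuation box is segmented exactly", {
  vals <- array(0, c(16, 16, 16))
  vals[5:12, 5:12, 5:12] <- -1000
  vol <- ct_volume(vals, c(1, 1, 1))
  cfg <- quant_config(min_component_voxels = 10)
  expect_warning(m <- segment_lung(vol, cfg), "one lung component")
  expect_identical(m$mask, vals == -1000)
})

test_that("volumes with no parenchymal voxels raise a no-lung error", {
  expect_error(segment_lung(flat_volume(0, c(16, 16, 16)),
                            quant_config(min_component_voxels = 10)),
               "no lung found")
})

test_that("airway removal leaves masks without an apical air column alone", {
  vals <- array(0, c(16, 16, 16))
  vals[5:12, 5:12, 5:12] <- -800 # lung-like but above airway ceiling
  vol <- ct_volume(vals, c(1, 1, 1))
  cfg <- quant_config(min_component_voxels = 10)
  m <- suppressWarnings(segment_lung(vol, cfg))
  m2 <- remove_airway(m, vol, cfg)
  expect_identical(m$mask, m2$mask)
})

test_that("an airway-only volume yields no lung downstream", {
  # a single tube of near-air touching the apical slice: removed as airway,
  # nothing remains
  vals <- array(0, c(16, 16, 16))
  vals[7:10, 7:10, 4:16] <- -1000
  vol <- ct_volume(vals, c(1, 1, 1))
  expect_error(segment_lung(vol, quant_config(min_component_voxels = 10)),
               "no lung found")
})

test_that("MLD is the arithmetic mean over the mask", {
  vals <- array(-850, c(10, 10, 10))
  vol <- ct_volume(vals, c(1, 1, 1))
  full <- array(TRUE, dim(vals))
  expect_equal(mean_lung_density(vol, full), -850)
  vals[1:5, , ] <- -900
  vals[6:10, , ] <- -800
  expect_equal(mean_lung_density(ct_volume(vals, c(1, 1, 1)), full), -850)
  expect_error(mean_lung_density(vol, array(FALSE, dim(vals))), "empty")
})

test_that("Gaussian voxels reproduce CLT and normal-tail predictions", {
  set.seed(42)
  n <- 1e6
  vals <- array(rnorm(n, -800, 50), c(100, 100, 100))
  vol <- ct_volume(vals, c(1, 1, 1))
  full <- array(TRUE, dim(vals))
  expect_lt(abs(mean_lung_density(vol, full) - (-800)), 0.15)
  # P(X <= -850) = pnorm(-1) = 15.87%
  p <- pnorm(-1)
  se <- sqrt(p * (1 - p) / n) * 100
  expect_lt(abs(laa_percent(vol, full, c(-1024, -850)) - 100 * p), 3 * se)
})

test_that("LAA bounds are inclusive and percentages behave trivially", {
  vol <- flat_volume(-900)
  full <- array(TRUE, dim(vol$values))
  expect_equal(laa_percent(vol, full, c(-1024, -850)), 100)
  expect_equal(laa_percent(vol, full, c(-1024, -900)), 100) # boundary in
  vals <- array(c(-900, -700), c(10, 10, 10))
  expect_equal(laa_percent(ct_volume(vals, c(1, 1, 1)), full,
                           c(-1024, -850)), 50)
})

test_that("HU translation shifts MLD exactly and LAA% follows the ranges", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                      spacing = c(3, 3, 3), seed = 21))
  vol <- ph$expiratory
  mask <- ph$truth$lung_mask
  shift <- 37.5
  shifted <- ct_volume(vol$values + shift, vol$spacing)
  expect_equal(mean_lung_density(shifted, mask),
               mean_lung_density(vol, mask) + shift)
  expect_equal(laa_percent(shifted, mask, c(-1024 + shift, -850 + shift)),
               laa_percent(vol, mask, c(-1024, -850)))
})

test_that("nesting and range monotonicity of LAA% hold on random volumes", {
  cfg <- quant_config()
  for (s in 1:5) {
    set.seed(s)
    vals <- array(rnorm(8000, -820, 80), c(20, 20, 20))
    vol <- ct_volume(vals, c(1, 1, 1))
    full <- array(TRUE, dim(vals))
    narrow <- laa_percent(vol, full, cfg$laa_narrow_range)
    wide <- laa_percent(vol, full, cfg$laa_full_range)
    expect_lte(narrow, wide)
    wider <- laa_percent(vol, full, c(-1024, -800))
    expect_lte(wide, wider)
  }
})

test_that("level summaries pool both sides, or average them on request", {
  vals <- array(0, c(20, 20, 8))
  vals[2:7, 5:16, ] <- -900    # left lung, 72 voxels/slice
  vals[14:19, 5:16, ] <- -700  # right lung, equal area
  vol <- ct_volume(vals, c(1, 1, 1))
  m <- suppressWarnings(
    segment_lung(vol, quant_config(min_component_voxels = 10))
  )
  s_pool <- summarize_level(vol, m, 4, quant_config())
  expect_equal(s_pool$mld, -800)
  expect_equal(s_pool$laa_full_pct, 50)
  s_avg <- summarize_level(vol, m, 4, quant_config(), combine = "average")
  expect_equal(s_avg$mld, -800) # equal areas: average equals pool
  expect_error(summarize_level(vol, m, 99, quant_config()), "bounds")
})

test_that("volume summaries average the four levels unweighted", {
  vals <- array(rep(c(-700, -750, -800, -850), each = 64), c(8, 8, 4))
  vol <- ct_volume(vals, c(1, 1, 1))
  mask <- array(TRUE, dim(vals))
  # slices ordered caudal -> cranial in z; levels given cranial first
  sv <- summarize_volume(vol, mask, c(4, 3, 2, 1))
  expect_equal(nrow(sv), 5L)
  expect_equal(sv$level_id, c("1", "2", "3", "4", "mean"))
  expect_equal(sv$mld[5], -775)
  # four identical slices: mean equals each level
  vals2 <- array(-780, c(8, 8, 4))
  sv2 <- summarize_volume(ct_volume(vals2, c(1, 1, 1)), mask, c(4, 3, 2, 1))
  expect_equal(sv2$mld, rep(-780, 5))
})

test_that("per-level LAA% tracks a cranio-caudal trapping gradient", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                      spacing = c(3, 3, 3),
                                      trapped_fraction = c(0.5, 0.05),
                                      seed = 8))
  m <- segment_lung(ph$expiratory)
  lev <- default_levels(m) # cranial (apex) first
  sv <- summarize_volume(ph$expiratory, m, lev)
  laa <- sv$laa_full_pct[1:4]
  expect_true(all(diff(laa) > 0)) # increases towards the base
})

test_that("segmentation recovers phantom ground truth", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64), seed = 13))
  m <- segment_lung(ph$expiratory)
  expect_gte(jaccard(m, ph$truth$lung_mask), 0.95)
  excl <- sum(ph$truth$airway_mask & !m$mask) / sum(ph$truth$airway_mask)
  expect_gte(excl, 0.9)
  expect_setequal(na.omit(m$components$side), c("left", "right"))
})
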