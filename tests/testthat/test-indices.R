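# The nine paired E/I criteria: arithmetic, the (E-I)/I = E/I - 1 identity,
# undefined-ratio handling, and directionality.

ds <- function(mld = -800, laa_full = 20, laa_narrow = 15, level = "1") {
  airtrapr:::density_summary(level, mld, laa_full, laa_narrow, 1000)
}

test_that("criteria match hand arithmetic on signed HU and LAA values", {
  out <- compute_indices(ds(mld = -780, laa_full = 10),
                         ds(mld = -860, laa_full = 31))
  expect_equal(out$e_over_i_mld, -780 / -860)        # 0.9070
  expect_equal(out$e_minus_i_mld, 80)
  expect_equal(out$rel_diff_mld, 80 / -860)          # -0.0930
  expect_equal(out$e_over_i_laa_full, 10 / 31)       # 0.3226
  expect_equal(out$e_minus_i_laa_full, -21)
  expect_equal(out$rel_diff_laa_full, -21 / 31)      # -0.6774
})

test_that("equal expiratory and inspiratory values give the identity point", {
  out <- compute_indices(ds(), ds())
  for (b in c("mld", "laa_full", "laa_narrow")) {
    expect_equal(out[[paste0("e_over_i_", b)]], 1)
    expect_equal(out[[paste0("e_minus_i_", b)]], 0)
    expect_equal(out[[paste0("rel_diff_", b)]], 0)
  }
})

test_that("(E-I)/I equals E/I - 1 to machine precision on random summaries", {
  set.seed(99)
  for (i in 1:200) {
    e <- ds(mld = runif(1, -1000, -510), laa_full = runif(1, 1, 99),
            laa_narrow = runif(1, 1, 99))
    i_ <- ds(mld = runif(1, -1000, -510), laa_full = runif(1, 1, 99),
             laa_narrow = runif(1, 1, 99))
    out <- compute_indices(e, i_)
    for (b in c("mld", "laa_full", "laa_narrow")) {
      expect_lt(abs(out[[paste0("rel_diff_", b)]] -
                      (out[[paste0("e_over_i_", b)]] - 1)), 1e-12)
      expect_gt(out$e_over_i_mld, 0) # both MLD values negative
    }
  }
})

test_that("zero inspiratory LAA flags ratio criteria but keeps differences", {
  expect_warning(out <- compute_indices(ds(laa_full = 10),
                                        ds(laa_full = 0)),
                 "undefined")
  expect_true(is.na(out$e_over_i_laa_full))
  expect_true(is.na(out$rel_diff_laa_full))
  expect_equal(out$e_minus_i_laa_full, 10)
  expect_false(is.na(out$e_over_i_mld))
})

test_that("criteria respond monotonically to the expiratory value", {
  i_ <- ds(mld = -860, laa_full = 30)
  lo <- compute_indices(ds(mld = -820, laa_full = 10), i_)
  hi <- compute_indices(ds(mld = -820, laa_full = 20), i_)
  # LAA basis: larger E raises all three criteria
  expect_gt(hi$e_over_i_laa_full, lo$e_over_i_laa_full)
  expect_gt(hi$e_minus_i_laa_full, lo$e_minus_i_laa_full)
  expect_gt(hi$rel_diff_laa_full, lo$rel_diff_laa_full)
  # MLD basis: E rising towards 0 (denser lung) lowers E/I
  denser <- compute_indices(ds(mld = -700), ds(mld = -860))
  airier <- compute_indices(ds(mld = -800), ds(mld = -860))
  expect_lt(denser$e_over_i_mld, airier$e_over_i_mld)
})

test_that("mismatched levels are rejected and tables bind row-wise", {
  expect_error(compute_indices(ds(level = "1"), ds(level = "2")),
               "level_id")
  e <- rbind(ds(level = "1"), ds(level = "2"))
  class(e) <- c("density_summary", "data.frame")
  out <- indices_table(e, e)
  expect_equal(nrow(out), 2L)
  expect_equal(out$e_over_i_mld, c(1, 1))
})
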