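test_that("reweighting penalises protected conformations exponentially", {
  w <- c(1, 1)
  np <- c(10, 0)
  expect_identical(reweight_frames(w, np, 0, 3, 300), w)    # s = 0
  expect_identical(reweight_frames(w, np, 0.1, 0, 300), w)  # den = 0
  rw <- reweight_frames(w, np, 0.1, 1, 300)
  rt <- 1.9872e-3 * 300
  expect_equal(rw[1] / rw[2], exp(-0.1 * 10 * 1 / rt), tolerance = 1e-12)
  expect_equal(sum(rw), sum(w), tolerance = 1e-12)  # renormalised
})

test_that("a strict two-state model gives an exactly linear isotherm", {
  m <- two_state_model(n_sites = 30, dG = 5)
  en <- sample_ensemble(m, mode = "enumeration")
  s <- 0.05
  cv <- dg_hx_curve(en$pm, 1, s, seq(0, 3, by = 0.5))
  # m_fit = s * (n_protected(N) - n_protected(U)) = 0.05 * 30
  expect_equal(cv$m_fit, s * 30, tolerance = 1e-9)
  # every grid point lies on the line dG0 - m * den
  expect_equal(cv$dG, 5 - s * 30 * cv$den_grid, tolerance = 1e-9)
})

test_that("dG_HX(den) is non-increasing for every site when s > 0", {
  m <- build_three_tier_model(12, 2, 5, 8)
  en <- sample_ensemble(m, mode = "enumeration")
  for (site in c(1, 5, 12)) {
    cv <- dg_hx_curve(en$pm, site, 0.05, seq(0, 6, by = 0.5))
    expect_true(all(diff(cv$dG) <= 1e-12))
  }
})

test_that("the local slope steepens as exchange shifts to larger openings", {
  # a site with a cheap local route and an expensive global route:
  # with denaturant the global route takes over and the slope grows
  m <- hierarchy_model(dG_local = 2, dG_subglobal = 5, dG_global = 8)
  en <- sample_ensemble(m, mode = "enumeration")
  cv <- dg_hx_curve(en$pm, 2, 0.05, seq(0, 6, by = 0.5))
  slopes <- cv$local_slope[!is.na(cv$local_slope)]
  expect_true(all(diff(slopes) < 1e-9))  # dG slope becomes more negative
  expect_gt(abs(slopes[length(slopes)]), abs(slopes[1]))
})

test_that("a single-frame ensemble is censored at every grid point", {
  pm <- protection_matrix_obj(matrix(1, 1, 3), temperature_K = 300)
  cv <- dg_hx_curve(pm, 1, 0.05, c(0, 1, 2))
  expect_true(all(cv$censored))
  expect_true(is.na(cv$m_fit))
})

test_that("m decomposes exactly into m_closed - m_open", {
  m <- build_three_tier_model(30, 2, 5, 8)
  en <- sample_ensemble(m, mode = "enumeration")
  s <- 0.05
  for (site in c(1, 7, 30)) for (den in c(0, 1.5, 4)) {
    dec <- decompose_m(en$pm, site, s, den)
    expect_equal(dec$m, dec$m_closed - dec$m_open, tolerance = 1e-12)
    # the analytic identity m = -d(dG_HX)/d(den)
    expect_lt(abs(dec$m - (-fd_slope(en$pm, site, s, den))), 1e-6)
    # and the enumeration oracle agrees
    expect_equal(dec$m, analytic_m(m, site, s, den), tolerance = 1e-10)
  }
})

test_that("fully unfolded open states give m = m_closed; singleton openings give m = s", {
  # open frames fully unfolded -> m_open = 0
  m <- two_state_model(n_sites = 20, dG = 4)
  en <- sample_ensemble(m, mode = "enumeration")
  dec <- decompose_m(en$pm, 3, 0.05, 0)
  expect_equal(dec$m_open, 0)
  expect_equal(dec$m, dec$m_closed)
  # a singleton opening in an otherwise intact native frame -> m = s * 1
  n <- 20
  t_local <- rep(1, n); t_local[4] <- 0
  ml <- state_model(list(
    list(name = "native", G = 0, template = rep(1, n)),
    list(name = "local_4", G = 2, template = t_local),
    list(name = "unfolded", G = 50, template = rep(0, n))), n)
  enl <- sample_ensemble(ml, mode = "enumeration")
  decl <- decompose_m(enl$pm, 4, 0.05, 0)
  expect_equal(decl$m, 0.05 * 1, tolerance = 1e-6)
  # empty sub-ensemble -> censored
  pm1 <- protection_matrix_obj(matrix(1, 4, 2))
  expect_true(decompose_m(pm1, 1, 0.05, 0)$censored)
})

test_that("calibration recovers s = m_global / delta_n in the two-state limit", {
  m <- two_state_model(n_sites = 30, dG = 5)
  en <- sample_ensemble(m, mode = "enumeration")
  s <- calibrate_s(en$pm, 1, experimental_m_global = 1.5)
  expect_equal(s, 1.5 / 30, tolerance = 1e-6)
  # linearity: doubling the experimental m doubles s
  s2 <- calibrate_s(en$pm, 1, experimental_m_global = 3.0)
  expect_equal(s2, 2 * s, tolerance = 1e-5)
  expect_error(calibrate_s(en$pm, 1, 0), "positive")
  # an m far beyond reach reports a calibration failure with diagnostics
  expect_error(calibrate_s(en$pm, 1, 1e6), "calibration failure")
})

test_that("openings are classified by their m-value ratio", {
  expect_equal(classify_opening(0.05, 1), "local")       # 5% of global
  expect_equal(classify_opening(0.5, 1), "subglobal")
  expect_equal(classify_opening(1.0, 1), "global")
  expect_equal(classify_opening(0.8, 1), "global")       # boundary closed
  expect_equal(classify_opening(NA, 1), "unresolved")
  expect_equal(classify_opening(c(0.1, 0.9), 1), c("local", "global"))
  expect_error(classify_opening(0.5, 0), "positive")
})

test_that("no site's m_fit exceeds the all-protected hypothetical bound", {
  m <- build_three_tier_model(15, 2, 5, 8)
  en <- sample_ensemble(m, mode = "enumeration")
  s <- 0.05
  # hypothetical site protected exactly in the frames where all NHs are
  # protected: its opening exposes every protection difference
  hyp_ps <- as.integer(en$pm$n_protected == 15)
  pm_h <- protection_matrix_obj(cbind(en$pm$ps, hyp_ps),
                                weights = en$pm$weights,
                                temperature_K = en$pm$temperature_K)
  grid <- seq(0, 2, by = 0.5)
  m_bound <- dg_hx_curve(pm_h, 16, s, grid)$m_fit
  for (site in 1:15)
    expect_lte(dg_hx_curve(en$pm, site, s, grid)$m_fit, m_bound + 1e-9)
})

test_that("site_m_values fills the m columns and opening classes", {
  m <- hierarchy_model()
  en <- sample_ensemble(m, mode = "enumeration")
  tab <- site_hdx(en$pm, n_boot = 0)
  tab <- site_m_values(tab, en$pm, 0.05, seq(0, 6, by = 0.5))
  expect_true(all(is.finite(tab$m_value)))
  # sites open only in the unfolded state carry the largest m
  expect_equal(tab$opening_class[15], "global")
  expect_equal(tab$opening_class[2], "local")
})
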