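test_that("exponential trace fit is a round trip at zero noise", {
  for (k in c(0.03, 0.1, 0.5)) {
    tr <- sim_unfolding_trace(k, 1, 0.2, time_s = seq(0, 5 / k, length.out = 80),
                              noise_sd = 0, seed = 1)
    fit <- fit_unfolding_trace(tr)
    expect_lt(abs(fit$k_obs - k) / k, 1e-6)
    expect_lt(abs(fit$amplitude - 1), 1e-6)
    expect_lt(abs(fit$offset - 0.2), 1e-6)
  }
})

test_that("constant trace raises a no-decay error", {
  flat <- tibble::tibble(time_s = seq(0, 60, 0.5), signal = 1)
  expect_error(fit_unfolding_trace(flat), "[Nn]o decay")
})

test_that("trace fit at SNR 20 has small median relative error", {
  errs <- vapply(1:200, function(s) {
    tr <- sim_unfolding_trace(0.1, 1, 0.2, time_s = seq(0, 60, 0.5),
                              noise_sd = 0.05, seed = s)
    abs(fit_unfolding_trace(tr)$k_obs - 0.1) / 0.1
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("chevron arm fit is exact on collinear data", {
  pts <- tibble::tibble(urea_M = 7:9, ku_per_s = exp(-6 + 0.5 * (7:9)))
  suppressWarnings(arm <- fit_unfolding_arm(pts))
  expect_equal(arm$ln_ku0, -6, tolerance = 1e-10)
  expect_equal(arm$m_ku, 0.5, tolerance = 1e-10)
  expect_equal(arm$ku0, exp(-6), tolerance = 1e-10)
  expect_error(fit_unfolding_arm(
    tibble::tibble(urea_M = 7:9, ku_per_s = c(1, -1, 2))), "ku_per_s")
})

test_that("arm slope is unbiased over noisy seeds", {
  slopes <- vapply(1:500, function(s) {
    set.seed(s)
    u <- seq(7, 9, 0.25)
    k <- exp(-6 + 0.5 * u + rnorm(length(u), 0, 0.05))
    fit_unfolding_arm(tibble::tibble(urea_M = u, ku_per_s = k))$m_ku
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.5) / 0.5, 0.01)
})

test_that("derived folding rate inverts K_eq and propagates errors", {
  expect_equal(derive_folding_rate(0.2, 0, 298.15)$kf0, 0.2)
  expect_equal(derive_folding_rate(1, 10, 298.15)$kf0,
               exp(10 / (8.314e-3 * 298.15)), tolerance = 1e-12)
  # inversion of a measured rate pair: dG0 chosen so kf = 0.5 at ku = 0.088
  RT <- 8.314e-3 * 303.15
  dG0 <- RT * log(0.5 / 0.088)
  expect_equal(derive_folding_rate(0.088, dG0, 303.15)$kf0, 0.5,
               tolerance = 1e-12)
  # zero input errors give zero output error
  expect_equal(derive_folding_rate(1, 5, 298.15)$kf0_se, 0)
  r <- derive_folding_rate(1, 5, 298.15, ku0_se = 0.1, dG0_se = 0.5)
  expect_gt(r$kf0_se, 0)
})

test_that("Tanford beta follows 1 - RT m_ku / m_eq", {
  expect_equal(compute_beta_urea(0, 5, 303.15)$beta_urea, 1)
  RT <- 8.314e-3 * 303.15
  expect_equal(compute_beta_urea(5 / RT, 5, 303.15)$beta_urea, 0,
               tolerance = 1e-12)
  expect_equal(compute_beta_urea(0.177, 5, 303.15)$beta_urea,
               1 - RT * 0.177 / 5, tolerance = 1e-12)
  expect_equal(round(compute_beta_urea(0.177, 5, 303.15)$beta_urea, 3), 0.911)
  expect_error(compute_beta_urea(0.2, -1, 303.15), "m_eq")
})

test_that("salt ddG decomposition handles the degenerate and clean cases", {
  same <- compute_salt_ddG(1, 1, 0.1, 0.1, 298.15)
  expect_equal(same$ddG_Ddagger_kJ, 0)
  expect_equal(same$ddG_DN_kJ, 0)
  expect_false(same$phi_defined)
  expect_true(is.na(same$phi_f_salt))

  RT <- 8.314e-3 * 298.15
  tenfold <- compute_salt_ddG(1, 10, 0.1, 0.1, 298.15)
  expect_equal(tenfold$ddG_Ddagger_kJ, -RT * log(10), tolerance = 1e-12)
  expect_equal(tenfold$ddG_DN_kJ, -RT * log(10), tolerance = 1e-12)
  expect_equal(tenfold$phi_f_salt, 1, tolerance = 1e-12)
  expect_error(compute_salt_ddG(0, 1, 0.1, 0.1, 298.15), "kf_low")
})

test_that("phi equals 1 exactly when the unfolding rate is salt-insensitive", {
  for (kf_ratio in c(2, 10, 500)) {
    r <- compute_salt_ddG(0.5, 0.5 * kf_ratio, 0.09, 0.09, 303.15)
    expect_equal(r$phi_f_salt, 1, tolerance = 1e-12)
  }
})

test_that("phi is temperature-invariant", {
  grid <- expand.grid(
    T = c(278.15, 293.15, 303.15, 310.15, 330),
    kf_low = c(0.5, 5.5), ku_ratio = c(1.1, 1.36, 3)
  )
  phis <- apply(grid, 1, function(g) {
    compute_salt_ddG(g["kf_low"], g["kf_low"] * 20, 0.08,
                     0.08 * g["ku_ratio"], g["T"])$phi_f_salt
  })
  for (kf in unique(grid$kf_low)) for (kr in unique(grid$ku_ratio)) {
    v <- phis[grid$kf_low == kf & grid$ku_ratio == kr]
    expect_lt(max(v) - min(v), 1e-12)
  }
})

test_that("equilibrium-route phi agrees with the kinetic route when K = kf/ku", {
  RT <- 8.314e-3 * 293.15
  # equilibrium ddG_DN implied by the same rates
  ddG_eq <- -RT * log((25 / 0.09) / (5.5 / 0.08))
  r <- compute_salt_ddG(5.5, 25, 0.08, 0.09, 293.15,
                        ddG_DN_equilibrium = ddG_eq)
  expect_equal(r$phi_f_salt_eq, r$phi_f_salt, tolerance = 1e-12)
})

test_that("ln k_u is linear in sqrt(I) for Debye-Hueckel data", {
  I <- c(0.09, 0.25, 0.49)
  d <- tibble::tibble(ionic_strength_M = I, ku_per_s = exp(1 + 2 * sqrt(I)))
  suppressWarnings(f <- fit_lnk_vs_sqrt_ionic_strength(d))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  # curvature in sqrt(I) is detected as R^2 < 1
  d2 <- tibble::tibble(ionic_strength_M = I,
                       ku_per_s = exp(1 + 2 * sqrt(I) + 3 * I))
  f2 <- fit_lnk_vs_sqrt_ionic_strength(d2)
  expect_lt(f2$r_squared, 1)
  expect_error(fit_lnk_vs_sqrt_ionic_strength(d[1, ]), "ionic_strength_M")
})

test_that("energy diagram is consistent with the ddG decomposition", {
  mk_summary <- function(ku0, kf0, label) {
    pts <- tibble::tibble(urea_M = 7:9, ku_per_s = ku0 * exp(0.2 * (7:9)))
    suppressWarnings(arm <- fit_unfolding_arm(pts))
    RT <- 8.314e-3 * 303.15
    folding_summary(arm, dG0 = RT * log(kf0 / arm$ku0), m_eq = 5,
                    temperature_K = 303.15, condition = label)
  }
  lo <- mk_summary(0.088, 0.5, "low")
  hi <- mk_summary(0.12, 297, "high")
  dia <- build_energy_diagram(lo, hi)
  ref <- compute_salt_ddG(lo$kf0, hi$kf0, lo$ku0, hi$ku0, 303.15)
  expect_equal(attr(dia, "ddG_Ddagger_kJ"), ref$ddG_Ddagger_kJ,
               tolerance = 1e-10)
  expect_equal(attr(dia, "ddG_DN_kJ"), ref$ddG_DN_kJ, tolerance = 1e-10)
  # identical conditions collapse to zero differences
  dia0 <- build_energy_diagram(lo, lo)
  expect_equal(dia0$G_rel_kJ[dia0$state == "TS"], c(0, 0))
  expect_equal(attr(dia0, "ddG_DN_kJ"), 0)
  hi_bad <- mk_summary(0.12, 297, "high")
  hi_bad$temperature_K <- 293.15
  expect_error(build_energy_diagram(lo, hi_bad), "temperature")
})

test_that("trace -> arm -> ku0 pipeline recovers the water unfolding rate", {
  ku0_true <- 0.002
  m_ku_true <- 0.55
  urea <- c(7, 7.5, 8, 8.5, 9)
  errs <- vapply(1:100, function(s) {
    ks <- vapply(seq_along(urea), function(j) {
      k <- ku0_true * exp(m_ku_true * urea[j])
      tr <- sim_unfolding_trace(k, 1, 0.2,
                                time_s = seq(0, 60, by = 0.1),
                                noise_sd = 0.02, seed = 1000 * s + j)
      fit_unfolding_trace(tr)$k_obs
    }, numeric(1))
    arm <- fit_unfolding_arm(tibble::tibble(urea_M = urea, ku_per_s = ks))
    abs(arm$ku0 - ku0_true) / ku0_true
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})
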