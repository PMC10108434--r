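test_that("all generators are byte-identical under a repeated seed", {
  gens <- list(
    function(s) sim_equilibrium_curve(4.4, 5, 1, -0.01, 0.2, 0.005,
                                      seq(0, 9, 0.5), noise_sd = 0.02, seed = s),
    function(s) sim_unfolding_trace(0.1, 1, 0.2, seq(0, 60, 0.5),
                                    noise_sd = 0.02, seed = s),
    function(s) sim_salt_series(4, 9, c(0.05, 0.1, 0.2, 0.4, 0.8),
                                noise_sd = 0.1, seed = s),
    function(s) sim_relaxation_set(
      tibble::tibble(residue = 1:6, S2 = seq(0.6, 0.9, length.out = 6),
                     tau_e_s = seq(2e-11, 2e-10, length.out = 6)),
      noise_sd = 0.02, seed = s
    ),
    function(s) sim_alignment(n_seqs = 30, length = 15, charge_target = -5,
                              covarying_pair = c(4, 11), seed = s)
  )
  for (g in gens) {
    expect_identical(g(42), g(42))
    expect_false(identical(g(42), g(43)))
  }
  ens1 <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 1, resid = "ASP", occupancy = 0.5),
    n_frames = 20, n_runs = 2, seed = 7
  )
  ens2 <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 1, resid = "ASP", occupancy = 0.5),
    n_frames = 20, n_runs = 2, seed = 7
  )
  expect_identical(ens1$runs[[1]]$xyz, ens2$runs[[1]]$xyz)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(sim_salt_series(4, 9, c(0.1, 0.4), noise_sd = 1, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("noiseless equilibrium curve matches the closed form", {
  # midpoint: signal is the mean of the two baselines
  dG0 <- 4.4; m_eq <- 5; cm <- dG0 / m_eq
  c1 <- sim_equilibrium_curve(dG0, m_eq, 1, 0, 0.2, 0, urea_M = cm,
                              noise_sd = 0, seed = 1)
  expect_equal(c1$signal, (1 + 0.2) / 2)
  # dG0 -> +Inf: native baseline everywhere
  c2 <- sim_equilibrium_curve(1e6, m_eq, 1, -0.01, 0.2, 0,
                              urea_M = c(0, 3, 9), noise_sd = 0, seed = 1)
  expect_equal(c2$signal, 1 - 0.01 * c(0, 3, 9))
  # u = 9 M against an independent hand evaluation of the two-state expression
  c3 <- sim_equilibrium_curve(dG0, m_eq, 1, 0, 0.2, 0, urea_M = 9,
                              noise_sd = 0, seed = 1)
  expect_equal(c3$signal,
               oracle_two_state_signal(9, dG0, m_eq, 1, 0, 0.2, 0, 303.15),
               tolerance = 1e-12)
})

test_that("noiseless unfolding trace matches the exponential", {
  tr <- sim_unfolding_trace(0.1, 1, 0, time_s = c(0.001, 5, 10, 1000),
                            noise_sd = 0, seed = 1)
  expect_equal(tr$signal[3], exp(-1), tolerance = 1e-12)
  expect_equal(tr$signal[4], 0, tolerance = 1e-12)
  tr2 <- sim_unfolding_trace(0.1, 2, 0.5, time_s = c(1e-12, 1, 2),
                             noise_sd = 0, seed = 1)
  expect_equal(tr2$signal[1], 2.5, tolerance = 1e-9)
})

test_that("noiseless salt series follows the square-root law", {
  s <- sim_salt_series(2, 10, c(0, 0.25), noise_sd = 0, seed = 1)
  expect_equal(s$dG_kJ_mol, c(2, 7))
})

test_that("generator preconditions are enforced", {
  expect_error(sim_equilibrium_curve(4, 5, 1, 0, 0, 0, urea_M = -1,
                                     noise_sd = 0, seed = 1), "urea_M")
  expect_error(sim_equilibrium_curve(4, 5, 1, 0, 0, 0, urea_M = 11,
                                     noise_sd = 0, seed = 1), "10.5")
  expect_error(sim_equilibrium_curve(4, 5, 1, 0, 0, 0, urea_M = 5,
                                     noise_sd = -1, seed = 1), "noise_sd")
  expect_error(sim_unfolding_trace(0, 1, 0, 1:10, seed = 1), "k_u")
  expect_error(sim_salt_series(2, 10, -0.1, seed = 1), "ionic_strength_M")
  expect_error(sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 1, resid = "ASP", occupancy = 1.5),
    n_frames = 5, seed = 1
  ), "[Oo]ccupanc")
  expect_error(sim_relaxation_set(
    tibble::tibble(residue = 1, S2 = 1.2, tau_e_s = 1e-11), seed = 1
  ), "S2")
  expect_error(sim_alignment(n_seqs = 10, length = 8, charge_target = -20,
                             covarying_pair = c(2, 5), seed = 1),
               "impossible")
})

test_that("relaxation generator is exact at zero noise and respects limits", {
  # on-resonance spin lock: R1rho equals R2
  truth <- tibble::tibble(residue = 1, S2 = 0.85, tau_e_s = 5e-11)
  rec <- sim_relaxation_set(truth, noise_sd = 0, seed = 1)
  r1rho_on <- r1rho_from_r2(rec$R1, rec$R2, nu_SL_Hz = 2000, offset_Hz = 0)
  expect_equal(r1rho_on, rec$R2)
  # rigid rotor: generated NOE equals the closed form at S2 = 1
  rigid <- sim_relaxation_set(
    tibble::tibble(residue = 1, S2 = 1, tau_e_s = 0),
    tau_c = 5.76e-9, noise_sd = 0, seed = 1
  )
  expect_equal(rigid$NOE,
               predict_relaxation_rates(1, 0, 5.76e-9)$NOE, tolerance = 1e-12)
})

test_that("fitted-parameter uncertainty grows with generator noise", {
  noise_levels <- c(0.02, 0.1, 0.5)
  ses <- vapply(noise_levels, function(ns) {
    se <- vapply(1:20, function(s) {
      ser <- sim_salt_series(4, 9, seq(0.05, 0.8, length.out = 8),
                             noise_sd = ns, seed = s)
      fit_salt_model(ser, "sqrt_I")$slope_se
    }, numeric(1))
    mean(se)
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("toy trajectory honours forced and fractional occupancies", {
  ens <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = c(1, 2), resid = c("ASP", "GLU"),
                                 occupancy = c(1, 0)),
    n_frames = 25, seed = 11
  )
  st <- ion_contact_stats(ens)
  expect_equal(st$per_residue$mean_fraction[st$per_residue$resno == 1], 1)
  expect_equal(st$per_residue$mean_fraction[st$per_residue$resno == 2], 0)

  ens2 <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 1, resid = "ASP", occupancy = 0.5),
    n_frames = 500, seed = 12
  )
  st2 <- ion_contact_stats(ens2)
  se <- sqrt(0.5 * 0.5 / 500)
  expect_lt(abs(st2$per_residue$mean_fraction[1] - 0.5), 3 * se)
})

test_that("planted covarying pair is complementary and deterministic", {
  aln <- sim_alignment(n_seqs = 40, length = 12, charge_target = -4,
                       covarying_pair = c(3, 9), seed = 21)
  M <- do.call(rbind, strsplit(aln$sequence, ""))
  expect_true(all((M[, 3] == "N") == (M[, 9] == "S")))
  expect_setequal(unique(M[, 3]), c("N", "S"))
})

test_that("alignment charge target is met in expectation", {
  aln <- sim_alignment(n_seqs = 100, length = 25, charge_target = -10,
                       covarying_pair = c(5, 20), seed = 31)
  cs <- alignment_charge_stats(aln)
  # per-sequence SD is sqrt(2) (two balanced K/E columns)
  expect_lt(abs(cs$summary$mean_net_charge - (-10)),
            3 * sqrt(2) / sqrt(100))
})
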