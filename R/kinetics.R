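#' Fit a single-exponential unfolding trace
#'
#' Least-squares fit of `signal(t) = offset + amplitude * exp(-k * t)` to a
#' fluorescence time course, the model for two-state unfolding after a jump to
#' high denaturant. Starting values come from a log-linear regression on the
#' baseline-subtracted signal; refinement uses Levenberg-Marquardt.
#'
#' @param data Data frame with columns `time_s` (strictly increasing) and
#'   `signal`; at least 10 points.
#' @return Object of class `exp_trace_fit`: list with `k_obs`, `amplitude`,
#'   `offset`, standard errors, `rss`, and the `nls` fit.
#' @export
#' @examples
#' tr <- sim_unfolding_trace(k_u = 0.1, amplitude = 1, offset = 0.2,
#'                           time_s = seq(0, 60, by = 0.5), noise_sd = 0,
#'                           seed = 1)
#' fit_unfolding_trace(tr)$k_obs # 0.1
fit_unfolding_trace <- function(data) {
  stopifnot(is.data.frame(data), all(c("time_s", "signal") %in% names(data)))
  t <- data$time_s
  y <- data$signal
  check_numeric_vec(t, "time_s", min_len = 10)
  check_numeric_vec(y, "signal", min_len = 10)
  if (any(diff(t) <= 0)) abort("`time_s` must be strictly increasing.")

  noise_hat <- stats::sd(diff(y, differences = 2)) / sqrt(6)
  if (!is.finite(noise_hat)) noise_hat <- 0
  if (diff(range(y)) <= 3 * noise_hat || diff(range(y)) == 0) {
    abort("No decay detected: trace is flat within noise.")
  }

  # start values: offset ~ tail mean; log-linear fit for k and amplitude
  off0 <- mean(tail(y, max(3, length(y) %/% 10)))
  amp_sgn <- if (y[1] >= off0) 1 else -1
  z <- amp_sgn * (y - off0)
  pos <- z > 0
  if (sum(pos) >= 3) {
    ll <- lm(log(z[pos]) ~ t[pos])
    k0 <- max(-coef(ll)[[2]], 1e-4)
    a0 <- amp_sgn * exp(coef(ll)[[1]])
  } else {
    k0 <- 1 / max(t)
    a0 <- y[1] - off0
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-k * t),
      data = df, start = list(offset = off0, amplitude = a0, k = k0),
      lower = c(-Inf, -Inf, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) abort(paste("Exponential fit failed:", conditionMessage(e)))
  )
  cf <- summary(fit)$coefficients
  k_obs <- cf["k", "Estimate"]
  if (k_obs <= 2e-8 || k_obs > 1e6) {
    abort("Fitted rate at search bound; trace does not resolve a decay.")
  }
  structure(
    list(
      k_obs = k_obs, k_obs_se = cf["k", "Std. Error"],
      amplitude = cf["amplitude", "Estimate"],
      amplitude_se = cf["amplitude", "Std. Error"],
      offset = cf["offset", "Estimate"],
      offset_se = cf["offset", "Std. Error"],
      rss = sum(stats::resid(fit)^2),
      fit = fit,
      data = tibble(time_s = t, signal = y)
    ),
    class = "exp_trace_fit"
  )
}

#' @export
print.exp_trace_fit <- function(x, ...) {
  cat(sprintf("<exp_trace_fit> k_obs = %.4g s^-1 (SE %.2g), amplitude = %.3g, offset = %.3g\n",
              x$k_obs, x$k_obs_se, x$amplitude, x$offset))
  invisible(x)
}

#' Fit the unfolding arm of a chevron plot
#'
#' Ordinary least squares of `ln k_u` on urea concentration over the unfolding
#' limb, giving the kinetic m-value (`m_ku`, slope) and the water unfolding
#' rate by extrapolation (`ku0 = exp(intercept)`).
#'
#' @param data Data frame with columns `urea_M` and `ku_per_s` (> 0); at least
#'   3 urea values on the unfolding limb.
#' @return Object of class `chevron_arm_fit`: list with `ln_ku0`, `m_ku`,
#'   standard errors, covariance of (intercept, slope), `ku0`, `ku0_se`
#'   (delta method), `r_squared`, and the `lm` fit.
#' @export
#' @examples
#' pts <- tibble::tibble(urea_M = 7:9, ku_per_s = exp(-6 + 0.5 * (7:9)))
#' fit_unfolding_arm(pts)$m_ku # 0.5
fit_unfolding_arm <- function(data) {
  stopifnot(is.data.frame(data), all(c("urea_M", "ku_per_s") %in% names(data)))
  u <- data$urea_M
  k <- data$ku_per_s
  check_numeric_vec(u, "urea_M", lower = 0, min_len = 3)
  check_numeric_vec(k, "ku_per_s", lower = 0, strict_lower = TRUE, min_len = 3)
  fit <- lm(log(k) ~ u)
  cf <- summary(fit)$coefficients
  ln_ku0 <- cf[1, 1]
  structure(
    list(
      ln_ku0 = ln_ku0, ln_ku0_se = cf[1, 2],
      m_ku = cf[2, 1], m_ku_se = cf[2, 2],
      cov = vcov(fit),
      ku0 = exp(ln_ku0), ku0_se = exp(ln_ku0) * cf[1, 2],
      r_squared = summary(fit)$r.squared,
      urea_range = range(u),
      fit = fit,
      data = tibble(urea_M = u, ku_per_s = k)
    ),
    class = "chevron_arm_fit"
  )
}

#' @export
print.chevron_arm_fit <- function(x, ...) {
  cat(sprintf("<chevron_arm_fit> ln ku = %.4f + %.4f * [urea] (fit over %.3g-%.3g M)\n",
              x$ln_ku0, x$m_ku, x$urea_range[1], x$urea_range[2]))
  cat(sprintf("  ku0 = %.4g s^-1 (SE %.2g)\n", x$ku0, x$ku0_se))
  invisible(x)
}

#' Derive the folding rate from the unfolding rate and equilibrium stability
#'
#' `kf0 = ku0 * exp(dG0 / RT)` with `dG0` the unfolding free energy
#' (native-to-denatured, positive when folded is favoured), i.e.
#' `kf/ku = K_eq(D->N)`. The standard error is propagated to first order from
#' independent errors on `ku0` and `dG0`.
#'
#' @param ku0 Water unfolding rate, s^-1 (> 0).
#' @param dG0 Unfolding free energy, kJ/mol.
#' @param temperature_K Temperature, Kelvin.
#' @param ku0_se,dG0_se Optional standard errors for propagation.
#' @return Tibble with `kf0` and `kf0_se`.
#' @export
#' @examples
#' derive_folding_rate(ku0 = 1, dG0 = 10, temperature_K = 298.15)$kf0 # ~56.5
derive_folding_rate <- function(ku0, dG0, temperature_K,
                                ku0_se = 0, dG0_se = 0) {
  check_number(ku0, "ku0", lower = 0, strict_lower = TRUE)
  check_number(dG0, "dG0")
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  RT <- .R_kJ * temperature_K
  kf0 <- ku0 * exp(dG0 / RT)
  # delta method: var(kf) = (dkf/dku)^2 var(ku) + (dkf/ddG)^2 var(dG)
  kf0_se <- kf0 * sqrt((ku0_se / ku0)^2 + (dG0_se / RT)^2)
  tibble(kf0 = kf0, kf0_se = kf0_se)
}

#' Tanford beta value from kinetic and equilibrium m-values
#'
#' `beta_urea = 1 - RT * m_ku / m_eq`: the fraction of the equilibrium
#' denaturant sensitivity accrued between the denatured state and the
#' transition state. `m_ku` is the slope of `ln k_u` versus urea (M^-1); the
#' factor RT converts it onto the free-energy scale of `m_eq` (kJ/mol/M).
#' Values near 1 indicate a compact, native-like transition state.
#'
#' @param m_ku Unfolding-arm slope, M^-1.
#' @param m_eq Equilibrium m-value, kJ/mol/M (> 0).
#' @param temperature_K Temperature, Kelvin.
#' @param m_ku_se,m_eq_se Optional standard errors for propagation.
#' @return Tibble with `beta_urea` and `beta_urea_se`.
#' @export
#' @examples
#' compute_beta_urea(m_ku = 0.177, m_eq = 5, temperature_K = 303.15) # ~0.911
compute_beta_urea <- function(m_ku, m_eq, temperature_K,
                              m_ku_se = 0, m_eq_se = 0) {
  check_number(m_ku, "m_ku")
  check_number(m_eq, "m_eq", lower = 0, strict_lower = TRUE)
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  RT <- .R_kJ * temperature_K
  beta <- 1 - RT * m_ku / m_eq
  ratio <- RT * m_ku / m_eq
  beta_se <- abs(ratio) * sqrt(
    ifelse(m_ku == 0, 0, (m_ku_se / m_ku)^2) + (m_eq_se / m_eq)^2
  )
  tibble(beta_urea = beta, beta_urea_se = beta_se)
}

#' Salt-induced free-energy decomposition and the salt Phi-value
#'
#' From folding/unfolding rates at a low- and a high-salt condition:
#' * `ddG_Ddagger = -RT * ln(kf_high / kf_low)` - change in the
#'   denatured-to-transition-state barrier caused by salt;
#' * `ddG_DN = -RT * ln((kf_high/ku_high) / (kf_low/ku_low))` - change in
#'   equilibrium stability (denatured-to-native);
#' * `phi_f_salt = ddG_Ddagger / ddG_DN` - the fraction of the equilibrium
#'   salt effect already present at the transition state. Phi > 1 means the
#'   transition state gains more from salt than the native state does.
#'
#' Phi is reported as `NA` (with `phi_defined = FALSE`) when `|ddG_DN|` falls
#' below `tol_kJ`, where the ratio is numerically meaningless.
#'
#' An optional equilibrium-route denominator can be supplied via
#' `ddG_DN_equilibrium` (e.g. the difference of equilibrium dG0 fits at the
#' two salt conditions); then `phi_f_salt_eq` is also returned. The kinetic
#' and equilibrium routes agree exactly when the equilibrium constant equals
#' kf/ku.
#'
#' @param kf_low,kf_high Folding rates at low/high salt, s^-1.
#' @param ku_low,ku_high Unfolding rates at low/high salt, s^-1.
#' @param temperature_K Temperature, Kelvin.
#' @param ddG_DN_equilibrium Optional equilibrium-measured ddG_DN (kJ/mol).
#' @param tol_kJ Tolerance below which Phi is flagged undefined (default 0.1).
#' @param kf_low_se,kf_high_se,ku_low_se,ku_high_se Optional standard errors.
#' @return Tibble with `ddG_Ddagger_kJ`, `ddG_DN_kJ`, `phi_f_salt`, their
#'   standard errors, `phi_defined`, and (if requested) `phi_f_salt_eq`.
#' @export
#' @examples
#' # Fyn R40N, 0 -> 600 mM NaCl at 293.15 K
#' compute_salt_ddG(kf_low = 5.5, kf_high = 25, ku_low = 0.08, ku_high = 0.09,
#'                  temperature_K = 293.15)
compute_salt_ddG <- function(kf_low, kf_high, ku_low, ku_high, temperature_K,
                             ddG_DN_equilibrium = NULL, tol_kJ = 0.1,
                             kf_low_se = 0, kf_high_se = 0,
                             ku_low_se = 0, ku_high_se = 0) {
  for (nm in c("kf_low", "kf_high", "ku_low", "ku_high")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  RT <- .R_kJ * temperature_K
  ddG_dagger <- -RT * log(kf_high / kf_low)
  ddG_DN <- -RT * log((kf_high / ku_high) / (kf_low / ku_low))
  # delta method on the logs: var(-RT ln k) = (RT)^2 (se/k)^2
  rel2 <- function(se, k) (se / k)^2
  ddG_dagger_se <- RT * sqrt(rel2(kf_low_se, kf_low) + rel2(kf_high_se, kf_high))
  ddG_DN_se <- RT * sqrt(rel2(kf_low_se, kf_low) + rel2(kf_high_se, kf_high) +
                           rel2(ku_low_se, ku_low) + rel2(ku_high_se, ku_high))
  defined <- abs(ddG_DN) >= tol_kJ
  phi <- if (defined) ddG_dagger / ddG_DN else NA_real_
  phi_se <- if (defined && abs(ddG_dagger) > 0) {
    abs(phi) * sqrt((ddG_dagger_se / ddG_dagger)^2 + (ddG_DN_se / ddG_DN)^2)
  } else {
    NA_real_
  }
  out <- tibble(
    ddG_Ddagger_kJ = ddG_dagger, ddG_Ddagger_se = ddG_dagger_se,
    ddG_DN_kJ = ddG_DN, ddG_DN_se = ddG_DN_se,
    phi_f_salt = phi, phi_f_salt_se = phi_se,
    phi_defined = defined
  )
  if (!is.null(ddG_DN_equilibrium)) {
    check_number(ddG_DN_equilibrium, "ddG_DN_equilibrium")
    out$phi_f_salt_eq <- if (abs(ddG_DN_equilibrium) >= tol_kJ) {
      ddG_dagger / ddG_DN_equilibrium
    } else {
      NA_real_
    }
  }
  out
}

#' Ionic-strength dependence of the unfolding rate
#'
#' Least squares of `ln k_u` on the square root of ionic strength; under
#' Debye-Hueckel screening of the unfolding barrier the relationship is
#' linear.
#'
#' @param data Data frame with columns `ionic_strength_M` (> 0) and
#'   `ku_per_s` (> 0); at least 3 points.
#' @return Tibble with `slope`, `intercept`, their standard errors, and
#'   `r_squared`.
#' @export
#' @examples
#' d <- tibble::tibble(ionic_strength_M = c(0.09, 0.25, 0.49),
#'                     ku_per_s = exp(1 + 2 * sqrt(c(0.09, 0.25, 0.49))))
#' fit_lnk_vs_sqrt_ionic_strength(d)
fit_lnk_vs_sqrt_ionic_strength <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("ionic_strength_M", "ku_per_s") %in% names(data)))
  I <- data$ionic_strength_M
  k <- data$ku_per_s
  check_numeric_vec(I, "ionic_strength_M", lower = 0, strict_lower = TRUE,
                    min_len = 3)
  check_numeric_vec(k, "ku_per_s", lower = 0, strict_lower = TRUE, min_len = 3)
  fit <- lm(log(k) ~ sqrt(I))
  cf <- summary(fit)$coefficients
  tibble(
    intercept = cf[1, 1], intercept_se = cf[1, 2],
    slope = cf[2, 1], slope_se = cf[2, 2],
    r_squared = summary(fit)$r.squared
  )
}

#' Assemble a folding summary for one salt condition
#'
#' Bundles the unfolding-arm fit with the equilibrium parameters into the
#' per-condition summary: extrapolated `ku0`, derived `kf0`, m-values,
#' `beta_urea`, all with first-order propagated errors.
#'
#' @param arm A [fit_unfolding_arm()] result.
#' @param dG0,m_eq Equilibrium stability (kJ/mol) and m-value (kJ/mol/M).
#' @param temperature_K Temperature, Kelvin.
#' @param dG0_se,m_eq_se Optional standard errors.
#' @param condition Label for the salt condition (e.g. "0 mM NaCl").
#' @return Tibble of class `folding_summary` with one row: `condition`, `ku0`,
#'   `kf0`, `m_eq`, `m_ku`, `beta_urea`, `temperature_K` and standard errors.
#' @export
folding_summary <- function(arm, dG0, m_eq, temperature_K,
                            dG0_se = 0, m_eq_se = 0, condition = "") {
  stopifnot(inherits(arm, "chevron_arm_fit"))
  kf <- derive_folding_rate(arm$ku0, dG0, temperature_K,
                            ku0_se = arm$ku0_se, dG0_se = dG0_se)
  beta <- compute_beta_urea(arm$m_ku, m_eq, temperature_K,
                            m_ku_se = arm$m_ku_se, m_eq_se = m_eq_se)
  out <- tibble(
    condition = condition,
    ku0 = arm$ku0, ku0_se = arm$ku0_se,
    kf0 = kf$kf0, kf0_se = kf$kf0_se,
    dG0 = dG0, dG0_se = dG0_se,
    m_eq = m_eq, m_eq_se = m_eq_se,
    m_ku = arm$m_ku, m_ku_se = arm$m_ku_se,
    beta_urea = beta$beta_urea, beta_urea_se = beta$beta_urea_se,
    temperature_K = temperature_K
  )
  class(out) <- c("folding_summary", class(out))
  out
}

#' Relative free-energy diagram for two salt conditions
#'
#' Places the denatured state at 0 for both conditions and reports only
#' differences that are independent of the (unknowable) kinetic prefactor:
#' the transition-state levels are expressed relative to the low-salt barrier,
#' and `dG_DN = -RT ln(kf0/ku0)` per condition. Consistent by construction
#' with [compute_salt_ddG()] on the same rates.
#'
#' @param low,high [folding_summary()] rows for the two conditions (same
#'   temperature).
#' @return Tibble with columns `state` (D, TS, N), `condition`, `G_rel_kJ`
#'   (D = 0; TS relative to the low-salt barrier; N = dG_DN), plus attributes
#'   `ddG_Ddagger_kJ` and `ddG_DN_kJ` (high minus low).
#' @export
build_energy_diagram <- function(low, high) {
  stopifnot(inherits(low, "folding_summary"), inherits(high, "folding_summary"))
  if (!isTRUE(all.equal(low$temperature_K, high$temperature_K))) {
    abort("Energy diagram requires both summaries at the same temperature.")
  }
  RT <- .R_kJ * low$temperature_K
  # barrier relative to low-salt barrier: prefactor cancels in the difference
  dTS <- -RT * log(high$kf0 / low$kf0)
  dDN <- function(s) -RT * log(s$kf0 / s$ku0)
  out <- tibble(
    state = rep(c("D", "TS", "N"), 2),
    condition = rep(c(low$condition, high$condition), each = 3),
    G_rel_kJ = c(0, 0, dDN(low), 0, dTS, dDN(high))
  )
  attr(out, "ddG_Ddagger_kJ") <- dTS
  attr(out, "ddG_DN_kJ") <- dDN(high) - dDN(low)
  out
}
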