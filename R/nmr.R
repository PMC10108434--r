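#' Combined 1H/15N chemical shift perturbation
#'
#' `csp = sqrt((0.1 * dN)^2 + dH^2)`: the usual weighted Euclidean distance in
#' the HSQC plane, with the nitrogen shift scaled by 0.1 to account for the
#' wider 15N chemical shift range.
#'
#' @param dH 1H shift difference, ppm (vectorised).
#' @param dN 15N shift difference, ppm.
#' @return CSP in ppm, `>= 0`, zero iff both inputs are zero.
#' @export
#' @examples
#' compute_csp(0.3, 1.0) # sqrt(0.09 + 0.01) = 0.3162
compute_csp <- function(dH, dN) {
  stopifnot(is.numeric(dH), is.numeric(dN), length(dH) == length(dN))
  sqrt((0.1 * dN)^2 + dH^2)
}

#' Convert an off-resonance R1rho to R2
#'
#' Off-resonance rotating-frame relaxation mixes longitudinal and transverse
#' rates: `R1rho = R1 cos^2(theta) + R2 sin^2(theta)` with tilt angle
#' `theta = atan(nu_SL / Omega)`. Solving for R2:
#' `R2 = (R1rho - R1 cos^2(theta)) / sin^2(theta)`. As the offset `Omega`
#' goes to 0 the spin lock is on resonance (theta = 90 deg) and R2 = R1rho.
#'
#' @param R1 Longitudinal rate, s^-1 (vectorised).
#' @param R1rho Rotating-frame rate, s^-1.
#' @param nu_SL_Hz Spin-lock field strength, Hz (> 0).
#' @param offset_Hz Resonance offset from the 15N carrier, Hz.
#' @return R2 in s^-1. Inputs implying `R2 <= 0` raise an error (they are
#'   physically inconsistent).
#' @export
#' @examples
#' r2_from_r1rho(R1 = 1, R1rho = 5, nu_SL_Hz = 2000, offset_Hz = 2000) # 9
r2_from_r1rho <- function(R1, R1rho, nu_SL_Hz, offset_Hz) {
  stopifnot(is.numeric(R1), is.numeric(R1rho))
  if (any(nu_SL_Hz <= 0)) abort("`nu_SL_Hz` must be > 0.")
  theta <- atan2(nu_SL_Hz, offset_Hz)
  s2 <- sin(theta)^2
  c2 <- cos(theta)^2
  R2 <- (R1rho - R1 * c2) / s2
  if (any(R2 <= 0)) {
    abort("Inconsistent rates: R1rho <= R1 cos^2(theta) implies R2 <= 0.")
  }
  R2
}

#' Compose R1rho from R1 and R2 (forward direction)
#'
#' Inverse of [r2_from_r1rho()]; used by the synthetic generator.
#' @inheritParams r2_from_r1rho
#' @param R2 Transverse rate, s^-1.
#' @return R1rho in s^-1.
#' @export
r1rho_from_r2 <- function(R1, R2, nu_SL_Hz, offset_Hz) {
  if (any(nu_SL_Hz <= 0)) abort("`nu_SL_Hz` must be > 0.")
  theta <- atan2(nu_SL_Hz, offset_Hz)
  R1 * cos(theta)^2 + R2 * sin(theta)^2
}

#' Lipari-Szabo spectral density
#'
#' Model-free form with an order parameter and one internal correlation time:
#' `J(w) = (2/5) * (S2 * tc / (1 + (w tc)^2) + (1 - S2) * tau / (1 + (w tau)^2))`
#' where `1/tau = 1/tc + 1/te`. Isotropic overall tumbling.
#'
#' @param omega Angular frequency, rad/s (vectorised).
#' @param S2 Generalised order parameter, in `[0, 1]`.
#' @param tau_e Effective internal correlation time, s (`0 < tau_e < tau_c`).
#' @param tau_c Global rotational correlation time, s.
#' @return J(omega) in s/rad.
#' @export
#' @examples
#' spectral_density(0, S2 = 0.8, tau_e = 50e-12, tau_c = 5.76e-9) # ~1.847e-9
spectral_density <- function(omega, S2, tau_e, tau_c) {
  check_number(S2, "S2", lower = 0, upper = 1)
  check_number(tau_c, "tau_c", lower = 0, strict_lower = TRUE)
  check_number(tau_e, "tau_e", lower = 0)
  tau <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
  internal <- if (tau_e > 0) (1 - S2) * tau / (1 + (omega * tau)^2) else 0
  (2 / 5) * (S2 * tau_c / (1 + (omega * tau_c)^2) + internal)
}

#' Predict 15N R1, R2 and heteronuclear NOE from model-free parameters
#'
#' Standard dipolar + CSA expressions for an amide 15N relaxed by its attached
#' proton, with the Lipari-Szabo spectral density:
#' \deqn{R1 = (d^2/4)[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c^2 J(wN)}
#' \deqn{R2 = (d^2/8)[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)]
#'        + (c^2/6)[4 J(0) + 3 J(wN)]}
#' \deqn{NOE = 1 + (d^2/4)(gH/gN)[6 J(wH+wN) - J(wH-wN)] / R1}
#' `d` and `c` come from the spectrometer configuration (bond length, CSA,
#' field).
#'
#' @param S2,tau_e,tau_c Model-free parameters (see [spectral_density()]).
#' @param config A [spectrometer_config()].
#' @return Tibble with columns `R1`, `R2`, `NOE`.
#' @export
#' @examples
#' predict_relaxation_rates(S2 = 0.85, tau_e = 50e-12, tau_c = 5.76e-9)
predict_relaxation_rates <- function(S2, tau_e, tau_c,
                                     config = spectrometer_config()) {
  stopifnot(inherits(config, "spectrometer_config"))
  # frequency magnitudes (the 15N Larmor frequency is negative); the sign of
  # gamma_N enters only through the gamma_H/gamma_N factor in the NOE
  wH <- abs(config$omega_H)
  wN <- abs(config$omega_N)
  J <- function(w) spectral_density(abs(w), S2, tau_e, tau_c)
  d2 <- config$d^2
  c2 <- config$c^2
  R1 <- (d2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- (d2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                      6 * J(wH + wN)) +
    (c2 / 6) * (4 * J(0) + 3 * J(wN))
  NOE <- 1 + (d2 / 4) * (.gamma_H / .gamma_N) *
    (6 * J(wH + wN) - J(wH - wN)) / R1
  tibble(R1 = R1, R2 = R2, NOE = NOE)
}

# unvalidated vectorised J and rate prediction for the optimiser hot loop;
# must stay numerically identical to spectral_density()/predict_relaxation_rates()
.J_fast <- function(omega, S2, tau_e, tau_c) {
  tau <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
  internal <- if (tau_e > 0) (1 - S2) * tau / (1 + (omega * tau)^2) else 0
  (2 / 5) * (S2 * tau_c / (1 + (omega * tau_c)^2) + internal)
}

.rates_fast <- function(S2, tau_e, tau_c, config) {
  wH <- abs(config$omega_H)
  wN <- abs(config$omega_N)
  J <- .J_fast(abs(c(0, wN, wH - wN, wH, wH + wN)), S2, tau_e, tau_c)
  d2 <- config$d^2
  c2 <- config$c^2
  R1 <- (d2 / 4) * (J[3] + 3 * J[2] + 6 * J[5]) + c2 * J[2]
  R2 <- (d2 / 8) * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] + 6 * J[5]) +
    (c2 / 6) * (4 * J[1] + 3 * J[2])
  NOE <- 1 + (d2 / 4) * (.gamma_H / .gamma_N) * (6 * J[5] - J[3]) / R1
  c(R1, R2, NOE)
}

# weighted residual vector of one residue's rates against model-free predictions
.mf_resid <- function(par, obs, sigma, tau_c, config) {
  S2 <- min(max(par[1], 0), 1)
  tau_e <- max(par[2], 0) * 1e-12 # optimiser works in ps
  pred <- .rates_fast(S2, tau_e, tau_c, config)
  (obs - pred) / sigma
}

# best (S2, tau_e) for one residue at fixed tau_c: coarse grid start +
# bounded Levenberg-Marquardt (auto-scales the badly conditioned S2/tau_e pair)
.fit_residue <- function(obs, sigma, tau_c, config) {
  # grid stays off the S2 = 1 boundary: there tau_e drops out of the model and
  # Levenberg-Marquardt cannot leave the resulting degenerate ridge
  grid <- expand.grid(
    S2 = seq(0.3, 0.95, by = 0.05),
    tau_e_ps = c(1, 10, 30, 100, 300, 1000, 3000)
  )
  vals <- apply(grid, 1, function(g) {
    sum(.mf_resid(c(g[1], g[2]), obs, sigma, tau_c, config)^2)
  })
  # multi-start from the best grid points over distinct S2 values
  ord <- order(vals)
  starts <- ord[!duplicated(grid$S2[ord])][1:4]
  starts <- starts[!is.na(starts)]
  best <- NULL
  for (s in starts) {
    opt <- minpack.lm::nls.lm(
      as.numeric(grid[s, ]), fn = .mf_resid,
      obs = obs, sigma = sigma, tau_c = tau_c, config = config,
      lower = c(0, 1e-3), upper = c(1, tau_c * 0.999 * 1e12),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           gtol = 0, maxiter = 500)
    )
    if (is.null(best) || opt$deviance < best$deviance) best <- opt
  }
  list(S2 = best$par[1], tau_e = best$par[2] * 1e-12, chisq = best$deviance)
}

#' Fit Lipari-Szabo "model 2" to per-residue relaxation rates
#'
#' Per residue, minimises `chi^2 = sum(((obs - calc)/sigma)^2)` over the order
#' parameter S2 and internal correlation time tau_e at a fixed global tumbling
#' time tau_c; tau_c itself is optimised by an outer one-dimensional Brent
#' search over `tau_c_range`, minimising the total chi-square over all
#' residues. S2 is constrained to `[0, 1]`.
#'
#' Residues whose R2 < R1 are physically inconsistent with nanosecond tumbling
#' and are excluded with a warning before fitting.
#'
#' @param records Data frame with columns `residue`, `R1`, `R2`, `NOE` and
#'   optionally per-rate errors `R1_err`, `R2_err`, `NOE_err` (used as chi-square
#'   sigmas; equal weights when absent). If `R2` is missing but `R1rho`,
#'   `nu_SL_Hz` and `offset_Hz` are present, R2 is computed via
#'   [r2_from_r1rho()] first. At least 5 residues.
#' @param config A [spectrometer_config()].
#' @param tau_c_range Bracket for the global tumbling time, in ns. Default
#'   `c(1, 20)`.
#' @param tau_c_tol Brent tolerance on tau_c, ns. Default 1e-7.
#' @return Object of class `model_free_fit`: list with `tau_c` (s),
#'   `tau_c_ns`, per-residue tibble `params` (`residue`, `S2`, `tau_e_s`,
#'   `chisq`), `total_chisq`, `excluded` (residues dropped as inconsistent).
#' @export
#' @examples
#' truth <- tibble::tibble(residue = 1:6, S2 = seq(0.6, 0.95, length.out = 6),
#'                         tau_e_s = seq(20e-12, 200e-12, length.out = 6))
#' rec <- sim_relaxation_set(truth, tau_c = 5.76e-9, noise_sd = 0, seed = 1)
#' fit <- fit_model2(rec)
#' fit$tau_c_ns # ~5.76
fit_model2 <- function(records, config = spectrometer_config(),
                       tau_c_range = c(1, 20), tau_c_tol = 1e-7) {
  stopifnot(is.data.frame(records))
  records <- as_tibble(records)
  if (!"R2" %in% names(records)) {
    need <- c("R1rho", "nu_SL_Hz", "offset_Hz")
    if (!all(need %in% names(records))) {
      abort("`records` needs either an R2 column or (R1rho, nu_SL_Hz, offset_Hz).")
    }
    records$R2 <- r2_from_r1rho(records$R1, records$R1rho,
                                records$nu_SL_Hz, records$offset_Hz)
  }
  need <- c("residue", "R1", "R2", "NOE")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns residue, R1, R2 (or R1rho...), NOE.")
  }
  if (anyNA(records[need])) abort("Missing rates in `records`.")
  bad <- records$R2 < records$R1
  if (any(bad)) {
    warn(sprintf(
      "Excluding %d residue(s) with R2 < R1 (inconsistent with ns tumbling): %s",
      sum(bad), paste(records$residue[bad], collapse = ", ")
    ))
  }
  excluded <- records$residue[bad]
  records <- records[!bad, ]
  if (nrow(records) < 5) abort("Need at least 5 consistent residues.")

  getcol <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(1, nrow(records))
  }
  sig <- cbind(getcol("R1_err"), getcol("R2_err"), getcol("NOE_err"))
  if (any(sig <= 0)) abort("Rate errors must be positive.")

  obs_list <- purrr::map(seq_len(nrow(records)), function(i) {
    c(records$R1[i], records$R2[i], records$NOE[i])
  })
  total_chisq <- function(tau_c_ns) {
    tau_c <- tau_c_ns * 1e-9
    sum(purrr::map_dbl(seq_along(obs_list), function(i) {
      .fit_residue(obs_list[[i]], sig[i, ], tau_c, config)$chisq
    }))
  }
  # two-stage Brent search: a coarse pass over the full bracket, then a
  # refinement on the *offset* from the coarse minimum (Brent's attainable
  # precision has a sqrt(eps)*|x| floor, which the offset parametrisation
  # removes since |x| ~ 0 at the refined minimum)
  coarse <- optimize(total_chisq, interval = tau_c_range, tol = 1e-4)
  halfwin <- 5e-4
  fine <- optimize(function(d) total_chisq(coarse$minimum + d),
                   interval = c(-halfwin, halfwin), tol = tau_c_tol)
  opt <- list(minimum = coarse$minimum + fine$minimum,
              objective = fine$objective)
  tau_c <- opt$minimum * 1e-9
  res <- purrr::map(seq_along(obs_list), function(i) {
    f <- .fit_residue(obs_list[[i]], sig[i, ], tau_c, config)
    tibble(residue = records$residue[i], S2 = f$S2, tau_e_s = f$tau_e,
           chisq = f$chisq)
  }) |> purrr::list_rbind()
  structure(
    list(
      tau_c = tau_c, tau_c_ns = opt$minimum,
      params = res,
      total_chisq = opt$objective,
      excluded = excluded,
      config = config
    ),
    class = "model_free_fit"
  )
}

#' @export
print.model_free_fit <- function(x, ...) {
  cat(sprintf("<model_free_fit> tau_c = %.4f ns, %d residues, total chi^2 = %.3g\n",
              x$tau_c_ns, nrow(x$params), x$total_chisq))
  if (length(x$excluded)) {
    cat("  excluded (R2 < R1):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
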