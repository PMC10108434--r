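#' Two-state equilibrium signal model (linear extrapolation method)
#'
#' Predicted fluorescence of a two-state folder with linear native and
#' denatured baselines:
#' `signal(u) = (F_N + a*u + (F_D + b*u) * K(u)) / (1 + K(u))` with
#' `K(u) = exp(-(dG0 - m_eq*u) / RT)`, the native-to-denatured equilibrium
#' constant under the linear extrapolation method. `dG0 > 0` means the folded
#' state is favoured in water.
#'
#' @param urea_M Urea concentrations (M).
#' @param dG0 Unfolding free energy at 0 M urea, kJ/mol.
#' @param m_eq Equilibrium m-value, kJ/mol/M (> 0 for a cooperative unfolder).
#' @param bn_int,bn_slope Native baseline intercept and slope (signal units).
#' @param bd_int,bd_slope Denatured baseline intercept and slope.
#' @param temperature_K Temperature in Kelvin.
#'
#' @return Predicted signal, same length as `urea_M`.
#' @export
#' @examples
#' # at the midpoint Cm = dG0/m_eq the signal is the mean of the baselines
#' two_state_signal(0.88, dG0 = 4.4, m_eq = 5, bn_int = 1, bn_slope = 0,
#'                  bd_int = 0.2, bd_slope = 0, temperature_K = 303.15)
two_state_signal <- function(urea_M, dG0, m_eq, bn_int, bn_slope,
                             bd_int, bd_slope, temperature_K = 303.15) {
  check_numeric_vec(urea_M, "urea_M", lower = 0)
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  RT <- .R_kJ * temperature_K
  K <- exp(-(dG0 - m_eq * urea_M) / RT)
  (bn_int + bn_slope * urea_M + (bd_int + bd_slope * urea_M) * K) / (1 + K)
}

#' Fraction of molecules in the native state
#'
#' `f_N(u) = 1 / (1 + K(u))` under the two-state linear extrapolation model;
#' exactly 1/2 at the midpoint `Cm = dG0/m_eq`.
#'
#' @inheritParams two_state_signal
#' @return Fraction folded, same length as `urea_M`.
#' @export
fraction_folded <- function(urea_M, dG0, m_eq, temperature_K = 303.15) {
  RT <- .R_kJ * temperature_K
  1 / (1 + exp(-(dG0 - m_eq * urea_M) / RT))
}

#' Fit a two-state equilibrium denaturation curve
#'
#' Nonlinear least squares of the six-parameter linear-extrapolation model
#' (stability, m-value, two linear baselines) to a fluorescence melt. Fitting
#' is multi-start from a deterministic grid over (dG0, m_eq); the start with
#' the lowest residual sum of squares wins. Standard errors come from the
#' least-squares covariance matrix.
#'
#' @param data Data frame with columns `urea_M` and `signal`; at least 6 points
#'   spanning the transition.
#' @param temperature_K Temperature of the melt in Kelvin (default 303.15 K,
#'   i.e. 30 C plate-reader conditions).
#'
#' @return An object of class `two_state_eq_fit`: a list with `estimate`
#'   (tibble of parameter estimates and standard errors), `dG0`, `m_eq`, `Cm`,
#'   `rss`, `temperature_K`, `data`, and the underlying `nls` fit.
#' @export
#' @examples
#' curve <- sim_equilibrium_curve(
#'   dG0 = 4.4, m_eq = 5, bn_int = 1, bn_slope = 0, bd_int = 0.2, bd_slope = 0,
#'   urea_M = seq(0, 9, by = 0.5), noise_sd = 0, seed = 1
#' )
#' fit <- fit_equilibrium_curve(curve)
#' fit$dG0 # ~ 4.4
fit_equilibrium_curve <- function(data, temperature_K = NULL) {
  stopifnot(is.data.frame(data), all(c("urea_M", "signal") %in% names(data)))
  temperature_K <- temperature_K %||% attr(data, "temperature_K") %||% 303.15
  u <- data$urea_M
  y <- data$signal
  check_numeric_vec(u, "urea_M", lower = 0, min_len = 6)
  check_numeric_vec(y, "signal", min_len = 6)
  if (length(u) != length(y)) abort("`urea_M` and `signal` differ in length.")

  # transition detectability: signal range must exceed 3x the point noise,
  # estimated from second differences (variance inflation factor sqrt(6))
  ord <- order(u)
  u <- u[ord]; y <- y[ord]
  noise_hat <- stats::sd(diff(y, differences = 2)) / sqrt(6)
  if (!is.finite(noise_hat)) noise_hat <- 0
  if (diff(range(y)) <= 3 * noise_hat || diff(range(y)) == 0) {
    abort("No transition detected: signal range is within noise of flat.")
  }

  # baseline starts from the curve extremes
  nlo <- max(3, floor(length(u) / 4))
  lo <- lm(y[seq_len(nlo)] ~ u[seq_len(nlo)])
  hi_idx <- seq(length(u) - nlo + 1, length(u))
  hi <- lm(y[hi_idx] ~ u[hi_idx])
  # crude midpoint guess: urea where the signal crosses the mid-range
  mid <- (max(y) + min(y)) / 2
  cm_guess <- u[which.min(abs(y - mid))]
  starts <- expand.grid(
    m_eq = c(1, 2, 4, 8),
    Cm = unique(c(max(cm_guess, 0.5), stats::median(u)))
  )
  if (nrow(starts) < 8) starts <- starts[rep(seq_len(nrow(starts)), length.out = 8), ]

  df <- data.frame(u = u, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(
      dG0 = starts$m_eq[i] * starts$Cm[i], m_eq = starts$m_eq[i],
      bn_int = coef(lo)[[1]], bn_slope = coef(lo)[[2]],
      bd_int = coef(hi)[[1]], bd_slope = coef(hi)[[2]]
    )
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_signal(u, dG0, m_eq, bn_int, bn_slope, bd_int, bd_slope,
                             temperature_K = temperature_K),
        data = df, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("Equilibrium fit did not converge from any start.")
  fit <- best$fit
  cf <- summary(fit)$coefficients
  if (cf["m_eq", "Estimate"] <= 0) {
    abort("No cooperative transition detected (fitted m-value <= 0).")
  }
  est <- tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"])
  )
  pick <- function(term) est$estimate[est$term == term]
  # a genuine transition must separate the baselines by more than the scatter
  resid_sd <- sqrt(best$rss / max(length(u) - 6, 1))
  cm <- pick("dG0") / pick("m_eq")
  amp <- abs((pick("bn_int") + pick("bn_slope") * cm) -
               (pick("bd_int") + pick("bd_slope") * cm))
  if (amp <= 3 * resid_sd) {
    abort("No transition detected: fitted amplitude is within noise.")
  }
  pick_se <- function(term) est$std_error[est$term == term]
  if (pick_se("dG0") > abs(pick("dG0")) || pick_se("m_eq") > pick("m_eq")) {
    abort("No transition detected: stability parameters are not identifiable.")
  }
  structure(
    list(
      estimate = est,
      dG0 = pick("dG0"),
      m_eq = pick("m_eq"),
      Cm = cm,
      rss = best$rss,
      temperature_K = temperature_K,
      data = tibble(urea_M = u, signal = y),
      fit = fit
    ),
    class = "two_state_eq_fit"
  )
}

#' @export
print.two_state_eq_fit <- function(x, ...) {
  cat("<two_state_eq_fit>\n")
  cat(sprintf("  dG0  = %.3f kJ/mol (SE %.3g)\n", x$dG0,
              x$estimate$std_error[x$estimate$term == "dG0"]))
  cat(sprintf("  m_eq = %.3f kJ/mol/M (SE %.3g)\n", x$m_eq,
              x$estimate$std_error[x$estimate$term == "m_eq"]))
  cat(sprintf("  Cm   = %.3f M, RSS = %.3g, T = %.2f K\n",
              x$Cm, x$rss, x$temperature_K))
  invisible(x)
}

#' @export
predict.two_state_eq_fit <- function(object, urea_M = NULL, ...) {
  urea_M <- urea_M %||% object$data$urea_M
  p <- setNames(object$estimate$estimate, object$estimate$term)
  two_state_signal(urea_M, p["dG0"], p["m_eq"], p["bn_int"], p["bn_slope"],
                   p["bd_int"], p["bd_slope"], object$temperature_K)
}

#' Fit one ionic-strength model to a stability series
#'
#' Ordinary (optionally weighted) least squares of unfolding free energy on a
#' transformed ionic strength predictor. The `sqrt_I` model is the
#' Debye-Hueckel screening form `dG(I) = dG0 + m_salt * sqrt(I)`; `linear_I`
#' (direct ion binding / Hofmeister) and `log_I` are the competitor shapes.
#'
#' @param series Data frame with columns `ionic_strength_M` and `dG_kJ_mol`,
#'   optionally `dG_err` (standard errors used as inverse-variance weights).
#' @param model One of `"sqrt_I"`, `"linear_I"`, `"log_I"`.
#'
#' @return Object of class `salt_model_fit`: list with `model`, `slope`,
#'   `intercept`, their standard errors, `r_squared`, `rss`, and the `lm` fit.
#' @export
#' @examples
#' s <- tibble::tibble(ionic_strength_M = c(0.04, 0.16, 0.36),
#'                     dG_kJ_mol = 4 + 5 * sqrt(c(0.04, 0.16, 0.36)))
#' fit_salt_model(s, "sqrt_I")$slope # 5
fit_salt_model <- function(series, model = c("sqrt_I", "linear_I", "log_I")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(series),
            all(c("ionic_strength_M", "dG_kJ_mol") %in% names(series)))
  I <- series$ionic_strength_M
  dG <- series$dG_kJ_mol
  check_numeric_vec(I, "ionic_strength_M", lower = 0, min_len = 3)
  check_numeric_vec(dG, "dG_kJ_mol", min_len = 3)
  if (model == "log_I" && any(I <= 0)) {
    abort("log_I model requires all ionic strengths > 0.")
  }
  x <- switch(model, sqrt_I = sqrt(I), linear_I = I, log_I = log(I))
  w <- if ("dG_err" %in% names(series)) {
    check_numeric_vec(series$dG_err, "dG_err", lower = 0, strict_lower = TRUE)
    1 / series$dG_err^2
  } else {
    NULL
  }
  fit <- if (is.null(w)) lm(dG ~ x) else lm(dG ~ x, weights = w)
  cf <- summary(fit)$coefficients
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((dG - mean(dG))^2)
  structure(
    list(
      model = model,
      intercept = cf[1, 1], slope = cf[2, 1],
      intercept_se = cf[1, 2], slope_se = cf[2, 2],
      r_squared = 1 - rss / tss,
      rss = rss,
      n = length(I),
      fit = fit,
      series = as_tibble(series)
    ),
    class = "salt_model_fit"
  )
}

#' @export
print.salt_model_fit <- function(x, ...) {
  cat(sprintf("<salt_model_fit: %s>  dG = %.3f + %.3f * %s,  R^2 = %.4f\n",
              x$model, x$intercept, x$slope,
              switch(x$model, sqrt_I = "sqrt(I)", linear_I = "I", log_I = "ln(I)"),
              x$r_squared))
  invisible(x)
}

#' Compare the three ionic-strength models on one stability series
#'
#' Fits the square-root (Debye-Hueckel), linear, and logarithmic ionic-strength
#' models to the same free-energy series and ranks them by R-squared (ties
#' broken by residual sum of squares). All three fits are always returned.
#'
#' @inheritParams fit_salt_model
#' @return Object of class `salt_model_comparison`: tibble with one row per
#'   model (columns `model`, `intercept`, `slope`, `r_squared`, `rss`, `rank`)
#'   plus the full fits in attribute `fits`.
#' @export
#' @examples
#' s <- sim_salt_series(dG0 = 4, m_salt = 5,
#'                      ionic_strength_M = c(0.05, 0.1, 0.2, 0.4, 0.8),
#'                      noise_sd = 0, seed = 1)
#' compare_salt_models(s)
compare_salt_models <- function(series) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < 4) {
    abort("Model comparison needs >= 4 points; fewer make the shapes indistinguishable.")
  }
  fits <- purrr::map(c("sqrt_I", "linear_I", "log_I"),
                     function(m) fit_salt_model(series, m))
  tab <- purrr::map(fits, function(f) {
    tibble(model = f$model, intercept = f$intercept, slope = f$slope,
           r_squared = f$r_squared, rss = f$rss)
  }) |> purrr::list_rbind()
  tab <- tab |> arrange(desc(.data$r_squared), .data$rss) |>
    mutate(rank = dplyr::row_number())
  structure(tab, fits = setNames(fits, purrr::map_chr(fits, "model")),
            class = c("salt_model_comparison", class(tab)))
}

#' @importFrom purrr map_chr
NULL
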