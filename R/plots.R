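# ggplot2 autoplot methods for result objects

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted equilibrium denaturation curve
#'
#' Data points with the fitted two-state curve overlaid.
#'
#' @param object A [fit_equilibrium_curve()] result.
#' @param n_grid Resolution of the fitted line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.two_state_eq_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(urea_M = seq(min(object$data$urea_M),
                              max(object$data$urea_M), length.out = n_grid))
  grid$signal <- predict(object, grid$urea_M)
  ggplot(object$data, aes(x = .data$urea_M, y = .data$signal)) +
    geom_point() +
    geom_line(data = grid, colour = "#2166AC") +
    labs(x = "[urea] (M)", y = "fluorescence signal",
         title = sprintf("Two-state fit: dG0 = %.2f kJ/mol, m = %.2f kJ/mol/M",
                         object$dG0, object$m_eq)) +
    theme_minimal()
}

#' Plot a chevron unfolding arm
#'
#' `ln k_u` versus urea with the fitted line.
#'
#' @param object A [fit_unfolding_arm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chevron_arm_fit <- function(object, ...) {
  d <- object$data |> mutate(ln_ku = log(.data$ku_per_s))
  grid <- tibble(urea_M = seq(0, max(d$urea_M), length.out = 50))
  grid$ln_ku <- object$ln_ku0 + object$m_ku * grid$urea_M
  ggplot(d, aes(x = .data$urea_M, y = .data$ln_ku)) +
    geom_line(data = grid, colour = "#B2182B") +
    geom_point() +
    labs(x = "[urea] (M)", y = "ln k_u (s^-1)",
         title = sprintf("Unfolding arm: ku0 = %.3g s^-1", object$ku0)) +
    theme_minimal()
}

#' Plot a salt-model comparison
#'
#' The stability series against each transformed predictor, one facet per
#' model, with the fitted line.
#'
#' @param object A [compare_salt_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.salt_model_comparison <- function(object, ...) {
  fits <- attr(object, "fits")
  d <- purrr::map(fits, function(f) {
    x <- switch(f$model,
                sqrt_I = sqrt(f$series$ionic_strength_M),
                linear_I = f$series$ionic_strength_M,
                log_I = log(f$series$ionic_strength_M))
    tibble(model = sprintf("%s (R2 = %.4f)", f$model, f$r_squared),
           x = x, dG = f$series$dG_kJ_mol,
           fitted = f$intercept + f$slope * x)
  }) |> purrr::list_rbind()
  ggplot(d, aes(x = .data$x, y = .data$dG)) +
    geom_line(aes(y = .data$fitted), colour = "#2166AC") +
    geom_point() +
    facet_wrap(~model, scales = "free_x") +
    labs(x = "transformed ionic strength", y = "dG (kJ/mol)") +
    theme_minimal()
}

#' Plot per-residue ion-contact fractions
#'
#' @param object An [ion_contact_stats()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_stats <- function(object, ...) {
  d <- object$per_residue |>
    mutate(label = paste0(.data$resid, .data$resno))
  ggplot(d, aes(x = .data$label, y = 100 * .data$mean_fraction)) +
    geom_col(fill = "#2166AC") +
    geom_errorbar(aes(ymin = 100 * (.data$mean_fraction - .data$sd_fraction),
                      ymax = 100 * (.data$mean_fraction + .data$sd_fraction)),
                  width = 0.25) +
    labs(x = NULL, y = "% of frames in ion contact",
         title = object$condition) +
    theme_minimal()
}

#' Plot model-free order parameters by residue
#'
#' @param object A [fit_model2()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_free_fit <- function(object, ...) {
  ggplot(object$params, aes(x = .data$residue, y = .data$S2)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "residue", y = expression(S^2),
         title = sprintf("tau_c = %.2f ns", object$tau_c_ns)) +
    theme_minimal()
}

#' Plot a two-condition folding free-energy diagram
#'
#' Relative levels of the denatured (D), transition (TS) and native (N) states
#' from [build_energy_diagram()].
#'
#' @param diagram A [build_energy_diagram()] result.
#' @return A ggplot object.
#' @export
plot_energy_diagram <- function(diagram) {
  d <- diagram |>
    mutate(xpos = match(.data$state, c("D", "TS", "N")))
  ggplot(d, aes(x = .data$xpos, y = .data$G_rel_kJ,
                colour = .data$condition)) +
    geom_line() +
    geom_point(size = 3) +
    ggplot2::scale_x_continuous(breaks = 1:3, labels = c("D", "TS", "N")) +
    labs(x = NULL, y = "relative G (kJ/mol)") +
    theme_minimal()
}
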