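# broom-style tidy()/glance() methods for the package's fitted objects

#' @export
tidy.two_state_eq_fit <- function(x, ...) x$estimate

#' @export
glance.two_state_eq_fit <- function(x, ...) {
  tibble(dG0 = x$dG0, m_eq = x$m_eq, Cm = x$Cm, rss = x$rss,
         temperature_K = x$temperature_K, nobs = nrow(x$data))
}

#' @export
tidy.salt_model_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.salt_model_fit <- function(x, ...) {
  tibble(model = x$model, r_squared = x$r_squared, rss = x$rss, nobs = x$n)
}

#' @export
tidy.chevron_arm_fit <- function(x, ...) {
  tibble(
    term = c("ln_ku0", "m_ku"),
    estimate = c(x$ln_ku0, x$m_ku),
    std_error = c(x$ln_ku0_se, x$m_ku_se)
  )
}

#' @export
glance.chevron_arm_fit <- function(x, ...) {
  tibble(ku0 = x$ku0, ku0_se = x$ku0_se, m_ku = x$m_ku, m_ku_se = x$m_ku_se,
         r_squared = x$r_squared, nobs = nrow(x$data))
}

#' @export
tidy.exp_trace_fit <- function(x, ...) {
  tibble(
    term = c("k_obs", "amplitude", "offset"),
    estimate = c(x$k_obs, x$amplitude, x$offset),
    std_error = c(x$k_obs_se, x$amplitude_se, x$offset_se)
  )
}

#' @export
glance.exp_trace_fit <- function(x, ...) {
  tibble(k_obs = x$k_obs, k_obs_se = x$k_obs_se, rss = x$rss,
         nobs = nrow(x$data))
}

#' @export
tidy.model_free_fit <- function(x, ...) x$params

#' @export
glance.model_free_fit <- function(x, ...) {
  tibble(tau_c_ns = x$tau_c_ns, total_chisq = x$total_chisq,
         n_residues = nrow(x$params), n_excluded = length(x$excluded))
}

#' @export
tidy.contact_stats <- function(x, ...) x$per_residue

#' @export
glance.contact_stats <- function(x, ...) {
  tidyr::pivot_wider(x$global, names_from = "species",
                     values_from = c("mean_count", "sd_count"))
}

#' @export
tidy.charge_profile <- function(x, ...) x$per_sequence

#' @export
glance.charge_profile <- function(x, ...) x$summary
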