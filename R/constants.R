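#' Physical constants used throughout saltfold
#'
#' One table collecting every physical constant the package relies on, so unit
#' conventions live in a single place. Energies are kilojoules per mole,
#' temperatures Kelvin, rates per second, field strengths Tesla.
#'
#' @format A tibble with columns `constant`, `value`, `unit`, `meaning`.
#'
#' @details
#' * `R_kJ` — gas constant, 8.314e-3 kJ mol^-1 K^-1. All free energies in the
#'   package are kJ/mol, matching common practice for chemical denaturation work.
#' * `gamma_H`, `gamma_N` — 1H and 15N gyromagnetic ratios (rad s^-1 T^-1).
#'   gamma_N is negative, which is what makes 15N heteronuclear NOEs < 1.
#' * `hbar` — reduced Planck constant (J s).
#' * `mu0_4pi` — magnetic constant over 4*pi (T^2 J^-1 m^3).
#' * `r_NH` — amide N-H bond length, 1.02 Angstrom, the standard value used in
#'   model-free analyses.
#' * `csa_N` — 15N chemical shift anisotropy, -160 ppm.
#'
#' @export
#' @examples
#' saltfold_constants()
saltfold_constants <- function() {
  tibble::tribble(
    ~constant, ~value,          ~unit,                 ~meaning,
    "R_kJ",    8.314e-3,        "kJ mol-1 K-1",        "gas constant",
    "gamma_H", 2.6752218744e8,  "rad s-1 T-1",         "1H gyromagnetic ratio",
    "gamma_N", -2.7126e7,       "rad s-1 T-1",         "15N gyromagnetic ratio",
    "hbar",    1.054571817e-34, "J s",                 "reduced Planck constant",
    "mu0_4pi", 1e-7,            "T2 J-1 m3",           "mu0 / 4 pi",
    "r_NH",    1.02e-10,        "m",                   "amide N-H bond length",
    "csa_N",   -160e-6,         "(dimensionless) ppm", "15N chemical shift anisotropy"
  )
}

# internal scalar shortcuts (values duplicated from saltfold_constants(),
# asserted equal in the test suite)
.R_kJ <- 8.314e-3
.gamma_H <- 2.6752218744e8
.gamma_N <- -2.7126e7
.hbar <- 1.054571817e-34
.mu0_4pi <- 1e-7
.r_NH <- 1.02e-10
.csa_N <- -160e-6

#' Spectrometer configuration for relaxation calculations
#'
#' Bundles the field-dependent and geometric constants entering the dipolar and
#' CSA relaxation expressions. The default is a 600 MHz (14.1 T) instrument
#' with the standard N-H bond length (1.02 Angstrom) and 15N CSA (-160 ppm).
#'
#' @param proton_frequency_MHz 1H Larmor frequency in MHz. Default 600.
#' @param r_NH_A N-H bond length in Angstrom. Default 1.02.
#' @param csa_ppm 15N chemical shift anisotropy in ppm. Default -160.
#'
#' @return A list of class `spectrometer_config` with elements `B0` (T),
#'   `omega_H`, `omega_N` (rad/s), `d` (dipolar coupling constant, rad/s),
#'   `c` (CSA constant, rad/s), and the inputs.
#' @export
#' @examples
#' cfg <- spectrometer_config()
#' cfg$omega_N / (2 * pi) / 1e6 # 15N Larmor frequency, ~ -60.8 MHz
spectrometer_config <- function(proton_frequency_MHz = 600,
                                r_NH_A = 1.02,
                                csa_ppm = -160) {
  stopifnot(proton_frequency_MHz > 0, r_NH_A > 0)
  B0 <- 2 * pi * proton_frequency_MHz * 1e6 / .gamma_H
  omega_H <- .gamma_H * B0
  omega_N <- .gamma_N * B0
  r <- r_NH_A * 1e-10
  d <- .mu0_4pi * .gamma_H * .gamma_N * .hbar / r^3
  cc <- omega_N * (csa_ppm * 1e-6) / sqrt(3)
  structure(
    list(
      proton_frequency_MHz = proton_frequency_MHz,
      r_NH_A = r_NH_A, csa_ppm = csa_ppm,
      B0 = B0, omega_H = omega_H, omega_N = omega_N, d = d, c = cc
    ),
    class = "spectrometer_config"
  )
}

#' @export
print.spectrometer_config <- function(x, ...) {
  cat("<spectrometer_config>\n")
  cat(sprintf("  1H frequency : %g MHz (B0 = %.4f T)\n", x$proton_frequency_MHz, x$B0))
  cat(sprintf("  15N frequency: %.2f MHz\n", x$omega_N / (2 * pi * 1e6)))
  cat(sprintf("  r(N-H) = %g A, CSA = %g ppm\n", x$r_NH_A, x$csa_ppm))
  invisible(x)
}
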