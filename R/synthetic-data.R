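#' Simulate a two-state equilibrium denaturation curve
#'
#' Evaluates the linear-extrapolation signal model [two_state_signal()] on a
#' urea grid and adds i.i.d. Gaussian noise. Same seed and parameters give
#' byte-identical output; the caller's RNG state is untouched.
#'
#' @param dG0 Unfolding free energy at 0 M urea, kJ/mol.
#' @param m_eq Equilibrium m-value, kJ/mol/M.
#' @param bn_int,bn_slope,bd_int,bd_slope Native/denatured baseline intercepts
#'   and slopes (signal units).
#' @param urea_M Urea grid, M (nonnegative, at most 10.5 M - the solubility
#'   ceiling of a urea stock).
#' @param temperature_K Temperature, Kelvin (default 303.15).
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `urea_M`, `signal`; attribute `temperature_K`.
#' @export
sim_equilibrium_curve <- function(dG0, m_eq, bn_int, bn_slope, bd_int, bd_slope,
                                  urea_M, temperature_K = 303.15,
                                  noise_sd = 0, seed) {
  check_numeric_vec(urea_M, "urea_M", lower = 0)
  if (any(urea_M > 10.5)) abort("`urea_M` must be <= 10.5 M.")
  check_number(noise_sd, "noise_sd", lower = 0)
  mu <- two_state_signal(urea_M, dG0, m_eq, bn_int, bn_slope, bd_int, bd_slope,
                         temperature_K)
  sig <- with_local_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  out <- tibble(urea_M = urea_M, signal = sig)
  attr(out, "temperature_K") <- temperature_K
  out
}

#' Simulate a single-exponential unfolding trace
#'
#' `signal(t) = offset + amplitude * exp(-k_u * t) + noise`.
#'
#' @param k_u Unfolding rate, s^-1 (> 0).
#' @param amplitude,offset Signal amplitude and long-time offset.
#' @param time_s Time grid, s (strictly increasing).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `time_s`, `signal`.
#' @export
sim_unfolding_trace <- function(k_u, amplitude, offset, time_s,
                                noise_sd = 0, seed) {
  check_number(k_u, "k_u", lower = 0, strict_lower = TRUE)
  check_numeric_vec(time_s, "time_s")
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  check_number(noise_sd, "noise_sd", lower = 0)
  mu <- offset + amplitude * exp(-k_u * time_s)
  sig <- with_local_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  tibble(time_s = time_s, signal = sig)
}

#' Simulate a stability-versus-ionic-strength series
#'
#' Debye-Hueckel screening: `dG(I) = dG0 + m_salt * sqrt(I) + noise`.
#'
#' @param dG0 Stability at zero ionic strength, kJ/mol.
#' @param m_salt Slope on the sqrt(I) scale, kJ/mol/M^0.5.
#' @param ionic_strength_M Ionic strength grid, M (>= 0).
#' @param noise_sd Gaussian noise SD in kJ/mol (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `ionic_strength_M`, `dG_kJ_mol`.
#' @export
sim_salt_series <- function(dG0, m_salt, ionic_strength_M, noise_sd = 0, seed) {
  check_numeric_vec(ionic_strength_M, "ionic_strength_M", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  mu <- dG0 + m_salt * sqrt(ionic_strength_M)
  dg <- with_local_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
  tibble(ionic_strength_M = ionic_strength_M, dG_kJ_mol = dg)
}

#' Simulate a per-residue 15N relaxation data set
#'
#' Forward-computes R1, R2 and NOE from Lipari-Szabo "model 2" parameters via
#' [predict_relaxation_rates()], adds relative Gaussian noise, and
#' back-computes R1rho from R1 and R2 at the stated spin-lock strength and
#' per-residue offsets via [r1rho_from_r2()].
#'
#' @param truth Data frame with columns `residue`, `S2` (in `[0, 1]`) and
#'   `tau_e_s` (each `< tau_c`).
#' @param tau_c Global tumbling time, s. Default 5.76 ns, typical of a small
#'   (~60-residue) domain at 20 C.
#' @param config A [spectrometer_config()].
#' @param nu_SL_Hz Spin-lock field strength, Hz. Default 2000.
#' @param noise_sd Relative noise level (fraction of each rate; >= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `residue`, `R1`, `R1rho`, `R2`, `NOE`,
#'   `nu_SL_Hz`, `offset_Hz`, and (when `noise_sd > 0`) `R1_err`, `R2_err`,
#'   `NOE_err`.
#' @export
sim_relaxation_set <- function(truth, tau_c = 5.76e-9,
                               config = spectrometer_config(),
                               nu_SL_Hz = 2000, noise_sd = 0, seed) {
  stopifnot(is.data.frame(truth),
            all(c("residue", "S2", "tau_e_s") %in% names(truth)))
  if (any(truth$S2 < 0 | truth$S2 > 1)) abort("S2 must lie in [0, 1].")
  if (any(truth$tau_e_s < 0 | truth$tau_e_s >= tau_c)) {
    abort("tau_e must satisfy 0 <= tau_e < tau_c.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  rates <- purrr::map(seq_len(nrow(truth)), function(i) {
    predict_relaxation_rates(truth$S2[i], truth$tau_e_s[i], tau_c, config)
  }) |> purrr::list_rbind()
  with_local_seed(seed, {
    n <- nrow(truth)
    offset_Hz <- round(runif(n, -1500, 1500))
    R1 <- rates$R1 * (1 + rnorm(n, 0, noise_sd))
    R2 <- rates$R2 * (1 + rnorm(n, 0, noise_sd))
    NOE <- rates$NOE * (1 + rnorm(n, 0, noise_sd))
    out <- tibble(
      residue = truth$residue,
      R1 = R1,
      R1rho = r1rho_from_r2(R1, R2, nu_SL_Hz, offset_Hz),
      R2 = R2,
      NOE = NOE,
      nu_SL_Hz = nu_SL_Hz,
      offset_Hz = offset_Hz
    )
    if (noise_sd > 0) {
      out$R1_err <- rates$R1 * noise_sd
      out$R2_err <- rates$R2 * noise_sd
      out$NOE_err <- abs(rates$NOE) * noise_sd
    }
    out
  })
}

# ---- toy trajectories -------------------------------------------------------

# side-chain group atoms written for each charged residue kind
.group_atom_names <- list(
  LYS = c("NZ"),
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2")
)

#' Simulate a toy ion/salt-bridge trajectory ensemble
#'
#' Builds a geometric (non-physical) multi-run trajectory whose only contract
#' is occupancy: per frame, each listed ion is placed inside (3 Angstrom) or
#' outside (8 Angstrom) the 4-Angstrom contact cutoff of its target charged
#' group by a seeded Bernoulli draw at the target occupancy, and each listed
#' salt-bridge partner pair is likewise placed at 3.5 or 6.5 Angstrom. Charged
#' residues are spaced 20 Angstrom apart so no accidental contacts occur.
#'
#' @param ion_targets Data frame with columns `resno`, `resid` (LYS, ASP or
#'   GLU) and `occupancy` in `[0, 1]`; one ion (CL- for LYS, NA+ otherwise) is
#'   created per row. May be `NULL`.
#' @param bridge_targets Data frame with columns `lys_resno`, `partner_resno`,
#'   `partner_resid` (ASP or GLU) and `occupancy`; the lysine NZ and the
#'   partner's distal carbon are the measured pair. May be `NULL`.
#' @param n_frames Frames per run (>= 1).
#' @param n_runs Number of independent runs (>= 1).
#' @param condition Label for the ensemble.
#' @param seed Integer seed.
#' @return A `run_ensemble` (see [run_ensemble()]).
#' @export
#' @examples
#' ens <- sim_toy_trajectory(
#'   ion_targets = tibble::tibble(resno = 10, resid = "ASP", occupancy = 0.5),
#'   n_frames = 50, seed = 1
#' )
#' ion_contact_stats(ens)
sim_toy_trajectory <- function(ion_targets = NULL, bridge_targets = NULL,
                               n_frames, n_runs = 1, condition = "toy", seed) {
  check_number(n_frames, "n_frames", lower = 1)
  check_number(n_runs, "n_runs", lower = 1)
  if (is.null(ion_targets) && is.null(bridge_targets)) {
    abort("Give at least one of `ion_targets`, `bridge_targets`.")
  }
  occs <- c(ion_targets$occupancy, bridge_targets$occupancy)
  if (any(occs < 0 | occs > 1)) abort("Occupancies must lie in [0, 1].")
  if (!is.null(bridge_targets) &&
      !all(bridge_targets$partner_resid %in% c("ASP", "GLU"))) {
    abort("Bridge partners must be ASP or GLU.")
  }
  if (!is.null(ion_targets) &&
      !all(ion_targets$resid %in% names(.group_atom_names))) {
    abort("Ion target residues must be LYS, ASP or GLU.")
  }

  # static topology: charged residues on a 20 A grid, one ion per ion target
  res_tab <- unique(rbind(
    if (!is.null(ion_targets)) {
      data.frame(resno = ion_targets$resno, resid = ion_targets$resid)
    },
    if (!is.null(bridge_targets)) {
      rbind(
        data.frame(resno = bridge_targets$lys_resno, resid = "LYS"),
        data.frame(resno = bridge_targets$partner_resno,
                   resid = bridge_targets$partner_resid)
      )
    }
  ))
  res_tab <- res_tab[order(res_tab$resno), , drop = FALSE]
  if (anyDuplicated(res_tab$resno)) {
    abort("Conflicting residue types for the same residue number.")
  }
  centers <- setNames(20 * seq_len(nrow(res_tab)), res_tab$resno)

  atoms <- purrr::map(seq_len(nrow(res_tab)), function(i) {
    nm <- .group_atom_names[[res_tab$resid[i]]]
    tibble(elety = c("CA", nm), resid = res_tab$resid[i],
           resno = res_tab$resno[i], chain = "A",
           type = "ATOM")
  }) |> purrr::list_rbind()
  if (!is.null(ion_targets)) {
    ion_resid <- ifelse(ion_targets$resid == "LYS", "CL-", "NA+")
    ion_elety <- ifelse(ion_targets$resid == "LYS", "CL", "NA")
    atoms <- bind_rows(atoms, tibble(
      elety = ion_elety, resid = ion_resid,
      resno = 1000L + seq_len(nrow(ion_targets)), chain = "B",
      type = "HETATM"
    ))
  }
  atoms$eleno <- seq_len(nrow(atoms))
  natom <- nrow(atoms)

  # base coordinates: group atoms clustered ~0.8 A around the residue center
  base <- matrix(0, natom, 3)
  for (i in seq_len(natom)) {
    if (atoms$type[i] == "ATOM") {
      cx <- centers[[as.character(atoms$resno[i])]]
      k <- sum(atoms$resno[seq_len(i)] == atoms$resno[i] &
                 atoms$type[seq_len(i)] == "ATOM")
      base[i, ] <- c(cx, 0.8 * (k - 1), 0)
    }
  }

  anchor_atom <- function(resno, names) {
    which(atoms$resno == resno & atoms$elety %in% names & atoms$type == "ATOM")[1]
  }

  runs <- with_local_seed(seed, {
    purrr::map(seq_len(n_runs), function(r) {
      xyz <- matrix(0, n_frames, 3 * natom)
      for (f in seq_len(n_frames)) {
        co <- base
        if (!is.null(ion_targets)) {
          for (j in seq_len(nrow(ion_targets))) {
            tgt <- anchor_atom(ion_targets$resno[j],
                               .group_atom_names[[ion_targets$resid[j]]])
            ion <- which(atoms$type == "HETATM")[j]
            d <- if (runif(1) < ion_targets$occupancy[j]) 3.0 else 8.0
            co[ion, ] <- co[tgt, ] + c(0, 0, d)
          }
        }
        if (!is.null(bridge_targets)) {
          for (j in seq_len(nrow(bridge_targets))) {
            nz <- anchor_atom(bridge_targets$lys_resno[j], "NZ")
            pres <- bridge_targets$partner_resno[j]
            pidx <- which(atoms$resno == pres & atoms$type == "ATOM" &
                            atoms$elety != "CA")
            d <- if (runif(1) < bridge_targets$occupancy[j]) 3.5 else 6.5
            # translate the whole partner group so its distal carbon sits at d
            carbon <- which(atoms$resno == pres &
                              atoms$elety %in% c("CG", "CD"))[1]
            shift <- co[nz, ] + c(d, 0, 0) - co[carbon, ]
            co[pidx, ] <- sweep(co[pidx, , drop = FALSE], 2, shift, "+")
          }
        }
        xyz[f, ] <- as.vector(t(co))
      }
      new_trajectory(atoms, xyz)
    })
  })
  run_ensemble(runs, condition = condition)
}

#' Simulate an ortholog alignment with a planted covarying pair
#'
#' Generates an ungapped amino-acid alignment in which:
#' * fixed charged columns (3 lysines plus enough aspartates/glutamates, or
#'   the mirror image for positive targets) set the net charge;
#' * two "balanced" columns carry K or E with probability 1/2 each, so
#'   per-sequence net charge varies around the target with mean exactly
#'   `charge_target`;
#' * the two `covarying_pair` columns take complementary polar states
#'   (N/S vs S/N, 50/50) - perfectly covarying, charge-neutral;
#' * every other column is an independent background column: a consensus
#'   residue plus two minor variants (85/10/5 by default), mimicking a
#'   conserved ortholog family.
#'
#' @param n_seqs Number of sequences. Default 262 (a typical deep ortholog
#'   set for a small domain).
#' @param length Alignment length (>= 2). Default 60, a single-domain span.
#' @param charge_target Target mean net charge per sequence. Default -10.
#' @param covarying_pair Two distinct 1-based column positions. Default
#'   c(40, 47).
#' @param conservation Consensus frequency of background columns. Default 0.85.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `sequence` (equal-length strings).
#' @export
sim_alignment <- function(n_seqs = 262, length = 60, charge_target = -10,
                          covarying_pair = c(40, 47), conservation = 0.85,
                          seed) {
  check_number(n_seqs, "n_seqs", lower = 2)
  check_number(length, "length", lower = 2)
  check_number(conservation, "conservation", lower = 0.5, upper = 1)
  if (length(covarying_pair) != 2 ||
      covarying_pair[1] == covarying_pair[2] ||
      any(covarying_pair < 1) || any(covarying_pair > length)) {
    abort("`covarying_pair` must be two distinct positions within the alignment.")
  }
  need <- abs(charge_target)
  if (need + 2 > length) {
    abort(sprintf(
      "Charge target %d is impossible at length %d: needs %d charged columns plus the covarying pair.",
      charge_target, length, need
    ))
  }
  # minority charges (the "wrong-sign" residues, each balanced by one extra
  # majority charge) and mean-zero jitter columns are included as space allows
  n_minor <- min(3L, (length - 2L - need) %/% 2L)
  n_major <- need + n_minor
  n_jitter <- min(2L, length - 2L - n_minor - n_major)
  neutral <- c("A", "G", "S", "T", "N", "Q", "V", "L", "I", "F", "P", "Y")
  with_local_seed(seed, {
    M <- matrix("", n_seqs, length)
    free <- setdiff(seq_len(length), covarying_pair)
    # deterministic layout over the free columns
    minor_cols <- free[seq_len(n_minor)]
    major_cols <- free[n_minor + seq_len(n_major)]
    jitter_cols <- free[n_minor + n_major + seq_len(n_jitter)]
    bg_cols <- setdiff(free, c(minor_cols, major_cols, jitter_cols))
    if (charge_target <= 0) {
      for (j in minor_cols) M[, j] <- "K"
      for (j in major_cols) M[, j] <- sample(c("D", "E"), 1)
    } else {
      for (j in minor_cols) M[, j] <- sample(c("D", "E"), 1)
      for (j in major_cols) M[, j] <- sample(c("K", "R"), 1)
    }
    for (j in jitter_cols) M[, j] <- sample(c("K", "E"), n_seqs, replace = TRUE)
    p_minor <- (1 - conservation) * c(2 / 3, 1 / 3)
    for (j in bg_cols) {
      cons <- sample(neutral, 1)
      alt <- sample(setdiff(neutral, cons), 2)
      M[, j] <- sample(c(cons, alt), n_seqs, replace = TRUE,
                       prob = c(conservation, p_minor))
    }
    state <- sample(c(TRUE, FALSE), n_seqs, replace = TRUE)
    M[, covarying_pair[1]] <- ifelse(state, "N", "S")
    M[, covarying_pair[2]] <- ifelse(state, "S", "N")
    tibble(
      id = sprintf("ortholog_%03d", seq_len(n_seqs)),
      sequence = apply(M, 1, paste0, collapse = "")
    )
  })
}
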