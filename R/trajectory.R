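#' Construct a trajectory object
#'
#' A lightweight container for labeled coordinate frames: an atom table plus a
#' frames-by-coordinates matrix (each row one frame, columns x1,y1,z1,x2,...).
#'
#' @param atoms Data frame with columns `elety` (atom name), `resid` (residue
#'   name), `resno` (residue number), `chain`, `type` ("ATOM"/"HETATM"),
#'   optionally `eleno`.
#' @param xyz Numeric matrix `n_frames x (3 * n_atoms)`, finite.
#' @return Object of class `saltfold_trajectory`.
#' @export
new_trajectory <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms)) {
    abort("`xyz` must have 3 columns per atom.")
  }
  if (any(!is.finite(xyz))) abort("Coordinates must be finite.")
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  if (!"type" %in% names(atoms)) atoms$type <- "ATOM"
  structure(list(atoms = as_tibble(atoms), xyz = xyz),
            class = "saltfold_trajectory")
}

#' @export
print.saltfold_trajectory <- function(x, ...) {
  cat(sprintf("<saltfold_trajectory> %d frames, %d atoms, %d residues\n",
              nrow(x$xyz), nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Bundle independent trajectories into a run ensemble
#'
#' Per-run statistics are averaged and their standard deviation across runs is
#' the reported uncertainty, mirroring how independent simulation repeats are
#' summarised.
#'
#' @param runs List of [new_trajectory()] objects with identical topology.
#' @param condition Label, e.g. "800 mM NaCl".
#' @return Object of class `run_ensemble`.
#' @export
run_ensemble <- function(runs, condition = "") {
  stopifnot(is.list(runs), length(runs) >= 1)
  for (r in runs) stopifnot(inherits(r, "saltfold_trajectory"))
  ref <- runs[[1]]$atoms[c("elety", "resid", "resno")]
  for (r in runs[-1]) {
    if (!identical(as.data.frame(ref),
                   as.data.frame(r$atoms[c("elety", "resid", "resno")]))) {
      abort("All runs must share an identical topology.")
    }
  }
  structure(list(runs = runs, condition = condition), class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("<run_ensemble> '%s': %d run(s) of %d frames\n",
              x$condition, length(x$runs),
              nrow(x$runs[[1]]$xyz)))
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Thin wrapper over `bio3d::read.pdb(multi = TRUE)`: MODEL/ENDMDL records
#' become frames.
#'
#' @param path PDB file path.
#' @return A [new_trajectory()] object.
#' @export
read_trajectory <- function(path) {
  p <- bio3d::read.pdb(path, multi = TRUE)
  atoms <- tibble(
    eleno = p$atom$eleno, elety = p$atom$elety, resid = p$atom$resid,
    resno = p$atom$resno, chain = p$atom$chain %||% "A",
    type = p$atom$type
  )
  atoms$chain[is.na(atoms$chain)] <- "A"
  new_trajectory(atoms, p$xyz)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [new_trajectory()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "saltfold_trajectory"))
  a <- traj$atoms
  bio3d::write.pdb(
    file = path, xyz = traj$xyz, type = a$type, resno = a$resno,
    resid = a$resid, eleno = a$eleno, elety = a$elety, chain = a$chain
  )
  invisible(path)
}

# ---- charged-group bookkeeping ---------------------------------------------

.cation_resids <- c("NA+", "NA", "SOD", "K+", "K", "POT", "LI+", "LI")
.anion_resids <- c("CL-", "CL", "CLA", "BR-", "BR")

#' Charged-group atoms of standard residues
#'
#' Maps each charged residue in a topology to the side-chain atoms that define
#' its charged group: lysine to the side-chain nitrogen NZ; aspartate to the
#' distal carbon and carboxylate oxygens CG/OD1/OD2; glutamate to CD/OE1/OE2.
#' The `bridge_atom` column names the single atom used for salt-bridge
#' distances (NZ, CG or CD). Uncharged residues are absent from the mapping.
#'
#' @param atoms Atom table of a trajectory (see [new_trajectory()]).
#' @return Tibble with columns `resno`, `resid`, `charge` (+1/-1),
#'   `group_atoms` (list of atom names), `bridge_atom`.
#' @export
charged_group_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  spec <- tibble(
    resid = c("LYS", "ASP", "GLU"),
    charge = c(1, -1, -1),
    group_atoms = list(c("NZ"), c("CG", "OD1", "OD2"), c("CD", "OE1", "OE2")),
    bridge_atom = c("NZ", "CG", "CD")
  )
  prot <- atoms[atoms$type == "ATOM" & atoms$resid %in% spec$resid, ]
  if (nrow(prot) == 0) {
    return(tibble(resno = integer(), resid = character(), charge = numeric(),
                  group_atoms = list(), bridge_atom = character()))
  }
  out <- unique(prot[c("resno", "resid")]) |>
    left_join(spec, by = "resid") |>
    arrange(.data$resno)
  # verify the naming dialect: every mapped residue must carry its group atoms
  for (i in seq_len(nrow(out))) {
    have <- atoms$elety[atoms$resno == out$resno[i] & atoms$type == "ATOM"]
    if (!any(out$group_atoms[[i]] %in% have)) {
      abort(sprintf(
        "Residue %s%d has none of the expected charged-group atoms (%s): unknown naming dialect.",
        out$resid[i], out$resno[i], paste(out$group_atoms[[i]], collapse = ", ")
      ))
    }
  }
  as_tibble(out)
}

# squared distances between one atom and a set of atoms, all frames
# xyz: n_frames x 3natom; returns n_frames x length(j)
.dist2_to <- function(xyz, i, j) {
  xi <- xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  out <- matrix(0, nrow(xyz), length(j))
  for (k in seq_along(j)) {
    dj <- xyz[, (3 * j[k] - 2):(3 * j[k]), drop = FALSE] - xi
    out[, k] <- rowSums(dj^2)
  }
  out
}

#' Ion-contact statistics for a run ensemble
#'
#' Per frame, a charged residue is "in contact" if any oppositely charged ion
#' lies within `cutoff_A` of any atom of its charged group (`rule = "any_atom"`)
#' or of its bridge atom only (`rule = "bridge_atom"`). Reports the per-residue
#' contact fraction per run, averaged across runs with its SD, plus the mean
#' number of distinct cations/anions in contact with the protein per frame
#' (the territorial ion-count statistic).
#'
#' @param ensemble A [run_ensemble()].
#' @param cutoff_A Contact cutoff in Angstrom (default 4).
#' @param rule Which atoms define a contact; see above.
#' @return Object of class `contact_stats`: list with `per_residue` (tibble:
#'   `resno`, `resid`, `mean_fraction`, `sd_fraction`, `n_runs`) and `global`
#'   (tibble: `species`, `mean_count`, `sd_count`).
#' @export
ion_contact_stats <- function(ensemble, cutoff_A = 4,
                              rule = c("any_atom", "bridge_atom")) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  rule <- match.arg(rule)
  check_number(cutoff_A, "cutoff_A", lower = 0, strict_lower = TRUE)
  atoms <- ensemble$runs[[1]]$atoms
  groups <- charged_group_atoms(atoms)
  # ions are flagged by residue name: PDB writers differ on ATOM vs HETATM
  cat_idx <- which(atoms$resid %in% .cation_resids)
  an_idx <- which(atoms$resid %in% .anion_resids)
  cut2 <- cutoff_A^2

  per_run <- purrr::map(ensemble$runs, function(run) {
    xyz <- run$xyz
    nf <- nrow(xyz)
    frac <- numeric(nrow(groups))
    # per-frame contact indicator per ion (for distinct-ion counts)
    cat_contact <- matrix(FALSE, nf, length(cat_idx))
    an_contact <- matrix(FALSE, nf, length(an_idx))
    for (g in seq_len(nrow(groups))) {
      gatoms <- if (rule == "any_atom") groups$group_atoms[[g]] else groups$bridge_atom[g]
      aidx <- which(atoms$resno == groups$resno[g] & atoms$type == "ATOM" &
                      atoms$elety %in% gatoms)
      ions <- if (groups$charge[g] > 0) an_idx else cat_idx
      if (length(ions) == 0 || length(aidx) == 0) next
      hit <- matrix(FALSE, nf, length(ions))
      for (ii in seq_along(ions)) {
        d2 <- .dist2_to(xyz, ions[ii], aidx)
        hit[, ii] <- apply(d2 <= cut2, 1, any)
      }
      frac[g] <- mean(apply(hit, 1, any))
      if (groups$charge[g] > 0) {
        an_contact <- an_contact | hit
      } else {
        cat_contact <- cat_contact | hit
      }
    }
    list(
      frac = frac,
      cation_count = if (length(cat_idx)) mean(rowSums(cat_contact)) else 0,
      anion_count = if (length(an_idx)) mean(rowSums(an_contact)) else 0
    )
  })

  fr <- do.call(rbind, purrr::map(per_run, "frac"))
  per_residue <- groups |>
    select("resno", "resid") |>
    mutate(
      mean_fraction = colMeans(fr),
      sd_fraction = if (nrow(fr) > 1) apply(fr, 2, stats::sd) else rep(0, ncol(fr)),
      n_runs = length(ensemble$runs)
    )
  counts <- tibble(
    species = c("cation", "anion"),
    mean_count = c(mean(purrr::map_dbl(per_run, "cation_count")),
                   mean(purrr::map_dbl(per_run, "anion_count"))),
    sd_count = c(
      if (length(per_run) > 1) stats::sd(purrr::map_dbl(per_run, "cation_count")) else 0,
      if (length(per_run) > 1) stats::sd(purrr::map_dbl(per_run, "anion_count")) else 0
    )
  )
  structure(list(per_residue = per_residue, global = counts,
                 condition = ensemble$condition, cutoff_A = cutoff_A),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("<contact_stats> '%s' (cutoff %g A)\n", x$condition, x$cutoff_A))
  print(x$per_residue)
  print(x$global)
  invisible(x)
}

#' Salt-bridge occupancy across a run ensemble
#'
#' A bridge is formed in a frame when the lysine NZ and the partner's distal
#' carbon (CG for Asp, CD for Glu) are within `cutoff_A` of each other.
#' Fractions are computed per run and summarised as mean and SD across runs.
#'
#' @param ensemble A [run_ensemble()].
#' @param pairs Data frame with columns `lys_resno` and `partner_resno`.
#' @param cutoff_A Distance cutoff in Angstrom (default 4).
#' @return Tibble with columns `pair`, `lys_resno`, `partner_resno`,
#'   `mean_fraction`, `sd_fraction`, `n_runs`.
#' @export
salt_bridge_fractions <- function(ensemble, pairs, cutoff_A = 4) {
  stopifnot(inherits(ensemble, "run_ensemble"), is.data.frame(pairs),
            all(c("lys_resno", "partner_resno") %in% names(pairs)))
  check_number(cutoff_A, "cutoff_A", lower = 0, strict_lower = TRUE)
  atoms <- ensemble$runs[[1]]$atoms
  groups <- charged_group_atoms(atoms)
  cut2 <- cutoff_A^2

  idx <- purrr::map(seq_len(nrow(pairs)), function(p) {
    nz <- which(atoms$resno == pairs$lys_resno[p] & atoms$elety == "NZ" &
                  atoms$type == "ATOM")
    cb <- which(atoms$resno == pairs$partner_resno[p] &
                  atoms$elety %in% c("CG", "CD") & atoms$type == "ATOM")
    if (length(nz) != 1 || length(cb) < 1) {
      abort(sprintf("Pair %d-%d not resolvable in the topology.",
                    pairs$lys_resno[p], pairs$partner_resno[p]))
    }
    c(nz = nz, cb = cb[1])
  })
  fr <- purrr::map(ensemble$runs, function(run) {
    purrr::map_dbl(idx, function(ij) {
      mean(.dist2_to(run$xyz, ij[["nz"]], ij[["cb"]]) <= cut2)
    })
  })
  fr <- do.call(rbind, fr)
  lab <- function(p) {
    pr <- groups$resid[match(pairs$partner_resno[p], groups$resno)]
    code <- c(LYS = "K", ASP = "D", GLU = "E")
    sprintf("K%d-%s%d", pairs$lys_resno[p],
            code[[pr %||% "GLU"]] %||% "X", pairs$partner_resno[p])
  }
  tibble(
    pair = purrr::map_chr(seq_len(nrow(pairs)), lab),
    lys_resno = pairs$lys_resno,
    partner_resno = pairs$partner_resno,
    mean_fraction = colMeans(fr),
    sd_fraction = if (nrow(fr) > 1) apply(fr, 2, stats::sd) else rep(0, ncol(fr)),
    n_runs = length(ensemble$runs)
  )
}

# Kabsch optimal rotation: returns 3x3 matrix rotating B onto A (both centred)
.kabsch <- function(A, B) {
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# superpose every frame of xyz (n_frames x 3n) onto ref coords (n x 3) using
# the fit atoms; returns the transformed xyz
.superpose <- function(xyz, ref, fit_idx) {
  nf <- nrow(xyz)
  out <- xyz
  refc <- ref[fit_idx, , drop = FALSE]
  ref_cm <- colMeans(refc)
  for (f in seq_len(nf)) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    fitc <- co[fit_idx, , drop = FALSE]
    cm <- colMeans(fitc)
    R <- .kabsch(sweep(refc, 2, ref_cm), sweep(fitc, 2, cm))
    moved <- sweep(sweep(co, 2, cm) %*% R, 2, ref_cm, "+")
    out[f, ] <- as.vector(t(moved))
  }
  out
}

#' Backbone atomic fluctuations (RMSF) per residue
#'
#' Each frame is least-squares superposed (Kabsch) onto the ensemble-average
#' structure in two passes (fit to the mean, recompute the mean, fit again),
#' then the root-mean-square fluctuation about the mean position is computed
#' per atom and averaged over the backbone selection within each residue.
#' Cross-run mean and SD are reported.
#'
#' @param ensemble A [run_ensemble()] with at least 2 frames per run.
#' @param selection Atom names to include (default backbone N, CA, C, O).
#' @return Tibble with columns `resno`, `resid`, `mean_rmsf_A`, `sd_rmsf_A`,
#'   `n_runs`.
#' @export
backbone_rmsf <- function(ensemble, selection = c("N", "CA", "C", "O")) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  atoms <- ensemble$runs[[1]]$atoms
  sel <- which(atoms$type == "ATOM" & atoms$elety %in% selection)
  if (length(sel) == 0) abort("No atoms match the backbone selection.")

  per_run <- purrr::map(ensemble$runs, function(run) {
    xyz <- run$xyz
    if (nrow(xyz) < 2) abort("RMSF needs at least 2 frames per run.")
    mean_coords <- function(z) {
      matrix(colMeans(z), ncol = 3, byrow = TRUE)
    }
    ref <- mean_coords(xyz)
    for (pass in 1:2) {
      xyz_fit <- .superpose(xyz, ref, sel)
      ref <- mean_coords(xyz_fit)
    }
    dev2 <- sweep(xyz_fit, 2, as.vector(t(ref)))^2
    # per-atom RMSF = sqrt(mean over frames of squared displacement)
    per_atom <- sqrt(colMeans(
      dev2[, seq(1, ncol(dev2), 3), drop = FALSE] +
        dev2[, seq(2, ncol(dev2), 3), drop = FALSE] +
        dev2[, seq(3, ncol(dev2), 3), drop = FALSE]
    ))
    per_atom
  })

  sel_atoms <- atoms[sel, ]
  res_tab <- unique(sel_atoms[c("resno", "resid")])
  rmsf_mat <- do.call(rbind, purrr::map(per_run, function(pa) {
    purrr::map_dbl(res_tab$resno, function(rn) {
      mean(pa[sel][sel_atoms$resno == rn])
    })
  }))
  tibble(
    resno = res_tab$resno, resid = res_tab$resid,
    mean_rmsf_A = colMeans(rmsf_mat),
    sd_rmsf_A = if (nrow(rmsf_mat) > 1) apply(rmsf_mat, 2, stats::sd) else rep(0, ncol(rmsf_mat)),
    n_runs = length(ensemble$runs)
  )
}

#' Count intramolecular hydrogen bonds per frame
#'
#' A bond is counted when a donor heavy atom (N or O carrying a hydrogen) is
#' within `d_cut_A` of an acceptor (N or O in a different residue) and the
#' donor-H-acceptor angle is at least `angle_cut_deg`. Hydrogens are assigned
#' to the nearest N/O of the same residue within 1.2 Angstrom in the first
#' frame. Protein atoms only; ions are ignored.
#'
#' @param ensemble A [run_ensemble()].
#' @param d_cut_A Donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.0).
#' @param angle_cut_deg Donor-H-acceptor angle cutoff, degrees (default 135).
#' @return Tibble with one row: `mean_hbonds`, `sd_hbonds`, `n_runs`.
#' @export
count_hbonds <- function(ensemble, d_cut_A = 3.0, angle_cut_deg = 135) {
  stopifnot(inherits(ensemble, "run_ensemble"))
  atoms <- ensemble$runs[[1]]$atoms
  prot <- atoms$type == "ATOM" & !(atoms$resid %in% c(.cation_resids, .anion_resids))
  h_idx <- which(prot & grepl("^[0-9]*H", atoms$elety))
  heavy_no <- which(prot & grepl("^[NO]", atoms$elety))
  if (length(heavy_no) == 0) abort("No N/O heavy atoms found.")

  # donor assignment from frame 1 of run 1
  co1 <- matrix(ensemble$runs[[1]]$xyz[1, ], ncol = 3, byrow = TRUE)
  donors <- purrr::map(h_idx, function(h) {
    cand <- heavy_no[atoms$resno[heavy_no] == atoms$resno[h]]
    if (length(cand) == 0) return(NULL)
    d <- sqrt(rowSums(sweep(co1[cand, , drop = FALSE], 2, co1[h, ])^2))
    if (min(d) > 1.2) return(NULL)
    c(D = cand[which.min(d)], H = h)
  })
  donors <- donors[!purrr::map_lgl(donors, is.null)]
  if (length(donors) == 0) abort("No identifiable donors (no hydrogens near N/O).")

  cosmin <- cos(angle_cut_deg * pi / 180)
  per_run <- purrr::map_dbl(ensemble$runs, function(run) {
    xyz <- run$xyz
    nf <- nrow(xyz)
    total <- 0
    for (f in seq_len(nf)) {
      co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      for (dn in donors) {
        D <- dn[["D"]]; H <- dn[["H"]]
        acc <- heavy_no[atoms$resno[heavy_no] != atoms$resno[D]]
        if (length(acc) == 0) next
        dv <- sweep(co[acc, , drop = FALSE], 2, co[D, ])
        dist <- sqrt(rowSums(dv^2))
        ok <- dist <= d_cut_A
        if (!any(ok)) next
        hv <- co[H, ] - co[D, ]
        for (a in acc[ok]) {
          v1 <- co[D, ] - co[H, ]
          v2 <- co[a, ] - co[H, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          # angle(D-H-A) >= cutoff  <=>  cos(angle) <= cos(cutoff)
          if (cosang <= cosmin) total <- total + 1
        }
      }
    }
    total / nf
  })
  tibble(
    mean_hbonds = mean(per_run),
    sd_hbonds = if (length(per_run) > 1) stats::sd(per_run) else 0,
    n_runs = length(per_run)
  )
}
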