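# hand-built two-frame fixture: an ASP with a sodium at 3.5 then 8 A, a
# LYS/GLU pair bridged at 3.9 then 4.1 A
make_two_frame_traj <- function() {
  atoms <- tibble::tibble(
    elety = c("CA", "CG", "OD1", "OD2", "CA", "NZ", "CA", "CD", "OE1", "OE2", "NA"),
    resid = c(rep("ASP", 4), rep("LYS", 2), rep("GLU", 4), "NA+"),
    resno = c(rep(10L, 4), rep(25L, 2), rep(42L, 4), 1001L),
    chain = c(rep("A", 10), "B"),
    type = c(rep("ATOM", 10), "HETATM")
  )
  co <- function(na_d, bridge_d) {
    m <- rbind(
      c(0, 0, 0), c(0, 1, 0), c(0, 1.5, 0.5), c(0, 1.5, -0.5),   # ASP
      c(20, 0, 0), c(20, 1, 0),                                  # LYS
      c(20 + bridge_d, 1, 0), c(20 + bridge_d, 1, 0) + c(0.8, 0, 0),
      c(20 + bridge_d, 1, 0) + c(1.2, 0.4, 0),                   # GLU CD/OE1
      c(20 + bridge_d, 1, 0) + c(1.2, -0.4, 0),                  # GLU OE2
      c(0, 1, na_d)                                              # sodium near OD-free axis
    )
    # GLU CD is atom 8; place CD itself at bridge distance from NZ
    m[8, ] <- c(20, 1, 0) + c(bridge_d, 0, 0)
    as.vector(t(m))
  }
  xyz <- rbind(co(3.5, 3.9), co(8, 4.1))
  new_trajectory(atoms, xyz)
}

test_that("charged-group mapping follows standard side-chain naming", {
  traj <- make_two_frame_traj()
  g <- charged_group_atoms(traj$atoms)
  expect_setequal(g$resid, c("ASP", "LYS", "GLU"))
  expect_equal(g$group_atoms[[match("LYS", g$resid)]], "NZ")
  expect_equal(g$bridge_atom[match("GLU", g$resid)], "CD")
  expect_equal(g$bridge_atom[match("ASP", g$resid)], "CG")
  # uncharged residues are absent
  atoms2 <- tibble::tibble(elety = c("CA", "CA"), resid = c("GLY", "ALA"),
                           resno = 1:2, chain = "A", type = "ATOM")
  expect_equal(nrow(charged_group_atoms(atoms2)), 0)
  # wrong dialect is an error
  atoms3 <- tibble::tibble(elety = c("CA", "XX"), resid = "LYS",
                           resno = 5L, chain = "A", type = "ATOM")
  expect_error(charged_group_atoms(atoms3), "dialect")
})

test_that("contact fraction on the two-frame fixture is exactly one half", {
  ens <- run_ensemble(list(make_two_frame_traj()))
  st <- ion_contact_stats(ens, cutoff_A = 4)
  asp <- st$per_residue[st$per_residue$resno == 10, ]
  expect_equal(asp$mean_fraction, 0.5)
  # lysine sees no anions at all
  expect_equal(st$per_residue$mean_fraction[st$per_residue$resno == 25], 0)
  # one sodium in contact in one of two frames
  expect_equal(st$global$mean_count[st$global$species == "cation"], 0.5)
  expect_equal(st$global$mean_count[st$global$species == "anion"], 0)
})

test_that("no ions means zero fractions and counts", {
  traj <- make_two_frame_traj()
  keep <- traj$atoms$type == "ATOM"
  sub <- new_trajectory(traj$atoms[keep, ],
                        traj$xyz[, rep(which(keep), each = 3) * 3 +
                                   rep(c(-2, -1, 0), sum(keep))])
  ens <- run_ensemble(list(sub))
  st <- ion_contact_stats(ens)
  expect_true(all(st$per_residue$mean_fraction == 0))
  expect_true(all(st$global$mean_count == 0))
})

test_that("salt bridge cutoff is inclusive at 4 A and fractions average over runs", {
  ens <- run_ensemble(list(make_two_frame_traj()))
  sb <- salt_bridge_fractions(ens, tibble::tibble(lys_resno = 25,
                                                  partner_resno = 42))
  expect_equal(sb$mean_fraction, 0.5) # 3.9 in, 4.1 out
  expect_equal(sb$pair, "K25-E42")
  # three runs with fractions 0.4 / 0.5 / 0.6
  mk <- function(occ, seed) sim_toy_trajectory(
    bridge_targets = tibble::tibble(lys_resno = 25, partner_resno = 42,
                                    partner_resid = "GLU", occupancy = occ),
    n_frames = 10, seed = seed
  )$runs[[1]]
  runs <- list(mk(0.4, 1), mk(0.5, 1), mk(0.6, 1))
  # force exact per-run fractions by construction: occupancy 1 for ceil(f*n)
  frames <- function(f) {
    tr <- mk(1, 1)
    xyz <- tr$xyz
    out <- mk(0, 1)$xyz
    n_in <- round(f * 10)
    if (n_in > 0) out[seq_len(n_in), ] <- xyz[seq_len(n_in), ]
    new_trajectory(tr$atoms, out)
  }
  ens3 <- run_ensemble(list(frames(0.4), frames(0.5), frames(0.6)))
  sb3 <- salt_bridge_fractions(ens3, tibble::tibble(lys_resno = 25,
                                                    partner_resno = 42))
  expect_equal(sb3$mean_fraction, 0.5, tolerance = 1e-12)
  expect_equal(sb3$sd_fraction, 0.1, tolerance = 1e-12)
  expect_error(salt_bridge_fractions(ens, tibble::tibble(
    lys_resno = 99, partner_resno = 42)), "not resolvable")
})

test_that("vectorised statistics equal the brute-force oracle exactly", {
  for (seed in 1:5) {
    ens <- sim_toy_trajectory(
      ion_targets = tibble::tibble(resno = c(10, 20, 30),
                                   resid = c("ASP", "GLU", "LYS"),
                                   occupancy = c(0.5, 0.2, 0.8)),
      bridge_targets = tibble::tibble(lys_resno = 40, partner_resno = 50,
                                      partner_resid = "GLU", occupancy = 0.5),
      n_frames = 10, n_runs = 1, seed = seed
    )
    traj <- ens$runs[[1]]
    st <- ion_contact_stats(ens)
    orc <- oracle_ion_contacts(traj)
    expect_identical(st$per_residue$mean_fraction, orc$fraction)
    sb <- salt_bridge_fractions(ens, tibble::tibble(lys_resno = 40,
                                                    partner_resno = 50))
    expect_identical(sb$mean_fraction, oracle_bridge_fraction(traj, 40, 50))
  }
})

test_that("fraction statistics are invariant to rigid motion of every frame", {
  ens <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 10, resid = "ASP", occupancy = 0.5),
    bridge_targets = tibble::tibble(lys_resno = 25, partner_resno = 42,
                                    partner_resid = "GLU", occupancy = 0.4),
    n_frames = 40, seed = 3
  )
  R <- rot_zx(0.7, -1.2)
  moved <- run_ensemble(list(transform_traj(ens$runs[[1]], R, c(5, -3, 11))))
  a <- ion_contact_stats(ens)$per_residue$mean_fraction
  b <- ion_contact_stats(moved)$per_residue$mean_fraction
  expect_equal(a, b, tolerance = 1e-12)
  pa <- salt_bridge_fractions(ens, tibble::tibble(lys_resno = 25, partner_resno = 42))
  pb <- salt_bridge_fractions(moved, tibble::tibble(lys_resno = 25, partner_resno = 42))
  expect_equal(pa$mean_fraction, pb$mean_fraction, tolerance = 1e-12)
})

test_that("identical runs give zero cross-run SD", {
  tr <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 10, resid = "ASP", occupancy = 0.5),
    n_frames = 30, seed = 4
  )$runs[[1]]
  ens <- run_ensemble(list(tr, tr, tr))
  st <- ion_contact_stats(ens)
  expect_true(all(st$per_residue$sd_fraction == 0))
  expect_true(all(st$global$sd_count == 0))
})

test_that("RMSF is zero for static or rigidly translated frames", {
  atoms <- tibble::tibble(
    elety = rep(c("N", "CA", "C", "O"), 2),
    resid = rep(c("ALA", "GLY"), each = 4),
    resno = rep(1:2, each = 4), chain = "A", type = "ATOM"
  )
  base <- as.vector(t(matrix(rnorm(24, sd = 3), ncol = 3)))
  xyz_static <- rbind(base, base, base)
  r1 <- backbone_rmsf(run_ensemble(list(new_trajectory(atoms, xyz_static))))
  expect_equal(r1$mean_rmsf_A, c(0, 0), tolerance = 1e-10)
  # pure translations are removed by superposition
  xyz_trans <- rbind(base, base + rep(c(4, -2, 7), 8), base + rep(c(-1, 5, 0), 8))
  r2 <- backbone_rmsf(run_ensemble(list(new_trajectory(atoms, xyz_trans))))
  expect_equal(r2$mean_rmsf_A, c(0, 0), tolerance = 1e-10)
  expect_error(backbone_rmsf(run_ensemble(list(new_trajectory(atoms, rbind(base))))),
               "2 frames")
})

test_that("a symmetric breathing displacement of +/- d gives RMSF = d", {
  # all atoms on a sphere, frames scaled by (1 +/- s): centroids coincide and
  # radial displacements exert no torque, so the optimal superposition is the
  # identity and every atom moves exactly +/- d about its mean position
  rho <- 5; d <- 0.3; s <- d / rho
  co <- rbind(
    c(rho, 0, 0), c(-rho, 0, 0), c(0, rho, 0), c(0, -rho, 0),
    c(0, 0, rho), c(0, 0, -rho),
    rho / sqrt(3) * c(1, 1, 1), -rho / sqrt(3) * c(1, 1, 1)
  )
  atoms <- tibble::tibble(
    elety = rep(c("N", "CA", "C", "O"), 2),
    resid = rep("ALA", 8),
    resno = rep(1:2, each = 4), chain = "A", type = "ATOM"
  )
  xyz <- rbind(as.vector(t((1 + s) * co)), as.vector(t((1 - s) * co)))
  r <- backbone_rmsf(run_ensemble(list(new_trajectory(atoms, xyz))))
  expect_equal(r$mean_rmsf_A, c(d, d), tolerance = 1e-10)
})

test_that("hydrogen bonds require both distance and angle", {
  # linear N-H...O at 2.9 A and 170 degrees
  mk <- function(no_dist, angle_deg) {
    ang <- angle_deg * pi / 180
    atoms <- tibble::tibble(
      elety = c("N", "H", "CA", "O", "C"),
      resid = c("ALA", "ALA", "ALA", "GLY", "GLY"),
      resno = c(1L, 1L, 1L, 5L, 5L), chain = "A", type = "ATOM"
    )
    N <- c(0, 0, 0)
    H <- c(1, 0, 0)
    # acceptor placed so the D-H-A angle at H is angle_deg and |N-O| = no_dist
    # solve along the direction making the required angle with H->N
    dir <- c(cos(pi - ang), sin(pi - ang), 0)
    # distance from H to O such that |N-O| = no_dist
    f <- function(t) sqrt(sum((H + t * dir - N)^2)) - no_dist
    t <- uniroot(f, c(0.1, 10))$root
    O <- H + t * dir
    co <- rbind(N, H, c(0, -1.5, 0), O, O + c(0.5, 1.1, 0))
    new_trajectory(atoms, rbind(as.vector(t(co)), as.vector(t(co))))
  }
  good <- run_ensemble(list(mk(2.9, 170)))
  expect_equal(count_hbonds(good)$mean_hbonds, 1)
  far <- run_ensemble(list(mk(3.4, 170)))
  expect_equal(count_hbonds(far)$mean_hbonds, 0)
  bent <- run_ensemble(list(mk(2.9, 100)))
  expect_equal(count_hbonds(bent)$mean_hbonds, 0)
})

test_that("multi-model PDB round trip preserves statistics", {
  ens <- sim_toy_trajectory(
    ion_targets = tibble::tibble(resno = 10, resid = "ASP", occupancy = 0.5),
    bridge_targets = tibble::tibble(lys_resno = 25, partner_resno = 42,
                                    partner_resid = "GLU", occupancy = 0.4),
    n_frames = 20, seed = 8
  )
  path <- tempfile(fileext = ".pdb")
  write_trajectory(ens$runs[[1]], path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 20)
  expect_equal(sum(grepl("^ENDMDL", txt)), 20)
  back <- read_trajectory(path)
  ens2 <- run_ensemble(list(back))
  a <- ion_contact_stats(ens)$per_residue
  b <- ion_contact_stats(ens2)$per_residue
  expect_equal(a$mean_fraction, b$mean_fraction, tolerance = 1e-6)
  sa <- salt_bridge_fractions(ens, tibble::tibble(lys_resno = 25, partner_resno = 42))
  sb <- salt_bridge_fractions(ens2, tibble::tibble(lys_resno = 25, partner_resno = 42))
  expect_equal(sa$mean_fraction, sb$mean_fraction, tolerance = 1e-6)
  unlink(path)
})

test_that("distinct-ion counts respect the charge asymmetry of the layout", {
  # acidic-heavy layout akin to a -12 domain: many cation targets, one lysine
  acid <- tibble::tibble(
    resno = seq(10, 150, by = 10),
    resid = rep(c("ASP", "GLU"), length.out = 15),
    occupancy = 0.3
  )
  lys <- tibble::tibble(resno = 200, resid = "LYS", occupancy = 0.05)
  ens <- sim_toy_trajectory(ion_targets = rbind(acid, lys),
                            n_frames = 150, n_runs = 2, seed = 13)
  st <- ion_contact_stats(ens)
  cat_n <- st$global$mean_count[st$global$species == "cation"]
  an_n <- st$global$mean_count[st$global$species == "anion"]
  expect_gt(cat_n, an_n)
  expect_lte(cat_n, 16) # never more ions in contact than exist
})
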