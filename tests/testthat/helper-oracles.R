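# Independent oracles used across tests. These deliberately avoid the package's
# vectorised code paths: plain loops and hand-written formulas only.

# two-state LEM signal, written out by hand
oracle_two_state_signal <- function(u, dG0, m_eq, fn, a, fd, b, T_K) {
  RT <- 8.314e-3 * T_K
  K <- exp(-(dG0 - m_eq * u) / RT)
  (fn + a * u + (fd + b * u) * K) / (1 + K)
}

# brute-force per-frame ion contact fractions: nested loops over frames,
# charged residues, group atoms and ions
oracle_ion_contacts <- function(traj, cutoff = 4) {
  atoms <- traj$atoms
  xyz <- traj$xyz
  group_map <- list(LYS = c("NZ"), ASP = c("CG", "OD1", "OD2"),
                    GLU = c("CD", "OE1", "OE2"))
  cations <- c("NA+", "NA", "SOD", "K+", "K", "POT", "LI+", "LI")
  anions <- c("CL-", "CL", "CLA", "BR-", "BR")
  charged <- unique(atoms[atoms$type == "ATOM" &
                            atoms$resid %in% names(group_map),
                          c("resno", "resid")])
  charged <- charged[order(charged$resno), ]
  nf <- nrow(xyz)
  frac <- numeric(nrow(charged))
  coord <- function(f, i) xyz[f, (3 * i - 2):(3 * i)]
  for (g in seq_len(nrow(charged))) {
    gat <- which(atoms$resno == charged$resno[g] & atoms$type == "ATOM" &
                   atoms$elety %in% group_map[[charged$resid[g]]])
    opp <- if (charged$resid[g] == "LYS") anions else cations
    ions <- which(atoms$resid %in% opp)
    hits <- 0
    for (f in seq_len(nf)) {
      found <- FALSE
      for (a in gat) for (i in ions) {
        if (sqrt(sum((coord(f, a) - coord(f, i))^2)) <= cutoff) found <- TRUE
      }
      if (found) hits <- hits + 1
    }
    frac[g] <- hits / nf
  }
  data.frame(resno = charged$resno, resid = charged$resid, fraction = frac)
}

# brute-force salt-bridge fraction for one pair (NZ to distal carbon)
oracle_bridge_fraction <- function(traj, lys_resno, partner_resno, cutoff = 4) {
  atoms <- traj$atoms
  xyz <- traj$xyz
  nz <- which(atoms$resno == lys_resno & atoms$elety == "NZ")
  cb <- which(atoms$resno == partner_resno & atoms$elety %in% c("CG", "CD"))[1]
  nf <- nrow(xyz)
  hits <- 0
  for (f in seq_len(nf)) {
    d <- sqrt(sum((xyz[f, (3 * nz - 2):(3 * nz)] -
                     xyz[f, (3 * cb - 2):(3 * cb)])^2))
    if (d <= cutoff) hits <- hits + 1
  }
  hits / nf
}

# analytic MI (bits) of a 2x2 joint distribution given as a matrix of counts
oracle_mi_2x2 <- function(counts) {
  p <- counts / sum(counts)
  pi <- rowSums(p); pj <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pi[i] * pj[j]))
  }
  mi
}

# rotate+translate every frame of a trajectory (for invariance tests)
transform_traj <- function(traj, R, t) {
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    co <- co %*% t(R)
    co <- sweep(co, 2, t, "+")
    xyz[f, ] <- as.vector(t(co))
  }
  new_trajectory(traj$atoms, xyz)
}

# seeded Gaussian vector for constructing noisy fixtures inline
with_seed_vec <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}

# a simple rotation matrix about z then x
rot_zx <- function(az, ax) {
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  Rz %*% Rx
}
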