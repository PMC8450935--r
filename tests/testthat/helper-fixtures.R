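# Fixtures are built in code; nothing binary ships with the package.

water_atoms_df <- function(n) {
  data.frame(
    atom_id = seq_len(3 * n),
    atom_name = rep(c("OW", "HW1", "HW2"), n),
    element = rep(c("O", "H", "H"), n),
    residue_id = rep(seq_len(n), each = 3),
    residue_name = rep("SOL", 3 * n), chain_id = rep("W", 3 * n),
    vdw_radius = rep(c(0.158, 0, 0), n),
    partial_charge = rep(c(-0.82, 0.41, 0.41), n),
    is_heavy = rep(c(TRUE, FALSE, FALSE), n),
    is_water = rep(TRUE, 3 * n), stringsAsFactors = FALSE
  )
}

water_xyz_of <- function(opos) {
  n <- nrow(opos)
  xyz <- matrix(0, 3 * n, 3)
  if (n > 0) {
    xyz[seq(1, by = 3, length.out = n), ] <- opos
    xyz[seq(2, by = 3, length.out = n), ] <- sweep(opos, 2, c(0.1, 0, 0), "+")
    xyz[seq(3, by = 3, length.out = n), ] <- sweep(opos, 2, c(0, 0.1, 0), "+")
  }
  xyz
}

# A minimal water-in-a-box trajectory with explicit oxygen positions; several
# frames may be supplied as a list of oxygen matrices (counts may differ).
toy_water_traj <- function(opos, box = c(5, 5, 5), n_frames = 1) {
  if (!is.list(opos)) opos <- rep(list(opos), n_frames)
  nmax <- max(0, vapply(opos, nrow, integer(1)))
  atoms <- water_atoms_df(nmax)
  frames <- lapply(seq_along(opos), function(i) {
    list(xyz = water_xyz_of(opos[[i]]), box = box, time = i - 1,
         atom_idx = seq_len(3 * nrow(opos[[i]])))
  })
  hydration_trajectory(atoms, frames)
}

# A toy protein topology: one CA atom per residue.
toy_protein_traj <- function(xyz, box = c(5, 5, 5), radius = 0.17, charge = 0,
                             chain = "A") {
  n <- nrow(xyz)
  atoms <- data.frame(
    atom_id = seq_len(n), atom_name = sprintf("CA%d", seq_len(n)),
    element = rep("C", n), residue_id = seq_len(n),
    residue_name = rep("ALA", n), chain_id = rep(chain, n),
    vdw_radius = rep(radius, length.out = n),
    partial_charge = rep(charge, length.out = n),
    is_heavy = rep(TRUE, n), is_water = rep(FALSE, n), stringsAsFactors = FALSE
  )
  hydration_trajectory(atoms, list(list(xyz = xyz, box = box, time = 0)))
}

# Combine a static protein with per-frame water oxygens (counts may differ).
solvated_traj <- function(prot, wat_opos_frames, box = c(5, 5, 5)) {
  np <- nrow(prot$atoms)
  nmax <- max(0, vapply(wat_opos_frames, nrow, integer(1)))
  watoms <- water_atoms_df(nmax)
  watoms$atom_id <- watoms$atom_id + np
  watoms$residue_id <- watoms$residue_id + (if (np > 0) max(prot$atoms$residue_id) else 0)
  atoms <- rbind(prot$atoms, watoms)
  frames <- lapply(seq_along(wat_opos_frames), function(i) {
    op <- wat_opos_frames[[i]]
    list(xyz = rbind(prot$frames[[1]]$xyz, water_xyz_of(op)), box = box,
         time = i - 1, atom_idx = c(seq_len(np), np + seq_len(3 * nrow(op))))
  })
  hydration_trajectory(atoms, frames)
}

# Uniform points inside an axis-aligned ellipsoid.
runif_ellipsoid <- function(n, a, center = c(0, 0, 0)) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    u <- matrix(runif(3 * max(n, 10), -1, 1), ncol = 3)
    u <- u[rowSums(u^2) <= 1, , drop = FALSE]
    out <- rbind(out, u)
  }
  sweep(sweep(out[seq_len(n), , drop = FALSE], 2, a, "*"), 2, center, "+")
}

# Area-weighted sampling of an ellipsoid surface (for brute-force distance
# oracles): uniform on the unit sphere, mapped, thinned by the local area
# element ratio.
sample_ellipsoid_surface <- function(n, a) {
  out <- matrix(NA_real_, 0, 3)
  gmax <- max(a[1] * a[2], a[1] * a[3], a[2] * a[3])
  while (nrow(out) < n) {
    m <- 2 * n
    z <- runif(m, -1, 1); ph <- runif(m, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    u <- cbind(s * cos(ph), s * sin(ph), z)
    g <- sqrt((a[2] * a[3] * u[, 1])^2 + (a[1] * a[3] * u[, 2])^2 +
              (a[1] * a[2] * u[, 3])^2)
    keep <- runif(m) < g / gmax
    out <- rbind(out, sweep(u[keep, , drop = FALSE], 2, a, "*"))
  }
  out[seq_len(n), , drop = FALSE]
}
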