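#' Specification of a synthetic solvated system
#'
#' Describes the statistical structure of a synthetic test system: a
#' pseudo-protein (atoms uniformly filling an ellipsoid at the box centre)
#' surrounded by water placed by a hard-core point process whose local
#' intensity is \eqn{\rho_{bulk}(1 + \eta_0(d))}, with \eqn{\eta_0}
#' decaying to zero within the plateau distance, mirroring the radial
#' enhancement of real protein hydration shells. There are no forces or
#' dynamics: the analysis consumes positions only, so a point process with
#' the right density structure is the appropriate test substrate.
#'
#' @param box orthorhombic box lengths (nm); must be at least
#'   `2 * (max(semi_axes) + plateau)` in every direction when a protein is
#'   present.
#' @param rho_bulk target bulk number density (molecules nm^-3).
#' @param semi_axes pseudo-protein ellipsoid semi-axes (nm), or `NULL` for a
#'   pure bulk box.
#' @param n_protein_atoms number of pseudo-protein atoms (>= 4).
#' @param amplitude shell enhancement amplitude \eqn{\eta_0}: a scalar, or a
#'   named vector `c(IBS = ..., NIBS = ...)` for patchwise enhancement keyed
#'   by the nearest protein atom's patch.
#' @param enhancement_shape function of distance `d` (nm) in `[0, 1]` scaling
#'   the amplitude; must vanish for `d >= plateau`. Default: unit step inside
#'   the plateau.
#' @param plateau distance beyond which the enhancement is zero (nm).
#' @param ibs_fraction fraction of protein atoms labelled IBS (one cap of the
#'   ellipsoid along its long axis).
#' @param polar_fraction named fractions of polar atoms (`|q| > 0.2`) per
#'   patch; makes the IBS-like patch relatively hydrophobic.
#' @param hard_core minimum O-O distance (nm); mimics water's exclusion so
#'   overlap/SASA logic sees realistic geometry.
#' @param probe probe radius defining the solvent-accessible surface waters
#'   are excluded from (nm).
#' @param water_radius vdW radius of the water oxygen (nm); hydrogens carry
#'   no vdW radius (SPC convention).
#' @param seed base seed; all frame sub-seeds derive from it.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(box = c(5.4, 5.2, 5.0),
                           rho_bulk = RHO_BULK_DEFAULT,
                           semi_axes = c(1.5, 1.2, 0.9),
                           n_protein_atoms = 120,
                           amplitude = 0,
                           enhancement_shape = NULL,
                           plateau = 1.0,
                           ibs_fraction = 0.3,
                           polar_fraction = c(IBS = 0.35, NIBS = 0.75),
                           hard_core = 0.26,
                           probe = 0.14,
                           water_radius = 0.158,
                           seed = 1) {
  if (any(box <= 0) || rho_bulk < 0) stopf("box lengths must be positive and density non-negative")
  enhancement_shape <- enhancement_shape %||% function(d) as.numeric(d < plateau)
  if (!is.null(semi_axes)) {
    if (n_protein_atoms < 4) stopf("need at least 4 protein atoms")
    if (min(box) < 2 * (max(semi_axes) + plateau) - 1e-9) {
      stopf("box too small: need at least %.2f nm in every direction for semi-axes %.2f and plateau %.2f",
            2 * (max(semi_axes) + plateau), max(semi_axes), plateau)
    }
  }
  if (!is.null(names(amplitude)) && !all(c("IBS", "NIBS") %in% names(amplitude))) {
    stopf("patchwise amplitude must name both IBS and NIBS")
  }
  dgrid <- seq(0, plateau * 2, by = 0.005)
  sh <- enhancement_shape(dgrid)
  if (any(sh[dgrid >= plateau] != 0)) stopf("enhancement_shape must vanish beyond the plateau distance")
  if (any(outer(sh, amplitude) <= -1)) stopf("enhancement must stay above -1 everywhere")
  # hard-core feasibility: packing fraction must stay clear of the random
  # sequential adsorption jamming limit (~0.384 for spheres)
  eta_max <- max(0, amplitude * max(sh))
  phi <- rho_bulk * (1 + eta_max) * (4 * pi / 3) * (hard_core / 2)^3
  if (phi > 0.36) {
    stopf("target density %.1f nm^-3 (enhanced %.1f) infeasible for a %.2f nm hard core (packing fraction %.3f vs RSA jamming ~0.384)",
          rho_bulk, rho_bulk * (1 + eta_max), hard_core, phi)
  }
  structure(list(box = box, rho_bulk = rho_bulk, semi_axes = semi_axes,
                 n_protein_atoms = n_protein_atoms, amplitude = amplitude,
                 enhancement_shape = enhancement_shape, plateau = plateau,
                 ibs_fraction = ibs_fraction, polar_fraction = polar_fraction,
                 hard_core = hard_core, probe = probe,
                 water_radius = water_radius, seed = seed,
                 eta_max = eta_max),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: box %s nm, rho_bulk %.2f nm^-3, seed %d\n",
              paste(x$box, collapse = " x "), x$rho_bulk, x$seed))
  if (!is.null(x$semi_axes)) {
    cat(sprintf("  pseudo-protein: %d atoms in ellipsoid (%s) nm, amplitude %s\n",
                x$n_protein_atoms, paste(x$semi_axes, collapse = ", "),
                paste(x$amplitude, collapse = "/")))
  }
  invisible(x)
}

# eta_0(d, patch) on the specified intensity.
spec_enhancement <- function(spec, d, patch = NULL) {
  sh <- spec$enhancement_shape(d)
  amp <- spec$amplitude
  if (length(amp) == 1 && is.null(names(amp))) return(amp * sh)
  if (is.null(patch)) stopf("patchwise amplitude requires patch labels")
  unname(amp[patch]) * sh
}

# Sequential hard-core insertion of exactly n points by batched dart
# throwing (randomness stays in R for seed reproducibility).
rsa_points <- function(n, box, rmin, max_attempts = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  max_attempts <- max_attempts %||% (2000 * n + 1e6)
  acc <- matrix(numeric(0), 0, 3)
  attempts <- 0
  while (nrow(acc) < n) {
    m <- min(max(50000, 20 * (n - nrow(acc))), 400000)
    if (attempts + m > max_attempts) {
      stopf("hard-core insertion failed: placed %d of %d points after %d attempts (density too close to jamming)",
            nrow(acc), n, attempts)
    }
    prop <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]), runif(m, 0, box[3]))
    keep <- hardcore_add_cpp(acc, prop, box, rmin)
    attempts <- attempts + m
    add <- prop[keep, , drop = FALSE]
    if (nrow(acc) + nrow(add) > n) add <- add[seq_len(n - nrow(acc)), , drop = FALSE]
    acc <- rbind(acc, add)
  }
  acc
}

# SPC-like hydrogen placement: two H at 0.1 nm, 109.47 degrees, random
# molecular orientation.
water_hydrogens <- function(opos) {
  n <- nrow(opos)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v - u * rowSums(v * u)
  v <- v / sqrt(rowSums(v^2))
  ang <- 109.47 * pi / 180
  h1 <- opos + 0.1 * u
  h2 <- opos + 0.1 * (cos(ang) * u + sin(ang) * v)
  list(h1 = h1, h2 = h2)
}

water_topology <- function(n_mol, spec) {
  data.frame(
    atom_id = seq_len(3 * n_mol),
    atom_name = rep(c("OW", "HW1", "HW2"), n_mol),
    element = rep(c("O", "H", "H"), n_mol),
    residue_id = rep(seq_len(n_mol), each = 3),
    residue_name = "SOL",
    chain_id = "W",
    vdw_radius = rep(c(spec$water_radius, 0, 0), n_mol),
    partial_charge = rep(c(-0.82, 0.41, 0.41), n_mol),
    is_heavy = rep(c(TRUE, FALSE, FALSE), n_mol),
    is_water = TRUE,
    stringsAsFactors = FALSE
  )
}

water_frame_xyz <- function(opos) {
  h <- water_hydrogens(opos)
  xyz <- matrix(0, 3 * nrow(opos), 3)
  xyz[seq(1, by = 3, length.out = nrow(opos)), ] <- opos
  xyz[seq(2, by = 3, length.out = nrow(opos)), ] <- h$h1
  xyz[seq(3, by = 3, length.out = nrow(opos)), ] <- h$h2
  xyz
}

#' Generate a bulk water box
#'
#' Water oxygens are placed by sequential hard-core insertion (minimum O-O
#' distance `hard_core`) with the per-frame molecule count drawn from a
#' Poisson law at the target density, so the mean density is exact by
#' construction. Hydrogens are attached at fixed SPC geometry with random
#' orientation. Frames are independent given their per-frame sub-seeds.
#'
#' @param spec a `"synthetic_spec"`.
#' @param n_frames number of frames.
#' @param density override for the target density (molecules nm^-3);
#'   defaults to `spec$rho_bulk`.
#' @return a `hydration_traj` of pure water.
#' @export
generate_bulk_box <- function(spec, n_frames = 1, density = NULL) {
  density <- density %||% spec$rho_bulk
  phi <- density * (4 * pi / 3) * (spec$hard_core / 2)^3
  if (phi > 0.36) stopf("density %.2f nm^-3 infeasible for %.2f nm hard core", density, spec$hard_core)
  V <- prod(spec$box)
  opos_list <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    set.seed(spec$seed + 100003L * 1L + 7919L * i)
    n <- rpois(1, density * V)
    opos_list[[i]] <- rsa_points(n, spec$box, spec$hard_core)
  }
  n_max <- max(1, vapply(opos_list, nrow, integer(1)))
  topo <- water_topology(n_max, spec)
  frames <- lapply(seq_len(n_frames), function(i) {
    op <- opos_list[[i]]
    list(xyz = water_frame_xyz(op), box = spec$box, time = i - 1,
         atom_idx = seq_len(3 * nrow(op)))
  })
  hydration_trajectory(topo, frames)
}

#' Generate a pseudo-protein
#'
#' Atoms uniformly sampled inside the spec ellipsoid (centred in the box),
#' with vdW radii in 0.15-0.19 nm and partial charges drawn from a
#' two-component polar/nonpolar mixture whose polar fraction differs between
#' an IBS-like cap (atoms beyond a quantile of the long-axis coordinate) and
#' the remaining NIBS-like patch.
#'
#' @param spec a `"synthetic_spec"` with non-`NULL` `semi_axes`.
#' @return list with `atoms` (topology rows including `patch`), `xyz` (nm),
#'   and `E_true` (the specified ellipsoid as an `"ellipsoid"`).
#' @export
generate_protein_mimic <- function(spec) {
  if (is.null(spec$semi_axes)) stopf("spec has no protein ellipsoid")
  n <- spec$n_protein_atoms
  a <- spec$semi_axes
  center <- spec$box / 2
  set.seed(spec$seed + 555007L)
  for (try in 1:100) {
    m <- 4 * n + 50
    u <- cbind(runif(m, -1, 1), runif(m, -1, 1), runif(m, -1, 1))
    u <- u[rowSums(u^2) <= 1, , drop = FALSE]
    if (nrow(u) < n) next
    xyz <- sweep(sweep(u[seq_len(n), , drop = FALSE], 2, a, "*"), 2, center, "+")
    ok <- tryCatch({ fit_ellipsoid(xyz); TRUE }, error = function(e) FALSE)
    if (ok) break
    if (try == 100) stopf("could not sample a non-degenerate protein mimic")
  }
  x1 <- (xyz[, 1] - center[1])
  patch <- ifelse(x1 > quantile(x1, 1 - spec$ibs_fraction), "IBS", "NIBS")
  pf <- spec$polar_fraction[patch]
  polar <- runif(n) < pf
  q <- ifelse(polar,
              sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.25, 0.8),
              runif(n, -0.2, 0.2))
  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = paste0(sample(c("C", "N", "O"), n, replace = TRUE, prob = c(0.6, 0.2, 0.2)), seq_len(n)),
    residue_id = seq_len(n),
    residue_name = "MIM",
    chain_id = "A",
    vdw_radius = runif(n, 0.15, 0.19),
    partial_charge = q,
    is_water = FALSE,
    patch = patch,
    stringsAsFactors = FALSE
  )
  atoms$element <- substr(atoms$atom_name, 1, 1)
  atoms$is_heavy <- TRUE
  list(atoms = atoms, xyz = xyz, E_true = ellipsoid(center, a))
}

#' Generate hydrated pseudo-protein frames with known density structure
#'
#' Each frame thins an elevated-density hard-core bulk configuration with
#' keep probability \eqn{(1 + \eta_0(d, patch))/(1 + \eta_{max})}, set to
#' zero inside the protein's solvent-accessible surface. Independent thinning
#' scales a point process intensity exactly, so the realised water intensity
#' is \eqn{\rho_{bulk}(1 + \eta_0(d, patch))} outside the SAS — the ground
#' truth against which the shell and surface estimators are validated (see
#' [expected_shell_stats()] and [expected_surface_stats()]).
#'
#' @param spec a `"synthetic_spec"`.
#' @param n_frames number of frames.
#' @param protein optional result of [generate_protein_mimic()] (regenerated
#'   from the spec when omitted).
#' @return a `hydration_traj`: protein atoms followed by water molecules;
#'   attribute `protein` carries the mimic (with `E_true`).
#' @export
generate_hydrated_frames <- function(spec, n_frames = 1, protein = NULL) {
  protein <- protein %||% generate_protein_mimic(spec)
  rho_gen <- spec$rho_bulk * (1 + spec$eta_max)
  V <- prod(spec$box)
  E <- protein$E_true
  patchwise <- length(spec$amplitude) > 1 || !is.null(names(spec$amplitude))
  opos_list <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    set.seed(spec$seed + 100003L * 2L + 7919L * i)
    n <- rpois(1, rho_gen * V)
    pts <- rsa_points(n, spec$box, spec$hard_core)
    d <- ellipsoid_distance(pts, E)
    margin <- min_margin_cpp(pts, protein$xyz, protein$atoms$vdw_radius, spec$box)
    sh <- spec$enhancement_shape(d)
    if (patchwise) {
      patch <- rep("NIBS", n)
      nz <- which(sh != 0)
      if (length(nz) > 0) {
        near <- nearest_ref_cpp(pts[nz, , drop = FALSE], protein$xyz, spec$box)
        patch[nz] <- protein$atoms$patch[near]
      }
      eta0 <- spec_enhancement(spec, d, patch)
    } else {
      eta0 <- spec$amplitude * sh
    }
    p <- (1 + eta0) / (1 + spec$eta_max)
    keep <- margin >= spec$probe & runif(n) < p
    opos_list[[i]] <- pts[keep, , drop = FALSE]
  }
  n_max <- max(1, vapply(opos_list, nrow, integer(1)))
  wtopo <- water_topology(n_max, spec)
  np <- nrow(protein$atoms)
  wtopo$atom_id <- wtopo$atom_id + np
  wtopo$residue_id <- wtopo$residue_id + max(protein$atoms$residue_id)
  patoms <- protein$atoms[, setdiff(names(protein$atoms), "patch")]
  topo <- rbind(patoms, wtopo)
  frames <- lapply(seq_len(n_frames), function(i) {
    op <- opos_list[[i]]
    list(xyz = rbind(protein$xyz, water_frame_xyz(op)), box = spec$box,
         time = i - 1, atom_idx = c(seq_len(np), np + seq_len(3 * nrow(op))))
  })
  out <- hydration_trajectory(topo, frames)
  attr(out, "protein") <- protein
  out
}

# QMC integration helper over a centred bounding block: evaluates fn on
# Halton points (chunked) and returns mean(fn) * block volume. fn must
# return a numeric vector of point weights (0 outside the region).
qmc_integrate <- function(lo, hi, fn, n_qmc, chunk = 2e5) {
  vol <- prod(hi - lo)
  total <- 0
  done <- 0
  while (done < n_qmc) {
    m <- min(chunk, n_qmc - done)
    pts <- sweep(sweep(halton(m, 3, skip = 10 + done), 2, hi - lo, "*"), 2, lo, "+")
    total <- total + sum(fn(pts))
    done <- done + m
  }
  total / n_qmc * vol
}

# Plain-R min margin to a set of padded spheres (independent of the C++
# kernel used by the estimators).
r_min_margin <- function(pts, refs, pad) {
  out <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(refs))) {
    dj <- sqrt((pts[, 1] - refs[j, 1])^2 + (pts[, 2] - refs[j, 2])^2 +
               (pts[, 3] - refs[j, 3])^2) - pad[j]
    out <- pmin(out, dj)
  }
  out
}

r_nearest_patch <- function(pts, refs, patch) {
  best <- rep(Inf, nrow(pts))
  idx <- rep(1L, nrow(pts))
  for (j in seq_len(nrow(refs))) {
    dj <- (pts[, 1] - refs[j, 1])^2 + (pts[, 2] - refs[j, 2])^2 + (pts[, 3] - refs[j, 3])^2
    upd <- dj < best
    best[upd] <- dj[upd]
    idx[upd] <- j
  }
  patch[idx]
}

#' Exact expectations for the whole-shell estimators of a synthetic spec
#'
#' Numerically integrates the specified water intensity over the shell
#' region (quasi-Monte-Carlo on Halton points) to obtain the expected shell
#' count, the true SAS-excluded volume, and the expected relative density
#' increment as the shell estimator defines it. This integration is
#' independent of the estimators under test.
#'
#' @param spec a `"synthetic_spec"`.
#' @param protein the protein mimic (regenerated from the spec if omitted).
#' @param thickness shell thickness (nm).
#' @param n_qmc integration points.
#' @return list with `E_N_shell`, `V_ex`, `V_shell`, `V_avail`, and
#'   `eta_expected`.
#' @export
expected_shell_stats <- function(spec, protein = NULL, thickness = 1.0, n_qmc = 1.5e6) {
  protein <- protein %||% generate_protein_mimic(spec)
  E <- protein$E_true
  a <- spec$semi_axes
  lo <- E$center - (a + thickness + 1e-6)
  hi <- E$center + (a + thickness + 1e-6)
  pad <- protein$atoms$vdw_radius
  patchwise <- length(spec$amplitude) > 1 || !is.null(names(spec$amplitude))
  acc <- c(vex = 0, avail = 0, inten = 0)
  fn <- function(pts) {
    d <- ellipsoid_distance(pts, E)
    margin <- r_min_margin(pts, protein$xyz, pad)
    in_sas <- margin < spec$probe
    avail <- (d <= thickness) & !in_sas
    w <- numeric(nrow(pts))
    if (any(avail)) {
      if (patchwise) {
        patch <- r_nearest_patch(pts[avail, , drop = FALSE], protein$xyz, protein$atoms$patch)
        w[avail] <- 1 + spec_enhancement(spec, d[avail], patch)
      } else {
        w[avail] <- 1 + spec$amplitude * spec$enhancement_shape(d[avail])
      }
    }
    acc <<- acc + c(sum(in_sas), sum(avail), sum(w))
    w
  }
  inten_int <- qmc_integrate(lo, hi, fn, n_qmc)
  vol_bb <- prod(hi - lo)
  V_ex <- acc[["vex"]] / n_qmc * vol_bb
  V_avail <- acc[["avail"]] / n_qmc * vol_bb
  V_shell <- parallel_body_volume(E, thickness)
  E_N <- spec$rho_bulk * inten_int
  list(E_N_shell = E_N, V_ex = V_ex, V_shell = V_shell, V_avail = V_avail,
       eta_expected = E_N / (spec$rho_bulk * (V_shell - V_ex)) - 1)
}

#' Exact expectations for the per-surface density estimator
#'
#' Integrates the specified intensity over the counting region of a patch
#' (within `cutoff` of the patch's atoms, outside the SAS) and the bulk
#' intensity over the corresponding fictitious availability region (outside
#' the vdW-overlap zone), giving the expected
#' \eqn{\eta_{surf} = I_{real}/I_{fict} - 1}.
#'
#' @param spec a `"synthetic_spec"` with patchwise amplitude.
#' @param protein the protein mimic.
#' @param patch `"IBS"` or `"NIBS"`.
#' @param cutoff counting cutoff (nm).
#' @param n_qmc integration points.
#' @return list with `I_real`, `I_fict`, `eta_surf_expected`.
#' @export
expected_surface_stats <- function(spec, protein = NULL, patch = "IBS",
                                   cutoff = 0.55, n_qmc = 1.5e6) {
  protein <- protein %||% generate_protein_mimic(spec)
  sel <- protein$atoms$patch == patch
  if (!any(sel)) stopf("no atoms in patch %s", patch)
  sxyz <- protein$xyz[sel, , drop = FALSE]
  lo <- apply(sxyz, 2, min) - cutoff - 1e-6
  hi <- apply(sxyz, 2, max) + cutoff + 1e-6
  E <- protein$E_true
  pad <- protein$atoms$vdw_radius
  acc <- c(real = 0, fict = 0)
  fn <- function(pts) {
    near <- r_min_margin(pts, sxyz, rep(0, nrow(sxyz))) <= cutoff
    if (!any(near)) return(numeric(nrow(pts)))
    margin <- rep(Inf, nrow(pts))
    margin[near] <- r_min_margin(pts[near, , drop = FALSE], protein$xyz, pad)
    real_ok <- near & margin >= spec$probe
    fict_ok <- near & margin >= spec$water_radius
    w <- numeric(nrow(pts))
    if (any(real_ok)) {
      d <- ellipsoid_distance(pts[real_ok, , drop = FALSE], E)
      pp <- r_nearest_patch(pts[real_ok, , drop = FALSE], protein$xyz, protein$atoms$patch)
      w[real_ok] <- 1 + spec_enhancement(spec, d, pp)
    }
    acc <<- acc + c(sum(w), sum(fict_ok))
    w
  }
  qmc_integrate(lo, hi, fn, n_qmc)
  vol_bb <- prod(hi - lo)
  I_real <- acc[["real"]] / n_qmc * vol_bb
  I_fict <- acc[["fict"]] / n_qmc * vol_bb
  list(I_real = I_real, I_fict = I_fict,
       eta_surf_expected = I_real / I_fict - 1)
}

#' Write a synthetic system to disk as standard files
#'
#' Emits a GRO structure of the protein + first-frame waters, a multi-frame
#' GRO trajectory, a bulk-water trajectory, a parameter TSV covering every
#' atom, an IBS selection YAML, and a run config YAML, so the full pipeline
#' can be exercised end-to-end from files.
#'
#' @param spec a `"synthetic_spec"`.
#' @param dir output directory (created if needed).
#' @param n_frames frames in the hydrated and bulk trajectories.
#' @return invisible list of written paths.
#' @export
write_synthetic_system <- function(spec, dir, n_frames = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protein <- generate_protein_mimic(spec)
  traj <- generate_hydrated_frames(spec, n_frames, protein)
  bulk <- generate_bulk_box(spec, n_frames)
  paths <- list(
    structure = file.path(dir, "system.gro"),
    trajectory = file.path(dir, "traj.gro"),
    bulk = file.path(dir, "bulk.gro"),
    params = file.path(dir, "params.tsv"),
    selection = file.path(dir, "selection.yaml"),
    config = file.path(dir, "config.yaml")
  )
  first <- hydration_trajectory(traj$atoms, traj$frames[1])
  write_structure(first, paths$structure, "gro")
  write_structure(traj, paths$trajectory, "gro")
  write_structure(bulk, paths$bulk, "gro")
  at <- traj$atoms
  par <- rbind(
    unique(data.frame(residue_name = at$residue_name[!at$is_water],
                      atom_name = at$atom_name[!at$is_water], element = NA,
                      vdw_radius = at$vdw_radius[!at$is_water],
                      charge = at$partial_charge[!at$is_water])),
    data.frame(residue_name = "SOL", atom_name = c("OW", "HW1", "HW2"),
               element = NA, vdw_radius = c(spec$water_radius, 0, 0),
               charge = c(-0.82, 0.41, 0.41))
  )
  write.table(par, paths$params, sep = "\t", quote = FALSE, row.names = FALSE)
  ibs_res <- protein$atoms$residue_id[protein$atoms$patch == "IBS"]
  yaml::write_yaml(list(ibs_residues = paste0("A:", ibs_res)), paths$selection)
  yaml::write_yaml(list(
    name = "synthetic", structure = "system.gro", trajectory = "traj.gro",
    bulk = "bulk.gro", params = "params.tsv", selection = "selection.yaml",
    shell_thickness = 1.0, surface_cutoff = 0.55, probe = spec$probe,
    charge_threshold = 0.2, rho_bulk = spec$rho_bulk
  ), paths$config)
  invisible(paths)
}
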