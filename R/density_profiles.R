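#' Solvent density profile versus distance from the ellipsoid surface
#'
#' Bins water oxygens by their signed distance from the protein-ellipsoid
#' surface into half-open slabs `[d_low, d_high)` starting at the surface,
#' averages counts over frames, and divides by the geometric slab volumes
#' (differences of outer-parallel-body volumes). No protein-occupancy
#' correction is applied to the raw density: the fictitious-shell ratio is
#' the mechanism that cancels the effect of protein atoms protruding through
#' the ellipsoid surface.
#'
#' @param traj a `hydration_traj` with waters flagged.
#' @param E the reference `"ellipsoid"`.
#' @param bin_width slab width (nm).
#' @param d_max outermost distance (nm); the shell out to `d_max` must fit in
#'   the periodic box without self-intersection.
#' @return an object of class `"density_profile"`: `edges`, `mid`, `density`
#'   (molecules nm^-3), `bin_volumes`, `counts` (frames x bins matrix),
#'   `n_frames`.
#' @export
density_profile <- function(traj, E, bin_width = 0.02, d_max = 2.0) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (d_max < bin_width) stopf("d_max must be at least one bin wide")
  box <- traj$frames[[1]]$box
  if (!is.null(box) && all(!is.na(box))) {
    if (max(E$semi_axes) + d_max > min(box) / 2) {
      stopf(paste("the %.2f nm shell self-intersects through periodic images",
                  "(max semi-axis %.2f nm, min box %.2f nm); use a larger box",
                  "or a smaller d_max"),
            d_max, max(E$semi_axes), min(box))
    }
  }
  edges <- seq(0, d_max, by = bin_width)
  if (abs(edges[length(edges)] - d_max) > 1e-12) edges <- c(edges, d_max)
  nb <- length(edges) - 1
  oidx <- water_oxygen_idx(traj$atoms)
  nf <- n_frames(traj)
  counts <- matrix(0, nf, nb)
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    present <- frame_atoms(traj, i)
    rows <- match(intersect(oidx, present), present)
    if (length(rows) == 0) next
    xyz <- fr$xyz[rows, , drop = FALSE]
    if (!is.null(fr$box) && all(!is.na(fr$box))) {
      xyz <- wrap_about(xyz, fr$box, E$center)
      Ec <- E; Ec$center <- fr$box / 2
      d <- ellipsoid_distance(xyz, Ec)
    } else {
      d <- ellipsoid_distance(xyz, E)
    }
    keep <- d >= 0 & d < d_max
    if (any(keep)) {
      bin <- findInterval(d[keep], edges, rightmost.closed = FALSE)
      tb <- tabulate(bin, nbins = nb)
      counts[i, ] <- tb
    }
  }
  vol <- diff(parallel_body_volume(E, edges))
  structure(list(edges = edges, mid = edges[-1] - bin_width / 2,
                 density = colMeans(counts) / vol, bin_volumes = vol,
                 counts = counts, n_frames = nf),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d bins on [0, %.2f) nm, %d frame(s)\n",
              length(x$mid), x$edges[length(x$edges)], x$n_frames))
  invisible(x)
}

#' Build fictitious protein + bulk-water configurations
#'
#' Overlays the protein coordinates of each frame on a bulk-water frame and
#' removes every water molecule having any atom closer (minimum image) to any
#' protein atom than the sum of their van der Waals radii. Waters are removed
#' as whole molecules. The result is the bulk-distributed reference whose
#' shell density \eqn{\rho_{b,fict}} normalises the real profiles.
#'
#' @param protein_traj trajectory providing protein coordinates (waters in it
#'   are ignored); radii must be assigned.
#' @param bulk_traj bulk-water trajectory; radii assigned; its box must be at
#'   least as large as the protein box.
#' @param pairing integer map from protein frame to bulk frame; defaults to
#'   frame `i` with bulk frame `((i - 1) %% n_bulk) + 1`.
#' @return a `hydration_traj` whose topology is the protein atoms followed by
#'   all bulk water atoms; each frame's `atom_idx` marks the retained atoms.
#' @export
fictitious_configs <- function(protein_traj, bulk_traj, pairing = NULL) {
  pat <- protein_traj$atoms
  prot_idx <- which(!pat$is_water)
  wat <- bulk_traj$atoms
  if (length(prot_idx) > 0 && anyNA(pat$vdw_radius[prot_idx])) {
    stopf("protein atoms lack vdW radii; run assign_parameters() first")
  }
  if (anyNA(wat$vdw_radius)) stopf("bulk atoms lack vdW radii; run assign_parameters() first")
  nb <- n_frames(bulk_traj)
  if (nb == 0) stopf("bulk trajectory has no frames")
  np <- n_frames(protein_traj)
  pairing <- pairing %||% (((seq_len(np) - 1) %% nb) + 1)

  prot_at <- pat[prot_idx, ]
  prot_at$.water_mol <- rep(NA_integer_, nrow(prot_at))
  wat2 <- wat
  wat2$.water_mol <- cumsum(!duplicated(paste(wat$chain_id, wat$residue_id)))
  topo <- rbind(prot_at, wat2)
  topo$atom_id <- seq_len(nrow(topo))
  nprot <- nrow(prot_at)

  frames <- vector("list", np)
  for (i in seq_len(np)) {
    bfr <- bulk_traj$frames[[pairing[i]]]
    if (nrow(bfr$xyz) == 0) stopf("bulk frame %d is empty", pairing[i])
    box <- bfr$box
    pxyz <- frame_xyz(protein_traj, i, prot_idx)
    pbox <- protein_traj$frames[[i]]$box
    if (!is.null(pbox) && all(!is.na(pbox)) && any(box + 1e-9 < pbox)) {
      stopf("bulk box (%s) is smaller than the protein box (%s)",
            paste(signif(box, 4), collapse = " x "), paste(signif(pbox, 4), collapse = " x "))
    }
    bidx <- frame_atoms(bulk_traj, pairing[i])
    wrows <- seq_len(nrow(bfr$xyz))
    wmol <- topo$.water_mol[nprot + match(bidx, seq_len(nrow(wat)))]
    if (nprot > 0) {
      margin <- min_margin_cpp(bfr$xyz, pxyz, prot_at$vdw_radius, box)
      clash <- margin < wat$vdw_radius[bidx]
      removed_mol <- unique(wmol[clash])
      keep_w <- !(wmol %in% removed_mol)
    } else {
      keep_w <- rep(TRUE, length(wrows))
    }
    frames[[i]] <- list(
      xyz = rbind(pxyz, bfr$xyz[keep_w, , drop = FALSE]),
      box = box,
      time = protein_traj$frames[[i]]$time %||% (i - 1),
      atom_idx = c(seq_len(nprot), nprot + match(bidx[keep_w], seq_len(nrow(wat))))
    )
  }
  hydration_trajectory(topo[, setdiff(names(topo), ".water_mol")], frames)
}

#' Ratio of real to fictitious density profiles
#'
#' Per-bin ratio \eqn{\rho/\rho_{b,fict}} with standard errors propagated
#' from the per-frame spread of both profiles. Bins where the fictitious
#' density is zero are flagged undefined (`NA` ratio), never infinite.
#'
#' @param real,fict `"density_profile"` objects with identical binning.
#' @return an object of class `"ratio_profile"`: `edges`, `mid`, `ratio`,
#'   `stderr`, logical `defined`.
#' @export
ratio_profile <- function(real, fict) {
  if (length(real$edges) != length(fict$edges) ||
      max(abs(real$edges - fict$edges)) > 1e-12) {
    stopf("real and fictitious profiles have different binning")
  }
  se_mean <- function(m) apply(m, 2, sd) / sqrt(nrow(m))
  mr <- colMeans(real$counts); mf <- colMeans(fict$counts)
  sr <- se_mean(real$counts); sf <- se_mean(fict$counts)
  defined <- mf > 0
  ratio <- rep(NA_real_, length(mr))
  stderr <- rep(NA_real_, length(mr))
  ratio[defined] <- (mr[defined] / real$bin_volumes[defined]) /
                    (mf[defined] / fict$bin_volumes[defined])
  pos <- defined & mr > 0
  stderr[pos] <- ratio[pos] * sqrt((sr[pos] / mr[pos])^2 + (sf[pos] / mf[pos])^2)
  stderr[defined & mr == 0] <- 0
  structure(list(edges = real$edges, mid = real$mid, ratio = ratio,
                 stderr = stderr, defined = defined),
            class = "ratio_profile")
}

#' Detect the bulk plateau of a ratio profile
#'
#' Smallest bin edge after which `|ratio - 1| < tol` holds for `run_length`
#' consecutive bins. A diagnostic confirming the hydration-shell thickness
#' (the 1 nm shell definition is never silently overridden by it).
#'
#' @param rp a `"ratio_profile"`.
#' @param tol tolerance on `|ratio - 1|`.
#' @param run_length required number of consecutive in-tolerance bins.
#' @return plateau distance (nm), or `NA` with attribute `found = FALSE` if
#'   no plateau exists within the profile range.
#' @export
detect_plateau <- function(rp, tol = 0.02, run_length = 3) {
  ok <- !is.na(rp$ratio) & abs(rp$ratio - 1) < tol
  nb <- length(ok)
  if (run_length > nb) stopf("run_length exceeds the number of bins")
  for (k in seq_len(nb - run_length + 1)) {
    if (all(ok[k:(k + run_length - 1)])) {
      return(structure(rp$edges[k], found = TRUE))
    }
  }
  structure(NA_real_, found = FALSE)
}

#' Write profile TSV
#'
#' @param real,fict `"density_profile"` objects; `rp` the corresponding
#'   `"ratio_profile"`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(real, fict, rp, path) {
  df <- data.frame(distance_mid = real$mid,
                   density_real = real$density,
                   density_fict = fict$density,
                   ratio = rp$ratio, stderr = rp$stderr)
  write.table(format(df, digits = 8, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
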