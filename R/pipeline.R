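#' Classify antifreeze activity from thermal hysteresis
#'
#' Moderately active proteins have a thermal hysteresis below 1 K;
#' hyperactive ones above.
#'
#' @param delta_T thermal hysteresis (K).
#' @return character vector `"moderate"` / `"hyperactive"`.
#' @export
activity_class <- function(delta_T) {
  ifelse(delta_T < 1, "moderate", "hyperactive")
}

#' Bundled reference tables for eight antifreeze proteins
#'
#' Published whole-shell statistics (excluded volume, shell volume, shell
#' water count, density increment, partial molar volume), solvent-accessible
#' surface areas with hydrophobic fractions, and per-surface density
#' increments for four moderately active and four hyperactive antifreeze
#' proteins, as obtained from 100 ns MD trajectories. Used as arithmetic
#' fixtures for the estimators and as inputs to the cross-protein
#' correlation analyses.
#'
#' @param which `"shell"` (Table of V_ex, V_shell, N_shell, eta, v),
#'   `"surface_area"` (S and S_pho/S for WP/IBS/NIBS), or
#'   `"surface_density"` (eta_surf for IBS/NIBS).
#' @return data frame.
#' @export
afp_reference <- function(which = c("shell", "surface_area", "surface_density")) {
  which <- match.arg(which)
  f <- switch(which, shell = "afp_shell_reference.tsv",
              surface_area = "afp_sasa_reference.tsv",
              surface_density = "afp_surface_reference.tsv")
  read.delim(system.file("extdata", f, package = "hydroshell"),
             stringsAsFactors = FALSE)
}

#' Full per-protein hydration-shell analysis on in-memory trajectories
#'
#' Runs the complete pipeline: ellipsoid fit on the protein heavy atoms,
#' whole-shell summary (excluded volume, shell count, density increment,
#' partial molar volume), fictitious bulk-overlay configurations, density
#' ratio profile with plateau diagnostic, SASA with hydrophobic fractions,
#' and per-surface local density increments for the whole protein and (when
#' an IBS is supplied) the IBS/NIBS split.
#'
#' @param traj solvated trajectory with parameters assigned.
#' @param bulk bulk-water trajectory (same or larger box), parameters
#'   assigned; `NULL` skips the fictitious-reference stages.
#' @param ibs IBS residue specification for [load_selection()], or `NULL`
#'   for a whole-protein-only analysis (with a warning).
#' @param shell_thickness hydration-shell thickness (nm).
#' @param surface_cutoff per-surface water counting cutoff (nm).
#' @param probe SASA/excluded-volume probe radius (nm).
#' @param charge_threshold nonpolar |charge| threshold (e).
#' @param rho_bulk bulk density (molecules nm^-3); measured from `bulk`
#'   when provided.
#' @param bin_width,d_max ratio-profile binning (profile skipped when the
#'   box cannot hold `d_max`, with a message).
#' @param n_blocks subtrajectories for error estimates.
#' @return list with `ellipsoid`, `shell` (a `"shell_summary"`), `profile`,
#'   `sasa` (per-selection areas and hydrophobic fractions), `surface`
#'   (rbind of `"surface_density"` rows), `fictitious`.
#' @export
analyze_system <- function(traj, bulk = NULL, ibs = NULL,
                           shell_thickness = 1.0, surface_cutoff = 0.55,
                           probe = 0.14, charge_threshold = 0.2,
                           rho_bulk = RHO_BULK_DEFAULT,
                           bin_width = 0.02, d_max = 2.0, n_blocks = 3) {
  prot_idx <- which(!traj$atoms$is_water)
  heavy_idx <- prot_idx[traj$atoms$is_heavy[prot_idx]]
  if (length(heavy_idx) < 4) stopf("fewer than 4 protein heavy atoms")

  E <- fit_ellipsoid(reference_structure(traj, heavy_idx))
  shell <- shell_summary(traj, E, thickness = shell_thickness, probe = probe,
                         rho_bulk = rho_bulk, n_blocks = n_blocks,
                         bulk_traj = bulk)

  fict <- NULL; prof <- NULL
  if (!is.null(bulk)) {
    fict <- fictitious_configs(traj, bulk)
    box <- traj$frames[[1]]$box
    d_use <- d_max
    if (!is.null(box) && all(!is.na(box)) &&
        max(E$semi_axes) + d_use > min(box) / 2) {
      d_use <- floor((min(box) / 2 - max(E$semi_axes)) / bin_width) * bin_width
      message(sprintf("profile range reduced to %.2f nm to fit the periodic box", d_use))
    }
    if (d_use >= bin_width) {
      real_p <- density_profile(traj, E, bin_width, d_use)
      fict_p <- density_profile(fict, E, bin_width, d_use)
      rp <- ratio_profile(real_p, fict_p)
      prof <- list(real = real_p, fict = fict_p, ratio = rp,
                   plateau = detect_plateau(rp))
    }
  }

  # SASA on the reference structure's heavy atoms (rigid protein gives a
  # constant series; flexible proteins get the per-frame series)
  at <- traj$atoms
  radii <- at$vdw_radius[heavy_idx]
  charges <- at$partial_charge[heavy_idx]
  static <- protein_is_static(traj, heavy_idx)
  sasa_frames <- if (static) 1L else seq_len(n_frames(traj))
  sasa_list <- lapply(sasa_frames, function(i) {
    compute_sasa(frame_xyz(traj, i, heavy_idx), radii, probe = probe)
  })
  sasa1 <- sasa_list[[1]]
  per_atom_mean <- Reduce("+", lapply(sasa_list, function(s) s$per_atom_area)) / length(sasa_list)

  sels <- NULL
  if (!is.null(ibs)) {
    sels <- load_selection(ibs, traj)
  } else {
    warnf("no IBS selection supplied; running whole-protein analysis only")
  }

  hatoms <- at[heavy_idx, ]
  key <- paste(hatoms$chain_id, hatoms$residue_id)
  sel_mask <- function(sel) {
    if (is.null(sel)) rep(TRUE, nrow(hatoms))
    else key %in% paste(sel$residues$chain_id, sel$residues$residue_id)
  }
  sel_list <- list(WP = NULL)
  if (!is.null(sels)) sel_list <- list(WP = sels$whole, IBS = sels$ibs, NIBS = sels$nibs)
  sasa_tab <- do.call(rbind, lapply(names(sel_list), function(lbl) {
    m <- sel_mask(sel_list[[lbl]])
    area <- sum(per_atom_mean[m])
    pho <- sum(per_atom_mean[m & abs(charges) <= charge_threshold])
    data.frame(selection = lbl, S = area, S_pho = pho, fraction_pho = pho / area,
               stringsAsFactors = FALSE)
  }))

  surf <- NULL
  if (!is.null(fict)) {
    nprot_fict <- sum(!fict$atoms$is_water)
    surf <- do.call(rbind, lapply(names(sel_list), function(lbl) {
      if (is.null(sel_list[[lbl]])) {
        sidx <- heavy_idx
      } else {
        sidx <- selection_atoms(traj, sel_list[[lbl]], heavy_only = TRUE)
      }
      # fictitious topology = protein atoms (in prot_idx order) then waters
      fidx <- match(sidx, prot_idx)
      if (anyNA(fidx)) stopf("selection atoms missing from the fictitious topology")
      sser <- sum(per_atom_mean[sel_mask(sel_list[[lbl]])])
      surface_density(traj, fict, sidx, sser, label = lbl,
                      cutoff = surface_cutoff, n_blocks = n_blocks,
                      fict_sel_idx = fidx)
    }))
  }

  list(ellipsoid = E, shell = shell, profile = prof, sasa = sasa_tab,
       surface = surf, fictitious = fict, selections = sels)
}

# Trajectory-average heavy-atom structure after rigid-body superposition of
# every frame onto the first (static trajectories shortcut to frame 1).
reference_structure <- function(traj, idx) {
  if (protein_is_static(traj, idx) || n_frames(traj) == 1) {
    return(frame_xyz(traj, 1, idx))
  }
  ref <- frame_xyz(traj, 1, idx)
  acc <- ref
  for (i in 2:n_frames(traj)) {
    acc <- acc + kabsch_superpose(frame_xyz(traj, i, idx), ref)
  }
  acc / n_frames(traj)
}

# Kabsch rigid-body superposition of mobile onto ref.
kabsch_superpose <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- crossprod(sweep(mobile, 2, cm), sweep(ref, 2, cr))
  s <- svd(A)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
}

#' Run the analysis for one protein from a config
#'
#' Thin file-level wrapper over [analyze_system()]: resolves paths, reads
#' structure/trajectory/bulk files, assigns parameters, loads the IBS
#' selection, runs the analysis and (optionally) writes TSV outputs.
#'
#' @param config named list or YAML file path with keys `name`, `structure`,
#'   `trajectory` (optional), `bulk` (optional), `params` (optional
#'   parameter-table TSV), `selection` (optional IBS YAML or residue spec),
#'   `delta_T` (optional, K), and cutoff overrides (`shell_thickness`,
#'   `surface_cutoff`, `probe`, `charge_threshold`, `rho_bulk`).
#' @param out_dir optional directory for TSV outputs.
#' @return the [analyze_system()] result, with `name`, `delta_T` and
#'   `activity` added.
#' @export
run_protein <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    rel <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
    for (k in c("structure", "trajectory", "bulk", "params", "selection")) {
      config[[k]] <- rel(config[[k]])
    }
  }
  params <- if (!is.null(config$params)) {
    read.delim(config$params, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else default_parameters()
  topo <- read_structure(config$structure)
  traj <- if (!is.null(config$trajectory)) read_trajectory(config$trajectory, topo) else topo
  traj <- assign_parameters(traj, params)
  bulk <- NULL
  if (!is.null(config$bulk)) {
    bulk <- assign_parameters(read_trajectory(config$bulk), params)
  }
  res <- analyze_system(
    traj, bulk = bulk, ibs = config$selection,
    shell_thickness = config$shell_thickness %||% 1.0,
    surface_cutoff = config$surface_cutoff %||% 0.55,
    probe = config$probe %||% 0.14,
    charge_threshold = config$charge_threshold %||% 0.2,
    rho_bulk = config$rho_bulk %||% RHO_BULK_DEFAULT
  )
  res$name <- config$name %||% "protein"
  res$delta_T <- config$delta_T
  res$activity <- if (!is.null(config$delta_T)) activity_class(config$delta_T) else NA
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write analysis results as TSV files
#'
#' @param res an [analyze_system()]/[run_protein()] result.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(format(as.data.frame(df), digits = 8, trim = TRUE), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  shell_tab <- cbind(data.frame(protein = res$name %||% "protein",
                                delta_T = res$delta_T %||% NA_real_),
                     as.data.frame(res$shell))
  wr(shell_tab, "shell_summary.tsv")
  wr(res$sasa, "sasa.tsv")
  if (!is.null(res$surface)) wr(res$surface, "surface_density.tsv")
  if (!is.null(res$profile)) {
    write_profile_tsv(res$profile$real, res$profile$fict, res$profile$ratio,
                      file.path(dir, "ratio_profile.tsv"))
    paths <- c(paths, file.path(dir, "ratio_profile.tsv"))
  }
  write_ellipsoid(res$ellipsoid, file.path(dir, "ellipsoid.txt"))
  invisible(c(paths, file.path(dir, "ellipsoid.txt")))
}

#' Correlate two per-protein quantities
#'
#' Pearson correlation with the two-sided t-transform p-value and an
#' ordinary least-squares fit, optionally with activity-class group means.
#' The published trends are reported visually; this is the minimal faithful
#' quantification.
#'
#' @param x,y numeric vectors (one value per protein).
#' @param classes optional activity classes aligned with `x`.
#' @return object of class `"correlation_report"`: `r`, `p`, `slope`,
#'   `intercept`, `n`, `group_means`.
#' @export
correlate_proteins <- function(x, y, classes = NULL) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3) stopf("need at least 3 points to correlate")
  if (sd(x) == 0) stopf("zero variance in x")
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  gm <- NULL
  if (!is.null(classes)) gm <- tapply(y, classes, mean)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n = length(x), group_means = gm),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation: r = %.3f (p = %.3g, n = %d), fit y = %.4g x + %.4g\n",
              x$r, x$p, x$n, x$slope, x$intercept))
  if (!is.null(x$group_means)) {
    cat("group means:", paste(sprintf("%s %.4g", names(x$group_means), x$group_means),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare a quantity between activity classes
#'
#' @param values numeric vector (one per protein).
#' @param classes activity classes (`"moderate"`/`"hyperactive"`).
#' @return list with per-class `means` and `difference`
#'   (hyperactive - moderate).
#' @export
group_compare <- function(values, classes) {
  classes <- as.character(classes)
  lev <- unique(classes)
  if (any(!table(factor(classes, levels = c("moderate", "hyperactive"))) > 0)) {
    stopf("both activity classes must be represented")
  }
  means <- tapply(values, classes, mean)
  list(means = means,
       difference = unname(means["hyperactive"] - means["moderate"]))
}
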