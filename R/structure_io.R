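#' Residue names recognised as water
#'
#' @return character vector of residue names treated as solvent water.
#' @export
water_residue_names <- function() c("SOL", "HOH", "WAT", "TIP3", "SPC")

#' Construct a trajectory object
#'
#' The internal container for a topology plus time-ordered configurations.
#' All lengths are nm, times ps. Frames may carry an `atom_idx` integer
#' vector (a subset of topology rows) when not all topology atoms are present
#' in that frame, as in fictitious bulk-overlay configurations where
#' overlapping waters have been removed.
#'
#' @param atoms data frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_id`, `residue_name`, `chain_id`, and (once parameters are
#'   assigned) `vdw_radius`, `partial_charge`; logical `is_heavy`, `is_water`.
#' @param frames list of frames, each `list(xyz, box, time, atom_idx = NULL)`
#'   with `xyz` an n x 3 matrix (nm) and `box` three orthorhombic box
#'   lengths (nm) or `NA` when unknown.
#' @return an object of class `"hydration_traj"`.
#' @export
hydration_trajectory <- function(atoms, frames) {
  req <- c("atom_id", "atom_name", "element", "residue_id", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stopf("topology is missing columns: %s", paste(miss, collapse = ", "))
  if (!"is_heavy" %in% names(atoms)) atoms$is_heavy <- atoms$element != "H"
  if (!"is_water" %in% names(atoms)) {
    atoms$is_water <- atoms$residue_name %in% water_residue_names()
  }
  if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- NA_real_
  if (!"partial_charge" %in% names(atoms)) atoms$partial_charge <- NA_real_
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    n_expect <- if (is.null(fr$atom_idx)) nrow(atoms) else length(fr$atom_idx)
    if (nrow(fr$xyz) != n_expect) {
      stopf("frame %d has %d coordinates but expects %d (topology has %d atoms)",
            i, nrow(fr$xyz), n_expect, nrow(atoms))
    }
    if (!all(is.finite(fr$xyz))) stopf("frame %d contains non-finite coordinates", i)
    if (!is.null(fr$box) && !all(is.na(fr$box)) && any(fr$box <= 0)) {
      stopf("frame %d has non-positive box lengths", i)
    }
  }
  structure(list(atoms = atoms, frames = frames), class = "hydration_traj")
}

#' @export
print.hydration_traj <- function(x, ...) {
  nw <- sum(x$atoms$is_water)
  cat(sprintf("hydration_traj: %d atoms (%d water, %d protein/other), %d frame(s)\n",
              nrow(x$atoms), nw, nrow(x$atoms) - nw, length(x$frames)))
  bx <- x$frames[[1]]$box
  if (!is.null(bx) && all(!is.na(bx))) {
    cat(sprintf("  box: %.3f x %.3f x %.3f nm\n", bx[1], bx[2], bx[3]))
  }
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `hydration_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Atom bookkeeping within frames
#'
#' `frame_atoms` returns the topology row indices present in frame `i` (all
#' atoms unless the frame carries an `atom_idx` subset); `frame_xyz` returns
#' coordinates of selected topology atoms in that frame;
#' `water_oxygen_idx` returns the topology rows of water oxygens.
#'
#' @param traj a `hydration_traj`.
#' @param i frame number.
#' @param sel optional topology row indices.
#' @param atoms a topology data frame.
#' @return integer indices or an n x 3 coordinate matrix.
#' @export
frame_atoms <- function(traj, i) {
  traj$frames[[i]]$atom_idx %||% seq_len(nrow(traj$atoms))
}

#' @rdname frame_atoms
#' @export
frame_xyz <- function(traj, i, sel = NULL) {
  fr <- traj$frames[[i]]
  present <- frame_atoms(traj, i)
  if (is.null(sel)) return(fr$xyz)
  pos <- match(sel, present)
  if (anyNA(pos)) stopf("frame %d does not contain %d requested atom(s)", i, sum(is.na(pos)))
  fr$xyz[pos, , drop = FALSE]
}

#' @rdname frame_atoms
#' @export
water_oxygen_idx <- function(atoms) which(atoms$is_water & atoms$element == "O")

known_elements <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                    "NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU")

#' Infer an element from an atom name
#'
#' Standard PDB/GRO heuristic: strip leading digits, take the leading
#' letter(s). Two-letter elements are recognised only when the full stripped
#' name matches (ions such as `CL`, `NA`); otherwise the first letter is used.
#'
#' @param atom_name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(atom_name)))
  two <- nm %in% setdiff(known_elements, c("H", "C", "N", "O", "S", "P", "F", "I", "K"))
  el <- substr(nm, 1, 1)
  el[two] <- nm[two]
  bad <- !(el %in% known_elements) | nm == ""
  if (any(bad)) {
    stopf("cannot infer element for atom name(s): %s",
          paste(unique(atom_name[bad]), collapse = ", "))
  }
  el
}

# ---- GRO ------------------------------------------------------------------

parse_gro_block <- function(lines, start, path) {
  if (start + 1 > length(lines)) stopf("truncated GRO file '%s' at line %d", path, start)
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(natoms)) stopf("cannot parse atom count at line %d of '%s'", start + 1, path)
  last <- start + 1 + natoms + 1
  if (last > length(lines)) {
    stopf("truncated GRO file '%s': frame starting at line %d declares %d atoms but the file ends early",
          path, start, natoms)
  }
  al <- lines[(start + 2):(start + 1 + natoms)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad) > 0) stopf("parse error in '%s' at line %d", path, start + 1 + bad[1])
  bl <- strsplit(trimws(lines[last]), "\\s+")[[1]]
  bv <- suppressWarnings(as.numeric(bl))
  if (anyNA(bv) || !(length(bv) %in% c(3, 9))) {
    stopf("cannot parse box line %d of '%s'", last, path)
  }
  if (length(bv) == 9 && any(abs(bv[4:9]) > 1e-9)) {
    stopf("triclinic box in '%s' is not supported (only orthorhombic boxes)", path)
  }
  tm <- NA_real_
  m <- regmatches(lines[start], regexec("t=\\s*([0-9eE.+-]+)", lines[start]))[[1]]
  if (length(m) == 2) tm <- as.numeric(m[2])
  list(resid = resid, resname = resname, aname = aname,
       xyz = cbind(x, y, z), box = bv[1:3], time = tm, next_start = last + 1)
}

gro_atoms_df <- function(blk) {
  data.frame(
    atom_id = seq_along(blk$resid),
    atom_name = blk$aname,
    element = infer_element(blk$aname),
    residue_id = blk$resid,
    residue_name = blk$resname,
    chain_id = "A",
    stringsAsFactors = FALSE
  )
}

# ---- PDB ------------------------------------------------------------------

read_pdb_internal <- function(path, multi) {
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  el <- trimws(at$elesy %||% "")
  if (length(el) == 0 || all(el == "")) el <- infer_element(at$elety)
  el[el == ""] <- infer_element(at$elety[el == ""])
  el <- toupper(el)
  bad <- !(el %in% known_elements)
  if (any(bad)) stopf("unknown element for atom(s): %s",
                      paste(unique(at$elety[bad]), collapse = ", "))
  atoms <- data.frame(
    atom_id = seq_len(nrow(at)),
    atom_name = trimws(at$elety),
    element = el,
    residue_id = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE
  )
  box <- c(NA_real_, NA_real_, NA_real_)
  cl <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
  if (length(cl) >= 1) {
    fields <- suppressWarnings(as.numeric(c(
      substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
      substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
    if (all(is.finite(fields[1:3])) && all(fields[1:3] > 0)) {
      if (any(abs(fields[4:6] - 90) > 1e-6, na.rm = TRUE)) {
        stopf("triclinic box in '%s' is not supported (only orthorhombic boxes)", path)
      }
      box <- fields[1:3] / 10
    }
  }
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    list(xyz = matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10,
         box = box, time = i - 1)
  })
  list(atoms = atoms, frames = frames)
}

detect_format <- function(path, format) {
  if (format != "auto") return(format)
  switch(tolower(tools::file_ext(path)),
         pdb = "pdb", ent = "pdb", gro = "gro", dcd = "dcd",
         xtc = stopf("XTC trajectories are not supported; convert to multi-frame GRO/PDB or DCD"),
         stopf("cannot detect format of '%s'; pass format=", path))
}

#' Read a structure file
#'
#' Reads a PDB or GRO file into a single-frame trajectory. PDB coordinates
#' (and any CRYST1 box) are converted from Angstrom to nm; GRO files are
#' already in nm. Only orthorhombic boxes are supported.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return a [hydration_trajectory()] with one frame.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  format <- detect_format(path, format)
  if (format == "pdb") {
    p <- read_pdb_internal(path, multi = FALSE)
    return(hydration_trajectory(p$atoms, p$frames[1]))
  }
  lines <- readLines(path)
  blk <- parse_gro_block(lines, 1, path)
  hydration_trajectory(gro_atoms_df(blk),
                       list(list(xyz = unname(blk$xyz), box = blk$box,
                                 time = ifelse(is.na(blk$time), 0, blk$time))))
}

#' Read a trajectory file
#'
#' Multi-frame GRO (concatenated blocks), multi-model PDB, or binary DCD (via
#' \pkg{bio3d}; requires `topology`). Frames are ordered by time; frames
#' without a time stamp are numbered sequentially.
#'
#' @param path file path.
#' @param topology optional `hydration_traj` providing the topology; when
#'   given, each frame's atom count must match it.
#' @param format `"auto"`, `"gro"`, `"pdb"` or `"dcd"`.
#' @return a [hydration_trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, format = c("auto", "gro", "pdb", "dcd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  format <- detect_format(path, format)
  if (format == "dcd") {
    if (is.null(topology)) stopf("reading DCD requires a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      list(xyz = matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10,
           box = topology$frames[[1]]$box, time = i - 1)
    })
  } else if (format == "pdb") {
    p <- read_pdb_internal(path, multi = TRUE)
    if (is.null(topology)) topology <- hydration_trajectory(p$atoms, p$frames[1])
    frames <- p$frames
  } else {
    lines <- readLines(path)
    frames <- list()
    blocks <- list()
    start <- 1
    while (start <= length(lines)) {
      if (all(trimws(lines[start:length(lines)]) == "")) break
      blk <- parse_gro_block(lines, start, path)
      blocks[[length(blocks) + 1]] <- blk
      frames[[length(frames) + 1]] <-
        list(xyz = unname(blk$xyz), box = blk$box,
             time = ifelse(is.na(blk$time), length(frames), blk$time))
      start <- blk$next_start
    }
    # frames may hold different molecule counts (e.g. bulk boxes with a
    # fluctuating number of waters); the largest block defines the topology
    # and smaller frames must be a prefix of it
    big <- which.max(vapply(blocks, function(b) length(b$resid), integer(1)))
    atoms <- gro_atoms_df(blocks[[big]])
    if (is.null(topology)) {
      topology <- hydration_trajectory(atoms, frames[big])
    } else if (nrow(topology$atoms) < nrow(atoms)) {
      if (!identical(topology$atoms$atom_name, atoms$atom_name[seq_len(nrow(topology$atoms))])) {
        stopf("trajectory '%s' has more atoms than the topology and is not an extension of it", path)
      }
      message(sprintf("topology extended from %d to %d atoms to cover the largest trajectory frame",
                      nrow(topology$atoms), nrow(atoms)))
      topology <- hydration_trajectory(atoms, frames[big])
    }
    nat <- nrow(topology$atoms)
    for (i in seq_along(frames)) {
      ni <- nrow(frames[[i]]$xyz)
      if (ni < nat) {
        if (!identical(blocks[[i]]$aname, topology$atoms$atom_name[seq_len(ni)])) {
          stopf("frame %d (%d atoms) is not a prefix of the %d-atom topology", i, ni, nat)
        }
        frames[[i]]$atom_idx <- seq_len(ni)
      }
    }
  }
  nat <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    n_expect <- if (is.null(frames[[i]]$atom_idx)) nat else length(frames[[i]]$atom_idx)
    if (nrow(frames[[i]]$xyz) != n_expect || nrow(frames[[i]]$xyz) > nat) {
      stopf("frame %d has %d atoms but the topology has %d", i, nrow(frames[[i]]$xyz), nat)
    }
  }
  tm <- vapply(frames, function(f) f$time, numeric(1))
  frames <- frames[order(tm)]
  message(sprintf("read %d frame(s) from '%s'", length(frames), path))
  hydration_trajectory(topology$atoms, frames)
}

#' Write a structure or trajectory
#'
#' GRO (nm, 3 decimals) or PDB (Angstrom, 3 decimals); multi-frame input is
#' written as concatenated GRO blocks or PDB MODEL records.
#'
#' @param traj a `hydration_traj`.
#' @param path output path.
#' @param format `"auto"`, `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path, "auto")
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    idx <- frame_atoms(traj, i)
    a <- at[idx, ]
    if (format == "gro") {
      writeLines(sprintf("synthetic configuration, t= %.3f", fr$time %||% 0), con)
      writeLines(sprintf("%5d", nrow(a)), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$residue_id %% 100000, a$residue_name,
                         substr(a$atom_name, 1, 5), a$atom_id %% 100000,
                         fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
      bx <- fr$box
      if (is.null(bx) || anyNA(bx)) bx <- c(0, 0, 0)
      writeLines(sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]), con)
    } else {
      if (i == 1) {
        bx <- fr$box
        if (!is.null(bx) && all(!is.na(bx))) {
          writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                             bx[1] * 10, bx[2] * 10, bx[3] * 10, 90, 90, 90), con)
        }
      }
      if (length(traj$frames) > 1) writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         a$atom_id %% 100000, substr(a$atom_name, 1, 4),
                         substr(a$residue_name, 1, 4), substr(a$chain_id, 1, 1),
                         a$residue_id %% 10000,
                         fr$xyz[, 1] * 10, fr$xyz[, 2] * 10, fr$xyz[, 3] * 10,
                         a$element), con)
      if (length(traj$frames) > 1) writeLines("ENDMDL", con)
    }
  }
  if (format == "pdb") writeLines("END", con)
  invisible(path)
}

#' Assign van der Waals radii and partial charges
#'
#' Looks each atom up in a parameter table, first by exact
#' `(residue_name, atom_name)` pair, then falling back to an element-level
#' entry. Atoms matched by neither are collected and reported in a single
#' error (no silent defaults). Water flags are (re)derived from the residue
#' name.
#'
#' @param traj a `hydration_traj`.
#' @param params data frame with columns `residue_name`, `atom_name`,
#'   `element`, `vdw_radius` (nm), `charge` (e). Element-fallback rows leave
#'   `residue_name`/`atom_name` empty (`NA` or `""`).
#' @param water_names residue names identifying water.
#' @return the trajectory with `vdw_radius`, `partial_charge`, `is_water`,
#'   `is_heavy` populated.
#' @export
assign_parameters <- function(traj, params = default_parameters(),
                              water_names = water_residue_names()) {
  at <- traj$atoms
  p <- params
  blank <- function(x) is.na(x) | trimws(as.character(x)) == ""
  pair_rows <- !blank(p$residue_name) & !blank(p$atom_name)
  elem_rows <- blank(p$residue_name) & blank(p$atom_name) & !blank(p$element)

  key <- paste(at$residue_name, at$atom_name, sep = "|")
  pkey <- paste(p$residue_name[pair_rows], p$atom_name[pair_rows], sep = "|")
  hit <- match(key, pkey)
  r <- p$vdw_radius[pair_rows][hit]
  q <- p$charge[pair_rows][hit]

  # element fallback only where the pair lookup failed
  need <- is.na(hit)
  ehit <- match(at$element[need], toupper(p$element[elem_rows]))
  r[need] <- p$vdw_radius[elem_rows][ehit]
  q[need] <- p$charge[elem_rows][ehit]

  missing <- is.na(r) | is.na(q)
  if (any(missing)) {
    lab <- unique(sprintf("%s:%s", at$residue_name[missing], at$atom_name[missing]))
    stopf("no vdW radius/charge for %d atom(s): %s", sum(missing), paste(lab, collapse = ", "))
  }
  if (any(r < 0)) stopf("negative vdW radius in parameter table")
  at$vdw_radius <- r
  at$partial_charge <- q
  at$is_water <- at$residue_name %in% water_names
  at$is_heavy <- at$element != "H"
  traj$atoms <- at
  traj
}

#' Default vdW radius and charge table
#'
#' Bondi-style element radii plus SPC water parameters, shipped as a plain
#' TSV in `extdata`. The element-level protein charges are zero placeholders:
#' meaningful hydrophobicity analysis requires force-field charges supplied
#' by the user (or carried by the synthetic generator).
#'
#' @return data frame usable with [assign_parameters()].
#' @export
default_parameters <- function() {
  read.delim(system.file("extdata", "vdw_params.tsv", package = "hydroshell"),
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

# ---- Selections -----------------------------------------------------------

parse_residue_spec <- function(spec) {
  out <- list()
  for (tok in unlist(strsplit(spec, "[,;[:space:]]+"))) {
    if (tok == "") next
    m <- regexec("^([A-Za-z0-9]+):([0-9]+)(?:-([0-9]+))?$", tok)[[1]]
    g <- regmatches(tok, list(m))[[1]]
    if (length(g) == 0) stopf("cannot parse residue token '%s' (expected CHAIN:FROM[-TO])", tok)
    from <- as.integer(g[3])
    to <- if (g[4] == "") from else as.integer(g[4])
    out[[length(out) + 1]] <- data.frame(chain_id = g[2], residue_id = from:to,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Load ice-binding-surface selection and its complement
#'
#' Given the IBS residues of a protein, builds the IBS selection and the
#' complementary NIBS selection over all non-water residues. The two are
#' disjoint by construction and their union covers the protein.
#'
#' @param ibs residue specification: a character vector of `"CHAIN:FROM-TO"`
#'   tokens, a data frame with `chain_id`/`residue_id`, or a YAML file path
#'   with an `ibs_residues` key.
#' @param traj a `hydration_traj` whose topology the residues must exist in.
#' @return list with elements `ibs`, `nibs`, `whole`, each of class
#'   `"surface_selection"` (fields `label`, `residues`).
#' @export
load_selection <- function(ibs, traj) {
  if (is.character(ibs) && length(ibs) == 1 && file.exists(ibs)) {
    cfg <- yaml::read_yaml(ibs)
    ibs <- cfg$ibs_residues %||% stopf("'%s' has no ibs_residues key", ibs)
  }
  if (is.character(ibs)) ibs <- parse_residue_spec(paste(ibs, collapse = ","))
  if (is.null(ibs) || nrow(ibs) == 0) {
    stopf("empty IBS selection: the analysis requires a nonempty ice-binding surface")
  }
  key <- paste(ibs$chain_id, ibs$residue_id)
  if (anyDuplicated(key)) {
    warnf("duplicate residues in IBS selection were deduplicated")
    ibs <- ibs[!duplicated(key), ]
  }
  prot <- traj$atoms[!traj$atoms$is_water, ]
  pres <- unique(prot[, c("chain_id", "residue_id")])
  pkey <- paste(pres$chain_id, pres$residue_id)
  missing <- setdiff(paste(ibs$chain_id, ibs$residue_id), pkey)
  if (length(missing) > 0) {
    stopf("IBS residue(s) not found in topology: %s", paste(missing, collapse = ", "))
  }
  in_ibs <- pkey %in% paste(ibs$chain_id, ibs$residue_id)
  mk <- function(label, res) structure(list(label = label, residues = res),
                                       class = "surface_selection")
  list(ibs = mk("IBS", pres[in_ibs, ]),
       nibs = mk("NIBS", pres[!in_ibs, ]),
       whole = mk("WHOLE", pres))
}

#' @export
print.surface_selection <- function(x, ...) {
  cat(sprintf("surface_selection %s: %d residue(s)\n", x$label, nrow(x$residues)))
  invisible(x)
}

#' Topology atom indices of a selection
#'
#' @param traj a `hydration_traj`.
#' @param sel a `surface_selection`.
#' @param heavy_only drop hydrogens.
#' @return integer vector of topology row indices.
#' @export
selection_atoms <- function(traj, sel, heavy_only = TRUE) {
  at <- traj$atoms
  key <- paste(at$chain_id, at$residue_id)
  skey <- paste(sel$residues$chain_id, sel$residues$residue_id)
  idx <- which(key %in% skey & !at$is_water)
  if (heavy_only) idx <- idx[at$is_heavy[idx]]
  if (length(idx) == 0) stopf("selection %s resolves to no atoms", sel$label)
  idx
}
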