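test_that("a minimal PDB parses into topology and nm coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  OW  HOH W   1      10.000  20.000  30.000  1.00  0.00           O",
    "ATOM      2  HW1 HOH W   1      10.900  20.000  30.000  1.00  0.00           H",
    "ATOM      3  HW2 HOH W   1       9.700  20.900  30.000  1.00  0.00           H",
    "END"), f)
  tr <- read_structure(f)
  expect_equal(nrow(tr$atoms), 3)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$frames[[1]]$xyz[1, ], c(1, 2, 3))      # Angstrom -> nm
  expect_equal(tr$frames[[1]]$box, c(5, 5, 5))
  expect_equal(tr$atoms$element, c("O", "H", "H"))
})

test_that("GRO box line and atom fields parse per format definition", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy", "    2",
               "    1SOL    OW    1   1.000   2.000   3.000",
               "    1SOL   HW1    2   1.100   2.000   3.000",
               "   5.00000   5.00000   5.00000"), f)
  tr <- read_structure(f)
  expect_equal(tr$frames[[1]]$box, c(5, 5, 5))
  expect_equal(tr$frames[[1]]$xyz[2, ], c(1.1, 2, 3))
  expect_equal(tr$atoms$residue_name, c("SOL", "SOL"))
})

test_that("triclinic GRO boxes are rejected explicitly", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               "    1SOL    OW    1   1.000   2.000   3.000",
               "   5.0 5.0 5.0 0.0 0.0 1.2 0.0 0.0 0.0"), f)
  expect_error(read_structure(f), "triclinic")
})

test_that("write-then-read round trip preserves coordinates to format precision", {
  set.seed(11)
  opos <- cbind(runif(20, 0, 4), runif(20, 0, 4), runif(20, 0, 4))
  tr <- toy_water_traj(opos, box = c(4.5, 4.5, 4.5))
  # format precision: GRO stores 3 decimals in nm, PDB 3 decimals in Angstrom
  for (fmt in c("gro", "pdb")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(tr, f, fmt)
    back <- read_structure(f)
    tol <- if (fmt == "gro") 5.1e-4 else 5.1e-5
    expect_lt(max(abs(back$frames[[1]]$xyz - tr$frames[[1]]$xyz)), tol)
  }
})

test_that("multi-frame GRO trajectories read back ordered and complete", {
  set.seed(12)
  frames <- lapply(1:10, function(i) cbind(runif(5, 0, 4), runif(5, 0, 4), runif(5, 0, 4)))
  tr <- toy_water_traj(frames[[1]], box = c(4.5, 4.5, 4.5))
  tr$frames <- lapply(seq_along(frames), function(i) {
    w <- toy_water_traj(frames[[i]], box = c(4.5, 4.5, 4.5))
    list(xyz = w$frames[[1]]$xyz, box = c(4.5, 4.5, 4.5), time = i - 1)
  })
  f <- withr::local_tempfile(fileext = ".gro")
  write_structure(tr, f, "gro")
  suppressMessages(back <- read_trajectory(f))
  expect_equal(n_frames(back), 10)
  tms <- vapply(back$frames, function(fr) fr$time, numeric(1))
  expect_true(all(diff(tms) > 0))
  expect_lt(max(abs(back$frames[[7]]$xyz - tr$frames[[7]]$xyz)), 5.1e-4)
})

test_that("a truncated trajectory file errors instead of silently reading part", {
  set.seed(13)
  tr <- toy_water_traj(cbind(runif(5), runif(5), runif(5)), box = c(3, 3, 3))
  f <- withr::local_tempfile(fileext = ".gro")
  write_structure(tr, f, "gro")
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 2)], f)  # drop an atom and the box line
  expect_error(suppressMessages(read_trajectory(f)), "truncated|parse")
})

test_that("parameter assignment covers pair lookup, element fallback and neutrality", {
  tr <- toy_water_traj(matrix(c(1, 1, 1), 1))
  tr$atoms$vdw_radius <- NULL; tr$atoms$partial_charge <- NULL
  params <- data.frame(residue_name = c("SOL", NA, NA),
                       atom_name = c("OW", NA, NA),
                       element = c(NA, "O", "H"),
                       vdw_radius = c(0.152, 0.999, 0.04),
                       charge = c(-0.82, 0, 0.41))
  out <- assign_parameters(tr, params)
  # pair entry beats the element fallback for OW; H falls back to element
  expect_equal(out$atoms$vdw_radius, c(0.152, 0.04, 0.04))
  expect_equal(sum(out$atoms$partial_charge), 0)  # -0.82 + 2 * 0.41
  expect_true(all(out$atoms$is_water))
})

test_that("unparameterised atoms are reported together, never defaulted", {
  xyz <- matrix(runif(9), 3)
  tr <- toy_protein_traj(xyz)
  tr$atoms$atom_name <- c("CA1", "CG1", "CD1")
  tr$atoms$vdw_radius <- NULL; tr$atoms$partial_charge <- NULL
  params <- data.frame(residue_name = "ALA", atom_name = "CA1", element = NA,
                       vdw_radius = 0.17, charge = 0)
  expect_error(assign_parameters(tr, params), "CG1")
  expect_error(assign_parameters(tr, params), "CD1")
})

test_that("IBS selection complements to NIBS and rejects bad input", {
  prot <- toy_protein_traj(runif_ellipsoid(10, c(1, 1, 1), c(2, 2, 2)))
  sels <- load_selection("A:1-5", prot)
  expect_equal(sort(sels$ibs$residues$residue_id), 1:5)
  expect_equal(sort(sels$nibs$residues$residue_id), 6:10)
  expect_equal(nrow(sels$whole$residues), 10)
  # disjoint and covering
  expect_length(intersect(sels$ibs$residues$residue_id, sels$nibs$residues$residue_id), 0)

  expect_error(load_selection(character(0), prot), "empty")
  expect_error(load_selection("A:99", prot), "99")
  expect_warning(s2 <- load_selection(c("A:1-3", "A:2"), prot), "dedup")
  expect_equal(sort(s2$ibs$residues$residue_id), 1:3)
})
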