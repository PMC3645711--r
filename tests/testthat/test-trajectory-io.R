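pdb_lines <- function(models, cryst = "CRYST1   50.000   50.000   70.000  90.00  90.00  90.00 P 1",
                      use_model_records = TRUE) {
  out <- if (!is.null(cryst)) cryst else character()
  for (m in seq_along(models)) {
    if (use_model_records) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, models[[m]])
    if (use_model_records) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

atom_line <- function(serial, name, resname, resid, x, y, z, altloc = " ") {
  sprintf(
    "ATOM  %5d %-4s%s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    serial, name, altloc, resname, resid, x, y, z, toupper(substr(name, 1, 1))
  )
}

test_that("single-model PDB with CRYST1 is read as a one-frame trajectory", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(list(c(
    atom_line(1, "P", "POPC", 1, 1.5, 2.25, 3.125),
    atom_line(2, "N", "POPC", 1, 4, 5, 6),
    atom_line(3, "OH2", "TIP3", 2, 7, 8, 9)
  )), use_model_records = FALSE), path)
  tr <- read_pdb(path)
  expect_equal(dim(tr$coords), c(3, 3, 1))
  expect_equal(tr$box[1, ], c(50, 50, 70))
  expect_equal(tr$coords[1, , 1], c(1.5, 2.25, 3.125))
  expect_equal(tr$topology$atoms$name, c("P", "N", "OH2"))
  expect_equal(tr$topology$atoms$resname, c("POPC", "POPC", "TIP3"))
  expect_true(all(tr$topology$atoms$role == "other"))
})

test_that("malformed PDBs are rejected with informative errors", {
  # second model drops an atom
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(list(
    c(atom_line(1, "P", "POPC", 1, 0, 0, 0), atom_line(2, "N", "POPC", 1, 1, 1, 1)),
    atom_line(1, "P", "POPC", 1, 0, 0, 0)
  )), path)
  expect_error(read_pdb(path), "atom-count mismatch")

  # no CRYST1 anywhere and no override
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(list(atom_line(1, "P", "POPC", 1, 0, 0, 0)), cryst = NULL), path2)
  expect_error(read_pdb(path2), "frame 1")
  tr <- read_pdb(path2, box = c(30, 30, 50))
  expect_equal(tr$box[1, ], c(30, 30, 50))

  # triclinic cell
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(
    list(atom_line(1, "P", "POPC", 1, 0, 0, 0)),
    cryst = "CRYST1   50.000   50.000   70.000  90.00  95.00  90.00 P 1"
  ), path3)
  expect_error(read_pdb(path3), "triclinic")

  # disallowed altLoc
  path4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines(list(atom_line(1, "P", "POPC", 1, 0, 0, 0, altloc = "B"))), path4)
  expect_error(read_pdb(path4), "alternate location")
})

test_that("PDB fixtures round-trip to format precision, including per-frame boxes", {
  spec <- small_spec(n_frames = 3, box_fluct_sd = 0.2)
  tr <- generate_bilayer(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, path)
  tr2 <- read_pdb(path)
  expect_equal(dim(tr2$coords), dim(tr$coords))
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-3)
  expect_lt(max(abs(tr2$coords - tr$coords)), 5.1e-4) # 3-decimal precision
  expect_equal(tr2$box, round(tr$box, 3), ignore_attr = TRUE)
  expect_equal(tr2$topology$atoms$name, tr$topology$atoms$name)

  tr3 <- read_pdb(path, model_range = c(2, 3))
  expect_equal(dim(tr3$coords)[3], 2)
  expect_equal(tr3$coords[, , 1], tr$coords[, , 2], tolerance = 1e-3)
})

test_that("PDB reader agrees with an independent reader on coordinates", {
  skip_if_not_installed("bio3d")
  spec <- small_spec(n_frames = 1)
  tr <- generate_bilayer(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(
    matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE),
    ours$coords[, , 1],
    ignore_attr = TRUE
  )
  expect_equal(trimws(ref$atom$elety), ours$topology$atoms$name)
})

test_that("DCD round-trips preserve frames, boxes and coordinates", {
  spec <- small_spec(n_frames = 5, box_fluct_sd = 0.2)
  tr <- generate_bilayer(spec)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, path)
  tr2 <- read_dcd(tr$topology, path)
  expect_equal(dim(tr2$coords)[3], 5)
  expect_equal(tr2$box, tr$box, ignore_attr = TRUE)
  expect_equal(tr2$times, tr$times, tolerance = 1e-6)
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-4) # float32 storage

  skip_if_not_installed("bio3d")
  ref <- bio3d::read.dcd(path, verbose = FALSE)
  expect_equal(
    matrix(ref[3, ], ncol = 3, byrow = TRUE),
    tr2$coords[, , 3],
    ignore_attr = TRUE, tolerance = 1e-6
  )
})

test_that("corrupt DCD inputs give explicit errors", {
  spec <- small_spec(n_frames = 4)
  tr <- generate_bilayer(spec)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, path)

  # atom-count mismatch against a different topology
  topo_small <- micro_topology(2)
  expect_error(read_dcd(topo_small, path), "does not match topology atom count")

  # truncate inside the last frame
  sz <- file.size(path)
  raw_all <- readBin(path, "raw", sz)
  path_tr <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw_all[1:(sz - 1000)], path_tr)
  expect_error(read_dcd(tr$topology, path_tr), "last complete frame is 3")

  # header only: no frames at all
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 84 + 8 + 84 + 8 + 12 + 8)
  close(con)
  path_empty <- withr::local_tempfile(fileext = ".dcd")
  writeBin(hdr, path_empty)
  expect_error(read_dcd(tr$topology, path_empty), "truncated|no frames")

  path_zero <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw(0), path_zero)
  expect_error(read_dcd(tr$topology, path_zero), "empty DCD")
})

test_that("role assignment follows the rules: lipids, chains, waters, ions", {
  spec <- small_spec(n_frames = 1)
  tr <- generate_bilayer(spec)
  a <- tr$topology$atoms
  lip <- tr$topology$lipids

  expect_equal(nrow(lip), 24)
  expect_equal(a$name[lip$head], rep("As", 24)) # arsenocholine headgroup
  expect_equal(a$name[lip$choline_n], rep("N", 24))
  # sn-1 carbon 1 is C31, sn-2 carbon 1 is C21; ordinals increase along the chain
  expect_equal(a$name[lip$sn1[[1]][1]], "C31")
  expect_equal(a$name[lip$sn2[[1]][1]], "C21")
  expect_equal(a$chain_ordinal[lip$sn1[[1]]], seq_along(lip$sn1[[1]]))
  # each carbon has two bonded hydrogens
  expect_true(all(lengths(lip$h_map[[1]]) == 2))
  # waters and ions
  expect_equal(sum(a$role == "water_O"), spec$n_waters)
  expect_equal(sum(a$role == "ion"), spec$n_na + spec$n_cl)
  expect_true(all(a$role[a$resname == "TIP3" & a$name != "OH2"] == "other"))
})

test_that("a lipid lacking a required role is reported by residue id", {
  atoms <- tibble::tibble(
    name = c("P", "C31", "HA1", "HB1", "C21", "HC1", "HD1"), # no choline N
    resname = "POPC", resid = 7L
  )
  expect_error(
    assign_roles(build_topology(atoms), default_role_rules("POPC", sn1_length = 1, sn2_length = 1)),
    "residue 7"
  )
})

test_that("role-rule files round-trip through the plain-text schema", {
  rules <- default_role_rules(c("POAC", "POPC"))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_role_rules(rules, path)
  rules2 <- read_role_rules(path)
  expect_equal(rules2$lipids$POAC$headgroup_center, "As")
  expect_equal(rules2$lipids$POPC$headgroup_center, "P")
  expect_equal(rules2$lipids$POPC$sn1_prefix, "C3")
  expect_equal(rules2$lipids$POPC$sn2_length, 18L)
  expect_equal(rules2$lipids$POPC$sn1_h_prefixes, c("HA", "HB"))
  expect_error(read_role_rules({
    p <- withr::local_tempfile()
    writeLines("bogus directive", p)
    p
  }), "unknown role-rule directive")
})
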