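test_that("PDB structures parse with roles, units and validation", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), p)
  cx <- read_structure(p)
  expect_equal(nrow(cx$residues), 3)
  expect_equal(unname(cx$chain_roles["A"]), "receptor")
  # Angstrom input converted to nm
  expect_equal(cx$atoms$x[1], 1.0)

  # water and ion chains recognised from residue names
  lines2 <- c(toy_pdb_lines()[-13],
              "ATOM     13  O   HOH W   1       1.000   1.000   1.000  1.00  0.00           O",
              "ATOM     14 NA    NA I   1       2.000   2.000   2.000  1.00  0.00          NA",
              "END")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines2, p2)
  cx2 <- read_structure(p2)
  expect_equal(unname(cx2$chain_roles[c("W", "I")]), c("water", "ion"))

  # truncated ATOM record names its line
  bad <- toy_pdb_lines()
  bad[5] <- substr(bad[5], 1, 40)
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, p3)
  expect_error(read_structure(p3), "line 5")

  # duplicate serial rejected
  dup <- toy_pdb_lines()
  dup[3] <- sub("    2", "    1", dup[3])
  p4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(dup, p4)
  expect_error(read_structure(p4), "duplicate atom serial")
})

test_that("structure round-trip preserves positions and annotations", {
  spec <- synthetic_spec(seed = 4, n_frames = 3,
                         helix_layout = two_helix_layout())
  cx <- generate_toy_complex(spec)
  cx <- apply_annotations(cx, tibble::tibble(
    chain = "A", resnum = 3L, icode = "", generic_number = "3.50",
    substructure = "TM3"))
  d <- withr::local_tempdir()
  f <- file.path(d, "s.pdb")
  write_structure(cx, f)
  back <- read_structure(f, chain_roles = c(A = "receptor", B = "partner"))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(cx$atoms[, c("x", "y", "z")]))), 1e-3)
  a <- file.path(d, "a.tsv")
  readr::write_tsv(annotation_table(cx), a)
  back <- read_annotation_table(a, back)
  expect_identical(annotation_table(back), annotation_table(cx))
})

test_that("annotation tables attach, validate and resolve", {
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- gsub("A   1", "A 141", toy_pdb_lines())
  writeLines(lines, p)
  cx <- read_structure(p)
  cx2 <- apply_annotations(cx, tibble::tibble(
    chain = "A", resnum = 141L, icode = "", generic_number = "3.50",
    substructure = "TM3"))
  r1 <- resolve(cx2, "3.50")
  r2 <- resolve(cx2, list(chain = "A", resnum = 141))
  expect_equal(r1$residue_index, r2$residue_index)
  expect_equal(r1$resname, "ALA")

  # empty table leaves the complex unchanged
  expect_identical(apply_annotations(cx, tibble::tibble(
    chain = character(0), resnum = integer(0), icode = character(0),
    generic_number = character(0), substructure = character(0))), cx)

  # duplicate generic number within a chain
  expect_error(apply_annotations(cx2, tibble::tibble(
    chain = "A", resnum = c(2L, 3L), icode = "",
    generic_number = c("3.50", "3.50"), substructure = "TM3")),
    "duplicate generic_number")

  # row referencing a nonexistent residue
  expect_error(apply_annotations(cx, tibble::tibble(
    chain = "A", resnum = 999L, icode = "", generic_number = "9.99",
    substructure = "TM9")), "nonexistent")

  expect_error(resolve(cx2, "9.99"), "9.99")
})

test_that("trajectories read back with unit conversion and validation", {
  spec <- synthetic_spec(seed = 4, n_frames = 10,
                         helix_layout = two_helix_layout())
  cx <- generate_toy_complex(spec)
  ens <- generate_trajectory(cx, spec)
  d <- withr::local_tempdir()
  f <- file.path(d, "traj.pdb")
  write_trajectory_pdb(cx, ens, f)
  back <- read_trajectory(f, cx)
  expect_equal(length(back$replicas), 1)
  expect_equal(nrow(back$replicas[[1]]$xyz), 10)
  expect_lt(max(abs(back$replicas[[1]]$xyz - ens$replicas[[1]]$xyz)), 1e-3)
  expect_equal(back$replicas[[1]]$time, ens$replicas[[1]]$time)

  # atom-count mismatch rejected
  spec2 <- synthetic_spec(seed = 4, n_frames = 2,
                          helix_layout = two_helix_layout(n_receptor = 14))
  cx2 <- generate_toy_complex(spec2)
  expect_error(read_trajectory(f, cx2), "does not match topology")
})

test_that("GRO files parse in native nm", {
  g <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "toy", "    3",
    "    1ALA      N    1   1.000   1.000   1.000",
    "    1ALA     CA    2   1.146   1.000   1.000",
    "    1ALA      C    3   1.201   1.142   1.000",
    "   3.00000   3.00000   3.00000"), g)
  cx <- read_structure(g)
  expect_equal(nrow(cx$atoms), 3)
  expect_equal(cx$atoms$x[2], 1.146)
  expect_equal(cx$atoms$element, c("N", "C", "C"))
})
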