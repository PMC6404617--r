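test_that("a written fixture round-trips through the PDB reader", {
  s <- make_mini_hairpin()
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- parse_structure(f)
  expect_length(s2$protomers, 1)
  a1 <- s$protomers[[1]]$atoms
  a2 <- s2$protomers[[1]]$atoms
  expect_equal(nrow(a2), nrow(a1))
  expect_equal(a2$name, a1$name)
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$resid, a1$resid)
  # PDB format carries 3 decimals
  expect_lt(max(abs(a2$x - a1$x), abs(a2$y - a1$y), abs(a2$z - a1$z)), 1e-3)
})

test_that("parser keeps the first altloc conformer and drops the rest", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.500   2.400   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       2.000  -1.000   1.000  0.60  0.00           C",
    "ATOM      6  CB BALA A   1       2.100  -1.100   1.100  0.40  0.00           C",
    "END")
  expect_message(s <- parse_structure(paste(lines, collapse = "\n")),
                 "discarded 1")
  at <- s$protomers[[1]]$atoms
  expect_equal(sum(at$name == "CB"), 1)
  expect_equal(at$altloc[at$name == "CB"], "A")
  expect_equal(s$n_altloc_discarded, 1L)
})

test_that("duplicate (name, altloc) atoms within a residue are rejected", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   1       1.458   0.100   0.000  1.00  0.00           C",
    "END")
  expect_error(parse_structure(paste(lines, collapse = "\n")),
               "duplicate atom")
})

test_that("malformed ATOM records raise a parse error naming the line", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       bad")
  expect_error(parse_structure(paste(lines, collapse = "\n")),
               "line 2")
})

test_that("radius assignment covers every heavy atom and conserves atoms", {
  s <- make_mini_hairpin()
  at <- s$protomers[[1]]$atoms
  n_before <- nrow(at)
  expect_true(all(at$vdw[!at$is_hydrogen] > 0))
  # carbon gets the Bondi value
  expect_equal(unique(at$vdw[at$element == "C"]), 1.70)
  s2 <- assign_vdw_radii(s, default_radius_table())
  expect_equal(nrow(s2$protomers[[1]]$atoms), n_before)
})

test_that("elements missing from the radius table are reported by name", {
  s <- make_mini_hairpin()
  s$protomers[[1]]$atoms$element[5] <- "SE"
  expect_error(assign_vdw_radii(s, default_radius_table()), "SE")
})

test_that("residue accessors expose numbering, amino acid and backbone", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  r <- get_residue(p, 5)
  expect_equal(r$amino_acid, "GLU")
  expect_false(r$incomplete)
  expect_equal(rownames(residue_coords(r)), c("N", "CA", "C", "O"))
  expect_error(get_residue(p, 999), "no residue")
  expect_error(residue_coords(r, "OZ9"), "lacks atom")
})

test_that("mmCIF atom_site loops parse to the same model as PDB", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N  . ALA A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 C CA . ALA A 1 1.458 0.000 0.000 1.00 1",
    "ATOM 3 C C  . ALA A 1 2.009 1.420 0.000 1.00 1",
    "ATOM 4 O O  . ALA A 1 1.251 2.390 0.000 1.00 1",
    "ATOM 5 C CB . ALA A 1 2.000 -0.773 -1.208 1.00 1",
    "ATOM 6 N N  . ALA A 1 9.000 0.000 0.000 1.00 2",
    "#")
  f <- tempfile(fileext = ".cif")
  writeLines(cif, f)
  s <- parse_structure(f, format = "cif")
  at <- s$protomers[[1]]$atoms
  expect_equal(nrow(at), 5)      # second model dropped
  expect_equal(at$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(at$resid[1], "ALA")
  expect_equal(unique(at$vdw[at$element == "C"]), 1.70)
})

test_that("radius tables load from key/value config files", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# custom radii", "C 1.75", "N 1.60", "O 1.50", "SE 1.90"), f)
  tab <- read_radius_table(f)
  expect_equal(unname(tab["SE"]), 1.90)
  expect_equal(unname(tab["C"]), 1.75)
})
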