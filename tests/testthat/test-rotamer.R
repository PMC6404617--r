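test_that("build/measure chi round-trips for every buildable amino acid", {
  set.seed(23)
  for (aa in setdiff(amino_acids(), c("PRO", "GLY", "ALA"))) {
    for (k in 1:3) {
      chi <- runif(chi_count(aa), -179, 179)
      p <- build_peptide(c("A", aa, "A"), chi = list(NULL, chi, NULL))
      m <- measure_chi(get_residue(p, 2))
      err <- max(abs(((m$values - chi + 180) %% 360) - 180))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("glycine has no chi and alanine a single trivial rotamer", {
  p <- build_peptide(c("A", "G", "A"))
  expect_length(measure_chi(get_residue(p, 2))$values, 0)
  expect_length(enumerate_rotamers("GLY"), 1)
  expect_length(enumerate_rotamers("GLY")[[1]]$chi, 0)
  expect_length(enumerate_rotamers("ALA"), 1)
})

test_that("canonical library holds the three staggered valine rotamers", {
  rots <- enumerate_rotamers("VAL")
  expect_length(rots, 3)
  expect_setequal(vapply(rots, function(r) r$chi, numeric(1)),
                  c(-60, 60, 180))
  # and matches the shipped library file read back directly
  csv <- utils::read.csv(system.file("extdata", "rotamer_library.csv",
                                     package = "steriscan"))
  expect_setequal(csv$chi1[csv$amino_acid == "VAL"], c(-60, 60, 180))
})

test_that("grid enumeration count is step-count^chi-count", {
  expect_length(enumerate_rotamers("GLU", mode = "grid", grid_step = 60),
                216)
  expect_length(enumerate_rotamers("VAL", mode = "grid", grid_step = 30),
                12)
  expect_length(enumerate_rotamers("SER", mode = "grid", grid_step = 120),
                3)
})

test_that("backbone-dependent mode needs phi/psi and filters chi1 wells", {
  expect_error(enumerate_rotamers("VAL", backbone_dependent = TRUE),
               "phi_psi")
  beta <- enumerate_rotamers("VAL", backbone_dependent = TRUE,
                             phi_psi = c(-139, 135))
  expect_true(all(vapply(beta, function(r) r$chi[1], numeric(1)) != 60))
  loop <- enumerate_rotamers("VAL", backbone_dependent = TRUE,
                             phi_psi = c(60, 60))
  expect_length(loop, 3)
})

test_that("glutamine and glutamate build identical geometry up to the
           terminal atom identities", {
  p <- build_peptide(c("A", "E", "A"), chi = list(NULL, c(-60, 180, 0),
                                                  NULL))
  bb <- residue_coords(get_residue(p, 2), c("N", "CA", "C"))
  e <- build_side_chain(bb, "GLU", rotamer("GLU", c(-60, 180, 0)))
  q <- build_side_chain(bb, "GLN", rotamer("GLN", c(-60, 180, 0)))
  shared <- c("CB", "CG", "CD")
  expect_equal(as.matrix(e[match(shared, e$name), c("x", "y", "z")]),
               as.matrix(q[match(shared, q$name), c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_setequal(setdiff(q$name, e$name), "NE2")
  # terminal oxygens sit near the amide atoms (ideal bond lengths for the
  # carboxylate and amide differ by ~0.02 A)
  expect_lt(max(abs(e[e$name == "OE1", c("x", "y", "z")] -
                      q[q$name == "OE1", c("x", "y", "z")])), 0.15)
})

test_that("aspartate reaches at least one bond shorter than glutamate", {
  p <- build_peptide(c("A", "E", "A"))
  r <- get_residue(p, 2)
  bb <- residue_coords(r, c("N", "CA", "C"))
  ca <- residue_coords(r, "CA")
  reach <- function(sc) {
    max(sqrt(rowSums(sweep(as.matrix(sc[, c("x", "y", "z")]), 2,
                           as.numeric(ca))^2)))
  }
  glu_reach <- max(vapply(enumerate_rotamers("GLU"), function(rt)
    reach(build_side_chain(bb, "GLU", rt)), numeric(1)))
  asp_reach <- max(vapply(enumerate_rotamers("ASP"), function(rt)
    reach(build_side_chain(bb, "ASP", rt)), numeric(1)))
  expect_lt(asp_reach, glu_reach - 1.0)
})

test_that("built side chains have L-amino-acid chirality", {
  p <- build_peptide(c("A", "V", "A"), chi = list(NULL, -60, NULL))
  co <- residue_coords(get_residue(p, 2), c("C", "N", "CA", "CB"))
  improper <- dihedral_angle(co[1, ], co[2, ], co[3, ], co[4, ])
  expect_lt(improper, -100)   # D-amino acids would give the mirror (+123)
  expect_gt(improper, -145)
})

test_that("replace_residue swaps exactly the side chain", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  v <- variant_spec(5, "GLU", "GLY")
  m <- replace_residue(p, v, rotamer("GLY", numeric(0)))
  r <- get_residue(m, 5)
  expect_setequal(r$atoms$name, c("N", "CA", "C", "O"))
  expect_equal(r$amino_acid, "GLY")

  m2 <- replace_residue(p, variant_spec(5, "GLU", "VAL"),
                        rotamer("VAL", 180))
  expect_setequal(setdiff(get_residue(m2, 5)$atoms$name,
                          c("N", "CA", "C", "O")),
                  c("CB", "CG1", "CG2"))

  # backbone of every residue bit-identical
  bb_names <- c("N", "CA", "C", "O")
  a0 <- p$atoms[p$atoms$name %in% bb_names, c("x", "y", "z")]
  a1 <- m$atoms[m$atoms$name %in% bb_names, c("x", "y", "z")]
  expect_identical(a0$x, a1$x)
  expect_identical(a0$z, a1$z)
})

test_that("identity substitution at the template chi reproduces the
           template side chain", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  chi <- measure_chi(get_residue(p, 5))$values
  m <- replace_residue(p, variant_spec(5, "GLU", "GLU"),
                       rotamer("GLU", chi))
  r0 <- get_residue(p, 5)$atoms
  r1 <- get_residue(m, 5)$atoms
  r1 <- r1[match(r0$name, r1$name), ]
  d <- sqrt((r0$x - r1$x)^2 + (r0$y - r1$y)^2 + (r0$z - r1$z)^2)
  expect_lt(max(d), 1e-3)
})

test_that("deletions and wild-type mismatches are refused", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  expect_error(replace_residue(p, variant_spec(5, "GLU", "DEL"),
                               rotamer("GLY", numeric(0))),
               "rule")
  expect_error(replace_residue(p, variant_spec(5, "ASP", "GLY"),
                               rotamer("GLY", numeric(0))),
               "GLU")
  expect_error(build_side_chain(residue_coords(get_residue(p, 5),
                                               c("N", "CA", "C")),
                                "PRO", rotamer("PRO", c(-30, 30))),
               "geometry table")
})

test_that("variant strings parse to specs and format back", {
  v <- parse_variant("E40G")
  expect_equal(v$position, 40L)
  expect_equal(v$wild_type, "GLU")
  expect_equal(v$substitution, "GLY")
  expect_equal(format(v), "E40G")
  vd <- parse_variant("E133del")
  expect_equal(vd$substitution, "DEL")
  expect_equal(format(vd), "E133del")
  expect_error(parse_variant("X!4"), "cannot parse")
})
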