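test_that("rigid copies superpose back onto the template exactly", {
  tmpl <- build_peptide(c("A", "E", "K", "A"), chain_id = "A")
  set.seed(61)
  prot <- lapply(1:4, function(i) {
    R <- rotation_about_axis(rnorm(3), runif(1, 0, 360))
    tr <- make_transform(R, rnorm(3, 0, 20))
    at <- tmpl$atoms
    xyz <- apply_transform(tr, as.matrix(at[, c("x", "y", "z")]))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    p <- tmpl; p$atoms <- at; p
  })
  sup <- superpose_ensemble(prot)
  expect_true(all(sup$rmsd < 1e-6))
  # every atom, not just the selection, lands on the reference
  a1 <- as.matrix(sup$protomers[[1]]$atoms[, c("x", "y", "z")])
  a3 <- as.matrix(sup$protomers[[3]]$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(a1 - a3)), 1e-6)
})

test_that("backbone superposition preserves side-chain spread", {
  chis <- list(c(-60, -60, 0), c(180, 60, 0), c(60, 180, 90))
  prot <- lapply(chis, function(ch)
    build_peptide(c("A", "E", "A"), chi = list(NULL, ch, NULL)))
  set.seed(62)
  prot <- lapply(prot, function(p) {
    tr <- make_transform(rotation_about_axis(rnorm(3), runif(1, 0, 360)),
                         rnorm(3, 0, 15))
    at <- p$atoms
    xyz <- apply_transform(tr, as.matrix(at[, c("x", "y", "z")]))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    p$atoms <- at; p
  })
  sup <- superpose_ensemble(prot)
  expect_true(all(sup$rmsd < 1e-6))   # backbones identical by construction
  # coordinate-variance oracle: side-chain tip spreads, backbone does not
  tip <- sapply(sup$protomers, function(p)
    as.numeric(p$atoms[p$atoms$name == "OE1", c("x", "y", "z")]))
  ca <- sapply(sup$protomers, function(p)
    as.numeric(p$atoms[p$atoms$name == "CA" & p$atoms$resno == 2,
                       c("x", "y", "z")]))
  expect_lt(max(apply(ca, 1, var)), 1e-10)
  expect_gt(sum(apply(tip, 1, var)), 1)
})

test_that("selections parse and missing atoms are reported by residue", {
  sel <- parse_selection("A:3-10@N,CA")
  expect_equal(sel$chain, "A")
  expect_equal(sel$resno, 3:10)
  expect_equal(sel$atoms, c("N", "CA"))
  expect_error(parse_selection("3-5@"), "empty")

  tmpl <- build_peptide(c("A", "A", "A"))
  expect_error(superpose_ensemble(list(tmpl, tmpl), selection = "1-5@CA"),
               "residue 4")
  expect_error(superpose_ensemble(list(tmpl, tmpl), selection = "1-2@CQ"),
               "CQ")
})

test_that("hbond census partitions protomers and honors tie-breaking", {
  en <- make_ensemble(c(A = 2, none = 1), seed = 5)
  cen <- census_hbonds(en, attr(en, "donor"), attr(en, "acceptors"))
  expect_equal(cen$total, 3)
  expect_equal(sum(cen$partner_counts), cen$total)
  expect_equal(unname(cen$partner_counts["A"]), 2L)
  expect_equal(unname(cen$partner_counts["none"]), 1L)
})

test_that("census with no candidate acceptors assigns everything to none", {
  en <- make_ensemble(c(A = 1, B = 1, none = 1), seed = 6)
  cen <- census_hbonds(en, attr(en, "donor"), list())
  expect_equal(unname(cen$partner_counts["none"]), 3L)
})

test_that("protomers lacking the donor are excluded and reported", {
  en <- make_ensemble(c(A = 2, none = 1), seed = 7)
  # amputate the donor NZ from the second protomer
  en[[2]]$atoms <- en[[2]]$atoms[en[[2]]$atoms$name != "NZ", ]
  cen <- census_hbonds(en, attr(en, "donor"), attr(en, "acceptors"))
  expect_equal(cen$total, 2)
  expect_equal(cen$excluded, 2L)
  expect_equal(sum(cen$partner_counts), 2L)
})
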