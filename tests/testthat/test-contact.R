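atom_row <- function(name, resno, x, y, z, vdw = 1.70) {
  data.frame(name = name, resno = resno, x = x, y = y, z = z, vdw = vdw,
             is_hydrogen = FALSE, stringsAsFactors = FALSE)
}

test_that("clash detection applies the overlap threshold arithmetic", {
  a <- atom_row("C1", 1, 0, 0, 0)
  # 3.40 - 3.5 < 0.4: no clash
  expect_equal(nrow(detect_clashes(a, atom_row("C2", 2, 3.5, 0, 0))), 0)
  # 3.40 - 2.9 = 0.50 > 0.4: one clash
  cl <- detect_clashes(a, atom_row("C2", 2, 2.9, 0, 0))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 0.5)
  expect_error(detect_clashes(a, atom_row("C2", 2, 2.9, 0, 0,
                                          vdw = NA_real_)),
               "radius")
})

test_that("contact shell bounds are honored", {
  a <- atom_row("C1", 1, 0, 0, 0)
  expect_equal(nrow(count_vdw_contacts(a, atom_row("C2", 2, 3.6, 0, 0))), 1)
  expect_equal(nrow(count_vdw_contacts(a, atom_row("C2", 2, 4.2, 0, 0))), 0)
  # clash pairs are not contacts
  expect_equal(nrow(count_vdw_contacts(a, atom_row("C2", 2, 2.5, 0, 0))), 0)
})

test_that("clash and contact sets equal the brute-force oracle", {
  for (seed in 1:20) {
    probe <- random_atom_set(12, seed = seed)
    env <- random_atom_set(50, seed = seed + 1000)
    env$resno <- env$resno + 100L
    got <- clash_keys(detect_clashes(probe, env))
    expect_identical(got, oracle_clash_keys(probe, env))
    gotc <- clash_keys(count_vdw_contacts(probe, env))
    expect_identical(gotc, oracle_contact_keys(probe, env))
  }
})

test_that("raising the overlap threshold never adds clashes", {
  probe <- random_atom_set(15, seed = 31)
  env <- random_atom_set(40, seed = 32)
  env$resno <- env$resno + 100L
  n <- vapply(c(0, 0.2, 0.4, 0.6, 1.0), function(th)
    nrow(detect_clashes(probe, env, th)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("pair sets are symmetric under probe/environment swap", {
  probe <- random_atom_set(10, seed = 41)
  env <- random_atom_set(25, seed = 42)
  env$resno <- env$resno + 100L
  swap_keys <- function(k) {
    parts <- strsplit(k, "~", fixed = TRUE)
    sort(vapply(parts, function(p) paste(p[2], p[1], sep = "~"),
                character(1)))
  }
  expect_identical(swap_keys(clash_keys(detect_clashes(probe, env))),
                   clash_keys(detect_clashes(env, probe)))
  expect_identical(swap_keys(clash_keys(count_vdw_contacts(probe, env))),
                   clash_keys(count_vdw_contacts(env, probe)))
})

test_that("hydrogen bonds require distance and antecedent angle", {
  hp <- make_hbond_pair(2.9)
  sites <- hbond_sites(hp$protomers[[1]]$atoms)
  hb <- detect_hbonds(sites$donors, sites$acceptors)
  # reciprocal pair: one bond per direction
  expect_equal(nrow(hb), 2)
  expect_setequal(hb$donor_name, "ND2")
  expect_setequal(hb$acceptor_name, "OD1")
  expect_true(all(hb$distance <= 3.5 & hb$angle >= 90))

  far <- make_hbond_pair(4.0)
  sfar <- hbond_sites(far$protomers[[1]]$atoms)
  expect_equal(nrow(detect_hbonds(sfar$donors, sfar$acceptors)), 0)
  # a looser distance criterion re-admits them
  expect_gt(nrow(detect_hbonds(sfar$donors, sfar$acceptors,
                               hbond_criteria(max_distance = 4.5))), 0)
})

test_that("hbond criteria validate their ranges", {
  expect_error(hbond_criteria(max_distance = 0))
  expect_error(hbond_criteria(max_distance = 7))
  expect_error(hbond_criteria(min_angle = 200))
})

test_that("probe in an empty environment reports nothing", {
  probe <- random_atom_set(5, seed = 51)
  empty <- probe[0, ]
  expect_equal(nrow(detect_clashes(probe, empty)), 0)
  expect_equal(nrow(count_vdw_contacts(probe, empty)), 0)
})

test_that("identity substitution scores like the wild type itself", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  chi <- measure_chi(get_residue(p, 5))$values
  sc <- score_rotamer(p, variant_spec(5, "GLU", "GLU"),
                      rotamer("GLU", chi))
  expect_equal(sc$report$n_clashes, 0)
  expect_equal(sc$report$n_contacts, sc$wt_report$n_contacts)
  expect_equal(sc$report$n_hbonds, sc$wt_report$n_hbonds)
})

test_that("bonded 1-2/1-3/1-4 pairs are excluded from scoring", {
  s <- make_mini_hairpin()
  p <- s$protomers[[1]]
  excl <- bonded_exclusions(5, "GLU", 4, 6)
  # CB-CA (1-2), CB-N (1-3), CG-C (1-4) all excluded; CG-O is 1-5, kept
  expect_true(any(excl$probe == "5:CB" & excl$env == "5:CA"))
  expect_true(any(excl$probe == "5:CB" & excl$env == "5:N"))
  expect_true(any(excl$probe == "5:CG" & excl$env == "5:C"))
  expect_false(any(excl$probe == "5:CG" & excl$env == "5:O"))
  # peptide link: CB against the previous residue's carbonyl carbon (1-4)
  expect_true(any(excl$probe == "5:CB" & excl$env == "4:C"))
})

test_that("clash-pair fixture produces the requested overlap", {
  cp <- make_clash_pair(2.8)
  p <- cp$protomers[[1]]
  probe <- p$atoms[p$atoms$resno == 1 &
                     !(p$atoms$name %in% c("N", "CA", "C", "O")), ]
  env <- p$atoms[p$atoms$resno == 5, ]
  cl <- detect_clashes(probe, env)
  expect_gte(nrow(cl), 1)
  expect_equal(min(cl$distance), 2.8, tolerance = 1e-6)
  # widened gap removes the clash
  cp2 <- make_clash_pair(3.6)
  p2 <- cp2$protomers[[1]]
  probe2 <- p2$atoms[p2$atoms$resno == 1 &
                       !(p2$atoms$name %in% c("N", "CA", "C", "O")), ]
  env2 <- p2$atoms[p2$atoms$resno == 5, ]
  expect_equal(nrow(detect_clashes(probe2, env2)), 0)
})
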