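test_that("inclusion percentages follow the display convention", {
  expect_equal(round(inclusion_fraction(
    inclusion_counts("E40G", 48, 238, 186))), 78)
  expect_equal(inclusion_fraction(
    inclusion_counts("E40Q", 48, 229, 0)), 0)
  expect_equal(inclusion_fraction(
    inclusion_counts("WT", 24, 656, 5), display = TRUE), "≤ 1%")
  # 60/255 = 23.53 rounds half-up to 24
  expect_equal(inclusion_fraction(
    inclusion_counts("E133Del", 48, 255, 60), display = TRUE), "24%")
  expect_error(inclusion_counts("X", 24, 0, 0), "positive")
  expect_error(inclusion_counts("X", 24, 10, 11), "n_counted")
})

test_that("packaged counts reproduce every printed percentage cell", {
  counts <- read_counts_table(packaged_counts_path())
  expect_length(counts, 24)
  printed <- list(
    WT = c(1, 1), G93A = c(23, 48), E40D = c(34, 23), E40G = c(29, 78),
    E40Q = c(0, 0), E40V = c(24, 25), E133D = c(0, 0), E133G = c(0, 0),
    E133L = c(0, 0), E133M = c(0, 0), E133V = c(12, 24),
    E133Del = c(6, 24))
  for (cc in counts) {
    want <- printed[[cc$variant]][if (cc$timepoint == 24) 1 else 2]
    expect_equal(floor(inclusion_fraction(cc) + 0.5), want,
                 info = paste(cc$variant, cc$timepoint))
  }
  # the near-background wild-type 24 hr cell displays as a bound
  wt24 <- Filter(function(x) x$variant == "WT" && x$timepoint == 24,
                 counts)[[1]]
  expect_equal(inclusion_fraction(wt24, display = TRUE), "≤ 1%")
})

test_that("counts tables validate rows and reject empty input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("variant,timepoint,n_counted,n_inclusions",
               "A,24,100,5", "B,24,50,60"), f)
  expect_error(read_counts_table(f), "row 2")
  f2 <- tempfile(fileext = ".csv")
  writeLines("variant,timepoint,n_counted,n_inclusions", f2)
  expect_error(read_counts_table(f2), "empty|no lines")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), f3)
  expect_error(read_counts_table(f3), "columns")
})

test_that("aggregator calls use a strict cutoff at either timepoint", {
  agg <- call_aggregator(inclusion_counts("E133V", 24, 324, 38),
                         inclusion_counts("E133V", 48, 254, 62),
                         cutoff = 5)
  expect_true(agg$aggregator)
  non <- call_aggregator(inclusion_counts("E133L", 24, 275, 0),
                         inclusion_counts("E133L", 48, 373, 0),
                         cutoff = 5)
  expect_false(non$aggregator)
  # exactly at the cutoff: strict inequality, not an aggregator
  at_cut <- call_aggregator(inclusion_counts("X", 24, 100, 5),
                            inclusion_counts("X", 48, 100, 5),
                            cutoff = 5)
  expect_false(at_cut$aggregator)
  expect_error(call_aggregator(inclusion_counts("A", 24, 10, 0),
                               inclusion_counts("B", 48, 10, 0)),
               "different variants")
})

test_that("aggregator calls are monotone in the cutoff", {
  counts <- read_counts_table(packaged_counts_path())
  n_agg <- vapply(c(1, 3, 5, 10, 30), function(cut)
    sum(summarise_counts(counts, cutoff = cut)$aggregators), numeric(1))
  expect_true(all(diff(n_agg) <= 0))
})

test_that("the packaged panel gives a perfectly concordant 2x2 table", {
  counts <- read_counts_table(packaged_counts_path())
  cons <- packaged_expected_consequences()
  sm <- summarise_counts(counts, consequences = cons)
  as_res <- sm$association
  expect_equal(as.numeric(as_res$contingency),
               c(6, 0, 0, 5))           # column-major: a, c, b, d
  expect_equal(as_res$p_value, oracle_fisher_p(as_res$contingency),
               tolerance = 1e-12)
})

test_that("fisher p equals hypergeometric enumeration on assorted tables", {
  tabs <- list(rbind(c(6, 0), c(0, 5)), rbind(c(3, 2), c(1, 4)),
               rbind(c(2, 2), c(2, 2)), rbind(c(5, 1), c(2, 3)),
               rbind(c(1, 7), c(6, 1)))
  for (tb in tabs) {
    expect_equal(stats::fisher.test(tb)$p.value, oracle_fisher_p(tb),
                 tolerance = 1e-12)
  }
})

test_that("degenerate margins take the Haldane correction", {
  res <- associate(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))
  expect_true(res$haldane)
  expect_true(is.finite(res$odds_ratio))
  expect_error(associate(logical(0), logical(0)), "at least 2")
  expect_error(associate(c(TRUE, FALSE), TRUE), "length")
})

test_that("simulated count tables are deterministic and calibrated", {
  t1 <- make_counts_table(list(A = 0.5, B = 0), n = 100, seed = 9)
  t2 <- make_counts_table(list(A = 0.5, B = 0), n = 100, seed = 9)
  expect_identical(lapply(t1, unclass), lapply(t2, unclass))
  expect_true(all(vapply(t1[3:4], function(x) x$n_inclusions, numeric(1))
                  == 0))
  expect_error(make_counts_table(list(A = 1.5)), "0, 1")
  # mean over many seeds within 3 standard errors of the true rate
  p <- 0.78; n <- 238
  fr <- vapply(1:60, function(sd)
    make_counts_table(list(X = p), n = n,
                      seed = sd)[[1]]$n_inclusions / n, numeric(1))
  se <- sqrt(p * (1 - p) / n) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - p), 3 * se)
})
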