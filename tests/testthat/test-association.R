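risk <- "02001-00401-01303"
unrelated <- cohort_filter(status = "control", relatedness = "unrelated")

test_that("odds ratio is the cross-product, with symmetry and null properties", {
  expect_equal(as.numeric(odds_ratio(two_by_two(35, 23, 162, 204))),
               1.92, tolerance = 0.005)
  expect_equal(as.numeric(odds_ratio(two_by_two(35, 23, 25, 67))),
               4.08, tolerance = 0.005)
  expect_equal(as.numeric(odds_ratio(two_by_two(10, 10, 10, 10))), 1)
  set.seed(31)
  for (rep in 1:20) {
    cells <- sample(1:200, 4)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(as.numeric(odds_ratio(t1)) * as.numeric(odds_ratio(t2)), 1)
  }
})

test_that("zero cells trigger the reported Haldane-Anscombe adjustment", {
  t <- two_by_two(0, 20, 10, 30)
  or <- odds_ratio(t)
  expect_true(attr(or, "adjusted"))
  expect_equal(as.numeric(or), (0.5 * 30.5) / (20.5 * 10.5))
  expect_false(attr(odds_ratio(two_by_two(1, 20, 10, 30)), "adjusted"))
})

test_that("Yates chi-squared matches hand values and is transpose-invariant", {
  expect_equal(yates_chi2(two_by_two(35, 23, 162, 204)), 4.58,
               tolerance = 0.002)
  expect_equal(yates_chi2(two_by_two(35, 23, 25, 67)), 15, tolerance = 0.005)
  expect_equal(yates_chi2(two_by_two(10, 10, 10, 10)), 0)
  # correction floored at zero, not negative
  expect_equal(yates_chi2(two_by_two(11, 10, 10, 10)), 0)
  set.seed(32)
  for (rep in 1:20) {
    cells <- sample(1:100, 4)
    t1 <- yates_chi2(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    tt <- yates_chi2(two_by_two(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(t1, tt)
    # cross-check against R's own continuity-corrected test
    m <- matrix(cells, 2, byrow = TRUE)
    suppressWarnings(ref <- stats::chisq.test(m, correct = TRUE))
    expect_equal(t1, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("chi-squared p-values are the 1-df upper tail and strictly decreasing", {
  expect_equal(chi2_p(0), 1)
  expect_equal(chi2_p(3.841), 0.050, tolerance = 5e-4)
  expect_equal(round(chi2_p(yates_chi2(two_by_two(35, 23, 162, 204))), 3),
               0.032)
  x <- seq(0, 30, by = 0.5)
  expect_true(all(diff(chi2_p(x)) < 0))
})

test_that("Cornfield intervals reproduce reference bounds and bracket the OR", {
  ci1 <- cornfield_ci(two_by_two(35, 23, 162, 204))
  expect_equal(unname(ci1), c(1.05, 3.5), tolerance = 0.02)
  ci2 <- cornfield_ci(two_by_two(35, 23, 25, 67))
  expect_equal(unname(ci2), c(1.92, 8.74), tolerance = 0.02)
  set.seed(33)
  for (rep in 1:15) {
    cells <- sample(1:80, 4)
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    ci <- cornfield_ci(t)
    or <- as.numeric(odds_ratio(t))
    expect_lt(ci[1], or); expect_gt(ci[2], or)
  }
})

test_that("Cornfield intervals narrow when all cells scale up", {
  t1 <- two_by_two(12, 18, 20, 25)
  for (k in c(2L, 5L)) {
    tk <- two_by_two(12 * k, 18 * k, 20 * k, 25 * k)
    r1 <- cornfield_ci(t1); rk <- cornfield_ci(tk)
    expect_lt(rk[2] / rk[1], r1[2] / r1[1])
  }
})

test_that("chromosome-level haplotype tables do honest 2n bookkeeping", {
  ec <- example_cohort()
  t <- haplotype_table(ec, risk)
  expect_equal(unlist(t[c("a", "b", "c", "d")], use.names = FALSE),
               c(35, 23, 162, 204))
  expect_equal(t$a + t$b, 2 * sum(ec$status == "case"))
  tu <- haplotype_table(ec, risk, controls = unrelated)
  expect_equal(unlist(tu[c("a", "b", "c", "d")], use.names = FALSE),
               c(35, 23, 25, 67))
  # absent target: zero exposed on both sides
  t0 <- haplotype_table(ec, "nope-nope-nope")
  expect_equal(c(t0$a, t0$c), c(0, 0))
  # degenerate group selection errors
  expect_error(
    haplotype_table(ec, risk,
                    controls = cohort_filter(status = "control", age_over = 99)),
    "degenerate")
})

test_that("genotype-dose analysis reproduces the cross-product identities", {
  dc <- example_dose_cohort()
  d <- dose_association(dc, risk, controls = unrelated)
  expect_equal(d$n_case, c(4, 15, 10))
  expect_equal(d$n_control, c(24, 18, 4))
  expect_equal(d$or, c(1, 5, 15))
  expect_equal(d$or[2], (15 * 24) / (4 * 18))
  expect_true(all(d$ci_low[2:3] < d$or[2:3] & d$or[2:3] < d$ci_high[2:3]))
  # class partition covers each group exactly
  expect_equal(sum(d$n_case), 29); expect_equal(sum(d$n_control), 46)
  # no carrier anywhere: het/hom ORs undefined but baseline intact
  none <- dc
  d0 <- dose_association(none, "nope-nope-nope", controls = unrelated)
  expect_true(all(is.na(d0$or[2:3])))
  expect_equal(d0$or[1], 1)
})

test_that("per-locus allelic tests count chromosomes and partition to 100 percent", {
  ec <- example_cohort()
  aa <- allelic_association(ec, "DQA1", controls = unrelated)
  row <- aa[aa$exposure == "DQA1*00101", ]
  expect_equal(c(row$a, row$c), c(5, 11))   # pooled across the two carrier haplotypes
  expect_equal(sum(aa$freq_case_pct), 100, tolerance = 1e-9)
  expect_equal(sum(aa$freq_control_pct), 100, tolerance = 1e-9)
  # single-allele locus: degenerate, reported not thrown
  mono <- ec
  mono$dqb1_1 <- "only"; mono$dqb1_2 <- "only"
  m <- allelic_association(mono, "DQB1")
  expect_equal(nrow(m), 1)
  expect_true(is.na(m$or))
})

test_that("the relatedness gradient is reported with its monotonicity flag", {
  ec <- example_cohort()
  g <- gradient_profile(ec, risk)
  expect_equal(g$freq_pct, c(60.3, 51.6, 46.6, 27.2), tolerance = 0.002)
  expect_equal(g$hom_pct[1], 34.5, tolerance = 0.002)
  expect_true(attr(g, "monotone_decreasing"))
  # single-stratum cohort: one row, trivially monotone
  solo <- ec[ec$status == "case", ]
  class(solo) <- class(ec)
  w <- capture_warnings(g1 <- gradient_profile(solo, risk))
  expect_length(w, 3)   # one per absent control stratum
  expect_match(w, "omitted", all = TRUE)
  expect_equal(nrow(g1), 1)
  expect_true(attr(g1, "monotone_decreasing"))
})

test_that("under a null simulation the decreasing gradient is rare", {
  set.seed(34)
  cfg <- sim_config(or_het = 1, or_hom = 1, f0 = 0.3, n_cases = 25L,
                    n_first = 25L, n_second = 25L, n_unrelated = 25L,
                    max_families = 20000L)
  hits <- vapply(1:60, function(i) {
    sim <- simulate_cohort(cfg)
    g <- gradient_profile(sim$cohort, cfg$risk)
    isTRUE(attr(g, "monotone_decreasing")) && nrow(g) == 4
  }, logical(1))
  # with four exchangeable strata a strict ordering has probability 1/24;
  # ties push it up a little, but it stays well below one in five
  expect_lt(mean(hits), 0.2)
})

test_that("declarative filters reproduce the subgroup counts and compose", {
  ec <- example_cohort()
  expect_equal(nrow(filter_cohort(ec, cohort_filter(
    status = "case", grades = c("definite", "probable")))), 17)
  expect_equal(nrow(filter_cohort(ec, cohort_filter(
    status = "case", grades = "possible"))), 12)
  expect_equal(nrow(filter_cohort(ec, cohort_filter(
    status = "control", relatedness = "unrelated", age_over = 8))), 17)
  # strictness: a dog aged exactly 8 is not "over 8"
  at8 <- ec[1, ]; at8$age_years <- 8
  expect_equal(nrow(filter_cohort(at8, cohort_filter(age_over = 8))), 0)
  # referencing a missing field is a validation error
  broken <- ec[, setdiff(names(ec), "age_years")]
  expect_error(filter_cohort(broken, cohort_filter(age_over = 8)), "missing")
  expect_error(cohort_filter(status = "dog"))
})

test_that("ambiguous dogs are excluded by default but can be weighted in", {
  co <- cohort_from_pairs(list(
    c("a-x-q", "a-x-q"), c("b-y-q", "b-y-q"),
    c("a-y-q", "a-y-q"), c("b-x-q", "b-x-q"),
    c("a-x-q", "b-y-q")), status = "control")
  co$status[1:2] <- "case"
  co$relatedness_grade[1:2] <- "case"
  co$diagnostic_grade[1:2] <- "definite"
  co <- as_cohort(as.data.frame(co))
  ph <- phase_cohort(co)
  pc <- phased_cohort(co, ph)
  t_excl <- haplotype_table(pc, "a-x-q")
  expect_equal(t_excl$c + t_excl$d, 4)   # ambiguous dog d005 left out
  t_incl <- haplotype_table(pc, "a-x-q", ambiguous = ph$ambiguous)
  expect_equal(t_incl$c + t_incl$d, 6)
  expect_equal(t_incl$c, 0.5)            # half-weight from the ambiguous dog
})
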