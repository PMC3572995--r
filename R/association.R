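# Case-control contingency statistics.
#
# Two counting units are explicit and never mixed:
#   * chromosome-level (2n): haplotype and allele frequencies and their
#     odds ratios -- every phased dog contributes exactly two chromosomes;
#   * dog-level: carrier / genotype-dose analyses (0, 1 or 2 copies of a
#     target haplotype).
# Statistics are the classical epidemiological set: cross-product odds
# ratio, Cornfield (chi-square inversion) 95% confidence interval, and the
# Yates continuity-corrected chi-squared test with its upper-tail p-value.

#' Construct a 2x2 case-control table
#'
#' @param a Exposed cases. @param b Unexposed cases.
#' @param c Exposed controls. @param d Unexposed controls.
#' @param unit Counting unit, `"chromosome"` or `"dog"`.
#' @return An object of class `dla_2x2`.
#' @export
two_by_two <- function(a, b, c, d, unit = c("chromosome", "dog")) {
  unit <- match.arg(unit)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("2x2 cells must be finite and nonnegative")
  }
  if (a + b <= 0 || c + d <= 0) {
    stop("degenerate 2x2 table: empty case or control margin")
  }
  structure(list(a = a, b = b, c = c, d = d, unit = unit), class = "dla_2x2")
}

#' @export
print.dla_2x2 <- function(x, ...) {
  cat(sprintf("2x2 (%s unit)\n          exposed unexposed\n cases    %7g %9g\n controls %7g %9g\n",
              x$unit, x$a, x$b, x$c, x$d))
  invisible(x)
}

# Haldane-Anscombe adjusted cells (+0.5 everywhere) iff any cell is zero;
# the raw table is kept and the adjustment is reported downstream.
haldane_cells <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) list(cells = cells + 0.5, adjusted = TRUE)
  else list(cells = cells, adjusted = FALSE)
}

#' Cross-product odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied first (reported via
#' `attr(, "adjusted")`).
#'
#' @param t A `dla_2x2`.
#' @return Positive numeric with attribute `adjusted`.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "dla_2x2"))
  h <- haldane_cells(t)
  or <- (h$cells[1] * h$cells[4]) / (h$cells[2] * h$cells[3])
  structure(or, adjusted = h$adjusted)
}

#' Yates continuity-corrected chi-squared statistic
#'
#' `n * (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))` on the raw counts,
#' with the correction floored: the statistic is 0 when `|ad - bc| <= n/2`.
#'
#' @param t A `dla_2x2`.
#' @return Nonnegative numeric (1 degree of freedom).
#' @export
yates_chi2 <- function(t) {
  stopifnot(inherits(t, "dla_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate 2x2 table: zero margin")
  corr <- max(abs(a * d - b * c) - n / 2, 0)
  n * corr^2 / prod(margins)
}

#' Upper-tail p-value of a 1-df chi-squared statistic
#'
#' @param chi2 Nonnegative statistic.
#' @return `P(X >= chi2)` for X ~ chi-squared(1).
#' @export
chi2_p <- function(chi2) {
  stopifnot(all(chi2 >= 0))
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# fitted exposed-case cell under odds ratio psi with the table's margins
# (the root of the Cornfield quadratic inside the admissible interval)
.cornfield_fitted_a <- function(psi, m1, m0, n1) {
  lo <- max(0, n1 - m0); hi <- min(m1, n1)
  A <- 1 - psi
  B <- (m0 - n1) + psi * (m1 + n1)
  C <- -psi * m1 * n1
  if (abs(A) < 1e-12) {
    x <- -C / B
  } else {
    disc <- sqrt(max(B^2 - 4 * A * C, 0))
    roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
    inside <- roots > lo & roots < hi
    x <- roots[inside][1]
    if (is.na(x)) x <- min(max(roots[which.min(abs(roots - (lo + hi) / 2))], lo), hi)
  }
  x
}

#' Cornfield confidence interval for the odds ratio
#'
#' Inverts the continuity-corrected Cornfield chi-square statistic: for a
#' candidate odds ratio psi the exposed-case cell is fitted to the table's
#' margins under psi, and the bounds are the two psi values at which
#' `(|a - fitted| - 0.5)^2 / V(fitted)` equals the level's critical value,
#' located by bisection on the log-odds-ratio scale. Zero cells receive
#' the Haldane-Anscombe adjustment first. The interval always contains
#' the point odds ratio.
#'
#' @param t A `dla_2x2`.
#' @param level Confidence level (default 0.95).
#' @param tol Bisection tolerance on log(psi) (default 1e-6).
#' @param max_iter Maximum bisection iterations per bound (default 200).
#' @return `c(low, high)`.
#' @export
cornfield_ci <- function(t, level = 0.95, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(t, "dla_2x2"), level > 0, level < 1)
  h <- haldane_cells(t)
  a <- h$cells[1]; b <- h$cells[2]; c <- h$cells[3]; d <- h$cells[4]
  m1 <- a + b; m0 <- c + d; n1 <- a + c
  if (n1 == 0 || b + d == 0) stop("degenerate 2x2 table: zero exposure margin")
  crit <- qchisq(level, df = 1)
  or_hat <- (a * d) / (b * c)

  stat <- function(psi, side) {
    x <- .cornfield_fitted_a(psi, m1, m0, n1)
    v <- 1 / (1 / x + 1 / (m1 - x) + 1 / (n1 - x) + 1 / (m0 - n1 + x))
    delta <- if (side == "low") a - x - 0.5 else x - a - 0.5
    if (delta <= 0) return(0)
    delta^2 / v
  }

  solve_bound <- function(side) {
    # bracket on log scale, then bisect
    l_hat <- log(or_hat)
    step <- 1
    l_far <- l_hat
    found <- FALSE
    for (k in seq_len(80L)) {
      l_far <- l_hat + if (side == "low") -step else step
      if (stat(exp(l_far), side) > crit) { found <- TRUE; break }
      step <- step * 2
    }
    if (!found) {
      # the continuity-corrected statistic never reaches the critical value
      # on this side: the bound is unbounded (possible after the
      # Haldane-Anscombe adjustment of an extreme table)
      return(if (side == "low") 0 else Inf)
    }
    lo <- min(l_hat, l_far); hi <- max(l_hat, l_far)
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      exceeds <- stat(exp(mid), side) > crit
      # statistic grows away from or_hat in both directions
      if (side == "low") { if (exceeds) lo <- mid else hi <- mid }
      else               { if (exceeds) hi <- mid else lo <- mid }
      if (hi - lo < tol) return(exp((lo + hi) / 2))
    }
    stop("Cornfield bisection (", side, ") did not converge in ", max_iter,
         " iterations; bracket [", signif(exp(lo), 6), ", ",
         signif(exp(hi), 6), "]")
  }

  c(low = solve_bound("low"), high = solve_bound("high"))
}

#' Full association statistics for a 2x2 table
#'
#' @param t A `dla_2x2`.
#' @param exposure,comparison Labels carried into reports.
#' @param level Confidence level for the Cornfield interval.
#' @return One-row data frame: labels, unit, raw cells, `or`, `ci_low`,
#'   `ci_high`, `chi2_yates`, `p_value`, `haldane_adjusted`.
#' @export
assoc_stats <- function(t, exposure = "", comparison = "", level = 0.95) {
  or <- odds_ratio(t)
  ci <- cornfield_ci(t, level = level)
  chi2 <- yates_chi2(t)
  data.frame(
    exposure = exposure, comparison = comparison, unit = t$unit,
    a = t$a, b = t$b, c = t$c, d = t$d,
    or = as.numeric(or), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    chi2_yates = chi2, p_value = chi2_p(chi2),
    haldane_adjusted = attr(or, "adjusted"),
    stringsAsFactors = FALSE
  )
}

# ---- cohort filters --------------------------------------------------------

#' Declarative subject filter
#'
#' Conditions compose with AND; `NULL` fields are inactive. `age_over` is
#' a strict `>` comparison (a dog aged exactly the threshold is excluded),
#' and subjects with missing age never pass an age filter.
#'
#' @param status Optional subset of `"case"`, `"control"`.
#' @param grades Optional subset of diagnostic grades.
#' @param relatedness Optional subset of relatedness grades.
#' @param age_over Optional strict lower age bound in years.
#' @return An object of class `dla_filter`.
#' @export
cohort_filter <- function(status = NULL, grades = NULL, relatedness = NULL,
                          age_over = NULL) {
  if (!is.null(status)) stopifnot(all(status %in% STATUS_LEVELS))
  if (!is.null(grades)) stopifnot(all(grades %in% GRADE_LEVELS))
  if (!is.null(relatedness)) stopifnot(all(relatedness %in% RELATEDNESS_LEVELS))
  if (!is.null(age_over)) stopifnot(is.numeric(age_over), length(age_over) == 1L)
  structure(list(status = status, grades = grades, relatedness = relatedness,
                 age_over = age_over), class = "dla_filter")
}

#' Apply a subject filter to a cohort
#'
#' @param cohort A cohort (or phased cohort) data frame.
#' @param filter A `dla_filter`.
#' @return The subset of rows passing every active condition.
#' @export
filter_cohort <- function(cohort, filter) {
  stopifnot(inherits(filter, "dla_filter"))
  fields <- c(status = "status", grades = "diagnostic_grade",
              relatedness = "relatedness_grade", age_over = "age_years")
  keep <- rep(TRUE, nrow(cohort))
  for (f in names(fields)) {
    if (is.null(filter[[f]])) next
    col <- fields[[f]]
    if (!col %in% names(cohort)) {
      stop("filter references missing cohort field '", col, "'")
    }
    keep <- keep & if (f == "age_over") {
      !is.na(cohort[[col]]) & cohort[[col]] > filter[[f]]
    } else {
      cohort[[col]] %in% filter[[f]]
    }
  }
  cohort[keep, , drop = FALSE]
}

# phased rows of a phased cohort passing a filter
.phased_group <- function(phased, filter) {
  stopifnot("phase_status" %in% names(phased),
            all(c("hap1", "hap2") %in% names(phased)))
  g <- filter_cohort(phased, filter)
  g[g$phase_status == "phased", , drop = FALSE]
}

# per-dog copy number of a target haplotype
.copies <- function(group, target) {
  (group$hap1 == target) + (group$hap2 == target)
}

# ---- haplotype-level analyses ----------------------------------------------

#' Chromosome-level 2x2 table for a target haplotype
#'
#' Each phased dog contributes two chromosomes; `a` counts case
#' chromosomes carrying the target (so `a + b = 2 *` phased cases).
#' Ambiguously phased dogs are excluded by default; passing the phasing
#' result's `ambiguous` list via `ambiguous` adds each dog's candidate
#' pairs with equal weight `1/k` (a sensitivity analysis -- cells then
#' need not be integers).
#'
#' @param phased A `dla_phased_cohort` from [phased_cohort()].
#' @param target Haplotype id, e.g. `"02001-00401-01303"`.
#' @param cases,controls `dla_filter`s selecting the two groups.
#' @param ambiguous Optional named list of candidate-pair tables.
#' @return A `dla_2x2` with `unit = "chromosome"`.
#' @export
haplotype_table <- function(phased, target,
                            cases = cohort_filter(status = "case"),
                            controls = cohort_filter(status = "control"),
                            ambiguous = NULL) {
  count_group <- function(filter) {
    g <- .phased_group(phased, filter)
    exposed <- sum(.copies(g, target))
    total <- 2 * nrow(g)
    if (!is.null(ambiguous)) {
      amb <- filter_cohort(phased, filter)
      amb <- amb[amb$phase_status == "ambiguous", , drop = FALSE]
      for (id in amb$id) {
        cand <- ambiguous[[id]]
        if (is.null(cand)) next
        w <- 1 / nrow(cand)
        exposed <- exposed +
          w * sum((cand$hap1 == target) + (cand$hap2 == target))
        total <- total + 2
      }
    }
    c(exposed = exposed, total = total)
  }
  ca <- count_group(cases); co <- count_group(controls)
  if (ca["total"] == 0 || co["total"] == 0) {
    stop("degenerate table: a selected group contains no phased dogs")
  }
  two_by_two(ca[["exposed"]], ca[["total"]] - ca[["exposed"]],
             co[["exposed"]], co[["total"]] - co[["exposed"]],
             unit = "chromosome")
}

#' Chromosome-level association of a target haplotype
#'
#' @inheritParams haplotype_table
#' @param level Confidence level.
#' @param comparison Label for the control group used.
#' @return One-row data frame of [assoc_stats()].
#' @export
haplotype_association <- function(phased, target,
                                  cases = cohort_filter(status = "case"),
                                  controls = cohort_filter(status = "control"),
                                  level = 0.95, comparison = "controls",
                                  ambiguous = NULL) {
  t <- haplotype_table(phased, target, cases, controls, ambiguous = ambiguous)
  assoc_stats(t, exposure = target, comparison = comparison, level = level)
}

#' Genotype-dose analysis of a target haplotype
#'
#' Dog-level classification by 0, 1 or 2 copies of the target, with odds
#' ratios for heterozygous and homozygous carriage relative to the
#' homozygous-negative baseline (baseline OR fixed at 1).
#'
#' @inheritParams haplotype_table
#' @param level Confidence level for the Cornfield intervals.
#' @return Data frame with one row per genotype class (`hom_negative`,
#'   `heterozygous`, `homozygous`): case and control counts and
#'   percentages, `or`, `ci_low`, `ci_high`.
#' @export
dose_association <- function(phased, target,
                             cases = cohort_filter(status = "case"),
                            controls = cohort_filter(status = "control"),
                             level = 0.95) {
  ca <- .phased_group(phased, cases)
  co <- .phased_group(phased, controls)
  if (nrow(ca) == 0 || nrow(co) == 0) {
    stop("degenerate table: a selected group contains no phased dogs")
  }
  n_case <- tabulate(.copies(ca, target) + 1L, nbins = 3L)
  n_ctrl <- tabulate(.copies(co, target) + 1L, nbins = 3L)
  if (n_case[1] + n_ctrl[1] == 0) {
    stop("degenerate baseline: no homozygous-negative dogs in either group")
  }
  out <- data.frame(
    genotype = c("hom_negative", "heterozygous", "homozygous"),
    copies = 0:2,
    n_case = n_case, pct_case = 100 * n_case / nrow(ca),
    n_control = n_ctrl, pct_control = 100 * n_ctrl / nrow(co),
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    stringsAsFactors = FALSE
  )
  out$or[1] <- 1
  for (k in 2:3) {
    if (n_case[k] + n_ctrl[k] == 0) next  # class absent: OR undefined
    t <- try(two_by_two(n_case[k], n_case[1], n_ctrl[k], n_ctrl[1],
                        unit = "dog"), silent = TRUE)
    if (inherits(t, "try-error")) next
    or <- odds_ratio(t)
    ci <- cornfield_ci(t, level = level)
    out$or[k] <- as.numeric(or)
    out$ci_low[k] <- ci[[1]]; out$ci_high[k] <- ci[[2]]
  }
  attr(out, "target") <- target
  out
}

#' Per-allele association at one locus
#'
#' Chromosome-level tests of every allele observed at the locus, from
#' unphased genotypes (phasing is not required: each typed dog contributes
#' its two allele copies). Alleles whose table is degenerate (e.g. a
#' single-allele locus) are reported with `NA` statistics rather than an
#' error.
#'
#' @param cohort A cohort data frame with genotype columns.
#' @param locus One of `"DRB1"`, `"DQA1"`, `"DQB1"`.
#' @param cases,controls `dla_filter`s.
#' @param level Confidence level.
#' @return Data frame with one row per allele: counts and [assoc_stats()]
#'   columns (`NA` where degenerate).
#' @export
allelic_association <- function(cohort, locus,
                                cases = cohort_filter(status = "case"),
                                controls = cohort_filter(status = "control"), level = 0.95) {
  assert_locus(locus)
  cols <- locus_cols(locus)
  typed <- cohort[!is.na(cohort[[cols[1]]]), , drop = FALSE]
  ca <- filter_cohort(typed, cases)
  co <- filter_cohort(typed, controls)
  alleles <- sort(unique(c(typed[[cols[1]]], typed[[cols[2]]])))
  copies_of <- function(group, allele) {
    sum(group[[cols[1]]] == allele) + sum(group[[cols[2]]] == allele)
  }
  rows <- lapply(alleles, function(al) {
    a <- copies_of(ca, al); b <- 2 * nrow(ca) - a
    c_ <- copies_of(co, al); d <- 2 * nrow(co) - c_
    res <- try(assoc_stats(two_by_two(a, b, c_, d, unit = "chromosome"),
                           exposure = paste0(locus, "*", al),
                           comparison = "controls", level = level),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- data.frame(exposure = paste0(locus, "*", al),
                        comparison = "controls", unit = "chromosome",
                        a = a, b = b, c = c_, d = d,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        chi2_yates = NA_real_, p_value = NA_real_,
                        haldane_adjusted = NA, stringsAsFactors = FALSE)
    }
    res
  })
  out <- do.call(rbind, rows)
  out$freq_case_pct <- 100 * out$a / (out$a + out$b)
  out$freq_control_pct <- 100 * out$c / (out$c + out$d)
  rownames(out) <- NULL
  out
}

#' Relatedness-graded frequency profile of a target haplotype
#'
#' Chromosome frequency and homozygote-dog frequency of the target in the
#' four strata, ordered cases, first-degree relatives, second-degree
#' relatives, unrelated controls, with a flag reporting whether the
#' chromosome frequency is non-increasing along that order (the gradient
#' expected under familial enrichment of a low-penetrance risk
#' haplotype).
#'
#' @param phased A `dla_phased_cohort`.
#' @param target Haplotype id.
#' @return Data frame (one row per present stratum): `stratum`, `n_dogs`,
#'   `two_n`, `n_carrier_chromosomes`, `freq_pct`, `n_homozygous`,
#'   `hom_pct`; attribute `"monotone_decreasing"`.
#' @export
gradient_profile <- function(phased, target) {
  strata <- list(
    cases = cohort_filter(status = "case"),
    first_degree = cohort_filter(relatedness = "first_degree"),
    second_degree = cohort_filter(relatedness = "second_degree"),
    unrelated = cohort_filter(relatedness = "unrelated")
  )
  rows <- list()
  for (s in names(strata)) {
    g <- .phased_group(phased, strata[[s]])
    if (nrow(g) == 0) {
      warning("stratum '", s, "' has no phased dogs; omitted from profile")
      next
    }
    copies <- .copies(g, target)
    rows[[s]] <- data.frame(
      stratum = s, n_dogs = nrow(g), two_n = 2L * nrow(g),
      n_carrier_chromosomes = sum(copies),
      freq_pct = 100 * sum(copies) / (2 * nrow(g)),
      n_homozygous = sum(copies == 2L),
      hom_pct = 100 * sum(copies == 2L) / nrow(g),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "monotone_decreasing") <- !is.unsorted(rev(out$freq_pct))
  out
}
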