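# Synthetic breed-cohort generator.
#
# Emulates the statistical structure a graded-control association study
# assumes: founders drawn under within-breed Hardy-Weinberg from an
# 11-haplotype pool, a logistic-odds dose model on risk-haplotype copy
# number (odds multiplied by or_het for one copy, or_hom for two), and
# proband-based ascertainment that fills the four strata -- cases,
# unaffected first-degree relatives, unaffected second-degree relatives
# (half-siblings from a re-mating), and unrelated unaffected founders.
# No recombination is modelled within the class II block and no
# genotyping error is injected; all randomness flows through R's RNG so a
# single set.seed() makes runs byte-identical.

#' Simulation configuration
#'
#' @param haplotypes Data frame with columns `haplotype`, `freq`
#'   (frequencies summing to 1); default the breed pool of
#'   [vizsla_haplotypes()].
#' @param risk Risk haplotype id present in `haplotypes`.
#' @param f0 Baseline penetrance: probability that a dog with 0 risk
#'   copies is affected. Default 0.01, giving a population prevalence of
#'   a few percent under the default pool.
#' @param or_het,or_hom Disease odds ratios for 1 and 2 copies relative to
#'   0 copies (defaults 5 and 15).
#' @param n_cases,n_first,n_second,n_unrelated Group sizes (defaults
#'   29 / 93 / 44 / 46).
#' @param grade_props Proportions of definite/probable/possible diagnoses
#'   among cases (default 13:4:12).
#' @param litter_size Offspring per simulated mating (default 6).
#' @param onset_meanlog,onset_sdlog Log-normal age-of-onset parameters for
#'   cases (median about 2.9 years), truncated to `onset_range`.
#' @param onset_range Truncation window for onset ages (years).
#' @param control_age_range Uniform age window for unaffected dogs
#'   (years).
#' @param max_families Ascertainment budget: maximum families simulated
#'   before an infeasibility error (suggesting a larger `f0`).
#' @param seed Optional RNG seed applied at the start of a simulation.
#' @return An object of class `dla_sim_config`.
#' @export
sim_config <- function(haplotypes = vizsla_haplotypes()[, c("haplotype", "freq")],
                       risk = risk_haplotype(),
                       f0 = 0.01, or_het = 5, or_hom = 15,
                       n_cases = 29L, n_first = 93L, n_second = 44L,
                       n_unrelated = 46L,
                       grade_props = c(definite = 13, probable = 4,
                                       possible = 12) / 29,
                       litter_size = 6L,
                       onset_meanlog = log(2.9), onset_sdlog = 0.5,
                       onset_range = c(0.5, 8),
                       control_age_range = c(0.58, 13.83),
                       max_families = 5000L, seed = NULL) {
  stopifnot(is.data.frame(haplotypes),
            all(c("haplotype", "freq") %in% names(haplotypes)),
            abs(sum(haplotypes$freq) - 1) <= 1e-9,
            all(haplotypes$freq >= 0),
            risk %in% haplotypes$haplotype,
            f0 > 0, f0 < 1, or_het >= 1, or_hom >= 1,
            n_cases >= 0, n_first >= 0, n_second >= 0, n_unrelated >= 0,
            litter_size >= 1)
  grade_props <- grade_props / sum(grade_props)
  structure(list(haplotypes = haplotypes, risk = risk, f0 = f0,
                 or_het = or_het, or_hom = or_hom,
                 n_cases = as.integer(n_cases), n_first = as.integer(n_first),
                 n_second = as.integer(n_second),
                 n_unrelated = as.integer(n_unrelated),
                 grade_props = grade_props, litter_size = as.integer(litter_size),
                 onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
                 onset_range = onset_range,
                 control_age_range = control_age_range,
                 max_families = as.integer(max_families), seed = seed),
            class = "dla_sim_config")
}

#' Draw founder haplotype pairs
#'
#' Two independent draws per founder from the pool frequencies (random
#' union of gametes within the breed; no inbreeding coefficient).
#'
#' @param n Number of founders.
#' @param config A `dla_sim_config`.
#' @return Data frame `hap1`, `hap2` (canonically ordered within rows).
#' @export
draw_founders <- function(n, config) {
  stopifnot(inherits(config, "dla_sim_config"))
  h <- config$haplotypes
  a <- sample(h$haplotype, n, replace = TRUE, prob = h$freq)
  b <- sample(h$haplotype, n, replace = TRUE, prob = h$freq)
  data.frame(hap1 = pmin(a, b), hap2 = pmax(a, b), stringsAsFactors = FALSE)
}

#' Penetrance under the dose model
#'
#' Disease odds are `f0/(1-f0)` multiplied by `or_het` for one risk copy
#' and `or_hom` for two; the probability is `odds/(1+odds)`.
#'
#' @param copies Integer vector of risk copy numbers (0, 1 or 2).
#' @param config A `dla_sim_config`.
#' @return Numeric vector of affection probabilities.
#' @export
affection_probability <- function(copies, config) {
  stopifnot(inherits(config, "dla_sim_config"), all(copies %in% 0:2))
  odds0 <- config$f0 / (1 - config$f0)
  mult <- c(1, config$or_het, config$or_hom)[copies + 1L]
  odds <- odds0 * mult
  odds / (1 + odds)
}

.risk_copies <- function(pairs, config) {
  (pairs$hap1 == config$risk) + (pairs$hap2 == config$risk)
}

.draw_onset <- function(n, config) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- exp(rnorm(2L * (n - length(out)) + 10L,
                   config$onset_meanlog, config$onset_sdlog))
    out <- c(out, x[x >= config$onset_range[1] & x <= config$onset_range[2]])
  }
  round(out[seq_len(n)], 2)
}

.assemble_subjects <- function(pairs, status, relatedness, config, prefix) {
  n <- if (is.null(pairs)) 0L else nrow(pairs)
  if (n == 0L) {
    df <- data.frame(id = character(), sex = character(), status = character(),
                     diagnostic_grade = character(),
                     relatedness_grade = character(), age_years = numeric(),
                     hap1 = character(), hap2 = character(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  grade <- if (status == "case") {
    sample(names(config$grade_props), n, replace = TRUE,
           prob = config$grade_props)
  } else "not_applicable"
  age <- if (status == "case") .draw_onset(n, config) else {
    round(runif(n, config$control_age_range[1], config$control_age_range[2]), 2)
  }
  data.frame(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    status = status, diagnostic_grade = grade,
    relatedness_grade = if (status == "case") "case" else relatedness,
    age_years = age, hap1 = pairs$hap1, hap2 = pairs$hap2,
    stringsAsFactors = FALSE
  )
}

#' Fast case-control simulation (no pedigree)
#'
#' Draws independent founders, applies the dose penetrance model, and
#' collects affected dogs as cases and unaffected dogs as unrelated
#' controls until both quotas are met. This is the sampling scheme for
#' parameter-recovery experiments, where family structure is irrelevant.
#'
#' @param n_cases,n_controls Target group sizes.
#' @param config A `dla_sim_config`.
#' @return A `dla_phased_cohort` with truth columns `copies`.
#' @export
simulate_case_control <- function(n_cases, n_controls, config) {
  stopifnot(inherits(config, "dla_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cases <- controls <- NULL
  guard <- 0L
  while ((is.null(cases) || nrow(cases) < n_cases) ||
         (is.null(controls) || nrow(controls) < n_controls)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("ascertainment error: case quota unreachable; ",
                             "consider a larger f0")
    pairs <- draw_founders(max(1000L, n_cases), config)
    p <- affection_probability(.risk_copies(pairs, config), config)
    aff <- runif(nrow(pairs)) < p
    cases <- rbind(cases, pairs[aff, , drop = FALSE])
    controls <- rbind(controls, pairs[!aff, , drop = FALSE])
  }
  cases <- cases[seq_len(n_cases), , drop = FALSE]
  controls <- controls[seq_len(n_controls), , drop = FALSE]
  out <- rbind(
    .assemble_subjects(cases, "case", "case", config, "sim_case"),
    .assemble_subjects(controls, "control", "unrelated", config, "sim_ctrl")
  )
  out$copies <- (out$hap1 == config$risk) + (out$hap2 == config$risk)
  out$phase_status <- rep("phased", nrow(out))
  class(out) <- c("dla_phased_cohort", "data.frame")
  out
}

# one gamete per parent, no recombination within the block
.mate <- function(sire, dam, n_off) {
  from_sire <- ifelse(runif(n_off) < 0.5, sire$hap1, sire$hap2)
  from_dam <- ifelse(runif(n_off) < 0.5, dam$hap1, dam$hap2)
  data.frame(hap1 = pmin(from_sire, from_dam),
             hap2 = pmax(from_sire, from_dam), stringsAsFactors = FALSE)
}

#' Pedigree-based cohort simulation with ascertainment
#'
#' Simulates nuclear families (two founders, a litter, and a half-sib
#' litter from re-mating the sire) under the dose penetrance model.
#' Affected offspring become cases (probands) until the case quota is
#' reached; unaffected full siblings and parents of a case family fill
#' the first-degree group; unaffected half-siblings fill the
#' second-degree group; unrelated controls are independent founders
#' conditioned on being unaffected. Ages, sexes and diagnostic grades are
#' assigned from the config distributions.
#'
#' @param config A `dla_sim_config`.
#' @return List with `cohort` (a `dla_phased_cohort` incl. genotype
#'   columns) and `truth` (per-dog record: family, role, parent ids, true
#'   haplotype pair, risk copy number, affection status).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "dla_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cases <- first <- second <- NULL
  truth <- list()
  fam <- 0L
  note_truth <- function(pairs, family, role, sire_id, dam_id, affected) {
    if (nrow(pairs) == 0L) return()
    truth[[length(truth) + 1L]] <<- data.frame(
      family = family, role = role, sire = sire_id, dam = dam_id,
      hap1 = pairs$hap1, hap2 = pairs$hap2, affected = affected,
      stringsAsFactors = FALSE)
  }
  affect <- function(pairs) {
    runif(nrow(pairs)) < affection_probability(.risk_copies(pairs, config),
                                               config)
  }
  need <- function() {
    (is.null(cases) || nrow(cases) < config$n_cases) ||
      (is.null(first) || nrow(first) < config$n_first) ||
      (is.null(second) || nrow(second) < config$n_second)
  }
  while (need() && config$n_cases > 0L) {
    fam <- fam + 1L
    if (fam > config$max_families) {
      stop("ascertainment error: quotas unreachable within ",
           config$max_families, " families; consider a larger f0")
    }
    sire <- draw_founders(1L, config)
    dam <- draw_founders(1L, config)
    litter <- .mate(sire, dam, config$litter_size)
    aff_off <- affect(litter)
    if (!any(aff_off)) next  # family never ascertained
    parents <- rbind(sire, dam)
    aff_par <- affect(parents)
    cases <- rbind(cases, litter[aff_off, , drop = FALSE])
    first <- rbind(first, litter[!aff_off, , drop = FALSE],
                   parents[!aff_par, , drop = FALSE])
    dam2 <- draw_founders(1L, config)
    half <- .mate(sire, dam2, config$litter_size)
    aff_half <- affect(half)
    second <- rbind(second, half[!aff_half, , drop = FALSE])
    sire_id <- sprintf("f%04d_sire", fam)
    dam_id <- sprintf("f%04d_dam", fam)
    note_truth(parents, fam, "parent", NA, NA, aff_par)
    note_truth(litter, fam, "offspring", sire_id, dam_id, aff_off)
    note_truth(half, fam, "half_sib", sire_id, sprintf("f%04d_dam2", fam),
               aff_half)
  }
  take <- function(x, n) if (is.null(x)) NULL else x[seq_len(min(n, nrow(x))), , drop = FALSE]
  cases <- take(cases, config$n_cases)
  first <- take(first, config$n_first)
  second <- take(second, config$n_second)
  unrel <- NULL
  while (config$n_unrelated > 0L &&
         (is.null(unrel) || nrow(unrel) < config$n_unrelated)) {
    pairs <- draw_founders(max(200L, config$n_unrelated), config)
    unrel <- rbind(unrel, pairs[!affect(pairs), , drop = FALSE])
  }
  unrel <- take(unrel, config$n_unrelated)
  cohort <- rbind(
    .assemble_subjects(cases, "case", "case", config, "sim_case"),
    .assemble_subjects(first, "control", "first_degree", config, "sim_fd"),
    .assemble_subjects(second, "control", "second_degree", config, "sim_sd"),
    .assemble_subjects(unrel, "control", "unrelated", config, "sim_uc")
  )
  cohort <- .genotype_from_haps(cohort)
  cohort$phase_status <- rep("phased", nrow(cohort))
  class(cohort) <- c("dla_phased_cohort", "data.frame")
  truth <- do.call(rbind, c(truth, list(NULL)))
  if (!is.null(truth)) {
    truth$copies <- (truth$hap1 == config$risk) + (truth$hap2 == config$risk)
  }
  list(cohort = cohort, truth = truth, n_families = fam)
}

#' Emit single-direction ambiguous reads for a cohort
#'
#' For every dog and locus, the two allele sequences are superposed into
#' the diploid IUPAC consensus and emitted in the locus's native read
#' orientation (antisense for DRB1 and DQA1, sense for DQB1), so the full
#' typing -> phasing -> association pipeline can run end to end.
#'
#' @param cohort Data frame with genotype columns (e.g. from
#'   [simulate_cohort()]).
#' @param library A `dla_library` containing every allele in the cohort.
#' @return List of `dla_read`.
#' @export
emit_reads <- function(cohort, library) {
  stopifnot(inherits(library, "dla_library"))
  reads <- list()
  for (loc in LOCUS_NAMES) {
    al <- locus_alleles(library, loc)
    seqs <- setNames(al$sequence, al$name)
    cols <- locus_cols(loc)
    for (i in seq_len(nrow(cohort))) {
      a1 <- cohort[[cols[1]]][i]; a2 <- cohort[[cols[2]]][i]
      if (is.na(a1)) next
      if (!(a1 %in% names(seqs)) || !(a2 %in% names(seqs))) {
        stop("consistency error: allele ", loc, "*",
             if (a1 %in% names(seqs)) a2 else a1, " missing from library")
      }
      cons <- superpose(seqs[[a1]], seqs[[a2]])
      ori <- NATIVE_ORIENTATION[[loc]]
      if (ori == "antisense") cons <- reverse_complement_iupac(cons)
      reads[[length(reads) + 1L]] <- ambiguous_read(
        locus = loc, sequence = cons, orientation = ori,
        sample = as.character(cohort$id[i]))
    }
  }
  reads
}
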