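# Bundled synthetic fixtures.
#
# A compact 11-haplotype breed pool over toy 24-bp exon-2 frames, plus a
# fully phased 212-dog example cohort (29 polymyositis cases and 183
# graded controls) whose stratum-level haplotype counts reproduce a
# typical single-breed class II association data set. The toy sequences
# are synthetic: within each locus every unordered allele pair superposes
# to a distinct IUPAC consensus, so sequence-based typing on them is
# exactly invertible.

.TOY_DRB1 <- c(
  "02001" = "AGGAGGCCCCGCGCTCAAGTAAGA",
  "00601" = "TATCGGTGGTCCCGGGCGTGCTTT",
  "00901" = "AATACCCCCCGTTCTATTACAATG",
  "00801" = "GCGCTGTTGTTTATAAAGAAAGTG",
  "02301" = "GTGTCCGCTAGGCACTGTTTGATA",
  "01501" = "ATATACAGTGAGTTGCAACTCCCA",
  "04801" = "GGCGGACTTTCGGGAATGCCTCTG",
  "01101" = "GACTGATCTGTTCACCCACGCAGA"
)
.TOY_DQA1 <- c(
  "00401"  = "GTATTCGGCTGCCTCGTACTACAG",
  "005011" = "GCAACCATGTATCCATAGCGGGAT",
  "00101"  = "GGTTAAGGACGAATTTCCCCGACC",
  "00301"  = "CCCCTCCCAGACAATACAAGCCCT",
  "00601"  = "CCCCGGTTGGGAGGTGTTGAAGTC",
  "00201"  = "CCTCTAAGGGGTAGCGAGTGCGAG",
  "00901"  = "CGGAGGATTGGACCCGCATGCTGC"
)
.TOY_DQB1 <- c(
  "01303"  = "GAATAACTGACTTTTAAGCCTTAC",
  "00701"  = "GTGCATTAGCCCGGTACCTGATAC",
  "008011" = "CCAGGGAAAGATTTGTTCCCGTTC",
  "00401"  = "GCTTCTCTTTAGATGCTCGCCGTA",
  "00501"  = "CACTAGCGTACGGATCCCGGGGTA",
  "02301"  = "TCTTGCTTCTGCTAGTTCGCGGCT",
  "01302"  = "CCTACGTGGGATTCAGTTTGCGTC",
  "02901"  = "GAGGTCCCGCATAAGTCCCTCCGA"
)

#' Toy DLA allele library
#'
#' Synthetic 24-bp exon-2 frames for the 8 DRB1, 7 DQA1 and 8 DQB1
#' alleles appearing in the breed haplotype pool of [vizsla_haplotypes()].
#' Designed so that every unordered allele pair at a locus superposes to a
#' distinct consensus (typing on this library never hits a genuine SBT
#' ambiguity).
#'
#' @return A `dla_library`.
#' @export
toy_allele_library <- function() {
  allele_library(
    data.frame(
      locus = rep(c("DRB1", "DQA1", "DQB1"),
                  c(length(.TOY_DRB1), length(.TOY_DQA1), length(.TOY_DQB1))),
      name = c(names(.TOY_DRB1), names(.TOY_DQA1), names(.TOY_DQB1)),
      sequence = c(.TOY_DRB1, .TOY_DQA1, .TOY_DQB1),
      stringsAsFactors = FALSE
    ),
    provenance = "dlahap synthetic toy library (24-bp frames)"
  )
}

#' Breed haplotype pool of the example cohort
#'
#' The eleven three-locus haplotypes of the example Hungarian Vizsla
#' cohort: seven common haplotypes plus four rare ones (grouped as "other"
#' in stratum tables), with their chromosome counts among the 183 controls
#' (2n = 366). `freq` is the corresponding relative frequency, the default
#' pool for the cohort simulator.
#'
#' @return Data frame: `haplotype`, `drb1`, `dqa1`, `dqb1`,
#'   `count_controls`, `freq`.
#' @export
vizsla_haplotypes <- function() {
  h <- data.frame(
    drb1 = c("02001", "00601", "00901", "00801", "02301", "01501", "04801",
             "01101", "02001", "00601", "00901"),
    dqa1 = c("00401", "005011", "00101", "00301", "00301", "00601", "00101",
             "00201", "00901", "005011", "00301"),
    dqb1 = c("01303", "00701", "008011", "00401", "00501", "02301", "008011",
             "01302", "02901", "02301", "00501"),
    count_controls = c(162L, 72L, 31L, 44L, 25L, 16L, 9L, 2L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  h$haplotype <- hap_id(h$drb1, h$dqa1, h$dqb1)
  h$freq <- h$count_controls / sum(h$count_controls)
  h[, c("haplotype", "drb1", "dqa1", "dqb1", "count_controls", "freq")]
}

#' The risk haplotype of the example cohort
#' @return `"02001-00401-01303"`.
#' @export
risk_haplotype <- function() hap_id("02001", "00401", "01303")

# build one group of dogs from hom/het/zero-copy counts and a vector of
# non-target chromosomes: het dogs pair the target with others[1..n_het],
# zero-copy dogs pair the remaining others consecutively
.build_group <- function(prefix, status, grade, relatedness,
                         n_hom, n_het, n_zero, others, target) {
  stopifnot(length(others) == n_het + 2L * n_zero)
  hap1 <- c(rep(target, n_hom), rep(target, n_het),
            others[n_het + 2L * seq_len(n_zero) - 1L])
  hap2 <- c(rep(target, n_hom), others[seq_len(n_het)],
            others[n_het + 2L * seq_len(n_zero)])
  n <- n_hom + n_het + n_zero
  swap <- hap1 > hap2
  tmp <- hap1[swap]; hap1[swap] <- hap2[swap]; hap2[swap] <- tmp
  data.frame(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    status = status, diagnostic_grade = grade, relatedness_grade = relatedness,
    hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE
  )
}

# derive the six genotype columns from a phased pair
.genotype_from_haps <- function(df) {
  h1 <- split_hap(df$hap1); h2 <- split_hap(df$hap2)
  for (loc in LOCUS_NAMES) {
    lc <- tolower(loc)
    a <- h1[[lc]]; b <- h2[[lc]]
    df[[paste0(lc, "_1")]] <- pmin(a, b)
    df[[paste0(lc, "_2")]] <- pmax(a, b)
  }
  df
}

#' Example phased cohort (212 dogs)
#'
#' A fully phased single-breed myositis cohort: 29 cases (13 definite, 4
#' probable, 12 possible) and 183 graded controls (93 first-degree, 44
#' second-degree, 46 unrelated), with per-stratum haplotype chromosome
#' counts over the [vizsla_haplotypes()] pool. Ages are arranged so that
#' exactly 17 unrelated controls are over 8 years old (carrying 10 risk
#' chromosomes between them). Because haplotype pairs are encoded
#' directly, the cohort exercises the association layer independently of
#' typing and phasing.
#'
#' @return A `dla_phased_cohort` data frame (`phase_status` all
#'   `"phased"`).
#' @export
example_cohort <- function() {
  H <- vizsla_haplotypes()$haplotype
  risk <- H[1]
  # cases: grade-wise dose (hom, het, zero): definite 5/7/1, probable 1/3/0,
  # possible 4/5/3 -> 35 risk chromosomes of 58, 10 homozygotes of 29
  case_others <- rep(H[2:6], c(12L, 5L, 3L, 2L, 1L))
  cases <- rbind(
    .build_group("case_def", "case", "definite", "case",
                 5L, 7L, 1L, case_others[1:9], risk),
    .build_group("case_prob", "case", "probable", "case",
                 1L, 3L, 0L, case_others[10:12], risk),
    .build_group("case_poss", "case", "possible", "case",
                 4L, 5L, 3L, case_others[13:23], risk)
  )
  first <- .build_group("fd", "control", "not_applicable", "first_degree",
                        25L, 46L, 22L,
                        rep(H[c(2, 3, 4, 5, 6, 7)],
                            c(35L, 19L, 17L, 13L, 5L, 1L)), risk)
  second <- .build_group("sd", "control", "not_applicable", "second_degree",
                         8L, 25L, 11L,
                         rep(H[c(2, 3, 4, 5, 6, 7)],
                             c(14L, 7L, 12L, 10L, 2L, 2L)), risk)
  # zero-copy pairs arranged so each protective 01501-00601-02301
  # chromosome sits in a distinct dog (9 heterozygous carriers)
  unrel_zero <- c(rep(H[c(6, 4)], 9L), rep(H[2], 6L), rep(H[3], 4L),
                  H[3], H[4], rep(H[4], 4L), H[4], H[5], H[5], H[7],
                  rep(H[7], 4L), H[7], H[8], H[8], H[9], H[9], H[10],
                  H[10], H[11])
  unrel <- .build_group("uc", "control", "not_applicable", "unrelated",
                        4L, 17L, 25L, c(rep(H[2], 17L), unrel_zero), risk)
  out <- rbind(cases, first, second, unrel)

  # ages: cases within the 0.5-8 y onset window; related controls <= 8 y;
  # unrelated controls: 2 hom + 6 het + 9 zero-copy dogs over 8 y (17 dogs)
  out$age_years <- NA_real_
  out$age_years[out$status == "case"] <-
    round(seq(0.5, 8, length.out = sum(out$status == "case")), 2)
  rel <- out$relatedness_grade %in% c("first_degree", "second_degree")
  out$age_years[rel] <- round(seq(1, 8, length.out = sum(rel)), 2)
  uc <- which(out$relatedness_grade == "unrelated")  # order: hom 4, het 17, zero 25
  uc_age <- c(9.5, 10.25, 5, 6,                                  # hom
              seq(8.5, 11, length.out = 6), seq(2, 7.8, length.out = 11),  # het
              seq(8.25, 13.83, length.out = 9), seq(0.58, 7.9, length.out = 16))
  out$age_years[uc] <- round(uc_age, 2)

  out$sex <- rep(c("female", "male"), length.out = nrow(out))
  out$sex[out$id %in% c("uc045", "uc046")] <- "unknown"
  out <- .genotype_from_haps(out)
  out$phase_status <- "phased"
  cols <- c("id", "sex", "status", "diagnostic_grade", "relatedness_grade",
            "age_years", GENOTYPE_COLS, "hap1", "hap2", "phase_status")
  out <- out[, cols]
  class(out) <- c("dla_phased_cohort", "data.frame")
  out
}

#' Example genotype-dose cohort (75 dogs)
#'
#' The 29 cases of [example_cohort()] together with a 46-dog unrelated
#' control group classified by risk-haplotype copy number as 24 / 18 / 4
#' (zero / one / two copies), the dog-level genotype-dose layout. Note the
#' dog-level control classification implies 26 risk chromosomes where the
#' chromosome-level stratum table of [example_cohort()] carries 25; the
#' two layouts are kept as separate fixtures, each internally consistent.
#'
#' @return A `dla_phased_cohort`.
#' @export
example_dose_cohort <- function() {
  full <- example_cohort()
  H <- vizsla_haplotypes()$haplotype
  cases <- full[full$status == "case", , drop = FALSE]
  unrel <- .build_group("dc", "control", "not_applicable", "unrelated",
                        4L, 18L, 24L,
                        c(rep(H[2], 18L),
                          rep(H[c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11)],
                              c(5L, 5L, 15L, 2L, 9L, 5L, 2L, 2L, 2L, 1L))),
                        risk_haplotype())
  unrel$age_years <- round(seq(1, 13, length.out = nrow(unrel)), 2)
  unrel$sex <- rep(c("female", "male"), length.out = nrow(unrel))
  unrel <- .genotype_from_haps(unrel)
  unrel$phase_status <- "phased"
  out <- rbind(as.data.frame(cases), unrel[, names(cases)])
  rownames(out) <- NULL
  class(out) <- c("dla_phased_cohort", "data.frame")
  out
}
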