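geno <- function(drb1, dqa1, dqb1) {
  list(DRB1 = drb1, DQA1 = dqa1, DQB1 = dqb1)
}

test_that("heterozygosity counts loci with two distinct alleles", {
  expect_equal(heterozygosity(geno(c("a", "a"), c("b", "b"), c("c", "c"))), 0)
  expect_equal(heterozygosity(geno(c("a", "x"), c("b", "b"), c("c", "c"))), 1)
  expect_equal(heterozygosity(geno(c("a", "x"), c("b", "y"), c("c", "z"))), 3)
})

test_that("enumerate_hap_pairs lists 2^(h-1) pairs, all reconstructing the genotype", {
  set.seed(55)
  for (rep in 1:20) {
    g <- geno(sample(c("a", "b"), 2, replace = TRUE),
              sample(c("c", "d"), 2, replace = TRUE),
              sample(c("e", "f"), 2, replace = TRUE))
    h <- heterozygosity(g)
    pairs <- enumerate_hap_pairs(g)
    expect_equal(nrow(pairs), max(1L, 2L^(h - 1L)))
    for (k in seq_len(nrow(pairs))) {
      expect_true(oracle_pair_ok(pairs$hap1[k], pairs$hap2[k], g))
    }
  }
})

test_that("full homozygotes seed the pool, deduplicated", {
  co <- cohort_from_pairs(list(
    c("02001-00401-01303", "02001-00401-01303"),
    c("02001-00401-01303", "02001-00401-01303"),
    c("00601-005011-00701", "00601-005011-00701")))
  s <- seed_from_homozygotes(co)
  expect_setequal(s$pool$haplotype,
                  c("02001-00401-01303", "00601-005011-00701"))
  expect_true(all(s$pool$provenance == "seed_full_homozygote"))
  expect_equal(nrow(s$assignments), 3)

  het <- cohort_from_pairs(list(c("a-b-c", "x-b-c")))
  expect_equal(nrow(seed_from_homozygotes(het)$pool), 0)
})

test_that("single-locus heterozygotes have a forced phase that extends the pool", {
  co <- cohort_from_pairs(list(
    c("02001-00401-01303", "00601-00401-01303")))  # h = 1 at DRB1
  s1 <- seed_from_homozygotes(co)
  s2 <- extend_with_partial_homozygotes(co, s1$pool)
  expect_setequal(c(s2$assignments$hap1, s2$assignments$hap2),
                  c("02001-00401-01303", "00601-00401-01303"))
  expect_setequal(s2$pool$haplotype,
                  c("02001-00401-01303", "00601-00401-01303"))
})

test_that("a 5-dog cohort with h=0 and h=1 dogs builds the exhaustively verified pool", {
  pairs <- list(
    c("02001-00401-01303", "02001-00401-01303"),   # h=0 seed
    c("02001-00401-01303", "00601-00401-01303"),   # h=1 at DRB1: adds 1
    c("00801-00301-00401", "00801-00301-00501"),   # h=1 at DQB1: adds 2
    c("02001-00401-01303", "02001-00401-01303"),
    c("02001-00401-01303", "00801-00301-00401"))   # h=2, pool-resolvable
  co <- cohort_from_pairs(pairs)
  ph <- phase_cohort(co)
  expect_setequal(ph$pool$haplotype,
                  c("02001-00401-01303", "00601-00401-01303",
                    "00801-00301-00401", "00801-00301-00501"))
  # all dogs phased; phased set matches the exhaustive pool-scan oracle
  expect_true(all(ph$assignments$status == "phased"))
  expect_setequal(ph$assignments$id[ph$assignments$status == "phased"],
                  oracle_unique_phased(co, ph$pool$haplotype))
})

test_that("multi-heterozygous dogs resolve, tie, or fall back as specified", {
  # h=3 dog whose four consistent pairs include exactly one fully pooled pair
  co <- cohort_from_pairs(list(
    c("02001-00401-01303", "02001-00401-01303"),
    c("00601-005011-00701", "00601-005011-00701"),
    c("02001-00401-01303", "00601-005011-00701")))   # h=3
  ph <- phase_cohort(co)
  a <- ph$assignments[ph$assignments$h == 3, ]
  expect_identical(a$status, "phased")
  expect_identical(a$provenance, "inferred")
  expect_setequal(c(a$hap1, a$hap2),
                  c("02001-00401-01303", "00601-005011-00701"))

  # constructed tie: both phase configurations fully pooled -> ambiguous
  tie <- cohort_from_pairs(list(
    c("a-x-q", "a-x-q"), c("b-y-q", "b-y-q"),
    c("a-y-q", "a-y-q"), c("b-x-q", "b-x-q"),
    c("a-x-q", "b-y-q")))                            # h=2
  pht <- phase_cohort(tie)
  amb <- pht$assignments[pht$assignments$h == 2, ]
  expect_identical(amb$status, "ambiguous")
  expect_equal(nrow(pht$ambiguous[[amb$id]]), 2)
  # ranking policy orders candidate pairs by pool support, status unchanged
  phr <- phase_cohort(tie, policy = "rank")
  cand <- phr$ambiguous[[amb$id]]
  expect_identical(phr$assignments$status[phr$assignments$h == 2], "ambiguous")
  expect_true(all(diff(cand$support) <= 0))

  # dog sharing no allele with the pool -> unresolved
  lone <- cohort_from_pairs(list(
    c("a-x-q", "a-x-q"),
    c("m-n-o", "p-q-r")))                            # h=3, disjoint
  phl <- phase_cohort(lone)
  expect_identical(phl$assignments$status[phl$assignments$h == 3],
                   "unresolved")
})

test_that("parsimony fallback admits exactly one novel haplotype per dog", {
  # h=2 dog with one pooled member in exactly one pair
  co <- cohort_from_pairs(list(
    c("a-x-q", "a-x-q"),
    c("a-x-q", "b-y-q")))                            # h=2, pairs: (axq,byq),(ayq,bxq)
  ph <- phase_cohort(co)
  a <- ph$assignments[ph$assignments$h == 2, ]
  expect_identical(a$status, "phased")
  expect_setequal(c(a$hap1, a$hap2), c("a-x-q", "b-y-q"))
  expect_identical(ph$pool$provenance[ph$pool$haplotype == "b-y-q"], "inferred")

  # two novel haplotypes needed -> unresolved (conservatism)
  co2 <- cohort_from_pairs(list(
    c("z-z-z", "z-z-z"),
    c("a-x-q", "b-y-q")))
  ph2 <- phase_cohort(co2)
  expect_identical(ph2$assignments$status[ph2$assignments$h == 2], "unresolved")
})

test_that("every phased pair reconstructs its genotype and assignments are order-independent", {
  set.seed(77)
  haps <- vizsla_haplotypes()
  for (rep in 1:5) {
    pairs <- replicate(60, sort(sample(haps$haplotype, 2, replace = TRUE,
                                       prob = haps$freq)), simplify = FALSE)
    co <- cohort_from_pairs(pairs)
    ph <- phase_cohort(co)
    ok <- ph$assignments$status == "phased"
    for (k in which(ok)) {
      i <- match(ph$assignments$id[k], co$id)
      g <- geno(c(co$drb1_1[i], co$drb1_2[i]), c(co$dqa1_1[i], co$dqa1_2[i]),
                c(co$dqb1_1[i], co$dqb1_2[i]))
      expect_true(oracle_pair_ok(ph$assignments$hap1[k],
                                 ph$assignments$hap2[k], g))
    }
    perm <- sample(nrow(co))
    co2 <- co[perm, , drop = FALSE]
    class(co2) <- class(co)
    ph2 <- phase_cohort(co2)
    o1 <- ph$assignments[order(ph$assignments$id), ]
    o2 <- ph2$assignments[order(ph2$assignments$id), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_identical(o1, o2)
    expect_identical(ph$pool, ph2$pool)
  }
})

test_that("adding a fully homozygous dog never unphases an already phased dog", {
  set.seed(88)
  haps <- vizsla_haplotypes()
  pairs <- replicate(30, sort(sample(haps$haplotype, 2, replace = TRUE,
                                     prob = haps$freq)), simplify = FALSE)
  co <- cohort_from_pairs(pairs)
  ph <- phase_cohort(co)
  phased_before <- ph$assignments$id[ph$assignments$status == "phased"]
  extra <- cohort_from_pairs(c(pairs, list(rep(haps$haplotype[5], 2))))
  ph2 <- phase_cohort(extra)
  phased_after <- ph2$assignments$id[ph2$assignments$status == "phased"]
  expect_true(all(phased_before %in% phased_after))
})

test_that("dogs with a missing locus are excluded and flagged", {
  co <- cohort_from_pairs(list(c("a-x-q", "a-x-q"), c("a-x-q", "b-y-q")))
  co$dqa1_1[2] <- NA; co$dqa1_2[2] <- NA
  ph <- phase_cohort(co)
  expect_identical(ph$excluded, "d002")
  expect_false("d002" %in% ph$assignments$id)
  pc <- phased_cohort(co, ph)
  expect_identical(pc$phase_status[pc$id == "d002"], "excluded")
})

test_that("cohorts of only full homozygotes phase completely with a pool of distinct triples", {
  co <- cohort_from_pairs(list(
    c("a-x-q", "a-x-q"), c("b-y-r", "b-y-r"), c("a-x-q", "a-x-q")))
  ph <- phase_cohort(co)
  expect_true(all(ph$assignments$status == "phased"))
  expect_equal(nrow(ph$pool), 2)
})

test_that("truth recovery on a simulated 500-dog cohort exceeds 90 percent", {
  set.seed(99)
  haps <- vizsla_haplotypes()
  truth <- replicate(500, sort(sample(haps$haplotype, 2, replace = TRUE,
                                      prob = haps$freq)), simplify = FALSE)
  co <- cohort_from_pairs(truth)
  ph <- phase_cohort(co)
  a <- ph$assignments
  phased <- a[a$status == "phased", ]
  expect_gt(nrow(phased) / nrow(a), 0.95)
  idx <- match(phased$id, co$id)
  hit <- vapply(seq_len(nrow(phased)), function(k) {
    identical(sort(c(phased$hap1[k], phased$hap2[k])), truth[[idx[k]]])
  }, logical(1))
  expect_gt(mean(hit), 0.90)
})
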