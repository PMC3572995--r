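# Independent oracles and generators used across the suite.
# These deliberately re-derive results through different machinery than the
# package (IUPAC unions via Biostrings' code table, exhaustive pair scans)
# so agreement is evidence, not tautology.

# IUPAC union of two bases, looked up in Biostrings' published code table
oracle_iupac_union <- function(a, b) {
  bases <- sort(unique(c(a, b)))
  map <- Biostrings::IUPAC_CODE_MAP
  names(map)[match(paste(bases, collapse = ""), map)]
}

# position-wise diploid consensus built solely from the code table
oracle_superpose <- function(x, y) {
  xa <- strsplit(x, "")[[1]]; ya <- strsplit(y, "")[[1]]
  paste(mapply(oracle_iupac_union, xa, ya), collapse = "")
}

# exhaustive typing oracle: all unordered pairs (i <= j) whose consensus
# equals the read (read must already be in sense orientation)
oracle_resolve <- function(read_seq, alleles) {
  hits <- list()
  n <- nrow(alleles)
  for (i in seq_len(n)) for (j in i:n) {
    if (oracle_superpose(alleles$sequence[i], alleles$sequence[j]) == read_seq) {
      hits[[length(hits) + 1L]] <- sort(c(alleles$name[i], alleles$name[j]))
    }
  }
  if (!length(hits)) return(data.frame(allele1 = character(),
                                       allele2 = character()))
  m <- do.call(rbind, hits)
  unique(data.frame(allele1 = m[, 1], allele2 = m[, 2],
                    stringsAsFactors = FALSE))
}

# unordered candidate sets as canonical strings, for set comparison
pair_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(pmin(df$allele1, df$allele2), pmax(df$allele1, df$allele2),
             sep = "/"))
}

# random allele library at one locus
random_locus_alleles <- function(n, len, locus = "DRB1") {
  repeat {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(seqs)) break
  }
  data.frame(locus = locus, name = sprintf("%05d", seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# ---- phasing oracles -------------------------------------------------------

# does the unordered haplotype pair reconstruct the genotype?
# (multiset equality per locus, computed without package helpers)
oracle_pair_ok <- function(hap1, hap2, geno) {
  s1 <- strsplit(hap1, "-")[[1]]; s2 <- strsplit(hap2, "-")[[1]]
  all(vapply(1:3, function(j) {
    identical(sort(c(s1[j], s2[j])),
              sort(geno[[c("DRB1", "DQA1", "DQB1")[j]]]))
  }, logical(1)))
}

# ids of dogs with exactly one pool-consistent pair, by exhaustive scan
# over pool x pool
oracle_unique_phased <- function(cohort, pool_haps) {
  out <- character()
  np <- length(pool_haps)
  for (i in seq_len(nrow(cohort))) {
    geno <- lapply(c("DRB1", "DQA1", "DQB1"), function(loc) {
      cols <- paste0(tolower(loc), c("_1", "_2"))
      c(cohort[[cols[1]]][i], cohort[[cols[2]]][i])
    })
    names(geno) <- c("DRB1", "DQA1", "DQB1")
    k <- 0L
    for (p in seq_len(np)) for (q in p:np) {
      if (oracle_pair_ok(pool_haps[p], pool_haps[q], geno)) k <- k + 1L
    }
    if (k == 1L) out <- c(out, as.character(cohort$id[i]))
  }
  out
}

# cohort data frame from a list of haplotype-pair rows
cohort_from_pairs <- function(pairs, status = "control",
                              relatedness = "unrelated") {
  n <- length(pairs)
  df <- data.frame(id = sprintf("d%03d", seq_len(n)), status = status,
                   relatedness_grade = relatedness, stringsAsFactors = FALSE)
  for (loc in c("DRB1", "DQA1", "DQB1")) {
    j <- match(loc, c("DRB1", "DQA1", "DQB1"))
    a <- vapply(pairs, function(p) strsplit(p[1], "-")[[1]][j], "")
    b <- vapply(pairs, function(p) strsplit(p[2], "-")[[1]][j], "")
    df[[paste0(tolower(loc), "_1")]] <- pmin(a, b)
    df[[paste0(tolower(loc), "_2")]] <- pmax(a, b)
  }
  as_cohort(df)
}

# random small cohort drawn from a random haplotype pool; returns cohort and
# the generating truth pairs
random_small_cohort <- function(n_dogs, n_haps) {
  alleles <- sprintf("%02d", 1:4)
  pool <- unique(replicate(n_haps, paste(sample(alleles, 3, replace = TRUE),
                                         collapse = "-")))
  pairs <- replicate(n_dogs, sort(sample(pool, 2, replace = TRUE)),
                     simplify = FALSE)
  list(cohort = cohort_from_pairs(pairs), pool = pool, truth = pairs)
}
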