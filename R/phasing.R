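# Homozygote-seeded three-locus haplotype phasing.
#
# The three class II loci sit on one tightly linked block, so a dog's two
# chromosomes each carry one DRB1-DQA1-DQB1 haplotype and no recombination
# is modelled. Phasing follows the classic Clark-style field procedure,
# made deterministic and order-independent by processing heterozygosity
# strata rather than dogs in input order:
#
#   1. dogs homozygous at all three loci (h = 0) each reveal one haplotype
#      unambiguously -- these seed the pool;
#   2. dogs heterozygous at exactly one locus (h = 1) have a forced phase
#      and confirm/extend the pool;
#   3. remaining dogs (h >= 2) are resolved against the accumulated pool,
#      iterated to a fixed point; a parsimony fallback admits at most one
#      novel haplotype per dog.

#' Haplotype identifier from its three allele names
#'
#' @param drb1,dqa1,dqb1 Allele name strings.
#' @return `"<drb1>-<dqa1>-<dqb1>"`.
#' @export
hap_id <- function(drb1, dqa1, dqb1) paste(drb1, dqa1, dqb1, sep = "-")

#' Split haplotype identifiers into allele names
#'
#' @param x Character vector of `"drb1-dqa1-dqb1"` identifiers.
#' @return Data frame with columns `drb1`, `dqa1`, `dqb1`.
#' @export
split_hap <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) stop("malformed haplotype id: ", x[which(bad)[1]])
  data.frame(drb1 = vapply(parts, `[`, "", 1L),
             dqa1 = vapply(parts, `[`, "", 2L),
             dqb1 = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

# genotype of cohort row i as list(DRB1 = c(a, b), ...), or NULL if untyped
genotype_of <- function(cohort, i) {
  g <- lapply(LOCUS_NAMES, function(loc) {
    as.character(unlist(cohort[i, locus_cols(loc)], use.names = FALSE))
  })
  names(g) <- LOCUS_NAMES
  if (any(vapply(g, anyNA, TRUE))) return(NULL)
  g
}

#' Number of heterozygous loci in a three-locus genotype
#'
#' @param genotype List with elements `DRB1`, `DQA1`, `DQB1`, each an
#'   unordered pair of allele names.
#' @return Integer in 0..3.
#' @export
heterozygosity <- function(genotype) {
  stopifnot(is.list(genotype), all(LOCUS_NAMES %in% names(genotype)))
  sum(vapply(LOCUS_NAMES, function(loc) {
    p <- genotype[[loc]]
    stopifnot(length(p) == 2L)
    p[1] != p[2]
  }, logical(1)))
}

#' Enumerate all haplotype pairs consistent with a genotype
#'
#' A genotype heterozygous at h loci has `2^(h-1)` distinct unordered
#' haplotype pairs (the phase at the first heterozygous locus is fixed to
#' break the mirror symmetry). Every returned pair reconstructs the
#' genotype exactly.
#'
#' @param genotype As for [heterozygosity()].
#' @return Data frame with columns `hap1`, `hap2` (canonically ordered
#'   within each row).
#' @export
enumerate_hap_pairs <- function(genotype) {
  het <- vapply(LOCUS_NAMES, function(loc) {
    genotype[[loc]][1] != genotype[[loc]][2]
  }, logical(1))
  het_idx <- which(het)
  free <- het_idx[-1]
  n_free <- length(free)
  combos <- as.matrix(expand.grid(rep(list(0:1), n_free)))
  if (n_free == 0L) combos <- matrix(integer(), nrow = 1L, ncol = 0L)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    a1 <- a2 <- character(3L)
    for (j in seq_along(LOCUS_NAMES)) {
      p <- genotype[[LOCUS_NAMES[j]]]
      if (!het[j]) {
        a1[j] <- p[1]; a2[j] <- p[1]
      } else if (length(het_idx) && j == het_idx[1]) {
        a1[j] <- p[1]; a2[j] <- p[2]
      } else {
        s <- combos[k, match(j, free)]
        a1[j] <- p[1 + s]; a2[j] <- p[2 - s]
      }
    }
    sort(c(hap_id(a1[1], a1[2], a1[3]), hap_id(a2[1], a2[2], a2[3])))
  })
  out <- data.frame(hap1 = vapply(rows, `[`, "", 1L),
                    hap2 = vapply(rows, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  unique(out)
}

# does unordered pair (hap1, hap2) reconstruct the genotype exactly?
pair_matches_genotype <- function(hap1, hap2, genotype) {
  h1 <- split_hap(hap1); h2 <- split_hap(hap2)
  all(vapply(seq_along(LOCUS_NAMES), function(j) {
    setequal_pair <- function(x, y) identical(sort(x), sort(y))
    setequal_pair(c(h1[[j]], h2[[j]]), sort(genotype[[LOCUS_NAMES[j]]]))
  }, logical(1)))
}

empty_pool <- function() {
  data.frame(haplotype = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

add_to_pool <- function(pool, haps, tag) {
  new <- setdiff(unique(haps), pool$haplotype)
  if (length(new)) {
    pool <- rbind(pool, data.frame(haplotype = new, provenance = tag,
                                   stringsAsFactors = FALSE))
  }
  pool[order(pool$haplotype), , drop = FALSE]
}

#' Seed the haplotype pool from fully homozygous dogs
#'
#' Every dog homozygous at all three loci carries two copies of a single,
#' directly observable haplotype; these enter the pool with provenance
#' `seed_full_homozygote` and the dogs are phased immediately.
#'
#' @param cohort A cohort data frame with genotype columns.
#' @return List with `pool` (data frame `haplotype`, `provenance`) and
#'   `assignments` (data frame `id`, `hap1`, `hap2`, `h`, `status`,
#'   `provenance`).
#' @export
seed_from_homozygotes <- function(cohort) {
  pool <- empty_pool()
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    g <- genotype_of(cohort, i)
    if (is.null(g) || heterozygosity(g) != 0L) next
    hap <- hap_id(g$DRB1[1], g$DQA1[1], g$DQB1[1])
    pool <- add_to_pool(pool, hap, "seed_full_homozygote")
    rows[[length(rows) + 1L]] <- data.frame(
      id = as.character(cohort$id[i]), hap1 = hap, hap2 = hap, h = 0L,
      status = "phased", provenance = "seed_full_homozygote",
      stringsAsFactors = FALSE)
  }
  list(pool = pool, assignments = do.call(rbind, c(rows, list(NULL))))
}

#' Extend the pool with single-locus heterozygotes
#'
#' A dog heterozygous at exactly one locus has a forced phase: each of the
#' two alleles at the heterozygous locus combines with the shared
#' homozygous background. Both implied haplotypes are confirmed or added
#' (provenance `seed_partial_homozygote`).
#'
#' @param cohort A cohort data frame.
#' @param pool Pool data frame from [seed_from_homozygotes()].
#' @return List with updated `pool` and the h = 1 `assignments`.
#' @export
extend_with_partial_homozygotes <- function(cohort, pool) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    g <- genotype_of(cohort, i)
    if (is.null(g) || heterozygosity(g) != 1L) next
    pair <- enumerate_hap_pairs(g)   # exactly one row when h = 1
    pool <- add_to_pool(pool, c(pair$hap1, pair$hap2), "seed_partial_homozygote")
    rows[[length(rows) + 1L]] <- data.frame(
      id = as.character(cohort$id[i]), hap1 = pair$hap1, hap2 = pair$hap2,
      h = 1L, status = "phased", provenance = "seed_partial_homozygote",
      stringsAsFactors = FALSE)
  }
  list(pool = pool, assignments = do.call(rbind, c(rows, list(NULL))))
}

#' Resolve multi-heterozygous dogs against an established pool
#'
#' For each dog heterozygous at two or three loci, the `2^(h-1)` consistent
#' haplotype pairs are enumerated and compared with the pool:
#' \itemize{
#'   \item exactly one pair with both members pooled: phased (`inferred`);
#'   \item several such pairs: `ambiguous`, all consistent pairs listed
#'     (ranked by pool support under `policy = "rank"`);
#'   \item none: parsimony fallback -- if exactly one pair has exactly one
#'     pooled member, the dog is phased and the novel partner joins the
#'     pool (`inferred`); otherwise `unresolved`.
#' }
#' Pool growth from the fallback can unlock further dogs, so the pass
#' iterates to a fixed point; final statuses are assigned against the
#' final pool (and novel haplotypes left carried by no phased dog are
#' pruned), which makes the result independent of subject order.
#'
#' @param cohort A cohort data frame.
#' @param pool Pool data frame (seeding steps done).
#' @param assignments Assignments data frame accumulated so far.
#' @param policy `"report"` (default) leaves ambiguity listed;
#'   `"rank"` additionally orders each ambiguous dog's candidate pairs by
#'   the product of pool haplotype carrier counts.
#' @return A `dla_phasing` object; see [phase_cohort()].
#' @export
resolve_remaining <- function(cohort, pool, assignments = NULL,
                              policy = c("report", "rank")) {
  policy <- match.arg(policy)
  ids <- as.character(cohort$id)
  todo <- integer()
  pairs_list <- list()
  h_of <- integer()
  excluded <- character()
  for (i in seq_len(nrow(cohort))) {
    g <- genotype_of(cohort, i)
    if (is.null(g)) { excluded <- c(excluded, ids[i]); next }
    h <- heterozygosity(g)
    if (h >= 2L) {
      todo <- c(todo, i)
      pairs_list[[as.character(i)]] <- enumerate_hap_pairs(g)
      h_of[as.character(i)] <- h
    }
  }

  # pool growth to fixed point (order-independent: each pass uses a snapshot)
  repeat {
    novel <- character()
    for (i in todo) {
      P <- pairs_list[[as.character(i)]]
      in1 <- P$hap1 %in% pool$haplotype
      in2 <- P$hap2 %in% pool$haplotype
      if (any(in1 & in2)) next
      one <- xor(in1, in2)
      if (sum(one) == 1L) {
        k <- which(one)
        novel <- c(novel, if (in1[k]) P$hap2[k] else P$hap1[k])
      }
    }
    novel <- setdiff(unique(novel), pool$haplotype)
    if (!length(novel)) break
    pool <- add_to_pool(pool, novel, "inferred")
  }

  # classification against the final pool; prune uncarried novel haplotypes
  ambiguous <- list()
  repeat {
    ambiguous <- list()
    rows <- list()
    for (i in todo) {
      P <- pairs_list[[as.character(i)]]
      both <- (P$hap1 %in% pool$haplotype) & (P$hap2 %in% pool$haplotype)
      k2 <- sum(both)
      hi <- h_of[[as.character(i)]]
      if (k2 == 1L) {
        k <- which(both)
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], hap1 = P$hap1[k], hap2 = P$hap2[k], h = hi,
          status = "phased", provenance = "inferred", stringsAsFactors = FALSE)
      } else if (k2 > 1L) {
        cand <- P[both, , drop = FALSE]
        rownames(cand) <- NULL
        ambiguous[[ids[i]]] <- cand
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], hap1 = NA_character_, hap2 = NA_character_, h = hi,
          status = "ambiguous", provenance = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], hap1 = NA_character_, hap2 = NA_character_, h = hi,
          status = "unresolved", provenance = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    multi <- do.call(rbind, c(rows, list(NULL)))
    all_assign <- rbind(assignments, multi)
    carried <- c(all_assign$hap1[all_assign$status == "phased"],
                 all_assign$hap2[all_assign$status == "phased"])
    drop <- pool$provenance == "inferred" & !(pool$haplotype %in% carried)
    if (!any(drop)) { assignments <- all_assign; break }
    pool <- pool[!drop, , drop = FALSE]
  }

  # chromosome counts among phased dogs
  phased <- assignments[!is.na(assignments$status) &
                          assignments$status == "phased", , drop = FALSE]
  counts <- table(c(phased$hap1, phased$hap2))
  pool$count <- as.integer(counts[pool$haplotype])
  pool$count[is.na(pool$count)] <- 0L

  if (policy == "rank") {
    cnt <- setNames(pool$count, pool$haplotype)
    ambiguous <- lapply(ambiguous, function(cand) {
      cand$support <- as.numeric(cnt[cand$hap1]) * as.numeric(cnt[cand$hap2])
      cand$support[is.na(cand$support)] <- 0
      cand[order(-cand$support), , drop = FALSE]
    })
  }

  hp <- split_hap(pool$haplotype)
  pool <- cbind(pool[, "haplotype", drop = FALSE], hp,
                pool[, c("provenance", "count"), drop = FALSE])
  rownames(pool) <- NULL
  rownames(assignments) <- NULL

  structure(list(assignments = assignments, pool = pool,
                 ambiguous = ambiguous, excluded = excluded),
            class = "dla_phasing")
}

#' Phase a cohort's three-locus genotypes
#'
#' Composes the three strata passes: full homozygotes seed the pool,
#' single-locus heterozygotes extend it with their forced phase, and
#' multi-heterozygous dogs are resolved against the pool iterated to a
#' fixed point (see [resolve_remaining()]). Dogs missing a genotype at any
#' locus are excluded and reported.
#'
#' @param cohort A cohort data frame with genotype columns.
#' @param policy Ambiguity policy; see [resolve_remaining()].
#' @return A `dla_phasing` object: `assignments` (one row per typed dog:
#'   `id`, `hap1`, `hap2`, `h`, `status` in phased/ambiguous/unresolved,
#'   `provenance`), `pool` (established haplotypes with provenance and
#'   chromosome counts), `ambiguous` (per-dog candidate pair tables), and
#'   `excluded` (ids of untyped dogs).
#' @export
phase_cohort <- function(cohort, policy = c("report", "rank")) {
  policy <- match.arg(policy)
  s1 <- seed_from_homozygotes(cohort)
  s2 <- extend_with_partial_homozygotes(cohort, s1$pool)
  resolve_remaining(cohort, s2$pool,
                    assignments = rbind(s1$assignments, s2$assignments),
                    policy = policy)
}

#' @export
print.dla_phasing <- function(x, ...) {
  tab <- table(factor(x$assignments$status,
                      levels = c("phased", "ambiguous", "unresolved")))
  cat("Three-locus phasing: ",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded)),
      "\n", sep = "")
  cat("Pool of", nrow(x$pool), "haplotypes\n")
  invisible(x)
}

#' Join phasing results back onto subject metadata
#'
#' @param cohort A cohort data frame.
#' @param phasing A `dla_phasing` from [phase_cohort()].
#' @return The cohort with `hap1`, `hap2`, `phase_status` columns merged
#'   on `id`; class `dla_phased_cohort`.
#' @export
phased_cohort <- function(cohort, phasing) {
  stopifnot(inherits(phasing, "dla_phasing"))
  a <- phasing$assignments[, c("id", "hap1", "hap2", "status")]
  names(a)[4] <- "phase_status"
  base <- as.data.frame(cohort)
  base <- base[, setdiff(names(base), c("hap1", "hap2", "phase_status")),
               drop = FALSE]
  out <- merge(base, a, by = "id", all.x = TRUE, sort = FALSE)
  out$phase_status[is.na(out$phase_status)] <- "excluded"
  class(out) <- c("dla_phased_cohort", "data.frame")
  out
}

#' Write phasing output tables
#'
#' Emits the per-subject assignment table and the haplotype pool table as
#' delimited text.
#'
#' @param phasing A `dla_phasing`.
#' @param assignments_path,pool_path Output paths.
#' @param sep Field separator.
#' @export
write_phasing <- function(phasing, assignments_path, pool_path, sep = ",") {
  write.table(phasing$assignments, assignments_path, sep = sep,
              row.names = FALSE, quote = FALSE, na = "")
  write.table(phasing$pool, pool_path, sep = sep,
              row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}
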