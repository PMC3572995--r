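# Sequence-based typing (SBT).
#
# Each dog is sequenced in a single direction per locus (reverse trace for
# DRB1 and DQA1, forward for DQB1). Heterozygous sites appear in the
# consensus as IUPAC ambiguity codes. Typing inverts superpose(): the
# candidate calls for a read are exactly the unordered allele pairs {a, b}
# of the locus library with superpose(a, b) equal to the read. Matching is
# exact -- no mismatch tolerance and no base-call error model.

#' Construct an ambiguous SBT read
#'
#' @param locus One of `"DRB1"`, `"DQA1"`, `"DQB1"`.
#' @param sequence IUPAC nucleotide string (single-direction consensus).
#' @param orientation `"sense"` or `"antisense"` relative to the reference
#'   library frame.
#' @param sample Optional sample identifier carried through reports.
#' @return An object of class `dla_read`.
#' @export
ambiguous_read <- function(locus, sequence, orientation = c("sense", "antisense"),
                           sample = NA_character_) {
  assert_locus(locus)
  orientation <- match.arg(orientation)
  sequence <- normalize_sequence(sequence)
  validate_iupac(sequence)
  structure(list(locus = locus, sequence = sequence,
                 orientation = orientation, sample = sample),
            class = "dla_read")
}

#' Normalise a read to the sense orientation
#'
#' Antisense reads are reverse-complemented under IUPAC complement rules
#' (R <-> Y, K <-> M, S and W self-complementary) into the sense frame of
#' the reference library; sense reads pass through unchanged. The
#' operation is idempotent.
#'
#' @param read A `dla_read`.
#' @return A `dla_read` in sense orientation.
#' @export
normalize_orientation <- function(read) {
  stopifnot(inherits(read, "dla_read"))
  if (read$orientation == "sense") return(read)
  read$sequence <- reverse_complement_iupac(read$sequence)
  read$orientation <- "sense"
  read
}

# all unordered index pairs (i <= j) for n alleles
unordered_pairs <- function(n) {
  if (n == 0L) return(matrix(integer(), ncol = 2L))
  idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Resolve the allele pair underlying an ambiguous read
#'
#' Enumerates every unordered pair of library alleles at the read's locus
#' (a pair may repeat one allele: a homozygote) and keeps those whose
#' superposition equals the read exactly. Statuses:
#' \describe{
#'   \item{`resolved`}{exactly one consistent pair}
#'   \item{`ambiguous`}{several consistent pairs (genuine SBT ambiguity);
#'     left unresolved by default, or broken by `resolve_by_frequency`}
#'   \item{`no_match`}{no consistent pair -- novel allele or sequencing
#'     error; a reportable outcome, not an exception}
#'   \item{`unresolvable_multibase`}{the read contains a 3- or 4-base code
#'     (N, V, ...), which no diploid superposition can produce}
#' }
#'
#' @param read A `dla_read` (any orientation; normalised internally).
#' @param library A `dla_library`.
#' @param resolve_by_frequency If `TRUE` and the call is ambiguous, pick
#'   the candidate pair with the highest product of prior allele
#'   frequencies from `priors`; ties remain ambiguous.
#' @param priors Optional named numeric vector of per-allele prior
#'   frequencies at this locus (names are allele names).
#' @return An object of class `dla_pair_call` with fields `locus`,
#'   `sample`, `candidates` (data frame `allele1`, `allele2`), `status`,
#'   and `resolved` (character pair or `NULL`).
#' @export
resolve_allele_pair <- function(read, library, resolve_by_frequency = FALSE,
                                priors = NULL) {
  stopifnot(inherits(read, "dla_read"), inherits(library, "dla_library"))
  read <- normalize_orientation(read)
  al <- locus_alleles(library, read$locus)
  if (nrow(al) == 0L) stop("library has no alleles at locus ", read$locus)
  if (nchar(read$sequence) != nchar(al$sequence[1])) {
    stop("frame error: read length ", nchar(read$sequence),
         " does not match library frame ", nchar(al$sequence[1]),
         " at locus ", read$locus)
  }
  call <- structure(
    list(locus = read$locus, sample = read$sample,
         candidates = data.frame(allele1 = character(), allele2 = character(),
                                 stringsAsFactors = FALSE),
         status = "no_match", resolved = NULL),
    class = "dla_pair_call"
  )
  if (has_multibase_code(read$sequence)) {
    call$status <- "unresolvable_multibase"
    return(call)
  }
  pairs <- unordered_pairs(nrow(al))
  hit <- vapply(seq_len(nrow(pairs)), function(k) {
    superpose(al$sequence[pairs[k, 1L]], al$sequence[pairs[k, 2L]]) ==
      read$sequence
  }, logical(1))
  if (any(hit)) {
    cand <- data.frame(allele1 = al$name[pairs[hit, 1L]],
                       allele2 = al$name[pairs[hit, 2L]],
                       stringsAsFactors = FALSE)
    call$candidates <- cand
    if (nrow(cand) == 1L) {
      call$status <- "resolved"
      call$resolved <- c(cand$allele1, cand$allele2)
    } else {
      call$status <- "ambiguous"
      if (resolve_by_frequency && !is.null(priors)) {
        w <- priors[cand$allele1] * priors[cand$allele2] *
          ifelse(cand$allele1 == cand$allele2, 1, 2)
        w[is.na(w)] <- 0
        top <- which(w == max(w))
        if (length(top) == 1L && max(w) > 0) {
          call$status <- "resolved"
          call$resolved <- c(cand$allele1[top], cand$allele2[top])
        }
      }
    }
  }
  call
}

#' @export
print.dla_pair_call <- function(x, ...) {
  cat(sprintf("SBT call %s @ %s: %s", x$sample, x$locus, x$status))
  if (!is.null(x$resolved)) {
    cat(sprintf(" (%s/%s)", x$resolved[1], x$resolved[2]))
  }
  cat(sprintf(" [%d candidate pair(s)]\n", nrow(x$candidates)))
  invisible(x)
}

# ---- read files ------------------------------------------------------------

#' Read SBT consensus reads from FASTA
#'
#' Headers follow `sample|locus|orientation`, e.g. `dog007|DRB1|antisense`.
#'
#' @param path FASTA of IUPAC consensus reads.
#' @return List of `dla_read`.
#' @export
load_reads <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) {
    stop("format error: read header '", headers[which(bad)[1]],
         "' does not parse as sample|locus|orientation")
  }
  lapply(seq_along(seqs), function(i) {
    p <- parts[[i]]
    ambiguous_read(locus = p[2], sequence = as.character(seqs[[i]]),
                   orientation = p[3], sample = p[1])
  })
}

#' Write SBT reads to FASTA
#'
#' @param reads List of `dla_read`.
#' @param path Output FASTA path.
#' @export
write_reads <- function(reads, path) {
  seqs <- Biostrings::BStringSet(vapply(reads, `[[`, "", "sequence"))
  names(seqs) <- vapply(reads, function(r) {
    paste(r$sample, r$locus, r$orientation, sep = "|")
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Type a set of reads into per-sample genotype calls
#'
#' Runs [resolve_allele_pair()] on every read and assembles a call table;
#' samples with a resolved call at all three loci additionally yield rows
#' of a genotype table suitable for [as_cohort()] merging.
#'
#' @param reads List of `dla_read`.
#' @param library A `dla_library`.
#' @param ... Passed to [resolve_allele_pair()].
#' @return List with `calls` (data frame: sample, locus, allele1, allele2,
#'   n_candidates, status) and `genotypes` (data frame: id + six genotype
#'   columns, fully resolved samples only).
#' @export
type_reads <- function(reads, library, ...) {
  calls <- do.call(rbind, lapply(reads, function(r) {
    pc <- resolve_allele_pair(r, library, ...)
    data.frame(
      sample = r$sample, locus = r$locus,
      allele1 = if (is.null(pc$resolved)) NA_character_ else min(pc$resolved),
      allele2 = if (is.null(pc$resolved)) NA_character_ else max(pc$resolved),
      n_candidates = nrow(pc$candidates), status = pc$status,
      stringsAsFactors = FALSE
    )
  }))
  genotypes <- NULL
  if (!is.null(calls) && nrow(calls)) {
    ok <- calls[calls$status == "resolved", , drop = FALSE]
    samples <- unique(calls$sample)
    rows <- lapply(samples, function(s) {
      g <- setNames(as.list(rep(NA_character_, 6L)), GENOTYPE_COLS)
      for (loc in LOCUS_NAMES) {
        row <- ok[ok$sample == s & ok$locus == loc, , drop = FALSE]
        if (nrow(row) == 1L) {
          g[locus_cols(loc)] <- list(row$allele1, row$allele2)
        }
      }
      cbind(data.frame(id = s, stringsAsFactors = FALSE),
            as.data.frame(g, stringsAsFactors = FALSE))
    })
    genotypes <- do.call(rbind, rows)
  }
  list(calls = calls, genotypes = genotypes)
}
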