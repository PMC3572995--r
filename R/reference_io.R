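# Reference allele libraries and cohort tables.
#
# The three class II loci form one tightly linked block; exon 2 of each is
# amplified and typed. Reference libraries are FASTA files with headers in
# the published DLA nomenclature, "DLA-<locus>*<allele>", e.g.
# "DLA-DRB1*02001". All alleles at one locus must share a sequence length
# (a pre-aligned exon-2 frame).

#' The three DLA class II loci
#'
#' Locus names with the exon-2 amplicon lengths of the standard typing
#' assay (documented defaults; a library may legitimately cover a different
#' exon-2 window, so validation is against library-internal consistency).
#'
#' @export
DLA_LOCI <- c(DRB1 = 303L, DQA1 = 345L, DQB1 = 300L)

LOCUS_NAMES <- names(DLA_LOCI)

# sequencing is single-direction: reverse reads for DRB1/DQA1, forward for DQB1
NATIVE_ORIENTATION <- c(DRB1 = "antisense", DQA1 = "antisense", DQB1 = "sense")

assert_locus <- function(locus) {
  if (!(is.character(locus) && length(locus) == 1L && locus %in% LOCUS_NAMES)) {
    stop("locus must be one of ", paste(LOCUS_NAMES, collapse = ", "))
  }
  locus
}

#' Construct an allele library from a data frame
#'
#' @param alleles Data frame with columns `locus`, `name`, `sequence`.
#' @param provenance Free-text source note.
#' @return An object of class `dla_library`.
#' @export
allele_library <- function(alleles, provenance = "") {
  stopifnot(is.data.frame(alleles),
            all(c("locus", "name", "sequence") %in% names(alleles)))
  alleles$locus <- as.character(alleles$locus)
  alleles$name <- as.character(alleles$name)
  alleles$sequence <- vapply(alleles$sequence, normalize_sequence, "",
                             USE.NAMES = FALSE)
  bad_locus <- !(alleles$locus %in% LOCUS_NAMES)
  if (any(bad_locus)) {
    stop("unknown locus '", alleles$locus[which(bad_locus)[1]], "'")
  }
  for (i in seq_len(nrow(alleles))) {
    chars <- strsplit(alleles$sequence[i], "", fixed = TRUE)[[1]]
    if (!all(chars %in% IUPAC_BASES)) {
      stop("allele ", alleles$locus[i], "*", alleles$name[i],
           " contains non-A/C/G/T characters")
    }
  }
  key <- paste(alleles$locus, alleles$name, sep = "*")
  if (anyDuplicated(key)) {
    stop("duplicate allele record: ", key[which(duplicated(key))[1]])
  }
  for (loc in unique(alleles$locus)) {
    lens <- nchar(alleles$sequence[alleles$locus == loc])
    if (length(unique(lens)) > 1L) {
      stop("alignment-frame error: unequal sequence lengths at locus ", loc,
           " (", paste(sort(unique(lens)), collapse = ", "), " bp)")
    }
  }
  alleles <- alleles[order(alleles$locus, alleles$name), , drop = FALSE]
  rownames(alleles) <- NULL
  structure(list(alleles = alleles, provenance = provenance),
            class = "dla_library")
}

#' Load a per-locus allele reference library from FASTA
#'
#' Headers must follow the DLA nomenclature `DLA-<locus>*<name>`; anything
#' after the first whitespace is ignored. Sequences are uppercased and `U`
#' is mapped to `T`. Within each locus all sequences must have equal length
#' (the exon-2 alignment frame); the frame length is taken from the file
#' itself, with the standard amplicon sizes in [DLA_LOCI] as documented
#' defaults only.
#'
#' @param path FASTA file of reference alleles.
#' @param expected_lengths Optional named vector (names in
#'   `DRB1`,`DQA1`,`DQB1`); when supplied, each locus frame must match.
#' @return A `dla_library`.
#' @export
load_allele_library <- function(path, expected_lengths = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  headers <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(headers, regexec("^DLA-([A-Za-z0-9]+)\\*([A-Za-z0-9]+)$", headers))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("format error: FASTA header '", headers[which(bad)[1]],
         "' does not parse as DLA-<locus>*<name>")
  }
  alleles <- data.frame(
    locus = vapply(m, `[`, "", 2L),
    name = vapply(m, `[`, "", 3L),
    sequence = vapply(as.character(seqs), normalize_sequence, "",
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  lib <- allele_library(alleles, provenance = path)
  if (!is.null(expected_lengths)) {
    for (loc in names(expected_lengths)) {
      lens <- nchar(lib$alleles$sequence[lib$alleles$locus == loc])
      if (length(lens) && any(lens != expected_lengths[[loc]])) {
        stop("alignment-frame error: locus ", loc, " frame is ", lens[1],
             " bp, expected ", expected_lengths[[loc]])
      }
    }
  }
  lib
}

#' Write an allele library to FASTA
#'
#' Inverse of [load_allele_library()]: headers are re-emitted as
#' `DLA-<locus>*<name>` so a load/write cycle round-trips exactly.
#'
#' @param library A `dla_library`.
#' @param path Output FASTA path.
#' @export
write_allele_library <- function(library, path) {
  stopifnot(inherits(library, "dla_library"))
  al <- library$alleles
  seqs <- Biostrings::BStringSet(al$sequence)
  names(seqs) <- paste0("DLA-", al$locus, "*", al$name)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Alleles of a library at one locus
#'
#' @param library A `dla_library`.
#' @param locus One of `"DRB1"`, `"DQA1"`, `"DQB1"`.
#' @return Data frame of `name`, `sequence` rows at that locus.
#' @export
locus_alleles <- function(library, locus) {
  stopifnot(inherits(library, "dla_library"))
  assert_locus(locus)
  al <- library$alleles[library$alleles$locus == locus, , drop = FALSE]
  rownames(al) <- NULL
  al
}

#' @export
print.dla_library <- function(x, ...) {
  cat("DLA allele library (", x$provenance, ")\n", sep = "")
  for (loc in LOCUS_NAMES) {
    al <- locus_alleles(x, loc)
    cat(sprintf("  %s: %d alleles, frame %s bp\n", loc, nrow(al),
                if (nrow(al)) nchar(al$sequence[1]) else "-"))
  }
  invisible(x)
}

# ---- cohort tables ---------------------------------------------------------

SEX_LEVELS <- c("female", "male", "unknown")
STATUS_LEVELS <- c("case", "control")
GRADE_LEVELS <- c("definite", "probable", "possible", "not_applicable")
RELATEDNESS_LEVELS <- c("first_degree", "second_degree", "unrelated", "case")

GENOTYPE_COLS <- c("drb1_1", "drb1_2", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")

locus_cols <- function(locus) {
  paste0(tolower(locus), c("_1", "_2"))
}

#' Load a cohort table
#'
#' Reads a delimited subject table (comma default, tab auto-detected) with
#' required columns `id` and `status` and optional columns `sex`,
#' `diagnostic_grade`, `relatedness_grade`, `age_years` and the six
#' genotype columns `drb1_1`,`drb1_2`,`dqa1_1`,`dqa1_2`,`dqb1_1`,`dqb1_2`
#' (unordered allele names per locus; both or neither per locus).
#'
#' Subject invariants: cases carry a diagnostic grade other than
#' `not_applicable` and relatedness grade `case`; controls carry grade
#' `not_applicable` and a relatedness grade describing their closest
#' affected relative (`first_degree`, `second_degree`, `unrelated`).
#'
#' @param path Delimited text file.
#' @param on_error `"stop"` (default) aborts on the first invalid row with
#'   its row number; `"reject"` returns the valid rows and attaches the
#'   rejected rows (with reasons) as attribute `"rejected"`, so that
#'   accepted + rejected = input rows.
#' @return A validated cohort data frame of class `dla_cohort`.
#' @export
load_cohort <- function(path, on_error = c("stop", "reject")) {
  on_error <- match.arg(on_error)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  as_cohort(raw, on_error = on_error)
}

#' Validate a subject table into a cohort
#'
#' @param x Data frame of subjects (see [load_cohort()] for columns).
#' @param on_error See [load_cohort()].
#' @return A `dla_cohort` data frame.
#' @export
as_cohort <- function(x, on_error = c("stop", "reject")) {
  on_error <- match.arg(on_error)
  need <- c("id", "status")
  if (!all(need %in% names(x))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(x)
  defaults <- list(sex = "unknown", diagnostic_grade = NA_character_,
                   relatedness_grade = NA_character_, age_years = NA)
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- rep(defaults[[col]], length.out = n)
  }
  for (col in GENOTYPE_COLS) {
    if (!col %in% names(x)) x[[col]] <- rep(NA_character_, n)
    x[[col]] <- as.character(x[[col]])
  }
  x$id <- as.character(x$id)
  x$status <- as.character(x$status)
  x$sex <- as.character(x$sex)
  x$age_years <- suppressWarnings(as.numeric(x$age_years))

  # default derived fields, then validate invariants row-wise
  x$diagnostic_grade <- ifelse(is.na(x$diagnostic_grade) & x$status == "control",
                               "not_applicable", as.character(x$diagnostic_grade))
  x$relatedness_grade <- ifelse(is.na(x$relatedness_grade) & x$status == "case",
                                "case", as.character(x$relatedness_grade))

  reason <- rep(NA_character_, n)
  flag <- function(idx, msg) {
    idx <- idx & is.na(reason)
    reason[idx] <<- msg
  }
  flag(!(x$status %in% STATUS_LEVELS), "unknown status token")
  flag(!(x$sex %in% SEX_LEVELS), "unknown sex token")
  flag(!is.na(x$diagnostic_grade) & !(x$diagnostic_grade %in% GRADE_LEVELS),
       "unknown diagnostic_grade token")
  flag(!is.na(x$relatedness_grade) & !(x$relatedness_grade %in% RELATEDNESS_LEVELS),
       "unknown relatedness_grade token")
  flag(x$status == "case" &
         (is.na(x$diagnostic_grade) | x$diagnostic_grade == "not_applicable"),
       "case without a diagnostic grade")
  flag(x$status == "case" &
         (is.na(x$relatedness_grade) | x$relatedness_grade != "case"),
       "case with a control relatedness grade")
  flag(x$status == "control" & x$diagnostic_grade != "not_applicable",
       "control with a diagnostic grade")
  flag(x$status == "control" & x$relatedness_grade == "case",
       "control with relatedness grade 'case'")
  flag(!is.na(x$age_years) & x$age_years < 0, "negative age")
  for (loc in LOCUS_NAMES) {
    cols <- locus_cols(loc)
    flag(xor(is.na(x[[cols[1]]]), is.na(x[[cols[2]]])),
         paste0("half-missing genotype at ", loc))
  }
  dup <- duplicated(x$id) | duplicated(x$id, fromLast = TRUE)
  flag(dup & duplicated(x$id), "duplicate id")

  bad <- !is.na(reason)
  if (any(bad) && on_error == "stop") {
    i <- which(bad)[1]
    stop("invalid cohort row ", i, " (id '", x$id[i], "'): ", reason[i])
  }
  ok <- x[!bad, , drop = FALSE]
  # canonical order within each locus pair so {a,b} == {b,a}
  for (loc in LOCUS_NAMES) {
    cols <- locus_cols(loc)
    a <- ok[[cols[1]]]; b <- ok[[cols[2]]]
    swap <- !is.na(a) & !is.na(b) & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    ok[[cols[1]]] <- a; ok[[cols[2]]] <- b
  }
  keep <- c("id", "sex", "status", "diagnostic_grade", "relatedness_grade",
            "age_years", GENOTYPE_COLS)
  extra <- setdiff(names(ok), keep)
  ok <- ok[, c(keep, extra), drop = FALSE]
  rownames(ok) <- NULL
  class(ok) <- c("dla_cohort", "data.frame")
  if (on_error == "reject") {
    rej <- x[bad, , drop = FALSE]
    rej$reason <- reason[bad]
    rej$row <- which(bad)
    attr(ok, "rejected") <- rej
  }
  ok
}

#' Write a cohort table
#'
#' @param cohort A `dla_cohort` (or compatible data frame).
#' @param path Output path.
#' @param sep Field separator, default comma.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  write.table(as.data.frame(cohort), path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

# TRUE for subjects typed at all three loci
fully_typed <- function(cohort) {
  ok <- rep(TRUE, nrow(cohort))
  for (loc in LOCUS_NAMES) ok <- ok & !is.na(cohort[[locus_cols(loc)[1]]])
  ok
}
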