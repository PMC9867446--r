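#' Sequence input/output, translation and in-silico point mutagenesis
#'
#' A sequence set is represented as a plain `data.frame` with columns `id`,
#' `description` and `sequence` (class `clc_seqs`, attribute `seqtype` either
#' `"protein"` or `"cds"`). All user-facing coordinates are 1-based and
#' inclusive.
#'
#' @name seqio
NULL

new_clc_seqs <- function(id, description, sequence, seqtype) {
  out <- data.frame(id = id, description = description, sequence = sequence,
                    stringsAsFactors = FALSE)
  attr(out, "seqtype") <- seqtype
  class(out) <- c("clc_seqs", "data.frame")
  out
}

#' Assemble a sequence set from vectors
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of sequences (upper-cased on input).
#' @param description optional descriptions (default empty strings).
#' @param seqtype `"protein"` or `"cds"`.
#' @return A `clc_seqs` data frame.
#' @export
clc_seqs <- function(id, sequence, description = rep("", length(id)),
                     seqtype = c("protein", "cds")) {
  seqtype <- match.arg(seqtype)
  stopifnot(length(id) == length(sequence), length(id) == length(description))
  out <- new_clc_seqs(as.character(id), as.character(description),
                      toupper(as.character(sequence)), seqtype)
  validate_clc_seqs(out)
  out
}

validate_clc_seqs <- function(x) {
  if (nrow(x) == 0L) stop("sequence set is empty")
  if (anyDuplicated(x$id))
    stop("duplicate record id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  seqtype <- attr(x, "seqtype")
  allowed <- if (seqtype == "protein") c(STANDARD_AA, "X") else c("A", "C", "G", "T")
  for (i in seq_len(nrow(x))) {
    s <- x$sequence[i]
    if (nchar(s) == 0L) stop("record '", x$id[i], "' has an empty sequence")
    ch <- seq_chars(s)
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop("record '", x$id[i], "': illegal character '", ch[bad[1]],
           "' at position ", bad[1])
  }
  invisible(x)
}

#' Read a FASTA file into a sequence set
#'
#' Wraps `Biostrings::readBStringSet` and layers the package's validation on
#' top: entry order is preserved, case is normalized to upper, and an empty
#' file, duplicate ids or illegal characters are rejected with a message
#' naming the offending record and position. Protein sequences may contain
#' `X` (unknown residue, flagged downstream); other ambiguity codes are
#' rejected rather than coerced.
#'
#' @param path path to a (possibly wrapped) multi-record FASTA file.
#' @param seqtype `"protein"` (20 letters + X) or `"cds"` (ACGT).
#' @return A `clc_seqs` data frame, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path, seqtype = c("protein", "cds")) {
  seqtype <- match.arg(seqtype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  clc_seqs(id, as.character(set), description, seqtype)
}

#' Write a sequence set to FASTA
#'
#' @param x a `clc_seqs` data frame.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "clc_seqs"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (nzchar(x$description[i]))
      paste(x$id[i], x$description[i]) else x$id[i]
    writeLines(paste0(">", header), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

#' Translate a coding sequence with the standard genetic code
#'
#' The CDS must be in frame 1 and of length divisible by 3. Trailing stop
#' codons are trimmed silently; an internal stop codon is a hard error, as is
#' a length not divisible by 3.
#'
#' @param cds a CDS as a single character string over ACGT.
#' @return The translated protein as a character string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- GENETIC_CODE_STD[codons]
  if (anyNA(aa))
    stop("unrecognized codon '", codons[which(is.na(aa))[1]], "' at codon ",
         which(is.na(aa))[1])
  while (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stops <- which(aa == "*")
  if (length(stops))
    stop("internal stop codon at codon ", stops[1])
  if (!length(aa)) stop("CDS translates to an empty protein")
  chars_seq(unname(aa))
}

#' Parse a compact substitution string such as "C544T"
#'
#' @param spec substitution in compact notation: reference base, 1-based CDS
#'   position, alternate base.
#' @return A list with elements `ref`, `pos`, `alt` (class `clc_substitution`).
#' @export
parse_substitution <- function(spec) {
  m <- regmatches(spec, regexec("^([ACGT])([0-9]+)([ACGT])$", toupper(spec)))[[1]]
  if (length(m) != 4L)
    stop("malformed substitution '", spec,
         "': expected <ref><1-based position><alt>, e.g. C544T")
  structure(list(ref = m[2], pos = as.integer(m[3]), alt = m[4]),
            class = "clc_substitution")
}

#' Apply a single-nucleotide substitution to a CDS
#'
#' The stored reference base must match the CDS at the stated position (a
#' guard against coordinate drift); only that position changes. The affected
#' codon index is `ceiling(pos / 3)`.
#'
#' @param cds CDS character string.
#' @param sub a `clc_substitution` (see [parse_substitution()]) or a compact
#'   string such as `"C544T"`.
#' @return The mutated CDS string, with attribute `codon` = affected codon.
#' @export
apply_substitution <- function(cds, sub) {
  if (is.character(sub)) sub <- parse_substitution(sub)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (sub$pos < 1L || sub$pos > n)
    stop("substitution position ", sub$pos, " outside CDS of length ", n)
  have <- substr(cds, sub$pos, sub$pos)
  if (have != sub$ref)
    stop("reference mismatch at position ", sub$pos, ": CDS has '", have,
         "', substitution expects '", sub$ref, "'")
  out <- cds
  substr(out, sub$pos, sub$pos) <- sub$alt
  attr(out, "codon") <- as.integer(ceiling(sub$pos / 3))
  out
}

#' Summarize the protein-level consequence of a CDS substitution
#'
#' @inheritParams apply_substitution
#' @return A list: `codon`, `residue` (codon index), `from`, `to`,
#'   `synonymous`.
#' @export
substitution_consequence <- function(cds, sub) {
  if (is.character(sub)) sub <- parse_substitution(sub)
  mut <- apply_substitution(cds, sub)
  p0 <- translate_cds(cds)
  p1 <- translate_cds(mut)
  codon <- attr(mut, "codon")
  from <- substr(p0, codon, codon)
  to <- substr(p1, codon, codon)
  list(codon = codon, residue = codon, from = from, to = to,
       synonymous = identical(from, to))
}
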