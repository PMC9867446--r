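#' Degenerate motif scanning and sorting-signal detection
#'
#' Motif patterns are written in the field's compact notation: fixed residues
#' as themselves, `x` for any standard residue, `F.` is not needed — the
#' hydrophobic wildcard is written `h` (or the Greek phi in documentation),
#' and bracketed classes such as `[DE]` allow any listed residue. The unknown
#' residue `X` never satisfies a constraint, not even `x`: low-quality
#' positions cannot create hits.
#'
#' @name motifscan
NULL

# conventional YXXphi hydrophobic class; configurable per motif
PHI_DEFAULT <- c("L", "I", "M", "F", "V")

#' Define a degenerate motif
#'
#' @param name motif name.
#' @param pattern pattern string: fixed residues, `x` (any standard residue),
#'   `h` (hydrophobic class), `[..]` residue classes.
#' @param phi residues matched by `h` (default L, I, M, F, V).
#' @return A `clc_motif`: list of per-position allowed-residue sets.
#' @export
motif_def <- function(name, pattern, phi = PHI_DEFAULT) {
  toks <- list()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed '[' in pattern '", pattern, "'")
      cls <- seq_chars(substr(pattern, i + 1L, i + j - 2L))
      if (!all(cls %in% STANDARD_AA))
        stop("invalid residue class in pattern '", pattern, "'")
      toks[[length(toks) + 1L]] <- cls
      i <- i + j
    } else {
      tok <- if (ch == "x") STANDARD_AA
             else if (ch == "h") phi
             else if (ch %in% STANDARD_AA) ch
             else stop("invalid pattern character '", ch, "'")
      toks[[length(toks) + 1L]] <- tok
      i <- i + 1L
    }
  }
  if (length(toks) < 4L) stop("pattern '", pattern, "' shorter than 4 positions")
  if (!any(vapply(toks, length, 1L) == 1L))
    stop("pattern '", pattern, "' has no fixed position")
  structure(list(name = name, pattern = pattern, positions = toks),
            class = "clc_motif")
}

#' The three conserved CLC-family motifs
#'
#' GxGxPE (the selectivity filter; its second residue sets anion
#' preference), GKxGPxxH and PxxGxLF.
#'
#' @return Named list of `clc_motif` objects.
#' @export
clc_motifs <- function() {
  list(GxGxPE   = motif_def("GxGxPE", "GxGxPE"),
       GKxGPxxH = motif_def("GKxGPxxH", "GKxGPxxH"),
       PxxGxLF  = motif_def("PxxGxLF", "PxxGxLF"))
}

#' Cytosolic sorting-signal motifs
#'
#' The tyrosine-based YXXphi signal and the two consensus dileucine signals
#' DXXLL and \[DE\]XXXL\[LI\]. Dileucine clusters with non-consensus
#' surroundings are deliberately not modelled.
#'
#' @param phi hydrophobic class for the YXXphi signal.
#' @return Named list of `clc_motif` objects keyed by signal kind.
#' @export
sorting_motifs <- function(phi = PHI_DEFAULT) {
  list(tyrosine          = motif_def("YXXphi", "Yxxh", phi = phi),
       dileucine_DXXLL   = motif_def("DXXLL", "DxxLL"),
       dileucine_DE_XXXL_LI = motif_def("[DE]XXXL[LI]", "[DE]xxxL[LI]"))
}

#' Load a motif set from a JSON config
#'
#' The shipped default lives at `system.file("extdata", "motifs.json",
#' package = "clcscan")`: an object mapping motif name to pattern string.
#'
#' @param path path to a JSON file of name -> pattern entries.
#' @param phi hydrophobic class for `h` positions.
#' @return Named list of `clc_motif` objects.
#' @export
load_motifs <- function(path, phi = PHI_DEFAULT) {
  defs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(defs), function(nm) motif_def(nm, defs[[nm]], phi = phi))
  setNames(out, names(defs))
}

#' Scan a protein for all (possibly overlapping) matches of a motif
#'
#' Every window satisfying the pattern is reported, left to right;
#' overlapping matches are all kept (downstream layers may deduplicate).
#'
#' @param seq protein sequence as a character string.
#' @param motif a `clc_motif`.
#' @return data.frame with columns `motif`, `start`, `end`, `matched`
#'   (1-based inclusive coordinates); zero rows when nothing matches.
#' @export
scan_motif <- function(seq, motif) {
  stopifnot(inherits(motif, "clc_motif"))
  ch <- seq_chars(toupper(seq))
  m <- length(motif$positions)
  n <- length(ch)
  starts <- integer(0)
  if (n >= m) {
    ok <- rep(TRUE, n - m + 1L)
    for (k in seq_len(m)) {
      ok <- ok & ch[seq_len(n - m + 1L) + k - 1L] %in% motif$positions[[k]]
    }
    starts <- which(ok)
  }
  matched <- if (length(starts)) substring(seq, starts, starts + m - 1L)
             else character(0)
  data.frame(motif = rep(motif$name, length(starts)),
             start = starts, end = starts + m - 1L,
             matched = matched, stringsAsFactors = FALSE)
}

#' Scan a protein for several motifs at once
#'
#' @param seq protein sequence string.
#' @param motifs list of `clc_motif` objects (default [clc_motifs()]).
#' @return Row-bound hits of [scan_motif()], ordered by motif then start.
#' @export
scan_motifs <- function(seq, motifs = clc_motifs()) {
  do.call(rbind, lapply(motifs, function(m) scan_motif(seq, m)))
}

#' Find cytosolic sorting signals in the terminal domains
#'
#' Signals are biologically meaningful only where the chain is cytosolic, so
#' the search is restricted to the N-terminal window `[1, n_limit]` and the
#' C-terminal window `[c_limit, length]`. A hit must lie entirely inside a
#' window; hits strictly between the limits are not reported.
#'
#' @param seq protein sequence string.
#' @param n_limit last position of the N-terminal window.
#' @param c_limit first position of the C-terminal window; default places a
#'   window of the same width as the N-terminal one at the C-terminus.
#' @param phi hydrophobic class for YXXphi.
#' @return data.frame with columns `kind`, `start`, `end`, `matched`,
#'   `terminus` (`"N"` or `"C"`).
#' @export
find_sorting_signals <- function(seq, n_limit = 120L, c_limit = NULL,
                                 phi = PHI_DEFAULT) {
  len <- nchar(seq)
  c_limit <- c_limit %||% max(1L, len - n_limit + 1L)
  if (n_limit < 1L || n_limit > len) stop("n_limit out of range")
  if (c_limit < 1L || c_limit > len) stop("c_limit out of range")
  if (n_limit >= c_limit && len > n_limit) stop("n_limit must be < c_limit")
  defs <- sorting_motifs(phi = phi)
  out <- list()
  for (kind in names(defs)) {
    hits <- scan_motif(seq, defs[[kind]])
    if (!nrow(hits)) next
    in_n <- hits$end <= n_limit
    in_c <- hits$start >= c_limit
    keep <- in_n | in_c
    if (!any(keep)) next
    h <- hits[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      kind = kind, start = h$start, end = h$end, matched = h$matched,
      terminus = ifelse(h$end <= n_limit, "N", "C"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      terminus = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$terminus <- ifelse(res$end <= n_limit, "N", "C")
  rownames(res) <- NULL
  res[order(res$start, res$kind), , drop = FALSE]
}
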