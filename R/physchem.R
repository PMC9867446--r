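#' Physicochemical summaries and hydropathy-based topology sketch
#'
#' Mass uses average isotopic residue masses plus one water; GRAVY is the
#' arithmetic mean of Kyte-Doolittle hydropathy values; pI solves
#' net-charge(pH) = 0 by bisection under a per-group Henderson-Hasselbalch
#' model with the Bjellqvist (ExPASy-style) pKa set. The transmembrane
#' sketch is a classic sliding-window hydropathy caller, an explicit
#' approximation of dedicated topology predictors.
#'
#' @name physchem
NULL

check_standard <- function(seq, what) {
  ch <- seq_chars(toupper(seq))
  bad <- which(!ch %in% STANDARD_AA)
  if (length(bad))
    stop(what, ": unknown residue '", ch[bad[1]], "' at position ", bad[1])
  ch
}

#' Protein mass in kilodaltons
#'
#' Sum of average residue masses plus one water molecule.
#'
#' @param seq protein sequence string (standard 20 residues; `X` is an
#'   error naming the position).
#' @return Mass in kDa.
#' @export
compute_mass <- function(seq) {
  ch <- check_standard(seq, "compute_mass")
  (sum(AA_MASS_AVG[ch]) + WATER_MASS_AVG) / 1000
}

#' Grand average of hydropathy (GRAVY)
#'
#' @inheritParams compute_mass
#' @return Mean Kyte-Doolittle value, in `[-4.5, 4.5]`.
#' @export
compute_gravy <- function(seq) {
  ch <- check_standard(seq, "compute_gravy")
  mean(KYTE_DOOLITTLE[ch])
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch per ionizable group: side chains D, E, C, Y, H, K,
#' R and the free termini, Bjellqvist pKa set. `X` residues contribute no
#' charge.
#'
#' @param seq protein sequence string.
#' @param ph pH value (vectorized).
#' @return Net charge at each `ph`.
#' @export
net_charge <- function(seq, ph) {
  ch <- seq_chars(toupper(seq))
  counts <- table(factor(ch, levels = names(PKA_SIDE)))
  pos_pka <- c(PKA_SIDE[["H"]], PKA_SIDE[["K"]], PKA_SIDE[["R"]],
               nterm_pka(ch[1]))
  pos_n <- c(counts[["H"]], counts[["K"]], counts[["R"]], 1)
  neg_pka <- c(PKA_SIDE[["D"]], PKA_SIDE[["E"]], PKA_SIDE[["C"]],
               PKA_SIDE[["Y"]], PKA_CTERM)
  neg_n <- c(counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]], 1)
  vapply(ph, function(p) {
    sum(pos_n / (1 + 10 ^ (p - pos_pka))) -
      sum(neg_n / (1 + 10 ^ (neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Net charge is strictly decreasing in pH and changes sign on `[0, 14]`,
#' so bisection converges to the unique root.
#'
#' @param seq protein sequence string.
#' @param tol stop when `|charge| < tol` (default 1e-4).
#' @return pI in pH units.
#' @export
compute_pi <- function(seq, tol = 1e-4) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Centered moving average; the `(window-1)/2` positions at each end are
#' truncated, so the profile has `length - window + 1` values and value `i`
#' describes the window centered at sequence position `i + (window-1)/2`.
#'
#' @param seq protein sequence string.
#' @param window odd window width, at most the sequence length.
#' @return Numeric vector with attribute `offset` (= `(window-1)/2`).
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  ch <- check_standard(seq, "hydropathy_profile")
  n <- length(ch)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  vals <- unname(KYTE_DOOLITTLE[ch])
  cs <- c(0, cumsum(vals))
  prof <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  attr(prof, "offset") <- (window - 1L) %/% 2L
  prof
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of profile values at or above `threshold` become candidate
#' segments; runs separated by a gap of at most `merge_gap` positions are
#' merged; segments shorter than `min_span` (in window-center positions)
#' are dropped. Coordinates are reported on the original sequence, spanning
#' the full windows of the run.
#'
#' @param profile output of [hydropathy_profile()].
#' @param threshold hydropathy threshold (default 1.6, classic calling).
#' @param min_span minimum run length in profile positions (default 10).
#' @param merge_gap merge runs separated by at most this many positions
#'   (default 3).
#' @return data.frame `start`, `end` (sequence coordinates),
#'   `mean_hydropathy`.
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_span = 10L,
                                merge_gap = 3L) {
  off <- attr(profile, "offset") %||% 0L
  above <- profile >= threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short sub-threshold gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_span, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(start = merged$start,
             end = merged$end + 2L * off,
             mean_hydropathy = vapply(seq_len(nrow(merged)), function(i) {
               mean(profile[merged$start[i]:merged$end[i]])
             }, numeric(1)))
}

#' All Table-style physicochemical numbers for one protein
#'
#' @param seq protein sequence string.
#' @return list: `length`, `mass_kda` (0.1 kDa precision in reports),
#'   `pi`, `gravy`.
#' @export
physchem_summary <- function(seq) {
  list(length = nchar(seq),
       mass_kda = compute_mass(seq),
       pi = compute_pi(seq),
       gravy = compute_gravy(seq))
}
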