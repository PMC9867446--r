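#' Synthetic CLC-like proteins with ground truth
#'
#' The generator emulates the architecture the analysis assumes: a
#' cytosolic N-terminal domain carrying sorting signals, a membrane core of
#' hydrophobic transmembrane helices separated by polar linkers that host
#' the three conserved CLC motifs and the gating/proton glutamates, and a
#' hydrophilic C-terminal domain with two CBS copies and further signals.
#' Every planted feature is returned as a ground-truth table, generators
#' are pure functions of (blueprint, seed), and spurious (unplanned)
#' matches of any modelled motif are scrubbed so planted-feature recovery
#' is an exact assertion.
#'
#' @name synthdata
NULL

# background compositions: membrane-protein-like hydrophobic core and a
# polar loop/terminal composition
TM_COMPOSITION <- c(L = 0.30, I = 0.20, V = 0.20, F = 0.15, A = 0.10,
                    M = 0.05)
POLAR_COMPOSITION <- c(S = 0.12, T = 0.10, N = 0.09, Q = 0.09, D = 0.10,
                       E = 0.10, K = 0.11, R = 0.09, G = 0.09, P = 0.05,
                       H = 0.04, A = 0.02)

sample_comp <- function(n, comp) {
  if (n == 0L) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

# fixed synthetic CBS reference segments (deterministic; labelled synthetic)
#' Synthetic CBS1/CBS2 reference segments
#'
#' Two fixed 50-residue segments generated deterministically, used as the
#' packaged CBS references in the synthetic bundle. They are stand-ins for
#' real CBS-domain sequences, which cannot be bundled.
#'
#' @return Named character vector `CBS1`, `CBS2`.
#' @export
synthetic_cbs_segments <- function() {
  with_local_seed(20230104, {
    c(CBS1 = chars_seq(sample_comp(50L, POLAR_COMPOSITION)),
      CBS2 = chars_seq(sample_comp(50L, POLAR_COMPOSITION)))
  })
}

#' Blueprint for a synthetic CLC-like protein
#'
#' Defaults describe the stated world: a 120-residue cytosolic N-terminus,
#' twelve 21-residue transmembrane helices separated by 12-residue polar
#' linkers, and a 180-residue hydrophilic C-terminus (684 residues total,
#' inside the 587-811 range of real family members).
#'
#' @param filter_residue2 `"P"` (nitrate), `"S"` (chloride) or `NA`
#'   (degenerate filter: the literal `SSKSSQ` replaces the motif, so no
#'   GxGxPE match exists).
#' @param gating_glutamate,proton_glutamate plant `E` at the anchor
#'   position (`FALSE` plants `A` / `T` respectively, the absent states
#'   seen in real family members).
#' @param tm_count,tm_len,linker_len,n_term_len,c_term_len architecture.
#' @param cbs_copies 0, 1 (CBS1 only) or 2.
#' @param sorting_n,sorting_c signal kinds to plant in the N-/C-terminal
#'   windows (subset of `"tyrosine"`, `"dileucine_DXXLL"`,
#'   `"dileucine_DE_XXXL_LI"`).
#' @param divergence fraction of background positions randomized relative
#'   to the shared background (default 0.05, a close paralog).
#' @param background_seed seed for the shared background; blueprints with
#'   equal `background_seed` and architecture are mutually alignable.
#' @param seed seed for feature divergence and scrubbing.
#' @return A `clc_blueprint` list.
#' @export
clc_blueprint <- function(filter_residue2 = "P",
                          gating_glutamate = TRUE, proton_glutamate = TRUE,
                          tm_count = 12L, tm_len = 21L, linker_len = 12L,
                          n_term_len = 120L, c_term_len = 180L,
                          cbs_copies = 2L,
                          sorting_n = "tyrosine",
                          sorting_c = "dileucine_DE_XXXL_LI",
                          divergence = 0.05,
                          background_seed = 42L, seed = 1L) {
  if (!is.na(filter_residue2) && !filter_residue2 %in% c("P", "S"))
    stop("filter_residue2 must be 'P', 'S' or NA")
  if (tm_count < 5L) stop("need at least 5 transmembrane helices to host the motifs")
  if (linker_len < 10L) stop("linker_len must be >= 10 to host the motifs")
  if (n_term_len < 20L || c_term_len < 120L)
    stop("terminal domains too short for the planted features")
  structure(list(filter_residue2 = filter_residue2,
                 gating_glutamate = gating_glutamate,
                 proton_glutamate = proton_glutamate,
                 tm_count = as.integer(tm_count), tm_len = as.integer(tm_len),
                 linker_len = as.integer(linker_len),
                 n_term_len = as.integer(n_term_len),
                 c_term_len = as.integer(c_term_len),
                 cbs_copies = as.integer(cbs_copies),
                 sorting_n = sorting_n, sorting_c = sorting_c,
                 divergence = divergence,
                 background_seed = as.integer(background_seed),
                 seed = as.integer(seed)),
            class = "clc_blueprint")
}

SIGNAL_INSTANCES <- c(tyrosine = "YSTL",
                      dileucine_DXXLL = "DPKLL",
                      dileucine_DE_XXXL_LI = "DEESLL")

blueprint_length <- function(bp) {
  bp$n_term_len + bp$tm_count * bp$tm_len +
    (bp$tm_count - 1L) * bp$linker_len + bp$c_term_len
}

# block coordinates of the architecture (1-based inclusive)
blueprint_layout <- function(bp) {
  tm_start <- bp$n_term_len +
    (seq_len(bp$tm_count) - 1L) * (bp$tm_len + bp$linker_len) + 1L
  linker_start <- tm_start[-bp$tm_count] + bp$tm_len
  list(n_term = c(1L, bp$n_term_len),
       tm = cbind(start = tm_start, end = tm_start + bp$tm_len - 1L),
       linker = cbind(start = linker_start,
                      end = linker_start + bp$linker_len - 1L),
       c_term = c(tail(tm_start, 1L) + bp$tm_len, blueprint_length(bp)))
}

scrub_motifs <- function(ch, planted, phi = PHI_DEFAULT, max_pass = 25L) {
  # remove unplanned matches of every modelled motif by rewriting one fixed
  # position of each spurious window (outside planted features)
  defs <- c(clc_motifs(), sorting_motifs(phi = phi))
  protected <- rep(FALSE, length(ch))
  for (i in seq_len(nrow(planted)))
    protected[planted$start[i]:planted$end[i]] <- TRUE
  for (pass in seq_len(max_pass)) {
    dirty <- FALSE
    s <- chars_seq(ch)
    for (d in defs) {
      hits <- scan_motif(s, d)
      for (k in seq_len(nrow(hits))) {
        st <- hits$start[k]
        en <- hits$end[k]
        if (any(protected[st:en]) &&
            any(planted$start == st & planted$end == en)) next
        if (all(protected[st:en])) next  # inside a planted block; leave
        fixed <- which(vapply(d$positions, length, 1L) == 1L)
        target <- NA_integer_
        for (f in fixed) {
          if (!protected[st + f - 1L]) { target <- st + f - 1L; break }
        }
        if (is.na(target)) next
        # replacements can satisfy no fixed position, no residue class and
        # no hydrophobic phi position of any modelled motif, so a rewrite
        # never creates a new match elsewhere
        forbidden <- unique(unlist(lapply(defs, function(dd)
          unlist(dd$positions[vapply(dd$positions, length, 1L) == 1L]))))
        repl <- setdiff(c("S", "T", "N", "Q", "A"), forbidden)
        ch[target] <- sample(repl, 1L)
        dirty <- TRUE
      }
      if (dirty) break
    }
    if (!dirty) return(ch)
  }
  stop("could not scrub spurious motif matches")
}

#' Generate a synthetic CLC-like protein with ground truth
#'
#' Deterministic given the blueprint (background from `background_seed`,
#' feature divergence and scrubbing from `seed`). The ground-truth table
#' lists every planted feature with 1-based coordinates.
#'
#' @param bp a [clc_blueprint()].
#' @param id record id (default `"SYN1"`).
#' @return list: `record` (one-row protein `clc_seqs`), `truth`
#'   (data.frame `feature`, `start`, `end`, `detail`).
#' @export
generate_clc_protein <- function(bp, id = "SYN1") {
  stopifnot(inherits(bp, "clc_blueprint"))
  lay <- blueprint_layout(bp)
  len <- blueprint_length(bp)

  ch <- with_local_seed(bp$background_seed, {
    out <- character(len)
    out[lay$n_term[1]:lay$n_term[2]] <-
      sample_comp(bp$n_term_len, POLAR_COMPOSITION)
    for (i in seq_len(bp$tm_count))
      out[lay$tm[i, "start"]:lay$tm[i, "end"]] <-
        sample_comp(bp$tm_len, TM_COMPOSITION)
    for (i in seq_len(bp$tm_count - 1L))
      out[lay$linker[i, "start"]:lay$linker[i, "end"]] <-
        sample_comp(bp$linker_len, POLAR_COMPOSITION)
    out[lay$c_term[1]:lay$c_term[2]] <-
      sample_comp(lay$c_term[2] - lay$c_term[1] + 1L, POLAR_COMPOSITION)
    out
  })

  truth <- data.frame(feature = character(0), start = integer(0),
                      end = integer(0), detail = character(0),
                      stringsAsFactors = FALSE)
  plant <- function(feature, start, instance, detail = instance) {
    stopifnot(start >= 1L, start + nchar(instance) - 1L <= len)
    ch[start:(start + nchar(instance) - 1L)] <<- seq_chars(instance)
    truth <<- rbind(truth, data.frame(
      feature = feature, start = start,
      end = start + nchar(instance) - 1L, detail = detail,
      stringsAsFactors = FALSE))
  }

  # conserved motifs and glutamates live in the inter-helix linkers
  filter_inst <- if (is.na(bp$filter_residue2)) "SSKSSQ"
                 else paste0("G", bp$filter_residue2, "GIPE")
  plant(if (is.na(bp$filter_residue2)) "filter_degenerate" else "GxGxPE",
        lay$linker[1, "start"] + 2L, filter_inst,
        detail = if (is.na(bp$filter_residue2)) "degenerate"
                 else bp$filter_residue2)
  plant("gating_glutamate", lay$linker[2, "start"] + 5L,
        if (bp$gating_glutamate) "E" else "A",
        detail = if (bp$gating_glutamate) "present" else "absent")
  plant("GKxGPxxH", lay$linker[3, "start"] + 2L, "GKEGPSVH")
  plant("proton_glutamate", lay$linker[4, "start"] + 5L,
        if (bp$proton_glutamate) "E" else "T",
        detail = if (bp$proton_glutamate) "present" else "absent")
  plant("PxxGxLF", lay$linker[5, "start"] + 2L, "PDNGSLF")

  for (kind in bp$sorting_n)
    plant(paste0("signal_", kind), 8L + 7L * (match(kind, bp$sorting_n) - 1L),
          SIGNAL_INSTANCES[[kind]], detail = "N")
  for (kind in bp$sorting_c)
    plant(paste0("signal_", kind),
          len - 20L + 7L * (match(kind, bp$sorting_c) - 1L),
          SIGNAL_INSTANCES[[kind]], detail = "C")

  cbs <- synthetic_cbs_segments()
  if (bp$cbs_copies >= 1L)
    plant("CBS1", lay$c_term[1] + 20L, cbs[["CBS1"]])
  if (bp$cbs_copies >= 2L)
    plant("CBS2", lay$c_term[1] + 90L, cbs[["CBS2"]])

  for (i in seq_len(nrow(lay$tm)))
    truth <- rbind(truth, data.frame(
      feature = "tm_segment", start = lay$tm[i, "start"],
      end = lay$tm[i, "end"], detail = as.character(i),
      stringsAsFactors = FALSE))

  ch <- with_local_seed(bp$seed, {
    protected <- rep(FALSE, len)
    for (i in which(truth$feature != "tm_segment"))
      protected[truth$start[i]:truth$end[i]] <- TRUE
    if (bp$divergence > 0) {
      free <- which(!protected)
      flip <- free[runif(length(free)) < bp$divergence]
      for (p in flip) {
        comp <- if (any(p >= lay$tm[, "start"] & p <= lay$tm[, "end"]))
          TM_COMPOSITION else POLAR_COMPOSITION
        ch[p] <- sample_comp(1L, comp)
      }
    }
    scrub_motifs(ch, truth[truth$feature != "tm_segment", , drop = FALSE])
  })

  list(record = clc_seqs(id, chars_seq(ch), seqtype = "protein"),
       truth = truth)
}

#' Reverse-translate a protein, sampling synonymous codons uniformly
#'
#' @param prot protein sequence string (standard residues only).
#' @param seed RNG seed.
#' @return A CDS string; [translate_cds()] inverts it exactly.
#' @export
reverse_translate <- function(prot, seed) {
  ch <- check_standard(prot, "reverse_translate")
  codons_by_aa <- split(names(GENETIC_CODE_STD), unname(GENETIC_CODE_STD))
  with_local_seed(seed, {
    chars_seq(vapply(ch, function(aa) {
      cands <- codons_by_aa[[aa]]
      cands[sample.int(length(cands), 1L)]
    }, character(1)))
  })
}

#' Simulate JTT evolution of a protein along a tree
#'
#' Site-independent substitution under the model, no indels: leaf
#' sequences come back aligned by construction. Deterministic given seed.
#'
#' @param root protein sequence string at the root (standard residues).
#' @param tree rooted or unrooted `ape::phylo` with branch lengths.
#' @param model a `clc_jtt`.
#' @param seed RNG seed.
#' @return Named character vector of leaf sequences.
#' @export
simulate_evolution <- function(root, tree, model = jtt_model(), seed) {
  if (missing(seed)) stop("simulate_evolution requires an explicit seed")
  idx <- aa_index(root)
  if (anyNA(idx)) stop("root sequence must use the 20 standard residues")
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  root_node <- tr$edge[nrow(tr$edge), 1]
  states <- vector("list", ntip + tr$Nnode)
  states[[root_node]] <- idx
  with_local_seed(seed, {
    for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder traversal
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      ps <- states[[parent]]
      if (t <= 0) {
        states[[child]] <- ps
      } else {
        P <- jtt_transition_matrix(model, t)
        cs <- integer(length(ps))
        for (s in unique(ps)) {
          at <- which(ps == s)
          cs[at] <- sample.int(20L, length(at), replace = TRUE, prob = P[s, ])
        }
        states[[child]] <- cs
      }
    }
  })
  leaves <- vapply(seq_len(ntip), function(i)
    chars_seq(AA_PAML[states[[i]]]), character(1))
  setNames(leaves, tr$tip.label)
}
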