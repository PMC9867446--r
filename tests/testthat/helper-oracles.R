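# Independent oracles used across the suite. Deliberately naive: these
# re-derive expected values by enumeration or direct definition, sharing no
# code path with the implementation they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- motif scanning: character-by-character sliding window ---------------
naive_scan <- function(seq, motif) {
  ch <- strsplit(seq, "")[[1]]
  m <- length(motif$positions)
  hits <- integer(0)
  if (length(ch) >= m) {
    for (s in 1:(length(ch) - m + 1)) {
      ok <- TRUE
      for (k in 1:m) {
        if (!(ch[s + k - 1] %in% motif$positions[[k]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

# --- alignment: exhaustive enumeration of gapped alignments --------------
# Affine cost: each maximal gap run costs gap_open + len * gap_extend,
# terminal gaps included (matches the global aligner's convention).
align_oracle_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j, state + 1L])) return(memo[i, j, state + 1L])
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {   # gap in b
      pen <- gap_extend + if (state == 1L) 0 else gap_open
      best <- max(best, -pen + rec(i + 1L, j, 1L))
    }
    if (j <= m) {   # gap in a
      pen <- gap_extend + if (state == 2L) 0 else gap_open
      best <- max(best, -pen + rec(i, j + 1L, 2L))
    }
    memo[i, j, state + 1L] <<- best
    best
  }
  rec(1L, 1L, 0L)
}

# --- isoelectric point: fine grid scan over the definition ---------------
pi_grid_oracle <- function(seq, step = 0.001) {
  grid <- seq(0, 14, by = step)
  q <- clcscan::net_charge(seq, grid)
  grid[which.min(abs(q))]
}

# --- hydropathy profile: direct window means -----------------------------
profile_oracle <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  v <- kd[strsplit(seq, "")[[1]]]
  n <- length(v)
  sapply(1:(n - window + 1), function(i) mean(v[i:(i + window - 1)]))
}

# --- tree likelihood: brute-force sum over internal-state assignments ----
# Works on any ape::phylo; exponential in the number of internal nodes.
loglik_enumeration_oracle <- function(tree, alignment, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- sort(unique(tr$edge[, 1]))
  seqs <- lapply(alignment[tr$tip.label], function(s) {
    match(strsplit(s, "")[[1]], AA20)
  })
  nsites <- length(seqs[[1]])
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
    jtt_transition_matrix(model, tr$edge.length[e]))
  total <- 0
  for (site in seq_len(nsites)) {
    lik <- 0
    grid <- do.call(expand.grid, rep(list(1:20), length(internals)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= ntip) seqs[[node]][site]
        else grid[g, match(node, internals)]
      }
      p <- unname(model$pi[assign_state(root)])
      for (e in seq_len(nrow(tr$edge))) {
        p <- p * Ps[[e]][assign_state(tr$edge[e, 1]),
                         assign_state(tr$edge[e, 2])]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# --- distances: path lengths on a tree (additive matrix constructor) -----
additive_matrix <- function(tree) ape::cophenetic.phylo(tree)

# unrooted topology equality
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
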