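#' JTT maximum-likelihood phylogenetics
#'
#' The Jones-Taylor-Thornton empirical amino-acid model drives everything:
#' transition matrices P(t) via a symmetrized eigendecomposition of the
#' rate matrix Q, pairwise maximum-likelihood distances, neighbor-joining
#' starting trees, Felsenstein-pruning log-likelihoods (uniform rates, gaps
#' as missing data), a deterministic NNI hill-climb, nonparametric
#' bootstrap supports, and assignment of taxa to the eukaryotic (I) /
#' prokaryotic (II) CLC subgroups from anchor leaves.
#'
#' The JTT exchangeabilities and stationary frequencies are read from the
#' phangorn installation at run time (the published Jones-Taylor-Thornton
#' values in PAML order); rows of Q sum to zero and the chain is reversible,
#' which the test suite asserts.
#'
#' @name phylo
NULL

.clcscan_cache <- new.env(parent = emptyenv())

#' The JTT substitution model
#'
#' @return A `clc_jtt` list: `pi` (stationary frequencies), `Q` (rate
#'   matrix scaled to one expected substitution per unit time), and the
#'   symmetrized eigendecomposition (`values`, `vectors`, `inv`) used to
#'   compute P(t). States follow PAML order `ARNDCQEGHILKMFPSTWYV`.
#' @export
jtt_model <- function() {
  if (!is.null(.clcscan_cache$jtt)) return(.clcscan_cache$jtt)
  raw <- get(".JTT", envir = asNamespace("phangorn"))
  pi <- unname(raw$bf)
  n <- 20L
  S <- matrix(0, n, n, dimnames = list(AA_PAML, AA_PAML))
  S[lower.tri(S)] <- raw$Q          # column-wise lower triangle
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))       # expected substitutions per unit time
  Q <- Q / scale
  # symmetrize: B = D^{1/2} Q D^{-1/2} with D = diag(pi) is symmetric
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  model <- structure(list(
    pi = setNames(pi, AA_PAML), Q = Q,
    values = eig$values,
    vectors = diag(1 / d) %*% eig$vectors,
    inv = t(eig$vectors) %*% diag(d)), class = "clc_jtt")
  .clcscan_cache$jtt <- model
  model
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `clc_jtt` from [jtt_model()].
#' @param t nonnegative branch length (expected substitutions per site).
#' @return 20x20 row-stochastic matrix in PAML state order.
#' @export
jtt_transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length t must be nonnegative")
  P <- model$vectors %*% (exp(model$values * t) * model$inv)
  dimnames(P) <- list(AA_PAML, AA_PAML)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P
}

aa_index <- function(seq) {
  idx <- match(seq_chars(toupper(seq)), AA_PAML)
  idx
}

# 20x20 table of aligned residue-pair counts (pairwise deletion of columns
# with a gap or nonstandard residue on either side)
pair_counts <- function(a, b) {
  ia <- aa_index(a)
  ib <- aa_index(b)
  if (length(ia) != length(ib))
    stop("sequences must have equal (aligned) length")
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no shared ungapped columns")
  matrix(tabulate(ia[keep] + 20L * (ib[keep] - 1L), nbins = 400L), 20L, 20L)
}

#' Maximum-likelihood pairwise distance under JTT
#'
#' Maximizes `sum_sites log(pi_x P_xy(t))` over `t` by bounded 1-D
#' optimization (identical sequences return 0 exactly). Gap or nonstandard
#' columns are dropped pairwise.
#'
#' @param a,b aligned protein sequences (equal length strings).
#' @param model a `clc_jtt`.
#' @param t_max upper search bound (default 10).
#' @return Distance in expected substitutions per site.
#' @export
ml_pairwise_distance <- function(a, b, model = jtt_model(), t_max = 10) {
  counts <- pair_counts(a, b)
  if (sum(counts) == sum(diag(counts))) return(0)
  logpi <- log(model$pi)
  nll <- function(t) {
    P <- jtt_transition_matrix(model, t)
    -sum(counts * (log(pmax(P, 1e-300)) + logpi))
  }
  opt <- optimize(nll, c(1e-8, t_max), tol = 1e-8)
  opt$minimum
}

#' All pairwise ML distances of an alignment
#'
#' @param alignment named character vector of equal-length aligned protein
#'   sequences.
#' @param model a `clc_jtt`.
#' @return Symmetric distance matrix with zero diagonal, taxa as dimnames.
#' @export
ml_distance_matrix <- function(alignment, model = jtt_model()) {
  taxa <- names(alignment)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("alignment must carry unique taxon names")
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        ml_pairwise_distance(alignment[[i]], alignment[[j]], model)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (`ape::nj`); taxa are sorted by label first so
#' ties are broken deterministically by taxon-label order. Negative branch
#' lengths arising from noise are clamped to zero.
#'
#' @param d symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  ord <- order(rownames(d))
  tree <- ape::nj(d[ord, ord])
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# per-leaf 20 x nsites likelihood surfaces; gap/X = all-ones (missing data)
leaf_likelihoods <- function(alignment) {
  lapply(alignment, function(s) {
    idx <- aa_index(s)
    L <- matrix(0, 20L, length(idx))
    known <- which(!is.na(idx))
    L[cbind(idx[known], known)] <- 1
    L[, is.na(idx)] <- 1
    L
  })
}

#' Log-likelihood of a tree by Felsenstein pruning
#'
#' Sites are independent with uniform rates; gaps and `X` are missing data;
#' the root sum is weighted by the stationary frequencies, so the value is
#' invariant to root placement on an unrooted tree (pulley principle).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param alignment named character vector of aligned sequences covering
#'   the tree's leaves.
#' @param model a `clc_jtt`.
#' @return Total log-likelihood.
#' @export
tree_log_likelihood <- function(tree, alignment, model = jtt_model()) {
  missing <- setdiff(tree$tip.label, names(alignment))
  if (length(missing))
    stop("alignment lacks tree leaves: ", paste(missing, collapse = ", "))
  leafL <- leaf_likelihoods(alignment[tree$tip.label])
  nsites <- ncol(leafL[[1]])
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) partial[[i]] <- leafL[[i]]
  scale_log <- 0
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    P <- jtt_transition_matrix(model, tr$edge.length[e])
    msg <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- msg
    } else {
      partial[[parent]] <- partial[[parent]] * msg
      # rescale to avoid underflow on long alignments
      m <- apply(partial[[parent]], 2, max)
      m[m == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, m, "/")
      scale_log <- scale_log + sum(log(m))
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sum(log(colSums(model$pi * partial[[root]]))) + scale_log
}

# optimize each branch length in turn (coordinate-wise), a few sweeps
optimize_branch_lengths <- function(tree, alignment, model = jtt_model(),
                                    sweeps = 2L, t_max = 10) {
  for (s in seq_len(sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tree$edge.length[e] <- t
        -tree_log_likelihood(tree, alignment, model)
      }
      tree$edge.length[e] <- optimize(f, c(0, t_max), tol = 1e-4)$minimum
    }
  }
  tree
}

#' Hill-climbing NNI search for the maximum-likelihood tree
#'
#' In each round every nearest-neighbor-interchange neighbor of the current
#' tree (via `phangorn::nni`) is scored after a coordinate-wise branch
#' length re-optimization; the best strictly improving neighbor is
#' accepted. Stops at a local optimum or after `max_rounds`. Deterministic:
#' ties keep the incumbent, neighbors are scored in generation order.
#'
#' @param tree starting `ape::phylo` (e.g. from [build_nj_tree()]).
#' @param alignment named character vector of aligned sequences.
#' @param model a `clc_jtt`.
#' @param max_rounds maximum accepted moves (default 10).
#' @param bl_sweeps branch-length sweeps per candidate (default 1).
#' @return list: `tree` (branch lengths re-optimized), `loglik`, `rounds`.
#' @export
nni_search <- function(tree, alignment, model = jtt_model(),
                       max_rounds = 10L, bl_sweeps = 1L) {
  cur <- optimize_branch_lengths(tree, alignment, model, sweeps = bl_sweeps)
  cur_ll <- tree_log_likelihood(cur, alignment, model)
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) break
    neighbors <- phangorn::nni(cur)
    best <- NULL
    best_ll <- cur_ll
    for (k in seq_along(neighbors)) {
      nb <- neighbors[[k]]   # [[ restores tip labels on compressed multiPhylo
      nb$edge.length <- rep(mean(cur$edge.length), nrow(nb$edge))
      nb <- optimize_branch_lengths(nb, alignment, model, sweeps = bl_sweeps)
      ll <- tree_log_likelihood(nb, alignment, model)
      if (ll > best_ll + 1e-9) {
        best <- nb
        best_ll <- ll
      }
    }
    if (is.null(best)) break
    cur <- best
    cur_ll <- best_ll
    rounds <- rounds + 1L
  }
  list(tree = cur, loglik = cur_ll, rounds = rounds)
}

#' Nonparametric bootstrap supports on a reference tree
#'
#' Alignment columns are resampled with replacement; each replicate tree is
#' neighbor joining on JTT ML distances (a documented, desk-scale stand-in
#' for a full ML search per replicate). Support for each internal edge of
#' the reference tree is the percentage of replicate trees containing the
#' corresponding split. Bit-reproducible for a fixed seed.
#'
#' @param alignment named character vector of aligned sequences (>= 4).
#' @param model a `clc_jtt`.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed (mandatory: resampling is stochastic).
#' @param reference_tree optional reference `phylo`; default is NJ on the
#'   full-alignment ML distances.
#' @return list: `tree` (reference tree with `node.label` = support, in
#'   percent of replicates), `replicate_trees`.
#' @export
bootstrap_support <- function(alignment, model = jtt_model(),
                              replicates = 100L, seed,
                              reference_tree = NULL) {
  if (missing(seed)) stop("bootstrap_support requires an explicit seed")
  if (replicates < 1L) stop("replicates must be >= 1")
  nsites <- nchar(alignment[[1]])
  chars <- lapply(alignment, seq_chars)
  ref <- reference_tree %||% build_nj_tree(ml_distance_matrix(alignment, model))
  reps <- with_local_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      cols <- sample.int(nsites, nsites, replace = TRUE)
      boot <- vapply(chars, function(ch) chars_seq(ch[cols]), character(1))
      build_nj_tree(ml_distance_matrix(boot, model))
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / replicates, 1)
  ref$node.label <- support
  list(tree = ref, replicate_trees = reps)
}

tree_splits <- function(tree) {
  # list of leaf-label sets, one per internal edge (side not containing
  # the first tip)
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  lapply(which(internal), function(e) {
    node <- tree$edge[e, 2]
    tips <- ape::extract.clade(tree, node)$tip.label
    sort(tips)
  })
}

#' Assign taxa to subgroup I or II from anchor leaves
#'
#' Subgroup I is the eukaryotic CLC branch (AtCLCa-d, AtCLCg homologs),
#' subgroup II the prokaryotic one (AtCLCe/AtCLCf homologs). Among the
#' internal edges that separate all subgroup-I anchors from all subgroup-II
#' anchors, the most balanced ("deepest") split is chosen; every non-anchor
#' taxon is assigned to the subgroup whose anchors share its side.
#'
#' @param tree an `ape::phylo`.
#' @param anchors_I,anchors_II non-empty character vectors of anchor leaf
#'   labels, each present in the tree.
#' @return Named character vector over all leaves with values `"I"` or
#'   `"II"`.
#' @export
assign_subgroup <- function(tree, anchors_I, anchors_II) {
  tips <- tree$tip.label
  if (!length(anchors_I) || !length(anchors_II))
    stop("both anchor sets must be non-empty")
  missing <- setdiff(c(anchors_I, anchors_II), tips)
  if (length(missing))
    stop("anchor leaves not in tree: ", paste(missing, collapse = ", "))
  splits <- tree_splits(tree)
  separating <- Filter(function(s) {
    inI <- anchors_I %in% s
    inII <- anchors_II %in% s
    (all(inI) && !any(inII)) || (all(inII) && !any(inI))
  }, splits)
  if (!length(separating))
    stop("anchor sets are interleaved: no split separates subgroup I from II")
  balance <- vapply(separating, function(s)
    abs(length(s) - (length(tips) - length(s))), numeric(1))
  s <- separating[[which.min(balance)]]
  side_I <- if (all(anchors_I %in% s)) s else setdiff(tips, s)
  setNames(ifelse(tips %in% side_I, "I", "II"), tips)
}

#' Read / write Newick with supports as internal node labels
#'
#' Thin wrappers over `ape::read.tree` / `ape::write.tree`.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
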