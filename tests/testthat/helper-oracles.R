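# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths.

# IUPAC expansion for the brute-force motif scan.
oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

# Brute-force sliding-window scan of one consensus over one strand.
# A sequence N matches only a consensus N (mirrors the scanner's
# subject-literal semantics).
oracle_scan <- function(seq_chr, consensus) {
  sym <- strsplit(toupper(consensus), "")[[1]]
  sc <- strsplit(toupper(seq_chr), "")[[1]]
  w <- length(sym)
  hits <- integer(0)
  if (length(sc) < w) return(hits)
  for (i in seq_len(length(sc) - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      b <- sc[i + j - 1]
      if (b == "N") {
        if (sym[j] != "N") { ok <- FALSE; break }
      } else if (!b %in% oracle_iupac[[sym[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(comp[rev(strsplit(toupper(x), "")[[1]])], collapse = "")
}

# Exhaustive affine-gap Needleman-Wunsch score (3-state DP), independent
# of Biostrings.  Gap of length k costs gap_open + k * gap_extend.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (A aligned to -)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# All-pairs tip path lengths of a phylo tree, by Floyd-Warshall over the
# edge list (independent of the package's traversal).
oracle_tip_dists <- function(tree) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    d[i, j] <- d[j, i] <- tree$edge.length[e]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- d[i, k] + d[k, ]
    upd <- dk < d[i, ]
    d[i, upd] <- dk[upd]
  }
  out <- d[seq_len(n_tip), seq_len(n_tip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Random tree with positive branch lengths (own generator: random
# sequential joining), returning its additive tip distance matrix too.
oracle_random_tree <- function(n_leaves) {
  # build by joining random pairs of subtrees
  nodes <- as.list(seq_len(n_leaves))
  edges <- NULL
  next_id <- n_leaves + 1L
  ids <- seq_len(n_leaves)
  while (length(ids) > 3) {
    pick <- sample(length(ids), 2)
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(u, ids[pick[1]], stats::runif(1, 0.1, 2)),
                   c(u, ids[pick[2]], stats::runif(1, 0.1, 2)))
    ids <- c(ids[-pick], u)
  }
  root <- next_id
  for (id in ids)
    edges <- rbind(edges, c(root, id, stats::runif(1, 0.1, 2)))
  tr <- list(edge = edges[, 1:2, drop = FALSE],
             edge.length = edges[, 3],
             Nnode = root - n_leaves,
             tip.label = paste0("t", seq_len(n_leaves)))
  # renumber internals in preorder for a valid cladewise phylo object
  tr <- reorder_phylo_preorder(tr, n_leaves, root)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

reorder_phylo_preorder <- function(tr, n_leaves, root) {
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  new_id <- integer(max(tr$edge))
  new_id[seq_len(n_leaves)] <- seq_len(n_leaves)
  counter <- n_leaves + 1L
  order_edges <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    new_id[v] <- counter; counter <- counter + 1L
    ke <- kids[[as.character(v)]]
    order_edges <- c(order_edges, ke)
    ch <- tr$edge[ke, 2]
    stack <- c(ch[ch > n_leaves], stack)
  }
  e <- tr$edge[order_edges, , drop = FALSE]
  list(edge = cbind(new_id[e[, 1]],
                    ifelse(e[, 2] <= n_leaves, e[, 2], new_id[e[, 2]])),
       edge.length = tr$edge.length[order_edges],
       Nnode = tr$Nnode,
       tip.label = tr$tip.label)
}
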