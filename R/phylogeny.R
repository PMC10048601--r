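#' Genotype-concordance distance matrix
#'
#' Defines the pairwise distance used for tree building: the fraction of
#' co-observed sites (non-missing in both samples) at which the two
#' samples' alternate-allele dosages differ.  This discordance fraction is
#' a pseudo-metric on `[0, 1]`.
#'
#' @param dosage samples x sites matrix of dosages in `{0, 1, 2, NA}`,
#'   with sample names as rownames.
#' @return A symmetric numeric distance matrix with zero diagonal.
#' @export
genotype_distance <- function(dosage) {
  stopifnot(is.matrix(dosage))
  n <- nrow(dosage)
  if (n < 2) stop_data("need at least 2 samples")
  labs <- rownames(dosage) %||% paste0("S", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    xi <- dosage[i, ]
    for (j in (i + 1):n) {
      xj <- dosage[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok))
        stop_data("samples '%s' and '%s' share no co-observed sites",
                  labs[i], labs[j], class = "introcand_overlap_error")
      v <- mean(xi[ok] != xj[ok])
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree reconstruction
#'
#' Canonical Saitou-Nei neighbor joining: iteratively joins the pair
#' minimizing the Q criterion, with the standard branch-length and
#' distance-update formulas.  On an additive distance matrix the
#' tree's path-length matrix reproduces the input exactly.  Negative
#' branch lengths (possible on non-additive input) are clamped to zero
#' with the deficit moved to the sibling branch, so emitted Newick always
#' carries nonnegative lengths.
#'
#' @param d symmetric nonnegative distance matrix with labels as
#'   dimnames (>= 3 taxa).
#' @return An unrooted tree of class `phylo` (ape), with a trifurcating
#'   root node.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  n <- nrow(d)
  if (n < 3) stop_data("neighbor joining needs >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop_data("distance matrix must be symmetric")
  if (any(d < 0)) stop_data("distance matrix must be nonnegative")
  labels <- rownames(d) %||% paste0("t", seq_len(n))

  # node ids: 1..n tips, internals n+1, n+2, ... in creation order
  active <- seq_len(n)
  D <- d
  dimnames(D) <- list(active, active)
  edges <- matrix(numeric(0), ncol = 3)  # parent, child, length
  next_id <- n + 1L

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lens <- clamp_pair(li, dij - li)
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(u, active[i], lens[1]),
                   c(u, active[j], lens[2]))
    du <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dn <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    active <- c(active[keep], u)
    dimnames(Dn) <- list(active, active)
    D <- Dn
  }

  # resolve the final three nodes around a trifurcating root
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  l1 <- (a + b - cc) / 2
  l2 <- (a + cc - b) / 2
  l3 <- (b + cc - a) / 2
  root <- next_id
  edges <- rbind(edges,
                 c(root, active[1], max(l1, 0)),
                 c(root, active[2], max(l2, 0)),
                 c(root, active[3], max(l3, 0)))

  # renumber internal nodes in preorder from the root (ape convention)
  children <- split(seq_len(nrow(edges)), edges[, 1])
  n_internal <- next_id - n
  new_id <- integer(next_id)
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n + 1L
  stack <- root
  order_edges <- integer(0)
  while (length(stack) > 0) {
    node <- stack[[1]]; stack <- stack[-1]
    new_id[node] <- counter; counter <- counter + 1L
    kid_edges <- children[[as.character(node)]]
    order_edges <- c(order_edges, kid_edges)
    kids <- edges[kid_edges, 2]
    stack <- c(kids[kids > n], stack)
  }
  edges <- edges[order_edges, , drop = FALSE]
  edge_mat <- cbind(new_id[edges[, 1]], ifelse(edges[, 2] <= n, edges[, 2],
                                               new_id[edges[, 2]]))
  tree <- list(edge = edge_mat, edge.length = edges[, 3],
               Nnode = n_internal, tip.label = labels)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

# Path lengths from one tip to all tips, by DFS over the tree's edges.
tip_path_lengths <- function(tree, from_tip) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; len <- tree$edge.length[e]
    adj[[p]] <- rbind(adj[[p]], c(ch, len))
    adj[[ch]] <- rbind(adj[[ch]], c(p, len))
  }
  dist <- rep(NA_real_, n_nodes)
  dist[from_tip] <- 0
  stack <- from_tip
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    nb <- adj[[v]]
    for (k in seq_len(NROW(nb))) {
      w <- nb[k, 1]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + nb[k, 2]
        stack <- c(stack, w)
      }
    }
  }
  dist[seq_len(n)]
}

# For each edge, the set of tip indices on the child side of the split.
edge_splits <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  # process edges in reverse cladewise order => children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(desc[[tree$edge[e, 2]]]))
}

#' Rank candidate species of origin for a focal sample
#'
#' Scores each species by (1) the minimum tree path length from the focal
#' leaf to any member of the species and (2) the size of the smallest
#' split (unrooted clade) containing the focal leaf together with a
#' member, with an alphabetical tie-break.  The top-ranked species is the
#' putative origin of the focal sample's chromosome.
#'
#' @param tree a `phylo` tree containing the focal leaf.
#' @param focal focal sample's tip label.
#' @param species_of named character vector mapping every other tip label
#'   to its species.
#' @return data.frame with rank, species, min_dist, clade_size.
#' @export
assign_origin <- function(tree, focal, species_of) {
  tips <- tree$tip.label
  fi <- match(focal, tips)
  if (is.na(fi)) stop_data("focal sample '%s' is not a leaf of the tree", focal)
  others <- setdiff(tips, focal)
  missing_sp <- others[!others %in% names(species_of)]
  if (length(missing_sp) > 0)
    stop_data("no species assigned for: %s", paste(missing_sp, collapse = ", "))
  dists <- tip_path_lengths(tree, fi)
  splits <- edge_splits(tree)
  n <- length(tips)
  # smallest split part containing both focal and tip m
  pair_clade <- function(mi) {
    best <- n
    for (s in splits) {
      in_s <- c(fi, mi) %in% s
      if (all(in_s)) best <- min(best, length(s))
      else if (!any(in_s)) best <- min(best, n - length(s))
    }
    best
  }
  species <- unique(unname(species_of[others]))
  score <- lapply(species, function(sp) {
    members <- match(others[species_of[others] == sp], tips)
    data.frame(species = sp,
               min_dist = min(dists[members]),
               clade_size = min(vapply(members, pair_clade, numeric(1))))
  })
  out <- do.call(rbind, score)
  out <- out[order(out$min_dist, out$clade_size, out$species), ]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  out
}

#' Per-chromosome trees and origin assignment
#'
#' Subsets a panel genotype matrix by chromosome, computes the
#' genotype-concordance distance, reconstructs a neighbor-joining tree
#' per chromosome and ranks the focal sample's putative species of
#' origin on each.
#'
#' @param panel result of [read_genotype_matrix()] (or a list with
#'   `dosage` and `sites` of the same shape).
#' @param focal focal sample name.
#' @param species_of named character vector: sample -> species for every
#'   non-focal sample.
#' @param newick_dir optional directory; when given, one Newick file per
#'   chromosome (`tree_<chrom>.nwk`) is written with [ape::write.tree()].
#' @return list with `trees` (named list of `phylo`) and `origins`
#'   (data.frame chrom, rank, species, min_dist, clade_size).
#' @export
chromosome_trees <- function(panel, focal, species_of, newick_dir = NULL) {
  chroms <- unique(panel$sites$chrom)
  trees <- list()
  origins <- list()
  for (chr in chroms) {
    cols <- which(panel$sites$chrom == chr)
    sub <- panel$dosage[, cols, drop = FALSE]
    d <- genotype_distance(sub)
    tr <- neighbor_joining(d)
    trees[[chr]] <- tr
    if (!is.null(newick_dir)) {
      ape::write.tree(tr, file.path(newick_dir,
                                    sprintf("tree_%s.nwk", chr)))
    }
    o <- assign_origin(tr, focal, species_of)
    origins[[chr]] <- data.frame(chrom = chr, o, stringsAsFactors = FALSE)
  }
  list(trees = trees, origins = do.call(rbind, origins))
}
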