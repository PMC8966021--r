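#' @include AllClasses.R utils.R
NULL

.gapChars <- c("-", ".", "X", "x", "*")

# alignment (AAStringSet / named character) -> character matrix, taxa in rows
.alignmentMatrix <- function(aln) {
  if (methods::is(aln, "XStringSet")) aln <- as.character(aln)
  if (is.null(names(aln))) names(aln) <- paste0("t", seq_along(aln))
  if (length(aln) < 2) stop("at least 2 sequences required")
  w <- unique(nchar(aln))
  if (length(w) != 1) stop("sequences must have equal aligned length")
  if (w < 1) stop("alignment length must be >= 1")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Poisson-corrected pairwise distances from a protein alignment
#'
#' Implements the Poisson correction for multiple hits: after removing
#' every alignment column that contains a gap or missing residue in any
#' sequence (the complete-deletion option), the proportion of differing
#' sites p is computed for each pair and corrected to
#' d = -ln(1 - p). A pair with p >= 1 is a saturated distance and an
#' error, as is an alignment with no surviving columns.
#'
#' @param aln Aligned sequences: an [Biostrings::AAStringSet] or named
#'   character vector of equal-length strings. `-`, `.`, `X` and `*` count
#'   as gap/missing.
#' @return A [PoissonDistances-class] carrying the distance matrix and the
#'   number of columns surviving complete deletion.
#' @examples
#' poissonDistance(c(a = "ACDE", b = "ACDF"))  # p = 0.25, d = -ln(0.75)
#' @export
poissonDistance <- function(aln) {
  m <- .alignmentMatrix(aln)
  keep <- colSums(matrix(m %in% .gapChars, nrow = nrow(m))) == 0
  if (!any(keep)) stop("zero columns survive complete deletion")
  m <- m[, keep, drop = FALSE]
  used <- ncol(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- sum(m[i, ] != m[j, ]) / used
      if (p >= 1)
        stop("saturated distance between '", rownames(m)[i], "' and '",
             rownames(m)[j], "' (p = ", p, ")")
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  new("PoissonDistances", distances = d, usedSites = as.integer(used))
}

# ---------------------------------------------------------------------------
# Neighbor joining
# ---------------------------------------------------------------------------

.checkDistanceMatrix <- function(dm) {
  if (methods::is(dm, "PoissonDistances")) dm <- dm@distances
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-9))
    stop("distance matrix must be square and symmetric")
  if (any(dm < 0)) stop("distance matrix must be nonnegative")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(nrow(dm)))
  dm
}

#' Neighbor-joining tree construction
#'
#' The agglomeration of Saitou & Nei: at each step the pair (i, j)
#' minimizing \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' is joined; limb lengths follow the standard NJ formulas, negative limb
#' lengths are clamped to 0 (the display convention of common tree
#' software) with the total deficit recorded in attribute
#' `clampedDeficit`. Ties in Q are broken by the lexicographically
#' smallest label pair (the label of an agglomerated node is the smallest
#' leaf label of its cluster), which makes the output independent of the
#' taxon input order. The result is the standard unrooted NJ tree,
#' represented with a trifurcating root; for an additive input matrix the
#' tree's path lengths reproduce the input distances exactly.
#'
#' With 2 taxa the tree is a single tip-to-tip path of total length
#' d(1,2), represented as two half-length edges around one internal node
#' (the phylo representation has no tipless edge).
#'
#' @param dm A [PoissonDistances-class], `dist` or symmetric nonnegative
#'   matrix with labels. Asymmetric or negative input is an error.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' njTree(d)
#' @export
njTree <- function(dm) {
  D <- .checkDistanceMatrix(dm)
  n0 <- nrow(D)
  labels <- rownames(D)
  if (n0 < 2) stop("at least 2 taxa required")

  if (n0 == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(D[1, 2] / 2, 2),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    attr(tree, "clampedDeficit") <- 0
    return(tree)
  }

  # active node bookkeeping: tips are 1..n0, internal nodes allocated from
  # n0+2 upward (n0+1 is reserved for the final trifurcating root)
  nodeIds <- seq_len(n0)
  nodeLabels <- labels            # lexicographically smallest leaf of cluster
  nextInternal <- n0 + 2L
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  deficit <- 0

  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + (-x); 0 } else x
  }

  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairLab <- apply(cand, 1, function(ij) {
      p <- sort(c(nodeLabels[ij[1]], nodeLabels[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pairLab)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    newId <- nextInternal
    nextInternal <- nextInternal + 1L
    edges <- rbind(edges, c(newId, nodeIds[i]), c(newId, nodeIds[j]))
    lens <- c(lens, li, lj)
    dNew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    lab2 <- c(nodeLabels[keep], min(nodeLabels[c(i, j)]))
    ids2 <- c(nodeIds[keep], newId)
    dimnames(D2) <- list(lab2, lab2)
    D <- D2; nodeLabels <- lab2; nodeIds <- ids2
  }

  root <- n0 + 1L
  if (nrow(D) == 3) {
    l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    edges <- rbind(edges, c(root, nodeIds[1]), c(root, nodeIds[2]),
                   c(root, nodeIds[3]))
    lens <- c(lens, l1, l2, l3)
  }

  storage.mode(edges) <- "integer"
  nInternal <- nextInternal - n0 - 1L

  # renumber internal nodes in preorder from the root (ape convention)
  adj <- split(seq_len(nrow(edges)), edges[, 1])
  newId <- integer(n0 + nInternal)
  newId[seq_len(n0)] <- seq_len(n0)
  counter <- n0
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    counter <- counter + 1L
    newId[node] <- counter
    kids <- edges[adj[[as.character(node)]], 2]
    stack <- c(stack, rev(kids[kids > n0]))
  }
  edges <- matrix(newId[edges], ncol = 2)
  storage.mode(edges) <- "integer"

  tree <- list(edge = edges, edge.length = lens, tip.label = labels,
               Nnode = nInternal)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clampedDeficit") <- deficit
  tree
}

# ---------------------------------------------------------------------------
# Splits and bootstrap
# ---------------------------------------------------------------------------

#' Nontrivial splits of an unrooted tree
#'
#' Every internal edge of an unrooted tree bipartitions the taxa; each
#' split is canonicalized as the sorted side that does not contain the
#' lexicographically smallest taxon, serialized as a single string. Used
#' for topology comparison and bootstrap support.
#'
#' @param tree An [ape::phylo].
#' @return Character vector of canonical split strings (taxa joined by
#'   `"|"`), one per internal edge; empty for trees with fewer than 4 tips.
#' @export
treeSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  splits <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2) next
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement `nReplicates` times,
#' rebuilds the Poisson-distance NJ tree for each replicate, and scores
#' every internal split of the original tree by the percentage of retained
#' replicates that contain it. Replicates producing a saturated distance
#' (or no usable columns) are dropped and counted; losing more than 10%
#' of replicates is an error. Deterministic for a fixed seed, and
#' invariant to the taxon input order.
#'
#' @param aln Alignment as for [poissonDistance()].
#' @param nReplicates Number of bootstrap replicates; 1000 is the
#'   conventional choice for publication trees.
#' @param seed Integer seed.
#' @param maxDropFraction Maximum tolerated fraction of dropped
#'   replicates; default 0.1.
#' @return The original NJ tree (an [ape::phylo]) with `node.label`
#'   holding the support (0--100, NA for the root and for 2-tip sides that
#'   are not internal splits) and attributes `splitSupport` (named numeric)
#'   and `droppedReplicates`.
#' @export
bootstrapSupport <- function(aln, nReplicates = 1000, seed = 1,
                             maxDropFraction = 0.1) {
  m <- .alignmentMatrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]
  aln0 <- stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  tree <- njTree(poissonDistance(aln0))
  origSplits <- treeSplits(tree)
  counts <- stats::setNames(numeric(length(origSplits)), origSplits)
  dropped <- 0L
  set.seed(stageSeed(seed, "bootstrap"))
  w <- ncol(m)
  for (b in seq_len(nReplicates)) {
    cols <- sample.int(w, w, replace = TRUE)
    rep <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                 collapse = ""), rownames(m))
    tr <- tryCatch(njTree(poissonDistance(rep)), error = function(e) NULL)
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    hit <- origSplits %in% treeSplits(tr)
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > maxDropFraction * nReplicates)
    stop("more than ", 100 * maxDropFraction, "% of bootstrap replicates ",
         "dropped (", dropped, "/", nReplicates, ", saturated distances)")
  retained <- nReplicates - dropped
  support <- if (retained > 0) 100 * counts / retained else counts

  # attach supports as node labels of the matching internal nodes
  ntip <- length(tree$tip.label)
  nodeLab <- rep(NA_character_, tree$Nnode)
  if (length(origSplits)) {
    parts <- ape::prop.part(tree)
    tips <- sort(tree$tip.label)
    anchor <- tips[1]
    for (k in seq_along(parts)) {
      side <- sort(tree$tip.label[parts[[k]]])
      if (length(side) < 2 || length(side) > ntip - 2) next
      if (anchor %in% side) side <- setdiff(tips, side)
      if (length(side) < 2) next
      key <- paste(side, collapse = "|")
      if (key %in% names(support))
        nodeLab[k] <- format(support[[key]], trim = TRUE)
    }
  }
  tree$node.label <- nodeLab
  attr(tree, "splitSupport") <- support
  attr(tree, "droppedReplicates") <- dropped
  tree
}

# ---------------------------------------------------------------------------
# Representative picking
# ---------------------------------------------------------------------------

# connected components of the tree graph after removing the edge rows in
# `removed`; returns a membership vector over node ids
.treeComponents <- function(tree, removed) {
  nNode <- length(tree$tip.label) + tree$Nnode
  parent <- seq_len(nNode)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(tree$edge))) {
    if (e %in% removed) next
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(nNode), find, integer(1))
}

#' Pick branch-diversified representatives from a tree
#'
#' Formalizes "one candidate per branch": the tree is cut into `kClades`
#' leaf groups and one taxon is returned per group -- a supplied anchor
#' taxon when the group contains one (the lexicographically smallest if
#' several), otherwise the group medoid (the leaf minimizing the summed
#' tree path distance to the other leaves of its group; ties broken
#' lexicographically). Cutting removes internal edges in order of
#' decreasing length (ties by lexicographically smallest split) until
#' `kClades` leaf groups exist; if the internal edges are exhausted first
#' (e.g. `kClades` equal to the leaf count), the longest pendant edges are
#' removed next, isolating single leaves.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param kClades Number of groups to cut (1 <= kClades <= leaf count).
#' @param anchors Character vector of taxa that take precedence over the
#'   medoid in their group (must be leaves of the tree).
#' @return Character vector of `kClades` selected taxa, one per group,
#'   ordered by each group's lexicographically smallest leaf; attribute
#'   `groups` holds the full grouping.
#' @export
pickRepresentatives <- function(tree, kClades, anchors = character()) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (kClades < 1) stop("kClades must be >= 1")
  if (kClades > ntip) stop("kClades cannot exceed the leaf count")
  bad <- setdiff(anchors, tree$tip.label)
  if (length(bad)) stop("anchors not in tree: ", paste(bad, collapse = ", "))

  internal <- which(tree$edge[, 2] > ntip)
  pendant <- which(tree$edge[, 2] <= ntip)
  # order internal edges: length desc, ties by smallest split string
  parts <- ape::prop.part(tree)  # element i describes node ntip + i
  splitOf <- function(e) {
    node <- tree$edge[e, 2]
    side <- sort(tree$tip.label[parts[[node - ntip]]])
    paste(side, collapse = "|")
  }
  intOrd <- internal[order(-tree$edge.length[internal],
                           vapply(internal, splitOf, character(1)))]
  penOrd <- pendant[order(-tree$edge.length[pendant],
                          tree$tip.label[tree$edge[pendant, 2]])]
  cutSeq <- c(intOrd, penOrd)

  removed <- integer(0)
  repeat {
    comp <- .treeComponents(tree, removed)
    tipComp <- comp[seq_len(ntip)]
    if (length(unique(tipComp)) >= kClades || length(removed) ==
        length(cutSeq)) break
    removed <- c(removed, cutSeq[length(removed) + 1L])
  }
  comp <- .treeComponents(tree, removed)
  tipComp <- comp[seq_len(ntip)]
  groups <- split(tree$tip.label, tipComp)

  pd <- ape::cophenetic.phylo(tree)
  reps <- vapply(groups, function(g) {
    g <- sort(g)
    a <- sort(intersect(anchors, g))
    if (length(a)) return(a[1])
    if (length(g) == 1) return(g)
    sums <- colSums(pd[g, g, drop = FALSE])
    g[order(sums, g)][1]
  }, character(1))
  ord <- order(vapply(groups, function(g) sort(g)[1], character(1)))
  out <- unname(reps[ord])
  attr(out, "groups") <- unname(groups[ord])
  out
}
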