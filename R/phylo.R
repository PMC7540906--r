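# sequences (named, equal length) -> integer matrix; 0 = gap/N/other
.seq_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must be equal length (aligned)",
                            call. = FALSE)
  ch <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
               byrow = TRUE, dimnames = list(names(seqs), NULL))
  m <- matrix(match(ch, c("A", "C", "G", "T"), nomatch = 0L),
              nrow = nrow(ch), dimnames = dimnames(ch))
  m
}

#' Pairwise distances from aligned (or gap-free) sequences
#'
#' Computes p-distances with pairwise deletion — for each pair, columns
#' holding a gap, `N` or other non-`ACGT` character in either sequence are
#' dropped — and optionally applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`. Saturated pairs (`p >= 3/4`, where the
#' correction diverges) are set to `cap`.
#'
#' @param seqs Named character vector of equal-length sequences over
#'   `A/C/G/T/-/N`.
#' @param model `"JC"` (Jukes-Cantor, default) or `"p"` (raw p-distance).
#' @param cap Distance assigned to saturated pairs under `"JC"`
#'   (default 5).
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @examples
#' pairwise_distance(c(a = "ACGT", b = "ACGA"), model = "p")
#' @export
pairwise_distance <- function(seqs, model = c("JC", "p"), cap = 5) {
  model <- match.arg(model)
  seqs <- seqs[order(names(seqs))]  # canonical order: leaf-order invariance
  m <- .seq_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- m[i, ] > 0L & m[j, ] > 0L
      nc <- sum(comp)
      if (nc == 0L) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j], call. = FALSE)
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d[i, j] <- d[j, i] <- if (model == "p") p else .jc_correct(p, cap)
    }
  }
  d
}

.jc_correct <- function(p, cap) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) cap else min(cap, -0.75 * log(arg))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (Q-criterion selection, standard
#' branch-length formulas); on an additive distance matrix the generating
#' topology and branch lengths are recovered exactly. Negative branch
#' lengths, an artefact of noisy distances, are clamped to zero with the
#' deficit transferred to the adjacent edge so path lengths are preserved.
#'
#' @param dm Symmetric distance matrix with labels as dimnames (>= 3).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 3L)
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (!is.null(rownames(dm))) {
    ord <- order(rownames(dm))   # canonical order for deterministic ties
    dm <- dm[ord, ord]
  }
  tree <- ape::nj(stats::as.dist(dm))
  .clamp_negative_edges(tree)
}

.clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  if (length(neg) == 0L) return(tree)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & seq_along(tree$edge[, 1]) != e)
    if (length(sib) > 0) {
      tree$edge.length[sib[1]] <- max(0, tree$edge.length[sib[1]] + deficit)
    }
  }
  message(length(neg), " negative branch length(s) clamped to zero")
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `B` times, rebuilds a replicate tree from each
#' resample, and annotates every internal edge of the base tree with the
#' number of replicates containing the same bipartition (stored in
#' `node.label`, scale 0..B).
#'
#' @inheritParams pairwise_distance
#' @param B Number of bootstrap replicates (0 = no supports).
#' @param seed Integer seed for column resampling; required when `B > 0`.
#' @return A `phylo` tree; `node.label` holds supports when `B > 0`.
#' @export
bootstrap_support <- function(seqs, B = 1000L, seed = NULL,
                              model = c("JC", "p"), cap = 5) {
  model <- match.arg(model)
  seqs <- seqs[order(names(seqs))]  # canonical order: leaf-order invariance
  m <- .seq_matrix(seqs)
  base <- neighbor_joining(pairwise_distance(seqs, model = model, cap = cap))
  if (B <= 0L) return(base)
  if (is.null(seed)) stop("seed required when B > 0", call. = FALSE)
  n <- nrow(m); L <- ncol(m)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  # per-column mismatch/comparability indicators for all pairs: a replicate
  # distance is then one matrix product with the column resampling weights
  mism <- matrix(0, np, L)
  comp <- matrix(0, np, L)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- m[i, ] > 0L & m[j, ] > 0L
    comp[k, ] <- as.numeric(ok)
    mism[k, ok] <- as.numeric(m[i, ok] != m[j, ok])
  }
  set.seed(as.integer(seed))
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    pm <- as.vector(mism %*% w)
    cm <- as.vector(comp %*% w)
    if (any(cm == 0)) cm[cm == 0] <- 1  # degenerate resample: p := 0
    p <- pm / cm
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    dv <- if (model == "p") p else vapply(p, .jc_correct, numeric(1),
                                          cap = cap)
    d[t(pairs)] <- dv
    d <- d + t(d)
    reps[[b]] <- suppressMessages(neighbor_joining(d))
  }
  supports <- ape::prop.clades(base, reps, rooted = FALSE)
  supports[is.na(supports)] <- 0L
  base$node.label <- as.character(supports)
  base$node.label[1] <- ""  # root surrogate of the unrooted tree
  base
}

#' Root a tree on the outgroup's pendant edge
#'
#' Places the root at the midpoint of the branch leading to the outgroup
#' leaf; the ingroup topology (bipartition set) is unchanged.
#'
#' @param tree A `phylo` tree containing `outgroup` as a leaf.
#' @param outgroup Leaf label to root on.
#' @return Rooted `phylo` tree.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a leaf of the tree",
         call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!is.null(rooted$edge.length)) {
    # split the outgroup's pendant edge at its midpoint: the two
    # root-incident edges share the original pendant length equally
    root_node <- ape::Ntip(rooted) + 1L
    kids <- which(rooted$edge[, 1] == root_node)
    if (length(kids) == 2L) {
      total <- sum(rooted$edge.length[kids])
      rooted$edge.length[kids] <- total / 2
    }
  }
  rooted
}
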