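# children list and postorder node sequence for a phylo tree
.tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

.tree_parents <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' Count order clusters in a rooted tree
#'
#' The tree-evaluation metric: for each order, a cluster is a maximal clade
#' whose leaves all belong to that order. Leaves with any other label —
#' including rOTU query leaves and the outgroup — break purity, so a
#' well-resolved order forms a single cluster (monophyly) and a scattered
#' order forms many. Orders represented by a single leaf are reported but
#' flagged `omitted`, as they are uninformative for this metric.
#'
#' @param tree Rooted `phylo` tree.
#' @param labels Named character vector mapping every leaf to its order (or
#'   `"rOTU"` / `"outgroup"`).
#' @param orders Which labels to report on; defaults to all labels except
#'   `"rOTU"`, `"outgroup"` and `"Outgroup"`.
#' @return Tibble `order`, `n_species`, `n_clusters`, `max_cluster_size`,
#'   `omitted`, plus a `clusters` list-column of leaf-label vectors.
#' @examples
#' tr <- ape::read.tree(text = "(((a1,a2),a3),b1);")
#' count_order_clusters(tr, c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
#' @export
count_order_clusters <- function(tree, labels, orders = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(labels))) {
    missing <- setdiff(tree$tip.label, names(labels))
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  leaf_lab <- unname(labels[tree$tip.label])
  if (is.null(orders)) {
    orders <- setdiff(sort(unique(leaf_lab)),
                      c("rOTU", "outgroup", "Outgroup"))
  }
  kids <- .tree_children(tree)
  parent <- .tree_parents(tree)
  n_node <- ntip + tree$Nnode
  # node label purity + subtree tip sets, computed bottom-up
  node_lab <- character(n_node)   # "" = impure
  tipsets <- vector("list", n_node)
  node_lab[seq_len(ntip)] <- leaf_lab
  tipsets[seq_len(ntip)] <- as.list(tree$tip.label)
  po_edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (nd in unique(po_edges[, 1])) {
    ls <- node_lab[kids[[nd]]]
    node_lab[nd] <- if (length(unique(ls)) == 1L && all(nzchar(ls))) {
      ls[1]
    } else {
      ""
    }
    tipsets[[nd]] <- unlist(tipsets[kids[[nd]]], use.names = FALSE)
  }
  root <- ntip + 1L
  parent_or_self <- parent
  parent_or_self[parent_or_self == 0L] <- root  # the root has no parent
  purrr::map_dfr(orders, function(ord) {
    pure <- node_lab == ord
    maximal <- which(pure & (seq_len(n_node) == root |
                               !pure[parent_or_self]))
    sizes <- lengths(tipsets[maximal])
    n_sp <- sum(leaf_lab == ord)
    tibble::tibble(
      order = ord, n_species = n_sp,
      n_clusters = length(maximal),
      max_cluster_size = if (length(maximal)) max(sizes) else 0L,
      omitted = n_sp <= 1L,
      clusters = list(tipsets[maximal])
    )
  })
}

#' Assign an rOTU leaf to a nematode order by tree placement
#'
#' Walks from the rOTU leaf to progressively larger ancestral clades and
#' assigns the first clade's unanimous reference order; if the first clade
#' containing reference leaves is mixed, the majority order among its
#' reference leaves is used, with ties deferred to the next ancestor.
#'
#' @param tree Rooted `phylo` tree containing the rOTU leaf.
#' @param rotu_leaf Leaf label of the rOTU.
#' @param ref_orders Named character vector mapping reference leaf labels
#'   to orders; leaves absent from it (other rOTUs, the outgroup) are
#'   ignored during the walk.
#' @return One-row tibble `rotu`, `order`, `clade_size` (number of
#'   reference leaves in the supporting clade).
#' @export
assign_rotu_order <- function(tree, rotu_leaf, ref_orders) {
  stopifnot(inherits(tree, "phylo"), rotu_leaf %in% tree$tip.label)
  refs <- intersect(tree$tip.label, names(ref_orders))
  if (length(refs) == 0L) stop("tree has no reference leaves", call. = FALSE)
  parent <- .tree_parents(tree)
  kids <- .tree_children(tree)
  ntip <- ape::Ntip(tree)
  tip_of <- function(nd) {  # tip labels under a node
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(kids[[nd]], tip_of), use.names = FALSE)
  }
  nd <- match(rotu_leaf, tree$tip.label)
  last <- NULL
  while (parent[nd] != 0L) {
    nd <- parent[nd]
    here <- intersect(tip_of(nd), refs)
    if (length(here) == 0L) next
    tab <- sort(table(ref_orders[here]), decreasing = TRUE)
    last <- list(order = names(tab)[1], size = length(here))
    if (length(tab) == 1L || tab[1] > tab[2]) {
      return(tibble::tibble(rotu = rotu_leaf, order = names(tab)[1],
                            clade_size = length(here)))
    }
    # tie: defer to the next ancestor
  }
  tibble::tibble(rotu = rotu_leaf,
                 order = if (is.null(last)) NA_character_ else last$order,
                 clade_size = if (is.null(last)) 0L else last$size)
}

#' Transfer a feeding-type code from the nearest reference species
#'
#' Assigns the feeding code of the reference leaf at minimum patristic
#' (branch-length) distance from the rOTU leaf; ties go to the
#' lexicographically smaller leaf label.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param rotu_leaf Leaf label of the rOTU.
#' @param annotation Named character vector mapping every reference leaf in
#'   the tree to its feeding code.
#' @param reference_leaves Which leaves are references (default: the names
#'   of `annotation` present in the tree).
#' @return One-row tibble `rotu`, `feeding_code`, `nearest_reference`,
#'   `distance`.
#' @export
assign_feeding_type <- function(tree, rotu_leaf, annotation,
                                reference_leaves = NULL) {
  stopifnot(inherits(tree, "phylo"), rotu_leaf %in% tree$tip.label)
  if (is.null(reference_leaves)) {
    reference_leaves <- intersect(tree$tip.label, names(annotation))
  }
  missing <- setdiff(reference_leaves, names(annotation))
  if (length(missing) > 0L) {
    stop("missing feeding annotation for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(reference_leaves) == 0L) {
    stop("tree has no annotated reference leaves", call. = FALSE)
  }
  pd <- stats::cophenetic(tree)[rotu_leaf, reference_leaves]
  ord <- order(pd, names(pd))
  best <- names(pd)[ord[1]]
  tibble::tibble(rotu = rotu_leaf,
                 feeding_code = unname(annotation[best]),
                 nearest_reference = best,
                 distance = unname(pd[ord[1]]))
}

#' Compare order-cluster counts across region sets
#'
#' Runs [count_order_clusters()] on each tree and binds the reports into
#' one long table (plus wide matrices for display): the layout used to
#' judge whether artificially concatenated long sequences tighten order
#' clusters relative to single-region trees.
#'
#' @param trees Named list of rooted `phylo` trees (names are region-set
#'   labels such as `"R1"`, `"R1_2_3_4"`).
#' @param labels Named leaf -> order vector covering every tree's leaves.
#' @param orders Passed to [count_order_clusters()].
#' @return List with `long` (tibble `region_set`, `order`, `n_species`,
#'   `n_clusters`, `max_cluster_size`, `omitted`), `n_clusters` and
#'   `max_cluster_size` (wide tibbles, orders x region sets).
#' @export
compare_concatenations <- function(trees, labels, orders = NULL) {
  stopifnot(is.list(trees), !is.null(names(trees)))
  long <- purrr::imap_dfr(trees, function(tr, nm) {
    count_order_clusters(tr, labels, orders = orders) |>
      dplyr::select(-"clusters") |>
      dplyr::mutate(region_set = nm, .before = 1)
  })
  wide <- function(col) {
    long |>
      dplyr::select("region_set", "order", "n_species",
                    value = dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "region_set",
                         values_from = "value")
  }
  list(long = long, n_clusters = wide("n_clusters"),
       max_cluster_size = wide("max_cluster_size"))
}
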