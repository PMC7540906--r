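# shared fixtures built in code at test time

small_config <- function(seed = 101, n_samples = 24, ...) {
  sim_config(seed = seed, n_orders = 3, species_per_order = 3,
             seq_length = 700, n_samples = n_samples, depth_mean = 8000,
             ...)
}

small_reference_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference_set(small_config())
    cache
  }
})

# a long profiles tibble from compact region-SV strings, one isolate per row
profiles_from <- function(...) {
  rows <- list(...)
  purrr::map_dfr(seq_along(rows), function(i) {
    svs <- rows[[i]]
    tibble::tibble(sample_id = names(rows)[i],
                   region = seq_along(svs)[!is.na(svs)],
                   sv_id = svs[!is.na(svs)])
  })
}

# minimal long SV table row
sv_row <- function(sample, region, sv, count, seq = "ACGT",
                   phylum = "Nematoda", order = "Rhabditida") {
  tibble::tibble(sample_id = sample, region = region, sv_id = sv,
                 count = count, sequence = seq, phylum = phylum,
                 order = order)
}

random_tip_tree <- function(n) {
  ape::rtree(n, tip.label = sprintf("t%02d", seq_len(n)))
}

# independent brute-force oracle for order-cluster counting: two leaves of
# order X share a cluster iff their MRCA's clade contains only X leaves;
# clusters are the connected components of that relation
oracle_order_clusters <- function(tree, labels, ord) {
  tips <- tree$tip.label[labels[tree$tip.label] == ord]
  if (length(tips) == 0L) return(list(n = 0L, max_size = 0L))
  if (length(tips) == 1L) return(list(n = 1L, max_size = 1L))
  pure_mrca <- function(a, b) {
    m <- ape::getMRCA(tree, c(a, b))
    clade <- ape::extract.clade(tree, m)$tip.label
    all(labels[clade] == ord)
  }
  pairs <- t(utils::combn(tips, 2))
  keep <- apply(pairs, 1, function(p) pure_mrca(p[1], p[2]))
  g <- igraph::graph_from_data_frame(
    as.data.frame(pairs[keep, , drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = tips)
  )
  comp <- igraph::components(g)
  list(n = comp$no, max_size = max(comp$csize))
}
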