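test_that("p-distance and Jukes-Cantor match closed forms", {
  expect_equal(pairwise_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(pairwise_distance(c(a = "ACGT", b = "ACGA"),
                                 model = "p")["a", "b"], 0.25)
  jc <- pairwise_distance(c(a = "ACGTACGT", b = "ACGAACGA"))["a", "b"]
  expect_equal(jc, -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-12)
  # saturation cap
  sat <- pairwise_distance(c(a = "AAAA", b = "CCCC"), cap = 7)["a", "b"]
  expect_equal(sat, 7)
})

test_that("pairwise deletion drops gap/N columns per pair", {
  d <- pairwise_distance(c(a = "ACGT-A", b = "ACGANA", c = "TCGTAA"),
                         model = "p")
  expect_equal(d["a", "b"], 1 / 5)      # gap/N column dropped, 1 of 5 differ
  expect_equal(d["a", "c"], 1 / 5)      # gap column dropped
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_error(pairwise_distance(c(a = "----", b = "ACGT", c = "ACGT")),
               "no comparable columns")
})

test_that("distances agree with ape's dist.dna on gap-free alignments", {
  set.seed(12)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  seqs <- vapply(1:6, function(i) {
    ch <- base
    flip <- sample(300, 40)
    ch[flip] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", 1:6)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  for (mod in c("p", "JC")) {
    ours <- pairwise_distance(seqs, model = mod)
    ref <- as.matrix(ape::dist.dna(bin,
                                   model = if (mod == "p") "raw" else "JC69",
                                   pairwise.deletion = TRUE))
    expect_equal(ours[names(seqs), names(seqs)],
                 ref[names(seqs), names(seqs)], tolerance = 1e-12)
  }
})

test_that("NJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  dm <- ape::cophenetic.phylo(tr)
  out <- neighbor_joining(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), out)), 0)
  expect_equal(ape::cophenetic.phylo(out)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-12)
  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(d3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("NJ minimizes least-squares fit over all topologies (additive, <= 6 taxa)", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  ls_score <- function(topo, dm) {
    fit <- phangorn::nnls.tree(stats::as.dist(dm), topo)
    fit$edge.length[fit$edge.length < 0] <- 0
    sum((ape::cophenetic.phylo(fit)[rownames(dm), colnames(dm)] - dm)^2)
  }
  for (n in 4:6) {
    for (rep in 1:3) {
      true <- ape::rtree(n, tip.label = letters[1:n])
      true$edge.length <- stats::runif(nrow(true$edge), 0.5, 2)
      dm <- ape::cophenetic.phylo(true)
      out <- neighbor_joining(dm)
      scores <- vapply(phangorn::allTrees(n, tip.label = letters[1:n]),
                       ls_score, numeric(1), dm = dm)
      expect_equal(ls_score(ape::unroot(out), dm), min(scores),
                   tolerance = 1e-8)
      expect_lt(min(scores), 1e-8)  # the additive tree fits exactly
    }
  }
})

test_that("NJ separates simulated orders into monophyletic clades", {
  refs <- small_reference_set()
  seqs <- setNames(refs$references$sequence, refs$references$species_id)
  tr <- neighbor_joining(pairwise_distance(seqs))
  rooted <- root_at_outgroup(tr, "Tardigrada_outgroup")
  labs <- setNames(refs$references$order, refs$references$species_id)
  labs["Tardigrada_outgroup"] <- "outgroup"
  rep <- count_order_clusters(rooted, labs)
  expect_true(all(rep$n_clusters == 1))
})

test_that("bootstrap supports are deterministic and strong for clear splits", {
  set.seed(7)
  block <- function(base, k) {
    vapply(1:k, function(i) {
      ch <- strsplit(base, "")[[1]]
      flip <- sample(length(ch), 3)
      ch[flip] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  }
  b1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  b2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  seqs <- c(setNames(block(b1, 3), paste0("x", 1:3)),
            setNames(block(b2, 3), paste0("y", 1:3)))
  t1 <- bootstrap_support(seqs, B = 100, seed = 5)
  t2 <- bootstrap_support(seqs, B = 100, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- as.integer(t1$node.label[nzchar(t1$node.label)])
  expect_true(any(sup >= 95))  # the x|y split is near-certain
  # B = 0: no supports
  t0 <- bootstrap_support(seqs, B = 0)
  expect_null(t0$node.label)
  expect_error(bootstrap_support(seqs, B = 10), "seed required")
})

test_that("bootstrap supports are invariant to leaf input order", {
  set.seed(8)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", 1:5)
  t1 <- bootstrap_support(seqs, B = 50, seed = 3)
  t2 <- bootstrap_support(rev(seqs), B = 50, seed = 3)
  key <- function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    sets <- lapply(parts, function(p) sort(labs[p]))
    ord <- order(vapply(sets, paste, character(1), collapse = ","))
    paste(vapply(sets[ord], paste, character(1), collapse = ","))
  }
  # same unrooted topology either way
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  # and the same support for each bipartition
  sup_by_split <- function(tr) {
    m <- ape::prop.clades(tr, list(tr), rooted = FALSE)
    stats::setNames(tr$node.label, seq_along(tr$node.label))
  }
  s1 <- sort(as.integer(t1$node.label[nzchar(t1$node.label)]))
  s2 <- sort(as.integer(t2$node.label[nzchar(t2$node.label)]))
  expect_equal(s1, s2)
})

test_that("outgroup rooting halves the pendant edge and keeps bipartitions", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,O:4):0.5);")
  rooted <- root_at_outgroup(tr, "O")
  expect_true(ape::is.rooted(rooted))
  root_node <- ape::Ntip(rooted) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root_node, 2]
  expect_true(match("O", rooted$tip.label) %in% kids)
  # pendant edge split at midpoint
  og_edge <- which(rooted$edge[, 2] == match("O", rooted$tip.label) &
                     rooted$edge[, 1] == root_node)
  expect_equal(rooted$edge.length[og_edge], 2)
  # unrooting restores the bipartition set
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted), ape::unroot(tr))), 0)
  expect_error(root_at_outgroup(tr, "missing"), "not a leaf")
})

test_that("concatenated distances are length-weighted averages of regional ones", {
  set.seed(44)
  mk <- function(L) {
    s <- vapply(1:4, function(i) paste(sample(c("A", "C", "G", "T"), L,
                                              replace = TRUE),
                                       collapse = ""), character(1))
    setNames(s, paste0("t", 1:4))
  }
  a <- mk(120); b <- mk(200)
  cat_seqs <- setNames(paste0(a, b), names(a))
  da <- pairwise_distance(a, model = "p")
  db <- pairwise_distance(b, model = "p")
  dc <- pairwise_distance(cat_seqs, model = "p")
  expect_equal(dc, (120 * da + 200 * db) / 320, tolerance = 1e-9)
})
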