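test_that("cluster counting handles monophyly, paraphyly and breakers", {
  tr <- ape::read.tree(text = "(((a1,a2),a3),b1);")
  rep <- count_order_clusters(tr, c(a1 = "A", a2 = "A", a3 = "A",
                                    b1 = "B"))
  expect_equal(rep$n_clusters[rep$order == "A"], 1L)
  expect_equal(rep$max_cluster_size[rep$order == "A"], 3L)
  expect_true(rep$omitted[rep$order == "B"])  # single-species order
  tr2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  rep2 <- count_order_clusters(tr2, c(a1 = "A", b1 = "B", a2 = "A",
                                      b2 = "B"))
  expect_equal(rep2$n_clusters[rep2$order == "A"], 2L)
  # an rOTU leaf inside an otherwise pure clade breaks it
  tr3 <- ape::read.tree(text = "(((a1,q1),a2),b1);")
  rep3 <- count_order_clusters(tr3, c(a1 = "A", q1 = "rOTU", a2 = "A",
                                      b1 = "B"))
  expect_equal(rep3$n_clusters[rep3$order == "A"], 2L)
  expect_false("rOTU" %in% rep3$order)
  expect_error(count_order_clusters(tr, c(a1 = "A")), "unlabeled")
})

test_that("cluster counts equal the brute-force oracle on random labeled trees", {
  set.seed(99)
  orders <- c("A", "B", "C")
  for (i in 1:60) {
    n <- sample(6:30, 1)
    tr <- random_tip_tree(n)
    labs <- setNames(sample(c(orders, "rOTU"), n, replace = TRUE,
                            prob = c(3, 3, 3, 1)),
                     tr$tip.label)
    rep <- count_order_clusters(tr, labs, orders = orders)
    for (ord in orders) {
      ora <- oracle_order_clusters(tr, labs, ord)
      row <- rep[rep$order == ord, ]
      expect_equal(row$n_clusters, ora$n,
                   info = sprintf("tree %d order %s", i, ord))
      expect_equal(row$max_cluster_size, ora$max_size)
      # cluster sizes sum to the order's leaf count
      expect_equal(sum(lengths(row$clusters[[1]])), row$n_species)
    }
  }
})

test_that("rOTU order assignment walks to the first decisive clade", {
  tr <- ape::read.tree(text = "(((q1,d1),(d2,d3)),((r1,r2),o1));")
  ref_orders <- c(d1 = "Dorylaimida", d2 = "Dorylaimida",
                  d3 = "Dorylaimida", r1 = "Rhabditida",
                  r2 = "Rhabditida")
  out <- assign_rotu_order(tr, "q1", ref_orders)
  expect_equal(out$order, "Dorylaimida")
  expect_equal(out$clade_size, 1L)  # sister reference decides immediately
  expect_error(assign_rotu_order(tr, "q1", c(zz = "X")), "no reference")
})

test_that("order assignment recovers the simulated source order", {
  refs <- small_reference_set()
  cfg <- small_config(seed = 120, n_samples = 20, fail_rate = 0,
                      contamination_rate = 0)
  sim <- simulate_sv_tables(cfg, refs)
  res <- run_pipeline(sim$sv_table, refs$references,
                      pipeline_config(seed = 3, bootstrap = 0,
                                      region_sets = list(1:4)))
  # each rOTU's assigned order equals the truth order of its members
  memb <- dplyr::inner_join(res$rotu_set$membership, sim$truth$samples,
                            by = "sample_id")
  truth_order <- memb |>
    dplyr::distinct(rotu_id, order)
  joined <- dplyr::inner_join(res$rotu_table, truth_order,
                              by = "rotu_id", suffix = c("_tree", "_truth"))
  expect_equal(joined$order_tree, joined$order_truth)
  # feeding transfer from nearest reference matches the truth order's code
  codes <- dplyr::distinct(refs$references[!refs$references$is_outgroup, ],
                           order, feeding_code)
  j2 <- dplyr::inner_join(joined, codes,
                          by = c(order_truth = "order"))
  expect_equal(j2$feeding_code.x, j2$feeding_code.y)
})

test_that("feeding transfer picks the patristic nearest annotated leaf", {
  tr <- ape::read.tree(text = "((q:0.1,ref1:0.2):0.3,(ref2:0.1,ref3:0.4):0.2);")
  ann <- c(ref1 = "2", ref2 = "1d", ref3 = "5")
  out <- assign_feeding_type(tr, "q", ann)
  expect_equal(out$feeding_code, "2")
  expect_equal(out$nearest_reference, "ref1")
  # oracle: brute-force all-pairs patristic distance
  pd <- ape::dist.nodes(tr)
  tips <- setNames(seq_along(tr$tip.label), tr$tip.label)
  d_brute <- pd[tips["q"], tips[c("ref1", "ref2", "ref3")]]
  expect_equal(out$distance, unname(min(d_brute)))
  expect_error(assign_feeding_type(tr, "q", c(ref1 = "2"),
                                   reference_leaves = c("ref1", "ref2")),
               "missing feeding annotation")
  # zero-distance reference wins outright
  tr0 <- ape::read.tree(text = "((q:0,refA:0):0.5,refB:0.1);")
  expect_equal(assign_feeding_type(tr0, "q",
                                   c(refA = "2", refB = "3"))$feeding_code,
               "2")
})

test_that("concatenation comparison aligns reports across region sets", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),o);")
  labs <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", o = "outgroup")
  cmp <- compare_concatenations(list(R1 = tr, R1_2 = tr), labs)
  expect_equal(cmp$long$n_clusters, rep(1L, 4))
  # identical trees give identical columns
  expect_equal(cmp$n_clusters$R1, cmp$n_clusters$R1_2)
  # a worse tree shows more clusters in its column
  bad <- ape::read.tree(text = "(((a1,b1),(a2,b2)),o);")
  cmp2 <- compare_concatenations(list(good = tr, bad = bad), labs)
  wide <- cmp2$n_clusters
  expect_true(all(wide$bad >= wide$good))
  expect_equal(wide$bad[wide$order == "A"], 2L)
})
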