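test_that("SV ranking picks the top nematode SV and floors minors", {
  tb <- dplyr::bind_rows(
    sv_row("s1", 1, "svA", 7000, seq = "AAAA"),
    sv_row("s1", 1, "svB", 2500, seq = "CCCC"),
    sv_row("s1", 1, "svC", 40, seq = "GGGG"),
    sv_row("s1", 1, "f", 500, seq = "TTTT", phylum = "Ascomycota",
           order = NA)
  )
  r <- rank_svs(tb)
  expect_equal(r$sv_id[r$role == "major"], "svA")
  expect_equal(r$sv_id[r$role == "minor"], "svB")  # svC below the 7% floor
  # single nematode SV: no minors
  solo <- rank_svs(sv_row("s2", 1, "only", 100))
  expect_equal(solo$role, "major")
})

test_that("minor classification separates alleles, second nematodes, ambiguity", {
  maj <- list(sv_id = "M", sequence = "ACGTACGTACGTACGTACGT",
              order = "Dorylaimida")
  # one base-mismatch, same order -> polymorphic allele
  allele <- list(sv_id = "m1", sequence = "ACGTACGTACGAACGTACGT",
                 order = "Dorylaimida")
  call <- classify_minor(maj, allele, n_cooccurring = 11)
  expect_equal(call$classification, "polymorphic_allele")
  expect_equal(call$edit_distance, 1L)
  expect_equal(call$edit_summary, "T/A")
  expect_equal(call$n_cooccurring_samples, 11L)
  # substitution + 2-nt insertion (distance 3), same order -> still allele
  ins <- list(sv_id = "m2", sequence = "ACGTACGGGTACGAACGTACGT",
              order = "Dorylaimida")
  expect_equal(classify_minor(maj, ins)$classification,
               "polymorphic_allele")
  expect_equal(classify_minor(maj, ins)$edit_distance, 3L)
  # different order -> second nematode regardless of distance
  other <- list(sv_id = "m3", sequence = "ACGTACGTACGAACGTACGT",
                order = "Rhabditida")
  expect_equal(classify_minor(maj, other)$classification,
               "second_nematode")
  # same order, distance beyond the ceiling -> ambiguous
  far <- list(sv_id = "m4", sequence = "GGGGGGGGGGGGGGGGGGGG",
              order = "Dorylaimida")
  expect_equal(classify_minor(maj, far)$classification, "ambiguous")
})

test_that("edit summaries mirror the allele-table notation", {
  expect_equal(edit_summary("ACGT", "ACGA"), "T/A")
  expect_equal(edit_summary("TTTTATTTTATTTTATTTTA", "TTTTCTTTTCTTTTCTTTTC"),
               "A/C (4 sites)")
  expect_equal(edit_summary("AACCTT", "AACCGGTT"), "GG insertion")
  expect_equal(edit_summary("AACGCTT", "AACCTT"), "G deletion")
  expect_equal(edit_summary("AAATTTAAA", "AAATTTAAA"), "")
  expect_equal(edit_summary("AACGAACCAA", "AACTAACCGGAA"),
               "G/T, GG insertion")
})

test_that("allele classification is symmetric under major/minor swap", {
  set.seed(17)
  for (i in 1:20) {
    base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    variant <- nematax:::.apply_allele_edits(base, sample(1:5, 1))
    a <- list(sv_id = "a", sequence = base, order = "X")
    b <- list(sv_id = "b", sequence = variant, order = "X")
    expect_equal(classify_minor(a, b)$classification, "polymorphic_allele")
    expect_equal(classify_minor(b, a)$classification, "polymorphic_allele")
  }
})

test_that("unresolvable multi-variant samples are flagged for exclusion", {
  calls <- tibble::tibble(
    sample_id = c("id14", "id14", "clean", "two_order"),
    region = c(3L, 3L, 1L, 1L),
    classification = c("ambiguous", "ambiguous", "polymorphic_allele",
                       "second_nematode")
  )
  expect_equal(flag_ambiguous_isolates(calls), "id14")
  # a single ambiguous call alongside an allele also trips the 3-SV rule
  calls2 <- tibble::tibble(
    sample_id = "mixed", region = 2L,
    classification = c("polymorphic_allele", "ambiguous")
  )
  expect_equal(flag_ambiguous_isolates(calls2), "mixed")
  expect_length(flag_ambiguous_isolates(calls[3, ]), 0)
})

test_that("resolution recovers truth with perfect sensitivity and specificity", {
  cfg <- small_config(seed = 88, n_samples = 40, polymorphism_rate = 0.5,
                      predation_rate = 0.15, fail_rate = 0,
                      contamination_rate = 0)
  sim <- simulate_sv_tables(cfg, small_reference_set())
  sel <- select_nematode_samples(sim$sv_table)
  res <- resolve_isolates(sim$sv_table, samples = sel$retained)
  truth_keys <- with(sim$truth$allele_pairs, paste(sample_id, region))
  called <- res$allele_calls
  allele_keys <- with(called[called$classification == "polymorphic_allele", ],
                      paste(sample_id, region))
  expect_setequal(allele_keys, truth_keys)   # sensitivity & specificity 1
  # second-nematode detection matches the predation truth
  truth_pred <- sim$truth$samples$sample_id[sim$truth$samples$second_nematode]
  called_pred <- unique(called$sample_id[called$classification ==
                                           "second_nematode"])
  expect_setequal(called_pred, truth_pred)
  expect_setequal(res$flags$sample_id[res$flags$multi_nematode], truth_pred)
  # majors come from the source specimen even in predation samples
  prof <- dplyr::inner_join(res$profiles, sim$truth$samples,
                            by = "sample_id")
  expect_true(all(prof$order.x == prof$order.y))
})
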