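#' Pipeline configuration
#'
#' Thresholds and settings for the end-to-end analysis. The defaults are
#' the study conditions of the survey design this package implements:
#' samples need more than 1,000 nematode-derived reads and a nematode
#' relative abundance over 65%; minor SVs qualify above a 7% share of
#' nematode reads; allele pairs may differ by up to 5 edits; phylum
#' fractions under 1% are dropped; distances are Jukes-Cantor; trees carry
#' 1,000 bootstrap replicates.
#'
#' @param min_reads,min_nem_frac,minor_floor,max_allele_edits,phylum_min_frac
#'   QC and resolution thresholds (see [select_nematode_samples()],
#'   [rank_svs()], [classify_minor()], [aggregate_phylum()]).
#' @param model Distance model, `"JC"` or `"p"`.
#' @param bootstrap Bootstrap replicates per tree.
#' @param experiment_code rOTU id prefix.
#' @param region_sets List of integer vectors: the region combinations to
#'   build trees for.
#' @param seed Integer seed driving the bootstrap (mandatory).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 1000, min_nem_frac = 0.65,
                            minor_floor = 0.07, max_allele_edits = 5L,
                            phylum_min_frac = 0.01, model = c("JC", "p"),
                            bootstrap = 1000L, experiment_code = "Z01",
                            region_sets = list(1L, 2L, 3L, 4L, 1:2, 3:4,
                                               2:4, 1:4),
                            seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  model <- match.arg(model)
  cfg <- list(min_reads = min_reads, min_nem_frac = min_nem_frac,
              minor_floor = minor_floor,
              max_allele_edits = as.integer(max_allele_edits),
              phylum_min_frac = phylum_min_frac, model = model,
              bootstrap = as.integer(bootstrap),
              experiment_code = experiment_code,
              region_sets = lapply(region_sets, as.integer),
              seed = as.integer(seed))
  stopifnot(cfg$min_reads >= 0, cfg$min_nem_frac >= 0,
            cfg$min_nem_frac <= 1, cfg$minor_floor >= 0,
            cfg$minor_floor <= 1, cfg$bootstrap >= 0)
  structure(cfg, class = "pipeline_config")
}

.region_set_label <- function(rs) paste0("R", paste(rs, collapse = "_"))

#' Run the full specimen-barcoding analysis
#'
#' Chains every stage: per-sample QC of the SV tables, phylum composition,
#' major/minor SV resolution into allele calls, exclusion of unresolvable
#' samples, rOTU clustering with polymorphic-allele attachment, NJ trees
#' with bootstrap over each configured region set (references + rOTU major
#' sequences, outgroup-rooted), the order-cluster-count evaluation, and
#' order/feeding assignment of each rOTU from its tree placement.
#'
#' @param sv_table Long SV tibble (`sample_id`, `region`, `sv_id`, `count`,
#'   `sequence`, `phylum`, `order`).
#' @param references Reference tibble as from [simulate_reference_set()]
#'   (`species_id`, `order`, `feeding_code`, `is_outgroup`, `sequence`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, every artifact is also
#'   written there (TSV/FASTA/newick).
#' @return A `nema_pipeline` object: list with `qc`, `phylum_composition`,
#'   `allele_calls`, `excluded_samples`, `rotu_set`, `rotu_table`,
#'   `polymorphic`, `trees`, `cluster_report`, `order_summary`,
#'   `feeding_summary`, `tree_exclusions`, `config`, `hash`.
#' @export
run_pipeline <- function(sv_table, references, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- select_nematode_samples(sv_table, min_reads = config$min_reads,
                                min_nem_frac = config$min_nem_frac,
                                minor_floor = config$minor_floor)
  phylum <- aggregate_phylum(relative_abundance(sv_table),
                             min_frac = config$phylum_min_frac)
  res <- resolve_isolates(sv_table, samples = qc$retained,
                          minor_floor = config$minor_floor,
                          max_allele_edits = config$max_allele_edits)
  keep <- res$flags$sample_id[!res$flags$ambiguous_excluded]
  profiles <- res$profiles |> dplyr::filter(.data$sample_id %in% keep)
  if (nrow(profiles) == 0L) {
    warning("no samples survived QC; returning empty result", call. = FALSE)
  }
  rotu_set <- cluster_isolates(profiles,
                               experiment_code = config$experiment_code)
  poly <- attach_alleles(rotu_set, res$allele_calls)

  # regional sequences: references by in-silico PCR, rOTUs by their SVs
  ref_regions <- extract_regions(references, ssu_primers())
  rotu_seqs <- rotu_set$regional |>
    dplyr::left_join(dplyr::distinct(sv_table, .data$region, .data$sv_id,
                                     .data$sequence),
                     by = c("region", "sv_id")) |>
    dplyr::transmute(species_id = .data$rotu_id, region = .data$region,
                     sequence = .data$sequence, complete = TRUE)
  all_regions <- dplyr::bind_rows(
    dplyr::select(ref_regions, "species_id", "region", "sequence",
                  "complete"),
    rotu_seqs
  )
  outgroup <- references$species_id[references$is_outgroup][1]
  trees <- list()
  exclusions <- list()
  set.seed(config$seed)
  tree_seeds <- sample.int(.Machine$integer.max,
                           length(config$region_sets))
  for (k in seq_along(config$region_sets)) {
    rs <- config$region_sets[[k]]
    label <- .region_set_label(rs)
    cc <- concatenate_regions(all_regions, regions = rs)
    exclusions[[label]] <- cc$excluded
    if (length(cc$sequences) < 3L || !outgroup %in% names(cc$sequences)) {
      next
    }
    tr <- bootstrap_support(cc$sequences, B = config$bootstrap,
                            seed = tree_seeds[k], model = config$model)
    trees[[label]] <- root_at_outgroup(tr, outgroup)
  }
  labels <- c(
    stats::setNames(references$order, references$species_id),
    stats::setNames(rep("rOTU", nrow(rotu_set$rotus)),
                    rotu_set$rotus$rotu_id)
  )
  labels[outgroup] <- "outgroup"
  cluster_report <- if (length(trees) > 0) {
    compare_concatenations(trees, labels)
  } else {
    NULL
  }
  # order/feeding per rOTU from the longest tree containing it, falling
  # back to shorter concatenations for rOTUs missing a region
  ref_orders <- stats::setNames(references$order[!references$is_outgroup],
                                references$species_id[!references$is_outgroup])
  annotation <- stats::setNames(
    references$feeding_code[!references$is_outgroup],
    references$species_id[!references$is_outgroup]
  )
  pref <- rev(names(trees))  # longest concatenations last in config order
  assign_one <- function(rid) {
    for (lab in pref) {
      tr <- trees[[lab]]
      if (rid %in% tr$tip.label) {
        ord <- assign_rotu_order(tr, rid, ref_orders)
        fd <- assign_feeding_type(tr, rid, annotation)
        return(dplyr::bind_cols(ord,
                                dplyr::select(fd, -"rotu"),
                                tibble::tibble(tree_used = lab)))
      }
    }
    tibble::tibble(rotu = rid, order = NA_character_, clade_size = 0L,
                   feeding_code = NA_character_,
                   nearest_reference = NA_character_,
                   distance = NA_real_, tree_used = NA_character_)
  }
  assignments <- if (length(trees) > 0 && nrow(rotu_set$rotus) > 0) {
    purrr::map_dfr(rotu_set$rotus$rotu_id, assign_one)
  } else {
    tibble::tibble(rotu = character(0), order = character(0),
                   clade_size = integer(0), feeding_code = character(0),
                   nearest_reference = character(0), distance = numeric(0),
                   tree_used = character(0))
  }
  rotu_table <- rotu_set$rotus |>
    dplyr::left_join(assignments, by = c(rotu_id = "rotu"))
  order_summary <- if (nrow(rotu_table) > 0) {
    summarize_orders(rotu_table)
  } else {
    tibble::tibble()
  }
  feeding_summary <- if (nrow(rotu_table) > 0) {
    summarize_feeding(rotu_table)
  } else {
    tibble::tibble()
  }
  result <- list(
    qc = qc, phylum_composition = phylum,
    allele_calls = res$allele_calls,
    excluded_samples = res$flags$sample_id[res$flags$ambiguous_excluded],
    flags = res$flags,
    rotu_set = rotu_set, rotu_table = rotu_table, polymorphic = poly,
    trees = trees, tree_exclusions = exclusions,
    cluster_report = cluster_report,
    order_summary = order_summary, feeding_summary = feeding_summary,
    config = config
  )
  result$hash <- rlang::hash(result[setdiff(names(result), "hash")])
  class(result) <- "nema_pipeline"
  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

#' Write every pipeline artifact to a directory
#'
#' @param result A `nema_pipeline` object.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result_bundle <- function(result, out_dir) {
  stopifnot(inherits(result, "nema_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(result$qc$report, p("qc_report.tsv"))
  readr::write_tsv(result$phylum_composition, p("phylum_composition.tsv"))
  readr::write_tsv(result$allele_calls, p("allele_calls.tsv"))
  readr::write_tsv(
    dplyr::mutate(result$rotu_table,
                  sample_ids = vapply(.data$sample_ids, paste,
                                      character(1), collapse = ",")),
    p("rotu_table.tsv")
  )
  if (!is.null(result$cluster_report)) {
    readr::write_tsv(result$cluster_report$long, p("cluster_report.tsv"))
  }
  if (nrow(result$order_summary) > 0) {
    readr::write_tsv(result$order_summary, p("order_summary.tsv"))
  }
  if (nrow(result$feeding_summary) > 0) {
    readr::write_tsv(result$feeding_summary, p("feeding_summary.tsv"))
  }
  for (nm in names(result$trees)) {
    write_newick(result$trees[[nm]], p(paste0("tree_", nm, ".nwk")))
  }
  writeLines(c(paste0("hash: ", result$hash),
               paste0("seed: ", result$config$seed)),
             p("run_stamp.txt"))
  invisible(out_dir)
}

#' @export
print.nema_pipeline <- function(x, ...) {
  cat("<nema_pipeline>\n")
  cat("  samples passing QC: ",
      length(unique(x$qc$retained$sample_id)), "\n", sep = "")
  cat("  rOTUs: ", nrow(x$rotu_set$rotus), "\n", sep = "")
  cat("  trees: ", paste(names(x$trees), collapse = ", "), "\n", sep = "")
  cat("  hash: ", x$hash, "\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline Tidy per-rOTU table of the result.
#' @param x A `nema_pipeline`.
#' @param ... Unused.
#' @method tidy nema_pipeline
#' @export
tidy.nema_pipeline <- function(x, ...) {
  x$rotu_table
}

#' @describeIn run_pipeline One-row pipeline summary.
#' @method glance nema_pipeline
#' @export
glance.nema_pipeline <- function(x, ...) {
  tibble::tibble(
    n_samples_retained = length(unique(x$qc$retained$sample_id)),
    n_excluded_ambiguous = length(x$excluded_samples),
    n_rotus = nrow(x$rotu_set$rotus),
    n_isolates = sum(x$rotu_set$rotus$n_isolates),
    n_polymorphic = nrow(x$polymorphic),
    n_trees = length(x$trees),
    seed = x$config$seed
  )
}
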