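#' Cluster isolates sharing identical regional major SVs into rOTUs
#'
#' Two isolates belong to the same SSU-derived operational taxonomic unit
#' (rOTU) iff their major SVs are identical in EVERY region where both have
#' data and they share at least one region. Merging is transitive through
#' isolates with partial region coverage, but a conflict (equal in one
#' region, different in another) blocks a merge even through intermediates.
#' rOTUs are ranked by descending member count (ties by smallest member
#' sample number) and named `<code>rOTU<NN>`.
#'
#' @param profiles Long tibble with `sample_id`, `region`, `sv_id` (one row
#'   per isolate x region with a major SV). Extra columns are ignored.
#' @param experiment_code Prefix for rOTU ids (default `"Z01"`).
#' @return An object of class `rotu_set`: list with `rotus` (tibble
#'   `rotu_id`, `n_isolates`, `sample_ids` list-column), `membership`
#'   (tibble `sample_id`, `rotu_id`), `regional` (tibble `rotu_id`,
#'   `region`, `regional_rotu`, `sv_id`) and `experiment_code`.
#' @examples
#' pr <- tibble::tibble(sample_id = rep(c("s1", "s2", "s3"), each = 2),
#'                      region = rep(1:2, 3),
#'                      sv_id = c("a", "b", "a", "b", "a", "c"))
#' cluster_isolates(pr)
#' @export
cluster_isolates <- function(profiles, experiment_code = "Z01") {
  stopifnot(is.data.frame(profiles),
            all(c("sample_id", "region", "sv_id") %in% names(profiles)))
  if (anyDuplicated(profiles[c("sample_id", "region")]) > 0) {
    stop("at most one major SV per sample and region", call. = FALSE)
  }
  ids <- unique(profiles$sample_id)
  n <- length(ids)
  if (n == 0L) {
    return(structure(list(
      rotus = tibble::tibble(rotu_id = character(0), n_isolates = integer(0),
                             sample_ids = list()),
      membership = tibble::tibble(sample_id = character(0),
                                  rotu_id = character(0)),
      regional = tibble::tibble(rotu_id = character(0), region = integer(0),
                                regional_rotu = character(0),
                                sv_id = character(0)),
      experiment_code = experiment_code
    ), class = "rotu_set"))
  }
  # per-isolate region -> SV map
  sv_of <- lapply(ids, function(s) {
    rows <- profiles[profiles$sample_id == s, ]
    stats::setNames(rows$sv_id, rows$region)
  })
  names(sv_of) <- ids
  relation <- function(i, j) {
    a <- sv_of[[i]]; b <- sv_of[[j]]
    shared <- intersect(names(a), names(b))
    if (length(shared) == 0L) return("none")
    if (all(a[shared] == b[shared])) "match" else "conflict"
  }
  rel <- matrix("none", n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) rel[i, j] <- rel[j, i] <- relation(i, j)
  }
  # union-find; a union is refused if it would co-cluster a conflicting pair
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  members <- function(root) which(vapply(seq_len(n), find, integer(1)) == root)
  edges <- which(rel == "match" & upper.tri(rel), arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri == rj) next
    mi <- members(ri); mj <- members(rj)
    if (any(rel[mi, mj, drop = FALSE] == "conflict")) {
      warning("merge of incompatible isolate chain refused", call. = FALSE)
      next
    }
    parent[rj] <- ri
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, comp)
  # rank: size desc, tie by smallest member sample number
  sample_num <- function(s) {
    num <- suppressWarnings(as.integer(stringr::str_extract(s, "\\d+$")))
    ifelse(is.na(num), .Machine$integer.max, num)
  }
  key <- tibble::tibble(
    grp = names(groups),
    size = lengths(groups),
    min_member = vapply(groups, function(g) min(sample_num(g)),
                        numeric(1)),
    min_id = vapply(groups, function(g) min(g), character(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_member, .data$min_id)
  rotu_ids <- sprintf("%srOTU%02d", experiment_code, seq_len(nrow(key)))
  rotus <- tibble::tibble(
    rotu_id = rotu_ids,
    n_isolates = unname(key$size),
    sample_ids = unname(lapply(key$grp, function(g) sort(groups[[g]])))
  )
  membership <- tidyr::unnest(
    dplyr::select(rotus, "rotu_id", sample_id = "sample_ids"),
    "sample_id"
  )[c("sample_id", "rotu_id")]
  regional <- profiles |>
    dplyr::inner_join(membership, by = "sample_id") |>
    dplyr::distinct(.data$rotu_id, .data$region, .data$sv_id) |>
    dplyr::mutate(regional_rotu = paste0(.data$rotu_id, "_R",
                                         .data$region)) |>
    dplyr::arrange(.data$rotu_id, .data$region) |>
    dplyr::select("rotu_id", "region", "regional_rotu", "sv_id")
  structure(list(rotus = rotus, membership = membership,
                 regional = regional, experiment_code = experiment_code),
            class = "rotu_set")
}

#' Attach polymorphic allelic SVs to their rOTUs
#'
#' Minor SVs classified as polymorphic alleles are attached to the rOTU of
#' their sample as regional polymorphic rOTUs, suffixed `a`, `b`, ... per
#' region in discovery order (first sample carrying them).
#'
#' @param rotu_set A [cluster_isolates()] result.
#' @param allele_calls Allele-call tibble from [resolve_isolates()].
#' @return Tibble `rotu_id`, `region`, `polymorphic_rotu`, `sv_id`,
#'   `allele` (edit summary), `n_isolates`, `sample_ids` (list-column).
#' @export
attach_alleles <- function(rotu_set, allele_calls) {
  stopifnot(inherits(rotu_set, "rotu_set"))
  poly <- allele_calls |>
    dplyr::filter(.data$classification == "polymorphic_allele") |>
    dplyr::inner_join(rotu_set$membership, by = "sample_id")
  if (nrow(poly) == 0L) {
    return(tibble::tibble(rotu_id = character(0), region = integer(0),
                          polymorphic_rotu = character(0),
                          sv_id = character(0), allele = character(0),
                          n_isolates = integer(0), sample_ids = list()))
  }
  poly |>
    dplyr::group_by(.data$rotu_id, .data$region, .data$minor_sv) |>
    dplyr::summarise(
      allele = .data$edit_summary[1],
      n_isolates = dplyr::n_distinct(.data$sample_id),
      sample_ids = list(sort(unique(.data$sample_id))),
      first_seen = min(.data$sample_id),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(.data$first_seen, .by_group = TRUE) |>
    dplyr::mutate(polymorphic_rotu = paste0(.data$rotu_id, "_R",
                                            .data$region,
                                            letters[dplyr::row_number()])) |>
    dplyr::ungroup() |>
    dplyr::select("rotu_id", "region", "polymorphic_rotu",
                  sv_id = "minor_sv", "allele", "n_isolates", "sample_ids")
}

#' Per-order isolate counts and percentages
#'
#' @param rotus Tibble with `n_isolates` and `order` columns (e.g.
#'   [tidy()][tidy.rotu_set] output joined with order assignments).
#' @return Tibble `order`, `n_rotus`, `n_isolates`, `percent` (of all
#'   isolates, rounded half away from zero to one decimal), ordered by
#'   descending isolate count.
#' @export
summarize_orders <- function(rotus) {
  stopifnot(all(c("n_isolates", "order") %in% names(rotus)))
  total <- sum(rotus$n_isolates)
  rotus |>
    dplyr::mutate(order = dplyr::coalesce(.data$order, "NA")) |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(n_rotus = dplyr::n(),
                     n_isolates = sum(.data$n_isolates), .groups = "drop") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_isolates / total,
                                          1)) |>
    dplyr::arrange(dplyr::desc(.data$n_isolates))
}

#' Map a feeding-type code to its trophic category
#'
#' Codes follow the conventional nematode feeding-type scheme: `1b`, `1d`,
#' `1e` plant feeding; `2` hyphal (fungal) feeding; `3` bacterial feeding;
#' `5` predation; `8` omnivory. A trailing `?` (uncertain call) is grouped
#' with its base code.
#'
#' @param code Character vector of feeding codes.
#' @return Character vector of categories (`"fungivore"`,
#'   `"plant_feeder"`, `"bacterivore"`, `"predator_omnivore"`, `"other"`).
#' @export
feeding_category <- function(code) {
  base <- sub("\\?$", "", code)
  out <- dplyr::case_when(
    base == "2" ~ "fungivore",
    base %in% c("1b", "1d", "1e") ~ "plant_feeder",
    base == "3" ~ "bacterivore",
    base %in% c("5", "8") ~ "predator_omnivore",
    TRUE ~ "other"
  )
  if (any(out == "other" & !is.na(code))) {
    warning("unknown feeding code(s) grouped as 'other': ",
            paste(unique(code[out == "other"]), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Per-feeding-type isolate counts and percentages
#'
#' @param rotus Tibble with `n_isolates` and `feeding_code` columns.
#' @return Tibble `feeding_type`, `n_rotus`, `n_isolates`, `percent`
#'   (rounded half away from zero to one decimal).
#' @export
summarize_feeding <- function(rotus) {
  stopifnot(all(c("n_isolates", "feeding_code") %in% names(rotus)))
  if (nrow(rotus) == 0L) {
    return(tibble::tibble(feeding_type = character(0), n_rotus = integer(0),
                          n_isolates = integer(0), percent = numeric(0)))
  }
  total <- sum(rotus$n_isolates)
  rotus |>
    dplyr::mutate(feeding_type = feeding_category(.data$feeding_code)) |>
    dplyr::group_by(.data$feeding_type) |>
    dplyr::summarise(n_rotus = dplyr::n(),
                     n_isolates = sum(.data$n_isolates), .groups = "drop") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_isolates / total,
                                          1)) |>
    dplyr::arrange(dplyr::desc(.data$n_isolates))
}

#' @describeIn cluster_isolates Tidy the rOTU table (one row per rOTU).
#' @param x A `rotu_set`.
#' @param ... Unused.
#' @method tidy rotu_set
#' @export
tidy.rotu_set <- function(x, ...) {
  x$rotus
}

#' @describeIn cluster_isolates One-row summary of the clustering.
#' @method glance rotu_set
#' @export
glance.rotu_set <- function(x, ...) {
  tibble::tibble(
    n_rotus = nrow(x$rotus),
    n_isolates = sum(x$rotus$n_isolates),
    largest_rotu = if (nrow(x$rotus)) max(x$rotus$n_isolates) else 0L,
    n_singletons = sum(x$rotus$n_isolates == 1L)
  )
}

#' @export
print.rotu_set <- function(x, ...) {
  g <- glance.rotu_set(x)
  cat("<rotu_set> ", g$n_rotus, " rOTUs from ", g$n_isolates,
      " isolates (largest: ", g$largest_rotu, ")\n", sep = "")
  print(x$rotus, ...)
  invisible(x)
}
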