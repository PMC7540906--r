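#' Rank nematode SVs within each sample and region
#'
#' The most abundant nematode-derived SV in a single-specimen sample is
#' taken to come from that specimen (the major SV). Remaining nematode SVs
#' are reported as minors only when their share of the sample's nematode
#' reads exceeds `minor_floor`; anything below is treated as noise. Count
#' ties are broken lexicographically by SV sequence for determinism.
#'
#' @param sv_table Long SV tibble (`sample_id`, `region`, `sv_id`, `count`,
#'   `sequence`, `phylum`, `order`).
#' @param samples Optional tibble (`sample_id`, `region`) restricting the
#'   ranking to QC-passing combinations.
#' @param minor_floor Minimum share of nematode reads for a minor SV
#'   (strict `>`, default 0.07).
#' @return Tibble with `sample_id`, `region`, `sv_id`, `sequence`, `order`,
#'   `count`, `nem_frac` (share of nematode reads) and `role`
#'   (`"major"`/`"minor"`); minors ordered by descending count.
#' @export
rank_svs <- function(sv_table, samples = NULL, minor_floor = 0.07) {
  tab <- sv_table |> dplyr::filter(.data$phylum %in% "Nematoda")
  if (!is.null(samples)) {
    tab <- dplyr::semi_join(tab, samples, by = c("sample_id", "region"))
  }
  tab |>
    dplyr::group_by(.data$sample_id, .data$region) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence,
                   .by_group = TRUE) |>
    dplyr::mutate(
      nem_frac = .data$count / sum(.data$count),
      role = dplyr::if_else(dplyr::row_number() == 1L, "major", "minor")
    ) |>
    dplyr::filter(.data$role == "major" | .data$nem_frac > minor_floor) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "region", "sv_id", "sequence", "order",
                  "count", "nem_frac", "role")
}

#' Classify a minor nematode SV against its sample's major SV
#'
#' A minor SV whose order label differs from the major's is a second
#' nematode (predation or carcass contamination). A same-order minor within
#' `max_allele_edits` Levenshtein edits of the major is a polymorphic rDNA
#' allele — recurrence of the same major/minor pair across samples is
#' recorded as supporting evidence but not required, since genuine allele
#' pairs can appear in a single specimen. Anything else is ambiguous.
#'
#' @param major,minor One-row slices (or lists) with `sv_id`, `sequence`,
#'   `order` for the major and minor SV.
#' @param max_allele_edits Edit-distance ceiling for allele calls
#'   (default 5).
#' @param n_cooccurring Number of samples in which this major/minor pair
#'   co-occurs (from [resolve_isolates()]; informational).
#' @return One-row tibble: `major_sv`, `minor_sv`, `edit_distance`,
#'   `edit_summary`, `n_cooccurring_samples`, `classification`.
#' @export
classify_minor <- function(major, minor, max_allele_edits = 5L,
                           n_cooccurring = 1L) {
  ed <- edit_distance(major$sequence, minor$sequence)
  cls <- if (!is.na(major$order) && !is.na(minor$order) &&
             major$order != minor$order) {
    "second_nematode"
  } else if (ed <= max_allele_edits) {
    "polymorphic_allele"
  } else {
    "ambiguous"
  }
  tibble::tibble(
    major_sv = major$sv_id, minor_sv = minor$sv_id,
    edit_distance = ed,
    edit_summary = edit_summary(major$sequence, minor$sequence),
    n_cooccurring_samples = as.integer(n_cooccurring),
    classification = cls
  )
}

#' Resolve every sample's minor SVs into allele calls and isolate profiles
#'
#' Runs [rank_svs()] and [classify_minor()] across a table, builds the
#' per-sample isolate profiles used for rOTU clustering, and flags samples
#' whose minor-SV structure cannot be resolved (see
#' [flag_ambiguous_isolates()]).
#'
#' @inheritParams rank_svs
#' @inheritParams classify_minor
#' @return List with `allele_calls` (one row per sample x region x minor),
#'   `profiles` (one row per sample x region: the major SV), and `flags`
#'   (per sample: `multi_nematode`, `ambiguous_excluded`).
#' @export
resolve_isolates <- function(sv_table, samples = NULL, minor_floor = 0.07,
                             max_allele_edits = 5L) {
  ranked <- rank_svs(sv_table, samples = samples, minor_floor = minor_floor)
  majors <- ranked |> dplyr::filter(.data$role == "major")
  minors <- ranked |> dplyr::filter(.data$role == "minor")
  # co-occurrence index: in how many samples does a (region, major, minor)
  # sequence pair appear together?
  pair_index <- minors |>
    dplyr::inner_join(majors, by = c("sample_id", "region"),
                      suffix = c("_min", "_maj")) |>
    dplyr::count(.data$region, .data$sequence_maj, .data$sequence_min,
                 name = "n_cooccurring")
  calls <- minors |>
    dplyr::inner_join(majors, by = c("sample_id", "region"),
                      suffix = c("_min", "_maj")) |>
    dplyr::left_join(pair_index,
                     by = c("region", "sequence_maj", "sequence_min"))
  allele_calls <- purrr::pmap_dfr(calls, function(...) {
    row <- list(...)
    dplyr::bind_cols(
      tibble::tibble(sample_id = row$sample_id, region = row$region),
      classify_minor(
        major = list(sv_id = row$sv_id_maj, sequence = row$sequence_maj,
                     order = row$order_maj),
        minor = list(sv_id = row$sv_id_min, sequence = row$sequence_min,
                     order = row$order_min),
        max_allele_edits = max_allele_edits,
        n_cooccurring = row$n_cooccurring
      )
    )
  })
  if (nrow(allele_calls) == 0L) {
    allele_calls <- tibble::tibble(
      sample_id = character(0), region = integer(0),
      major_sv = character(0), minor_sv = character(0),
      edit_distance = integer(0), edit_summary = character(0),
      n_cooccurring_samples = integer(0), classification = character(0)
    )
  }
  excluded <- flag_ambiguous_isolates(allele_calls)
  flags <- tibble::tibble(sample_id = unique(majors$sample_id)) |>
    dplyr::mutate(
      multi_nematode = .data$sample_id %in%
        allele_calls$sample_id[allele_calls$classification ==
                                 "second_nematode"],
      ambiguous_excluded = .data$sample_id %in% excluded
    )
  list(
    allele_calls = allele_calls,
    profiles = dplyr::select(majors, "sample_id", "region", "sv_id",
                             "sequence", "order"),
    flags = flags
  )
}

#' Flag samples whose minor-SV structure cannot be resolved
#'
#' A sample is excluded when, in any region, it carries two or more
#' same-order minors beyond the allele edit ceiling, or three or more
#' distinct same-order SVs that do not form a single allele family — the
#' situation where "two related nematodes" and "polymorphic alleles"
#' cannot be told apart.
#'
#' @param allele_calls Tibble from [resolve_isolates()] (or built by hand)
#'   with `sample_id`, `region`, `classification`.
#' @return Character vector of excluded sample ids.
#' @export
flag_ambiguous_isolates <- function(allele_calls) {
  if (nrow(allele_calls) == 0L) return(character(0))
  allele_calls |>
    dplyr::group_by(.data$sample_id, .data$region) |>
    dplyr::summarise(
      n_ambig = sum(.data$classification == "ambiguous"),
      n_same_order = sum(.data$classification != "second_nematode"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_ambig >= 2L |
                    (.data$n_same_order >= 2L & .data$n_ambig >= 1L)) |>
    dplyr::pull(.data$sample_id) |>
    unique()
}
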