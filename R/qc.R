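#' Round half away from zero
#'
#' Fixed-convention rounding used for every percentage the package reports,
#' so that printed summaries are reproducible across platforms (base
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Convert SV counts to within-sample relative abundances
#'
#' @param sv_table Long SV tibble with `sample_id`, `region`, `sv_id`,
#'   `count` (and any metadata columns, carried through).
#' @return The input with an added `rel_abundance` column (per sample x
#'   region proportions summing to 1) and a logical `zero_total` flag for
#'   samples with no reads in a region (left undivided, `rel_abundance`
#'   `NA`).
#' @examples
#' tb <- tibble::tibble(sample_id = "s1", region = 1,
#'                      sv_id = c("a", "b"), count = c(750, 250))
#' relative_abundance(tb)
#' @export
relative_abundance <- function(sv_table) {
  stopifnot(is.data.frame(sv_table),
            all(c("sample_id", "region", "sv_id", "count") %in%
                  names(sv_table)))
  if (any(sv_table$count < 0)) stop("negative counts", call. = FALSE)
  sv_table |>
    dplyr::group_by(.data$sample_id, .data$region) |>
    dplyr::mutate(
      zero_total = sum(.data$count) == 0,
      rel_abundance = dplyr::if_else(.data$zero_total, NA_real_,
                                     .data$count / sum(.data$count))
    ) |>
    dplyr::ungroup()
}

#' Phylum-level composition per sample
#'
#' Sums SV relative abundances into per-phylum fractions and then removes
#' phyla whose summed fraction falls strictly below `min_frac` (the
#' "less than 1%" rule: a phylum at exactly 1% is retained). Unassigned
#' SVs (`NA` phylum) are kept as their own `"NA"` category.
#'
#' @param rel_table Output of [relative_abundance()]; must carry a
#'   `phylum` column.
#' @param min_frac Removal floor applied AFTER summation (default 0.01).
#' @return Tibble `sample_id`, `region`, `phylum`, `fraction`.
#' @export
aggregate_phylum <- function(rel_table, min_frac = 0.01) {
  stopifnot("phylum" %in% names(rel_table),
            "rel_abundance" %in% names(rel_table))
  rel_table |>
    dplyr::filter(!.data$zero_total) |>
    dplyr::mutate(phylum = dplyr::coalesce(.data$phylum, "NA")) |>
    dplyr::group_by(.data$sample_id, .data$region, .data$phylum) |>
    dplyr::summarise(fraction = sum(.data$rel_abundance),
                     .groups = "drop") |>
    dplyr::filter(.data$fraction >= min_frac) |>
    dplyr::arrange(.data$sample_id, .data$region,
                   dplyr::desc(.data$fraction))
}

#' Select samples dominated by nematode-derived SVs
#'
#' Applies the two per-sample selection rules, per region: (1) strictly
#' more than `min_reads` nematode-derived reads, and (2) nematode relative
#' abundance strictly above `min_nem_frac`, where the nematode fraction
#' counts the most abundant nematode SV plus any minor nematode SV whose
#' own share of the sample's nematode reads exceeds `minor_floor` (the
#' polymorphic-SV allowance).
#'
#' @param sv_table Long SV tibble with `sample_id`, `region`, `sv_id`,
#'   `count`, `phylum`.
#' @param min_reads Read floor (strict `>`, default 1000).
#' @param min_nem_frac Nematode-fraction floor (strict `>`, default 0.65).
#' @param minor_floor Share of nematode reads a minor nematode SV must
#'   exceed to count toward the fraction (default 0.07).
#' @return List with `retained` (tibble `sample_id`, `region` of passing
#'   combinations) and `report` (per sample x region QC tibble with
#'   totals, fractions, per-criterion flags and a failure `reason`).
#' @export
select_nematode_samples <- function(sv_table, min_reads = 1000,
                                    min_nem_frac = 0.65,
                                    minor_floor = 0.07) {
  stopifnot("phylum" %in% names(sv_table))
  per <- sv_table |>
    dplyr::group_by(.data$sample_id, .data$region) |>
    dplyr::group_modify(function(df, key) {
      total <- sum(df$count)
      nem <- df[df$phylum %in% "Nematoda", , drop = FALSE]
      nem_reads <- sum(nem$count)
      if (nrow(nem) == 0L || total == 0L) {
        return(tibble::tibble(total_reads = total, nematode_reads = nem_reads,
                              nematode_frac = 0))
      }
      nem <- nem[order(-nem$count), ]
      counted <- nem$count[1] +
        sum(nem$count[-1][nem$count[-1] / nem_reads > minor_floor])
      tibble::tibble(total_reads = total, nematode_reads = nem_reads,
                     nematode_frac = counted / total)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pass_reads = .data$nematode_reads > min_reads,
      pass_frac = .data$nematode_frac > min_nem_frac,
      pass = .data$pass_reads & .data$pass_frac,
      reason = dplyr::case_when(
        pass ~ NA_character_,
        !pass_reads & !pass_frac ~ "read count; nematode fraction",
        !pass_reads ~ "read count",
        TRUE ~ "nematode fraction"
      )
    )
  list(
    retained = dplyr::select(dplyr::filter(per, .data$pass),
                             "sample_id", "region"),
    report = per
  )
}

#' PCR success rate from poor-reaction counts
#'
#' @param n_poor Number of reactions with poor amplification.
#' @param n_total Total reactions attempted.
#' @return Percentage of successful reactions, rounded half away from zero
#'   to one decimal.
#' @examples
#' pcr_success_rate(37, 96)  # 61.5
#' @export
pcr_success_rate <- function(n_poor, n_total) {
  if (length(n_total) != 1L || n_total <= 0) {
    stop("n_total must be a positive count", call. = FALSE)
  }
  if (any(n_poor < 0) || any(n_poor > n_total)) {
    stop("n_poor must satisfy 0 <= n_poor <= n_total", call. = FALSE)
  }
  round_half_up(100 * (n_total - n_poor) / n_total, 1)
}
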