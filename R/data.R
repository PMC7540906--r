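#' Worked-example survey: 68 soil nematode isolates at four SSU regions
#'
#' The package's bundled worked example: per-isolate major-SV assignments
#' for 68 individually isolated copse-soil nematodes genotyped at the four
#' SSU target regions, together with the published order and feeding-type
#' call for each isolate. One isolate (a 5'-problematic specimen) lacks a
#' region-3 SV. Feeding codes follow the conventional scheme (see
#' [feeding_category()]); a trailing `?` marks an uncertain call.
#'
#' @return Tibble with columns `sample_id`, `rotu` (published cluster
#'   label, for reference), `region1`-`region4` (major SV id per region,
#'   `NA` when absent), `order`, `feeding_code`.
#' @examples
#' iso <- copse_isolates()
#' nrow(iso)  # 68
#' @export
copse_isolates <- function() {
  path <- system.file("extdata", "copse_isolates.tsv", package = "nematax",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) |>
    tibble::as_tibble()
}

#' Reshape a wide isolate table into long clustering profiles
#'
#' @param isolates Wide tibble as from [copse_isolates()] (`sample_id`,
#'   `region1`..`region4`).
#' @return Long tibble `sample_id`, `region`, `sv_id` with absent regions
#'   dropped — the input contract of [cluster_isolates()].
#' @export
isolate_profiles <- function(isolates) {
  isolates |>
    dplyr::select("sample_id", dplyr::starts_with("region")) |>
    tidyr::pivot_longer(dplyr::starts_with("region"),
                        names_to = "region", values_to = "sv_id",
                        names_prefix = "region",
                        names_transform = as.integer) |>
    dplyr::filter(!is.na(.data$sv_id))
}
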