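#' Excise one primer-delimited region from a full-length sequence
#'
#' Emulates the PCR + primer-trimming step in silico: the forward primer is
#' matched on the sense strand, the reverse primer is reverse-complemented
#' and matched downstream, and the insert BETWEEN the two primer sites is
#' returned (primer sequences removed, as an adapter/primer trimmer would).
#' The leftmost forward match and the nearest valid downstream reverse match
#' are used; if several non-nested forward sites have a valid reverse
#' partner the leftmost pair is returned with a warning.
#'
#' @param source Full-length nucleotide string over `A/C/G/T/N`.
#' @param forward,reverse Primer strings (IUPAC; reverse given 5'->3' on the
#'   antisense strand).
#' @param region Region id (1-4) carried through to the output.
#' @param species_id Optional label carried through to the output.
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return One-row tibble with `species_id`, `region`, `start`, `end`
#'   (0-based half-open insert coordinates on `source`), `complete` and
#'   `sequence`. When either primer site is absent, `complete` is `FALSE`,
#'   the sequence empty and the coordinates `NA`.
#' @examples
#' p <- ssu_primers()
#' src <- paste0(p$forward[1], "AAA", revcomp_iupac(p$reverse[1]))
#' extract_region(src, p$forward[1], p$reverse[1], region = 1)
#' @export
extract_region <- function(source, forward, reverse, region = NA_integer_,
                           species_id = NA_character_, max_mismatch = 0L) {
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  empty <- tibble::tibble(
    species_id = species_id, region = as.integer(region),
    start = NA_integer_, end = NA_integer_,
    complete = FALSE, sequence = ""
  )
  fwd <- match_degenerate(source, forward, max_mismatch)
  if (length(fwd) == 0L) return(empty)
  rc <- revcomp_iupac(reverse)
  rev_hits <- match_degenerate(source, rc, max_mismatch)
  fl <- nchar(forward)
  # valid pair: reverse site entirely downstream of the forward site
  pair_for <- function(f) {
    cand <- rev_hits[rev_hits >= f + fl]
    if (length(cand) == 0L) NA_integer_ else min(cand)
  }
  partners <- vapply(fwd, pair_for, integer(1))
  ok <- which(!is.na(partners))
  if (length(ok) == 0L) return(empty)
  if (length(unique(partners[ok])) > 1L) {
    warning("multiple non-nested primer pairs found; using leftmost",
            call. = FALSE)
  }
  f <- fwd[ok[1]]
  r <- partners[ok[1]]
  start <- f + fl          # 0-based, first base after the forward primer
  end <- r                 # 0-based half-open, first base of the reverse site
  tibble::tibble(
    species_id = species_id, region = as.integer(region),
    start = as.integer(start), end = as.integer(end),
    complete = TRUE,
    sequence = substr(source, start + 1L, end)
  )
}

#' Extract all primer-defined regions from a set of reference sequences
#'
#' @param references Tibble with at least `species_id` and `sequence`
#'   columns (e.g. from [simulate_reference_set()]).
#' @param primers Primer tibble as returned by [ssu_primers()].
#' @param max_mismatch Mismatches tolerated per primer site.
#' @return Tibble with one row per species x region: `species_id`, `region`,
#'   `start`, `end`, `complete`, `sequence`.
#' @export
extract_regions <- function(references, primers = ssu_primers(),
                            max_mismatch = 0L) {
  stopifnot(is.data.frame(references),
            all(c("species_id", "sequence") %in% names(references)))
  .validate_primers(primers)
  purrr::pmap_dfr(
    expand.grid(i = seq_len(nrow(references)), j = seq_len(nrow(primers))),
    function(i, j) {
      extract_region(
        references$sequence[i],
        forward = primers$forward[j], reverse = primers$reverse[j],
        region = primers$region[j], species_id = references$species_id[i],
        max_mismatch = max_mismatch
      )
    }
  ) |>
    dplyr::arrange(.data$species_id, .data$region)
}

#' Concatenate regional sequences into artificial long sequences
#'
#' Builds the "connected" long SSU sequences used to test whether longer
#' barcodes improve tree structure: for each species the requested regional
#' inserts are pasted in the stated numeric order. Species missing (or with
#' incomplete) any requested region are excluded and reported rather than
#' silently padded.
#'
#' @param region_seqs Tibble with `species_id`, `region`, `sequence` and
#'   (optionally) `complete` columns, e.g. from [extract_regions()].
#' @param regions Integer vector of region ids, in concatenation order.
#' @return List with `sequences` (named character vector, one element per
#'   retained species), `excluded` (tibble `species_id`, `missing_region`)
#'   and `regions`.
#' @examples
#' rs <- tibble::tibble(species_id = "x", region = 1:2,
#'                      sequence = c("AAA", "CCGG"), complete = TRUE)
#' concatenate_regions(rs, regions = c(1, 2))$sequences
#' @export
concatenate_regions <- function(region_seqs, regions = 1:4) {
  stopifnot(is.data.frame(region_seqs),
            all(c("species_id", "region", "sequence") %in% names(region_seqs)))
  if (!"complete" %in% names(region_seqs)) region_seqs$complete <- TRUE
  regions <- as.integer(regions)
  avail <- region_seqs |>
    dplyr::filter(.data$region %in% regions, .data$complete,
                  nzchar(.data$sequence))
  species <- unique(region_seqs$species_id)
  have <- split(avail$region, avail$species_id)
  missing <- purrr::map(species, function(sp) setdiff(regions, have[[sp]]))
  names(missing) <- species
  excluded <- tibble::tibble(
    species_id = rep(species, lengths(missing)),
    missing_region = unlist(missing, use.names = FALSE) %||% integer(0)
  )
  keep <- setdiff(species, excluded$species_id)
  seqs <- vapply(keep, function(sp) {
    rows <- avail[avail$species_id == sp, ]
    paste(rows$sequence[match(regions, rows$region)], collapse = "")
  }, character(1))
  list(sequences = seqs, excluded = excluded, regions = regions)
}
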