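#' PCR primer pairs for the four 18S SSU target regions
#'
#' The four primer pairs used to amplify regions 1-4 of the nematode 18S
#' small-subunit rRNA gene (sequencing-adapter tails excluded). Reverse
#' primers are written 5'->3' on the antisense strand, as is conventional;
#' [extract_region()] reverse-complements them before scanning the sense
#' strand.
#'
#' @return A tibble with columns `region` (integer 1-4), `forward` and
#'   `reverse` (IUPAC nucleotide strings).
#' @examples
#' ssu_primers()
#' @export
ssu_primers <- function() {
  tibble::tibble(
    region = 1:4,
    forward = c(
      "GCTTRTCTCAAAGATTAAGCCATGCATG",
      "AGCAGCCGCGGTAATTCCAGCTC",
      "GTTCGAAGGCGATYAGATACCGCC",
      "GGTGGTGCATGGCCGTTCTTAGTT"
    ),
    reverse = c(
      "GCCTGCTGCCTTCCTTGGA",
      "AAGACATTCTTGGCAAATGCTTTCG",
      "TCGYTCGTTATCGGAATWAACCAGAC",
      "GGTGTGTACAAAKSGCAGGGACGTA"
    )
  )
}

.validate_primers <- function(primers) {
  stopifnot(is.data.frame(primers),
            all(c("region", "forward", "reverse") %in% names(primers)))
  if (!all(primers$region %in% 1:4)) {
    stop("primer regions must be in 1:4", call. = FALSE)
  }
  for (p in c(primers$forward, primers$reverse)) {
    .check_alphabet(p, names(iupac_codes), "primer")
  }
  invisible(primers)
}
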