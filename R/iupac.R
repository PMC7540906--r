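#' IUPAC nucleotide codes
#'
#' Named character vector mapping each IUPAC nucleotide code to the set of
#' concrete bases it stands for. Degenerate codes (R, Y, W, S, K, M, B, D, H,
#' V, N) are how published SSU primers encode tolerated variation at a site.
#'
#' @format Named character vector; names are IUPAC codes, values the bases
#'   they cover (e.g. `R` -> `"AG"`).
#' @export
iupac_codes <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", W = "AT", S = "CG", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# complement map covering degenerate codes (R<->Y, K<->M, B<->V, D<->H)
.iupac_from <- "ACGTRYWSKMBDHVN"
.iupac_to   <- "TGCAYRWSMKVHDBN"

.check_alphabet <- function(x, allowed, what) {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), allowed)
  if (length(bad) > 0) {
    stop("invalid character(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements degenerate codes correctly (R <-> Y, K <-> M, B <-> V,
#' D <-> H; W, S and N are self-complementary) and reverses the string.
#'
#' @param x A nucleotide string over the IUPAC alphabet.
#' @return The reverse complement as a single string.
#' @examples
#' revcomp_iupac("GCTTRTCT")
#' @export
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  .check_alphabet(x, strsplit(.iupac_from, "")[[1]], "sequence")
  paste(rev(strsplit(chartr(.iupac_from, .iupac_to, x), "")[[1]]),
        collapse = "")
}

#' Find all matches of an IUPAC-degenerate pattern in a sequence
#'
#' Scans `seq` for every (possibly overlapping) occurrence of `pattern`,
#' where each pattern character matches the IUPAC class it denotes. An `N`
#' in `seq` matches nothing: primer sites must be called on real bases.
#'
#' @param seq Subject nucleotide string over `A/C/G/T/N`.
#' @param pattern Query string over the full IUPAC alphabet (a primer).
#' @param max_mismatch Number of tolerated mismatches against the pattern
#'   (default 0, strict matching).
#' @return Integer vector of 0-based match start positions (possibly empty).
#' @examples
#' match_degenerate("GCTTATCTCAAAGATTAAGCCATGCATG", "GCTTRTCT")
#' @export
match_degenerate <- function(seq, pattern, max_mismatch = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq),
            is.character(pattern), length(pattern) == 1L, nzchar(pattern),
            max_mismatch >= 0L)
  .check_alphabet(seq, c("A", "C", "G", "T", "N"), "seq")
  .check_alphabet(pattern, names(iupac_codes), "pattern")
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  n_start <- length(s) - m + 1L
  if (n_start < 1L) return(integer(0))
  mism <- integer(n_start)
  idx <- seq_len(n_start)
  for (k in seq_len(m)) {
    allowed <- strsplit(iupac_codes[[p[k]]], "")[[1]]
    mism <- mism + !(s[idx + k - 1L] %in% allowed)
  }
  idx[mism <= max_mismatch] - 1L
}
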