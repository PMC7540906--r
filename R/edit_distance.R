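#' Levenshtein distance between two sequences
#'
#' Full dynamic-programming edit distance (substitutions + single-base
#' insertions/deletions), via [utils::adist()].
#'
#' @param a,b Nucleotide strings.
#' @return Non-negative integer edit distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Human-readable summary of the edits between two allele sequences
#'
#' Walks one optimal Levenshtein alignment and reports substitutions as
#' `major/minor` base pairs (collapsed as e.g. `"T/C (4 sites)"` when the
#' same exchange recurs) and indels as e.g. `"GG insertion"` or
#' `"C deletion"` (relative to the major sequence) — the conventional way
#' polymorphic rDNA allele pairs are tabulated.
#'
#' @param major,minor The two allele sequences (major first).
#' @return Single summary string; `""` for identical sequences.
#' @examples
#' edit_summary("ACGTACGT", "ACATACGT")   # "G/A"
#' @export
edit_summary <- function(major, minor) {
  d <- utils::adist(major, minor, counts = TRUE)
  ops <- strsplit(drop(attr(d, "trafos")), "")[[1]]
  a <- strsplit(major, "")[[1]]
  b <- strsplit(minor, "")[[1]]
  i <- 1L; j <- 1L
  subs <- character(0)
  indels <- character(0)
  run_type <- ""; run <- character(0)
  flush_run <- function() {
    if (length(run) == 0L) return()
    word <- if (run_type == "I") "insertion" else "deletion"
    indels[[length(indels) + 1L]] <<- paste0(paste(run, collapse = ""), " ",
                                             word)
    run <<- character(0); run_type <<- ""
  }
  for (op in ops) {
    if (op != run_type) flush_run()
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
    } else if (op == "S") {
      subs <- c(subs, paste0(a[i], "/", b[j]))
      i <- i + 1L; j <- j + 1L
    } else if (op == "I") {
      run_type <- "I"; run <- c(run, b[j]); j <- j + 1L
    } else if (op == "D") {
      run_type <- "D"; run <- c(run, a[i]); i <- i + 1L
    }
  }
  flush_run()
  parts <- character(0)
  if (length(subs) > 0) {
    tab <- table(subs)
    parts <- c(parts, vapply(names(tab), function(s) {
      if (tab[[s]] > 1L) paste0(s, " (", tab[[s]], " sites)") else s
    }, character(1)))
  }
  paste(c(parts, indels), collapse = ", ")
}
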