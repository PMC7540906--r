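#' Configuration for the synthetic nematode community generator
#'
#' Bundles and validates every knob of the simulator. The defaults describe
#' a plate of 96 individually isolated soil nematodes genotyped at four SSU
#' regions: most samples yield one dominant nematode SV, a fraction carry a
#' polymorphic rDNA allele pair, some are contaminated by fungal or
#' chordate DNA, a few contain a second nematode (predation/contamination),
#' and some PCRs fail outright.
#'
#' @param n_orders Number of nematode orders in the reference set.
#' @param species_per_order Reference species simulated per order.
#' @param seq_length Length (nt) of each full-length reference sequence;
#'   must be long enough to host all eight primer sites (>= 385 nt).
#' @param n_samples Number of specimen samples (wells).
#' @param polymorphism_rate Probability a specimen carries an allelic SV
#'   pair in its polymorphic regions.
#' @param allele_edit_count Exact Levenshtein distance between the two
#'   alleles of a pair (>= 1).
#' @param contamination_rate Probability a sample is dominated by
#'   non-nematode DNA (and so fails the 65% rule).
#' @param predation_rate Probability a sample carries a second,
#'   different-order nematode SV.
#' @param fail_rate Probability a sample yields fewer than 1,000 reads.
#' @param depth_mean Expected reads per successful sample per region.
#' @param truncation_rate Probability a reference sequence is 5'-truncated
#'   (losing the region-1 forward primer site), emulating incomplete
#'   database entries.
#' @param div_between,div_within,div_outgroup Per-site substitution
#'   probabilities in the variable blocks: order ancestors from the root,
#'   species from their order ancestor, and the outgroup from the root.
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(seed = 1, n_samples = 24)
#' @export
sim_config <- function(n_orders = 4L, species_per_order = 3L,
                       seq_length = 1200L, n_samples = 96L,
                       polymorphism_rate = 0.3, allele_edit_count = 1L,
                       contamination_rate = 0.2, predation_rate = 0.07,
                       fail_rate = 0.25, depth_mean = 20000,
                       truncation_rate = 0,
                       div_between = 0.12, div_within = 0.015,
                       div_outgroup = 0.30, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(
    n_orders = as.integer(n_orders),
    species_per_order = as.integer(species_per_order),
    seq_length = as.integer(seq_length),
    n_samples = as.integer(n_samples),
    polymorphism_rate = polymorphism_rate,
    allele_edit_count = as.integer(allele_edit_count),
    contamination_rate = contamination_rate,
    predation_rate = predation_rate,
    fail_rate = fail_rate,
    depth_mean = depth_mean,
    truncation_rate = truncation_rate,
    div_between = div_between, div_within = div_within,
    div_outgroup = div_outgroup,
    seed = as.integer(seed)
  )
  probs <- c("polymorphism_rate", "contamination_rate", "predation_rate",
             "fail_rate", "truncation_rate", "div_between", "div_within",
             "div_outgroup")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(cfg$n_orders >= 1L, cfg$species_per_order >= 1L,
            cfg$n_samples >= 1L, cfg$allele_edit_count >= 1L,
            cfg$depth_mean > 0)
  if (cfg$seq_length < .layout_min_length()) {
    stop("seq_length too short to place the eight primer sites (need >= ",
         .layout_min_length(), " nt)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_orders, " orders x ", x$species_per_order,
      " species, ", x$n_samples, " samples, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- reference sequence layout -------------------------------------------
# A full-length sequence is a fixed scaffold of the eight primer sites with
# variable blocks between them.  Region 3 and region 4 share block B (and
# region 3's insert additionally contains the region-4 forward site), so the
# two inserts overlap on the sense strand as on the real gene.
.layout_segments <- function(seq_length) {
  p <- ssu_primers()
  fixed <- list(
    F1 = p$forward[1], rcR1 = revcomp_iupac(p$reverse[1]),
    F2 = p$forward[2], rcR2 = revcomp_iupac(p$reverse[2]),
    F3 = p$forward[3], rcR3 = revcomp_iupac(p$reverse[3]),
    F4 = p$forward[4], rcR4 = revcomp_iupac(p$reverse[4])
  )
  # segment order along the gene; B is the designed region-3/4 overlap core
  ord <- c("pad5", "F1", "V1", "rcR1", "s1", "F2", "V2", "rcR2",
           "s2", "F3", "A", "F4", "B", "rcR3", "C", "rcR4", "pad3")
  var_w <- c(pad5 = 1, V1 = 4, s1 = 1, V2 = 4, s2 = 1, A = 2, C = 2, pad3 = 1)
  fixed_len <- sum(nchar(unlist(fixed))) + 63L   # B fixed at 63 nt
  free <- seq_length - fixed_len
  lens <- floor(free * var_w / sum(var_w))
  lens["pad3"] <- lens["pad3"] + (free - sum(lens))  # absorb remainder
  seg_len <- integer(length(ord)); names(seg_len) <- ord
  for (s in ord) {
    seg_len[s] <- if (s %in% names(fixed)) nchar(fixed[[s]])
                  else if (s == "B") 63L else lens[[s]]
  }
  list(order = ord, fixed = fixed, seg_len = seg_len,
       var = c(names(var_w), "B"))
}

.layout_min_length <- function() {
  p <- ssu_primers()
  prim <- sum(nchar(p$forward)) + sum(nchar(p$reverse))
  prim + 63L + 8L * 16L  # eight variable segments of >= ~16 nt
}

.realize_iupac <- function(x) {
  ch <- strsplit(x, "")[[1]]
  paste(vapply(ch, function(c) {
    opts <- strsplit(iupac_codes[[c]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.mutate_seq <- function(chars, p_sub) {
  hit <- which(stats::runif(length(chars)) < p_sub)
  if (length(hit) > 0) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  chars
}

.order_pool <- c("Dorylaimida", "Rhabditida", "Triplonchida", "Plectida",
                 "Enoplida", "Mononchida", "Monhysterida", "Chromadorida",
                 "Araeolaimida", "Desmodorida", "Strongylida", "Trichinellida")
.feeding_pool <- c("2", "1d", "3", "5", "1b", "8", "1e", "3?", "2", "5",
                   "1d", "3")

#' Simulate a reference species set with planted primer sites
#'
#' Generates full-length SSU-like sequences for `n_orders x
#' species_per_order` nematode reference species plus one tardigrade-like
#' outgroup. Each sequence is a fixed scaffold of the eight primer sites of
#' [ssu_primers()] (one concrete base drawn for every degenerate position)
#' separated by variable blocks that evolve by substitution only: orders
#' diverge from a common root, species diverge less within their order, so
#' within-order divergence stays below between-order divergence and the
#' sequences remain trivially alignable (no gaps). Optionally some species
#' are 5'-truncated and lose the region-1 forward primer site.
#'
#' @param config A [sim_config()].
#' @return List with `references` (tibble: `species_id`, `order`,
#'   `feeding_code`, `truncated`, `is_outgroup`, `sequence`) and `truth`
#'   (list with `region_coords`: 0-based half-open insert coordinates of
#'   every complete region on every sequence).
#' @examples
#' refs <- simulate_reference_set(sim_config(seed = 7, seq_length = 600))
#' refs$references
#' @export
simulate_reference_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- .layout_segments(config$seq_length)
  # root content for every variable segment
  root <- lapply(lay$seg_len[lay$var], function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })
  orders <- rep_len(.order_pool, config$n_orders)
  feeding <- rep_len(.feeding_pool, config$n_orders)
  anc <- lapply(seq_len(config$n_orders), function(o) {
    lapply(root, .mutate_seq, p_sub = config$div_between)
  })
  build_seq <- function(blocks) {
    parts <- vapply(lay$order, function(s) {
      if (s %in% names(lay$fixed)) .realize_iupac(lay$fixed[[s]])
      else paste(blocks[[s]], collapse = "")
    }, character(1))
    paste(parts, collapse = "")
  }
  rows <- list()
  for (o in seq_len(config$n_orders)) {
    for (k in seq_len(config$species_per_order)) {
      blocks <- lapply(anc[[o]], .mutate_seq, p_sub = config$div_within)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species_id = sprintf("%s_sp%02d", orders[o], k),
        order = orders[o], feeding_code = feeding[o],
        truncated = FALSE, is_outgroup = FALSE,
        sequence = build_seq(blocks)
      )
    }
  }
  out_blocks <- lapply(root, .mutate_seq, p_sub = config$div_outgroup)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    species_id = "Tardigrada_outgroup", order = "Outgroup",
    feeding_code = NA_character_, truncated = FALSE, is_outgroup = TRUE,
    sequence = build_seq(out_blocks)
  )
  refs <- dplyr::bind_rows(rows)
  # optional 5'-truncation: drop everything through mid-region-1-forward
  if (config$truncation_rate > 0) {
    trunc <- stats::runif(nrow(refs)) < config$truncation_rate &
      !refs$is_outgroup
    cut_at <- lay$seg_len[["pad5"]] + 10L  # lands inside the F1 site
    refs$truncated <- trunc
    refs$sequence[trunc] <- substr(refs$sequence[trunc], cut_at + 1L,
                                   nchar(refs$sequence[trunc]))
  }
  coords <- extract_regions(refs, ssu_primers())
  list(
    references = refs,
    truth = list(region_coords = dplyr::select(
      coords, "species_id", "region", "start", "end", "complete"
    ))
  )
}

# apply exactly n well-separated edits to a sequence; returns the edited
# sequence plus a Levenshtein-exact edit count (substitutions, with at most
# one single-base insertion mixed in when n >= 2)
.apply_allele_edits <- function(seq, n_edits) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  pos <- sort(sample(seq(5L, L - 5L), n_edits))
  while (n_edits > 1L && min(diff(pos)) < 4L) {
    pos <- sort(sample(seq(5L, L - 5L), n_edits))
  }
  use_ins <- n_edits >= 2L && stats::runif(1) < 0.3
  out <- ch
  for (i in seq_len(n_edits)) {
    p <- pos[i]
    if (use_ins && i == n_edits) {
      ins <- sample(setdiff(c("A", "C", "G", "T"), c(out[p], out[p + 1L])), 1L)
      out <- append(out, ins, after = p)
    } else {
      out[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  }
  paste(out, collapse = "")
}

.random_insert <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate per-sample SV count tables for the four SSU regions
#'
#' Draws, for every sample and region, a multinomial read-count vector over
#' the SVs present in that sample: the specimen's dominant SV (its source
#' species' regional insert), an allelic minor SV in the specimen's
#' polymorphic regions, a second nematode's SV in predation samples,
#' fungal/chordate contaminant SVs, and an occasional sub-1% background
#' fungal SV. Depths are log-normal around `depth_mean`; failed samples
#' draw fewer than 1,000 reads. SV ids are assigned per region by
#' descending total read count (`R1_SV_1` is region 1's most abundant SV).
#'
#' @param config A [sim_config()]; the same seed drives every draw.
#' @param reference_set Output of [simulate_reference_set()].
#' @return List with `sv_table` (long tibble: `sample_id`, `region`,
#'   `sv_id`, `count`, `sequence`, `phylum`, `order`) and `truth` (list of
#'   tibbles: `samples` with per-sample source species / failure /
#'   contamination / predation flags, `allele_pairs` with one row per
#'   sample x region carrying a true allele pair, and `depths`).
#' @export
simulate_sv_tables <- function(config, reference_set) {
  stopifnot(inherits(config, "sim_config"))
  refs <- reference_set$references
  set.seed(config$seed + 1L)
  regions <- extract_regions(refs, ssu_primers()) |>
    dplyr::filter(.data$complete)
  ingroup <- refs[!refs$is_outgroup, ]
  insert_of <- function(sp, r) {
    row <- regions[regions$species_id == sp & regions$region == r, ]
    if (nrow(row) == 0L) NA_character_ else row$sequence
  }

  # species-level allele definitions: the same pair recurs across samples
  allele_def <- list()
  for (sp in ingroup$species_id) {
    poly_regions <- which(stats::runif(4) < 0.6)
    if (length(poly_regions) == 0L) poly_regions <- sample(1:4, 1L)
    for (r in poly_regions) {
      maj <- insert_of(sp, r)
      if (is.na(maj)) next
      allele_def[[paste(sp, r)]] <- list(
        species_id = sp, region = r, major = maj,
        minor = .apply_allele_edits(maj, config$allele_edit_count)
      )
    }
  }

  # contaminant SV pool per region (non-nematode phyla)
  contam_pool <- purrr::map_dfr(1:4, function(r) {
    len <- nchar(insert_of(ingroup$species_id[1], r))
    if (is.na(len)) len <- 300L
    tibble::tibble(
      region = r,
      sequence = vapply(seq_len(3), function(i) .random_insert(len),
                        character(1)),
      phylum = c("Ascomycota", "Chordata", "Basidiomycota")
    )
  })

  n <- config$n_samples
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  src <- sample(ingroup$species_id, n, replace = TRUE)
  src_order <- ingroup$order[match(src, ingroup$species_id)]
  failed <- stats::runif(n) < config$fail_rate
  contaminated <- stats::runif(n) < config$contamination_rate
  predated <- stats::runif(n) < config$predation_rate
  carries_allele <- stats::runif(n) < config$polymorphism_rate
  prey <- vapply(seq_len(n), function(i) {
    if (!predated[i]) return(NA_character_)
    pool <- ingroup$species_id[ingroup$order != src_order[i]]
    if (length(pool) == 0L) NA_character_ else sample(pool, 1L)
  }, character(1))
  predated <- predated & !is.na(prey)

  entries <- list()
  allele_truth <- list()
  depth_truth <- list()
  for (i in seq_len(n)) {
    for (r in 1:4) {
      maj <- insert_of(src[i], r)
      if (is.na(maj)) next  # truncated source species: region absent
      comp <- tibble::tibble(sequence = maj, phylum = "Nematoda",
                             order = src_order[i], frac = NA_real_)
      f_minor <- 0
      key <- paste(src[i], r)
      has_allele <- carries_allele[i] && !is.null(allele_def[[key]])
      f_a <- 0; f_s <- 0
      if (has_allele) {
        f_a <- stats::runif(1, 0.10, if (predated[i]) 0.30 else 0.45)
      }
      if (predated[i]) {
        f_s <- stats::runif(1, 0.08, if (has_allele) 0.15 else 0.20)
      }
      if (has_allele) {
        comp <- dplyr::add_row(comp, sequence = allele_def[[key]]$minor,
                               phylum = "Nematoda", order = src_order[i],
                               frac = f_a)
        allele_truth[[length(allele_truth) + 1L]] <- tibble::tibble(
          sample_id = sample_ids[i], region = r,
          major = maj, minor = allele_def[[key]]$minor,
          n_edits = config$allele_edit_count
        )
      }
      if (predated[i]) {
        prey_seq <- insert_of(prey[i], r)
        if (!is.na(prey_seq)) {
          comp <- dplyr::add_row(comp, sequence = prey_seq,
                                 phylum = "Nematoda",
                                 order = ingroup$order[ingroup$species_id ==
                                                         prey[i]],
                                 frac = f_s)
        }
      }
      f_c <- 0
      if (contaminated[i]) {
        f_c <- stats::runif(1, 0.40, 0.60)
        picks <- contam_pool[contam_pool$region == r, ][1:2, ]
        share <- f_c * c(0.7, 0.3)
        comp <- dplyr::add_row(comp, sequence = picks$sequence,
                               phylum = picks$phylum, order = NA_character_,
                               frac = share)
      } else if (stats::runif(1) < 0.5) {
        # sub-1% fungal background, removed by the phylum-level floor
        f_c <- 0.004
        picks <- contam_pool[contam_pool$region == r, ][1, ]
        comp <- dplyr::add_row(comp, sequence = picks$sequence,
                               phylum = picks$phylum, order = NA_character_,
                               frac = f_c)
      }
      # f_a/f_s are shares of the nematode reads; scale the nematode block
      # to its fraction of the sample so everything sums to one
      nem_rows <- which(comp$phylum == "Nematoda")
      comp$frac[nem_rows[1]] <-
        1 - sum(comp$frac[nem_rows[-1]], na.rm = TRUE)
      comp$frac[nem_rows] <- comp$frac[nem_rows] * (1 - f_c)
      depth <- if (failed[i]) {
        sample(80:900, 1L)
      } else {
        max(1500L, round(stats::rlnorm(1,
          meanlog = log(config$depth_mean) - 0.35^2 / 2, sdlog = 0.35)))
      }
      counts <- as.vector(stats::rmultinom(1, depth, comp$frac))
      keep <- counts > 0
      if (!any(keep)) next
      entries[[length(entries) + 1L]] <- tibble::tibble(
        sample_id = sample_ids[i], region = r,
        sequence = comp$sequence[keep], phylum = comp$phylum[keep],
        order = comp$order[keep], count = counts[keep]
      )
      depth_truth[[length(depth_truth) + 1L]] <- tibble::tibble(
        sample_id = sample_ids[i], region = r, depth = depth
      )
    }
  }
  tab <- dplyr::bind_rows(entries) |>
    dplyr::group_by(.data$sample_id, .data$region, .data$sequence,
                    .data$phylum, .data$order) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  # SV ids per region by descending total abundance (ties by sequence)
  ids <- tab |>
    dplyr::group_by(.data$region, .data$sequence) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence,
                   .by_group = TRUE) |>
    dplyr::mutate(sv_id = sprintf("R%d_SV_%d", .data$region,
                                  dplyr::row_number())) |>
    dplyr::ungroup()
  tab <- tab |>
    dplyr::left_join(dplyr::select(ids, "region", "sequence", "sv_id"),
                     by = c("region", "sequence")) |>
    dplyr::select("sample_id", "region", "sv_id", "count", "sequence",
                  "phylum", "order") |>
    dplyr::arrange(.data$sample_id, .data$region, dplyr::desc(.data$count))
  list(
    sv_table = tab,
    truth = list(
      samples = tibble::tibble(
        sample_id = sample_ids, species_id = src, order = src_order,
        failed = failed, contaminated = contaminated,
        second_nematode = predated, prey_species = prey,
        carries_allele = carries_allele
      ),
      allele_pairs = dplyr::bind_rows(allele_truth),
      depths = dplyr::bind_rows(depth_truth),
      region_coords = reference_set$truth$region_coords
    )
  )
}
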