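#' Analysis configuration for the FISH quantification pipeline
#'
#' Thresholds and options for nucleus QC, spot matching, contact calling and
#' binning. Defaults follow standard practice for U2OS imaging data: nuclei
#' below 90 um^2 (use 50 for HeLa) or with solidity below 0.9 are discarded;
#' cross-channel spot pairs further apart than 2 um are not considered the
#' same allele; pairs closer than 0.27 um — a typical DNA-FISH spot radius,
#' within the diffraction limit — are classified as DNA contacts.
#'
#' @param min_area minimum nuclear area in um^2 (90 U2OS, 50 HeLa).
#' @param min_solidity minimum nuclear solidity.
#' @param max_pair_distance um; cap above which a matched pair is discarded.
#' @param contact_threshold um; strict upper bound for calling a contact.
#' @param ploidy expected number of FISH spots per DNA channel per nucleus
#'   (2 diploid, 3 triploid, 4 tetraploid).
#' @param n_bins number of equal-count bins for [bin_cells()].
#' @param pixel_size_um acquisition pixel size for px-to-um conversion.
#' @param match_mode `"one_to_one"` (greedy ascending assignment, default)
#'   or `"per_spot_min"` (per-spot nearest neighbour, for sensitivity
#'   analysis).
#' @param control_condition condition label used as the normalization
#'   reference for "relative to control" report columns (optional).
#' @return a validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(min_area = 90, min_solidity = 0.9,
                            max_pair_distance = 2, contact_threshold = 0.27,
                            ploidy = 2L, n_bins = 4L,
                            pixel_size_um = 0.108,
                            match_mode = c("one_to_one", "per_spot_min"),
                            control_condition = NULL) {
  check_pos(min_area, "min_area")
  check_prob(min_solidity, "min_solidity")
  check_pos(max_pair_distance, "max_pair_distance")
  check_pos(contact_threshold, "contact_threshold")
  if (contact_threshold >= max_pair_distance) {
    stop("`contact_threshold` must be < `max_pair_distance`", call. = FALSE)
  }
  ploidy <- check_count(ploidy, "ploidy")
  n_bins <- check_count(n_bins, "n_bins")
  check_pos(pixel_size_um, "pixel_size_um")
  structure(list(min_area = min_area, min_solidity = min_solidity,
                 max_pair_distance = max_pair_distance,
                 contact_threshold = contact_threshold,
                 ploidy = ploidy, n_bins = n_bins,
                 pixel_size_um = pixel_size_um,
                 match_mode = match.arg(match_mode),
                 control_condition = control_condition),
            class = "analysis_config")
}

#' Quality-control filter on segmented nuclei
#'
#' Keeps nuclei with `area_um2 >= min_area` and `solidity >= min_solidity`;
#' small or poorly segmented (low-solidity) nuclei are typically debris,
#' mitotic cells or merged segmentations.
#'
#' @param nuclei data.frame with `area_um2` and `solidity` columns.
#' @param config an [analysis_config()].
#' @return list with `kept` (filtered data.frame) and `report`, a
#'   data.frame counting rejections per criterion (a nucleus failing both
#'   is counted under both).
#' @export
qc_filter_nuclei <- function(nuclei, config) {
  stopifnot(inherits(config, "analysis_config"))
  check_cols(nuclei, c("area_um2", "solidity"), "nuclei")
  small <- nuclei$area_um2 < config$min_area
  ragged <- nuclei$solidity < config$min_solidity
  keep <- !small & !ragged
  report <- data.frame(
    criterion = c("area_below_min", "solidity_below_min", "kept"),
    n = c(sum(small), sum(ragged), sum(keep))
  )
  list(kept = nuclei[keep, , drop = FALSE], report = report)
}

# spot counts per nucleus for one channel, aligned to `ids`
count_spots <- function(spots, ids, channel) {
  sub <- spots$nucleus_id[spots$channel == channel]
  as.integer(table(factor(sub, levels = ids)))
}

#' Ploidy filter: keep nuclei with the expected spot count in each channel
#'
#' Retains only nuclei whose DNA-FISH spot count in EACH of the two DNA
#' channels equals the configured ploidy of the targeted genome region,
#' discarding cells with segmentation dropouts, extra (false) spots or
#' abnormal karyotypes.
#'
#' @param nuclei QC-filtered nucleus table.
#' @param spots spot table with `nucleus_id` and `channel` columns
#'   (channels `dna_a` and `dna_b` are counted).
#' @return kept nuclei, with attribute `"n_rejected"`.
#' @export
ploidy_filter <- function(nuclei, spots, config) {
  stopifnot(inherits(config, "analysis_config"))
  check_cols(spots, c("nucleus_id", "channel"), "spots")
  ids <- nuclei$nucleus_id
  na <- count_spots(spots, ids, "dna_a")
  nb <- count_spots(spots, ids, "dna_b")
  keep <- na == config$ploidy & nb == config$ploidy
  out <- nuclei[keep, , drop = FALSE]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

# Greedy ascending one-to-one assignment on a small distance matrix;
# returns assigned distances (ascending). Stops once the running minimum
# reaches `cap`, since later assignments can only be larger.
greedy_match <- function(ax, ay, bx, by, cap) {
  na <- length(ax); nb <- length(bx)
  if (!na || !nb) return(numeric(0))
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  m <- min(na, nb)
  out <- numeric(m)
  kept <- 0L
  for (k in seq_len(m)) {
    i <- which.min(d)
    dm <- d[i]
    if (dm >= cap) break
    kept <- kept + 1L
    out[kept] <- dm
    row <- (i - 1L) %% na + 1L
    col <- (i - 1L) %/% na + 1L
    d[row, ] <- Inf
    d[, col] <- Inf
  }
  out[seq_len(kept)]
}

per_spot_min_match <- function(ax, ay, bx, by, cap) {
  if (!length(ax) || !length(bx)) return(numeric(0))
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  mins <- apply(d, 1, min)
  mins[mins < cap]
}

#' Match cross-channel DNA spots into allele pairs
#'
#' Computes all pairwise x,y Euclidean distances between the two DNA
#' channels of one nucleus and assigns spots one-to-one in ascending
#' distance order (each spot used at most once), so a single bright spot
#' cannot absorb two alleles. Assigned pairs with distance below the 2 um
#' cap are retained as single-allele distances; pairs further apart are not
#' plausible same-allele signals.
#'
#' @param spots_a,spots_b data.frames of the two DNA channels of one
#'   nucleus, with `x_um`, `y_um` columns.
#' @param config an [analysis_config()]; `match_mode = "per_spot_min"`
#'   instead keeps, for every channel-A spot, its nearest channel-B
#'   neighbour (spots may be reused).
#' @return data.frame with column `distance_um` (ascending), at most
#'   `min(nrow(spots_a), nrow(spots_b))` rows.
#' @export
match_spots <- function(spots_a, spots_b, config) {
  stopifnot(inherits(config, "analysis_config"))
  if (nrow(spots_a)) check_cols(spots_a, c("x_um", "y_um"), "spots_a")
  if (nrow(spots_b)) check_cols(spots_b, c("x_um", "y_um"), "spots_b")
  d <- if (config$match_mode == "one_to_one") {
    greedy_match(spots_a$x_um, spots_a$y_um, spots_b$x_um, spots_b$y_um,
                 config$max_pair_distance)
  } else {
    per_spot_min_match(spots_a$x_um, spots_a$y_um, spots_b$x_um,
                       spots_b$y_um, config$max_pair_distance)
  }
  data.frame(distance_um = d)
}

#' Match spots for every nucleus of a spot table
#'
#' @param spots full spot table (`nucleus_id`, `channel`, `x_um`, `y_um`).
#' @param config an [analysis_config()].
#' @return data.frame of allele pairs: `nucleus_id`, `distance_um`.
#' @export
match_spots_by_nucleus <- function(spots, config) {
  stopifnot(inherits(config, "analysis_config"))
  check_cols(spots, c("nucleus_id", "channel", "x_um", "y_um"), "spots")
  a <- spots[spots$channel == "dna_a", c("nucleus_id", "x_um", "y_um")]
  b <- spots[spots$channel == "dna_b", c("nucleus_id", "x_um", "y_um")]
  ids <- union(unique(a$nucleus_id), unique(b$nucleus_id))
  ia <- split(seq_len(nrow(a)), factor(a$nucleus_id, levels = ids))
  ib <- split(seq_len(nrow(b)), factor(b$nucleus_id, levels = ids))
  one_to_one <- config$match_mode == "one_to_one"
  cap <- config$max_pair_distance
  res <- lapply(ids, function(id) {
    ja <- ia[[id]]; jb <- ib[[id]]
    if (one_to_one) {
      greedy_match(a$x_um[ja], a$y_um[ja], b$x_um[jb], b$y_um[jb], cap)
    } else {
      per_spot_min_match(a$x_um[ja], a$y_um[ja], b$x_um[jb], b$y_um[jb], cap)
    }
  })
  n_each <- lengths(res)
  data.frame(nucleus_id = rep(ids, n_each),
             distance_um = unlist(res, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Classify allele pairs as DNA contacts
#'
#' A pair is a contact iff its distance is strictly below the configured
#' threshold (default 0.27 um). Lowering the threshold can only shrink the
#' contact set.
#'
#' @param pairs data.frame with `distance_um`.
#' @param config an [analysis_config()].
#' @return `pairs` with a logical `is_contact` column.
#' @export
call_contacts <- function(pairs, config) {
  stopifnot(inherits(config, "analysis_config"))
  check_cols(pairs, "distance_um", "pairs")
  pairs$is_contact <- pairs$distance_um < config$contact_threshold
  pairs
}

#' Per-cell summaries of contacts and transcription
#'
#' For every nucleus: number of retained allele pairs, number of contacts,
#' fraction of close alleles, RNA transcription-site count, total and mean
#' RNA spot intensity, and the nuclear GFP intensity (fusion-protein level).
#' Cells with zero retained pairs get `fraction_close = NA` — absence of a
#' measurement is not absence of contact — and are excluded from contact
#' analyses downstream.
#'
#' @param nuclei filtered nucleus table (with `condition`, `gfp_mean`).
#' @param pairs allele pairs with `is_contact` (from [call_contacts()]).
#' @param rna_spots RNA-channel spot table (`nucleus_id`, `intensity`);
#'   pass a zero-row data.frame for DNA-only experiments.
#' @return data.frame with one row per nucleus: `nucleus_id`, `condition`,
#'   `n_pairs`, `n_contacts`, `fraction_close`, `rna_spot_count`,
#'   `rna_total_intensity`, `rna_mean_intensity`, `gfp_intensity`.
#' @export
summarize_cells <- function(nuclei, pairs, rna_spots = NULL) {
  check_cols(nuclei, c("nucleus_id", "condition", "gfp_mean"), "nuclei")
  check_cols(pairs, c("nucleus_id", "distance_um", "is_contact"), "pairs")
  ids <- nuclei$nucleus_id
  f <- factor(pairs$nucleus_id, levels = ids)
  n_pairs <- as.integer(table(f))
  n_contacts <- as.integer(tapply(pairs$is_contact, f, sum, default = 0))
  if (is.null(rna_spots) || !nrow(rna_spots)) {
    rna_count <- integer(length(ids))
    rna_total <- numeric(length(ids))
  } else {
    check_cols(rna_spots, c("nucleus_id", "intensity"), "rna_spots")
    fr <- factor(rna_spots$nucleus_id, levels = ids)
    rna_count <- as.integer(table(fr))
    rna_total <- as.numeric(tapply(rna_spots$intensity, fr, sum, default = 0))
  }
  data.frame(
    nucleus_id = ids, condition = nuclei$condition,
    n_pairs = n_pairs, n_contacts = n_contacts,
    fraction_close = ifelse(n_pairs > 0, n_contacts / n_pairs, NA_real_),
    rna_spot_count = rna_count,
    rna_total_intensity = rna_total,
    rna_mean_intensity = ifelse(rna_count > 0, rna_total / rna_count,
                                NA_real_),
    gfp_intensity = nuclei$gfp_mean,
    stringsAsFactors = FALSE
  )
}

#' Equal-count binning of cell summaries
#'
#' Bins cells on the chosen variable with quantile-based edges, so bins hold
#' similar numbers of cells (populations differ only by ties at an edge).
#' When binning by `fraction_close`, cells with exactly zero close alleles
#' form their own first bin labelled `"0"` — the natural reference group of
#' cells with no measured contact — and the `n_bins` quantile bins are
#' formed on the remaining cells. Cells with `NA` in the binning variable
#' are dropped with a message.
#'
#' @param summaries output of [summarize_cells()].
#' @param by binning variable: `"fraction_close"` or `"gfp_intensity"`.
#' @param n_bins number of quantile bins (excluding the `"0"` bin).
#' @return `summaries` (rows with defined binning values) with `bin`
#'   (ordered factor) and `bin_index` columns.
#' @export
bin_cells <- function(summaries, by = c("fraction_close", "gfp_intensity"),
                      n_bins = 4L) {
  by <- match.arg(by)
  n_bins <- check_count(n_bins, "n_bins")
  check_cols(summaries, by, "summaries")
  x <- summaries[[by]]
  keep <- !is.na(x)
  if (any(!keep)) {
    message(sum(!keep), " cell(s) without defined ", by, " dropped")
  }
  s <- summaries[keep, , drop = FALSE]
  x <- x[keep]
  labels <- character(nrow(s))
  if (by == "fraction_close") {
    zero <- x == 0
    labels[zero] <- "0"
    xq <- x[!zero]
  } else {
    zero <- rep(FALSE, length(x))
    xq <- x
  }
  if (length(xq)) {
    if (length(unique(xq)) == 1L) {
      warning("binning variable is constant; a single bin was formed")
      labels[!zero] <- formatC(xq[1], digits = 3, format = "g")
    } else {
      edges <- unique(quantile(xq, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
      if (length(edges) - 1L < n_bins) {
        warning("tied quantile edges collapsed; fewer bins than requested")
      }
      cutx <- cut(xq, breaks = edges, include.lowest = TRUE)
      labels[!zero] <- as.character(cutx)
    }
  }
  ord <- unique(labels[order(zero * -1, x)])  # "0" (if any) first, then by value
  s$bin <- factor(labels, levels = ord, ordered = TRUE)
  s$bin_index <- as.integer(s$bin)
  s
}

condition_of <- function(pairs, nuclei) {
  if (!"condition" %in% names(pairs)) {
    if (is.null(nuclei)) {
      stop("`pairs` has no condition column and no `nuclei` table given",
           call. = FALSE)
    }
    pairs$condition <- nuclei$condition[match(pairs$nucleus_id,
                                              nuclei$nucleus_id)]
  }
  pairs
}

#' Per-condition fraction of alleles in contact
#'
#' @param pairs allele pairs with `is_contact` and either a `condition`
#'   column or a `nuclei` table to take it from.
#' @param nuclei optional nucleus table supplying `condition`.
#' @return data.frame: `condition`, `fraction_close`, `n_alleles`.
#'   Conditions with zero alleles report `NA`.
#' @export
condition_contact_fraction <- function(pairs, nuclei = NULL) {
  check_cols(pairs, c("nucleus_id", "is_contact"), "pairs")
  pairs <- condition_of(pairs, nuclei)
  f <- factor(pairs$condition)
  n <- as.integer(table(f))
  frac <- as.numeric(tapply(pairs$is_contact, f, mean))
  data.frame(condition = levels(f), fraction_close = frac, n_alleles = n,
             stringsAsFactors = FALSE)
}

#' Per-condition median allele-pair distance
#'
#' @inheritParams condition_contact_fraction
#' @return data.frame: `condition`, `median_distance_um`, `n_alleles`.
#' @export
median_pair_distance <- function(pairs, nuclei = NULL) {
  check_cols(pairs, c("nucleus_id", "distance_um"), "pairs")
  pairs <- condition_of(pairs, nuclei)
  f <- factor(pairs$condition)
  data.frame(condition = levels(f),
             median_distance_um = as.numeric(tapply(pairs$distance_um, f,
                                                    median)),
             n_alleles = as.integer(table(f)),
             stringsAsFactors = FALSE)
}
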