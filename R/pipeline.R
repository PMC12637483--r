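#' Run the full single-allele contact analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC filter -> ploidy filter -> spot
#' matching -> contact calling -> per-cell summaries -> binning ->
#' independence statistics, writes all tables as CSV plus a JSON run
#' manifest, and renders a plain-text report. Stage order is fixed; each
#' filtering stage's counts are recorded in the manifest so every input
#' nucleus is accounted for across kept / rejected-by-QC /
#' rejected-by-ploidy.
#'
#' @param config either a list or the path of a YAML file with entries:
#'   \describe{
#'     \item{simulate}{arguments for [sim_config()] (a list per condition,
#'       or a single list), or `NULL` when `nuclei_csv`/`spots_csv` are
#'       given.}
#'     \item{nuclei_csv, spots_csv}{paths of input tables when not
#'       simulating.}
#'     \item{analysis}{arguments for [analysis_config()].}
#'     \item{bin_by}{binning variable for the report (default
#'       `"fraction_close"`).}
#'     \item{seed}{integer; overrides the seeds of simulated conditions
#'       (condition i uses `seed + i - 1`).}
#'   }
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and returns results invisibly.
#' @return (invisibly) a list with `nuclei`, `spots`, `pairs`, `cells`,
#'   `binned`, `stats` (per-condition contact fractions, medians,
#'   independence tests, Marascuilo table), `report` (character vector) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  acfg <- do.call(analysis_config, as.list(config$analysis))

  if (!is.null(config$simulate)) {
    sims <- config$simulate
    if (!is.null(names(sims)) && any(names(sims) %in% names(formals(sim_config)))) {
      sims <- list(synthetic = sims)  # single unnamed condition
    }
    base_seed <- config$seed
    parts <- lapply(seq_along(sims), function(i) {
      args <- as.list(sims[[i]])
      if (!is.null(base_seed)) args$seed <- as.integer(base_seed) + i - 1L
      sc <- do.call(sim_config, args)
      generate_fish_dataset(sc, contact_threshold = acfg$contact_threshold,
                            condition = names(sims)[i])
    })
    nuclei <- do.call(rbind, lapply(parts, `[[`, "nuclei"))
    spots <- do.call(rbind, lapply(parts, `[[`, "spots"))
    # nucleus ids must be unique across conditions
    tag <- rep(names(sims), vapply(parts, function(p) nrow(p$nuclei), 1L))
    nuclei$nucleus_id <- paste(tag, nuclei$nucleus_id, sep = ".")
    tag_s <- rep(names(sims), vapply(parts, function(p) nrow(p$spots), 1L))
    spots$nucleus_id <- paste(tag_s, spots$nucleus_id, sep = ".")
  } else {
    if (is.null(config$nuclei_csv) || is.null(config$spots_csv)) {
      stop("config needs either `simulate` or `nuclei_csv` + `spots_csv`",
           call. = FALSE)
    }
    nuclei <- read.csv(config$nuclei_csv, stringsAsFactors = FALSE)
    spots <- read.csv(config$spots_csv, stringsAsFactors = FALSE)
  }
  n_in <- nrow(nuclei)

  qc <- qc_filter_nuclei(nuclei, acfg)
  kept <- ploidy_filter(qc$kept, spots, acfg)
  n_ploidy_rej <- attr(kept, "n_rejected")

  spots_kept <- spots[spots$nucleus_id %in% kept$nucleus_id, , drop = FALSE]
  pairs <- match_spots_by_nucleus(spots_kept, acfg)
  pairs <- call_contacts(pairs, acfg)
  pairs$condition <- kept$condition[match(pairs$nucleus_id, kept$nucleus_id)]

  rna <- spots_kept[spots_kept$channel == "rna", , drop = FALSE]
  cells <- summarize_cells(kept, pairs, rna)

  bin_by <- if (is.null(config$bin_by)) "fraction_close" else config$bin_by
  binned <- suppressMessages(bin_cells(cells, by = bin_by,
                                       n_bins = acfg$n_bins))

  stats <- compute_condition_stats(cells, pairs, acfg)

  manifest <- list(
    package_version = as.character(utils::packageVersion("alleloop")),
    seed = config$seed,
    config = config,
    counts = list(nuclei_in = n_in,
                  rejected_qc = n_in - nrow(qc$kept),
                  rejected_ploidy = n_ploidy_rej,
                  nuclei_kept = nrow(kept),
                  allele_pairs = nrow(pairs),
                  cells_summarized = nrow(cells))
  )
  report <- pipeline_report(list(cells = cells, binned = binned,
                                 stats = stats, manifest = manifest,
                                 config = acfg))

  res <- list(nuclei = nuclei, spots = spots, pairs = pairs, cells = cells,
              binned = binned, stats = stats, report = report,
              manifest = manifest, config = acfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, f) write.csv(df, file.path(out_dir, f),
                                      row.names = FALSE)
    wcsv(nuclei, "nuclei.csv"); wcsv(spots, "spots.csv")
    wcsv(pairs, "pairs.csv"); wcsv(cells, "cells.csv")
    wcsv(binned, "cells_binned.csv")
    wcsv(stats$contact_fractions, "contact_fractions.csv")
    wcsv(stats$median_distances, "median_distances.csv")
    wcsv(stats$independence, "independence_tests.csv")
    if (!is.null(stats$marascuilo)) wcsv(stats$marascuilo, "marascuilo.csv")
    manifest$outputs <- list.files(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  invisible(res)
}

compute_condition_stats <- function(cells, pairs, acfg) {
  frac <- condition_contact_fraction(pairs)
  med <- median_pair_distance(pairs)
  conds <- frac$condition
  indep <- do.call(rbind, lapply(conds, function(cc) {
    sub <- cells[cells$condition == cc & cells$n_pairs == acfg$ploidy, ,
                 drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(condition = cc, N = 0L, p_c = NA_real_,
                        chi2 = NA_real_, df = NA_real_, p_value = NA_real_,
                        stars = NA_character_, stringsAsFactors = FALSE))
    }
    d <- observed_distribution(sub, n = acfg$ploidy, condition = cc)
    ht <- independence_test(d)
    data.frame(condition = cc, N = d$N, p_c = d$p_c,
               chi2 = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value, stars = p_stars(ht$p.value),
               stringsAsFactors = FALSE)
  }))
  mar <- if (nrow(frac) >= 2 && !anyNA(frac$fraction_close)) {
    marascuilo(frac$fraction_close, frac$n_alleles, labels = frac$condition)
  }
  list(contact_fractions = frac, median_distances = med,
       independence = indep, marascuilo = mar)
}

#' Render a plain-text analysis report
#'
#' Per-condition contact fractions with allele counts, median distances,
#' binned RNA metrics (normalized to the declared control condition when
#' set), observed vs expected close-allele distributions with chi-square
#' results, and the Marascuilo pairwise table, using the conventional
#' significance asterisks (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param results list with `cells`, `binned`, `stats`, `manifest`,
#'   `config` as assembled by [run_pipeline()].
#' @return character vector of report lines.
#' @export
pipeline_report <- function(results) {
  st <- results$stats
  acfg <- results$config
  out <- c("Single-allele chromatin contact analysis report",
           strrep("=", 48), "")
  out <- c(out, "Per-condition fraction of alleles in contact:")
  f <- st$contact_fractions
  if (!nrow(f)) {
    out <- c(out, "  [no data]")
  } else {
    for (i in seq_len(nrow(f))) {
      out <- c(out, if (is.na(f$fraction_close[i]))
        sprintf("  %-20s [no data]", f$condition[i])
      else
        sprintf("  %-20s %.4f  (n = %d alleles)", f$condition[i],
                f$fraction_close[i], f$n_alleles[i]))
    }
  }
  out <- c(out, "", "Median allele-pair distance (um):")
  m <- st$median_distances
  for (i in seq_len(nrow(m))) {
    out <- c(out, sprintf("  %-20s %.3f", m$condition[i],
                          m$median_distance_um[i]))
  }
  out <- c(out, "", "Allele independence (observed vs binomial expectation):")
  ind <- st$independence
  for (i in seq_len(nrow(ind))) {
    out <- c(out, if (is.na(ind$p_value[i]))
      sprintf("  %-20s [test undefined]", ind$condition[i])
    else
      sprintf("  %-20s chi2 = %.3f, df = %d, p = %.3g %s",
              ind$condition[i], ind$chi2[i], ind$df[i], ind$p_value[i],
              ind$stars[i]))
  }
  if (!is.null(st$marascuilo)) {
    out <- c(out, "", "Marascuilo pairwise comparison of contact fractions:")
    mr <- st$marascuilo
    for (i in seq_len(nrow(mr))) {
      out <- c(out, sprintf("  %s vs %s: |diff| = %.4f, critical = %.4f%s",
                            mr$group_i[i], mr$group_j[i], mr$abs_diff[i],
                            mr$critical_range[i],
                            if (mr$significant[i]) "  *" else ""))
    }
  }
  b <- results$binned
  if (!is.null(b) && nrow(b)) {
    out <- c(out, "", "Binned per-cell transcription metrics:")
    norm <- 1
    ctrl <- acfg$control_condition
    if (!is.null(ctrl)) {
      ref <- b$rna_total_intensity[b$condition == ctrl]
      if (!length(ref)) {
        stop(sprintf("control_condition '%s' not present in the data", ctrl),
             call. = FALSE)
      }
      norm <- mean(ref)
      out <- c(out, sprintf("  (RNA intensity relative to condition '%s')",
                            ctrl))
    }
    for (lv in levels(b$bin)) {
      sub <- b[b$bin == lv, , drop = FALSE]
      if (!nrow(sub)) next
      out <- c(out, sprintf(
        "  bin %-12s n = %4d  mean TS count = %.3f  mean RNA intensity = %.3f",
        lv, nrow(sub), mean(sub$rna_spot_count),
        mean(sub$rna_total_intensity) / norm))
    }
  }
  cn <- results$manifest$counts
  out <- c(out, "", sprintf(
    "Nuclei: %d in, %d rejected by QC, %d rejected by ploidy, %d analysed.",
    cn$nuclei_in, cn$rejected_qc, cn$rejected_ploidy, cn$nuclei_kept))
  out
}
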