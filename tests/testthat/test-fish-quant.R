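nuc <- function(id, area, solidity, condition = "c1", gfp = 100) {
  data.frame(nucleus_id = id, field_id = "f1", condition = condition,
             area_um2 = area, solidity = solidity, gfp_mean = gfp,
             stringsAsFactors = FALSE)
}
spot <- function(id, channel, x, y, intensity = 1) {
  data.frame(nucleus_id = id, channel = channel, x_um = x, y_um = y,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("QC filter applies the area and solidity thresholds inclusively", {
  ac <- analysis_config(min_area = 90)
  nn <- rbind(nuc("n1", 100, 0.95), nuc("n2", 89.9, 0.95),
              nuc("n3", 100, 0.89), nuc("n4", 90, 0.9), nuc("n5", 80, 0.8))
  out <- qc_filter_nuclei(nn, ac)
  expect_setequal(out$kept$nucleus_id, c("n1", "n4"))
  rep <- out$report
  expect_equal(rep$n[rep$criterion == "area_below_min"], 2)
  expect_equal(rep$n[rep$criterion == "solidity_below_min"], 2)
  # empty input passes through
  expect_equal(nrow(qc_filter_nuclei(nn[0, ], ac)$kept), 0)
})

test_that("ploidy filter keeps cells with the expected count in each channel", {
  ac <- analysis_config(ploidy = 2)
  nn <- rbind(nuc("n1", 100, 0.95), nuc("n2", 100, 0.95),
              nuc("n3", 100, 0.95))
  sp <- rbind(spot("n1", "dna_a", 1:2, 1:2), spot("n1", "dna_b", 1:2, 1:2),
              spot("n2", "dna_a", 1:2, 1:2), spot("n2", "dna_b", 1:3, 1:3),
              spot("n3", "dna_a", 1:2, 1:2))  # n3 has no dna_b at all
  kept <- ploidy_filter(nn, sp, ac)
  expect_equal(kept$nucleus_id, "n1")
  expect_equal(attr(kept, "n_rejected"), 2L)
  ac3 <- analysis_config(ploidy = 3)
  sp3 <- rbind(spot("n1", "dna_a", 1:3, 1:3), spot("n1", "dna_b", 1:3, 1:3))
  expect_equal(ploidy_filter(nn[1, ], sp3, ac3)$nucleus_id, "n1")
})

test_that("spot matching follows the greedy one-to-one rule with the 2 um cap", {
  ac <- analysis_config()
  p1 <- match_spots(spot("n", "dna_a", 0, 0), spot("n", "dna_b", 0.1, 0), ac)
  expect_equal(p1$distance_um, 0.1)

  # far pair discarded by the cap
  p2 <- match_spots(spot("n", "dna_a", c(0, 5), c(0, 5)),
                    spot("n", "dna_b", c(0.1, 5), c(0, 7.5)), ac)
  expect_equal(p2$distance_um, 0.1)

  # two A spots compete for one B spot: nearest wins, other unpaired
  p3 <- match_spots(spot("n", "dna_a", c(0, 0.2), c(0, 0)),
                    spot("n", "dna_b", 0.1, 0), ac)
  expect_equal(p3$distance_um, 0.1)

  expect_equal(nrow(match_spots(spot("n", "dna_a", 1, 1)[0, ],
                                spot("n", "dna_b", 1, 1), ac)), 0)
})

test_that("greedy matching agrees with the enumeration oracle on small sets", {
  ac <- analysis_config()
  set.seed(42)
  for (i in 1:150) {
    na <- sample(0:4, 1); nb <- sample(0:4, 1)
    ax <- runif(na, 0, 3); ay <- runif(na, 0, 3)
    bx <- runif(nb, 0, 3); by <- runif(nb, 0, 3)
    got <- match_spots(data.frame(x_um = ax, y_um = ay),
                       data.frame(x_um = bx, y_um = by), ac)$distance_um
    want <- oracle_greedy_match(ax, ay, bx, by, 2)
    expect_equal(got, want, tolerance = 1e-12)
    expect_lte(length(got), min(na, nb))
    expect_true(all(got < 2))
  }
})

test_that("contact calls use a strict threshold and are monotone in it", {
  pairs <- data.frame(nucleus_id = "n",
                      distance_um = c(0.26, 0.27, 0.28, 0.1, 1.9))
  out <- call_contacts(pairs, analysis_config())
  expect_equal(out$is_contact, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  wide <- call_contacts(pairs, analysis_config(contact_threshold = 0.4))
  expect_true(all(out$is_contact <= wide$is_contact))  # superset at 0.4
})

test_that("cell summaries compute contact fractions and RNA metrics", {
  nn <- rbind(nuc("n1", 100, 0.95, gfp = 50), nuc("n2", 100, 0.95, gfp = 60))
  pairs <- data.frame(nucleus_id = c("n1", "n1", "n2", "n2"),
                      distance_um = c(0.1, 0.5, 0.9, 1.2),
                      is_contact = c(TRUE, FALSE, FALSE, FALSE))
  rna <- spot("n1", "rna", 1:3, 1:3, intensity = c(10, 20, 30))
  cs <- summarize_cells(nn, pairs, rna)
  expect_equal(cs$fraction_close, c(0.5, 0))
  expect_equal(cs$rna_spot_count, c(3L, 0L))
  expect_equal(cs$rna_total_intensity, c(60, 0))
  expect_equal(cs$rna_mean_intensity, c(20, NA_real_))
  expect_equal(cs$gfp_intensity, c(50, 60))
  # zero retained pairs: fraction undefined, not zero
  cs2 <- summarize_cells(nuc("n9", 100, 0.95), pairs[0, ], rna[0, ])
  expect_true(is.na(cs2$fraction_close))
})

test_that("equal-count binning isolates the zero bin and balances the rest", {
  s <- data.frame(nucleus_id = paste0("n", 1:100), condition = "c",
                  n_pairs = 2L, n_contacts = 0L,
                  fraction_close = seq(0.01, 1, length.out = 100),
                  rna_spot_count = 0L, rna_total_intensity = 0,
                  rna_mean_intensity = NA_real_, gfp_intensity = runif(100))
  b <- bin_cells(s, "fraction_close", n_bins = 4)
  expect_equal(unname(table(b$bin)), rep(25L, 4), ignore_attr = TRUE)

  s$fraction_close <- c(rep(0, 3), rep(0.5, 2), 1, rep(NA, 94))
  b2 <- suppressMessages(suppressWarnings(
    bin_cells(s, "fraction_close", n_bins = 2)))
  expect_equal(sum(b2$bin == "0"), 3)
  expect_equal(levels(b2$bin)[1], "0")
  expect_equal(nrow(b2), 6)  # NA rows dropped

  s$fraction_close <- rep(0.5, 100)
  expect_warning(bin_cells(s, "fraction_close", n_bins = 3), "constant")

  b4 <- bin_cells(s, "gfp_intensity", n_bins = 5)
  expect_true(max(table(b4$bin)) - min(table(b4$bin)) <= 1)
})

test_that("condition-level fractions and medians match direct computation", {
  pairs <- data.frame(
    nucleus_id = rep(c("n1", "n2"), each = 3),
    condition = rep(c("dark", "light"), each = 3),
    distance_um = c(0.1, 0.5, 0.9, 0.2, 0.4, 0.25),
    is_contact = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  cf <- condition_contact_fraction(pairs)
  expect_equal(cf$fraction_close[cf$condition == "dark"], 1 / 3)
  expect_equal(cf$fraction_close[cf$condition == "light"], 2 / 3)
  expect_equal(cf$n_alleles, c(3L, 3L))
  md <- median_pair_distance(pairs)
  expect_equal(md$median_distance_um, c(0.5, 0.25))
  # even count uses the midpoint convention
  expect_equal(median_pair_distance(
    data.frame(nucleus_id = "n", condition = "c",
               distance_um = c(0.2, 0.4)))$median_distance_um, 0.3)
  # empty condition level flagged as NA
  pairs$condition <- factor(pairs$condition, levels = c("dark", "light", "x"))
  expect_true(is.na(condition_contact_fraction(pairs)$fraction_close[3]))
})

test_that("median of free-only pairs approaches the Rayleigh closed form", {
  sigma <- 0.6
  ds <- generate_fish_dataset(sim_config(n_cells = 3000, p_loop = 0,
                                         free_distance_params = sigma,
                                         seed = 17))
  q <- quantify(ds, analysis_config())
  med <- median(q$pairs$distance_um)
  # Rayleigh median sigma*sqrt(2 log 2), conditioned on the 2 um cap
  expect_equal(med, sigma * sqrt(2 * log(2)), tolerance = 0.03)
})

test_that("pipeline recovers true contact labels without dropout or noise", {
  ds <- generate_fish_dataset(sim_config(n_cells = 300, p_loop = 0.3,
                                         spot_detection_prob = 1,
                                         false_spot_rate = 0, seed = 23))
  q <- quantify(ds, analysis_config())
  truth_n <- tapply(ds$truth$contact_true, ds$truth$nucleus_id, sum)
  ok <- q$cells$n_contacts == truth_n[q$cells$nucleus_id]
  # identical up to rare anchor collisions that swap partner assignment
  expect_gt(mean(ok), 0.97)
})

test_that("between-condition contact differences are threshold-stable", {
  mk <- function(p, seed) {
    q <- quantify(generate_fish_dataset(sim_config(n_cells = 800,
                                                   p_loop = p, seed = seed)),
                  analysis_config())
    q$pairs
  }
  dark <- mk(0.10, 51); light <- mk(0.35, 52)
  for (thr in c(0.2, 0.27, 0.35)) {
    ac <- analysis_config(contact_threshold = thr)
    f_d <- mean(call_contacts(dark, ac)$is_contact)
    f_l <- mean(call_contacts(light, ac)$is_contact)
    expect_gt(f_l, f_d)  # sign of the effect is threshold-stable
  }
  # contact fraction nonincreasing as the threshold decreases
  fr <- vapply(c(0.2, 0.27, 0.35), function(thr) {
    mean(call_contacts(light, analysis_config(contact_threshold = thr))$is_contact)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
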