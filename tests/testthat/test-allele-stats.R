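test_that("binomial null matches brute-force enumeration and closed forms", {
  # diploid / triploid expansions, term by term
  expect_equal(unname(binomial_expected(0.5, 2)$expected_fractions),
               c(0.25, 0.5, 0.25))
  p <- 0.36
  expect_equal(unname(binomial_expected(p, 2)$expected_fractions),
               c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_equal(unname(binomial_expected(p, 3)$expected_fractions),
               c((1 - p)^3, 3 * p * (1 - p)^2, 3 * p^2 * (1 - p), p^3))
  expect_equal(unname(binomial_expected(0.36, 3)$expected_fractions),
               c(0.262144, 0.442368, 0.248832, 0.046656))
  expect_equal(unname(binomial_expected(0, 3)$expected_fractions),
               c(1, 0, 0, 0))
  # enumeration oracle across random p and n
  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:6, 1); p <- runif(1)
    f <- binomial_expected(p, n)$expected_fractions
    expect_equal(unname(f), brute_force_binomial(p, n), tolerance = 1e-12)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
  expect_error(binomial_expected(1.2, 2), "p_c")
})

test_that("observed distribution counts cells and pools p_c", {
  cells <- data.frame(n_pairs = 2L, n_contacts = c(0L, 1L, 2L))
  d <- observed_distribution(cells, 2)
  expect_equal(unname(d$counts), c(1L, 1L, 1L))
  expect_equal(d$p_c, 0.5)
  expect_equal(d$N, 3L)
  # all-zero case is degenerate but well defined
  d0 <- observed_distribution(rep(0L, 5), 2)
  expect_equal(unname(d0$counts), c(5L, 0L, 0L))
  expect_equal(d0$p_c, 0)
  # wrong pair count refused
  bad <- data.frame(n_pairs = c(2L, 3L), n_contacts = c(1L, 1L))
  expect_error(observed_distribution(bad, 2), "ploidy_filter")
})

test_that("pooled p_c equals the allele-level contact fraction", {
  ds <- generate_fish_dataset(sim_config(n_cells = 500, p_loop = 0.25,
                                         seed = 13))
  q <- quantify(ds, analysis_config())
  complete <- q$cells[q$cells$n_pairs == 2, ]
  d <- observed_distribution(complete, 2)
  cf <- condition_contact_fraction(
    q$pairs[q$pairs$nucleus_id %in% complete$nucleus_id, ], q$kept)
  expect_equal(d$p_c, cf$fraction_close)
})

test_that("chi-square worked example and degenerate guards", {
  d <- observed_distribution(rep(0:2, c(36, 28, 36)), 2)
  expect_equal(d$p_c, 0.5)
  ht <- independence_test(d)
  expect_equal(unname(ht$statistic), 19.36, tolerance = 1e-10)
  expect_equal(ht$expected, c(25, 50, 25))
  expect_lt(ht$p.value, 0.001)
  # exact agreement with expectation: chi2 = 0, p = 1
  dd <- observed_distribution(rep(0:2, c(25, 50, 25)), 2)
  ht0 <- independence_test(dd)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  # p_c at the boundary: undefined, flagged
  hdeg <- independence_test(observed_distribution(rep(0L, 10), 2))
  expect_true(is.na(hdeg$p.value))
  expect_match(hdeg$method, "undefined")
  # df options: statistic identical, p-value larger with plain df
  hplain <- independence_test(d, df_estimated = FALSE)
  expect_equal(unname(hplain$statistic), unname(ht$statistic))
  expect_gt(hplain$p.value, ht$p.value)
})

test_that("statistic matches stats::chisq.test given the same expectations", {
  set.seed(8)
  for (i in 1:20) {
    k <- simulate_close_allele_counts(sim_config(n_cells = 400,
                                                 p_loop = runif(1, .1, .5),
                                                 seed = i), use_seed = FALSE)
    d <- observed_distribution(k, 2)
    if (d$p_c %in% c(0, 1)) next
    ht <- independence_test(d, expected_floor = 0)
    ref <- suppressWarnings(stats::chisq.test(
      unname(d$counts), p = unname(binomial_expected(d$p_c, 2)$expected_fractions)))
    expect_equal(unname(ht$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
  }
})

test_that("sparse expected categories are pooled inward", {
  # tiny p_c: the c2 expectation falls below the floor and merges into c1
  d <- observed_distribution(rep(0:2, c(96, 4, 0)), 2)  # p_c = 0.01
  ht <- independence_test(d, expected_floor = 1)
  expect_equal(length(ht$expected), 2L)
  expect_equal(sum(ht$observed), 100)
  expect_equal(sum(ht$expected), 100, tolerance = 1e-9)
})

test_that("independence test detects coupled alleles and stays calibrated", {
  # scaled-down calibration check (the full-size one lives in acceptance)
  set.seed(31)
  rej0 <- mean(replicate(60, {
    k <- simulate_close_allele_counts(sim_config(n_cells = 2000,
                                                 p_loop = 0.2), use_seed = FALSE)
    independence_test(observed_distribution(k, 2))$p.value < 0.05
  }))
  expect_lt(rej0, 0.17)
  rej6 <- mean(replicate(30, {
    k <- simulate_close_allele_counts(sim_config(n_cells = 2000, p_loop = 0.2,
                                                 allele_coupling = 0.4),
                                      use_seed = FALSE)
    independence_test(observed_distribution(k, 2))$p.value < 0.05
  }))
  expect_gt(rej6, 0.9)
})

test_that("Marascuilo critical ranges match the formula and behave at limits", {
  # two identical groups never differ
  m0 <- marascuilo(c(0.3, 0.3), c(100, 100))
  expect_equal(m0$abs_diff, 0)
  expect_false(any(m0$significant))

  p <- c(0.15, 0.21, 0.50); n <- c(5000, 5000, 5000)
  m <- marascuilo(p, n, labels = c("a", "b", "c"), alpha = 0.05)
  # independent re-evaluation of the critical range formula
  crit <- sqrt(qchisq(0.95, df = 2))
  want <- apply(utils::combn(3, 2), 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    crit * sqrt(p[i] * (1 - p[i]) / n[i] + p[j] * (1 - p[j]) / n[j])
  })
  expect_equal(m$critical_range, want, tolerance = 1e-12)
  expect_equal(m$significant, abs(c(p[1] - p[2], p[1] - p[3], p[2] - p[3])) > want)

  # alpha -> 1: critical ranges collapse, all unequal pairs significant
  m1 <- marascuilo(p, n, alpha = 0.999999)
  expect_true(all(m1$significant))

  # monotone in n: growing samples never lose significance
  for (nn in c(50, 500, 5000)) {
    prev <- marascuilo(c(0.15, 0.21), c(nn, nn))$significant
    nxt <- marascuilo(c(0.15, 0.21), c(nn * 10, nn * 10))$significant
    expect_true(all(nxt >= prev))
  }
  expect_error(marascuilo(c(0.5), 10), "2 groups")
  expect_error(marascuilo(c(0.5, 0.6), c(0, 10)), "sizes")
})
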