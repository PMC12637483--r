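#' Simulation configuration for synthetic FISH datasets
#'
#' Builds and validates the parameter set from which
#' [generate_fish_dataset()] draws per-nucleus and per-spot tables with known
#' ground truth. Defaults emulate a U2OS-like diploid DNA-FISH experiment:
#' nuclei around 120 um^2, a two-component pair-distance law whose free
#' (unlooped) component lands below the 0.27 um contact threshold in roughly
#' 9% of alleles, and a lognormal fusion-protein expression distribution.
#'
#' @param n_cells number of nuclei to simulate.
#' @param ploidy alleles per cell (2, 3 or 4).
#' @param p_loop marginal probability that an allele is in the looped state.
#' @param allele_coupling intra-cell correlation of loop states in \[0, 1):
#'   0 gives fully independent alleles; positive values draw a cell-level
#'   loop probability from a Beta law with mean `p_loop` and intra-class
#'   correlation `allele_coupling` (a beta-binomial hierarchy).
#' @param looped_distance_params `c(location, scale)` in um of the
#'   half-normal law for looped pair distances: `location + |N(0, scale)|`.
#' @param free_distance_params `c(scale)` in um of the Rayleigh law for
#'   unlooped pair distances (the 2D isotropic separation law).
#' @param spot_detection_prob probability each true spot appears in the table.
#' @param false_spot_rate expected spurious spots per nucleus per channel
#'   (Poisson).
#' @param nucleus_area_params `c(mean, sd)` in um^2 of the nuclear area law.
#' @param nucleus_solidity_params `c(alpha, beta)` of the Beta solidity law.
#' @param expression_params `c(meanlog, sdlog)` of the lognormal per-cell
#'   fusion-protein (GFP) intensity.
#' @param expression_effect slope linking centred log expression to the
#'   log-odds of looping; 0 disables expression dependence.
#' @param rna_p_on probability an allele shows an active transcription site
#'   when NOT in contact.
#' @param repression_effect multiplicative reduction of `rna_p_on` for
#'   alleles in contact (0 = no repression, 1 = full silencing).
#' @param ts_intensity_params `c(meanlog, sdlog)` of transcription-site
#'   intensities.
#' @param seed integer seed; identical configs give byte-identical tables.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 1000L,
                       ploidy = 2L,
                       p_loop = 0.2,
                       allele_coupling = 0,
                       looped_distance_params = c(location = 0.10, scale = 0.05),
                       free_distance_params = c(scale = 0.6),
                       spot_detection_prob = 1,
                       false_spot_rate = 0,
                       nucleus_area_params = c(mean = 120, sd = 20),
                       nucleus_solidity_params = c(alpha = 40, beta = 2),
                       expression_params = c(meanlog = log(500), sdlog = 0.5),
                       expression_effect = 0,
                       rna_p_on = 0.4,
                       repression_effect = 0,
                       ts_intensity_params = c(meanlog = log(200), sdlog = 0.4),
                       seed = 1L) {
  check_count(n_cells, "n_cells")
  ploidy <- check_count(ploidy, "ploidy", min = 2L)
  if (ploidy > 4L) stop("`ploidy` must be 2, 3 or 4", call. = FALSE)
  check_prob(p_loop, "p_loop")
  check_prob(allele_coupling, "allele_coupling")
  if (allele_coupling >= 1) {
    stop("`allele_coupling` must be in [0, 1)", call. = FALSE)
  }
  if (length(looped_distance_params) != 2L ||
      any(!is.finite(looped_distance_params)) ||
      looped_distance_params[1] < 0 || looped_distance_params[2] <= 0) {
    stop("`looped_distance_params` must be c(location >= 0, scale > 0)",
         call. = FALSE)
  }
  check_pos(free_distance_params[1], "free_distance_params")
  check_prob(spot_detection_prob, "spot_detection_prob")
  check_pos(false_spot_rate, "false_spot_rate", strict = FALSE)
  check_pos(nucleus_area_params[1], "nucleus_area_params[mean]")
  check_pos(nucleus_area_params[2], "nucleus_area_params[sd]")
  check_pos(nucleus_solidity_params[1], "nucleus_solidity_params[alpha]")
  check_pos(nucleus_solidity_params[2], "nucleus_solidity_params[beta]")
  if (any(!is.finite(expression_params)) || expression_params[2] <= 0) {
    stop("`expression_params` must be finite with sdlog > 0", call. = FALSE)
  }
  if (!is.finite(expression_effect)) {
    stop("`expression_effect` must be finite", call. = FALSE)
  }
  check_prob(rna_p_on, "rna_p_on")
  check_prob(repression_effect, "repression_effect")
  if (any(!is.finite(ts_intensity_params)) || ts_intensity_params[2] <= 0) {
    stop("`ts_intensity_params` must be finite with sdlog > 0", call. = FALSE)
  }
  check_count(seed, "seed", min = 0L)
  structure(list(
    n_cells = as.integer(n_cells), ploidy = ploidy, p_loop = p_loop,
    allele_coupling = allele_coupling,
    looped_distance_params = unname(looped_distance_params),
    free_distance_params = unname(free_distance_params[1]),
    spot_detection_prob = spot_detection_prob,
    false_spot_rate = false_spot_rate,
    nucleus_area_params = unname(nucleus_area_params),
    nucleus_solidity_params = unname(nucleus_solidity_params),
    expression_params = unname(expression_params),
    expression_effect = expression_effect,
    rna_p_on = rna_p_on, repression_effect = repression_effect,
    ts_intensity_params = unname(ts_intensity_params),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Cell-level loop probabilities under the beta-binomial hierarchy.
# With coupling rho the Beta has mean m and ICC rho: shape a = m(1-rho)/rho.
cell_loop_prob <- function(m, rho) {
  if (rho == 0) return(m)
  out <- m
  mid <- m > 0 & m < 1
  if (any(mid)) {
    a <- m[mid] * (1 - rho) / rho
    b <- (1 - m[mid]) * (1 - rho) / rho
    out[mid] <- rbeta(sum(mid), a, b)
  }
  out
}

# Pair-distance draws: half-normal (looped) / Rayleigh (free).
draw_pair_distance <- function(looped, looped_params, free_scale) {
  n <- length(looped)
  d <- numeric(n)
  nl <- sum(looped)
  if (nl) {
    d[looped] <- looped_params[1] + abs(rnorm(nl, 0, looped_params[2]))
  }
  nf <- n - nl
  if (nf) {
    d[!looped] <- free_scale * sqrt(-2 * log(runif(nf)))
  }
  d
}

#' Contact probability implied by the configured distance mixture
#'
#' Closed-form probability that a pair distance falls below `threshold`
#' under the half-normal (looped) / Rayleigh (free) mixture, at the marginal
#' loop probability. Used as the ground-truth center when checking recovered
#' contact fractions.
#'
#' @param config a [sim_config()].
#' @param threshold contact-calling distance in um.
#' @return a probability.
#' @export
implied_contact_prob <- function(config, threshold = 0.27) {
  stopifnot(inherits(config, "sim_config"))
  loc <- config$looped_distance_params[1]
  sc <- config$looped_distance_params[2]
  p_looped <- if (threshold <= loc) 0 else
    2 * stats::pnorm((threshold - loc) / sc) - 1
  p_free <- 1 - exp(-threshold^2 / (2 * config$free_distance_params^2))
  config$p_loop * p_looped + (1 - config$p_loop) * p_free
}

#' Generate a synthetic nucleus/spot dataset with ground truth
#'
#' Draws a full single-allele FISH experiment: per-nucleus morphology and
#' expression, allele anchors placed uniformly in the nuclear disk, loop
#' states from the (optionally coupled, optionally expression-dependent)
#' beta-binomial hierarchy, channel-B spots displaced from their anchors by
#' the looped or free distance law in a uniform direction, transcription-site
#' RNA spots whose emission probability is reduced for alleles in contact,
#' plus spot dropout and uniform false spots. The output tables have the
#' shape of high-throughput imaging segmentation output.
#'
#' @param config a [sim_config()].
#' @param contact_threshold distance in um below which a generated allele is
#'   recorded as a true contact (drives transcriptional repression and
#'   `realized_p_c`).
#' @param condition label copied into the nucleus table.
#' @return list with elements
#'   \item{nuclei}{data.frame: `nucleus_id`, `field_id`, `condition`,
#'     `area_um2`, `solidity`, `gfp_mean`}
#'   \item{spots}{data.frame: `nucleus_id`, `channel` (`dna_a`/`dna_b`/`rna`),
#'     `x_um`, `y_um`, `intensity`}
#'   \item{truth}{data.frame with one row per generated allele
#'     (`nucleus_id`, `allele`, `loop_state`, `true_distance_um`,
#'     `contact_true`, `rna_on`, `expression`), with attribute
#'     `realized_p_c`, the realized fraction of alleles in contact.}
#' @export
generate_fish_dataset <- function(config, contact_threshold = 0.27,
                                  condition = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  check_pos(contact_threshold, "contact_threshold")
  set.seed(config$seed)
  n <- config$n_cells
  k <- config$ploidy

  area <- pmax(rnorm(n, config$nucleus_area_params[1],
                     config$nucleus_area_params[2]), 10)
  solidity <- rbeta(n, config$nucleus_solidity_params[1],
                    config$nucleus_solidity_params[2])
  expr <- rlnorm(n, config$expression_params[1], config$expression_params[2])

  # expression shifts the loop log-odds around its configured marginal
  m <- if (config$p_loop %in% c(0, 1) || config$expression_effect == 0) {
    rep(config$p_loop, n)
  } else {
    stats::plogis(stats::qlogis(config$p_loop) +
                  config$expression_effect *
                    (log(expr) - config$expression_params[1]))
  }
  p_cell <- cell_loop_prob(m, config$allele_coupling)

  cell <- rep(seq_len(n), each = k)
  loop_state <- rbinom(n * k, 1L, p_cell[cell]) == 1L
  dist_true <- draw_pair_distance(loop_state, config$looped_distance_params,
                                  config$free_distance_params)
  contact_true <- dist_true < contact_threshold

  # nucleus centers scattered across fields of ~100 cells
  field <- (seq_len(n) - 1L) %/% 100L + 1L
  cx <- runif(n, 0, 200)
  cy <- runif(n, 0, 200)
  radius <- sqrt(area / pi)

  # allele anchors uniform in the nuclear disk
  r_a <- radius[cell] * sqrt(runif(n * k))
  th_a <- runif(n * k, 0, 2 * pi)
  ax <- cx[cell] + r_a * cos(th_a)
  ay <- cy[cell] + r_a * sin(th_a)
  th_d <- runif(n * k, 0, 2 * pi)
  bx <- ax + dist_true * cos(th_d)
  by <- ay + dist_true * sin(th_d)

  p_ts <- config$rna_p_on * (1 - config$repression_effect * contact_true)
  rna_on <- rbinom(n * k, 1L, p_ts) == 1L

  nucleus_id <- sprintf("cell_%05d", seq_len(n))
  spot_int <- function(nn) rlnorm(nn, log(100), 0.3)

  spots <- rbind(
    data.frame(nucleus_id = nucleus_id[cell], channel = "dna_a",
               x_um = ax, y_um = ay, intensity = spot_int(n * k),
               stringsAsFactors = FALSE),
    data.frame(nucleus_id = nucleus_id[cell], channel = "dna_b",
               x_um = bx, y_um = by, intensity = spot_int(n * k),
               stringsAsFactors = FALSE),
    if (any(rna_on)) {
      data.frame(nucleus_id = nucleus_id[cell][rna_on], channel = "rna",
                 x_um = ax[rna_on], y_um = ay[rna_on],
                 intensity = rlnorm(sum(rna_on), config$ts_intensity_params[1],
                                    config$ts_intensity_params[2]),
                 stringsAsFactors = FALSE)
    }
  )

  if (config$spot_detection_prob < 1) {
    keep <- runif(nrow(spots)) < config$spot_detection_prob
    spots <- spots[keep, , drop = FALSE]
  }

  if (config$false_spot_rate > 0) {
    fs <- lapply(c("dna_a", "dna_b", "rna"), function(ch) {
      n_false <- rpois(n, config$false_spot_rate)
      tot <- sum(n_false)
      if (!tot) return(NULL)
      idx <- rep(seq_len(n), n_false)
      rr <- radius[idx] * sqrt(runif(tot))
      tt <- runif(tot, 0, 2 * pi)
      data.frame(nucleus_id = nucleus_id[idx], channel = ch,
                 x_um = cx[idx] + rr * cos(tt), y_um = cy[idx] + rr * sin(tt),
                 intensity = spot_int(tot), stringsAsFactors = FALSE)
    })
    spots <- rbind(spots, do.call(rbind, fs))
  }
  rownames(spots) <- NULL

  nuclei <- data.frame(
    nucleus_id = nucleus_id, field_id = sprintf("field_%03d", field),
    condition = condition, area_um2 = area, solidity = solidity,
    gfp_mean = expr, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    nucleus_id = nucleus_id[cell], allele = rep(seq_len(k), times = n),
    loop_state = loop_state, true_distance_um = dist_true,
    contact_true = contact_true, rna_on = rna_on,
    expression = expr[cell], stringsAsFactors = FALSE
  )
  attr(truth, "realized_p_c") <- mean(contact_true)
  list(nuclei = nuclei, spots = spots, truth = truth)
}

#' Fast draw of per-cell close-allele counts
#'
#' Samples only the loop-state / pair-distance layer of the generative model
#' and returns the number of alleles in contact per cell. Used for
#' calibration and power studies of the allele-independence test, where the
#' spot tables themselves are not needed.
#'
#' @inheritParams generate_fish_dataset
#' @param use_seed set the RNG from `config$seed` (disable inside replicate
#'   loops that manage their own stream).
#' @return integer vector of length `n_cells` with values in `0:ploidy`.
#' @export
simulate_close_allele_counts <- function(config, contact_threshold = 0.27,
                                         use_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (use_seed) set.seed(config$seed)
  n <- config$n_cells
  k <- config$ploidy
  p_cell <- cell_loop_prob(rep(config$p_loop, n), config$allele_coupling)
  cell <- rep(seq_len(n), each = k)
  looped <- rbinom(n * k, 1L, p_cell[cell]) == 1L
  d <- draw_pair_distance(looped, config$looped_distance_params,
                          config$free_distance_params)
  as.integer(tabulate(cell[d < contact_threshold], nbins = n))
}

#' Generate a clustering kinetic trace with analytic ground truth
#'
#' The noiseless curve rises from `cv0` toward `cv_max` after light
#' activation at t = 0 and reverts exponentially after its peak:
#' \deqn{CV(t) = cv_0 + (cv_{max} - cv_0)(1 - e^{-r t}) e^{-d \max(0, t - t_{peak})}}
#' with \eqn{t_{peak} = \log(1 + r/d)/r}, the unique point where the rising
#' branch hands over smoothly to the decaying branch (continuous first
#' derivative, interior maximum exactly at \eqn{t_{peak}}). Analytic
#' half-maximal clustering/declustering times are computed by root-finding
#' on this curve and stored as ground truth.
#'
#' @param cv0 CV at t = 0 (> 0).
#' @param cv_max asymptotic CV scale of the rise (> `cv0`); the realized
#'   peak is `cv0 + (cv_max - cv0) * r/(r + d)`.
#' @param rise_rate clustering rate r in 1/min.
#' @param decay_rate declustering rate d in 1/min; must be < `rise_rate`
#'   so the curve has a usable interior maximum.
#' @param frame_interval sampling interval in seconds.
#' @param duration total imaging time in minutes.
#' @param noise_sd additive Gaussian noise on each sampled CV.
#' @param seed RNG seed for the noise.
#' @return object of class `"kinetic_trace"`: list with `times` (seconds),
#'   `cv`, `activation_index` (1), and analytic ground truth in seconds:
#'   `tc_true`, `td_true` (half-maximal return time measured from
#'   activation, matching the [estimate_td()] default), `td_true_from_peak`
#'   and `t_peak`.
#' @export
generate_kinetic_trace <- function(cv0, cv_max, rise_rate, decay_rate,
                                   frame_interval = 30, duration = 10,
                                   noise_sd = 0, seed = 1L) {
  check_pos(cv0, "cv0"); check_pos(cv_max, "cv_max")
  check_pos(rise_rate, "rise_rate"); check_pos(decay_rate, "decay_rate")
  check_pos(frame_interval, "frame_interval"); check_pos(duration, "duration")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (cv_max <= cv0) stop("`cv_max` must exceed `cv0`", call. = FALSE)
  if (decay_rate >= rise_rate) {
    stop("`decay_rate` >= `rise_rate` yields no usable interior maximum",
         call. = FALSE)
  }
  r <- rise_rate; d <- decay_rate
  A <- cv_max - cv0
  t_peak <- log(1 + r / d) / r  # minutes
  curve <- function(t_min) {
    cv0 + A * (1 - exp(-r * t_min)) * exp(-d * pmax(0, t_min - t_peak))
  }
  cv_peak <- curve(t_peak)
  L <- cv0 + (cv_peak - cv0) / 2
  tc_min <- uniroot(function(t) curve(t) - L, c(0, t_peak),
                    tol = 1e-10)$root
  upper <- t_peak + 1 / d
  while (curve(upper) > L) upper <- upper * 2
  td_cross <- uniroot(function(t) curve(t) - L, c(t_peak, upper),
                      tol = 1e-10)$root

  times <- seq(0, duration * 60, by = frame_interval)
  cv <- curve(times / 60)
  if (noise_sd > 0) {
    set.seed(seed)
    cv <- cv + rnorm(length(times), 0, noise_sd)
  }
  structure(list(times = times, cv = cv, activation_index = 1L,
                 tc_true = tc_min * 60, td_true = td_cross * 60,
                 td_true_from_peak = (td_cross - t_peak) * 60,
                 t_peak = t_peak * 60),
            class = "kinetic_trace")
}

#' Generate a synthetic nuclear cluster image
#'
#' A circular binary mask with uniform background intensity plus Gaussian
#' peaks at uniform positions inside the mask; zero outside. Pixel data for
#' the CV clustering statistic.
#'
#' @param nucleus_radius_px mask radius in pixels.
#' @param n_clusters number of Gaussian peaks.
#' @param cluster_amplitude peak amplitude above background.
#' @param cluster_sigma_px peak standard deviation in pixels.
#' @param background intensity inside the mask (> 0).
#' @param seed RNG seed for peak positions.
#' @return list with `image` and `mask` matrices (side `2*radius + 1`).
#' @export
generate_cluster_image <- function(nucleus_radius_px = 32L, n_clusters = 10L,
                                   cluster_amplitude = 5, cluster_sigma_px = 2,
                                   background = 1, seed = 1L) {
  R <- check_count(nucleus_radius_px, "nucleus_radius_px")
  check_count(n_clusters, "n_clusters", min = 0L)
  check_pos(cluster_amplitude, "cluster_amplitude", strict = FALSE)
  check_pos(cluster_sigma_px, "cluster_sigma_px")
  check_pos(background, "background")
  side <- 2L * R + 1L
  xs <- seq_len(side) - (R + 1L)
  xg <- matrix(xs, side, side)
  yg <- t(xg)
  mask <- (xg^2 + yg^2) <= R^2
  img <- matrix(0, side, side)
  img[mask] <- background
  if (n_clusters > 0 && cluster_amplitude > 0) {
    set.seed(seed)
    placed <- 0L
    while (placed < n_clusters) {
      px <- runif(1, -R, R); py <- runif(1, -R, R)
      if (px^2 + py^2 > R^2) next
      img <- img + cluster_amplitude *
        exp(-((xg - px)^2 + (yg - py)^2) / (2 * cluster_sigma_px^2))
      placed <- placed + 1L
    }
    img[!mask] <- 0
  }
  list(image = img, mask = mask * 1)
}

#' Cyclically translate an image to make a registration fixture
#'
#' @param image numeric matrix.
#' @param shift_px integer `c(dx, dy)`: dx shifts along columns (x), dy
#'   along rows (y); positive values move content toward larger indices,
#'   wrapping around.
#' @return list with the original `image` and the `shifted` copy;
#'   [phase_correlation()] on the pair recovers `shift_px`.
#' @export
generate_image_pair <- function(image, shift_px) {
  stopifnot(is.matrix(image), length(shift_px) == 2L,
            shift_px == round(shift_px))
  nr <- nrow(image); nc <- ncol(image)
  dy <- as.integer(shift_px[2]) %% nr
  dx <- as.integer(shift_px[1]) %% nc
  rows <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
  cols <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
  list(image = image, shifted = image[rows, cols, drop = FALSE])
}
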