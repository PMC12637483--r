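#' Coefficient of variation of masked nuclear intensity
#'
#' The clustering statistic: standard deviation of the intensities inside
#' the nuclear mask divided by their mean. The population (divide-by-N)
#' standard deviation is used throughout so per-cell values are internally
#' consistent; as a ratio the CV is invariant to intensity scaling.
#'
#' @param image numeric matrix of pixel intensities.
#' @param mask matrix of the same dimensions; pixels with `mask > 0` belong
#'   to the nucleus.
#' @param nucleus_id optional label used in error messages.
#' @return the CV, a non-negative scalar.
#' @export
#' @examples
#' img <- matrix(c(1, 1, 1, 3), 2)
#' compute_cv(img, matrix(1, 2, 2))  # 0.5774
compute_cv <- function(image, mask, nucleus_id = "nucleus") {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  px <- image[mask > 0]
  if (!length(px)) {
    stop(sprintf("empty mask for %s", nucleus_id), call. = FALSE)
  }
  m <- mean(px)
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("non-positive mean intensity for %s", nucleus_id),
         call. = FALSE)
  }
  sqrt(mean((px - m)^2)) / m
}

#' Kinetic trace constructor
#'
#' @param times times in seconds from light activation; strictly increasing.
#' @param cv non-negative CV value per frame.
#' @param activation_index frame index of t = 0 (default: first frame).
#' @return object of class `"kinetic_trace"`.
#' @export
kinetic_trace <- function(times, cv, activation_index = 1L) {
  stopifnot(length(times) == length(cv), all(diff(times) > 0),
            all(cv >= 0), activation_index >= 1,
            activation_index <= length(times))
  structure(list(times = as.numeric(times), cv = as.numeric(cv),
                 activation_index = as.integer(activation_index)),
            class = "kinetic_trace")
}

#' Normalize a kinetic trace to its value at activation
#'
#' Divides every CV by the CV at the activation frame, so the trace equals
#' exactly 1 at t = 0. Relative normalization preserves the location of the
#' maximum and of all half-maximal crossings.
#'
#' @param trace a [kinetic_trace()].
#' @return a `kinetic_trace` with normalized CV values.
#' @export
relative_cv_series <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  cv0 <- trace$cv[trace$activation_index]
  if (!is.finite(cv0) || cv0 <= 0) {
    stop("CV at the activation frame must be > 0", call. = FALSE)
  }
  out <- trace
  out$cv <- trace$cv / cv0
  out
}

# Earliest interpolated crossing of level L on frames idx (ascending) of the
# piecewise-linear series; direction +1 = upward, -1 = downward. NA if none.
first_crossing <- function(times, cv, idx, L, direction = 1) {
  if (length(idx) < 2L) return(NA_real_)
  for (j in seq_along(idx)[-1L]) {
    i0 <- idx[j - 1L]; i1 <- idx[j]
    y0 <- cv[i0]; y1 <- cv[i1]
    hit <- if (direction > 0) y0 < L && y1 >= L else y0 > L && y1 <= L
    if (hit) {
      return(times[i0] + (L - y0) / (y1 - y0) * (times[i1] - times[i0]))
    }
    # node exactly at L counts as a crossing at that frame
    if ((direction > 0 && y0 >= L) || (direction < 0 && y0 <= L)) {
      return(times[i0])
    }
  }
  last <- idx[length(idx)]
  if ((direction > 0 && cv[last] >= L) || (direction < 0 && cv[last] <= L)) {
    return(times[last])
  }
  NA_real_
}

#' Half-maximal clustering time
#'
#' Time (seconds from activation) at which the CV series first reaches the
#' half-maximal level \eqn{L = CV(0) + (\max CV - CV(0))/2}, found by linear
#' interpolation of the raw series; `NA` when the series never rises above
#' its activation value. Crossings are detected without smoothing; pass
#' `smooth_window > 1` to pre-average noisy traces.
#'
#' @param trace a [kinetic_trace()] with at least 3 frames at/after
#'   activation.
#' @param smooth_window odd moving-average window (1 = off).
#' @return time in seconds, or `NA_real_` when undefined.
#' @export
estimate_tc <- function(trace, smooth_window = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  act <- trace$activation_index
  idx <- seq(act, length(trace$cv))
  if (length(idx) < 3L) {
    stop("trace needs >= 3 frames at/after activation", call. = FALSE)
  }
  cv <- smooth_cv(trace$cv, smooth_window)
  cv0 <- cv[act]
  cvmax <- max(cv[idx])
  if (cvmax <= cv0) return(NA_real_)
  L <- cv0 + (cvmax - cv0) / 2
  t <- first_crossing(trace$times, cv, idx, L, direction = 1)
  t - trace$times[act]
}

#' Half-maximal declustering time
#'
#' Time for the CV series to fall back to the half-maximal level during
#' reversion. The level L is as in [estimate_tc()]; the crossing is the
#' earliest interpolated time after the (first) maximum at which the series
#' returns to L. By default the time is measured from activation (t = 0);
#' `from = "peak"` measures from the first frame attaining the maximum CV
#' instead. The activation reference is the default because the location of
#' the sampled maximum is only known to within one frame on asymmetric
#' rise/decay curves, which makes a peak-referenced time intrinsically
#' coarser than the crossing itself.
#'
#' @inheritParams estimate_tc
#' @param from reference point for the returned time.
#' @return time in seconds (units of the trace's time axis), or `NA_real_`
#'   when the series never declines back to L.
#' @export
estimate_td <- function(trace, from = c("activation", "peak"),
                        smooth_window = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  from <- match.arg(from)
  act <- trace$activation_index
  idx <- seq(act, length(trace$cv))
  if (length(idx) < 3L) {
    stop("trace needs >= 3 frames at/after activation", call. = FALSE)
  }
  cv <- smooth_cv(trace$cv, smooth_window)
  cv0 <- cv[act]
  cvmax <- max(cv[idx])
  if (cvmax <= cv0) return(NA_real_)
  L <- cv0 + (cvmax - cv0) / 2
  i_max <- idx[which.max(cv[idx])]  # first frame attaining the maximum
  post <- seq(i_max, length(cv))
  if (length(post) < 2L) return(NA_real_)
  t <- first_crossing(trace$times, cv, post, L, direction = -1)
  if (is.na(t)) return(NA_real_)
  ref <- if (from == "peak") trace$times[i_max] else trace$times[act]
  t - ref
}

smooth_cv <- function(cv, window) {
  window <- as.integer(window)
  if (window <= 1L) return(cv)
  if (window %% 2L == 0L) stop("`smooth_window` must be odd", call. = FALSE)
  sm <- as.numeric(stats::filter(cv, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- cv[is.na(sm)]  # edges keep the raw values
  sm
}

#' Logistic fit of clustering versus expression level
#'
#' Per variant, fits the 3-parameter logistic
#' \deqn{CV(I) = CV_{max} / (1 + e^{-k (\log I - \log I_0)})}
#' to per-cell (CV, nuclear intensity) measurements by least squares,
#' describing how clustering saturates with fusion-protein concentration.
#'
#' @param measurements data.frame with columns `cv`, `mean_intensity` and
#'   `variant` (a label); at least 8 points per variant.
#' @return data.frame with one row per variant: `variant`, `cv_max`, `k`,
#'   `log_i0`, `rss`, `n`, `converged`. Non-convergence is reported per
#'   variant without affecting the others; a variant with (near-)constant CV
#'   gets `cv_max` equal to that constant and `k = NA`, flagged
#'   `converged = FALSE`.
#' @export
fit_cv_expression <- function(measurements) {
  check_cols(measurements, c("cv", "mean_intensity", "variant"),
             "measurements")
  stopifnot(all(measurements$mean_intensity > 0), all(measurements$cv >= 0))
  out <- lapply(split(measurements, measurements$variant), function(df) {
    if (nrow(df) < 8L) {
      stop(sprintf("variant '%s' has %d points; >= 8 required",
                   df$variant[1], nrow(df)), call. = FALSE)
    }
    li <- log(df$mean_intensity)
    res <- data.frame(variant = df$variant[1], cv_max = NA_real_,
                      k = NA_real_, log_i0 = NA_real_, rss = NA_real_,
                      n = nrow(df), converged = FALSE,
                      stringsAsFactors = FALSE)
    if (sd(df$cv) < 1e-12 * max(mean(df$cv), 1)) {
      res$cv_max <- mean(df$cv)
      res$rss <- sum((df$cv - mean(df$cv))^2)
      return(res)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        cv ~ cv_max / (1 + exp(-k * (li - log_i0))),
        data = data.frame(cv = df$cv, li = li),
        start = list(cv_max = max(df$cv), k = 1, log_i0 = median(li)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(res)
    cf <- coef(fit)
    res$cv_max <- cf[["cv_max"]]; res$k <- cf[["k"]]
    res$log_i0 <- cf[["log_i0"]]
    res$rss <- sum(stats::residuals(fit)^2)
    res$converged <- TRUE
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
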