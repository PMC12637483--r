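# Internal validation helpers. Error messages name the offending field so
# config mistakes are directly actionable.

check_prob <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", field),
         call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- length(x) == 1L && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single finite %s number", field,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", field, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Significance asterisks: * p<0.05, ** p<0.01, *** p<0.001.
#' Significance asterisks for p-values
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `"ns"` otherwise (`NA` stays `NA`).
#' @export
#' @examples
#' p_stars(c(0.2, 0.04, 0.004, 0.0004))
p_stars <- function(p) {
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}
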