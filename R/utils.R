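# shared helpers: validation errors, display rounding, seeded substreams

abort_invalid <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s: %s", field, msg)
  stop(rlang::error_cnd(class = c("saltcost_invalid", "saltcost_error"),
                        message = msg, call = NULL))
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_na = FALSE) {
  if (length(x) != 1 || !is.numeric(x)) {
    abort_invalid("must be a single number", field)
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    abort_invalid("must not be NA", field)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_invalid(sprintf("must be in %s%s, %s%s (got %g)",
                          if (strict_lower) "(" else "[", lower,
                          upper, if (strict_upper) ")" else "]", x),
                  field)
  }
  invisible(x)
}

check_columns <- function(df, cols, field) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_invalid(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
                  field)
  }
  invisible(df)
}

#' Round half away from zero
#'
#' Display rounding used throughout the reporting layer: ties round away from
#' zero (2.5 -> 3, -2.5 -> -3), unlike base [round()]'s round-half-even.
#' National cost tables in this field print integer thousands and integer
#' percentage shares under this convention.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 14.53))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# integer percentage shares of a positive vector, at full precision until the
# final rounding step
integer_share <- function(x, total = sum(x)) {
  if (total == 0) return(rep(0, length(x)))
  round_half_away(100 * x / total)
}

# scale raw currency to printed "thousand USD" units
render_thousands <- function(x) round_half_away(x / 1000)

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-cell substream seed: one global seed plus a string tag
# (e.g. "rr/CHD/male/45-49") hashed into a 31-bit integer.  Adding a new
# tagged stream never perturbs existing ones.
substream_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 97 + 1) %% 2147483646 + 1)
}
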