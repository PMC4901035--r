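# Shared validation helpers and numeric conventions.

#' Round half away from zero
#'
#' Printed summary tables in the rumen-fermentation literature round
#' half-up (5 always rounds away from zero), unlike [base::round()]'s
#' round-half-even. Used wherever computed quantities are compared with
#' printed table cells.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.1635, 3) # 0.164
#' round(0.1635, 3)         # 0.163 (banker's)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_rusitecr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rusitecr_error")))
}

check_nonnegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_rusitecr(sprintf("`%s` must be finite and >= 0", what),
                  "rusitecr_validation_error")
  }
  invisible(x)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_rusitecr(sprintf("`%s` must be finite and > 0", what),
                  "rusitecr_undefined_result")
  }
  invisible(x)
}

check_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_rusitecr(sprintf("`%s` must lie in [0, 1]", what),
                  "rusitecr_validation_error")
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. A NULL seed uses (and advances) the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
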