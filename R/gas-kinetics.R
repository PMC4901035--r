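# Gas-production kinetics and the 14C bacterial-release assay.

#' Construct a pressure series for one bottle
#'
#' Ordered headspace pressure-excess readings from a semi-automated
#' transducer. Each reading is taken just before venting, so successive
#' readings are incremental gas accumulations by default.
#'
#' @param sample_id bottle identifier.
#' @param time_h sampling times, h; strictly increasing, >= 0.
#' @param pressure_kpa pressure excess over ambient at each time, kPa.
#' @param headspace_ml bottle headspace volume, mL (default 70: 120-mL
#'   bottles holding 50 mL of medium).
#' @param ambient_kpa ambient pressure, kPa (default 101.325).
#' @return object of class `pressure_series`.
#' @export
pressure_series <- function(sample_id, time_h, pressure_kpa,
                            headspace_ml = 70, ambient_kpa = 101.325) {
  if (length(time_h) != length(pressure_kpa)) {
    stop_rusitecr("time and pressure vectors differ in length",
                  "rusitecr_validation_error")
  }
  if (any(time_h < 0) || any(diff(time_h) <= 0)) {
    stop_rusitecr("times must be >= 0 and strictly increasing",
                  "rusitecr_validation_error")
  }
  check_positive(headspace_ml, "headspace_ml")
  check_positive(ambient_kpa, "ambient_kpa")
  structure(list(sample_id = sample_id, time_h = time_h,
                 pressure_kpa = pressure_kpa,
                 headspace_ml = headspace_ml, ambient_kpa = ambient_kpa),
            class = "pressure_series")
}

#' Convert transducer pressures to a cumulative gas volume curve
#'
#' Ideal-gas conversion at fixed incubation temperature: each reading's
#' volume is `headspace * pressure_excess / ambient`. With venting
#' (default) readings are incremental and are cumulated; without
#' venting each reading already reflects total accumulated gas.
#'
#' @param series a [pressure_series()].
#' @param vented logical; `TRUE` (default) treats each reading as a
#'   vented increment.
#' @return data.frame of class `gas_curve`: `sample_id`, `time_h`,
#'   `volume_ml` (cumulative).
#' @export
pressure_to_volume <- function(series, vented = TRUE) {
  stopifnot(inherits(series, "pressure_series"))
  v <- series$headspace_ml * series$pressure_kpa / series$ambient_kpa
  if (vented) v <- cumsum(v)
  out <- data.frame(sample_id = series$sample_id,
                    time_h = series$time_h, volume_ml = v,
                    stringsAsFactors = FALSE)
  class(out) <- c("gas_curve", "data.frame")
  out
}

#' Blank-correct a gas curve
#'
#' Subtracts the time-point-wise mean of blank-bottle curves (rumen
#' fluid without feed) from a sample curve. All curves must share the
#' sample's time grid.
#'
#' @param sample a `gas_curve` (see [pressure_to_volume()]).
#' @param blanks list of `gas_curve`s from blank bottles; may be empty.
#' @param floor_zero clip negative corrected volumes to 0 (default
#'   FALSE, keeping noise visible).
#' @return corrected `gas_curve`.
#' @export
blank_correct <- function(sample, blanks, floor_zero = FALSE) {
  if (length(blanks) == 0) return(sample)
  for (b in blanks) {
    if (length(b$time_h) != length(sample$time_h) ||
        any(b$time_h != sample$time_h)) {
      stop_rusitecr("blank curves must share the sample's time grid",
                    "rusitecr_validation_error")
    }
  }
  bg <- rowMeans(vapply(blanks, function(b) b$volume_ml,
                        numeric(length(sample$time_h))))
  sample$volume_ml <- sample$volume_ml - bg
  if (floor_zero) sample$volume_ml <- pmax(sample$volume_ml, 0)
  sample
}

# Starting values for the exponential fit: A0 slightly above the
# largest observation, c0 from a log-linear regression of the residual
# pool log(1 - Y/(1.05 A0)) on time.
france_start <- function(time_h, volume_ml) {
  a0 <- 1.05 * max(volume_ml)
  frac <- 1 - volume_ml / a0
  ok <- frac > 0 & volume_ml > 0
  c0 <- if (sum(ok) >= 2) {
    max(1e-4, -coef(lm(log(frac[ok]) ~ 0 + time_h[ok]))[[1]])
  } else 0.05
  c(A = a0 / 1.05, c = c0)
}

#' Fit the single-pool exponential (France) gas-production model
#'
#' Least-squares fit of Y = A (1 - exp(-c t)) to a cumulative gas
#' curve: `A` is the asymptotic gas pool (mL) and `c` the fractional
#' production rate (1/h). Levenberg-Marquardt with analytic start
#' values; if not converged, a multi-start sweep over a coarse (A, c)
#' grid is tried before flagging failure. `initial_rate_ml_h` = A*c is
#' also reported, the model's gas-production rate at t = 0.
#'
#' @param time_h,volume_ml the curve; at least 3 distinct times with
#'   positive volume.
#' @return list of class `france_fit`: `A`, `c`, `rss`,
#'   `initial_rate_ml_h`, `converged`, `fitted` (function of time).
#' @export
#' @examples
#' t <- c(2, 4, 6, 9, 12, 24, 48, 72, 96)
#' y <- 116 * (1 - exp(-0.065 * t))
#' fit_france(t, y)[c("A", "c")]
fit_france <- function(time_h, volume_ml) {
  if (inherits(time_h, "gas_curve")) {
    volume_ml <- time_h$volume_ml
    time_h <- time_h$time_h
  }
  keep <- is.finite(time_h) & is.finite(volume_ml)
  time_h <- time_h[keep]; volume_ml <- volume_ml[keep]
  if (all(volume_ml <= 0)) {
    stop_rusitecr("all volumes are <= 0; gas curve is degenerate",
                  "rusitecr_degenerate_fit")
  }
  if (length(unique(time_h[volume_ml > 0])) < 3) {
    stop_rusitecr("need >= 3 distinct time points with positive volume",
                  "rusitecr_validation_error")
  }
  dat <- data.frame(t = time_h, y = volume_ml)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-c * t)), data = dat,
                        start = as.list(start),
                        lower = c(A = 1e-8, c = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(france_start(time_h, volume_ml))
  if (is.null(fit)) {
    grid <- expand.grid(A = max(volume_ml) * c(1, 1.2, 2),
                        c = c(0.01, 0.05, 0.1, 0.2))
    for (i in seq_len(nrow(grid))) {
      fit <- try_fit(c(A = grid$A[i], c = grid$c[i]))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, c = NA_real_, rss = NA_real_,
                          initial_rate_ml_h = NA_real_, converged = FALSE,
                          fitted = NULL),
                     class = "france_fit"))
  }
  est <- coef(fit)
  structure(list(
    A = unname(est["A"]), c = unname(est["c"]),
    rss = sum(resid(fit)^2),
    initial_rate_ml_h = unname(est["A"] * est["c"]),
    converged = TRUE,
    fitted = function(t) unname(est["A"]) * (1 - exp(-unname(est["c"]) * t))
  ), class = "france_fit")
}

#' @export
print.france_fit <- function(x, ...) {
  cat(sprintf("<france_fit A=%.2f mL  c=%.4f /h  A*c=%.2f mL/h  rss=%.3g%s>\n",
              x$A, x$c, x$initial_rate_ml_h, x$rss,
              if (x$converged) "" else "  NOT CONVERGED"))
  invisible(x)
}

#' Bacterial-degradation rate from a 14C release series
#'
#' Protozoal activity assay: percent of the 14C-labelled bacterial
#' inoculum released to the supernatant is regressed on incubation time
#' (0-4 h); the OLS slope is the bacterial degradation rate in %/h.
#'
#' @param time_h sampling times, h.
#' @param released_pct percent of label released at each time.
#' @return list: `slope` (%/h), `intercept`, `r_squared`.
#' @export
release_rate <- function(time_h, released_pct) {
  if (length(unique(time_h)) < 2) {
    stop_rusitecr("need >= 2 distinct time points for a regression",
                  "rusitecr_validation_error")
  }
  fit <- lm(released_pct ~ time_h)
  tss <- sum((released_pct - mean(released_pct))^2)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = if (tss > 0) 1 - sum(resid(fit)^2) / tss else NA_real_)
}
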