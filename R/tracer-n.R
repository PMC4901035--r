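# 15N tracer partitioning of nitrogen flows.
#
# The ammonia pool is labelled with (15NH4)2SO4 so that microbial N
# synthesised from ammonia becomes enriched. At steady state two
# enrichment ratios partition the non-ammonia N (NAN) outflow:
#
#   microbial N / NAN        = E(digesta NAN) / E(bacterial pellet)
#   microbial N from NH3 (%) = 100 * E(bacterial pellet) / E(ammonia)
#
# Both are ratios of atom % excess over a common background, so the
# absolute calibration cancels.

#' Construct a set of 15N enrichments
#'
#' Atom % excess above one shared background for the three measured
#' pools. Bacterial enrichment above the ammonia-pool enrichment is
#' physically unexpected (bacteria draw on labelled ammonia plus
#' unlabelled preformed N) and triggers a warning, not an error.
#'
#' @param digesta_nan_enrichment enrichment of the digesta non-ammonia
#'   N pool.
#' @param bacterial_enrichment enrichment of the isolated total-bacteria
#'   pellet.
#' @param ammonia_enrichment enrichment of the ammonia-N pool.
#' @return object of class `enrichment_15n`.
#' @export
enrichment_15n <- function(digesta_nan_enrichment, bacterial_enrichment,
                           ammonia_enrichment) {
  e <- c(digesta_nan_enrichment, bacterial_enrichment, ammonia_enrichment)
  check_nonnegative(e, "enrichments")
  if (bacterial_enrichment > ammonia_enrichment) {
    warning("bacterial enrichment exceeds ammonia enrichment; ",
            "check the shared background", call. = FALSE)
  }
  structure(list(digesta_nan = digesta_nan_enrichment,
                 bacterial = bacterial_enrichment,
                 ammonia = ammonia_enrichment),
            class = "enrichment_15n")
}

#' Microbial fraction of the NAN outflow
#'
#' E(digesta NAN) : E(bacteria), clipped to \[0, 1\] with a warning if
#' outside (a fraction above 1 indicates enrichment measurement error).
#'
#' @param e an [enrichment_15n()].
#' @return fraction of NAN that is microbial, 0-1.
#' @export
microbial_fraction <- function(e) {
  check_positive(e$bacterial, "bacterial enrichment")
  f <- e$digesta_nan / e$bacterial
  if (f > 1 || f < 0) {
    warning(sprintf("microbial fraction %.3f outside [0, 1]; clipped", f),
            call. = FALSE)
    f <- min(max(f, 0), 1)
  }
  f
}

#' Percent of microbial N synthesised from ammonia
#'
#' 100 * E(bacteria) : E(ammonia).
#'
#' @param e an [enrichment_15n()].
#' @return %, the ammonia-derived share of microbial N.
#' @export
microbial_n_from_ammonia <- function(e) {
  check_positive(e$ammonia, "ammonia enrichment")
  100 * e$bacterial / e$ammonia
}

#' Daily nitrogen intake of a mixed forage:concentrate diet
#'
#' dm_intake (g/d) times the intake-weighted N content (%), times 10 to
#' express the result in mg/d.
#'
#' @param dm_intake g DM/d.
#' @param forage_n_pct,concentrate_n_pct N contents, % of DM.
#' @param forage_fraction forage share of DM intake (default 0.8).
#' @return N intake, mg/d.
#' @export
#' @examples
#' n_intake(11.25, 1.83, 2.51) # grass diet, 221.2 mg/d
n_intake <- function(dm_intake, forage_n_pct, concentrate_n_pct,
                     forage_fraction = 0.8) {
  check_nonnegative(dm_intake, "dm_intake")
  check_fraction(forage_fraction, "forage_fraction")
  dm_intake * (forage_fraction * forage_n_pct +
                 (1 - forage_fraction) * concentrate_n_pct) * 10
}

#' Apparent and true rumen N degradability
#'
#' Apparent degradability charges the whole NAN outflow against intake,
#' 100 (intake - NAN) / intake; true degradability removes only the
#' feed by-pass fraction (NANM-N = NAN - microbial N), 100 (intake -
#' NANM-N) / intake, crediting microbial N as degraded-then-resynthesised.
#' An alternative apparent form that also subtracts the ammonia outflow
#' is reported for comparison (`apparent_with_ammonia`).
#'
#' @param n_intake mg/d, e.g. from [n_intake()].
#' @param nan_outflow non-ammonia N outflow, mg/d.
#' @param nanm_n non-ammonia non-microbial N outflow, mg/d.
#' @param ammonia_outflow optional ammonia-N outflow, mg/d, used only
#'   for the alternative apparent form.
#' @return list: `apparent`, `true`, `apparent_with_ammonia` (NA when
#'   no ammonia outflow is given), all %.
#' @export
degradabilities <- function(n_intake, nan_outflow, nanm_n,
                            ammonia_outflow = NULL) {
  check_positive(n_intake, "n_intake")
  check_nonnegative(c(nan_outflow, nanm_n), "N outflows")
  list(
    apparent = 100 * (n_intake - nan_outflow) / n_intake,
    true = 100 * (n_intake - nanm_n) / n_intake,
    apparent_with_ammonia = if (is.null(ammonia_outflow)) NA_real_ else
      100 * (n_intake - nan_outflow - ammonia_outflow) / n_intake
  )
}

#' Efficiencies of microbial protein synthesis
#'
#' The four efficiency-of-synthesis ratios: microbial N per unit NAN
#' outflow, per unit N intake, per unit truly degraded N (intake -
#' NANM-N), and per g of degraded OM (EMPS, mg/g).
#'
#' @param microbial_n mg/d.
#' @param nan_outflow mg/d.
#' @param n_intake mg/d.
#' @param nanm_n mg/d.
#' @param degraded_om g/d.
#' @return list: `eff_nan`, `eff_intake`, `eff_true_deg` (all g/g),
#'   `emps` (mg microbial N / g degraded OM).
#' @export
synthesis_efficiencies <- function(microbial_n, nan_outflow, n_intake,
                                   nanm_n, degraded_om) {
  check_nonnegative(microbial_n, "microbial_n")
  check_positive(nan_outflow, "nan_outflow")
  check_positive(n_intake, "n_intake")
  truly_deg <- n_intake - nanm_n
  check_positive(truly_deg, "truly degraded N")
  check_positive(degraded_om, "degraded_om")
  list(eff_nan = microbial_n / nan_outflow,
       eff_intake = microbial_n / n_intake,
       eff_true_deg = microbial_n / truly_deg,
       emps = microbial_n / degraded_om)
}

#' Full nitrogen budget for one vessel
#'
#' Combines the tracer partitioning with the flow bookkeeping:
#' microbial N = microbial fraction x NAN outflow; NANM-N = NAN -
#' microbial N (clipped at 0 with a warning when the enrichment ratio
#' exceeds 1); degradabilities and the four synthesis efficiencies.
#'
#' @param nan_outflow,ammonia_outflow mg/d.
#' @param enrichment an [enrichment_15n()].
#' @param n_intake mg/d, from [n_intake()].
#' @param degraded_om g/d, from [degraded_om()].
#' @return one-row data.frame with columns `n_intake`, `microbial_n`,
#'   `nanm_n`, `apparent_deg`, `true_deg`, `microbial_from_ammonia`,
#'   `eff_nan`, `eff_intake`, `eff_true_deg`, `emps`.
#' @export
nitrogen_budget <- function(nan_outflow, ammonia_outflow, enrichment,
                            n_intake, degraded_om) {
  check_nonnegative(c(nan_outflow, ammonia_outflow), "N outflows")
  frac <- microbial_fraction(enrichment)
  microbial_n <- frac * nan_outflow
  nanm_n <- max(nan_outflow - microbial_n, 0)
  deg <- degradabilities(n_intake, nan_outflow, nanm_n, ammonia_outflow)
  eff <- synthesis_efficiencies(microbial_n, nan_outflow, n_intake,
                                nanm_n, degraded_om)
  data.frame(n_intake = n_intake,
             microbial_n = microbial_n,
             nanm_n = nanm_n,
             apparent_deg = deg$apparent,
             true_deg = deg$true,
             microbial_from_ammonia = microbial_n_from_ammonia(enrichment),
             eff_nan = eff$eff_nan,
             eff_intake = eff$eff_intake,
             eff_true_deg = eff$eff_true_deg,
             emps = eff$emps)
}
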