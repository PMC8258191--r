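#' Summarize control weighings
#'
#' Distilled-water control boats carry the same container residue as the
#' plankton boats; their weight gain estimates the additive measurement
#' error of the drying/weighing procedure. This summarizes the control
#' gains (mean, sd), tests the mean against zero with a one-sample t test,
#' and derives the reliability threshold as `multiplier` standard
#' deviations of the controls.
#'
#' @param gains numeric vector of control weight gains (mg), length >= 2.
#' @param multiplier threshold multiplier on the control sd (default 4).
#' @return An object of class `"control_summary"`: list with `n`,
#'   `mean_error`, `sd_error`, `threshold`, `t_stat`, `df`, `p_value`.
#'   With zero spread the t statistic is undefined and flagged `NA`.
#' @examples
#' cs <- summarize_controls(rnorm(72, 0.016, 0.011))
#' cs$threshold
#' @export
summarize_controls <- function(gains, multiplier = 4) {
  if (!is.numeric(gains) || length(gains) < 2)
    stop("at least two control gains are required")
  m  <- mean(gains)
  s  <- stats::sd(gains)
  if (s > 0) {
    tt <- stats::t.test(gains, mu = 0)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    warning("control gains have zero spread; t statistic undefined")
    t_stat <- NA_real_; p <- NA_real_
  }
  structure(list(n = length(gains), mean_error = m, sd_error = s,
                 threshold = multiplier * s, multiplier = multiplier,
                 t_stat = t_stat, df = length(gains) - 1L, p_value = p),
            class = "control_summary")
}

#' @export
print.control_summary <- function(x, ...) {
  cat(sprintf("Control weighings: n = %d\n", x$n))
  cat(sprintf("  mean error  %.4f mg, sd %.5f mg\n", x$mean_error, x$sd_error))
  if (is.na(x$t_stat)) cat("  t test: undefined (zero spread)\n")
  else cat(sprintf("  t(%d) = %.3f, p = %.3g\n", x$df, x$t_stat, x$p_value))
  cat(sprintf("  reliability threshold (%g x SD) = %.3f mg\n",
              x$multiplier, x$threshold))
  invisible(x)
}

#' Subtract the measurement error and flag unreliable records
#'
#' Every measured weight gain is corrected by subtracting the mean control
#' error; records whose gain does not exceed the reliability threshold
#' (by default 4 control standard deviations) are flagged unreliable but
#' never deleted.
#'
#' @param raw_gain numeric vector of raw weight gains (mg) of plankton
#'   boats (controls must not be passed here).
#' @param controls a `"control_summary"`, or a list with `mean_error` and
#'   `threshold`.
#' @param reliable_on `"corrected"` (default; threshold compared to the
#'   error-corrected gain) or `"raw"`.
#' @return data frame with `corrected` (mg) and `reliable` (logical).
#' @examples
#' cs <- list(mean_error = 0.016, threshold = 0.043)
#' correct_and_filter(c(0.200, 0.050, 0.016), cs)
#' @export
correct_and_filter <- function(raw_gain, controls, reliable_on = "corrected") {
  if (!is.numeric(raw_gain)) stop("raw_gain must be numeric")
  if (is.null(controls$mean_error) || is.null(controls$threshold))
    stop("'controls' must provide mean_error and threshold")
  corrected <- raw_gain - controls$mean_error
  basis <- switch(match.arg(reliable_on, c("corrected", "raw")),
                  corrected = corrected, raw = raw_gain)
  data.frame(corrected = corrected, reliable = basis > controls$threshold)
}

#' Reverse the formalin preservation mass loss
#'
#' Formaldehyde preservation leaches mass from zooplankton tissue; assuming
#' a fractional loss `loss` (default 40%), the pre-preservation dry weight
#' is `mass / (1 - loss)`. At 40% loss the multiplier is 1/0.6 = 1.6667,
#' conventionally reported as 1.67; the exact value is used internally to
#' avoid compounding rounding.
#'
#' @param mass numeric, measured dry mass (mg).
#' @param loss fractional mass loss in `[0, 1)`.
#' @return corrected mass (mg).
#' @examples
#' formalin_correct(0.6, 0.40)         # 1.0
#' formalin_multiplier(0.40)           # 1.666667, prints as 1.67
#' @export
formalin_correct <- function(mass, loss = 0.40) {
  if (!is.numeric(loss) || loss < 0 || loss >= 1)
    stop("loss fraction must be in [0, 1)")
  mass / (1 - loss)
}

#' @rdname formalin_correct
#' @export
formalin_multiplier <- function(loss = 0.40) {
  if (loss < 0 || loss >= 1) stop("loss fraction must be in [0, 1)")
  1 / (1 - loss)
}

#' Standardize a measured mass to 1 m2 of sea surface
#'
#' A weighed mass represents one Motoda split fraction of the haul, diluted
#' to `dilution_ml` and subsampled with `n_subsamples` pipette aliquots of
#' `pipette_ml` each; the net samples `net_area` of surface. The areal
#' biomass is
#' `mass * split * (dilution / (pipette * n_subsamples)) / net_area`.
#'
#' @param mass corrected mass (mg).
#' @param split Motoda split denominator, one of 4, 8, 16.
#' @param n_subsamples number of 2-ml aliquots pooled (1..100).
#' @param net_area net mouth area (m2).
#' @param dilution_ml,pipette_ml dilution and aliquot volumes (ml).
#' @return areal biomass, mg DW per m2.
#' @examples
#' standardize_to_area(1, split = 8, n_subsamples = 5)  # 640
#' @export
standardize_to_area <- function(mass, split, n_subsamples,
                                net_area = 0.25, dilution_ml = 200,
                                pipette_ml = 2) {
  if (any(!split %in% c(4, 8, 16))) stop("split must be one of 4, 8, 16")
  if (any(n_subsamples < 1 | n_subsamples > dilution_ml / pipette_ml))
    stop("n_subsamples out of range")
  mass * split * (dilution_ml / (pipette_ml * n_subsamples)) / net_area
}

#' Mean individual dry weight
#'
#' The corrected — but **not** areal-standardized — pooled mass divided by
#' the number of individuals that produced it.
#'
#' @param mass corrected mass (mg).
#' @param n number of pooled individuals (>= 1).
#' @return mg per individual.
#' @examples
#' individual_dw(12.496, 4128)  # 0.0030 at 4 d.p.
#' @export
individual_dw <- function(mass, n) {
  if (any(n < 1)) stop("n_individuals must be >= 1")
  mass / n
}

#' Settling carbon as a fraction of benthic carbon demand
#'
#' Expresses a settling carbon flux (mg C per m2) as a percentage of an
#' annual epibenthic carbon demand given in g C per m2 per year.
#'
#' @param settling_carbon mg C per m2.
#' @param demand g C per m2 per year; may be a vector (e.g. a low/high pair).
#' @return percentages, same length as `demand`.
#' @examples
#' carbon_demand_fraction(278.6, c(70, 6))  # c(0.398, 4.643) -> "0.4 to 5%"
#' @export
carbon_demand_fraction <- function(settling_carbon, demand) {
  if (any(demand <= 0)) stop("carbon demand must be positive")
  if (settling_carbon < 0) stop("settling carbon must be nonnegative")
  100 * settling_carbon / (demand * 1000)
}
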