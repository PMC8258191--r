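## Length-weight formula registry and the evaluation framework comparing
## calculated against measured mean individual dry weights per sample.
## Functional forms (logs are base 10 throughout, the convention of the
## allometric literature these formulas come from):
##   power:        DW = a * PL^b
##   log_linear:   log10 DW = a * PL + b
##   log_log:      log10 DW = a * log10 PL + b
##   fixed:        DW = a                       (PL ignored)
##   power_scaled: DW = a * PL^b / s            (e.g. AFDW:DW rescaling)

.mass_to_mg <- c(mg = 1, ug = 1e-3)
.len_from_um <- c(mm = 1e-3, um = 1)

#' Evaluate a length-weight formula
#'
#' Evaluates one registry row at prosome length(s) given in the formula's
#' own length unit and returns dry weight in mg (canonical mass unit).
#'
#' @param formula one row of the formula registry (data frame or list with
#'   `functional_form`, `coef_a`, `coef_b`, `scale_div`, `mass_unit`).
#' @param PL prosome length(s), positive, in the formula's `length_unit`.
#' @return dry weight(s) in mg.
#' @examples
#' reg <- load_reference_tables()$formulas
#' evaluate_formula(reg[reg$method_id == "calanus_i", ], 2.5)   # ~0.230 mg
#' evaluate_formula(reg[reg$method_id == "oithona_i", ], 999)   # 0.003 mg
#' @export
evaluate_formula <- function(formula, PL) {
  if (any(PL <= 0)) stop("PL must be positive")
  a <- formula$coef_a; b <- formula$coef_b
  dw <- switch(formula$functional_form,
    power        = a * PL^b,
    log_linear   = 10^(a * PL + b),
    log_log      = 10^(a * log10(PL) + b),
    fixed        = rep(a, length(PL)),
    power_scaled = a * PL^b / formula$scale_div,
    stop("unknown functional form: ", formula$functional_form))
  unit <- .mass_to_mg[[formula$mass_unit]]
  if (is.null(unit)) stop("unknown mass unit: ", formula$mass_unit)
  dw * unit
}

#' @rdname evaluate_formula
#' @param length_um length(s) in µm (the package's canonical length unit);
#'   converted to the formula's unit internally.
#' @export
dw_from_length_um <- function(formula, length_um) {
  fac <- .len_from_um[[formula$length_unit]]
  if (is.null(fac)) stop("unknown length unit: ", formula$length_unit)
  evaluate_formula(formula, length_um * fac)
}

#' Calculated mean individual dry weight of a sample
#'
#' Evaluates the formula for every measured individual and averages the
#' per-individual dry weights (mean of transformed values, not the
#' transform of the mean length — the two differ for the convex power
#' forms).
#'
#' @param lengths_um individual lengths in µm, at least one.
#' @param formula a formula registry row.
#' @return mean dry weight, mg.
#' @export
sample_calculated_mean <- function(lengths_um, formula) {
  if (length(lengths_um) < 1) stop("at least one length is required")
  mean(dw_from_length_um(formula, lengths_um))
}

band_label <- function(relative_percent, lower = 80, upper = 120) {
  ifelse(relative_percent < lower, "under",
         ifelse(relative_percent > upper, "over", "satisfactory"))
}

#' Compare length-weight methods against measured individual dry weights
#'
#' For every sample holding both length measurements and a measured mean
#' individual dry weight of the target taxon, computes the calculated mean
#' individual DW under each method and expresses it relative to the
#' measured mean (100% = exact agreement). Estimates within ±20% of the
#' measurement (80--120%, boundaries inclusive) are labelled satisfactory.
#'
#' @details The measured mean is the error- and formalin-corrected,
#'   non-standardized pooled mass divided by the number of weighed
#'   individuals. For *Calanus*, nauplii and copepodite records are pooled
#'   per sample (one mean per taxon per sample) unless `split_stages`.
#'
#' @param est a `"zoosurvey_biomass"` object.
#' @param lengths length-measurement table (`sample_id`, `taxon_name`,
#'   `length` in µm), e.g. `survey$lengths`.
#' @param methods formula registry rows to evaluate; defaults to the
#'   packaged registry.
#' @param taxon target taxon of the comparison; methods not targeting it
#'   are dropped.
#' @param split_stages keep *Calanus* stages separate instead of pooling.
#' @param band satisfactory band as percent `c(lower, upper)`.
#' @return data frame of class `"method_comparison"`: one row per
#'   sample x method with `calculated_mean_dw`, `measured_mean_dw`,
#'   `relative_percent`, `band`.
#' @export
compare_methods <- function(est, lengths,
                            methods = load_reference_tables()$formulas,
                            taxon = "Calanus spp.", split_stages = FALSE,
                            band = c(80, 120)) {
  stopifnot(inherits(est, "zoosurvey_biomass"))
  methods <- methods[taxon_key(methods$target_taxon) == taxon_key(taxon), ,
                     drop = FALSE]
  if (nrow(methods) == 0) stop("no methods target taxon ", taxon)

  b <- est$biomass
  b <- b[b$reliable & taxon_key(b$taxon_name) == taxon_key(taxon), , drop = FALSE]
  l <- lengths[taxon_key(lengths$taxon_name) == taxon_key(taxon), , drop = FALSE]
  grp <- function(df) if (split_stages)
    paste(df$sample_id, ifelse(is.na(df$stage_tag), "", df$stage_tag)) else df$sample_id

  mass_by <- tapply(b$corrected_mass, grp(b), sum)
  n_by <- tapply(b$n_individuals, grp(b), sum)
  keys <- names(mass_by)

  out <- list()
  for (key in keys) {
    sample_id <- if (split_stages) sub(" .*$", "", key) else key
    sel <- grp(l) == key
    if (!any(sel)) { warning("no lengths for ", key, "; skipped"); next }
    measured <- mass_by[[key]] / n_by[[key]]
    if (!is.finite(measured) || measured <= 0) { warning("no measured mean for ", key); next }
    for (mi in seq_len(nrow(methods))) {
      m <- methods[mi, ]
      calc <- sample_calculated_mean(l$length[sel], m)
      rel <- 100 * calc / measured
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, method_id = m$method_id,
        calculated_mean_dw = calc, measured_mean_dw = measured,
        relative_percent = rel,
        band = band_label(rel, band[1], band[2]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("method_comparison", class(res))
  res
}

#' Per-event summary of method comparisons
#'
#' Mean and standard deviation of the relative percent across the stations
#' sampled at each event, per method (the station mean is unweighted). The
#' SD is `NA` when an event has a single station.
#'
#' @param comparisons a `"method_comparison"` table; `sample_id` must be
#'   `station_event`.
#' @return data frame keyed by (`event_id`, `method_id`) with `mean_percent`,
#'   `sd_percent`, `n_stations`.
#' @export
event_summary <- function(comparisons) {
  ev <- sub("^[^_]*_", "", comparisons$sample_id)
  key <- paste(ev, comparisons$method_id, sep = "\r")
  agg <- function(f) tapply(comparisons$relative_percent, key, f)
  mu <- agg(mean); s <- agg(stats::sd); n <- agg(length)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  data.frame(event_id = vapply(parts, `[`, "", 1),
             method_id = vapply(parts, `[`, "", 2),
             mean_percent = as.numeric(mu),
             sd_percent = as.numeric(s),
             n_stations = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}
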