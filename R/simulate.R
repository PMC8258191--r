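#' Default synthetic survey scenario
#'
#' A year-round mesozooplankton survey emulating a sub-Arctic shelf:
#' 3 stations (coast/bank/trough) times 8 sampling events between September
#' and the following August, with 17 taxon/stage combinations drawn from
#' the packaged reference table. Seasonal abundance follows a circular
#' Gaussian bump per taxon around its peak day of year on top of a winter
#' floor. The scenario encodes the qualitative structure the analysis
#' expects: a *Calanus* copepodite stock dominating annual biomass, a
#' pteropod (*Limacina retroversa*) autumn peak, cirripede nauplii peaking
#' in April--May whose median length grows from 392 to 703 µm, amphinomid
#' larvae present only around the July event, and winter-active *Metridia
#' longa* near the coast.
#'
#' @details The observation model reproduces the sampling chain: Poisson
#'   counts per taxon (areal abundance times the 0.25-m2 net mouth),
#'   logistic length-dependent capture efficiency emulating 200-µm-mesh
#'   under-catch of small individuals, log-normal lengths, power-law
#'   length-to-fresh-dry-weight truth per taxon, 40% formalin mass loss,
#'   a density-dependent Motoda split (haul >= 8000 individuals -> 1/16,
#'   >= 4000 -> 1/8, else 1/4), dilution to 200 ml, pooling of 2-ml pipette
#'   aliquots, and additive weighing error Normal(0.016, 0.01075) mg.
#'
#' @return An object of class `"zoo_scenario"`: list with `stations`,
#'   `events`, `taxa` (per-taxon abundance/length/allometry parameters) and
#'   `obs` (observation-model constants).
#' @examples
#' sc <- default_scenario()
#' names(sc$taxa)
#' @export
default_scenario <- function() {
  ref <- load_reference_tables()
  taxa <- utils::read.csv(text = "taxon_name|stage_tag|abund_C|abund_B|abund_T|peak_doy|width|floor|len_med|len_sd|len_med_late|ramp_start|ramp_end|allo_a|allo_b
Calanus spp.|copepodites|2000|5000|20000|150|60|0.15|2400|0.18|NA|NA|NA|0.006458|3.9
Calanus spp.|nauplii|4000|8000|6000|121|30|0.02|500|0.08|NA|NA|NA|0.024|3
Oithona spp.|NA|3000|3000|3000|200|90|0.4|520|0.10|NA|NA|NA|0.0289|3.643
Limacina retroversa|NA|12000|8000|3000|296|35|0.01|800|0.25|NA|NA|NA|0.02|3
Cirripedia|NA|4000|3000|1200|105|25|0.005|392|0.18|703|91|121|0.06|3.2
Copepoda nauplii|NA|12000|30000|20000|121|35|0.02|500|0.09|NA|NA|NA|0.024|3
Clausocalanidae|NA|3000|4000|4000|170|70|0.25|900|0.12|NA|NA|NA|0.0085|3.2
Amphinomidae|NA|30000|20000|5000|203|5|0|950|0.15|NA|NA|NA|0.02|3
Fritillaria borealis|NA|2000|1500|1000|100|60|0.1|300|0.15|NA|NA|NA|0.004|2.8
Bivalvia|NA|3000|2500|1000|180|50|0.02|328|0.12|NA|NA|NA|0.005|2.5
Gastropoda|NA|2500|2000|800|190|55|0.02|350|0.20|NA|NA|NA|0.006|2.5
Bryozoa|NA|1500|1200|500|160|60|0.05|400|0.15|NA|NA|NA|0.004|2.5
Metridia longa|NA|2000|1200|3000|20|70|0.3|1800|0.15|NA|NA|NA|0.0055|3.5
Temora longicornis|NA|3000|2000|800|253|12|0|700|0.12|NA|NA|NA|0.008|3
Centropages typicus|NA|2500|2000|700|253|12|0|900|0.12|NA|NA|NA|0.007|3
Cod larvae|NA|100|150|120|121|20|0|4500|0.10|NA|NA|NA|0.02|3
Fish eggs|NA|300|400|300|105|18|0|1300|0.05|NA|NA|NA|0.05|3",
    sep = "|", stringsAsFactors = FALSE)

  structure(list(
    stations = ref$stations,
    events = ref$events,
    taxa = taxa,
    obs = list(
      formalin_loss = 0.40,
      error_mean = 0.016, error_sd = 0.01075,
      net_area = 0.25, dilution_ml = 200, pipette_ml = 2,
      split_thresholds = c(16, 8000, 8, 4000, 4, 0),
      target_count = 50, max_lengths = 100,
      capture = list(enabled = TRUE, l50 = 550, scale = 60),
      overdispersion = NA_real_
    )),
    class = "zoo_scenario")
}

#' Length-dependent capture probability of the sampling net
#'
#' Logistic probability that an individual of a given body length is
#' retained by the 200-µm mesh. Small individuals pass through: under the
#' defaults the probability is below 0.1 at 400 µm (a >90% under-catch of
#' sub-500-µm taxa) and saturates near 1 above 1000 µm.
#'
#' @param length_um body length(s) in µm, positive.
#' @param l50 length of 50% retention (µm).
#' @param scale logistic scale (µm).
#' @return probabilities in `[0, 1]`, nondecreasing in length.
#' @examples
#' capture_probability(c(400, 1000, 2000))
#' @export
capture_probability <- function(length_um, l50 = 550, scale = 60) {
  if (any(length_um <= 0)) stop("length must be positive")
  stats::plogis((length_um - l50) / scale)
}

seasonal_multiplier <- function(doy, peak, width, floor) {
  d <- abs(doy - peak)
  d <- pmin(d, 365 - d)
  s <- floor + (1 - floor) * exp(-0.5 * (d / width)^2)
  # negligible seasonal tails are true absences, not trace densities
  ifelse(s < 1e-4, 0, s)
}

scenario_abundance <- function(tx, station_id, doy) {
  base <- tx[[paste0("abund_", station_id)]]
  base * seasonal_multiplier(doy, tx$peak_doy, tx$width, tx$floor)
}

scenario_length_median <- function(tx, doy) {
  if (is.na(tx$len_med_late)) return(tx$len_med)
  if (doy <= tx$ramp_start) return(tx$len_med)
  if (doy >= tx$ramp_end) return(tx$len_med_late)
  w <- (doy - tx$ramp_start) / (tx$ramp_end - tx$ramp_start)
  (1 - w) * tx$len_med + w * tx$len_med_late
}

choose_split <- function(total_individuals, thresholds) {
  th <- matrix(thresholds, ncol = 2, byrow = TRUE)
  th <- th[order(-th[, 2]), , drop = FALSE]
  for (i in seq_len(nrow(th)))
    if (total_individuals >= th[i, 2]) return(as.integer(th[i, 1]))
  as.integer(th[nrow(th), 1])
}

#' Simulate a survey from a scenario
#'
#' Draws one realized survey (weighing records, length measurements,
#' stations, events) and the matching ground truth from a scenario's
#' abundance, length and observation model. The whole chain is simulated:
#' Poisson haul counts thinned by the capture curve, per-individual
#' lengths and allometric fresh dry weights, formalin mass loss, Motoda
#' splitting (binomial at 1/split), multinomial placement of the split
#' part's individuals into 2-ml aliquots of the 200-ml dilution, pooling
#' of as many aliquots as the haul density suggests, and an additive
#' Normal weighing error. Three distilled-water control records are
#' emitted per sample.
#'
#' @details The number of pooled aliquots per taxon is chosen from the
#'   haul count before the aliquot contents are observed, so the areal
#'   estimator of the processing chain stays unbiased. Ground truth is the
#'   realized haul before splitting: areal biomass is the summed fresh dry
#'   weight of captured individuals per m2. Identical seeds give identical
#'   output.
#'
#' @param scenario a `"zoo_scenario"`, e.g. [default_scenario()].
#' @param seed integer; required, every draw depends on it.
#' @return list with `survey` (a `"zoo_survey"`) and `truth` (data frame
#'   with per station/event/taxon true areal biomass (mg DW/m2, fresh
#'   scale), abundance (ind/m2) and mean individual DW (mg)).
#' @examples
#' sim <- simulate_survey(default_scenario(), seed = 17)
#' head(sim$truth)
#' @export
simulate_survey <- function(scenario, seed) {
  stopifnot(inherits(scenario, "zoo_scenario"))
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  obs <- scenario$obs
  n_aliquots <- as.integer(obs$dilution_ml / obs$pipette_ml)

  wrows <- list(); lrows <- list(); trows <- list(); ri <- 0L
  for (si in seq_len(nrow(scenario$stations))) {
    st <- scenario$stations$station_id[si]
    for (ei in seq_len(nrow(scenario$events))) {
      ev <- scenario$events$event_id[ei]
      doy <- scenario$events$day_of_year[ei]
      sample_id <- paste(st, ev, sep = "_")

      # realized haul per taxon
      haul <- vector("list", nrow(scenario$taxa))
      for (ti in seq_len(nrow(scenario$taxa))) {
        tx <- scenario$taxa[ti, ]
        lambda <- scenario_abundance(tx, st, doy) * obs$net_area
        n_raw <- if (is.finite(obs$overdispersion) && obs$overdispersion > 0)
          stats::rnbinom(1, size = obs$overdispersion, mu = lambda)
        else stats::rpois(1, lambda)
        if (n_raw == 0) { haul[[ti]] <- numeric(0); next }
        med <- scenario_length_median(tx, doy)
        len <- stats::rlnorm(n_raw, meanlog = log(med), sdlog = tx$len_sd)
        if (isTRUE(obs$capture$enabled)) {
          p <- capture_probability(len, obs$capture$l50, obs$capture$scale)
          len <- len[stats::runif(n_raw) < p]
        }
        haul[[ti]] <- len
      }
      total <- sum(lengths(haul))
      split <- choose_split(total, obs$split_thresholds)

      for (ti in seq_len(nrow(scenario$taxa))) {
        tx <- scenario$taxa[ti, ]
        len <- haul[[ti]]
        n_haul <- length(len)
        fresh <- tx$allo_a * (len / 1000)^tx$allo_b
        trows[[length(trows) + 1L]] <- data.frame(
          station_id = st, event_id = ev, sample_id = sample_id,
          taxon_name = tx$taxon_name, stage_tag = tx$stage_tag,
          true_abundance = n_haul / obs$net_area,
          true_biomass = sum(fresh) / obs$net_area,
          true_mean_dw = if (n_haul > 0) mean(fresh) else NA_real_,
          stringsAsFactors = FALSE)
        if (n_haul == 0) next

        in_part <- stats::runif(n_haul) < 1 / split
        n_part <- sum(in_part)
        if (n_part == 0) next
        expected_per_aliquot <- max(n_haul / split / n_aliquots, 1e-9)
        k <- min(n_aliquots, max(1L, ceiling(obs$target_count / expected_per_aliquot)))
        aliquot <- sample.int(n_aliquots, n_part, replace = TRUE)
        sub <- which(in_part)[aliquot <= k]
        n_sub <- length(sub)
        if (n_sub == 0) next

        # a boat with plankton cannot record a negative gain; the additive
        # error is censored at zero (matters only for near-zero masses)
        gain <- max(0, sum(fresh[sub]) * (1 - obs$formalin_loss) +
                      stats::rnorm(1, obs$error_mean, obs$error_sd))
        ri <- ri + 1L
        wrows[[ri]] <- data.frame(
          sample_id = sample_id, taxon_name = tx$taxon_name,
          stage_tag = tx$stage_tag, n_individuals = n_sub,
          raw_gain = gain, split_denominator = split,
          n_subsamples = as.integer(k), is_control = FALSE,
          stringsAsFactors = FALSE)
        meas <- utils::head(sub, obs$max_lengths)
        lrows[[length(lrows) + 1L]] <- data.frame(
          sample_id = sample_id, taxon_name = tx$taxon_name,
          stage_tag = tx$stage_tag, length = len[meas],
          stringsAsFactors = FALSE)
      }

      for (ci in 1:3) {
        ri <- ri + 1L
        wrows[[ri]] <- data.frame(
          sample_id = sample_id, taxon_name = "",
          stage_tag = NA_character_, n_individuals = 0L,
          raw_gain = stats::rnorm(1, obs$error_mean, obs$error_sd),
          split_denominator = split, n_subsamples = 1L, is_control = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }

  survey <- structure(list(
    weighings = do.call(rbind, wrows),
    lengths = if (length(lrows)) do.call(rbind, lrows) else
      data.frame(sample_id = character(0), taxon_name = character(0),
                 stage_tag = character(0), length = numeric(0)),
    stations = scenario$stations,
    events = scenario$events), class = "zoo_survey")
  validate_weighings(survey$weighings)
  list(survey = survey, truth = do.call(rbind, trows))
}
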