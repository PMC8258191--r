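#' Process a survey into areal biomass, carbon and energy content
#'
#' Runs the full estimation chain on a survey bundle: summarize the control
#' weighings (or fall back to the configured error constants when the bundle
#' has no controls), subtract the mean measurement error, flag records below
#' the reliability threshold, reverse the formalin mass loss, standardize to
#' 1 m2 of sea surface, compute mean individual dry weights, assign size
#' classes and plankton groups, convert to organic carbon and energy
#' content, and summarize every sample.
#'
#' @details Unreliable records are excluded from all downstream statistics
#'   but retained in the output with `reliable = FALSE` and `NA` derived
#'   quantities. Size classes come from the reference taxon table with the
#'   stage exceptions: *Calanus* nauplii are small (SMZ) while copepodites
#'   are large (LMZ), and the two cross-class taxa (*Limacina retroversa*,
#'   *Oikopleura* spp.) are always large. Standardization is per record, not
#'   per sample, because the number of subsamples may differ between taxa
#'   within one haul. Taxa missing from the reference table get `NA`
#'   factors and are flagged with a warning.
#'
#' @param survey a `"zoo_survey"` bundle from [read_survey()] or
#'   [simulate_survey()].
#' @param config a `"zoo_config"` list, see [default_config()].
#' @param taxa reference taxon table; defaults to the packaged Table of 28.
#' @return An object of class `"zoosurvey_biomass"`: list with `controls`
#'   (a `"control_summary"` or the configured fallback), `biomass` (one row
#'   per weighing record), `summaries` (per-sample), `station_means`,
#'   `config`, and discard accounting `n_discarded` / `n_measurements`.
#' @examples
#' sim <- simulate_survey(default_scenario(), seed = 1)
#' est <- process_survey(sim$survey)
#' est
#' @export
process_survey <- function(survey, config = default_config(),
                           taxa = load_reference_tables()$taxa) {
  stopifnot(inherits(survey, "zoo_survey"))
  validate_config(config)
  w <- survey$weighings

  ctl <- w[w$is_control, , drop = FALSE]
  if (nrow(ctl) >= 2) {
    controls <- summarize_controls(ctl$raw_gain, multiplier = config$sd_multiplier)
  } else {
    controls <- structure(list(
      n = 0L, mean_error = config$mean_control_error,
      sd_error = config$control_sd,
      threshold = config$sd_multiplier * config$control_sd,
      multiplier = config$sd_multiplier,
      t_stat = NA_real_, df = NA_integer_, p_value = NA_real_),
      class = "control_summary")
  }

  b <- w[!w$is_control, , drop = FALSE]
  if (nrow(b) == 0L) stop("survey contains no plankton weighing records")

  cf <- correct_and_filter(b$raw_gain, controls, reliable_on = config$reliable_on)
  corrected_mass <- formalin_correct(cf$corrected, config$formalin_loss)

  rec <- data.frame(
    sample_id = b$sample_id,
    taxon_name = b$taxon_name,
    stage_tag = b$stage_tag,
    n_individuals = b$n_individuals,
    raw_gain = b$raw_gain,
    split_denominator = b$split_denominator,
    n_subsamples = b$n_subsamples,
    corrected_mass = corrected_mass,
    reliable = cf$reliable,
    stringsAsFactors = FALSE
  )

  rec$areal_biomass <- ifelse(
    rec$reliable,
    standardize_to_area(rec$corrected_mass, rec$split_denominator,
                        rec$n_subsamples, net_area = config$net_area,
                        dilution_ml = config$dilution_ml,
                        pipette_ml = config$pipette_ml),
    NA_real_)
  rec$individual_dw <- ifelse(rec$reliable,
                              rec$corrected_mass / rec$n_individuals, NA_real_)

  rec <- merge_taxon_attributes(rec, taxa)
  rec$size_class <- assign_size_class(rec$taxon_name, rec$stage_tag, taxa)
  rec$carbon <- ifelse(rec$reliable, rec$areal_biomass * rec$carbon_factor, NA_real_)
  rec$energy <- ifelse(rec$reliable, rec$areal_biomass * rec$energy_factor, NA_real_)

  summaries <- summarize_samples(rec)
  st <- sub("_.*$", "", summaries$sample_id)
  station_means <- tapply(summaries$total_biomass, st, mean)

  structure(list(controls = controls, biomass = rec, summaries = summaries,
                 station_means = station_means, config = config,
                 n_measurements = nrow(rec),
                 n_discarded = sum(!rec$reliable)),
            class = "zoosurvey_biomass")
}

merge_taxon_attributes <- function(rec, taxa) {
  idx <- match(taxon_key(rec$taxon_name), taxon_key(taxa$taxon_name))
  if (anyNA(idx)) {
    unk <- unique(rec$taxon_name[is.na(idx)])
    warning("taxa without reference factors (NA carried): ",
            paste(unk, collapse = ", "))
  }
  rec$plankton_group <- taxa$plankton_group[idx]
  rec$carbon_factor <- taxa$carbon_factor[idx]
  rec$energy_factor <- taxa$energy_factor[idx]
  rec
}

#' Assign the size class of each record
#'
#' Size classes follow the reference taxon table (small vs large
#' mesozooplankton at the 1-mm boundary) with the stage exceptions
#' described in [process_survey()].
#'
#' @param taxon_name,stage_tag character vectors, recycled together.
#' @param taxa reference taxon table.
#' @return character vector of `"SMZ"` / `"LMZ"` (NA for unmapped taxa).
#' @examples
#' assign_size_class("Calanus spp.", "nauplii")      # "SMZ"
#' assign_size_class("Limacina retroversa", NA)      # "LMZ"
#' @export
assign_size_class <- function(taxon_name, stage_tag = NA_character_,
                              taxa = load_reference_tables()$taxa) {
  idx <- match(taxon_key(taxon_name), taxon_key(taxa$taxon_name))
  size <- taxa$size_class[idx]
  is_cal <- !is.na(idx) & taxon_key(taxon_name) == "calanus spp."
  size[is_cal & !is.na(stage_tag) & grepl("naupli", stage_tag, ignore.case = TRUE)] <- "SMZ"
  size[is_cal & !(!is.na(stage_tag) & grepl("naupli", stage_tag, ignore.case = TRUE))] <- "LMZ"
  size[!is.na(idx) & taxa$cross_class_flag[idx]] <- "LMZ"
  size
}

#' Per-sample composition fractions
#'
#' Reliable areal biomass per sample partitioned by plankton group
#' (holo-/mero-/ichthyoplankton) and by size class (SMZ/LMZ). Each
#' partition's fractions sum to 1; unmapped taxa are excluded with a
#' warning.
#'
#' @param rec processed biomass record table (from a `"zoosurvey_biomass"`).
#' @return data frame keyed by `sample_id` with fraction columns.
#' @export
partition_size_and_group <- function(rec) {
  r <- rec[rec$reliable & !is.na(rec$areal_biomass), , drop = FALSE]
  if (any(is.na(r$plankton_group) | is.na(r$size_class))) {
    warning("unmapped taxa excluded from composition fractions")
    r <- r[!is.na(r$plankton_group) & !is.na(r$size_class), , drop = FALSE]
  }
  samples <- unique(rec$sample_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  tot <- tapply(r$areal_biomass, r$sample_id, sum)
  frac <- function(sel) {
    s <- tapply(r$areal_biomass[sel], r$sample_id[sel], sum)
    v <- as.numeric(s[samples]) / as.numeric(tot[samples])
    v[is.na(v)] <- 0
    v
  }
  out$frac_holo <- frac(r$plankton_group == "holoplankton")
  out$frac_mero <- frac(r$plankton_group == "meroplankton")
  out$frac_ichthyo <- frac(r$plankton_group == "ichthyoplankton")
  out$frac_smz <- frac(r$size_class == "SMZ")
  out$frac_lmz <- frac(r$size_class == "LMZ")
  out
}

#' Convert reliable biomass to carbon and energy content
#'
#' Elementwise multiplication of areal biomass by the taxon-specific
#' conversion factors (mg C per mg DW, J per mg DW). Records with missing
#' factors are skipped with a warning.
#'
#' @param rec processed biomass record table.
#' @return data frame with `sample_id`, `taxon_name`, `carbon` (mg C/m2)
#'   and `energy` (J/m2).
#' @export
convert_composition <- function(rec) {
  r <- rec[rec$reliable, , drop = FALSE]
  if (any(is.na(r$carbon_factor))) {
    warning("records without conversion factors skipped")
    r <- r[!is.na(r$carbon_factor), , drop = FALSE]
  }
  data.frame(sample_id = r$sample_id, taxon_name = r$taxon_name,
             carbon = r$areal_biomass * r$carbon_factor,
             energy = r$areal_biomass * r$energy_factor,
             stringsAsFactors = FALSE)
}

#' Summarize each sample of a processed survey
#'
#' @param rec processed biomass record table.
#' @return data frame with per-sample total areal biomass, number of
#'   reliable taxa, the dominant taxon, and group/size fractions.
#' @export
summarize_samples <- function(rec) {
  if (nrow(rec) == 0L) {
    warning("empty biomass table; empty summary returned")
    return(data.frame(sample_id = character(0)))
  }
  r <- rec[rec$reliable & !is.na(rec$areal_biomass), , drop = FALSE]
  samples <- unique(rec$sample_id)
  tot <- tapply(r$areal_biomass, r$sample_id, sum)
  ntx <- tapply(r$taxon_name, r$sample_id, function(x) length(unique(x)))
  dom <- vapply(samples, function(s) {
    rs <- r[r$sample_id == s, , drop = FALSE]
    if (nrow(rs) == 0L) return(NA_character_)
    rs$taxon_name[which.max(rs$areal_biomass)]
  }, character(1))
  out <- data.frame(sample_id = samples,
                    total_biomass = as.numeric(tot[samples]),
                    n_taxa_reliable = as.integer(ntx[samples]),
                    dominant_taxon = dom,
                    stringsAsFactors = FALSE)
  out$total_biomass[is.na(out$total_biomass)] <- 0
  out$n_taxa_reliable[is.na(out$n_taxa_reliable)] <- 0L
  fr <- suppressWarnings(partition_size_and_group(rec))
  merge(out, fr, by = "sample_id", sort = FALSE)
}

#' Samples-by-taxa biomass matrix for multivariate analysis
#'
#' Builds the community matrix of reliable areal biomass, with *Calanus*
#' stages kept as separate columns so the two size fractions can be
#' assigned correctly. The `"smz"` subset keeps only small-class columns
#' (cross-class taxa excluded per their LMZ assignment).
#'
#' @param est a `"zoosurvey_biomass"` object.
#' @param subset `"all"` or `"smz"`.
#' @return numeric matrix (samples x taxa) with attribute `state = "raw"`.
#' @export
community_matrix <- function(est, subset = c("all", "smz")) {
  stopifnot(inherits(est, "zoosurvey_biomass"))
  subset <- match.arg(subset)
  r <- est$biomass[est$biomass$reliable & !is.na(est$biomass$areal_biomass), ,
                   drop = FALSE]
  col <- ifelse(!is.na(r$stage_tag) & taxon_key(r$taxon_name) == "calanus spp.",
                paste(r$taxon_name, r$stage_tag), r$taxon_name)
  if (subset == "smz") {
    keep <- !is.na(r$size_class) & r$size_class == "SMZ"
    r <- r[keep, , drop = FALSE]; col <- col[keep]
  }
  samples <- sort(unique(est$biomass$sample_id))
  taxa <- sort(unique(col))
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  for (i in seq_len(nrow(r)))
    m[r$sample_id[i], col[i]] <- m[r$sample_id[i], col[i]] + r$areal_biomass[i]
  attr(m, "state") <- "raw"
  m
}

#' @export
print.zoosurvey_biomass <- function(x, ...) {
  cat("Processed mesozooplankton survey\n")
  cat(sprintf("  %d measurements, %d discarded as unreliable (threshold %.3f mg)\n",
              x$n_measurements, x$n_discarded, x$controls$threshold))
  cat(sprintf("  %d samples, %d taxa\n", nrow(x$summaries),
              length(unique(x$biomass$taxon_name))))
  cat(sprintf("  formalin multiplier %.2f, net area %.2f m2\n",
              formalin_multiplier(x$config$formalin_loss), x$config$net_area))
  invisible(x)
}

#' @export
summary.zoosurvey_biomass <- function(object, ...) {
  cat("Per-station study-period mean total biomass (mg DW/m2):\n")
  print(round(object$station_means, 1))
  cat("\nPer-sample summaries:\n")
  print(object$summaries, digits = 4)
  invisible(object$summaries)
}
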