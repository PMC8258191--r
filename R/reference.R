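#' Packaged reference tables
#'
#' Loads the reference fixtures shipped with the package: the taxon table
#' (28 taxa with plankton group, size class and carbon/energy conversion
#' factors), the length-weight formula registry (3 Calanus relationships
#' and 5 Oithona methods including the fixed 0.003 mg individual weight),
#' the three survey stations and the eight sampling events.
#'
#' @details Conversion factors are mg C per mg DW and J per mg DW. Two taxa
#'   span both size classes (*Limacina retroversa* and *Oikopleura* spp.,
#'   `cross_class_flag`) and are always assigned to the large fraction.
#'   An integrity check asserts the expected shape (28 taxa split 17/9/2
#'   across groups, factors in range, 3 stations, 8 events) and fails if
#'   a fixture was corrupted.
#'
#' @return A list with data frames `taxa`, `formulas`, `stations`, `events`.
#' @examples
#' ref <- load_reference_tables()
#' subset(ref$taxa, taxon_name == "Calanus spp.")
#' @export
load_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mesozoo", mustWork = TRUE)
  taxa     <- utils::read.csv(path("taxa.csv"), stringsAsFactors = FALSE)
  formulas <- utils::read.csv(path("allometric_formulas.csv"), stringsAsFactors = FALSE)
  stations <- utils::read.csv(path("stations.csv"), stringsAsFactors = FALSE)
  events   <- utils::read.csv(path("events.csv"), stringsAsFactors = FALSE)
  events$calendar_date <- as.Date(events$calendar_date)
  events$day_of_year <- as.integer(format(events$calendar_date, "%j"))

  ok <- nrow(taxa) == 28 &&
    sum(taxa$plankton_group == "holoplankton") == 17 &&
    sum(taxa$plankton_group == "meroplankton") == 9 &&
    sum(taxa$plankton_group == "ichthyoplankton") == 2 &&
    all(taxa$carbon_factor > 0 & taxa$carbon_factor < 1) &&
    all(taxa$energy_factor > 0) &&
    all(taxa$size_class %in% c("SMZ", "LMZ")) &&
    identical(sort(taxa$taxon_name[taxa$cross_class_flag]),
              c("Limacina retroversa", "Oikopleura spp.")) &&
    nrow(stations) == 3 && all(stations$depth_m > 0) &&
    nrow(events) == 8 &&
    all(events$day_of_year >= 1 & events$day_of_year <= 366) &&
    sum(formulas$target_taxon == "Calanus spp.") == 3 &&
    sum(formulas$target_taxon == "Oithona spp.") == 5
  if (!ok) stop("packaged reference fixtures failed the integrity check")

  list(taxa = taxa, formulas = formulas, stations = stations, events = events)
}

#' Water-column depth ratios between stations
#'
#' Biomass is reported per m\eqn{^2} surface area without tow-depth
#' normalization; per-volume comparisons therefore divide by station depth.
#' This helper reports station depths relative to the shallowest station:
#' areal biomass in these ratios indicates equal biomass per unit volume.
#'
#' @param depths positive numeric vector of station depths (m).
#' @param digits rounding applied to the printed ratios.
#' @return Named numeric vector of `depth / min(depth)` ratios.
#' @examples
#' depth_ratio(c(C = 40, B = 80, T = 215))  # 1 : 2 : 5.4
#' @export
depth_ratio <- function(depths, digits = 1) {
  if (!is.numeric(depths) || any(depths <= 0))
    stop("depths must be positive numbers")
  round(depths / min(depths), digits)
}
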