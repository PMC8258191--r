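# Scenario builders shared across tests. All are derived from the default
# scenario by subsetting, so parameter meanings stay in one place.

# Small, fast scenario: 2 stations x 4 events x 5 taxa.
trimmed_scenario <- function() {
  sc <- default_scenario()
  sc$stations <- sc$stations[sc$stations$station_id %in% c("C", "T"), ]
  sc$events <- sc$events[c(1, 4, 6, 7), ]
  keep <- c("Calanus spp.", "Oithona spp.", "Copepoda nauplii",
            "Limacina retroversa")
  sc$taxa <- sc$taxa[sc$taxa$taxon_name %in% keep, ]
  sc
}

# Ideal observation: full capture, unbiased weighing (zero mean error).
ideal_obs <- function(sc, error_sd = sc$obs$error_sd) {
  sc$obs$capture$enabled <- FALSE
  sc$obs$error_mean <- 0
  sc$obs$error_sd <- error_sd
  sc
}

# Scenario with zero abundance everywhere (controls only).
empty_scenario <- function() {
  sc <- trimmed_scenario()
  for (st in sc$stations$station_id) sc$taxa[[paste0("abund_", st)]] <- 0
  sc
}

# Single Calanus taxon whose length-to-weight truth equals a multiple of
# the calanus_i registry formula.
calanus_scenario <- function(coef_scale = 1) {
  sc <- default_scenario()
  sc$taxa <- sc$taxa[sc$taxa$taxon_name == "Calanus spp." &
                       sc$taxa$stage_tag == "copepodites", ]
  sc$taxa$allo_a <- 0.006458 * coef_scale
  sc$taxa$allo_b <- 3.9
  sc$obs$max_lengths <- 10000L   # lengths of every weighed individual
  sc
}

# Reference config/controls used where only the constants matter.
paper_controls <- function() {
  list(mean_error = 0.016, threshold = 0.043)
}
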