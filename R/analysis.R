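#' Full multivariate analysis of a processed survey
#'
#' Convenience orchestrator running the whole multivariate suite on the
#' community matrix of a processed survey: Hellinger transformation, PCA,
#' the four-linkage cluster comparison with method selection, the
#' cluster-number diagnostics on the selected tree, the species
#' contribution analysis at the chosen number of clusters, and variation
#' partitioning between the station factor and the circular seasonal
#' predictor. The analysis is intended to be run twice — on the complete
#' matrix and on the small-size-class (`"smz"`) submatrix.
#'
#' @param est a `"zoosurvey_biomass"` object.
#' @param events event table with `event_id`, `day_of_year` (e.g.
#'   `survey$events`); matched to samples via the `station_event` id.
#' @param subset `"all"` or `"smz"`, see [community_matrix()].
#' @param k number of clusters for the SCA; `NULL` uses the diagnostics'
#'   suggestion.
#' @return list of class `"community_analysis"` with `matrix` (Hellinger),
#'   `pca`, `clustering`, `diagnostics`, `k`, `memberships`, `sca`,
#'   `varpart`.
#' @examples
#' sim <- simulate_survey(default_scenario(), seed = 1)
#' est <- process_survey(sim$survey)
#' an <- community_analysis(est, sim$survey$events)
#' an$varpart
#' @export
community_analysis <- function(est, events, subset = c("all", "smz"), k = NULL) {
  subset <- match.arg(subset)
  m <- community_matrix(est, subset)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  H <- hellinger_transform(m)
  d <- stats::dist(H)
  suite <- cluster_suite(d)
  tree <- suite$models[[suite$selected]]$tree
  diag_ <- cluster_number_diagnostics(tree, d)
  if (is.null(k)) k <- diag_$suggested_k
  mem <- stats::cutree(tree, k = k)
  station <- sub("_.*$", "", rownames(H))
  ev <- sub("^[^_]*_", "", rownames(H))
  doy <- events$day_of_year[match(ev, events$event_id)]
  structure(list(matrix = H, pca = pca_community(H),
                 clustering = suite, diagnostics = diag_, k = k,
                 memberships = mem,
                 sca = species_contribution(H, mem),
                 varpart = variation_partition(H, station, doy)),
            class = "community_analysis")
}

#' @export
print.community_analysis <- function(x, ...) {
  cat(sprintf("Community analysis: %d samples x %d taxa (Hellinger)\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  clustering: %s linkage, k = %d\n",
              x$clustering$selected, x$k))
  cat(sprintf("  SCA flag threshold: %.0f%%\n", sca_flag_threshold(ncol(x$matrix))))
  print(x$varpart)
  invisible(x)
}
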