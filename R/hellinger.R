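#' Hellinger transformation of a community matrix
#'
#' Row-wise transform `y'_ij = sqrt(y_ij / y_i+)` where `y_i+` is the row
#' (sample) total. Transformed rows have unit sum of squares, which makes
#' Euclidean-distance methods (PCA, Ward clustering, RDA) appropriate for
#' compositional abundance/biomass data; Euclidean distances between
#' transformed rows are bounded by sqrt(2).
#'
#' @param x nonnegative numeric matrix, samples in rows.
#' @return transformed matrix with attribute `state = "hellinger"`. All-zero
#'   rows are left as zeros with a warning.
#' @examples
#' hellinger_transform(rbind(c(4, 1, 4)))  # 2/3, 1/3, 2/3
#' @export
hellinger_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("community matrix must be nonnegative")
  tot <- rowSums(x)
  if (any(tot == 0)) warning("all-zero rows left as zeros")
  out <- sqrt(sweep(x, 1, ifelse(tot > 0, tot, 1), "/"))
  attr(out, "state") <- "hellinger"
  out
}

#' Principal component analysis of a (transformed) community matrix
#'
#' Covariance-based PCA: columns are centred but not rescaled, the usual
#' convention for transformation-based ordination where the transform
#' already puts taxa on a common scale. Computed by singular value
#' decomposition of the centred matrix.
#'
#' @param x numeric matrix, samples in rows (typically Hellinger
#'   transformed). At least 2 rows.
#' @param scaling `1` (distance biplot: scores `U d`, loadings `V`) or
#'   `2` (correlation biplot: scores `U`, loadings `V d / sqrt(n-1)`).
#' @param correlation use the correlation matrix (columns standardized)
#'   instead of the covariance; constant columns are rejected.
#' @return list of class `"zoo_pca"`: `eigenvalues` (variances along each
#'   axis, summing to the total variance), `scores` (samples), `loadings`
#'   (taxa), `prop_explained`.
#' @export
pca_community <- function(x, scaling = 1, correlation = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (correlation) {
    s <- apply(x, 2, stats::sd)
    if (any(s == 0)) stop("constant columns cannot be standardized")
    xc <- sweep(xc, 2, s, "/")
  }
  if (all(abs(xc) < 1e-14)) warning("constant matrix; all eigenvalues zero")
  sv <- svd(xc)
  n <- nrow(x)
  ev <- sv$d^2 / (n - 1)
  keep <- seq_len(min(dim(xc)))
  scores <- if (scaling == 1) sv$u %*% diag(sv$d, length(sv$d)) else sv$u
  loadings <- if (scaling == 1) sv$v else sv$v %*% diag(sv$d / sqrt(n - 1), length(sv$d))
  dimnames(scores) <- list(rownames(x), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(x), paste0("PC", keep))
  structure(list(eigenvalues = ev,
                 prop_explained = if (sum(ev) > 0) ev / sum(ev) else ev * 0,
                 scores = scores, loadings = loadings, scaling = scaling),
            class = "zoo_pca")
}

#' @export
print.zoo_pca <- function(x, ...) {
  cat("PCA of community matrix\n")
  k <- min(5, length(x$eigenvalues))
  cat("  eigenvalues:", paste(signif(x$eigenvalues[1:k], 4), collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  cat(sprintf("  first two axes explain %.1f%% of total variance\n",
              100 * sum(x$prop_explained[1:min(2, k)])))
  invisible(x)
}

#' @export
plot.zoo_pca <- function(x, axes = c(1, 2), ...) {
  s <- x$scores[, axes, drop = FALSE]
  plot(s, type = "n",
       xlab = sprintf("PC%d (%.1f%%)", axes[1], 100 * x$prop_explained[axes[1]]),
       ylab = sprintf("PC%d (%.1f%%)", axes[2], 100 * x$prop_explained[axes[2]]),
       ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::text(s, labels = rownames(s), cex = 0.8)
  invisible(x)
}

#' Flag threshold of the species contribution analysis
#'
#' Taxa contributing at least twice the average contribution are flagged;
#' with `n` taxa the average is `100/n` percent, so the threshold is
#' `2 * 100 / n` percent (7% for 28 taxa, 13% for 15 taxa at the printed
#' integer precision).
#'
#' @param n_taxa number of taxa in the analysed matrix.
#' @param digits rounding of the printed percentage.
#' @return threshold in percent.
#' @examples
#' sca_flag_threshold(28)  # 7
#' sca_flag_threshold(15)  # 13
#' @export
sca_flag_threshold <- function(n_taxa, digits = 0) {
  if (n_taxa < 1) stop("n_taxa must be positive")
  round(2 * 100 / n_taxa, digits)
}

#' Species contributions to between-cluster differences
#'
#' For every pair of clusters, decomposes the squared Euclidean distance
#' between the cluster centroids of the (Hellinger-transformed) community
#' matrix into per-taxon shares:
#' `contribution_j = (c_Aj - c_Bj)^2 / sum_k (c_Ak - c_Bk)^2`.
#' Shares sum to 1 per pair; taxa at or above twice the average share
#' (`2 / n_taxa`) are flagged.
#'
#' @param x community matrix (samples x taxa), typically Hellinger state.
#' @param memberships cluster assignment per row of `x` (>= 2 clusters).
#' @return data frame of class `"sca_table"`: `cluster_a`, `cluster_b`,
#'   `taxon`, `contribution`, `flagged`. Pairs with identical centroids
#'   get `NA` contributions and a warning.
#' @export
species_contribution <- function(x, memberships) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  memberships <- as.character(memberships)
  if (length(memberships) != nrow(x))
    stop("memberships must match the rows of x")
  cl <- sort(unique(memberships))
  if (length(cl) < 2) stop("at least 2 clusters are required")
  cent <- t(vapply(cl, function(g) colMeans(x[memberships == g, , drop = FALSE]),
                   numeric(ncol(x))))
  thr <- 2 / ncol(x)
  out <- list()
  for (i in seq_along(cl)) for (j in seq_along(cl)) {
    if (j <= i) next
    d2 <- (cent[i, ] - cent[j, ])^2
    tot <- sum(d2)
    if (tot == 0) {
      warning("identical centroids for clusters ", cl[i], " and ", cl[j])
      contrib <- rep(NA_real_, ncol(x))
    } else contrib <- d2 / tot
    out[[length(out) + 1L]] <- data.frame(
      cluster_a = cl[i], cluster_b = cl[j], taxon = colnames(x),
      contribution = contrib,
      flagged = !is.na(contrib) & contrib >= thr,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("sca_table", class(res))
  res
}
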