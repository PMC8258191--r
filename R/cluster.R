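## Agglomerative hierarchical clustering implemented via Lance-Williams
## updates for the four linkages used in community analysis, returning an
## hclust-compatible merge tree so standard tree cutting applies. Ward is
## the squared-increment (Ward.D2) variant on Euclidean distances.

.lw_update <- function(method, dki, dkj, dij, ni, nj, nk) {
  switch(method,
    single   = pmin(dki, dkj),
    complete = pmax(dki, dkj),
    upgma    = (ni * dki + nj * dkj) / (ni + nj),
    ward     = sqrt(((nk + ni) * dki^2 + (nk + nj) * dkj^2 - nk * dij^2) /
                      (ni + nj + nk)),
    stop("unknown linkage method: ", method))
}

#' Agglomerative clustering of a distance matrix
#'
#' Builds the dendrogram for one linkage method (`"single"`, `"complete"`,
#' `"upgma"`, `"ward"`). The merge tree follows the [stats::hclust()]
#' conventions (negative entries are singletons) so [stats::cutree()]
#' works directly on the result.
#'
#' @param d a `dist` or symmetric matrix of distances (Euclidean for Ward).
#' @param method linkage method.
#' @return an object of classes `"zoo_hclust"` and `"hclust"` with
#'   `merge`, `height`, `order`, `labels`, `method`.
#' @export
agglomerate <- function(d, method = c("single", "complete", "upgma", "ward")) {
  method <- match.arg(method)
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop("at least 2 points are required")
  labels <- rownames(D)
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust coding of active clusters
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    w <- which.min(sub)
    i <- idx[(w - 1L) %% length(idx) + 1L]
    j <- idx[(w - 1L) %/% length(idx) + 1L]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- D[i, j]
    height[step] <- dij
    merge[step, ] <- sort(c(id[i], id[j]))

    others <- idx[idx != i & idx != j]
    if (length(others)) {
      D[i, others] <- D[others, i] <-
        .lw_update(method, D[i, others], D[j, others], dij,
                   size[i], size[j], size[others])
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
  }

  structure(list(merge = merge, height = height,
                 order = .tree_order(merge, n), labels = labels,
                 method = method, dist.method = "euclidean",
                 call = match.call()),
            class = c("zoo_hclust", "hclust"))
}

.tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Cophenetic distances of a merge tree
#'
#' The cophenetic distance of two samples is the fusion height at which
#' they first join in the dendrogram; the resulting matrix is ultrametric
#' for the monotone linkages.
#'
#' @param tree a `"zoo_hclust"` (or any `hclust`-shaped) object.
#' @return a `dist` object.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$height) + 1L
  members <- vector("list", n - 1L)
  cd <- matrix(0, n, n)
  for (step in seq_len(n - 1L)) {
    left <- if (tree$merge[step, 1] < 0) -tree$merge[step, 1] else members[[tree$merge[step, 1]]]
    right <- if (tree$merge[step, 2] < 0) -tree$merge[step, 2] else members[[tree$merge[step, 2]]]
    cd[left, right] <- cd[right, left] <- tree$height[step]
    members[[step]] <- c(left, right)
  }
  dimnames(cd) <- list(tree$labels, tree$labels)
  stats::as.dist(cd)
}

#' Fit and compare the four linkage methods
#'
#' Runs single, complete, UPGMA and Ward clustering on one distance matrix
#' and scores how faithfully each dendrogram represents it: the Pearson
#' correlation between original and cophenetic distances (higher is
#' better) and Gower's dendrogram-fit criterion, the sum of squared
#' differences between the two (lower is better). The selected method
#' maximizes the cophenetic correlation, ties broken by the smaller Gower
#' criterion; if the original distances have zero variance the correlation
#' is undefined (`NA`, flagged) and selection falls back to the Gower
#' criterion alone.
#'
#' @param d a `dist` (Euclidean distances of a Hellinger matrix in the
#'   intended use) over at least 3 samples.
#' @return list of class `"cluster_suite"`: per-method models (each with
#'   `tree`, `cophenetic`, `cophenetic_correlation`, `gower`), `selection`
#'   table, `selected` method name, `degenerate` flag.
#' @export
cluster_suite <- function(d) {
  dv <- as.vector(stats::as.dist(d))
  if (length(dv) < 3 || attr(stats::as.dist(d), "Size") < 3)
    stop("at least 3 samples are required")
  degenerate <- stats::sd(dv) == 0
  if (degenerate)
    warning("zero variance in distances; cophenetic correlation undefined")
  methods <- c("single", "complete", "upgma", "ward")
  models <- lapply(methods, function(m) {
    tree <- agglomerate(d, m)
    cd <- cophenetic_distances(tree)
    cv <- as.vector(cd)
    list(method = m, tree = tree, cophenetic = cd,
         cophenetic_correlation =
           if (degenerate || stats::sd(cv) == 0) NA_real_ else stats::cor(dv, cv),
         gower = sum((dv - cv)^2))
  })
  names(models) <- methods
  sel <- data.frame(method = methods,
                    cophenetic_correlation =
                      vapply(models, `[[`, 0, "cophenetic_correlation"),
                    gower = vapply(models, `[[`, 0, "gower"),
                    row.names = NULL)
  cc <- sel$cophenetic_correlation
  if (all(is.na(cc))) best <- which.min(sel$gower)
  else {
    top <- which(cc == max(cc, na.rm = TRUE))
    best <- top[which.min(sel$gower[top])]
  }
  structure(list(models = models, selection = sel,
                 selected = methods[best], degenerate = degenerate),
            class = "cluster_suite")
}

#' @export
print.cluster_suite <- function(x, ...) {
  cat("Hierarchical clustering method comparison\n")
  print(transform(x$selection,
                  cophenetic_correlation = round(cophenetic_correlation, 4),
                  gower = signif(gower, 5)))
  cat("selected:", x$selected,
      if (x$degenerate) "(degenerate distances; Gower fallback)" else "", "\n")
  invisible(x)
}

#' Mean silhouette width of a partition
#'
#' Standard silhouette: `a(i)` is the mean distance of sample `i` to the
#' other members of its cluster, `b(i)` the smallest mean distance to any
#' other cluster, and `s(i) = (b - a) / max(a, b)`. Singletons get
#' `s(i) = 0` by convention.
#'
#' @param d a `dist`.
#' @param membership integer/character cluster assignment per sample.
#' @return list with per-sample `widths` and the `mean` width.
#' @export
silhouette_widths <- function(d, membership) {
  D <- as.matrix(d)
  n <- nrow(D)
  membership <- as.character(membership)
  cl <- unique(membership)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- membership == membership[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(cl[cl != membership[i]],
                    function(g) mean(D[i, membership == g]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = s, mean = mean(s))
}

#' Correlation between distances and a binary partition matrix
#'
#' Pearson correlation between the original distances and the binary
#' dissimilarity induced by a partition (0 for pairs in the same cluster,
#' 1 otherwise). A partition matching the distance structure yields a high
#' positive correlation, so the best cluster number maximizes this value.
#'
#' @inheritParams silhouette_widths
#' @return correlation (NA when either vector is constant).
#' @export
binary_matrix_correlation <- function(d, membership) {
  dv <- as.vector(stats::as.dist(d))
  membership <- as.character(membership)
  bm <- as.vector(stats::as.dist(outer(membership, membership, `!=`) * 1))
  if (stats::sd(dv) == 0 || stats::sd(bm) == 0) return(NA_real_)
  stats::cor(dv, bm)
}

#' Diagnostics for choosing the number of clusters
#'
#' For every candidate `k` this evaluates three criteria on the tree cut
#' into `k` groups: the fusion-level gap (the drop in merge height crossed
#' by the cut — large gaps indicate natural splits), the mean silhouette
#' width, and the binary-matrix correlation. Each criterion suggests the
#' `k` it maximizes; the overall suggestion is the majority vote, ties
#' resolved toward the smallest `k`. The suggestion is advisory — all
#' per-`k` values are returned so the final choice can be made by
#' inspection.
#'
#' @param tree a `"zoo_hclust"` tree.
#' @param d the original `dist` the tree was built from.
#' @param k_range candidate numbers of clusters (within `2..n-1`).
#' @return list of class `"cluster_diagnostics"`: per-`k` `table`
#'   (`k`, `fusion_gap`, `mean_silhouette`, `binary_correlation`),
#'   `votes`, `suggested_k`.
#' @export
cluster_number_diagnostics <- function(tree, d, k_range = NULL) {
  n <- length(tree$height) + 1L
  if (is.null(k_range)) k_range <- 2:(n - 1L)
  if (any(k_range < 2 | k_range > n - 1L))
    stop("k must be within 2..n-1")
  h <- c(0, sort(tree$height))   # h[m+1] = height of merge m
  tab <- data.frame(k = k_range, fusion_gap = NA_real_,
                    mean_silhouette = NA_real_, binary_correlation = NA_real_)
  for (r in seq_along(k_range)) {
    k <- k_range[r]
    mem <- stats::cutree(tree, k = k)
    # cutting into k clusters crosses the gap between merges n-k and n-k+1
    tab$fusion_gap[r] <- h[n - k + 2L] - h[n - k + 1L]
    tab$mean_silhouette[r] <- silhouette_widths(d, mem)$mean
    tab$binary_correlation[r] <- binary_matrix_correlation(d, mem)
  }
  votes <- c(fusion = tab$k[which.max(tab$fusion_gap)],
             silhouette = tab$k[which.max(tab$mean_silhouette)],
             binary = tab$k[which.max(tab$binary_correlation)])
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  structure(list(table = tab, votes = votes, suggested_k = min(winners)),
            class = "cluster_diagnostics")
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat("Cluster-number diagnostics\n")
  print(transform(x$table,
                  fusion_gap = signif(fusion_gap, 4),
                  mean_silhouette = round(mean_silhouette, 4),
                  binary_correlation = round(binary_correlation, 4)))
  cat("votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "), "\n")
  cat("suggested k:", x$suggested_k, "(advisory)\n")
  invisible(x)
}
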