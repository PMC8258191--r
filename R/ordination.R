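#' Circular seasonal predictor from day of year
#'
#' Projects sampling days onto the unit circle so that dates near the turn
#' of the year are numerically close: each day of year `t` maps to
#' `(sin(2*pi*t/365), cos(2*pi*t/365))`. A late-September and a late-August
#' sample of adjacent years thus end up near one another, as seasonal
#' predictors should.
#'
#' @param day_of_year integer vector in `[1, 366]`.
#' @return two-column matrix `doy_sin`, `doy_cos`; every row has unit norm.
#' @examples
#' circular_date_predictor(c(91, 365))
#' @export
circular_date_predictor <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must be in [1, 366]")
  theta <- 2 * pi * day_of_year / 365
  cbind(doy_sin = sin(theta), doy_cos = cos(theta))
}

# Centred multivariate least squares of Y on X; returns R^2 and the
# Ezekiel-adjusted R^2 with m = rank of the centred predictor matrix.
.mlr_r2 <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  qr_x <- qr(X)
  m <- qr_x$rank
  fitted <- qr.fitted(qr_x, Y)
  tot <- sum(Y^2)
  r2 <- if (tot > 0) sum(fitted^2) / tot else 0
  adj <- if (n - m - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - m - 1) else NA_real_
  list(r2 = r2, adj = adj, rank = m)
}

#' Redundancy-analysis R2 of a community matrix on predictors
#'
#' The canonical R2 of multivariate least squares: the share of the total
#' variance of the (column-centred) response matrix captured by its
#' projection onto the predictor space. Adjusted by the Ezekiel formula
#' `1 - (1 - R2) (n - 1) / (n - m - 1)` with `m` the rank of the centred
#' predictor matrix; rank-deficient predictor codings therefore give
#' identical results for any full-rank equivalent, with a warning when
#' columns are dropped by rank reduction.
#'
#' @param Y response matrix (samples x taxa), typically Hellinger state.
#' @param X predictor matrix or data frame (factors are expanded to
#'   indicator contrasts).
#' @return list with `r2`, `adj_r2`, `rank`.
#' @examples
#' Y <- hellinger_transform(matrix(rpois(60, 5), 12))
#' X <- circular_date_predictor(seq(10, 350, length.out = 12))
#' rda_adjusted_r2(Y, X)
#' @export
rda_adjusted_r2 <- function(Y, X) {
  X <- .as_model_matrix(X)
  if (nrow(as.matrix(Y)) != nrow(X)) stop("Y and X must have matching rows")
  if (nrow(X) <= qr(scale(X, center = TRUE, scale = FALSE))$rank + 1)
    stop("too few samples for the predictor rank")
  fit <- .mlr_r2(Y, X)
  ncol_centered <- ncol(X)
  if (fit$rank < ncol_centered)
    warning("rank-deficient predictors; effective rank ", fit$rank)
  list(r2 = fit$r2, adj_r2 = fit$adj, rank = fit$rank)
}

.as_model_matrix <- function(X) {
  if (is.data.frame(X) || is.factor(X) || is.character(X)) {
    df <- if (is.data.frame(X)) X else data.frame(x = X)
    mm <- stats::model.matrix(~ ., data = df)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  } else as.matrix(X)
}

#' Partition community variation between space and season
#'
#' Two-set variation partitioning by redundancy analysis: the adjusted R2
#' of the seasonal predictor alone (`a + b`), the station factor alone
#' (`b + c`), and both combined (`a + b + c`) yield the unique seasonal
#' fraction `a`, the unique spatial fraction `c`, the shared fraction `b`
#' and the residual `d = 1 - (a + b + c)`. Small negative adjusted
#' fractions are reported as computed — they carry no explanatory power
#' and are read as zero in displays.
#'
#' @param Y community matrix (samples x taxa), typically Hellinger state.
#' @param station factor (or coercible) of sampling stations, >= 2 levels.
#' @param date seasonal predictor matrix, e.g. [circular_date_predictor()]
#'   output, or a day-of-year vector (converted automatically).
#' @return object of class `"variation_partition"`: adjusted R2 of the
#'   three models and fractions `a`, `b`, `c`, `d` (identity
#'   `a + b + c + d = 1` holds by construction).
#' @export
variation_partition <- function(Y, station, date) {
  if (is.numeric(date) && is.null(dim(date)))
    date <- circular_date_predictor(date)
  station <- factor(station)
  if (nlevels(station) < 2) stop("station factor needs >= 2 levels")
  Xs <- .as_model_matrix(station)
  Xd <- as.matrix(date)

  adj_date <- .mlr_r2(Y, Xd)$adj
  adj_station <- .mlr_r2(Y, Xs)$adj
  adj_both <- .mlr_r2(Y, cbind(Xd, Xs))$adj

  a <- adj_both - adj_station
  c_ <- adj_both - adj_date
  b <- adj_date + adj_station - adj_both
  d <- 1 - adj_both
  structure(list(adj_date = adj_date, adj_station = adj_station,
                 adj_combined = adj_both,
                 fractions = c(a = a, b = b, c = c_, d = d)),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("Variation partitioning (adjusted R2)\n")
  cat(sprintf("  date [a+b]      %7.3f\n", x$adj_date))
  cat(sprintf("  station [b+c]   %7.3f\n", x$adj_station))
  cat(sprintf("  combined [a+b+c]%7.3f\n", x$adj_combined))
  f <- x$fractions
  disp <- pmax(f, 0)
  cat(sprintf("  unique date a = %.3f, shared b = %.3f, unique station c = %.3f, residual d = %.3f\n",
              f["a"], f["b"], f["c"], f["d"]))
  if (any(f < 0))
    cat("  (negative fractions carry no explanatory power; read as",
        paste(sprintf("%s=%.3f", names(disp)[f < 0], disp[f < 0]), collapse = ", "),
        "i.e. 0)\n")
  invisible(x)
}
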