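#' Coefficient of variation, in percent
#'
#' @param values numeric vector (at least 2 values, nonzero mean).
#' @return `100 * sd / mean` with the sample (n-1) standard deviation.
#' @examples
#' coefficient_of_variation(c(30, 35, 32))
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop("coefficient_of_variation() needs >= 2 non-missing values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Coefficient of variation from reported moments
#'
#' Same statistic as [coefficient_of_variation()] but computed from an
#' already-summarized mean and standard deviation, as when re-deriving the
#' relative variation printed for a cohort summary cell.
#'
#' @param mean,sd the cell's mean and sample standard deviation.
#' @return `100 * sd / mean`.
#' @examples
#' cv_percent(188.5, 19.7) # ~10 percent
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("coefficient of variation undefined for zero mean",
                           call. = FALSE)
  100 * sd / mean
}

#' Levene / Brown-Forsythe test of variance heterogeneity
#'
#' Tests equality of spread across k groups via a one-way ANOVA on the
#' absolute deviations from each group's centre. The default centre is the
#' group median (Brown-Forsythe variant, the default of the car package);
#' `center = "mean"` gives the original Levene test. The statistic is
#' W = ((N-k)/(k-1)) * sum_i n_i (Zbar_i - Zbar)^2 / sum_ij (Z_ij - Zbar_i)^2
#' with Z_ij = |x_ij - centre_i|, compared to F(k-1, N-k).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param center `"median"` (default) or `"mean"`.
#' @return list of class `levene_result`: `W`, `df1`, `df2`, `p`, `center`.
#' @examples
#' levene_test(list(c(1, 2, 3, 4), c(1, 3, 5, 7)))
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    stop("levene_test() needs a list of >= 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n_i))
  cfun <- if (center == "median") stats::median else mean
  z <- abs(y - ave(y, g, FUN = cfun))
  if (all(z == 0))
    stop("Levene statistic undefined: all groups have zero spread", call. = FALSE)
  if (sum((z - ave(z, g))^2) == 0) {
    # all absolute deviations equal within groups; if the group means of Z
    # also agree the data are perfectly homogeneous in spread (W = 0/0 -> 0)
    if (stats::var(tapply(z, g, mean)) > 0)
      stop("Levene statistic undefined: zero within-group spread of absolute deviations",
           call. = FALSE)
    return(structure(list(W = 0, df1 = nlevels(g) - 1L,
                          df2 = length(y) - nlevels(g), p = 1,
                          center = center),
                     class = "levene_result"))
  }
  lt <- car::leveneTest(y, g, center = cfun)
  structure(list(W = lt[1L, "F value"],
                 df1 = lt[1L, "Df"], df2 = lt[2L, "Df"],
                 p = lt[1L, "Pr(>F)"], center = center),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("Levene test (center = %s): W = %.4g, F(%d, %d), p = %.4g\n",
              x$center, x$W, x$df1, x$df2, x$p))
  invisible(x)
}

#' Cumulative flight-hour curve for one bird and season
#'
#' The step curve of cumulative migratory flight hours over the season's
#' flight nights (odd flights excluded): non-decreasing, flat through
#' stopovers, ending at the season's total flight hours.
#'
#' @param migration a [segment_migration()] result.
#' @param season `"autumn"` (segments 1-3) or `"spring"` (segments 4-6).
#' @return `data.frame` with `date` and `cumulative_h`, one row per flight
#'   night; zero rows if the bird has no flights in that season.
#' @export
cumulative_curve <- function(migration, season = c("autumn", "spring")) {
  stopifnot(inherits(migration, "migration"))
  season <- match.arg(season)
  labs <- if (season == "autumn") c("1", "2", "3") else c("4", "5", "6")
  fl <- migration$flights[migration$flights$label %in% labs, , drop = FALSE]
  if (nrow(fl) == 0L)
    return(data.frame(date = as.Date(character(0)), cumulative_h = numeric(0)))
  fl <- fl[order(fl$night), ]
  data.frame(date = fl$night, cumulative_h = cumsum(fl$duration_h))
}
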