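#' Center each covariate group at its bivariate mean
#'
#' First step of the slope-trend permutation test: every group (one per
#' covariate value, e.g. rearing temperature) is translated so its
#' bivariate mean is exactly (0, 0).  Centering leaves each group's SMA
#' slope unchanged and makes the pooled points exchangeable under the
#' null hypothesis that plasticity does not depend on the covariate.
#'
#' @param groups named list; names are numeric covariate values, each
#'   element a two-column matrix (or a list with `x` and `y`) of log
#'   sizes.
#' @return A list with `xy` (pooled centered matrix), `group` (integer
#'   index of the source group per row), `covariate` (numeric value per
#'   group) and `sizes`.
#' @export
center_groups <- function(groups) {
  groups <- lapply(groups, as_xy)
  if (any(vapply(groups, nrow, 0L) < 2))
    stop("every group needs at least 2 points", call. = FALSE)
  centered <- lapply(groups, function(m) sweep(m, 2, colMeans(m)))
  sizes <- vapply(centered, nrow, 0L)
  list(xy = do.call(rbind, centered),
       group = rep(seq_along(centered), sizes),
       covariate = as.numeric(names(groups)),
       sizes = sizes)
}

as_xy <- function(g) {
  m <- if (is.list(g) && !is.data.frame(g)) cbind(g$x, g$y) else as.matrix(g)
  if (ncol(m) != 2 || anyNA(m))
    stop("each group must be complete bivariate data", call. = FALSE)
  unname(m)
}

#' Trend of SMA slope on a covariate
#'
#' Fits the SMA slope within each covariate group and returns the
#' ordinary-least-squares coefficient of those slopes regressed on the
#' covariate values — the quantity whose null distribution the
#' permutation test resamples.
#'
#' @inheritParams center_groups
#' @param permissive with fewer than 3 covariate values the OLS
#'   coefficient is not a meaningful trend; by default this is an error,
#'   with `permissive = TRUE` a 2-group "trend" is returned with a
#'   warning.
#' @return The OLS regression coefficient (slope per covariate unit).
#' @export
slope_trend <- function(groups, permissive = FALSE) {
  if (length(groups) < 3) {
    if (!permissive || length(groups) < 2)
      stop("need at least 3 covariate values to regress slopes on",
           call. = FALSE)
    warning("trend over only 2 covariate values", call. = FALSE)
  }
  covariate <- as.numeric(names(groups))
  if (anyNA(covariate))
    stop("group names must be numeric covariate values", call. = FALSE)
  slopes <- vapply(groups, function(g) {
    m <- as_xy(g)
    b <- slope_signed(m[, 1], m[, 2])
    if (is.na(b)) stop("degenerate group (zero variance or zero ",
                       "correlation)", call. = FALSE)
    b
  }, 0)
  ols_slope(covariate, slopes)
}

ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Permutation test for a trend in SMA slope along a covariate
#'
#' Tests whether organ plasticity (the SMA slope of log organ on log body
#' size) changes systematically with a covariate such as rearing
#' temperature.  The observed statistic `b_obs` is the OLS coefficient of
#' per-group SMA slope on covariate value.  Under the null the centered
#' points are exchangeable across groups, so each permutation shuffles
#' the pooled group-centered points into new groups of the original sizes
#' without replacement (covariate values stay attached to the groups, not
#' the points), refits the per-group SMA slopes and recomputes the trend
#' coefficient.  The default lower-tail p-value is the proportion of
#' permuted coefficients less than or equal to the observed one (ties
#' count as "as extreme"); the add-one estimate `(k + 1)/(n_perm + 1)` is
#' reported alongside since the raw proportion can be zero.
#'
#' A permuted allocation that produces a degenerate group (zero variance
#' on an axis, or exactly zero correlation) has no defined SMA slope and
#' is redrawn; the number of redraws is reported for audit.
#'
#' @inheritParams center_groups
#' @param tail `"lower"` (default, matching a predicted decrease),
#'   `"upper"`, or `"two_sided"` (uses `|b_perm| >= |b_obs|`).
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory; the test is resampling-based).
#' @return An object of class `"perm_trend"`: `observed_b`, `permuted_b`,
#'   `n_perm`, `p_value` (raw proportion), `p_value_add_one`, `tail`,
#'   `seed`, `group_sizes`, `redraws`.
#' @export
permutation_trend_test <- function(groups,
                                   tail = c("lower", "upper", "two_sided"),
                                   n_perm = 1000, seed = NULL) {
  tail <- match.arg(tail)
  if (is.null(seed))
    stop("`seed` is required (reproducibility contract)", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  observed_b <- slope_trend(groups)
  cg <- center_groups(groups)
  ntot <- nrow(cg$xy)
  bounds <- c(0L, cumsum(cg$sizes))
  k <- length(cg$sizes)

  set.seed(as.integer(seed))
  permuted_b <- numeric(n_perm)
  redraws <- 0L
  max_redraws <- 1000L + 10L * n_perm
  p <- 1L
  while (p <= n_perm) {
    idx <- sample.int(ntot)
    slopes <- numeric(k)
    ok <- TRUE
    for (g in seq_len(k)) {
      i <- idx[(bounds[g] + 1L):bounds[g + 1L]]
      b <- slope_signed(cg$xy[i, 1], cg$xy[i, 2])
      if (is.na(b)) { ok <- FALSE; break }
      slopes[g] <- b
    }
    if (!ok) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many degenerate permutations; data are close to ",
             "degenerate", call. = FALSE)
      next
    }
    permuted_b[p] <- ols_slope(cg$covariate, slopes)
    p <- p + 1L
  }
  extreme <- switch(tail,
    lower = permuted_b <= observed_b,
    upper = permuted_b >= observed_b,
    two_sided = abs(permuted_b) >= abs(observed_b))
  structure(list(observed_b = observed_b, permuted_b = permuted_b,
                 n_perm = n_perm, p_value = mean(extreme),
                 p_value_add_one = (sum(extreme) + 1) / (n_perm + 1),
                 tail = tail, seed = as.integer(seed),
                 group_sizes = stats::setNames(cg$sizes,
                                               names(groups)),
                 redraws = redraws),
            class = "perm_trend")
}

#' @export
print.perm_trend <- function(x, digits = 4, ...) {
  cat("Permutation trend test (", x$tail, " tail, ", x$n_perm,
      " permutations)\n  observed trend coefficient b = ",
      format(x$observed_b, digits = digits),
      "\n  p = ", format(x$p_value, digits = digits),
      " (add-one ", format(x$p_value_add_one, digits = digits), ")\n",
      sep = "")
  if (x$redraws > 0)
    cat("  ", x$redraws, " degenerate permutation(s) redrawn\n", sep = "")
  invisible(x)
}

#' @export
plot.perm_trend <- function(x, ...) {
  graphics::hist(x$permuted_b, breaks = 30,
                 main = "Permutation null distribution",
                 xlab = "trend coefficient under the null", ...)
  graphics::abline(v = x$observed_b, lwd = 2)
  invisible(x)
}

#' Split an allometry dataset into covariate groups for the trend test
#'
#' Convenience bridge from an [allometry_data] object to the named-list
#' interface of [permutation_trend_test()].
#'
#' @param data a log-scale [allometry_data] object with a numeric
#'   condition column.
#' @param organ organ name (y axis).
#' @param reference `"body"` or organ name (x axis).
#' @param condition column holding the numeric covariate.
#' @return A named list of two-column matrices, one per covariate value.
#' @export
split_by_condition <- function(data, organ, reference = "body",
                               condition = "temperature") {
  stopifnot(inherits(data, "allometry_data"))
  cond <- data[[condition]]
  if (is.null(cond)) stop("no `", condition, "` column", call. = FALSE)
  xcol <- if (identical(reference, "body")) "body_size" else reference
  keep <- !is.na(cond) & !is.na(data[[xcol]]) & !is.na(data[[organ]])
  sp <- split(data.frame(x = data[[xcol]][keep], y = data[[organ]][keep]),
              cond[keep])
  lapply(sp, as.matrix)
}
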