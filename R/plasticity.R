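#' Allometric coefficient of an organ against a reference trait
#'
#' Fits the SMA of log organ size on log reference size (body size by
#' default).  Under nutrition-driven size variation the fitted slope is
#' the organ's nutritional plasticity relative to the reference: slope 1
#' means the organ scales proportionally with the reference, a shallow
#' slope means the organ is buffered against nutritional variation.
#'
#' @param data a log-scale [allometry_data] object.
#' @param organ organ name (must be in the dataset's organ vocabulary).
#' @param reference `"body"` (default) or another organ name.
#' @param alpha nominal error rate for the slope CI.
#' @return An object of class `"plasticity_estimate"`: `organ`,
#'   `reference`, `fit` (an [sma()] object) and `n_pairs`, the number of
#'   complete (organ, reference) pairs used after pairwise exclusion of
#'   missing measurements.
#' @export
allometric_coefficient <- function(data, organ, reference = "body",
                                   alpha = 0.05) {
  stopifnot(inherits(data, "allometry_data"))
  if (attr(data, "size_scale") != "log")
    stop("allometric coefficients are defined on log-scale data; ",
         "call log_transform() first", call. = FALSE)
  p <- complete_pairs(data, organ, reference)
  if (p$n < 3)
    stop("fewer than 3 complete (", organ, ", ", reference, ") pairs",
         call. = FALSE)
  structure(list(organ = organ, reference = reference,
                 fit = sma.default(p$x, p$y, alpha = alpha),
                 n_pairs = p$n),
            class = "plasticity_estimate")
}

#' @export
print.plasticity_estimate <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Allometric coefficient: ", x$organ, " ~ ", x$reference,
      " (n = ", x$n_pairs, ")\n  b = ",
      format(f$slope, digits = digits), " [",
      format(f$ci[1], digits = digits), ", ",
      format(f$ci[2], digits = digits), "]\n", sep = "")
  invisible(x)
}

#' Compare nutritional plasticity across organs
#'
#' Estimates the allometric coefficient of each organ against a common
#' reference and tests every pair of organs for slope homogeneity with
#' [common_slope_test()].  Pairwise p-values are Holm-adjusted to control
#' the family-wise error rate over the comparisons requested; unadjusted
#' values are reported alongside.
#'
#' @inheritParams allometric_coefficient
#' @param organs character vector of at least two organ names.
#' @param method,n_perm,seed passed to [common_slope_test()].
#' @return An object of class `"organ_plasticity"`: a list with
#'   `estimates` (named list of [allometric_coefficient()] results) and
#'   `comparisons` (data frame with one row per organ pair: statistic,
#'   common slope, `p_value`, `p_adjusted`).
#' @export
compare_organ_plasticity <- function(data, organs, reference = "body",
                                     alpha = 0.05,
                                     method = c("lr", "permutation"),
                                     n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  if (length(organs) < 2)
    stop("need at least 2 organs to compare", call. = FALSE)
  estimates <- stats::setNames(
    lapply(organs, allometric_coefficient, data = data,
           reference = reference, alpha = alpha), organs)
  pairs <- utils::combn(sort(organs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    pa <- complete_pairs(data, a, reference)
    pb <- complete_pairs(data, b, reference)
    tst <- common_slope_test(c(pa$x, pb$x), c(pa$y, pb$y),
                             rep(c(a, b), c(pa$n, pb$n)),
                             alpha = alpha, method = method,
                             n_perm = n_perm, seed = seed)
    data.frame(organ_a = a, organ_b = b,
               common_slope = tst$common_slope,
               statistic = tst$statistic, p_value = tst$p_value)
  })
  comparisons <- do.call(rbind, rows)
  comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value,
                                            method = "holm")
  structure(list(estimates = estimates, comparisons = comparisons,
                 reference = reference, method = method),
            class = "organ_plasticity")
}

#' @export
print.organ_plasticity <- function(x, digits = 4, ...) {
  cat("Organ plasticity against", x$reference, "\n")
  for (e in x$estimates)
    cat(sprintf("  %-10s b = %s [%s, %s]\n", e$organ,
                format(e$fit$slope, digits = digits),
                format(e$fit$ci[1], digits = digits),
                format(e$fit$ci[2], digits = digits)))
  cat("Pairwise common-slope tests (Holm-adjusted):\n")
  print(x$comparisons, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Proportional size reduction of an organ under a perturbation
#'
#' Compares raw-scale group mean sizes of one organ between a control and
#' a perturbed dataset and reports the proportional reduction
#' `1 - perturbed/control`, with a seeded nonparametric bootstrap
#' (percentile) interval obtained by resampling individuals within each
#' group.
#'
#' @param control,perturbed raw-scale [allometry_data] objects.
#' @param organ organ name present in both datasets.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (mandatory; the interval is resampling-based).
#' @param alpha interval error rate.
#' @return An object of class `"effect_size"` with the group means, the
#'   proportional reduction, the bootstrap CI and the group sizes.
#' @export
relative_size_effect <- function(control, perturbed, organ,
                                 n_boot = 2000, seed = NULL,
                                 alpha = 0.05) {
  for (d in list(control, perturbed)) {
    stopifnot(inherits(d, "allometry_data"))
    if (attr(d, "size_scale") != "raw")
      stop("effect sizes are computed on raw-scale data", call. = FALSE)
    if (!organ %in% attr(d, "organs"))
      stop("organ `", organ, "` absent from a dataset", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is required for the bootstrap interval",
                          call. = FALSE)
  a <- control[[organ]]; a <- a[!is.na(a)]
  b <- perturbed[[organ]]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 measured individuals per group", call. = FALSE)
  est <- 1 - mean(b) / mean(a)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(i) {
    1 - mean(sample(b, replace = TRUE)) / mean(sample(a, replace = TRUE))
  }, 0)
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  structure(list(organ = organ, control_mean = mean(a),
                 perturbed_mean = mean(b), proportional_reduction = est,
                 ci = ci, n_control = length(a), n_perturbed = length(b),
                 n_boot = n_boot, seed = as.integer(seed), alpha = alpha),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, digits = 4, ...) {
  cat("Relative size effect on ", x$organ, ": reduction = ",
      format(x$proportional_reduction, digits = digits), " [",
      format(x$ci[1], digits = digits), ", ",
      format(x$ci[2], digits = digits), "] (bootstrap, n = ",
      x$n_control, "/", x$n_perturbed, ")\n", sep = "")
  invisible(x)
}

#' Permutation test for organ-specific perturbation effects
#'
#' Tests whether a perturbation (starvation, an IIS mutation, ...) reduces
#' the size of organ A by a different proportion than organ B — the
#' organ-by-treatment interaction.  The observed interaction is the
#' difference of mean log-size differences,
#' `(mean log A_ctrl - mean log A_pert) - (mean log B_ctrl - mean log
#' B_pert)`, computed on individuals that carry both organ measurements;
#' the null distribution is built by permuting the treatment labels of
#' whole individuals.  Log differences are used for variance
#' stabilization; equal proportional change in the two organs gives an
#' interaction of exactly zero.
#'
#' @param control,perturbed raw-scale [allometry_data] objects.
#' @param organ_a,organ_b organ names present in both datasets.
#' @param n_perm number of label permutations (at least 100 in strict
#'   mode).
#' @param seed integer seed (mandatory).
#' @param strict if `TRUE` (default), `n_perm < 100` is an error rather
#'   than a warning.
#' @return An object of class `"differential_effect"` with the observed
#'   interaction on the log scale, the permuted interactions, the raw
#'   two-sided permutation p-value and the add-one estimate.
#' @export
differential_effect_test <- function(control, perturbed, organ_a, organ_b,
                                     n_perm = 1000, seed = NULL,
                                     strict = TRUE) {
  for (d in list(control, perturbed)) {
    stopifnot(inherits(d, "allometry_data"))
    if (attr(d, "size_scale") != "raw")
      stop("pass raw-scale data; logs are taken internally", call. = FALSE)
    for (org in c(organ_a, organ_b))
      if (!org %in% attr(d, "organs"))
        stop("organ `", org, "` absent from a dataset", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is required for the permutation test",
                          call. = FALSE)
  if (n_perm < 100) {
    msg <- "`n_perm` < 100 gives a very coarse p-value"
    if (strict) stop(msg, " (strict mode)", call. = FALSE)
    warning(msg, call. = FALSE)
  }
  take <- function(d) {
    la <- log(d[[organ_a]]); lb <- log(d[[organ_b]])
    ok <- !is.na(la) & !is.na(lb)
    cbind(a = la[ok], b = lb[ok])
  }
  mc <- take(control); mp <- take(perturbed)
  n1 <- nrow(mc); n2 <- nrow(mp)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 individuals with both organs per group",
         call. = FALSE)
  pool <- rbind(mc, mp)
  interaction_stat <- function(is_ctrl) {
    d <- colMeans(pool[is_ctrl, , drop = FALSE]) -
         colMeans(pool[!is_ctrl, , drop = FALSE])
    d[["a"]] - d[["b"]]
  }
  obs <- interaction_stat(seq_len(n1 + n2) <= n1)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) {
    lab <- logical(n1 + n2)
    lab[sample.int(n1 + n2, n1)] <- TRUE
    interaction_stat(lab)
  }, 0)
  structure(list(organ_a = organ_a, organ_b = organ_b,
                 interaction = obs, permuted = perm,
                 p_value = mean(abs(perm) >= abs(obs)),
                 p_value_add_one =
                   (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = as.integer(seed),
                 n_control = n1, n_perturbed = n2),
            class = "differential_effect")
}

#' @export
print.differential_effect <- function(x, digits = 4, ...) {
  cat("Differential perturbation effect: ", x$organ_a, " vs ", x$organ_b,
      "\n  interaction (log scale) = ",
      format(x$interaction, digits = digits),
      "\n  permutation p = ", format(x$p_value, digits = digits),
      " (add-one ", format(x$p_value_add_one, digits = digits), ", ",
      x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Quadratic trend of plasticity on a covariate
#'
#' Least-squares fit of `y = a0 + a1 x + a2 x^2`, used for relating organ
#' plasticity to an expression level where the response is expected to be
#' hump-shaped.  Reports the coefficients, the residual sum of squares, a
#' pointwise confidence band and the location of the fitted extremum.
#'
#' @param x,y numeric vectors (e.g. expression level and per-individual or
#'   per-group plasticity values).
#' @param alpha error rate for the pointwise band.
#' @return An object of class `"quadratic_trend"` with `coefficients`
#'   (a0, a1, a2), `n`, `rss`, `extremum_x` (`NA` if the fit is linear),
#'   `band` (data frame `x`, `fit`, `lower`, `upper` on a 100-point grid)
#'   and the underlying `lm` model.
#' @export
quadratic_trend <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("quadratic trend needs at least 4 points", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("degenerate design: need at least 3 distinct x values",
         call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  grid <- data.frame(x = seq(min(x), max(x), length.out = 100))
  pr <- stats::predict(fit, newdata = grid, interval = "confidence",
                       level = 1 - alpha)
  structure(list(coefficients = c(a0 = cf[1], a1 = cf[2], a2 = cf[3]),
                 n = n, rss = sum(stats::residuals(fit)^2),
                 extremum_x = if (abs(cf[3]) > 0) -cf[2] / (2 * cf[3])
                              else NA_real_,
                 band = data.frame(x = grid$x, fit = pr[, "fit"],
                                   lower = pr[, "lwr"],
                                   upper = pr[, "upr"]),
                 alpha = alpha, model = fit),
            class = "quadratic_trend")
}

#' @export
print.quadratic_trend <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Quadratic trend (n = ", x$n, "): y = ",
      format(cf[1], digits = digits), " + ",
      format(cf[2], digits = digits), " x + ",
      format(cf[3], digits = digits), " x^2\n  rss = ",
      format(x$rss, digits = digits), ", extremum at x = ",
      format(x$extremum_x, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
plot.quadratic_trend <- function(x, ...) {
  m <- x$model$model
  graphics::plot(m$x, m$y, xlab = "x", ylab = "y", ...)
  graphics::lines(x$band$x, x$band$fit)
  graphics::lines(x$band$x, x$band$lower, lty = 2)
  graphics::lines(x$band$x, x$band$upper, lty = 2)
  invisible(x)
}
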