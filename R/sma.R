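#' Standardized major axis (SMA) line fitting
#'
#' Fits the standardized major axis to a bivariate sample.  The SMA is the
#' model-II line whose slope magnitude is `sd(y)/sd(x)` with the sign of
#' the Pearson correlation; it is the appropriate estimator for an
#' allometric scaling relationship because both traits carry biological and
#' measurement error, so neither axis can be treated as fixed.  On log-log
#' size data the fitted slope is the allometric coefficient *b*: `b = 1`
#' is isometry (proportional scaling), `b < 1` means the y-trait is less
#' plastic than the x-trait.
#'
#' The confidence interval for the slope uses the standard
#' correlation-based construction
#' `B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2)`,
#' `CI = b * (sqrt(B + 1) +/- sqrt(B))`.
#'
#' @param x for the default method, numeric vector of the reference trait
#'   (conventionally log body size); for the formula method, a formula
#'   `y ~ x`.
#' @param y numeric vector of the dependent trait (same length as `x`).
#' @param alpha nominal error rate for the confidence interval.
#' @param data data frame in which a formula is evaluated.
#' @param ... passed between methods.
#' @return An object of class `"sma"`: a list with elements `n`, `slope`,
#'   `intercept`, `r`, `ci` (length-2), `alpha`, plus the data used.
#' @examples
#' fit <- sma(x = 1:5, y = 2 * (1:5) + 1)
#' coef(fit)
#' @export
sma <- function(x, ...) UseMethod("sma")

#' @rdname sma
#' @export
sma.default <- function(x, y, alpha = 0.05, ...) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: SMA fit needs at least 3 points",
                  call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate data: zero variance on ",
         if (sx == 0) "x" else "y", " axis", call. = FALSE)
  r <- stats::cor(x, y)
  if (r == 0)
    stop("degenerate slope sign: correlation is exactly zero, so the SMA ",
         "slope sign is undefined; inspect the data before fitting",
         call. = FALSE)
  b <- sign(r) * sy / sx
  a <- mean(y) - b * mean(x)
  # exactly collinear data get a degenerate interval (1 - r^2 is then
  # pure floating-point residue)
  one_minus_r2 <- if (1 - r^2 < 1e-14) 0 else 1 - r^2
  B <- stats::qf(1 - alpha, 1, n - 2) * one_minus_r2 / (n - 2)
  ci <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  structure(list(n = n, slope = b, intercept = a, r = r,
                 ci = ci, alpha = alpha, x = x, y = y),
            class = "sma")
}

#' @rdname sma
#' @export
sma.formula <- function(x, data = parent.frame(), alpha = 0.05, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.omit)
  if (ncol(mf) != 2)
    stop("formula must be of the form y ~ x", call. = FALSE)
  fit <- sma.default(mf[[2]], mf[[1]], alpha = alpha)
  fit$call <- match.call()
  fit
}

#' @export
print.sma <- function(x, digits = 4, ...) {
  cat("Standardized major axis fit (n = ", x$n, ")\n", sep = "")
  cat("  slope     ", format(x$slope, digits = digits),
      "   ", format(100 * (1 - x$alpha)), "% CI [",
      format(x$ci[1], digits = digits), ", ",
      format(x$ci[2], digits = digits), "]\n", sep = "")
  cat("  intercept ", format(x$intercept, digits = digits),
      "\n  r         ", format(x$r, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sma <- function(object, ...) {
  out <- object[c("n", "slope", "intercept", "r", "ci", "alpha")]
  out$r_squared <- object$r^2
  # departure from isometry: does the CI exclude slope 1?
  out$isometry_excluded <- object$ci[1] > 1 || object$ci[2] < 1
  class(out) <- "summary.sma"
  out
}

#' @export
print.summary.sma <- function(x, digits = 4, ...) {
  cat("SMA fit: n =", x$n, "\n")
  cat("  allometric coefficient b =", format(x$slope, digits = digits),
      sprintf("[%s, %s] (%d%% CI)\n", format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits),
              round(100 * (1 - x$alpha))))
  cat("  intercept =", format(x$intercept, digits = digits),
      " r^2 =", format(x$r_squared, digits = digits), "\n")
  cat("  isometry (b = 1)",
      if (x$isometry_excluded) "excluded" else "not excluded",
      "by the CI\n")
  invisible(x)
}

#' @export
coef.sma <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.sma <- function(object, parm = "slope", level = NULL, ...) {
  if (!is.null(level) && abs((1 - level) - object$alpha) > 1e-12) {
    object <- sma.default(object$x, object$y, alpha = 1 - level)
  }
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("slope",
                              paste0(100 * c(object$alpha / 2,
                                             1 - object$alpha / 2), " %")))
  m
}

#' @export
predict.sma <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' @export
fitted.sma <- function(object, ...) predict.sma(object)

#' @export
residuals.sma <- function(object, ...) object$y - fitted.sma(object)

#' @export
plot.sma <- function(x, xlab = "x (log size)", ylab = "y (log size)", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

# signed sd-ratio slope, minimal checks -- hot path for permutation loops;
# callers guarantee length >= 2.  Returns NA if degenerate (zero variance
# or exactly zero correlation).
slope_signed <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- stats::cor(x, y)
  if (is.na(r) || r == 0) return(NA_real_)
  sign(r) * sy / sx
}
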