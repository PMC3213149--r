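#' Translate bivariate data so a subset's mean hits a reference point
#'
#' Applies one rigid translation to every row of `xy` such that the
#' bivariate mean of the rows selected by `mask` becomes exactly
#' `reference_mean`.  Used to pin each rearing condition's un-starved
#' control mean onto the reference condition's before rotating.
#'
#' @param xy two-column numeric matrix of (log reference, log organ)
#'   sizes.
#' @param mask logical vector selecting the mean-defining rows.
#' @param reference_mean length-2 numeric target point.
#' @return A list with `xy` (translated matrix) and `offset` (the length-2
#'   translation applied).
#' @export
translate_to_anchor <- function(xy, mask, reference_mean) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, length(reference_mean) == 2)
  if (!any(mask)) stop("empty mean-defining subset", call. = FALSE)
  offset <- as.numeric(reference_mean) -
    colMeans(xy[mask, , drop = FALSE])
  list(xy = sweep(xy, 2, -offset), offset = unname(offset))
}

#' Rotate bivariate data about an anchor to match a target slope
#'
#' Rotates every point rigidly about `anchor` by
#' `theta = atan(target_slope) - atan(current_slope)`.  A rigid rotation
#' maps the slope of a perfectly collinear set exactly; for a noisy cloud
#' the SMA slope after rotation differs slightly from the target, so when
#' `control_mask` is supplied the rotation angle is refined by a bounded
#' fixed-point iteration until the control subset's re-fitted SMA slope
#' matches `target_slope` to `tol`.  The composed map is still a single
#' rigid rotation, so distances to the anchor are preserved exactly.
#'
#' @param xy two-column numeric matrix in log-size coordinates.
#' @param anchor length-2 numeric rotation center.
#' @param current_slope slope of the (control) scaling relationship before
#'   rotation.
#' @param target_slope slope it should have afterwards.
#' @param control_mask optional logical vector: rows whose SMA slope
#'   defines convergence.  When `NULL` a single exact-angle rotation is
#'   performed.
#' @param tol convergence tolerance on the control slope.
#' @param max_iter iteration cap for the refinement.
#' @return A list with `xy` (rotated matrix), `angle` (total rotation,
#'   radians), `iterations`, and `slope_after` (control slope after
#'   rotation; `NA` without a `control_mask`).
#' @export
rotate_about_anchor <- function(xy, anchor, current_slope, target_slope,
                                control_mask = NULL, tol = 1e-9,
                                max_iter = 100) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, length(anchor) == 2)
  if (!is.finite(current_slope) || !is.finite(target_slope))
    stop("slopes must be finite", call. = FALSE)
  if (any(!is.finite(anchor))) stop("anchor must be finite", call. = FALSE)

  apply_rot <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    sweep(sweep(xy, 2, anchor) %*% t(R), 2, -anchor)
  }
  theta <- atan(target_slope) - atan(current_slope)
  out <- apply_rot(theta)
  iterations <- 0L
  slope_after <- NA_real_
  if (!is.null(control_mask)) {
    repeat {
      slope_after <- slope_signed(out[control_mask, 1], out[control_mask, 2])
      if (is.na(slope_after))
        stop("degenerate control subset during rotation", call. = FALSE)
      if (abs(slope_after - target_slope) <= tol || iterations >= max_iter)
        break
      theta <- theta + atan(target_slope) - atan(slope_after)
      out <- apply_rot(theta)
      iterations <- iterations + 1L
    }
    if (abs(slope_after - target_slope) > tol)
      warning("rotation did not reach target slope within tolerance",
              call. = FALSE)
  }
  list(xy = out, angle = theta, iterations = iterations,
       slope_after = slope_after)
}

#' Normalize scaling relationships across rearing conditions
#'
#' Makes one organ-vs-reference scaling relationship comparable across the
#' levels of a condition (rearing temperature in the motivating design) by
#' a rigid two-step transform per non-reference condition: (1) translate
#' all of the condition's rows so the bivariate mean of its anchor subset
#' (the un-starved controls) coincides with the reference condition's
#' anchor mean; (2) rotate all of the condition's rows about that anchor
#' so the control subset's SMA slope equals the reference condition's
#' control slope.  Experimental rows ride along under exactly the same
#' rigid motions as their controls, so their positions relative to the
#' control scaling relationship are preserved.  The reference condition is
#' returned untouched.
#'
#' Both steps are rigid, all within-condition pairwise distances are
#' preserved, and the procedure is idempotent: re-normalizing normalized
#' data yields identity transforms.
#'
#' @param data a log-scale [allometry_data] object.
#' @param organ organ whose scaling relationship is normalized (the y
#'   axis).
#' @param reference reference trait for the x axis (`"body"` or an organ
#'   name).
#' @param condition name of the column holding the condition labels
#'   (default `"temperature"`).
#' @param control logical vector (length `nrow(data)`) flagging control
#'   rows, which define the slope in every condition.
#' @param anchor logical vector flagging the rows whose bivariate mean is
#'   the anchor (default: the control rows; pass e.g. control & fed for
#'   the un-starved controls).
#' @param reference_condition the condition level left untouched.
#' @param tol slope-matching tolerance.
#' @return A list with `data` (the normalized dataset) and `transforms`,
#'   a named list of `anchor_transform` records (one per non-reference
#'   condition) holding the anchor, translation, rotation angle and the
#'   control slopes before/after for audit.
#' @export
normalize_across_conditions <- function(data, organ, reference = "body",
                                        condition = "temperature",
                                        control, anchor = control,
                                        reference_condition,
                                        tol = 1e-9) {
  stopifnot(inherits(data, "allometry_data"))
  if (attr(data, "size_scale") != "log")
    stop("normalization acts in log-size coordinates; call ",
         "log_transform() first", call. = FALSE)
  cond <- data[[condition]]
  if (is.null(cond)) stop("no `", condition, "` column", call. = FALSE)
  stopifnot(length(control) == nrow(data), length(anchor) == nrow(data))
  if (!reference_condition %in% cond)
    stop("reference condition `", reference_condition,
         "` not present", call. = FALSE)

  xcol <- if (identical(reference, "body")) "body_size" else reference
  xy <- cbind(data[[xcol]], data[[organ]])
  if (anyNA(xy))
    stop("missing values in (", reference, ", ", organ,
         ") are not supported by the normalization", call. = FALSE)

  ref_rows <- cond == reference_condition
  ctrl_fit_rows <- function(rows) {
    m <- rows & control
    if (sum(m) < 3) stop("fewer than 3 control rows in a condition",
                         call. = FALSE)
    m
  }
  anchor_rows <- function(rows) {
    m <- rows & anchor
    if (sum(m) < 3)
      stop("anchor-defining subset has fewer than 3 rows in a condition",
           call. = FALSE)
    m
  }
  rm <- ctrl_fit_rows(ref_rows)
  ref_slope <- slope_signed(xy[rm, 1], xy[rm, 2])
  if (is.na(ref_slope)) stop("degenerate control fit in the reference ",
                             "condition", call. = FALSE)
  ra <- anchor_rows(ref_rows)
  ref_anchor <- colMeans(xy[ra, , drop = FALSE])

  transforms <- list()
  for (lev in setdiff(unique(cond[!is.na(cond)]), reference_condition)) {
    rows <- !is.na(cond) & cond == lev
    sub <- xy[rows, , drop = FALSE]
    ctrl_sub <- control[rows]
    anch_sub <- anchor[rows]
    if (sum(anch_sub) < 1) stop("empty anchor subset in condition ", lev,
                                call. = FALSE)
    if (sum(ctrl_sub) < 3) stop("fewer than 3 control rows in condition ",
                                lev, call. = FALSE)
    tr <- translate_to_anchor(sub, anch_sub, ref_anchor)
    before <- slope_signed(tr$xy[ctrl_sub, 1], tr$xy[ctrl_sub, 2])
    if (is.na(before)) stop("degenerate control fit in condition ", lev,
                            call. = FALSE)
    rot <- rotate_about_anchor(tr$xy, ref_anchor, before, ref_slope,
                               control_mask = ctrl_sub, tol = tol)
    xy[rows, ] <- rot$xy
    transforms[[as.character(lev)]] <- structure(
      list(anchor = unname(ref_anchor), translation = tr$offset,
           rotation_angle = rot$angle, iterations = rot$iterations,
           source_label = lev, reference_label = reference_condition,
           control_slope_before = before,
           control_slope_after = rot$slope_after,
           reference_slope = ref_slope),
      class = "anchor_transform")
  }
  out <- as.data.frame(data)
  out[[xcol]] <- xy[, 1]
  out[[organ]] <- xy[, 2]
  list(data = allometry_data(out, organs = attr(data, "organs"),
                             size_scale = "log",
                             log_base = attr(data, "log_base")),
       transforms = transforms)
}

#' @export
print.anchor_transform <- function(x, digits = 6, ...) {
  cat("Anchor transform ", x$source_label, " -> ", x$reference_label,
      "\n  translation (", format(x$translation[1], digits = digits), ", ",
      format(x$translation[2], digits = digits), "), rotation ",
      format(x$rotation_angle, digits = digits), " rad (",
      x$iterations, " refinement iterations)\n  control slope ",
      format(x$control_slope_before, digits = digits), " -> ",
      format(x$control_slope_after, digits = digits), " (target ",
      format(x$reference_slope, digits = digits), ")\n", sep = "")
  invisible(x)
}
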