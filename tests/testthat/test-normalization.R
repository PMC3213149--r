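# three synthetic temperature conditions with distinct control means and
# slopes, experimental rows riding along; returns a log-scale dataset
make_conditions <- function(seed, n = 40) {
  set.seed(seed)
  rows <- list()
  cfg <- list(`17` = list(mu = c(4.6, 3.4), b = 1.15),
              `23` = list(mu = c(5.0, 4.0), b = 1.00),
              `25` = list(mu = c(5.3, 4.5), b = 0.85))
  for (tmp in names(cfg)) {
    p <- cfg[[tmp]]
    for (role in c("control", "experimental")) {
      z <- rnorm(n, p$mu[1], 0.25)
      x <- z + rnorm(n, 0, 0.08)
      y <- p$mu[2] + p$b * (z - p$mu[1]) + rnorm(n, 0, p$b * 0.08) +
        if (role == "experimental") -0.15 else 0
      rows[[length(rows) + 1L]] <- data.frame(
        body_size = x, wing = y, temperature = as.numeric(tmp),
        group = role, treatment = "fed")
    }
  }
  allometry_data(do.call(rbind, rows), organs = "wing",
                 size_scale = "log", log_base = exp(1))
}

test_that("translation pins the subset mean exactly and is rigid", {
  set.seed(1)
  xy <- matrix(rnorm(40), ncol = 2)
  mask <- c(rep(TRUE, 8), rep(FALSE, 12))
  target <- c(2.5, -1)
  tr <- translate_to_anchor(xy, mask, target)
  expect_equal(colMeans(tr$xy[mask, ]), target, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.vector(dist(tr$xy)), as.vector(dist(xy)),
               tolerance = 1e-12)
  # already on target -> zero offset
  tr2 <- translate_to_anchor(tr$xy, mask, target)
  expect_equal(tr2$offset, c(0, 0), tolerance = 1e-12)
  expect_error(translate_to_anchor(xy, rep(FALSE, 20), target), "empty")
})

test_that("rotation about the anchor does exact geometry", {
  # collinear slope-1 points rotated to slope 0 land on a horizontal line
  anchor <- c(1, 1)
  xy <- cbind(seq(0, 2, 0.5), seq(0, 2, 0.5))
  rot <- rotate_about_anchor(xy, anchor, current_slope = 1,
                             target_slope = 0)
  expect_equal(rot$xy[, 2], rep(1, 5), tolerance = 1e-12)
  # identity when target equals current
  rid <- rotate_about_anchor(xy, anchor, 1, 1)
  expect_equal(rid$angle, 0)
  expect_equal(rid$xy, xy, tolerance = 1e-15)
  expect_error(rotate_about_anchor(xy, anchor, Inf, 1), "finite")
})

test_that("refined rotation hits the target SMA slope on a noisy cloud", {
  set.seed(5)
  p <- sim_sma_pair(50, b = 1.3, mu = 0, v = 0.4, s = 0.1)
  xy <- cbind(p$x, p$y)
  anchor <- colMeans(xy)
  cur <- sma(x = p$x, y = p$y)$slope
  rot <- rotate_about_anchor(xy, anchor, cur, 0.7,
                             control_mask = rep(TRUE, 50))
  expect_equal(rot$slope_after, 0.7, tolerance = 1e-9)
  d0 <- sqrt(rowSums(sweep(xy, 2, anchor)^2))
  d1 <- sqrt(rowSums(sweep(rot$xy, 2, anchor)^2))
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("across-condition normalization equalizes controls exactly", {
  d <- make_conditions(808)
  ctrl <- d$group == "control"
  res <- normalize_across_conditions(d, organ = "wing",
                                     control = ctrl,
                                     reference_condition = 23)
  nd <- res$data
  expect_length(res$transforms, 2)

  ref_ctrl <- nd$temperature == 23 & ctrl
  ref_slope <- sma(x = nd$body_size[ref_ctrl],
                   y = nd$wing[ref_ctrl])$slope
  ref_mean <- c(mean(nd$body_size[ref_ctrl]), mean(nd$wing[ref_ctrl]))
  for (tmp in c(17, 25)) {
    m <- nd$temperature == tmp & ctrl
    expect_equal(sma(x = nd$body_size[m], y = nd$wing[m])$slope,
                 ref_slope, tolerance = 1e-9)
    expect_equal(c(mean(nd$body_size[m]), mean(nd$wing[m])), ref_mean,
                 tolerance = 1e-9)
    # rigid motion: within-condition pairwise distances preserved
    sel <- d$temperature == tmp
    expect_equal(as.vector(dist(cbind(nd$body_size[sel], nd$wing[sel]))),
                 as.vector(dist(cbind(d$body_size[sel], d$wing[sel]))),
                 tolerance = 1e-9)
  }
  # reference rows bit-identical
  sel <- d$temperature == 23
  expect_identical(nd$body_size[sel], d$body_size[sel])
  expect_identical(nd$wing[sel], d$wing[sel])

  # experimental rows' offsets from the anchor, in the rotated frame,
  # are preserved: distances between each experimental row and every
  # control row of its condition are unchanged (same rigid motion)
  for (tmp in c(17, 25)) {
    sel <- d$temperature == tmp
    expect_equal(as.vector(dist(cbind(nd$body_size[sel], nd$wing[sel]))),
                 as.vector(dist(cbind(d$body_size[sel], d$wing[sel]))),
                 tolerance = 1e-9)
  }
})

test_that("normalization is idempotent and validates its inputs", {
  d <- make_conditions(909)
  ctrl <- d$group == "control"
  once <- normalize_across_conditions(d, "wing", control = ctrl,
                                      reference_condition = 23)
  twice <- normalize_across_conditions(once$data, "wing", control = ctrl,
                                       reference_condition = 23)
  for (tr in twice$transforms) {
    expect_equal(tr$translation, c(0, 0), tolerance = 1e-9)
    expect_equal(tr$rotation_angle, 0, tolerance = 1e-9)
  }
  expect_error(normalize_across_conditions(d, "wing", control = ctrl,
                                           reference_condition = 99),
               "not present")
  expect_error(normalize_across_conditions(exp_transform(d), "wing",
                                           control = ctrl,
                                           reference_condition = 23),
               "log")
  # single condition: output identical to input
  ref_only <- filter_records(d, d$temperature == 23)
  same <- normalize_across_conditions(ref_only, "wing",
                                      control = ctrl[d$temperature == 23],
                                      reference_condition = 23)
  expect_identical(same$data$wing, ref_only$wing)
  expect_length(same$transforms, 0)
})
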