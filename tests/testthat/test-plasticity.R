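make_log_data <- function(df, organs = NULL) {
  log_transform(allometry_data(df, organs = organs))
}

test_that("allometric coefficient recovers isometry and rejects misuse", {
  body <- exp(rnorm(20, 5, 0.3))
  d <- allometry_data(data.frame(body_size = body, wing = 0.1 * body))
  expect_error(allometric_coefficient(d, "wing"), "log")
  est <- allometric_coefficient(log_transform(d), "wing")
  expect_equal(est$fit$slope, 1, tolerance = 1e-10)
  expect_equal(est$n_pairs, 20)

  # organ completely insensitive to body size: zero variance on y
  d2 <- make_log_data(data.frame(body_size = body, gen = rep(2, 20)))
  expect_error(allometric_coefficient(d2, "gen"), "zero variance")
})

test_that("a genital-like slope is recovered with CI coverage", {
  params <- allometry_sim_params(
    organs = list(genital = c(b = 0.55, c = -0.5)),
    body_mean = c(fed = 5), n = 60)
  d <- log_transform(simulate_allometry(params, seed = 4242))
  est <- allometric_coefficient(d, "genital")
  expect_gt(0.55, est$fit$ci[1])
  expect_lt(0.55, est$fit$ci[2])
})

test_that("organ comparison is order-invariant and needs two organs", {
  d <- log_transform(simulate_foxo_experiment("organ_panel", n = 40,
                                              seed = 7)$data)
  a <- compare_organ_plasticity(d, c("wing", "genital", "palp"))
  b <- compare_organ_plasticity(d, c("palp", "wing", "genital"))
  key <- function(x) x$comparisons[order(x$comparisons$organ_a,
                                         x$comparisons$organ_b), ]
  expect_equal(key(a)$p_value, key(b)$p_value, tolerance = 1e-12)
  expect_equal(key(a)$p_adjusted, key(b)$p_adjusted, tolerance = 1e-12)
  # the buffered organ stands out from the proportional one
  gw <- a$comparisons[a$comparisons$organ_a == "genital" &
                        a$comparisons$organ_b == "wing", ]
  expect_lt(gw$p_adjusted, 0.05)
  expect_error(compare_organ_plasticity(d, "wing"), "at least 2")
})

test_that("relative size effect is exact arithmetic plus a sane interval", {
  ctrl <- allometry_data(data.frame(body_size = rep(10, 4),
                                    wing = c(99, 100, 101, 100)))
  pert <- allometry_data(data.frame(body_size = rep(10, 4),
                                    wing = c(69, 70, 71, 70)))
  res <- relative_size_effect(ctrl, pert, "wing", n_boot = 500, seed = 1)
  expect_equal(res$proportional_reduction, 0.30, tolerance = 1e-12)
  expect_lt(res$ci[1], res$proportional_reduction)
  expect_gt(res$ci[2], res$proportional_reduction)

  same <- relative_size_effect(ctrl, ctrl, "wing", n_boot = 500, seed = 1)
  expect_equal(same$proportional_reduction, 0)
  expect_lte(same$ci[1], 0)
  expect_gte(same$ci[2], 0)
  expect_error(relative_size_effect(ctrl, pert, "wing"), "seed")
})

test_that("equal proportional shrinkage gives a null interaction", {
  set.seed(55)
  body <- exp(rnorm(30, 5, 0.2))
  ctrl <- allometry_data(data.frame(body_size = body,
                                    wing = exp(rnorm(30, 4, 0.1)),
                                    gen = exp(rnorm(30, 3, 0.1))))
  pert <- ctrl
  pert$wing <- pert$wing * 0.8   # same factor on both organs
  pert$gen <- pert$gen * 0.8
  res <- differential_effect_test(ctrl, pert, "wing", "gen",
                                  n_perm = 400, seed = 3)
  expect_equal(res$interaction, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.5)
})

test_that("permutation interaction p matches exhaustive enumeration", {
  ctrl <- allometry_data(data.frame(
    body_size = rep(10, 3),
    wing = c(10.0, 11.0, 10.5), gen = c(5.0, 5.2, 5.1)))
  pert <- allometry_data(data.frame(
    body_size = rep(10, 3),
    wing = c(7.1, 6.8, 7.3), gen = c(4.3, 4.5, 4.2)))
  res <- differential_effect_test(ctrl, pert, "wing", "gen",
                                  n_perm = 20000, seed = 10)
  # enumeration oracle: all choose(6, 3) control assignments
  la <- log(c(ctrl$wing, pert$wing)); lb <- log(c(ctrl$gen, pert$gen))
  stat <- function(ic) {
    (mean(la[ic]) - mean(la[-ic])) - (mean(lb[ic]) - mean(lb[-ic]))
  }
  obs <- stat(1:3)
  all_stats <- apply(combn(6, 3), 2, stat)
  p_exact <- mean(abs(all_stats) >= abs(obs) - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.02)
  expect_error(differential_effect_test(ctrl, pert, "wing", "gen",
                                        n_perm = 50, seed = 1),
               "strict")
})

test_that("quadratic trend fits exactly, nests the linear model, finds humps", {
  x <- c(0, 1, 2, 3, 4)
  y <- 1 + 2 * x - x^2
  fit <- quadratic_trend(x, y)
  expect_equal(unname(fit$coefficients), c(1, 2, -1), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$extremum_x, 1, tolerance = 1e-8)

  set.seed(66)
  xl <- runif(20); yl <- 2 + 3 * xl + rnorm(20, 0, 0.05)
  qfit <- quadratic_trend(xl, yl)
  lin_rss <- sum(residuals(lm(yl ~ xl))^2)
  expect_lte(qfit$rss, lin_rss + 1e-10)

  xh <- seq(0, 2, length.out = 30)
  yh <- 1 + 2 * xh - xh^2 + rnorm(30, 0, 0.05)
  hfit <- quadratic_trend(xh, yh)
  expect_lt(unname(hfit$coefficients["a2"]), 0)
  expect_gt(hfit$extremum_x, 0)
  expect_lt(hfit$extremum_x, 2)

  expect_error(quadratic_trend(rep(1, 5), 1:5), "degenerate")
  expect_error(quadratic_trend(1:3, 1:3), "at least 4")
})
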