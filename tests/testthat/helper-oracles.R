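# Independent oracles and fixture builders shared across test files.

# Brute-force SMA estimator: minimize the triangle-area loss
# sum_i (y_i - c - b x_i)^2 / (2|b|) (area between each point and the
# line along both axes), profiling out c = mean(y) - b mean(x).
# Grid search over both slope signs plus local refinement; independent
# of the closed-form sd-ratio estimator it is used to check.
sma_loss_oracle <- function(x, y) {
  loss <- function(b) {
    c0 <- mean(y) - b * mean(x)
    sum((y - c0 - b * x)^2) / (2 * abs(b))
  }
  best_b <- NA_real_
  best_val <- Inf
  mags <- exp(seq(log(1e-3), log(1e3), length.out = 600))
  for (sgn in c(-1, 1)) {
    vals <- vapply(sgn * mags, loss, 0)
    m0 <- mags[which.min(vals)]
    iv <- sort(sgn * c(m0 / 3, m0 * 3))
    opt <- stats::optimize(loss, interval = iv, tol = 1e-12)
    if (opt$objective < best_val) {
      best_val <- opt$objective
      best_b <- opt$minimum
    }
  }
  best_b
}

# all permutations of a vector (rows of the returned matrix)
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = max(1, length(v))))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  unname(out)
}

# 3 covariate values x 2 points for exhaustive-enumeration checks of the
# trend permutation test; all pooled centered coordinates are distinct so
# every permuted pairing has a defined SMA slope
toy_trend_groups <- function() {
  list(`17` = cbind(c(0.11, 0.93), c(0.31, 1.24)),
       `20` = cbind(c(0.22, 1.07), c(0.83, 0.41)),
       `23` = cbind(c(0.54, 1.46), c(1.52, 0.97)))
}

# exact enumeration oracle for the trend test on the toy groups: the
# lower-tail p over all orderings of the pooled centered points
toy_trend_exact_p <- function(groups) {
  cg <- center_groups(groups)
  slope2 <- function(m) {
    r <- cor(m[, 1], m[, 2])
    sign(r) * sd(m[, 2]) / sd(m[, 1])
  }
  obs <- slope_trend(groups)
  perms <- all_perms(seq_len(nrow(cg$xy)))
  k <- length(cg$sizes)
  b_all <- apply(perms, 1, function(idx) {
    s <- vapply(seq_len(k), function(g)
      slope2(cg$xy[idx[(2 * g - 1):(2 * g)], ]), 0)
    tt <- cg$covariate
    sum((tt - mean(tt)) * (s - mean(s))) / sum((tt - mean(tt))^2)
  })
  mean(b_all <= obs + 1e-12)
}

# small randomized raw-scale dataset with one missing organ measurement
rand_raw_dataset <- function(seed, n = 12) {
  set.seed(seed)
  df <- data.frame(
    individual_id = sprintf("i%02d", seq_len(n)),
    group = sample(c("g1", "g2"), n, replace = TRUE),
    temperature = sample(c(17, 25), n, replace = TRUE),
    treatment = sample(c("fed", "starved"), n, replace = TRUE),
    body_size = exp(rnorm(n, 5, 0.3)),
    wing = exp(rnorm(n, 4, 0.3)),
    genital = exp(rnorm(n, 3, 0.3)))
  df$genital[1] <- NA
  allometry_data(df, organs = c("wing", "genital"))
}

# bivariate sample whose SMA estimand is exactly `b` (noise on both axes
# in the SMA-consistent variance ratio); plain rnorm, no package code
sim_sma_pair <- function(n, b, mu = 5, v = 0.3, s = 0.15, intercept = 0) {
  z <- rnorm(n, mu, v)
  list(x = z + rnorm(n, 0, s),
       y = intercept + b * z + rnorm(n, 0, abs(b) * s))
}
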