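#' Construct a clone dataset
#'
#' One row per mitotic clone from a mosaic (MARCM-style) experiment: the
#' larva it came from, the imaginal disc type, the clone's genotype, its
#' cell count and age, and optionally the mean cross-sectional cell area.
#' Larvae are the independent experimental units; clones are nested
#' within larva x disc.
#'
#' @param data data frame with columns `larva_id`, `disc_type`,
#'   `genotype`, `clone_id`, `cell_count`, `clone_age_h` and optionally
#'   `mean_cell_area`.
#' @param disc_types allowed disc-type vocabulary.
#' @return A data frame of class `clone_data`.
#' @export
clone_data <- function(data,
                       disc_types = c("wing", "eye_antennal", "genital")) {
  stopifnot(is.data.frame(data))
  need <- c("larva_id", "disc_type", "genotype", "clone_id",
            "cell_count", "clone_age_h")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing clone column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"mean_cell_area" %in% names(data)) data$mean_cell_area <- NA_real_
  bad_disc <- setdiff(unique(data$disc_type), disc_types)
  if (length(bad_disc))
    stop("unknown disc type(s): ", paste(bad_disc, collapse = ", "),
         call. = FALSE)
  n <- data$cell_count
  if (any(is.na(n) | n < 1 | n != round(n)))
    stop("`cell_count` must be integers >= 1", call. = FALSE)
  t <- data$clone_age_h
  if (any(is.na(t) | t <= 0))
    stop("`clone_age_h` must be positive", call. = FALSE)
  if (any(!is.na(data$mean_cell_area) & data$mean_cell_area <= 0))
    stop("`mean_cell_area` must be positive when present", call. = FALSE)
  data <- data[, c(need, "mean_cell_area")]
  structure(data, disc_types = disc_types,
            class = c("clone_data", "data.frame"))
}

#' Read clone records from CSV
#'
#' @param path CSV with the [clone_data()] columns.
#' @param disc_types allowed disc-type vocabulary.
#' @return A `clone_data` object.
#' @export
read_clones_csv <- function(path,
                            disc_types = c("wing", "eye_antennal",
                                           "genital")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  clone_data(utils::read.csv(path, fileEncoding = "UTF-8"),
             disc_types = disc_types)
}

#' Per-clone proliferation rate
#'
#' A clone founded by one cell that divides at rate `r` for `t` hours
#' contains about `exp(r t)` cells, so the rate is recovered as
#' `log(N) / t`.  The natural log is used, giving a rate in e-fold
#' divisions per hour; `base = 2` expresses the same quantity as cell
#' doublings per hour (the base changes all rates by a constant factor
#' only).
#'
#' @param N integer cell count(s), at least 1.
#' @param t clone age(s) in hours, positive.
#' @param base logarithm base.
#' @return Numeric vector of proliferation rates per hour.
#' @examples
#' clone_rate(64, 48)       # log(64)/48 ~ 0.0866 per hour
#' clone_rate(1, 10)        # founder never divided: rate 0
#' @export
clone_rate <- function(N, t, base = exp(1)) {
  if (any(is.na(N) | N < 1)) stop("`N` must be >= 1", call. = FALSE)
  if (any(is.na(t) | t <= 0)) stop("`t` must be positive", call. = FALSE)
  log(N, base) / t
}

#' Estimate proliferation rates per disc type and genotype
#'
#' Two-stage estimator that respects the nesting of clones within
#' larvae: per-clone rates `log(N)/t` are first averaged within each
#' larva (per disc type), then the group estimate is the unweighted mean
#' of the larva means with its standard error across larvae.  The larva
#' is the independent unit, so clone-rich larvae are not over-weighted
#' and the group point estimate is invariant to the within-larva clone
#' count distribution.  A larva-level variance component is reported by
#' method of moments: the variance of the larva means minus the expected
#' contribution of within-larva clone noise, truncated at zero.
#'
#' @param clones a [clone_data()] object.
#' @param base log base for the rates.
#' @return A data frame of class `rate_estimates`, one row per disc type
#'   x genotype: `mean_rate`, `se` (`NA` with fewer than 2 larvae),
#'   `n_larvae`, `n_clones`, `larva_variance`.
#' @export
estimate_rates <- function(clones, base = exp(1)) {
  stopifnot(inherits(clones, "clone_data"))
  r <- clone_rate(clones$cell_count, clones$clone_age_h, base = base)
  key <- interaction(clones$disc_type, clones$genotype, drop = TRUE,
                     sep = "\r")
  out <- lapply(split(data.frame(r = r, larva = clones$larva_id),
                      key), function(d) {
    lm_ <- tapply(d$r, d$larva, mean)
    m_j <- tapply(d$r, d$larva, length)
    k <- length(lm_)
    est <- mean(lm_)
    se <- if (k >= 2) stats::sd(lm_) / sqrt(k) else NA_real_
    # method-of-moments larva variance: var of larva means minus the
    # clone-noise share, using the pooled within-larva clone variance
    within <- unlist(lapply(split(d$r, d$larva), function(v)
      if (length(v) >= 2) (v - mean(v)) else NULL))
    dfw <- sum(pmax(m_j - 1, 0))
    s2c <- if (dfw > 0) sum(within^2) / dfw else NA_real_
    lv <- if (k >= 2) {
      v <- stats::var(lm_) -
        (if (is.na(s2c)) 0 else s2c * mean(1 / m_j))
      max(v, 0)
    } else NA_real_
    data.frame(mean_rate = est, se = se, n_larvae = k,
               n_clones = nrow(d), larva_variance = lv)
  })
  keys <- do.call(rbind, strsplit(names(out), "\r", fixed = TRUE))
  res <- cbind(data.frame(disc_type = keys[, 1], genotype = keys[, 2]),
               do.call(rbind, out))
  rownames(res) <- NULL
  structure(res, log_base = base,
            class = c("rate_estimates", "data.frame"))
}

#' @export
print.rate_estimates <- function(x, digits = 4, ...) {
  cat("Clone proliferation rates (per hour, larva-aggregated)\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pairwise permutation comparisons of proliferation rates
#'
#' Compares the mean proliferation rate between pairs of disc-type x
#' genotype cells with a permutation test on the larva-level means:
#' larva means from the two cells are pooled and reallocated at random,
#' and the two-sided p-value is the proportion of permuted mean
#' differences at least as extreme as the observed one.  P-values are
#' Holm-adjusted across the requested family of contrasts.  Because the
#' larva is the unit of relabeling, the two cells of a contrast must not
#' share larvae (cells measured on the same animals are not exchangeable
#' units).
#'
#' @param clones a [clone_data()] object.
#' @param contrasts data frame with columns `disc_a`, `genotype_a`,
#'   `disc_b`, `genotype_b`, one row per requested comparison.
#' @param n_perm permutations per contrast.
#' @param seed integer seed (mandatory).
#' @param base log base for the rates.
#' @return A data frame of class `rate_comparisons` with the observed
#'   larva-mean difference, raw and add-one permutation p-values and the
#'   Holm-adjusted p per contrast.
#' @export
pairwise_rate_comparison <- function(clones, contrasts, n_perm = 10000,
                                     seed = NULL, base = exp(1)) {
  stopifnot(inherits(clones, "clone_data"), is.data.frame(contrasts))
  need <- c("disc_a", "genotype_a", "disc_b", "genotype_b")
  if (!all(need %in% names(contrasts)))
    stop("`contrasts` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  r <- clone_rate(clones$cell_count, clones$clone_age_h, base = base)
  cell_means <- function(disc, geno) {
    i <- clones$disc_type == disc & clones$genotype == geno
    if (!any(i)) stop("empty design cell: ", disc, " x ", geno,
                      call. = FALSE)
    tapply(r[i], clones$larva_id[i], mean)
  }
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(contrasts)), function(k) {
    a <- cell_means(contrasts$disc_a[k], contrasts$genotype_a[k])
    b <- cell_means(contrasts$disc_b[k], contrasts$genotype_b[k])
    if (length(a) < 2 || length(b) < 2)
      stop("each contrasted cell needs >= 2 larvae", call. = FALSE)
    if (length(intersect(names(a), names(b))))
      stop("contrasted cells share larvae; larva-level permutation ",
           "requires disjoint animals", call. = FALSE)
    pool <- c(a, b); na <- length(a)
    obs <- mean(a) - mean(b)
    perm <- vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(length(pool), na)
      mean(pool[ia]) - mean(pool[-ia])
    }, 0)
    data.frame(disc_a = contrasts$disc_a[k],
               genotype_a = contrasts$genotype_a[k],
               disc_b = contrasts$disc_b[k],
               genotype_b = contrasts$genotype_b[k],
               diff = obs, n_larvae_a = length(a), n_larvae_b = length(b),
               p_value = mean(abs(perm) >= abs(obs)),
               p_value_add_one =
                 (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1))
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "holm")
  structure(res, n_perm = n_perm, seed = as.integer(seed),
            class = c("rate_comparisons", "data.frame"))
}

#' Cell-size summaries per disc type and genotype
#'
#' Larva-aggregated mean cell cross-sectional areas per disc x genotype,
#' and for each non-control genotype the proportional change versus the
#' control (`1 - mutant/control`) per disc, with a seeded bootstrap
#' (percentile) interval from resampling larvae within each cell.
#'
#' @param clones a [clone_data()] object with `mean_cell_area` present
#'   for the summarized records.
#' @param control_genotype genotype label used as the reference.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed (mandatory).
#' @param alpha interval error rate.
#' @return A data frame of class `cell_size_summary`: per disc x
#'   genotype the larva-aggregated `mean_area`, `n_larvae`, and (for
#'   non-control genotypes) `prop_change`, `ci_lower`, `ci_upper`.
#' @export
cell_size_summary <- function(clones, control_genotype, n_boot = 2000,
                              seed = NULL, alpha = 0.05) {
  stopifnot(inherits(clones, "clone_data"))
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  has <- !is.na(clones$mean_cell_area)
  d <- as.data.frame(clones)[has, ]
  if (!control_genotype %in% d$genotype)
    stop("control genotype `", control_genotype,
         "` absent (with areas)", call. = FALSE)
  larva_means <- function(disc, geno) {
    i <- d$disc_type == disc & d$genotype == geno
    tapply(d$mean_cell_area[i], d$larva_id[i], mean)
  }
  cells <- unique(d[, c("disc_type", "genotype")])
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    disc <- cells$disc_type[k]; geno <- cells$genotype[k]
    lm_ <- larva_means(disc, geno)
    out <- data.frame(disc_type = disc, genotype = geno,
                      mean_area = mean(lm_), n_larvae = length(lm_),
                      prop_change = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_)
    if (geno != control_genotype) {
      ctrl <- larva_means(disc, control_genotype)
      if (length(ctrl)) {
        out$prop_change <- 1 - mean(lm_) / mean(ctrl)
        boot <- vapply(seq_len(n_boot), function(i)
          1 - mean(sample(lm_, replace = TRUE)) /
              mean(sample(ctrl, replace = TRUE)), 0)
        q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2))
        out$ci_lower <- q[[1]]; out$ci_upper <- q[[2]]
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, control_genotype = control_genotype, seed = seed,
            class = c("cell_size_summary", "data.frame"))
}
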