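#' Fit an exponential growth curve to clone sizes
#'
#' Least-squares fit of log cell count against time. With exactly two
#' points the fit is exact and the parameter covariance is zero; with more
#' points the covariance of (intercept, rate) quantifies curve-fit
#' uncertainty and can be propagated by [sample_growth_params()].
#'
#' @param time Numeric vector of measurement times (years).
#' @param size Positive clone cell counts at those times.
#' @return A `growth_fit`: list with `intercept` (log cells at time 0),
#'   `rate` (per year), `cov` (2x2 covariance of the parameters) and `n`.
#' @examples
#' fit_growth(c(0, 2), c(1e5, 4e5))$rate  # log(4)/2
#' @export
fit_growth <- function(time, size) {
  if (length(time) != length(size) || length(time) < 2)
    stop("need at least two (time, size) points")
  if (any(!is.finite(size)) || any(size <= 0))
    stop("clone sizes must be positive")
  if (anyDuplicated(time)) stop("measurement times must be distinct")
  fit <- lm(log(size) ~ time)
  # an exactly collinear fit has zero covariance; silence the perfect-fit note
  cv <- if (length(time) == 2L) matrix(0, 2, 2)
  else suppressWarnings(vcov(fit))
  cv[!is.finite(cv)] <- 0
  structure(list(intercept = unname(coef(fit)[1]),
                 rate = unname(coef(fit)[2]),
                 cov = unname(cv), n = length(time)),
            class = "growth_fit")
}

#' Sample growth parameters from their fitted distribution
#'
#' Draws (intercept, rate) pairs from a bivariate normal distribution with
#' mean equal to the fitted parameters and covariance equal to the fit
#' covariance. A degenerate (zero) covariance returns the fitted mean for
#' every draw.
#'
#' @param fit A [fit_growth()] result.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An `n` x 2 matrix with columns `intercept`, `rate`.
#' @export
sample_growth_params <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!is.null(seed)) set.seed(seed)
  mu <- c(fit$intercept, fit$rate)
  draws <- if (all(fit$cov == 0)) {
    matrix(mu, nrow = n, ncol = 2, byrow = TRUE)
  } else {
    MASS::mvrnorm(n, mu = mu, Sigma = fit$cov)
  }
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- c("intercept", "rate")
  draws
}

#' Minimal feasible growth rate for an observed clone size
#'
#' A clone observed at `size` cells must have grown at least at rate
#' `log(size) / available_time` to exist at all: a single founder cell can
#' have expanded no earlier than the available time allows (the patient's
#' age at observation, less the origin of the clone's parent lineage when
#' one is estimated). When a fitted growth rate — possibly negative, as for
#' declining subclones — falls below this bound, downstream quantities
#' (mutation rate, driver times, time since driver, detectability) use the
#' minimal rate via `max(r, r_min)`; the raw fitted rate is still reported.
#'
#' @param size Observed clone cell count (> 1).
#' @param available_time Time available for the expansion (> 0, years).
#' @return The minimal net growth rate (per year).
#' @examples
#' minimal_growth_rate(exp(10), 20)  # 0.5
#' @export
minimal_growth_rate <- function(size, available_time) {
  if (any(size <= 1)) stop("'size' must exceed 1 cell")
  if (any(available_time <= 0)) stop("'available_time' must be positive")
  log(size) / available_time
}

#' Posterior draws of a driver time given its clonal mutation count
#'
#' The clonal passenger count `m` is a single Poisson observation with mean
#' `u * t`; under a flat prior on `t > 0` the posterior is Gamma with shape
#' `m + 1` and rate `u`, whose mode `m / u` coincides with the maximum
#' likelihood estimate.
#'
#' @param m Observed (corrected) clonal mutation count (>= 0; need not be
#'   an integer after correction).
#' @param u Mutation rate (> 0).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` posterior draws of the driver time.
#' @export
sample_t1_posterior <- function(m, u, n, seed = NULL) {
  if (m < 0) stop("'m' must be non-negative")
  if (u <= 0) stop("'u' must be positive")
  if (!is.null(seed)) set.seed(seed)
  rgamma(n, shape = m + 1, rate = u)
}

#' Age at which the tumor reaches a detectable size
#'
#' Solves \eqn{\sum_i e^{\theta_{0i} + \theta_{1i} t} = T} for `t` by
#' bracketed root finding, where each clone's exponential growth curve comes
#' from [fit_growth()] (or a sampled draw of its parameters) and the
#' threshold `T` defaults to the leukocytosis criterion of 11,500 white
#' blood cells per microliter in 5 L of blood, i.e. `5.75e10` cells.
#'
#' @param fits A list of `growth_fit` objects, or a matrix with columns
#'   (intercept, rate), one row per clone.
#' @param threshold Detectable cell count (default `5.75e10`).
#' @param interval Search bracket in years (default birth to 150), expanded
#'   automatically if the root lies outside.
#' @param tol Root tolerance in years.
#' @return The age (years) at which the summed clone sizes reach
#'   `threshold`.
#' @export
detectability_time <- function(fits, threshold = 5.75e10,
                               interval = c(0, 150), tol = 1e-6) {
  if (threshold <= 0) stop("'threshold' must be positive")
  theta <- if (is.matrix(fits)) fits
  else do.call(rbind, lapply(fits, function(f) c(f$intercept, f$rate)))
  if (all(theta[, 2] <= 0))
    stop("no clone has a positive growth rate; total never reaches threshold")
  total <- function(t)
    sum(exp(theta[, 1] + theta[, 2] * t)) - threshold
  if (total(interval[1]) >= 0) return(interval[1])
  out <- tryCatch(
    uniroot(total, interval = interval, extendInt = "upX", tol = tol),
    error = function(e)
      stop("total size never reaches the threshold in the search bracket"))
  out$root
}

#' Confidence intervals for all patient-level estimates by sampling
#'
#' Propagates measurement and model uncertainty through the full estimator
#' chain. Each draw samples subclone CCFs from their posterior samples
#' (rejecting draws that violate the phylogeny's nesting constraints),
#' recomputes growth rates — directly from two timepoints, or by sampling
#' fitted growth parameters from their bivariate normal distribution when
#' more are available — applies the minimal-growth-rate substitution, and
#' recomputes the mutation rate (averaged over timepoints), driver times
#' (sampled from their Gamma posteriors), MRCA age, time since the last
#' driver, and detectability age. Point estimates are medians; intervals
#' are percentile intervals across draws.
#'
#' @param bundle A [patient_bundle()].
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Optional integer seed.
#' @param ci Interval percentiles (default `c(2.5, 97.5)`).
#' @param threshold Detectability threshold in cells (default the
#'   leukocytosis count in the bundle config, or `5.75e10`).
#' @return An `estimate_set`: list with `point` (medians), `lower`, `upper`,
#'   the raw (unsubstituted) fitted `rates`, selective advantages `g`, and
#'   the per-draw trace matrix `draws`.
#' @export
ci_pipeline <- function(bundle, n_draws = 1000, seed = NULL,
                        ci = c(2.5, 97.5), threshold = NULL) {
  stopifnot(inherits(bundle, "patient_bundle"))
  if (!is.null(seed)) set.seed(seed)
  k <- bundle$n_clones - 1L
  parent <- bundle$parent
  tp <- sort(unique(bundle$observations$timepoint))
  n_tp <- length(tp)
  ages <- vapply(tp, function(t)
    bundle$observations$age_yr[match(t, bundle$observations$timepoint)],
    numeric(1))
  M <- vapply(tp, function(t)
    bundle$observations$M[match(t, bundle$observations$timepoint)],
    numeric(1))
  if (is.null(threshold)) {
    threshold <- bundle$config$leukocytosis_per_ul %||% 11500
    threshold <- wbc_to_cell_count(threshold,
                                   bundle$config$blood_volume_l %||% 5)
  }
  gam <- bundle$gamma
  f1 <- gam$f1[1]; f2 <- gam$f2[1]
  # posterior samples: list [[clone]][[timepoint]] -> numeric vector
  post <- lapply(seq_len(k), function(i) lapply(tp, function(t) {
    v <- bundle$ccf_posterior$ccf[bundle$ccf_posterior$clone == i &
                                    bundle$ccf_posterior$timepoint == t]
    if (!length(v)) stop("no CCF posterior samples for clone ", i,
                         " at timepoint ", t)
    v
  }))

  draw_ccfs <- function() {
    # one cumulative CCF per driver per timepoint; reject nesting violations
    for (try in seq_len(100L)) {
      a <- matrix(0, nrow = k, ncol = n_tp)
      for (i in seq_len(k)) for (j in seq_len(n_tp))
        a[i, j] <- sample(post[[i]][[j]], 1L)
      ok <- tryCatch({
        for (j in seq_len(n_tp)) clone_exclusive_fractions(a[, j], parent)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(a)
    }
    stop("could not draw nesting-consistent CCFs in 100 attempts")
  }

  # point-estimate parent origin ages for the minimal-rate available time
  point_origin <- bundle$config$parent_origin_ages %||% rep(0, k + 1L)

  nm <- c(paste0("r", 0:k), "u", "mrca_age",
          if (k > 0) paste0("t", seq_len(k)),
          if (k > 0) paste0("age", seq_len(k)), "tau", "detect_age")
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(nm),
                  dimnames = list(NULL, nm))
  for (dr in seq_len(n_draws)) {
    a <- if (k > 0) draw_ccfs() else matrix(0, 0, n_tp)
    excl <- vapply(seq_len(n_tp),
                   function(j) clone_exclusive_fractions(a[, j], parent),
                   numeric(k + 1L))
    excl <- matrix(excl, nrow = k + 1L)
    sizes <- excl * matrix(M, nrow = k + 1L, ncol = n_tp, byrow = TRUE)
    fits <- lapply(seq_len(k + 1L), function(c) fit_growth(ages, sizes[c, ]))
    r <- if (n_tp == 2L) {
      vapply(fits, `[[`, numeric(1), "rate")
    } else {
      vapply(fits, function(f) sample_growth_params(f, 1L)[1, "rate"],
             numeric(1))
    }
    # minimal-rate substitution for downstream quantities only; available
    # time runs from the parent lineage's origin (birth for clone 0)
    par_origin <- c(0, point_origin[parent + 1L])
    avail <- pmax(ages[n_tp] - par_origin, 1e-6)
    r_min <- minimal_growth_rate(pmax(sizes[, n_tp], 1 + 1e-9), avail)
    r_eff <- pmax(r, r_min)
    u_tp <- vapply(seq_len(n_tp), function(j) {
      g_row <- gam[gam$timepoint == tp[j], ]
      if (!nrow(g_row) || is.na(g_row$gamma_obs[1])) return(NA_real_)
      gc <- gamma_corrected(g_row$gamma_obs[1], f1, f2, g_row$coverage[1],
                            g_row$purity[1], g_row$threshold[1])
      estimate_mutation_rate(gc, excl[, j], r_eff, f1, f2)
    }, numeric(1))
    u <- average_mutation_rate(u_tp[!is.na(u_tp)])
    mrca <- sample_t1_posterior(
      max(0, bundle$m_obs[1] - u / r_eff[1]), u, 1L)
    t_drv <- numeric(k)
    for (i in seq_len(k)) {
      p <- parent[i]
      m_i <- correct_clonal_count(bundle$m_obs[i + 1L], u, r_eff[i + 1L],
                                  if (p == 0L) NULL else r_eff[p + 1L])
      t_drv[i] <- sample_t1_posterior(m_i, u, 1L)
    }
    age_drv <- driver_ages(t_drv, parent, mrca)
    last <- if (k > 0) which.max(age_drv) + 1L else 1L
    tau <- time_since_driver(max(excl[last, 1], 1.0000001 / M[1]), M[1],
                             r_eff[last])
    th0 <- log(sizes[, n_tp]) - r_eff * ages[n_tp]
    detect <- tryCatch(
      detectability_time(cbind(th0, r_eff), threshold,
                         interval = c(0, ages[n_tp] + 50)),
      error = function(e) NA_real_)
    draws[dr, ] <- c(r, u, mrca, if (k > 0) t_drv, if (k > 0) age_drv,
                     tau, detect)
  }
  qs <- apply(draws, 2, quantile, probs = c(0.5, ci / 100), na.rm = TRUE)
  structure(list(point = qs[1, ], lower = qs[2, ], upper = qs[3, ],
                 draws = draws, n_draws = n_draws, ci = ci),
            class = "estimate_set")
}

#' @export
print.estimate_set <- function(x, ...) {
  df <- data.frame(parameter = names(x$point), estimate = round(x$point, 3),
                   lower = round(x$lower, 3), upper = round(x$upper, 3))
  cat("Estimates (medians with [", x$ci[1], ",", x$ci[2],
      "] percentile intervals over", x$n_draws, "draws):\n")
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
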