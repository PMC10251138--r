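# Event-peak analysis of Ks distributions: Gaussian kernel density, mixture
# fitting against the density curve by least squares (with component means
# refined by maximum likelihood on the raw values), two-round lineage-rate
# correction, and linear calibration dating.

#' Gaussian kernel density of a Ks sample
#'
#' @param ks_values numeric vector of Ks values (finite, >= 0).
#' @param bandwidth kernel standard deviation in Ks units (default 0.05).
#' @param grid optional evaluation grid; by default 512 points spanning the
#'   data range extended by four bandwidths (floored at 0), over which the
#'   curve integrates to 1 within 1e-3 for samples away from the origin.
#' @return data.frame with columns `x`, `y`.
#' @export
kde_density <- function(ks_values, bandwidth = 0.05, grid = NULL) {
  ks_values <- ks_values[is.finite(ks_values)]
  if (length(ks_values) < 2L)
    stop("kernel density needs at least 2 finite Ks values")
  if (is.null(grid)) {
    lo <- max(0, min(ks_values) - 4 * bandwidth)
    hi <- max(ks_values) + 4 * bandwidth
    grid <- seq(lo, hi, length.out = 512L)
  }
  d <- stats::density(ks_values, bw = bandwidth, kernel = "gaussian",
                      from = min(grid), to = max(grid), n = length(grid))
  data.frame(x = d$x, y = d$y)
}

gauss_mix_curve <- function(x, pars) {
  # pars: vector c(A1, mu1, sigma1, A2, mu2, sigma2, ...)
  k <- length(pars) / 3L
  y <- 0
  for (i in seq_len(k)) {
    A <- pars[3 * i - 2]; mu <- pars[3 * i - 1]; s <- pars[3 * i]
    y <- y + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

find_curve_peaks <- function(x, y, k) {
  n <- length(y)
  loc <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  loc <- loc[order(y[loc], decreasing = TRUE)]
  mus <- x[loc]
  if (length(mus) < k) {
    extra <- stats::quantile(x, probs = seq(0.2, 0.8, length.out = k))
    mus <- c(mus, extra[!extra %in% mus])
  }
  mus[seq_len(k)]
}

ls_fit_k <- function(x, y, k) {
  mus <- find_curve_peaks(x, y, k)
  heights <- vapply(mus, function(m) y[which.min(abs(x - m))], numeric(1))
  start <- as.numeric(rbind(heights, mus, rep(0.1, k)))
  span <- diff(range(x))
  lower <- as.numeric(rbind(rep(1e-8, k), rep(min(x), k), rep(1e-3, k)))
  upper <- as.numeric(rbind(rep(max(y) * 3, k), rep(max(x), k), rep(span, k)))
  obj <- function(p) sum((y - gauss_mix_curve(x, p))^2)
  fit <- tryCatch({
    res <- minpack.lm::nls.lm(par = start,
                              fn = function(p) y - gauss_mix_curve(x, p),
                              lower = lower, upper = upper,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    res$par
  }, error = function(e) NULL)
  if (is.null(fit)) {
    res <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper)
    fit <- res$par
  }
  ss_res <- obj(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(pars = fit, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Fit Gaussian event peaks to a Ks distribution
#'
#' Fits a sum of Gaussian components to the kernel density curve by bounded
#' least squares, using the smallest number of components whose coefficient
#' of determination against the curve reaches `min_r2` (the distribution is
#' represented by the fewest possible normal components). When raw Ks values
#' are supplied, component means and standard deviations are refined by
#' maximum likelihood on the values assigned to each component.
#'
#' @param x numeric vector of Ks values, or a density curve as returned by
#'   [kde_density()] (data.frame with `x`, `y`).
#' @param max_components largest number of components tried.
#' @param min_r2 goodness-of-fit target (default 0.95).
#' @param bandwidth kernel bandwidth used when `x` is a value vector.
#' @param ks_ceiling Ks values above this are excluded before density
#'   estimation (saturation guard; default 3).
#' @param source optional label describing the sample.
#' @return object of class `ks_peak_model`: list with `components`
#'   (data.frame `mu`, `sigma`, `weight`, sorted by `mu`, weights summing
#'   to 1), `r_squared`, `n_components`, `source`, `flag`
#'   (`"low_r2"` when `min_r2` was not reached at `max_components`).
#' @export
fit_ks_peaks <- function(x, max_components = 3L, min_r2 = 0.95,
                         bandwidth = 0.05, ks_ceiling = 3, source = "") {
  values <- NULL
  if (is.data.frame(x) || (is.list(x) && all(c("x", "y") %in% names(x)))) {
    curve <- data.frame(x = x$x, y = x$y)
  } else {
    values <- x[is.finite(x) & x >= 0 & x <= ks_ceiling]
    curve <- kde_density(values, bandwidth = bandwidth)
  }
  best <- NULL
  flag <- NA_character_
  for (k in seq_len(max_components)) {
    fit <- ls_fit_k(curve$x, curve$y, k)
    if (is.null(best) || fit$r2 > best$r2) best <- c(fit, k = k)
    if (fit$r2 >= min_r2) { best <- c(fit, k = k); break }
  }
  if (best$r2 < min_r2) flag <- "low_r2"
  k <- best$k
  A <- best$pars[3 * seq_len(k) - 2]
  mu <- best$pars[3 * seq_len(k) - 1]
  sigma <- best$pars[3 * seq_len(k)]
  w <- A * sigma * sqrt(2 * pi)
  w <- w / sum(w)
  comp <- data.frame(mu = mu, sigma = sigma, weight = w)
  if (!is.null(values) && length(values) && k >= 1L) {
    # hard-assign raw values to the most likely component, refine by ML
    dens <- vapply(seq_len(k), function(i)
      comp$weight[i] * stats::dnorm(values, comp$mu[i], comp$sigma[i]),
      numeric(length(values)))
    dens <- matrix(dens, ncol = k)
    assign_ <- max.col(dens)
    for (i in seq_len(k)) {
      v <- values[assign_ == i]
      if (length(v) >= 2L) {
        comp$mu[i] <- mean(v)
        comp$sigma[i] <- stats::sd(v)
      }
      comp$weight[i] <- length(v) / length(values)
    }
    comp$weight <- comp$weight / sum(comp$weight)
  }
  comp <- comp[order(comp$mu), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, r_squared = best$r2,
                 n_components = k, source = source, flag = flag,
                 curve = curve),
            class = "ks_peak_model")
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat(sprintf("<ks_peak_model>%s %d component(s), R^2 = %.4f%s\n",
              if (nzchar(x$source)) paste0(" [", x$source, "]") else "",
              x$n_components, x$r_squared,
              if (!is.na(x$flag)) paste0(" (", x$flag, ")") else ""))
  print(round(x$components, 4))
  invisible(x)
}

#' @export
coef.ks_peak_model <- function(object, ...) object$components

#' Lineage rate-correction coefficient from divergence peaks
#'
#' Two lineages diverging from a common ancestor accumulate substitutions on
#' both branches; aligning lineage i's divergence peak with the slowest
#' lineage's by rescaling only lineage i's branch gives
#' `(1 + lambda)/2 * mu_i = mu_s`, i.e. `lambda = 2 * mu_s / mu_i - 1`.
#' The slowest lineage has `lambda = 1`.
#'
#' @param mu_i divergence-peak Ks of lineage i (vs the reference outgroup).
#' @param mu_s divergence-peak Ks of the slowest lineage (the benchmark).
#' @return the correction coefficient `lambda` (> 0).
#' @export
correction_coefficient <- function(mu_i, mu_s) {
  stopifnot(mu_i > 0, mu_s > 0)
  lambda <- 2 * mu_s / mu_i - 1
  if (lambda <= 0)
    stop("correction coefficient <= 0 (mu_i = ", mu_i, ", mu_s = ", mu_s,
         "): benchmark is inconsistently slow")
  lambda
}

#' Apply a rate-correction coefficient to a Ks peak
#'
#' Rescales a normal peak `(mu, sigma^2)` to `(lambda * mu,
#' lambda^2 * sigma^2)`.
#'
#' @param peak numeric `c(mu, sigma)`.
#' @param lambda correction coefficient (> 0).
#' @return numeric `c(mu, sigma)` after correction.
#' @export
apply_correction <- function(peak, lambda) {
  stopifnot(lambda > 0, length(peak) >= 2)
  c(mu = unname(peak[1]) * lambda, sigma = unname(peak[2]) * lambda)
}

#' First-round rate correction across lineages
#'
#' Computes per-lineage correction coefficients from reference-divergence
#' peaks (benchmark = slowest lineage, smallest peak Ks). Both the corrected
#' peak `lambda * mu_i` (the rescaled distribution's mode) and the
#' branch-aligned value `mu_s` implied by `(1 + lambda)/2 * mu_i = mu_s`
#' are reported.
#'
#' @param divergence_peaks named numeric vector: per lineage, the Ks peak of
#'   its divergence from the common reference.
#' @return data.frame with `lineage`, `mu`, `lambda`, `corrected_mu`,
#'   `aligned_mu`.
#' @export
first_round_correction <- function(divergence_peaks) {
  stopifnot(length(divergence_peaks) >= 1, !is.null(names(divergence_peaks)))
  mu_s <- min(divergence_peaks, na.rm = TRUE)
  lambda <- vapply(divergence_peaks, correction_coefficient, numeric(1),
                   mu_s = mu_s)
  data.frame(lineage = names(divergence_peaks),
             mu = unname(divergence_peaks),
             lambda = unname(lambda),
             corrected_mu = unname(divergence_peaks * lambda),
             aligned_mu = mu_s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Second-round rate correction from shared-polyploidy paralog peaks
#'
#' After the first round, paralog peaks of the shared hexaploidization may
#' still disagree between lineages. Both branches of a paralog pair lie in
#' the same lineage, so the full scale factor `lambda^2 = mu_s / mu_i`
#' aligns lineage i's paralog peak with the slowest lineage's. Lineages with
#' a missing peak are skipped and flagged.
#'
#' @param ach_peaks named numeric vector of round-1-corrected paralog peak
#'   Ks values, one per lineage (`NA` allowed).
#' @return data.frame with `lineage`, `mu_ach`, `factor` (the `lambda^2`
#'   multiplier), `corrected_mu`, `flag`.
#' @export
second_round_correction <- function(ach_peaks) {
  stopifnot(length(ach_peaks) >= 1, !is.null(names(ach_peaks)))
  ok <- !is.na(ach_peaks)
  if (!any(ok)) stop("no lineage has a defined paralog peak")
  mu_s <- min(ach_peaks[ok])
  fac <- ifelse(ok, mu_s / ach_peaks, NA_real_)
  data.frame(lineage = names(ach_peaks),
             mu_ach = unname(ach_peaks),
             factor = unname(fac),
             corrected_mu = unname(ach_peaks * fac),
             flag = ifelse(ok, NA_character_, "missing_ach_peak"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Date an event by linear Ks-to-time calibration
#'
#' Converts a corrected Ks peak to an age by proportionality against a
#' calibrated event: `T = corrected_mu * T_cal / mu_cal`, applied to each
#' endpoint of an interval calibration.
#'
#' @param corrected_mu corrected Ks peak of the event to date.
#' @param calibration list with `time_mya` (scalar or `c(low, high)`), and
#'   `corrected_mu` (the calibrated event's corrected Ks peak).
#' @return numeric age(s) in Mya, same length as `calibration$time_mya`.
#' @export
date_event <- function(corrected_mu, calibration) {
  stopifnot(calibration$corrected_mu > 0, all(calibration$time_mya > 0))
  corrected_mu * calibration$time_mya / calibration$corrected_mu
}
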