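#' Closed-form decay of unadapted cooperative sites
#'
#' Solves dsigma/dt = -k sigma^n for the surface density of not-yet-adapted
#' cooperative sites. Order 1 gives exponential decay; order n > 1 gives the
#' power-law solution `sigma0 * (1 + (n-1) k sigma0^(n-1) t)^(-1/(n-1))`.
#' The third-order case models trios of sterol molecules reorienting
#' cooperatively at the probe contact.
#'
#' @param t time (s), nonnegative; vectorized.
#' @param k rate constant, `(surface density)^(1-n) s^-1`, `>= 0`.
#' @param sigma0 initial site density (arbitrary surface-density units), `> 0`.
#' @param order integer reaction order `n >= 1`.
#' @return `sigma(t)`, same length as `t`.
#' @export
bond_density_solution <- function(t, k, sigma0, order) {
  if (length(order) != 1L || order < 1 || order != round(order))
    stop_se("'order' must be a single integer >= 1")
  if (any(t < 0)) stop_se("'t' must be nonnegative")
  if (k < 0) stop_se("'k' must be >= 0")
  if (sigma0 <= 0) stop_se("'sigma0' must be > 0")
  if (order == 1) sigma0 * exp(-k * t)
  else sigma0 * (1 + (order - 1) * k * sigma0^(order - 1) * t)^(-1 / (order - 1))
}

#' Adhesion force vs contact time
#'
#' Interaction force is proportional to the density of adapted (bonded)
#' sites: `F(t) = force_scale * (1 - sigma(t)/sigma0)`. It starts at zero,
#' increases monotonically with contact time and saturates at `force_scale`.
#'
#' @param t contact time (s); vectorized.
#' @param order,rate,sigma0 kinetic parameters, see [bond_density_solution()].
#' @param force_scale maximal force F-infinity (nN).
#' @return force (nN).
#' @export
force_model <- function(t, order, rate, sigma0, force_scale) {
  force_scale * (1 - bond_density_solution(t, rate, sigma0, order) / sigma0)
}

## Lumped-parameter form used by the fitter: kappa = k * sigma0^(n-1).
## sigma(t)/sigma0 depends on (kappa, n) only, so (k, sigma0) are not
## separately identifiable from force data.
force_model_lumped <- function(t, order, kappa, force_scale) {
  frac <- if (order == 1) exp(-kappa * t)
  else (1 + (order - 1) * kappa * t)^(-1 / (order - 1))
  force_scale * (1 - frac)
}

#' Kinetics generator parameters
#'
#' @param order reaction order (default 3, the cooperative-trio process).
#' @param rate rate constant k (default 0.15, half-recovery near 10 s on
#'   the 0-60 s contact-time range).
#' @param sigma0 initial site density (default 1).
#' @param force_scale saturation force F-infinity in nN (default 2).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise (default 0.05).
#' @param seed RNG seed.
#' @return a `kinetics_params` list.
#' @export
kinetics_params <- function(order = 3L, rate = 0.15, sigma0 = 1,
                            force_scale = 2, noise_cv = 0.05, seed = 1L) {
  if (order < 1) stop_se("'order' must be >= 1")
  if (rate < 0) stop_se("'rate' must be >= 0")
  if (noise_cv < 0) stop_se("'noise_cv' must be >= 0")
  if (sigma0 <= 0 || force_scale <= 0)
    stop_se("'sigma0' and 'force_scale' must be > 0")
  structure(list(order = as.integer(order), rate = rate, sigma0 = sigma0,
                 force_scale = force_scale, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "kinetics_params")
}

#' Generate contact-time-dependent adhesion force curves
#'
#' Simulates force-vs-contact-time series following the order-n adaptation
#' law with multiplicative lognormal noise of the stated coefficient of
#' variation (unit mean, so noise-free expectation equals the model curve).
#'
#' @param params a [kinetics_params()] object.
#' @param times contact times (s), nonnegative and strictly increasing.
#' @param n_curves number of replicate curves.
#' @param condition condition label attached to the output.
#' @return data frame `contact_time_s, force_nN, condition, replicate_id`
#'   with the generator parameters in attribute `"params"`.
#' @export
gen_adhesion_force_curves <- function(params, times = seq(0, 60, length.out = 13),
                                      n_curves = 1L,
                                      condition = "cholesterol_scl") {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(times < 0)) stop_se("'times' must be nonnegative")
  if (any(diff(times) <= 0)) stop_se("'times' must be strictly increasing")
  mu <- force_model(times, params$order, params$rate, params$sigma0,
                    params$force_scale)
  out <- with_seed(params$seed, {
    do.call(rbind, lapply(seq_len(n_curves), function(i) {
      f <- if (params$noise_cv > 0) {
        sdl <- sqrt(log(1 + params$noise_cv^2))
        mu * stats::rlnorm(length(mu), meanlog = -sdl^2 / 2, sdlog = sdl)
      } else mu
      data.frame(contact_time_s = times, force_nN = f,
                 condition = condition,
                 replicate_id = sprintf("rep%03d", i),
                 stringsAsFactors = FALSE)
    }))
  })
  attr(out, "params") <- params
  out
}

#' Pool replicate force curves into a mean curve
#'
#' Averages replicate curves at each shared contact time and attaches the
#' empirical standard error of the mean, mirroring how repeated
#' force-spectroscopy experiments are reduced to a mean curve with s.e.m.
#' before regression. Order discrimination is driven by sub-percent shape
#' differences, so fitting the pooled curve (noise down by the square root
#' of the number of curves) is the default analysis route.
#'
#' @param series force data frame with `contact_time_s`, `force_nN` and
#'   `replicate_id`.
#' @return data frame `contact_time_s, force_nN, force_sem_nN, n_curves`.
#' @export
pool_curves <- function(series) {
  ag <- stats::aggregate(force_nN ~ contact_time_s, series, mean)
  sem <- stats::aggregate(force_nN ~ contact_time_s, series,
                          function(v) stats::sd(v) / sqrt(length(v)))
  nrep <- stats::aggregate(force_nN ~ contact_time_s, series, length)
  ag$force_sem_nN <- pmax(sem$force_nN, 1e-9)
  ag$n_curves <- nrep$force_nN
  ag
}

#' Fit the order-n adaptation model to a force curve
#'
#' Nonlinear least squares of `F(t) = A (1 - (1 + (n-1) kappa t)^(-1/(n-1)))`
#' (exponential form for n = 1) over the lumped rate `kappa = k sigma0^(n-1)`
#' and the saturation force `A`. Unweighted unless a `force_sem_nN` column is
#' present, in which case inverse-variance weights are used.
#'
#' @param series data frame with `contact_time_s` and `force_nN`
#'   (optionally `force_sem_nN`), one curve.
#' @param order integer reaction order to fit.
#' @return a `kinetics_fit` list: `order`, `kappa`, `kappa_se`,
#'   `force_scale`, `force_scale_se`, `r_squared`, `aicc`, `rss`, `n`,
#'   `converged`, `flag` (`NA` or a short diagnostic string).
#' @export
fit_kinetics <- function(series, order) {
  if (order < 1) stop_se("'order' must be >= 1")
  t <- series$contact_time_s
  y <- series$force_nN
  if (length(t) < 4) stop_se("need at least 4 points to fit")
  if (any(!is.finite(y))) stop_se("forces must be finite")
  w <- if (!is.null(series$force_sem_nN) && all(series$force_sem_nN > 0))
    1 / series$force_sem_nN^2 else rep(1, length(y))
  n <- length(y)
  p <- 2L                              # kappa, force_scale
  flag <- NA_character_

  if (max(abs(y)) < 1e-12) {
    ## degenerate: no measurable force at any contact time
    return(structure(list(order = as.integer(order), kappa = NA_real_,
                          kappa_se = NA_real_, force_scale = 0,
                          force_scale_se = 0, r_squared = NA_real_,
                          aicc = Inf, rss = 0, n = n, converged = FALSE,
                          flag = "low-information: zero force series"),
                     class = "kinetics_fit"))
  }

  a0 <- max(y)
  pos <- t > 0 & y > 0 & y < a0
  k0 <- if (any(pos)) 1 / stats::median(t[pos]) else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ force_model_lumped(t, order, kappa, A),
      start = list(kappa = k0, A = a0),
      lower = c(1e-10, 0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(order = as.integer(order), kappa = NA_real_,
                          kappa_se = NA_real_, force_scale = NA_real_,
                          force_scale_se = NA_real_, r_squared = NA_real_,
                          aicc = Inf, rss = NA_real_, n = n, converged = FALSE,
                          flag = paste("non-convergence:",
                                       conditionMessage(fit))),
                     class = "kinetics_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  res <- y - force_model_lumped(t, order, cf[["kappa"]], cf[["A"]])
  rss <- sum(w * res^2)
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  ## Gaussian-likelihood AICc with sigma counted as a parameter
  kpar <- p + 1L
  aicc <- n * log(max(rss, 1e-300) / n) + 2 * kpar +
    if (n - kpar - 1 > 0) 2 * kpar * (kpar + 1) / (n - kpar - 1) else Inf
  structure(list(order = as.integer(order), kappa = unname(cf[["kappa"]]),
                 kappa_se = unname(se[1]), force_scale = unname(cf[["A"]]),
                 force_scale_se = unname(se[2]), r_squared = r2, aicc = aicc,
                 rss = rss, n = n, converged = TRUE, flag = flag),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("order-%d kinetics fit: kappa = %.4g +/- %.2g, F_inf = %.4g +/- %.2g\n",
              x$order, x$kappa, x$kappa_se, x$force_scale, x$force_scale_se))
  cat(sprintf("  R^2 = %.4f, AICc = %.2f, n = %d%s\n", x$r_squared, x$aicc,
              x$n, if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Select the reaction order by small-sample AICc
#'
#' Fits every candidate order to each curve (grouped by `replicate_id` when
#' present) and returns the AICc-minimizing order per curve plus the
#' majority order across curves. AICc ties (e.g. short noise-free curves
#' where the correction diverges) are broken by residual sum of squares.
#'
#' @param series force data frame (one or many curves).
#' @param orders candidate integer orders (default 1:4).
#' @return list: `order` (majority winner), `per_curve` (data frame of
#'   selected order per curve), `table` (per curve x order fit summary).
#' @export
select_order <- function(series, orders = 1:4) {
  if (!length(orders)) stop_se("'orders' must be nonempty")
  ids <- if (!is.null(series$replicate_id)) unique(series$replicate_id) else "curve"
  rows <- list(); sel <- integer(0)
  for (id in ids) {
    cur <- if (!is.null(series$replicate_id))
      series[series$replicate_id == id, ] else series
    fits <- lapply(orders, function(o) fit_kinetics(cur, o))
    ok <- vapply(fits, function(f) f$converged, TRUE)
    if (!any(ok))
      stop_se("all fits failed for curve ", id, ": ",
              paste(sprintf("order %d: %s", orders, vapply(fits, `[[`, "", "flag")),
                    collapse = "; "))
    aicc <- vapply(fits, `[[`, 0, "aicc")
    rss <- vapply(fits, `[[`, 0, "rss")
    aicc[!ok] <- Inf
    best <- which(aicc == min(aicc))
    if (length(best) > 1) best <- best[which.min(rss[best])]
    sel <- c(sel, orders[best])
    rows[[id]] <- data.frame(replicate_id = id, order = orders,
                             aicc = aicc, rss = rss,
                             r_squared = vapply(fits, `[[`, 0, "r_squared"),
                             kappa = vapply(fits, `[[`, 0, "kappa"),
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  per_curve <- data.frame(replicate_id = ids, selected_order = sel,
                          stringsAsFactors = FALSE)
  counts <- table(sel)
  list(order = as.integer(names(counts)[which.max(counts)]),
       per_curve = per_curve, table = tab)
}

#' Normalize sequentially repeated force measurements
#'
#' Each dataset (one location) is divided by its own mean, as in
#' repeated-force variability plots; dispersion is summarized as the
#' coefficient of variation (population standard deviation over mean) per
#' location and pooled per condition (root mean squared deviation of the
#' pooled normalized values from 1).
#'
#' @param series data frame with `force_nN` and optionally
#'   `sequence_index`, `location_id`, `condition`.
#' @return list: `normalized` (input with `force_norm` column),
#'   `cv_by_location`, `cv_by_condition` (data frames).
#' @export
normalize_repeat_forces <- function(series) {
  if (nrow(series) < 2) stop_se("need at least 2 points")
  loc <- series$location_id %||% rep("loc1", nrow(series))
  cond <- series$condition %||% rep("all", nrow(series))
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  norm <- numeric(nrow(series)); cvl <- list()
  for (l in unique(loc)) {
    i <- loc == l
    m <- mean(series$force_nN[i])
    if (m == 0) stop_se("zero mean force in location ", l,
                        "; cannot normalize")
    norm[i] <- series$force_nN[i] / m
    cvl[[l]] <- data.frame(location_id = l, condition = cond[i][1],
                           cv = sd_pop(series$force_nN[i]) / abs(m),
                           stringsAsFactors = FALSE)
  }
  cv_by_location <- do.call(rbind, cvl)
  cv_by_condition <- do.call(rbind, lapply(unique(cond), function(cc) {
    v <- norm[cond == cc]
    data.frame(condition = cc, cv = sqrt(mean((v - 1)^2)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  out <- series
  out$force_norm <- norm
  list(normalized = out, cv_by_location = cv_by_location,
       cv_by_condition = cv_by_condition)
}
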