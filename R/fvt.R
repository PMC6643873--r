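# Function-valued trait fitting: three-parameter logistic TPC limbs and the
# Gaussian peak model, with Wald uncertainty and CI-overlap comparisons.
#
# Fits are Levenberg-Marquardt nonlinear least squares (minpack.lm) from an
# analytic start, with jittered restarts on failure. SEs come from the
# Jacobian-based covariance at the optimum; 95% CIs are t-based Wald
# intervals (estimate +/- t(n - p, 0.975) * SE).

new_tpc_fit <- function(model, half, estimate, se, r_squared, n, converged,
                        sigma = NA_real_, vcov = NULL) {
  p <- length(estimate)
  tq <- if (converged && n > p) stats::qt(0.975, n - p) else NA_real_
  ci <- rbind(lower = estimate - tq * se, upper = estimate + tq * se)
  structure(list(model = model, half = half, estimate = estimate, se = se,
                 ci = ci, r_squared = r_squared, n = n, converged = converged,
                 sigma = sigma, vcov = vcov),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("%s TPC fit%s (n = %d, R^2 = %.4f, %s)\n", x$model,
              if (is.na(x$half)) "" else paste0(" [", x$half, " half]"),
              x$n, x$r_squared,
              if (x$converged) "converged" else "NOT converged"))
  tab <- rbind(estimate = x$estimate, se = x$se, x$ci)
  print(round(tab, 4))
  invisible(x)
}

nls_with_restarts <- function(formula, data, start, lower, upper,
                              n_restarts = 5) {
  fit <- NULL
  starts <- c(list(start), lapply(seq_len(n_restarts), function(i) {
    lapply(start, function(v) v * stats::runif(1, 0.7, 1.3) +
             stats::rnorm(1, 0, 0.05 * (abs(v) + 0.1)))
  }))
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = s, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  fit
}

fit_summary <- function(fit, y) {
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(est)) else sqrt(pmax(diag(vc), 0))
  list(estimate = est, se = se, r_squared = r2, vcov = vc,
       sigma = sqrt(rss / max(1, length(y) - length(est))))
}

#' Fit the three-parameter logistic TPC to one limb of a strain-mean series
#'
#' Fits `LI(T) = alpha / (1 + exp(-beta * (T - tau)))` by nonlinear least
#' squares to strain-mean normalized locomotion values on one monotone limb
#' of the thermal performance curve. On the hot limb activity declines with
#' rising temperature so `beta` is negative; on the cold limb it is positive.
#' The analytic start uses `alpha0 = max(y)`, `tau0` at the first crossing of
#' `alpha0 / 2`, `beta0 = sign * 4 / span`.
#'
#' @param temps Assay temperatures (degrees C), >= 4 points.
#' @param li Strain-mean normalized locomotion index at `temps`.
#' @param half `"hot"` or `"cold"` (sets the slope sign convention).
#' @return A `tpc_fit` with fields `estimate` (`alpha`, `beta`, `tau`), `se`,
#'   `ci`, `r_squared`, `n`, `converged`.
#' @export
fit_logistic <- function(temps, li, half = c("hot", "cold")) {
  half <- match.arg(half)
  if (length(temps) < 4) stop("need at least 4 points", call. = FALSE)
  if (length(temps) != length(li)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(temps)) || any(!is.finite(li)))
    stop("non-finite inputs", call. = FALSE)
  o <- order(temps)
  temps <- temps[o]
  li <- li[o]
  span <- diff(range(temps))
  a0 <- max(li)
  sign0 <- if (half == "hot") -1 else 1
  half_cross <- if (half == "hot") {
    idx <- which(li <= a0 / 2)
    if (length(idx)) temps[min(idx)] else stats::median(temps)
  } else {
    idx <- which(li >= a0 / 2)
    if (length(idx)) temps[min(idx)] else stats::median(temps)
  }
  start <- list(alpha = max(a0, 1e-3), beta = sign0 * 4 / span,
                tau = half_cross)
  beta_bound <- 50 / max(span, 1)
  lower <- c(alpha = 0, beta = if (half == "hot") -beta_bound else 0,
             tau = min(temps) - span)
  upper <- c(alpha = max(2 * a0, 1), beta = if (half == "hot") 0 else beta_bound,
             tau = max(temps) + span)
  fit <- nls_with_restarts(li ~ alpha / (1 + exp(-beta * (temps - tau))),
                           data = data.frame(temps = temps, li = li),
                           start = start, lower = lower, upper = upper)
  if (is.null(fit)) {
    return(new_tpc_fit("logistic", half,
                       estimate = c(alpha = NA_real_, beta = NA_real_,
                                    tau = NA_real_),
                       se = rep(NA_real_, 3), r_squared = NA_real_,
                       n = length(li), converged = FALSE))
  }
  s <- fit_summary(fit, li)
  at_bound <- abs(abs(s$estimate[["beta"]]) - beta_bound) < 1e-8
  new_tpc_fit("logistic", half, estimate = s$estimate, se = s$se,
              r_squared = s$r_squared, n = length(li),
              converged = !at_bound && all(is.finite(s$estimate)),
              sigma = s$sigma, vcov = s$vcov)
}

#' Fit the Gaussian peak model inside a temperature window
#'
#' Fits `LI(T) = Pmax * exp(-0.5 * ((T - Topt) / c)^2)` to strain-mean
#' locomotion over the low-skew central window of the TPC (default
#' 18-32.5 degrees C), estimating peak performance, its temperature, and
#' curvature.
#'
#' @param temps Assay temperatures.
#' @param li Strain-mean locomotion index.
#' @param window `c(lo, hi)` window in degrees C; only in-window points are
#'   used (>= 4 required).
#' @return A `tpc_fit` with `estimate` (`p_max`, `t_opt`, `curvature`).
#' @export
fit_gaussian_peak <- function(temps, li, window = c(18, 32.5)) {
  keep <- temps >= window[1] & temps <= window[2]
  if (sum(keep) < 4)
    stop("fewer than 4 points inside the fitting window", call. = FALSE)
  temps <- temps[keep]
  li <- li[keep]
  start <- list(p_max = max(li), t_opt = temps[which.max(li)],
                curvature = max(diff(range(temps)) / 4, 0.5))
  fit <- nls_with_restarts(
    li ~ p_max * exp(-0.5 * ((temps - t_opt) / curvature)^2),
    data = data.frame(temps = temps, li = li), start = start,
    lower = c(p_max = 0, t_opt = min(temps) - 20, curvature = 1e-3),
    upper = c(p_max = Inf, t_opt = max(temps) + 20, curvature = Inf))
  if (is.null(fit)) {
    return(new_tpc_fit("gaussian", NA_character_,
                       estimate = c(p_max = NA_real_, t_opt = NA_real_,
                                    curvature = NA_real_),
                       se = rep(NA_real_, 3), r_squared = NA_real_,
                       n = length(li), converged = FALSE))
  }
  s <- fit_summary(fit, li)
  new_tpc_fit("gaussian", NA_character_, estimate = s$estimate, se = s$se,
              r_squared = s$r_squared, n = length(li),
              converged = all(is.finite(s$estimate)), sigma = s$sigma,
              vcov = s$vcov)
}

#' Derived breadth and midpoint of a TPC from its two logistic limbs
#'
#' Breadth `delta_tau = tau_H - tau_C` and midpoint `(tau_H + tau_C) / 2`,
#' computed only when both limb fits converged (otherwise `NA` with
#' `complete = FALSE`).
#'
#' @param fit_cold,fit_hot Logistic `tpc_fit` objects for the two limbs.
#' @return `list(delta_tau, midpoint, complete)`.
#' @export
derive_traits <- function(fit_cold, fit_hot) {
  ok <- isTRUE(fit_cold$converged) && isTRUE(fit_hot$converged)
  if (!ok) return(list(delta_tau = NA_real_, midpoint = NA_real_,
                       complete = FALSE))
  tc <- fit_cold$estimate[["tau"]]
  th <- fit_hot$estimate[["tau"]]
  list(delta_tau = th - tc, midpoint = (th + tc) / 2, complete = TRUE)
}

#' Compare two strains on one fitted parameter by CI overlap
#'
#' Declares strains `"different"` if and only if the two 95% confidence
#' intervals for the chosen parameter do not overlap; the comparison is
#' symmetric in its arguments.
#'
#' @param fit_a,fit_b Converged `tpc_fit` objects of the same model.
#' @param parameter Parameter name present in both fits.
#' @return `"different"` or `"not_different"`.
#' @export
compare_strains_ci <- function(fit_a, fit_b, parameter) {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("both fits must have converged", call. = FALSE)
  if (!parameter %in% colnames(fit_a$ci) || !parameter %in% colnames(fit_b$ci))
    stop(sprintf("parameter '%s' not present in both fits", parameter),
         call. = FALSE)
  a <- fit_a$ci[, parameter]
  b <- fit_b$ci[, parameter]
  if (a["lower"] > b["upper"] || b["lower"] > a["upper"]) "different"
  else "not_different"
}

#' Fit logistic TPCs for every strain in an assay table
#'
#' Computes strain-mean series of a (normalized) metric and fits the logistic
#' model per strain.
#'
#' @param table Normalized, QC-filtered `thermal_assay` table.
#' @param metric Column to fit (default `"li7"`).
#' @param half Limb passed to [fit_logistic()].
#' @return Named list of `tpc_fit` objects, plus a tidy data.frame summary as
#'   attribute `"summary"` (strain, alpha, beta, tau, their SEs, r_squared,
#'   converged).
#' @export
fit_strains <- function(table, metric = "li7", half = "hot") {
  if (!nrow(table)) stop("empty assay table: nothing to fit", call. = FALSE)
  means <- stats::aggregate(table[[metric]],
                            list(strain = table$strain,
                                 assay_temp = table$assay_temp), mean)
  fits <- lapply(split(means, means$strain), function(d) {
    fit_logistic(d$assay_temp, d$x, half = half)
  })
  summ <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    data.frame(strain = s, alpha = f$estimate[["alpha"]],
               beta = f$estimate[["beta"]], tau = f$estimate[["tau"]],
               alpha_se = f$se[[1]], beta_se = f$se[[2]], tau_se = f$se[[3]],
               r_squared = f$r_squared, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(fits, "summary") <- summ
  fits
}

#' Write strain fit results to CSV / JSON
#'
#' @param fits Result of [fit_strains()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @export
write_fit_results <- function(fits, csv_path = NULL, json_path = NULL) {
  summ <- attr(fits, "summary")
  if (!is.null(csv_path))
    utils::write.csv(summ, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(fits, function(f) {
      list(model = f$model, half = f$half,
           estimate = as.list(f$estimate), se = as.list(f$se),
           ci = list(lower = as.list(f$ci["lower", ]),
                     upper = as.list(f$ci["upper", ])),
           r_squared = f$r_squared, n = f$n, converged = f$converged,
           vcov = if (is.null(f$vcov)) NULL else unclass(f$vcov))
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
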