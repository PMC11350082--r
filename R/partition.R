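# Core partitioning procedure: monthly nonlinear least-squares
# parameterization of respiration on the low-sap-flow dark-chamber subset,
# residual transport and chamber-difference photosynthesis, monthly light-
# response and transport fits, and Wald inference on the parameters.

#' Nonlinear least-squares fit with covariance
#'
#' Thin deterministic wrapper around Levenberg-Marquardt least squares
#' (`minpack.lm::nlsLM`) returning estimates, the covariance
#' `RSE^2 (J'J)^-1` at the solution, and convergence status. Tolerances are
#' set tight so exact-data fits resolve parameters to near machine
#' precision.
#'
#' @param formula model formula, response on the left.
#' @param data data.frame of observations.
#' @param start named list of initial values.
#' @param lower,upper optional box constraints (named or positional).
#' @param maxiter iteration cap.
#' @return list: `estimates`, `se`, `cov`, `rse`, `df`, `n`, `converged`.
#' @export
nls_fit <- function(formula, data, start, lower = NULL, upper = NULL,
                    maxiter = 200) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 1e-15, maxiter = maxiter)
  args <- list(formula = formula, data = data, start = start, control = ctrl)
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    if (grepl("singular", conditionMessage(fit), ignore.case = TRUE)) {
      stop(sprintf("rank-deficient model: %s", conditionMessage(fit)),
           call. = FALSE)
    }
    return(list(estimates = NULL, converged = FALSE,
                message = conditionMessage(fit)))
  }
  est <- stats::coef(fit)
  n <- length(stats::resid(fit))
  p <- length(est)
  dof <- n - p
  rse <- sqrt(sum(stats::resid(fit)^2) / dof)
  cov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(diag(cov)) else rep(NA_real_, p)
  list(estimates = est, se = se, cov = cov, rse = rse, df = dof, n = n,
       converged = fit$convInfo$isConv %||% TRUE)
}

#' Wald inference on fitted parameters
#'
#' Computes t statistics (estimate / standard error), two-sided p-values
#' from the t distribution, and 95% confidence intervals
#' `estimate +/- t(0.975, dof) * SE` — the test of the null hypothesis that
#' each model parameter equals zero.
#'
#' @param estimate,se numeric vectors of estimates and standard errors.
#' @param dof residual degrees of freedom, `n - #parameters`.
#' @param level confidence level (default 0.95).
#' @return data.frame: `parameter`, `estimate`, `se`, `t`, `p`, `ci_lo`,
#'   `ci_hi`.
#' @export
parameter_inference <- function(estimate, se, dof, level = 0.95) {
  if (dof <= 0) stop("degrees of freedom must be positive")
  tval <- estimate / se
  p <- 2 * stats::pt(-abs(tval), dof)
  tq <- stats::qt(1 - (1 - level) / 2, dof)
  data.frame(parameter = names(estimate) %||% seq_along(estimate),
             estimate = unname(estimate), se = unname(se),
             t = unname(tval), p = unname(p),
             ci_lo = unname(estimate - tq * se),
             ci_hi = unname(estimate + tq * se),
             stringsAsFactors = FALSE)
}

param_result <- function(infer, n, rse, month, valid = TRUE, note = "",
                         cov = NULL) {
  structure(list(table = infer, n = n, rse = rse, month = month,
                 valid = valid, note = note, cov = cov),
            class = "stemflux_fit")
}

#' Fit the exponential temperature response of stem respiration
#'
#' Fits `-dFCO2 = R0 exp(b temp)` by nonlinear least squares on the
#' low-sap-flow dark-chamber subset, where the transport term vanishes and
#' the dark-chamber efflux is pure respiration. Initial values come from an
#' ordinary regression of `log(-dFCO2)` on temperature (rows with
#' non-positive efflux are excluded from the initialization only, with a
#' count); if too few rows remain, the fallback initialization assumes
#' Q10 = 2 (`b0 = 0.07`).
#'
#' @param subset aligned-table rows (low sap flow) with `dfco2` and `temp`.
#' @param month calendar month label for the result.
#' @param min_n minimum observations (default 30).
#' @return a `stemflux_fit` with parameters `R0`, `b`.
#' @export
fit_respiration <- function(subset, month = NA_integer_, min_n = 30) {
  y <- -subset$dfco2
  temp <- subset$temp
  ok <- is.finite(y) & is.finite(temp)
  y <- y[ok]; temp <- temp[ok]
  n <- length(y)
  if (n < min_n) {
    stop(sprintf("respiration fit needs >= %d observations, got %d",
                 min_n, n))
  }
  if (stats::sd(temp) < 1e-10) {
    stop("rank-deficient model: temperature has no variation, R0 and b are not jointly identifiable")
  }
  pos <- y > 0
  n_excl <- sum(!pos)
  if (sum(pos) >= 3) {
    ll <- stats::lm(log(y[pos]) ~ temp[pos])
    start <- list(R0 = unname(exp(stats::coef(ll)[1])),
                  b = unname(stats::coef(ll)[2]))
  } else {
    b0 <- 0.07  # Q10 of 2
    start <- list(R0 = stats::median(y) / exp(b0 * mean(temp)), b = b0)
  }
  start$R0 <- max(start$R0, 1e-6)
  fit <- nls_fit(y ~ R0 * exp(b * temp), data.frame(y = y, temp = temp),
                 start, lower = c(R0 = 1e-9, b = -10),
                 upper = c(R0 = Inf, b = 10))
  if (is.null(fit$estimates)) {
    return(param_result(NULL, n, NA_real_, month, valid = FALSE,
                        note = fit$message))
  }
  infer <- parameter_inference(fit$estimates, fit$se, fit$df)
  res <- param_result(infer, n, fit$rse, month, cov = fit$cov)
  res$n_loginit_excluded <- n_excl
  res
}

#' Predict respiration from fitted parameters
#'
#' `R' = R0 exp(b temp)`; evaluated over the entire record (all light and
#' sap-flow conditions) once the parameters are known.
#'
#' @param params a `stemflux_fit` from [fit_respiration()], or a named
#'   vector/list with `R0` and `b`.
#' @param temp xylem temperature series, degC.
#' @return predicted respiration `R'`, umol m-2 s-1 (always positive).
#' @export
predict_respiration <- function(params, temp) {
  if (inherits(params, "stemflux_fit")) {
    est <- stats::setNames(params$table$estimate, params$table$parameter)
  } else {
    est <- unlist(params)
  }
  resp_model(est[["R0"]], est[["b"]], temp)
}

#' Transport term as the residual of dark-chamber flux and respiration
#'
#' Under the efflux-negative convention the dark chamber obeys
#' `dFCO2 = -R' + T`, so `T = dFCO2 + R'`. Negative values are retained
#' (they occur at low residual flux in the morning hours).
#'
#' @param dfco2 dark-chamber flux series.
#' @param r_prime predicted respiration series, same length.
#' @return transport series `T`.
#' @export
compute_transport <- function(dfco2, r_prime) {
  if (length(dfco2) != length(r_prime)) {
    stop("misaligned series: dark flux and predicted respiration differ in length")
  }
  dfco2 + r_prime
}

#' Photosynthesis as the daytime chamber difference
#'
#' `P = tFCO2 - dFCO2` during daytime (PPFD above the threshold); night
#' rows are undefined (`NA`) and excluded from light-response fitting.
#' Negative values are retained, with a diagnostic count in attribute
#' `n_negative`.
#'
#' @param tfco2,dfco2 aligned transparent and dark chamber flux series.
#' @param ppfd PPFD series defining the daytime mask.
#' @param day_ppfd daytime threshold, umol m-2 s-1 (default 10).
#' @return photosynthesis series with `NA` at night.
#' @export
compute_photosynthesis <- function(tfco2, dfco2, ppfd, day_ppfd = 10) {
  if (length(tfco2) != length(dfco2) || length(tfco2) != length(ppfd)) {
    stop("misaligned series: chamber fluxes and PPFD differ in length")
  }
  p <- tfco2 - dfco2
  p[ppfd <= day_ppfd] <- NA_real_
  structure(p, n_negative = sum(p < 0, na.rm = TRUE))
}

#' Fit the Michaelis-Menten light response of bark photosynthesis
#'
#' Fits `P = Pmax f PPFD / (f PPFD + Pmax)` by nonlinear least squares on
#' daytime rows. Initialization: `Pmax0` from the 95th percentile of P and
#' `f0` from an origin-constrained slope over the lowest PPFD quartile;
#' both parameters bounded positive. A fit that fails to converge is
#' returned flagged invalid rather than raising.
#'
#' @param p photosynthesis series (chamber difference, daytime).
#' @param ppfd PPFD series.
#' @param month calendar month label.
#' @param min_n minimum observations (default 30).
#' @return a `stemflux_fit` with parameters `Pmax`, `f`.
#' @export
fit_photosynthesis <- function(p, ppfd, month = NA_integer_, min_n = 30) {
  ok <- is.finite(p) & is.finite(ppfd) & ppfd > 0
  p <- p[ok]; ppfd <- ppfd[ok]
  n <- length(p)
  if (n < min_n) {
    stop(sprintf("light-response fit needs >= %d daytime observations, got %d",
                 min_n, n))
  }
  pmax0 <- max(unname(stats::quantile(p, 0.95)), 0.05)
  qlo <- ppfd <= stats::quantile(ppfd, 0.25)
  f0 <- sum(p[qlo] * ppfd[qlo]) / sum(ppfd[qlo]^2)
  f0 <- min(max(f0, 1e-5), 0.5)
  fit <- nls_fit(p ~ Pmax * f * ppfd / (f * ppfd + Pmax),
                 data.frame(p = p, ppfd = ppfd),
                 start = list(Pmax = pmax0, f = f0),
                 lower = c(Pmax = 1e-6, f = 1e-8))
  if (is.null(fit$estimates) || !isTRUE(fit$converged)) {
    return(param_result(NULL, n, NA_real_, month, valid = FALSE,
                        note = fit$message %||% "non-convergent fit"))
  }
  param_result(parameter_inference(fit$estimates, fit$se, fit$df),
               n, fit$rse, month)
}

#' Fit the zero-intercept transport response to sap flux
#'
#' The transport model `T = e J` is linear through the origin, so the
#' least-squares slope has the closed form `e = sum(T J) / sum(J^2)` with
#' `SE = RSE / sqrt(sum(J^2))` and `dof = n - 1`; exactly reproducible
#' without iteration.
#'
#' Because `T` is constructed as `dFCO2 + R'` with plug-in respiration
#' parameters, the slope inherits their estimation uncertainty; `extra_var`
#' adds that delta-method variance contribution to the slope's SE (computed
#' by [fit_stem_partition()] from the respiration covariance; the two fits
#' use disjoint observations, so the contributions add).
#'
#' @param t_resid transport series (residual of dark flux and respiration).
#' @param j sap flux density series.
#' @param month calendar month label.
#' @param min_n minimum observations (default 30).
#' @param extra_var additional variance of the slope propagated from the
#'   upstream respiration fit (default 0).
#' @return a `stemflux_fit` with parameter `e`.
#' @export
fit_transport <- function(t_resid, j, month = NA_integer_, min_n = 30,
                          extra_var = 0) {
  ok <- is.finite(t_resid) & is.finite(j)
  t_resid <- t_resid[ok]; j <- j[ok]
  n <- length(t_resid)
  if (n < min_n) {
    stop(sprintf("transport fit needs >= %d observations, got %d", min_n, n))
  }
  sj2 <- sum(j^2)
  if (sj2 == 0) stop("undefined slope: all sap flux values are zero")
  e <- sum(t_resid * j) / sj2
  resid <- t_resid - e * j
  dof <- n - 1
  rse <- sqrt(sum(resid^2) / dof)
  se <- sqrt(rse^2 / sj2 + extra_var)
  infer <- parameter_inference(c(e = e), c(e = se), dof)
  param_result(infer, n, rse, month)
}

#' Monthly parameterization of all three flux components
#'
#' Runs the full monthly procedure on an aligned table: (1) respiration fit
#' on the low-sap-flow dark-chamber subset of each month; (2) prediction of
#' `R'` over the month's full record from xylem temperature; (3) transport
#' residual `T = dFCO2 + R'` and daytime chamber-difference photosynthesis
#' `P = tFCO2 - dFCO2`; (4) monthly light-response and zero-intercept
#' transport fits.
#'
#' @param aligned aligned table from [align_chambers()].
#' @param sap_threshold,sap_mode,sap_fraction low-sap-flow selection, see
#'   [select_low_sapflow()].
#' @param day_ppfd daytime PPFD threshold, umol m-2 s-1.
#' @param min_n minimum observations per fit.
#' @return list of class `stemflux_partition`:
#'   * `params`: data.frame (`tree_id`, `month`, `parameter`, `estimate`,
#'     `se`, `t`, `p`, `ci_lo`, `ci_hi`, `n`, `rse`) over `R0`, `b`,
#'     `Pmax`, `f`, `e`;
#'   * `components`: per-timestamp series `r_prime`, `p_meas`, `t_resid`,
#'     `p_model`, `t_model` alongside the measured fluxes and drivers;
#'   * `fits`: the underlying `stemflux_fit` objects per month.
#' @export
fit_stem_partition <- function(aligned, sap_threshold = 5,
                               sap_mode = "fixed", sap_fraction = 0.05,
                               day_ppfd = 10, min_n = 30) {
  low <- select_low_sapflow(aligned, threshold = sap_threshold,
                            mode = sap_mode, fraction = sap_fraction)
  months <- sort(unique(aligned$month))
  tree <- aligned$tree_id[1]
  params <- list()
  fits <- list()
  comp <- aligned
  comp$r_prime <- NA_real_
  comp$p_meas <- NA_real_
  comp$t_resid <- NA_real_
  comp$p_model <- NA_real_
  comp$t_model <- NA_real_

  for (m in months) {
    rows <- aligned$month == m
    rfit <- fit_respiration(low[low$month == m, ], month = m, min_n = min_n)
    comp$r_prime[rows] <- predict_respiration(rfit, aligned$temp[rows])
    comp$t_resid[rows] <- compute_transport(aligned$dfco2[rows],
                                            comp$r_prime[rows])
    comp$p_meas[rows] <- compute_photosynthesis(aligned$tfco2[rows],
                                                aligned$dfco2[rows],
                                                aligned$ppfd[rows],
                                                day_ppfd = day_ppfd)
    pfit <- fit_photosynthesis(comp$p_meas[rows], aligned$ppfd[rows],
                               month = m, min_n = min_n)
    # delta-method propagation of respiration-parameter uncertainty into
    # the transport slope: e depends on theta = (R0, b) through T = d + R'
    extra_var <- 0
    if (!is.null(rfit$cov)) {
      est <- stats::setNames(rfit$table$estimate, rfit$table$parameter)
      jj <- aligned$j[rows]
      ok <- is.finite(comp$t_resid[rows]) & is.finite(jj)
      jj_ok <- jj[ok]
      ex <- exp(est[["b"]] * aligned$temp[rows][ok])
      sj2 <- sum(jj_ok^2)
      if (sj2 > 0) {
        g <- c(sum(jj_ok * ex), sum(jj_ok * est[["R0"]] *
                                      aligned$temp[rows][ok] * ex)) / sj2
        extra_var <- drop(t(g) %*% rfit$cov %*% g)
      }
    }
    tfit <- fit_transport(comp$t_resid[rows], aligned$j[rows],
                          month = m, min_n = min_n, extra_var = extra_var)
    if (pfit$valid) {
      est <- stats::setNames(pfit$table$estimate, pfit$table$parameter)
      comp$p_model[rows] <- photo_model(est[["Pmax"]], est[["f"]],
                                        aligned$ppfd[rows])
    }
    comp$t_model[rows] <- transport_model(tfit$table$estimate[1],
                                          aligned$j[rows])
    fits[[month.abb[m]]] <- list(respiration = rfit, photosynthesis = pfit,
                                 transport = tfit)
    for (ft in list(rfit, pfit, tfit)) {
      if (is.null(ft$table)) next
      tab <- ft$table
      tab$tree_id <- tree
      tab$month <- m
      tab$n <- ft$n
      tab$rse <- ft$rse
      params[[length(params) + 1L]] <- tab
    }
  }
  params <- do.call(rbind, params)
  params <- params[, c("tree_id", "month", "parameter", "estimate", "se",
                       "t", "p", "ci_lo", "ci_hi", "n", "rse")]
  rownames(params) <- NULL
  structure(list(params = params, components = comp, fits = fits),
            class = "stemflux_partition")
}

#' Predict all three modeled components from a monthly parameter table
#'
#' Evaluates `R' = R0 exp(b temp)`, `P' = Pmax f PPFD / (f PPFD + Pmax)` and
#' `T' = e J` row-wise using each row's calendar-month parameters.
#'
#' @param params the `params` data.frame of a [fit_stem_partition()] result.
#' @param newdata data.frame with `month`, `temp`, `ppfd`, `j`.
#' @return data.frame `r_prime`, `p_model`, `t_model` (one row per input
#'   row).
#' @export
predict_components <- function(params, newdata) {
  get_par <- function(m, p) {
    v <- params$estimate[params$month == m & params$parameter == p]
    if (length(v) != 1) {
      stop(sprintf("no fitted parameter '%s' for month %s", p, month.abb[m]))
    }
    v
  }
  months <- unique(newdata$month)
  out <- data.frame(r_prime = NA_real_, p_model = NA_real_,
                    t_model = NA_real_)[rep(1, nrow(newdata)), ]
  for (m in months) {
    rows <- newdata$month == m
    out$r_prime[rows] <- resp_model(get_par(m, "R0"), get_par(m, "b"),
                                    newdata$temp[rows])
    out$p_model[rows] <- photo_model(get_par(m, "Pmax"), get_par(m, "f"),
                                     newdata$ppfd[rows])
    out$t_model[rows] <- transport_model(get_par(m, "e"), newdata$j[rows])
  }
  rownames(out) <- NULL
  out
}
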