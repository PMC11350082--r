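# Monthly parameterization: NLS fits of the three component models,
# residual algebra, inference, and the estimator contracts.

test_that("respiration fit recovers exact exponential data", {
  temp <- seq(2, 18, length.out = 200)
  sub <- data.frame(dfco2 = -0.5 * exp(0.09 * temp), temp = temp)
  fit <- fit_respiration(sub, month = 6)
  est <- setNames(fit$table$estimate, fit$table$parameter)
  expect_equal(est[["R0"]], 0.5, tolerance = 1e-8)
  expect_equal(est[["b"]], 0.09, tolerance = 1e-8)
  expect_lt(fit$rse, 1e-10)
})

test_that("respiration fit rejects degenerate designs", {
  sub <- data.frame(dfco2 = rep(-1, 50), temp = rep(10, 50))
  expect_error(fit_respiration(sub), "identifiable|rank")
  expect_error(fit_respiration(data.frame(dfco2 = -1, temp = 1)[0, ]),
               ">= 30")
})

test_that("log-linear initialization excludes non-positive effluxes but fits all rows", {
  set.seed(2)
  temp <- runif(300, 2, 18)
  sub <- data.frame(dfco2 = -(0.5 * exp(0.09 * temp) + rnorm(300, 0, 0.3)),
                    temp = temp)
  fit <- fit_respiration(sub, month = 6)
  expect_equal(fit$n, 300)
  expect_equal(fit$n_loginit_excluded, sum(sub$dfco2 >= 0))
  est <- setNames(fit$table$estimate, fit$table$parameter)
  expect_equal(est[["R0"]], 0.5, tolerance = 0.2)
})

test_that("predicted respiration is positive and increasing in temperature", {
  r <- predict_respiration(c(R0 = 0.5, b = 0.1), c(0, 10, 20))
  expect_equal(r[1], 0.5)
  expect_equal(r[2], 0.5 * exp(1))
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0))
})

test_that("transport and photosynthesis follow the chamber algebra", {
  expect_equal(compute_transport(-2.0, 2.5), 0.5)
  expect_equal(compute_transport(c(-1, -2), c(1, 2)), c(0, 0))
  expect_error(compute_transport(1:3, 1:2), "misaligned")

  p <- compute_photosynthesis(tfco2 = c(-1.5, -2.3, -3),
                              dfco2 = c(-2.0, -2.0, -2.5),
                              ppfd = c(500, 500, 0))
  expect_equal(p[1], 0.5)
  expect_equal(p[2], -0.3)   # negative daytime P retained
  expect_true(is.na(p[3]))   # night rows undefined
  expect_equal(attr(p, "n_negative"), 1)
})

test_that("light-response fit recovers exact Michaelis-Menten data", {
  ppfd <- c(seq(1, 100, length.out = 60), seq(120, 1500, length.out = 60))
  p <- 1.0 * 0.01 * ppfd / (0.01 * ppfd + 1.0)
  fit <- fit_photosynthesis(p, ppfd, month = 6)
  est <- setNames(fit$table$estimate, fit$table$parameter)
  expect_equal(est[["Pmax"]], 1.0, tolerance = 1e-7)
  expect_equal(est[["f"]], 0.01, tolerance = 1e-7)

  # the fitted curve vanishes at zero light and saturates below Pmax
  curve <- est[["Pmax"]] * est[["f"]] * c(0, 10^(0:5)) /
    (est[["f"]] * c(0, 10^(0:5)) + est[["Pmax"]])
  expect_equal(curve[1], 0)
  expect_true(all(curve <= est[["Pmax"]]))
})

test_that("transport slope has the closed form and matches iterative NLS", {
  j <- c(1, 2, 3)
  t_obs <- c(1, 2, 4)
  fit <- fit_transport(t_obs, j, min_n = 3)
  expect_equal(fit$table$estimate, 17 / 14, tolerance = 1e-12)

  exact <- fit_transport(0.02 * (1:50), 1:50, min_n = 3)
  expect_equal(exact$table$estimate, 0.02, tolerance = 1e-12)
  expect_equal(exact$rse, 0)

  # closed form against the generic Levenberg-Marquardt route
  set.seed(9)
  j2 <- runif(200, 0, 80)
  t2 <- 0.01 * j2 + rnorm(200, 0, 0.1)
  cf <- fit_transport(t2, j2)
  nl <- nls_fit(t2 ~ e * j2, data.frame(t2 = t2, j2 = j2),
                start = list(e = 0.5))
  expect_equal(cf$table$estimate, unname(nl$estimates), tolerance = 1e-10)

  expect_error(fit_transport(rep(0.1, 40), rep(0, 40)), "undefined slope")
})

test_that("Wald inference computes t, p and confidence intervals", {
  inf <- parameter_inference(c(a = 0.5), c(a = 0.1), dof = 98)
  expect_equal(inf$t, 5)
  expect_equal(inf$p, 2 * pt(-5, 98))
  expect_equal(inf$ci_lo, 0.5 - qt(0.975, 98) * 0.1)

  # vanishing SE drives p to zero
  tiny <- parameter_inference(c(a = 0.5), c(a = 1e-12), dof = 10)
  expect_lt(tiny$p, 1e-30)

  expect_error(parameter_inference(c(a = 1), c(a = 1), dof = 0), "positive")
})

test_that("the NLS wrapper reduces to OLS on linear problems and is a fixed point", {
  set.seed(4)
  x <- runif(100)
  y <- 2 + 3 * x + rnorm(100, 0, 0.1)
  nl <- nls_fit(y ~ a + b * x, data.frame(x = x, y = y),
                start = list(a = 0, b = 1))
  ols <- coef(lm(y ~ x))
  expect_equal(unname(nl$estimates), unname(ols), tolerance = 1e-7)

  again <- nls_fit(y ~ a + b * x, data.frame(x = x, y = y),
                   start = as.list(nl$estimates))
  expect_equal(again$estimates, nl$estimates, tolerance = 1e-12)
})

test_that("NLS objective never exceeds the best point of a coarse grid", {
  set.seed(12)
  for (i in 1:5) {
    R0 <- runif(1, 0.3, 0.8); b <- runif(1, 0.05, 0.15)
    temp <- runif(60, 2, 20)
    y <- R0 * exp(b * temp) + rnorm(60, 0, 0.05)
    fit <- fit_respiration(data.frame(dfco2 = -y, temp = temp))
    est <- setNames(fit$table$estimate, fit$table$parameter)
    ssr_nls <- sum((y - est[["R0"]] * exp(est[["b"]] * temp))^2)

    r0g <- seq(0.1, 1.2, length.out = 200)
    bg <- seq(0.01, 0.2, length.out = 200)
    E <- exp(outer(bg, temp))                    # 200 x 60
    sy2 <- sum(y^2)
    syE <- E %*% y                               # per-b cross terms
    sE2 <- rowSums(E^2)
    ssr_grid <- min(outer(r0g^2, sE2) - 2 * outer(r0g, drop(syE)) + sy2)
    expect_lte(ssr_nls, ssr_grid + 1e-10)
  }
})

test_that("monthly partitioning reconstructs the transparent flux exactly", {
  truth <- sim_truth(noise_sd = 0.1)
  drivers <- generate_drivers(sim_config(seed = 21))
  fl <- generate_true_fluxes(drivers, truth, seed = 21)
  al <- align_chambers(fl$dark, fl$transparent, drivers)
  part <- fit_stem_partition(al)
  comp <- part$components
  ok <- is.finite(comp$p_meas)
  # -R' + P + T = tFCO2 is an algebraic identity of the construction
  expect_lt(max(abs(-comp$r_prime[ok] + comp$p_meas[ok] +
                      comp$t_resid[ok] - comp$tfco2[ok])), 1e-12)
  # every month yields all five parameters
  expect_equal(sum(table(part$params$month, part$params$parameter)), 20)
})

test_that("noiseless end-to-end recovery reaches numerical precision", {
  ss <- noiseless_season()
  part <- fit_stem_partition(ss$aligned)
  rec <- recovery_report(part$params, ss$truth)
  expect_equal(nrow(rec), 20)
  expect_lt(max(abs(rec$rel_error)), 1e-6)
  # noiseless transport equals the generator's e * J exactly
  tc <- ss$fluxes$truth_components
  expect_equal(part$components$t_resid, tc$t_true, tolerance = 1e-6)
})

test_that("component prediction errors on a month without parameters", {
  ss <- noiseless_season()
  part <- fit_stem_partition(ss$aligned)
  bad <- data.frame(month = 12, temp = 5, ppfd = 0, j = 0)
  expect_error(predict_components(part$params, bad), "Dec")
})
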