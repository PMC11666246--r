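test_that("saturation functions obey their closed forms and limits", {
  expect_equal(alpha_rnap_A(0, 1), 0)
  expect_equal(alpha_rnap_A(1, 1), 0.5)
  expect_equal(alpha_rnap_A(2, 1), 2 / 3)
  Z <- seq(0, 50, by = 0.5)
  a <- alpha_rnap_A(Z, 2)
  expect_true(all(diff(a) > 0) && all(a >= 0 & a < 1))
  expect_equal(alpha_ribo(0, 5), 0)
  expect_equal(alpha_ribo(5, 5), 0.5)
  expect_equal(alpha_ribo(10, 5), 2 / 3)
  expect_error(alpha_rnap_A(-1, 1), ">= 0")
})

test_that("mass-action RNAP fractions hit their limits and the kinetic oracle", {
  p <- model_params(variant = "B", k_on = 2e-3, k_off = 1, k_init = 1,
                    k_term = 1, n_promoter = 1000, rnap_conc = 2000)
  # no binding
  p0 <- p; p0$k_on <- 0
  expect_equal(alpha_rnap_B(1, p0), 0)
  # absorbing limit: with promoters in excess of RNAPs, all end up bound
  pa <- model_params(variant = "B", k_on = 2e-3, k_off = 0, k_init = 0,
                     k_term = 1, n_promoter = 1000, rnap_conc = 500)
  expect_equal(alpha_rnap_B(1, pa), 1)
  # when promoters are scarcer than RNAPs the bound fraction saturates at P/R
  pb <- model_params(variant = "B", k_on = 2e-3, k_off = 0, k_init = 0,
                     k_term = 1, n_promoter = 1000, rnap_conc = 2000)
  expect_equal(alpha_rnap_B(1, pb), 0.5)
  # quasi-steady state equals long-time kinetic integration on random draws
  set.seed(16)
  for (i in 1:8) {
    kon <- runif(1, 1e-4, 1e-2); koff <- runif(1, 0.2, 2)
    kini <- runif(1, 0.2, 2); kter <- runif(1, 0.2, 2)
    Z <- runif(1, 0.1, 3); R <- runif(1, 500, 4000); npr <- 1000
    pi_ <- model_params(variant = "B", k_on = kon, k_off = koff,
                        k_init = kini, k_term = kter, n_promoter = npr,
                        rnap_conc = R)
    got <- alpha_rnap_B(Z, pi_)
    oracle <- kinetic_rnap_fraction(R, npr * Z, kon, koff, kini, kter)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
  # monotone in genome concentration
  av <- alpha_rnap_B(seq(0.1, 3, by = 0.1), p)
  expect_true(all(diff(av) > 0))
})

test_that("model B reduces to the Michaelis-Menten form when RNAPs are scarce", {
  # with negligible promoter depletion, alpha_B(Z) = Z / (K + Z) with
  # K = 1 / (n_promoter * gamma * (1 + tau))
  p <- model_params(variant = "B", k_on = 2e-3, k_off = 1, k_init = 1,
                    k_term = 1, n_promoter = 1000, rnap_conc = 1e-6)
  gamma <- 2e-3 / (1 + 1); tau <- 1
  K_eq <- 1 / (1000 * gamma * (1 + tau))
  Z <- seq(0.05, 5, by = 0.05)
  expect_lt(max(abs(alpha_rnap_B(Z, p) - alpha_rnap_A(Z, K_eq)) /
                  alpha_rnap_A(Z, K_eq)), 0.02)
})

test_that("with saturated machinery the model grows exactly exponentially", {
  p <- model_params(delta = 0, K1 = 0, K2 = 0)
  tr <- simulate_model(p, "multiN", X0 = 1, Y0 = 1e6, t_end = 200, dt_out = 50)
  expect_equal(tr$Y, 1e6 * exp(p$r2 * tr$t_min), tolerance = 1e-3)
  expect_equal(tr$alpha_ribo, rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("balanced growth is exponential with the algebraic fixed-point ratio", {
  p <- model_params()
  init <- balanced_growth_init(p, Y_target = 2.5 / p$c_prime)
  tr <- simulate_model(p, "multiN", init["X"], init["Y"], t_end = 300)
  lambda <- tr$rel_rate_per_min[1]
  # constant relative rate over > 5 doublings (300 min at ~56-min doubling)
  expect_lt(diff(range(tr$rel_rate_per_min)) / lambda, 1e-3)
  # fixed point: X/Y = r1 alpha_RNAP / (lambda + delta)
  expect_equal(init[["X"]] / init[["Y"]],
               p$r1 * tr$alpha_rnap[1] / (lambda + p$delta),
               tolerance = 1e-5)
  # V and A stay proportional to Y
  expect_equal(tr$A_um2, p$c_prime * tr$Y)
  expect_equal(tr$V_um3, p$c * tr$Y)
})

test_that("balanced initialization is unique and hits its closed-form limit", {
  p <- model_params()
  i1 <- balanced_growth_init(p, 1e6, X0_frac = 1e-4)
  i2 <- balanced_growth_init(p, 1e6, X0_frac = 1e-1)
  expect_equal(i1[["X"]] / i1[["Y"]], i2[["X"]] / i2[["Y"]], tolerance = 1e-6)
  expect_equal(i1[["Y"]], 1e6)
  # saturated, non-degrading limit: X/Y -> r1 / r2
  ps <- model_params(delta = 0, K1 = 0, K2 = 0)
  is <- balanced_growth_init(ps, 1e6)
  expect_equal(is[["X"]] / is[["Y"]], ps$r1 / ps$r2, tolerance = 1e-4)
  expect_error(balanced_growth_init(model_params(r2 = 0), 1e6), "r2")
})

test_that("genome dilution drives the DNA-limited cascade", {
  p <- model_params()
  init <- balanced_growth_init(p, Y_target = 2.5 / p$c_prime)
  tr <- simulate_model(p, "oneN", init["X"], init["Y"], t_end = 1200,
                       dt_out = 5)
  post <- tr[-(1:10), ]                      # drop the initial transient
  expect_true(all(diff(post$rel_rate_per_min) <= 1e-9))
  expect_true(all(diff(post$alpha_ribo) <= 1e-9))
  expect_true(all(diff(post$alpha_rnap) < 0))      # Z = 1/V dilutes
  expect_true(all(diff(post$X / post$V_um3) < 0))  # mRNA concentration falls
  # genome concentration halves when the cell doubles
  iA <- which.min(abs(post$A_um2 - 5)); iB <- which.min(abs(post$A_um2 - 10))
  expect_equal(post$Z[iB] / post$Z[iA], post$A_um2[iA] / post$A_um2[iB],
               tolerance = 1e-3)
})

test_that("model B simulation shows the same qualitative dilution cascade", {
  p <- model_params(variant = "B")
  init <- balanced_growth_init(p, Y_target = 2.5 / p$c_prime)
  tr <- simulate_model(p, "oneN", init["X"], init["Y"], t_end = 800,
                       dt_out = 5)
  post <- tr[-(1:10), ]
  expect_true(all(diff(post$alpha_rnap) < 0))
  expect_true(all(diff(post$rel_rate_per_min) <= 1e-9))
})

test_that("six-dataset fitting recovers the identifiable parameters", {
  truth <- model_params()
  areas <- seq(2.5, 12, by = 1)
  obs <- predict_six_curves(truth, areas, areas)
  datasets <- lapply(obs, function(d) {
    d$sd <- pmax(abs(d$value) * 0.1, 1e-6); d
  })
  start <- model_params(r1 = truth$r1 * 1.5, delta = truth$delta * 0.6,
                        K1 = truth$K1 * 1.8, K2 = truth$K2 * 0.5)
  fit <- fit_model_params(datasets, start, n_starts = 2, seed = 1)
  expect_false(fit$underdetermined)
  # identifiable reparameterization: delta, K1 and the ratio r1/K2
  # (r1 and K2 trade off exactly: scaling X is unobservable)
  expect_lt(abs(fit$params$delta - truth$delta) / truth$delta, 0.05)
  expect_lt(abs(fit$params$K1 - truth$K1) / truth$K1, 0.05)
  expect_lt(abs(fit$params$r1 / fit$params$K2 - truth$r1 / truth$K2) /
              (truth$r1 / truth$K2), 0.05)
  # one-law-only data is flagged under-determined
  fit1 <- fit_model_params(datasets[c("growth_multiN", "alpha_rnap_multiN",
                                      "alpha_ribo_multiN")],
                           truth, n_starts = 1, seed = 1)
  expect_true(fit1$underdetermined)
})

test_that("limiting-concentration arithmetic and deviation detection agree", {
  expect_equal(estimate_limiting_concentration(2, 1), 0.5)
  expect_equal(estimate_limiting_concentration(1, 1), 1)
  expect_equal(estimate_limiting_concentration(4, 2), 0.5)
  expect_error(estimate_limiting_concentration(0), "> 0")

  centers <- seq(0.5, 6, by = 0.5)
  wt_slope <- 4e4
  # identical curve: no deviation
  expect_true(is.na(detect_deviation_area(
    data.frame(bin_center_um2 = centers, value = wt_slope * centers),
    wt_slope)))
  # constructed drop below 90% of the fit from 2 um^2 onward
  v <- wt_slope * centers
  v[centers >= 2] <- 0.85 * wt_slope * centers[centers >= 2]
  dev <- detect_deviation_area(data.frame(bin_center_um2 = centers, value = v),
                               wt_slope, threshold = 0.1)
  expect_equal(dev, 2)
  # larger threshold never gives a smaller deviation area
  dev2 <- detect_deviation_area(data.frame(bin_center_um2 = centers,
                                           value = v), wt_slope,
                                threshold = 0.2)
  expect_true(is.na(dev2) || dev2 >= dev)
})
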