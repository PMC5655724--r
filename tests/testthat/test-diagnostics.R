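test_that("monotonicity holds on clean synthetic data and at the mean", {
  truth <- translog_fixture("stage2")
  pan <- small_panel(seed = 61)
  fit <- list(params = truth, norm = attr(pan, "norm"))
  mon <- monotonicity_check(fit, pan)
  expect_gte(mon$fraction, 0.95)
  # the mean hospital's predicted shares are the (all positive) gammas
  nrm <- attr(pan, "norm")
  expect_true(all(predicted_shares(truth, mean_point(nrm)) > 0))
})

test_that("a violating point is detected", {
  # large output-price interaction drives a share negative off the mean
  outs <- "admissions"
  delta <- matrix(c(0.5, -0.1, -0.1, -0.1, -0.1, -0.1), 1, 6,
                  dimnames = list(outs, hospital_inputs()))
  p <- translog_params(0.2, c(admissions = 0.5), gamma = default_gamma(),
                       delta = delta)
  nrm <- make_norm(y = c(admissions = 30000),
                   w = c(man_adm = 48000, nursing = 45000,
                         paramedical = 42000, auxiliary = 30000,
                         material = 1, capital = 11000),
                   cost = 1e8, base_year = 2003)
  pan <- data.frame(year = 2003, admissions = 30000 * exp(-2),
                    total_cost = 1e8)
  for (i in hospital_inputs()) pan[[paste0("w_", i)]] <- nrm$w[[i]]
  mon <- monotonicity_check(list(params = p, norm = nrm), pan)
  expect_false(mon$ok[1])
  expect_error(substitution_elasticities(
    p, translog_point(c(admissions = 30000 * exp(-2)), nrm$w, norm = nrm)),
    "monotonicity")
})

test_that("Cobb-Douglas curvature: own elasticities share - 1, NSD holds", {
  p <- translog_params(0.1, c(admissions = 0.6, er_visits = 0.2),
                       gamma = default_gamma())
  nrm <- make_norm(y = c(admissions = 30000, er_visits = 15000),
                   w = c(man_adm = 48000, nursing = 45000,
                         paramedical = 42000, auxiliary = 30000,
                         material = 1, capital = 11000),
                   cost = 1e8, base_year = 2003)
  pt <- mean_point(nrm)
  sig <- substitution_elasticities(p, pt)
  s <- predicted_shares(p, pt)
  expect_equal(diag(sig), (s - 1) / s, tolerance = 1e-12)
  expect_equal(sig[1, 2], 1, tolerance = 1e-12)  # unitary substitution
  pan <- data.frame(year = 2003, admissions = 30000, er_visits = 15000,
                    total_cost = 1e8)
  for (i in hospital_inputs()) pan[[paste0("w_", i)]] <- nrm$w[[i]]
  cc <- concavity_check(list(params = p, norm = nrm), pan)
  expect_true(cc$own_negative[1])
  expect_true(cc$nsd[1])
})

test_that("a convex price structure is flagged", {
  # G with a strongly positive diagonal violates concavity
  ins <- hospital_inputs()
  G <- diag(6) * 0.6
  G <- G - outer(rowMeans(G), rep(1, 6)) - outer(rep(1, 6), colMeans(G)) +
    mean(G)
  dimnames(G) <- list(ins, ins)
  p <- translog_params(0.1, c(admissions = 0.6), G = G,
                       gamma = default_gamma())
  nrm <- make_norm(y = c(admissions = 30000),
                   w = setNames(c(48000, 45000, 42000, 30000, 1, 11000),
                                ins),
                   cost = 1e8, base_year = 2003)
  pan <- data.frame(year = 2003, admissions = 30000, total_cost = 1e8)
  for (i in ins) pan[[paste0("w_", i)]] <- nrm$w[[i]]
  cc <- concavity_check(list(params = p, norm = nrm), pan)
  expect_false(cc$nsd[1])
  expect_false(cc$own_negative[1])
})

test_that("eigenvalue verdicts agree with quadratic-form sampling", {
  set.seed(62)
  for (s in 1:20) {
    p <- rand_params(seed = 600 + s, scale = 0.12)
    nrm <- rand_norm(seed = 620 + s)
    pt <- rand_point(nrm, seed = 640 + s, spread = 0.2)
    sh <- predicted_shares(p, pt)
    if (any(sh <= 0)) next
    M <- p$G + tcrossprod(sh) - diag(sh)
    ev_nsd <- max(eigen(M, symmetric = TRUE,
                        only.values = TRUE)$values) <= 1e-8
    dirs <- matrix(rnorm(6 * 1000), 1000, 6)
    qf <- rowSums((dirs %*% M) * dirs)
    sampled_nsd <- all(qf <= 1e-8 * rowSums(dirs^2))
    expect_equal(ev_nsd, sampled_nsd)
  }
})

test_that("published parameter set: own negativity at the mean, one small
           positive eigenvalue", {
  truth <- translog_fixture("stage2")
  nrm <- reference_norm()
  pan <- data.frame(year = 2003, admissions = nrm$y[["admissions"]],
                    outpatients = nrm$y[["outpatients"]],
                    other_revenues = nrm$y[["other_revenues"]],
                    er_visits = nrm$y[["er_visits"]], total_cost = nrm$cost)
  for (i in hospital_inputs()) pan[[paste0("w_", i)]] <- nrm$w[[i]]
  for (k in hedonic_vars()) pan[[paste0("z_", k)]] <- nrm$z[[k]]
  cc <- concavity_check(list(params = truth, norm = nrm), pan)
  expect_true(cc$own_negative[1])
  # the printed coefficients leave one eigenvalue slightly above zero
  expect_gt(cc$max_eigenvalue[1], 0)
  expect_lt(cc$max_eigenvalue[1], 0.02)
  expect_false(cc$nsd[1])
})

test_that("fit summary: perfect fit, calibrated fit and convergence info", {
  truth <- translog_fixture("stage2")
  pan0 <- small_panel(seed = 63, n_hospitals = 40, years = 2009:2011)
  pan0 <- generate_costs(pan0, truth, noise_sd = 0, share_noise_sd = 0)
  fit0 <- fit_system(pan0, system_spec(outputs = hospital_outputs()),
                     norm = attr(pan0, "norm"))
  s0 <- fit_summary(fit0)
  expect_equal(s0$cost_r2, 1, tolerance = 1e-10)
  expect_true(s0$converged)
  pan <- small_panel(seed = 64, n_hospitals = 80, years = 2003:2011)
  fit <- fit_system(pan, system_spec(outputs = hospital_outputs()),
                    norm = attr(pan, "norm"))
  s <- fit_summary(fit)
  expect_equal(s$cost_r2, 0.98, tolerance = 0.01)
  expect_gt(s$share_significant, 0.3)
  # repeated calls on the same inputs are identical
  expect_identical(fit_summary(fit), s)
})

test_that("a zero-effect regressor is significant at about the nominal rate", {
  # ER enters the design but has no effect in the truth
  truth <- translog_fixture("stage2")
  null_truth <- translog_params(
    truth$alpha0, replace(truth$beta, "er_visits", 0),
    {B <- truth$B; B["er_visits", ] <- 0; B[, "er_visits"] <- 0; B},
    truth$gamma, truth$G,
    {D <- truth$delta; D["er_visits", ] <- 0; D},
    truth$tau, truth$theta, truth$year_effects)
  R <- 60
  rej <- logical(R)
  for (r in 1:R) {
    pan <- small_panel(seed = 7000 + r, n_hospitals = 40, years = 2010:2011,
                       truth = null_truth)
    fit <- fit_system(pan, system_spec(outputs = hospital_outputs()),
                      norm = attr(pan, "norm"))
    rej[r] <- abs(fit$zstat[["er_visits"]]) > qnorm(0.975)
  }
  expect_gt(mean(rej), 0.0)
  expect_lt(mean(rej), 0.17)  # nominal 5%, wide band for 60 replicates
})
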