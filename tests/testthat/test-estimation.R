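test_that("coefficient layout maps symmetric pairs to one free parameter", {
  lay <- chainscale:::.layout(hospital_outputs()[1:2], years = 2004,
                              theta_names = character(0))
  # one entry for the admissions-outpatients cross term, none for the swap
  expect_equal(sum(lay$name == "admissions_x_outpatients"), 1)
  expect_false("outpatients_x_admissions" %in% lay$name)
  spec <- system_spec(outputs = hospital_outputs()[1:2], hedonics = FALSE)
  fixed0 <- setNames(numeric(nrow(lay)), lay$name)
  cm <- chainscale:::.constraint_map(lay, spec, fixed0)
  # capital column derived, not free
  expect_false("price_capital" %in% cm$free_names)
  expect_false("trend_x_price_capital" %in% cm$free_names)
  expect_true("price_nursing" %in% cm$free_names)
  # derived gamma_capital: 1 - sum of the free gammas
  j <- which(lay$name == "price_capital")
  expect_equal(cm$b[[j]], 1)
  expect_equal(sum(cm$A[j, grep("^price_[a-z_]+$", colnames(cm$A))]), -5)
})

test_that("free -> full -> free reconstruction is the identity", {
  p <- rand_params(seed = 41, years = c("2004", "2005"))
  lay <- chainscale:::.layout(p$outputs, years = c(2004, 2005),
                              theta_names = names(p$theta))
  spec <- system_spec(outputs = p$outputs)
  full <- chainscale:::.params_to_full(p, lay)
  cm <- chainscale:::.constraint_map(lay, spec, full * 0)
  theta_free <- full[cm$free_names]
  full2 <- drop(cm$A %*% theta_free) + cm$b
  expect_equal(unname(full2), unname(full), tolerance = 1e-12)
  p2 <- chainscale:::.full_to_params(full2, lay)
  expect_equal(p2$B, p$B, tolerance = 1e-12)
  expect_equal(p2$G, p$G, tolerance = 1e-12)
  expect_equal(p2$delta, p$delta, tolerance = 1e-12)
})

test_that("a noiseless system is recovered exactly", {
  truth <- translog_fixture("stage2")
  pan <- small_panel(seed = 42, n_hospitals = 40, years = 2009:2011)
  pan <- generate_costs(pan, truth, noise_sd = 0, share_noise_sd = 0)
  fit <- fit_system(pan, system_spec(outputs = hospital_outputs()),
                    norm = attr(pan, "norm"))
  for (k in c("beta", "B", "gamma", "G", "delta", "tau", "theta"))
    expect_equal(fit$params[[k]], truth[[k]], tolerance = 1e-8, label = k)
  # intercept and year effects are identified jointly relative to the
  # panel's base year: compare the combined per-year intercept
  for (yr in as.character(sort(unique(pan$year)))) {
    tru <- truth$alpha0 +
      (if (yr %in% names(truth$year_effects)) truth$year_effects[[yr]] else 0)
    est <- fit$params$alpha0 +
      (if (yr %in% names(fit$params$year_effects))
        fit$params$year_effects[[yr]] else 0)
    expect_equal(est, tru, tolerance = 1e-8, label = paste("year", yr))
  }
  expect_true(fit$converged)
})

test_that("imposed restrictions hold exactly and the objective never rises", {
  truth <- translog_fixture("stage2")
  pan <- small_panel(seed = 43)
  fit <- fit_system(pan, system_spec(outputs = hospital_outputs()),
                    norm = attr(pan, "norm"))
  expect_silent(validate_translog_params(fit$params, tol = 1e-10))
  obj <- fit$objective
  expect_true(all(diff(obj) <= 1e-6 * pmax(1, abs(obj[-length(obj)]))))
  # predicted shares from the fit sum to one at arbitrary points
  pt <- rand_point(rand_norm(seed = 44), seed = 45)
  expect_equal(sum(predicted_shares(fit$params, pt)), 1, tolerance = 1e-10)
})

test_that("zero-variance ER regressor yields a clear identification error", {
  truth <- translog_fixture("stage2")
  pan <- small_panel(seed = 46, n_hospitals = 60, years = 2010:2011)
  pan$er_visits <- 20000
  pan$er_visits_full <- 20000
  expect_error(fit_system(pan, system_spec(outputs = hospital_outputs()),
                          norm = attr(pan, "norm")),
               "not identified")
})

test_that("two-stage estimation fixes the stage-1 price block bit-for-bit", {
  pan <- small_panel(seed = 47, n_hospitals = 60, years = 2008:2011,
                     er_coverage = 0.5)
  ts <- two_stage_fit(pan)
  expect_identical(ts$stage2$params$gamma, ts$stage1$params$gamma)
  expect_identical(ts$stage2$params$G, ts$stage1$params$G)
  expect_identical(ts$stage2$params$tau, ts$stage1$params$tau)
  expect_identical(ts$stage2$params$theta, ts$stage1$params$theta)
  expect_identical(ts$stage2$params$year_effects,
                   ts$stage1$params$year_effects)
  # cross-output second-order terms carried, ER cross terms zero
  expect_identical(ts$stage2$params$B["admissions", "outpatients"],
                   ts$stage1$params$B["admissions", "outpatients"])
  expect_identical(ts$stage2$params$B["admissions", "er_visits"], 0)
  # stage 2 uses only the ER-complete rows
  expect_equal(ts$stage2$n, sum(!is.na(pan$er_visits)))
  # free stage-2 blocks actually moved
  expect_false(isTRUE(all.equal(ts$stage2$params$delta["admissions", ],
                                ts$stage1$params$delta["admissions", ])))
})

test_that("analytic standard errors agree with a nonparametric bootstrap", {
  cfg <- sim_config(n_hospitals = 300, years = 2010:2011,
                    target_n_obs = NULL, er_coverage = 1, seed = 48)
  pan <- generate_costs(generate_panel(cfg), translog_fixture("stage2"))
  spec <- system_spec(outputs = hospital_outputs()[1:3], hedonics = FALSE,
                      B_mode = "none")
  fit <- fit_system(pan, spec, norm = attr(pan, "norm"))
  bs <- bootstrap_fit(pan, spec, n_boot = 200, seed = 49,
                      norm = attr(pan, "norm"))
  rel <- attr(bs, "se") / fit$se
  # 200 draws carry ~5% Monte-Carlo noise per ratio: require the bulk of
  # the coefficients inside the 20% band and none far outside it
  expect_gte(mean(rel > 0.8 & rel < 1.2), 0.9)
  expect_true(all(rel > 0.75 & rel < 1.25))
  expect_lt(abs(median(rel) - 1), 0.1)
})
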