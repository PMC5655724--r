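# a log-linear (Cobb-Douglas) system: c = k * prod_m y_m^beta_m
cd_params <- function(beta) {
  translog_params(0.1, beta, gamma = default_gamma())
}

cd_norm <- function(outputs) {
  make_norm(y = setNames(rep(30000, length(outputs)), outputs),
            w = c(man_adm = 48000, nursing = 45000, paramedical = 42000,
                  auxiliary = 30000, material = 1, capital = 11000),
            cost = 1e8, base_year = 2003)
}

test_that("overall scale elasticity inverts the elasticity sum everywhere", {
  p <- rand_params(seed = 51)
  nrm <- rand_norm(seed = 52)
  for (s in 1:10) {
    pt <- rand_point(nrm, seed = 520 + s)
    e <- cost_elasticity(p, pt)
    # Eq.-3 cross-check (cost over weighted marginal costs) runs inside
    expect_equal(overall_scale_elasticity(p, pt), 1 / sum(e),
                 tolerance = 1e-12)
  }
})

test_that("Cobb-Douglas limits: v = 1/sum(beta), and 1/k for c = y^k", {
  p <- cd_params(c(admissions = 0.5, outpatients = 0.3,
                   other_revenues = 0.2))
  nrm <- cd_norm(p$outputs)
  for (s in 1:5) {
    pt <- rand_point(nrm, seed = 530 + s)
    expect_equal(overall_scale_elasticity(p, pt), 1, tolerance = 1e-12)
  }
  for (k in c(0.5, 1, 2)) {
    pk <- cd_params(c(admissions = k))
    nk <- cd_norm("admissions")
    pt <- rand_point(nk, seed = 54)
    expect_equal(overall_scale_elasticity(pk, pt), 1 / k, tolerance = 1e-12)
  }
})

test_that("linear cost gives unit product-specific and chain elasticities", {
  # c proportional to y_adm, flat in everything else
  p <- cd_params(c(admissions = 1, er_visits = 0))
  nrm <- cd_norm(p$outputs)
  pt <- mean_point(nrm)
  expect_equal(product_scale_elasticity(p, pt, "admissions", 5000), 1,
               tolerance = 1e-10)
  lk <- chain_link("er_visits", "admissions", y12 = 8000)
  expect_equal(chain_scale_elasticity(p, pt, lk), 1, tolerance = 1e-10)
})

test_that("power-law closed forms match for product-specific elasticities", {
  # c = k y^2: v = ((y^2 - ymin^2)/(y - ymin)) / (2y) = (y + ymin)/(2y) < 1
  p <- cd_params(c(admissions = 2))
  nrm <- cd_norm("admissions")
  pt <- mean_point(nrm)
  y <- pt$y[["admissions"]]
  for (ymin in c(1000, 10000, 25000)) {
    expect_equal(product_scale_elasticity(p, pt, "admissions", ymin),
                 (y + ymin) / (2 * y), tolerance = 1e-10)
  }
  # general power b: closed form (y^b - ymin^b)/((y - ymin) * b * y^(b-1))
  for (b in c(0.4, 0.8, 1.6)) {
    pb <- cd_params(c(admissions = b))
    v <- product_scale_elasticity(pb, pt, "admissions", 9000)
    expect_equal(v, (y^b - 9000^b) / ((y - 9000) * b * y^(b - 1)),
                 tolerance = 1e-10)
  }
})

test_that("chain elasticity matches the two-service power-law closed form", {
  # c = k y1^b1 y2^b2 with decreasing marginal costs in both services
  b1 <- 0.35; b2 <- 0.55
  p <- cd_params(c(er_visits = b1, admissions = b2))
  nrm <- cd_norm(p$outputs)
  pt <- mean_point(nrm)
  y1 <- pt$y[["er_visits"]]; y2 <- pt$y[["admissions"]]
  C <- cost_level(p, pt)
  for (y12 in c(500, 5000, 15000)) {
    closed <- (C - C * ((y1 - y12) / y1)^b1 * ((y2 - y12) / y2)^b2) / y12 /
      (b1 * C / y1 + b2 * C / y2)
    got <- chain_scale_elasticity(p, pt, chain_link("er_visits",
                                                    "admissions", y12))
    expect_equal(got, closed, tolerance = 1e-10)
    expect_gt(got, 1)  # chain economies under decreasing marginal costs
  }
  # vanishing joint volume: average incremental cost tends to MC1 + MC2
  tiny <- chain_scale_elasticity(p, pt, chain_link("er_visits",
                                                   "admissions",
                                                   1e-6 * y1))
  expect_equal(tiny, 1, tolerance = 1e-4)
})

test_that("chain and product elasticities agree with a composition oracle", {
  p <- rand_params(seed = 55)
  nrm <- rand_norm(seed = 56)
  for (s in 1:5) {
    pt <- rand_point(nrm, seed = 560 + s, spread = 0.3)
    cbar <- nrm$cost
    lev <- function(q) cbar * exp(translog_log_cost(p, q))
    num_mc <- function(m) {
      h <- 1e-5 * pt$y[[m]]
      up <- chainscale:::.point_with_outputs(pt, setNames(pt$y[[m]] + h, m))
      dn <- chainscale:::.point_with_outputs(pt, setNames(pt$y[[m]] - h, m))
      (lev(up) - lev(dn)) / (2 * h)
    }
    m <- "admissions"
    ymin <- 0.3 * pt$y[[m]]
    cf <- chainscale:::.point_with_outputs(pt, setNames(ymin, m))
    oracle <- ((lev(pt) - lev(cf)) / (pt$y[[m]] - ymin)) / num_mc(m)
    expect_equal(product_scale_elasticity(p, pt, m, ymin), oracle,
                 tolerance = 1e-3)
    y12 <- 0.2 * min(pt$y[["er_visits"]], pt$y[["admissions"]])
    cf2 <- chainscale:::.point_with_outputs(
      pt, setNames(c(pt$y[["er_visits"]] - y12, pt$y[["admissions"]] - y12),
                   c("er_visits", "admissions")))
    oracle2 <- ((lev(pt) - lev(cf2)) / y12) /
      (num_mc("er_visits") + num_mc("admissions"))
    expect_equal(
      chain_scale_elasticity(p, pt, chain_link("er_visits", "admissions",
                                               y12)),
      oracle2, tolerance = 1e-3)
  }
})

test_that("bound violations raise instructive errors", {
  p <- cd_params(c(admissions = 0.8, er_visits = 0.1))
  nrm <- cd_norm(p$outputs)
  pt <- mean_point(nrm)
  expect_error(product_scale_elasticity(p, pt, "admissions", -5), "positive")
  expect_error(product_scale_elasticity(p, pt, "admissions", 40000),
               "below")
  expect_error(chain_scale_elasticity(p, pt,
                                      chain_link("er_visits", "admissions",
                                                 40000)),
               "below both")
  expect_error(chain_link("er_visits", "admissions", 0), "positive")
})

test_that("conditional derivative: zero for separable costs, negative under
           complementary curvature, and matching a polynomial-fit slope", {
  nrm <- cd_norm(c("admissions", "er_visits"))
  # separable power law: v(er | adm) does not depend on admissions
  p0 <- cd_params(c(admissions = 0.6, er_visits = 0.2))
  pt <- mean_point(nrm)
  expect_equal(conditional_scale_derivative(p0, pt, "er_visits", 5000,
                                            "admissions"), 0,
               tolerance = 1e-10)
  # positive cross-curvature: increasing returns of ER diminish with scale
  outs <- c("admissions", "er_visits")
  B <- matrix(c(-0.02, 0.08, 0.08, -0.04), 2, 2,
              dimnames = list(outs, outs))
  p1 <- translog_params(0.2, c(admissions = 0.6, er_visits = 0.2), B,
                        gamma = default_gamma())
  d <- conditional_scale_derivative(p1, pt, "er_visits", 5000, "admissions")
  expect_lt(d, 0)
  # slope of a 5-point quadratic fit around the same point
  ys <- pt$y[["admissions"]] * (1 + 1e-3 * (-2:2))
  vs <- vapply(ys, function(ya) {
    q <- chainscale:::.point_with_outputs(pt, c(admissions = ya))
    product_scale_elasticity(p1, q, "er_visits", 5000)
  }, 0)
  slope <- coef(lm(vs ~ ys + I(ys^2)))[["ys"]] +
    2 * coef(lm(vs ~ ys + I(ys^2)))[["I(ys^2)"]] * pt$y[["admissions"]]
  expect_equal(d, slope, tolerance = 1e-4)
  expect_error(conditional_scale_derivative(p1, pt, "er_visits",
                                            pt$y[["er_visits"]] * 0.99999,
                                            "er_visits"),
               "crosses")
})

test_that("quartile report has the published layout and handles one hospital", {
  truth <- translog_fixture("stage2")
  pan <- small_panel(seed = 57, n_hospitals = 25, years = 2011)
  fit <- list(params = truth, norm = attr(pan, "norm"))
  rep1 <- quartile_report(fit, pan[3, , drop = FALSE],
                          y_min = c(admissions = 15000, outpatients = 30000,
                                    other_revenues = 1500,
                                    er_visits = 7000))
  expect_equal(rep1$q1, rep1$median)
  expect_equal(rep1$q3, rep1$median)
  full <- quartile_report(fit, pan)
  expect_setequal(unique(full$measure),
                  c("marginal_cost", "overall_scale", "product_scale",
                    "chain_scale"))
  expect_true(all(c("er_visits-admissions", "er_visits-outpatients") %in%
                    full$service[full$measure == "chain_scale"]))
  expect_true(all(full$q1 <= full$median & full$median <= full$q3))
})
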