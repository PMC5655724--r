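# Shared fixtures: random valid parameter sets, normalization points and
# an independent term-by-term log-cost oracle.

default_gamma <- function() {
  c(man_adm = 0.12, nursing = 0.34, paramedical = 0.05,
    auxiliary = 0.09, material = 0.30, capital = 0.10)
}

# random parameter set satisfying symmetry and homogeneity exactly
rand_params <- function(seed = 1, outputs = hospital_outputs(),
                        hedonics = TRUE, years = character(0),
                        scale = 0.05) {
  set.seed(seed)
  M <- length(outputs)
  ins <- hospital_inputs()
  beta <- setNames(runif(M, 0.05, 0.6), outputs)
  B0 <- matrix(rnorm(M * M, 0, scale), M, M)
  B <- (B0 + t(B0)) / 2
  dimnames(B) <- list(outputs, outputs)
  g <- abs(rnorm(6, c(0.12, 0.34, 0.05, 0.09, 0.30, 0.10), 0.01))
  gamma <- setNames(g / sum(g), ins)
  G0 <- matrix(rnorm(36, 0, scale), 6, 6)
  G0 <- (G0 + t(G0)) / 2
  G <- G0 - outer(rowMeans(G0), rep(1, 6)) - outer(rep(1, 6), colMeans(G0)) +
    mean(G0)
  dimnames(G) <- list(ins, ins)
  D0 <- matrix(rnorm(M * 6, 0, scale / 2), M, 6)
  delta <- D0 - rowMeans(D0)
  dimnames(delta) <- list(outputs, ins)
  tau0 <- rnorm(6, 0, scale)
  tau <- setNames(tau0 - mean(tau0), ins)
  theta <- if (hedonics)
    setNames(rnorm(6, 0, 0.1), hedonic_vars())
  else setNames(numeric(0), character(0))
  ye <- if (length(years)) setNames(rnorm(length(years), 0, 0.05), years)
  else setNames(numeric(0), character(0))
  translog_params(rnorm(1, 0.2, 0.05), beta, B, gamma, G, delta, tau,
                  theta, ye)
}

rand_norm <- function(seed = 2, outputs = hospital_outputs()) {
  set.seed(seed)
  make_norm(
    y = setNames(exp(runif(length(outputs), 8, 11.5)), outputs),
    w = setNames(c(exp(runif(4, 10, 11)), 1, exp(runif(1, 9, 10))),
                 hospital_inputs()),
    z = setNames(c(0.12, 0.3, 0.2, 3.3, 0.01, 0.004), hedonic_vars()),
    cost = 1.3e8, base_year = 2003L)
}

# random point in the neighbourhood of the mean (log spread `spread`)
rand_point <- function(norm, seed = 3, spread = 0.5, year = NULL) {
  set.seed(seed)
  y <- norm$y * exp(runif(length(norm$y), -spread, spread))
  w <- norm$w * exp(runif(6, -spread, spread))
  z <- norm$z * exp(runif(length(norm$z), -0.3, 0.3))
  translog_point(y, w, z, year %||% norm$base_year, norm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent term-by-term enumeration of the translog polynomial,
# written with explicit scalar loops (no shared code with the package's
# vectorised evaluator)
oracle_log_cost <- function(params, point) {
  outs <- params$outputs
  ins <- hospital_inputs()
  yh <- log(point$y[outs] / point$norm$y[outs])
  wh <- log(point$w / point$norm$w)
  total <- params$alpha0
  yr <- as.character(point$year)
  if (yr %in% names(params$year_effects))
    total <- total + params$year_effects[[yr]]
  for (m in outs) total <- total + params$beta[[m]] * yh[[m]]
  for (m in outs) for (n in outs)
    total <- total + 0.5 * params$B[m, n] * yh[[m]] * yh[[n]]
  for (i in ins) total <- total + params$gamma[[i]] * wh[[i]]
  for (i in ins) for (j in ins)
    total <- total + 0.5 * params$G[i, j] * wh[[i]] * wh[[j]]
  for (m in outs) for (i in ins)
    total <- total + params$delta[m, i] * yh[[m]] * wh[[i]]
  trend <- (point$year - point$norm$base_year) / 10
  for (i in ins) total <- total + trend * params$tau[[i]] * wh[[i]]
  if (length(params$theta)) {
    for (k in names(params$theta))
      total <- total + yh[["admissions"]] * params$theta[[k]] *
        (point$z[[k]] - point$norm$z[[k]])
  }
  total
}

# central finite difference of log cost in one standardized direction
fd_elasticity <- function(params, point, m, h = 1e-6) {
  shift <- function(s) {
    y <- point$y
    y[m] <- y[m] * exp(s)
    translog_point(y, point$w, point$z, point$year, point$norm)
  }
  (translog_log_cost(params, shift(h)) -
     translog_log_cost(params, shift(-h))) / (2 * h)
}

fd_share <- function(params, point, i, h = 1e-6) {
  shift <- function(s) {
    w <- point$w
    w[i] <- w[i] * exp(s)
    translog_point(point$y, w, point$z, point$year, point$norm)
  }
  (translog_log_cost(params, shift(h)) -
     translog_log_cost(params, shift(-h))) / (2 * h)
}

# small calibrated synthetic panel, cached per test file run
small_panel <- function(seed = 101, n_hospitals = 40, years = 2009:2011,
                        er_coverage = 1, truth = translog_fixture("stage2"),
                        ...) {
  cfg <- sim_config(n_hospitals = n_hospitals, years = years,
                    target_n_obs = NULL, er_coverage = er_coverage,
                    seed = seed, ...)
  generate_costs(generate_panel(cfg), truth)
}
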