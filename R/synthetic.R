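# Synthetic hospital-year panel generator.
#
# The generator emulates the statistical structure the cost-system analysis
# assumes: right-skewed, cross-correlated service volumes with target
# cross-section moments; labor unit values driven by region and year;
# a CPI-indexed material price; capital components correlated with
# admissions; ER follow-up disposition shares summing to one; and — via
# generate_costs() — a cost/share system generated from a known translog
# parameter set with cross-equation-correlated noise.

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic panel
#' generator.  Defaults emulate the 2003-2011 Dutch general-hospital
#' estimation sample: 682 hospital-year observations, an ER subsample of
#' 249, 2011 cross-section moments for volumes and hedonics, and published
#' ER disposition shares.
#'
#' @param n_hospitals Number of hospitals.
#' @param years Calendar years of the panel.
#' @param target_n_obs Total rows kept (random subsample emulating an
#'   unbalanced panel); `NULL` keeps the full balanced panel.
#' @param er_coverage Fraction of kept rows with observed ER data.
#' @param region_count Number of health regions.
#' @param output_targets Data frame with columns `mean` and `sd`, rows
#'   named by [hospital_outputs()]: reference-year (last year) lognormal
#'   moment targets.
#' @param output_growth Named annual log-growth rates backcasting levels to
#'   earlier years.
#' @param output_corr Log-scale correlation matrix of the four services.
#' @param output_year_noise_sd SD of idiosyncratic per-year log jitter.
#' @param hedonic_targets Data frame (`mean`, `sd`) rows named by
#'   [hedonic_vars()]; characteristics are constant within hospital.
#' @param disposition_targets Data frame (`mean`, `sd`) for the six ER
#'   follow-up categories (`none`, `outpatient`, `admission`, `ic`,
#'   `other_hosp`, `other`); draws are renormalized to sum to one per row.
#' @param labor_base Named base-year unit values (EUR/FTE-year) of the four
#'   labor categories.
#' @param wage_growth,region_sd,unit_value_noise_sd Log-scale annual wage
#'   growth, SD of region effects, and SD of idiosyncratic unit-value
#'   noise.
#' @param cpi_growth Annual CPI growth for the material index.
#' @param capital_weights Named true per-unit capital costs of `beds`,
#'   `ic_beds_n`, `radiotherapists`, `theatres`.
#' @param capital_cost_noise_sd Log SD of capital-cost noise.
#' @param capital_component_noise_sd Base log SD of the idiosyncratic
#'   variation of capital components around their admissions-driven level
#'   (IC beds and theatres use 3x and 2.5x this SD; zero makes the
#'   components deterministic, radiotherapists included).
#' @param mean_total_cost Mean total cost (EUR) anchoring cost levels.
#' @param noise_sd_logcost SD of the cost-equation disturbance; `NULL`
#'   calibrates it to `target_r2` (see [calibrate_cost_noise()]).
#' @param target_r2 Cost-equation R-squared the calibrated noise implies.
#' @param share_noise_sd SD of per-equation share noise before the
#'   adding-up projection.
#' @param seed RNG seed; identical config and seed give identical panels.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_hospitals = 76, years = 2003:2011, target_n_obs = 682,
    er_coverage = 249 / 682, region_count = 8,
    output_targets = NULL, output_growth = NULL, output_corr = NULL,
    output_year_noise_sd = 0.02,
    hedonic_targets = NULL, disposition_targets = NULL,
    labor_base = c(man_adm = 48000, nursing = 45000,
                   paramedical = 42000, auxiliary = 30000),
    wage_growth = 0.025, region_sd = 0.03, unit_value_noise_sd = 0.02,
    cpi_growth = 0.018,
    capital_weights = c(beds = 12000, ic_beds_n = 60000,
                        radiotherapists = 150000, theatres = 80000),
    capital_cost_noise_sd = 0.05, capital_component_noise_sd = 0.1,
    mean_total_cost = 130e6, noise_sd_logcost = NULL, target_r2 = 0.98,
    share_noise_sd = 0.01, seed = 1L) {
  outs <- hospital_outputs()
  if (is.null(output_targets))
    output_targets <- data.frame(
      mean = c(44767, 76347, 14896, 24115),
      sd   = c(20854, 29048, 10079, 12771),
      row.names = outs)
  if (is.null(output_growth))
    output_growth <- c(admissions = log(1.66) / 8, outpatients = log(1.30) / 8,
                       other_revenues = 0.03, er_visits = 0.03)
  if (is.null(output_corr)) {
    output_corr <- matrix(0.5, 4, 4, dimnames = list(outs, outs))
    output_corr["admissions", "er_visits"] <-
      output_corr["er_visits", "admissions"] <- 0.8
    output_corr["admissions", "outpatients"] <-
      output_corr["outpatients", "admissions"] <- 0.7
    diag(output_corr) <- 1
  }
  if (is.null(hedonic_targets))
    hedonic_targets <- data.frame(
      mean = c(0.117, 0.27, 0.23, 3.3, 0.008, 0.003),
      sd   = c(0.024, 0.40, 0.09, 0.3, 0.019, 0.009),
      row.names = hedonic_vars())
  if (is.null(disposition_targets))
    disposition_targets <- data.frame(
      mean = c(0.35, 0.27, 0.32, 0.03, 0.01, 0.03),
      sd   = c(0.19, 0.17, 0.08, 0.03, 0.01, 0.03),
      row.names = c("none", "outpatient", "admission", "ic",
                    "other_hosp", "other"))
  cfg <- list(
    n_hospitals = as.integer(n_hospitals), years = as.integer(years),
    target_n_obs = if (is.null(target_n_obs)) NULL else
      as.integer(target_n_obs),
    er_coverage = er_coverage, region_count = as.integer(region_count),
    output_targets = output_targets, output_growth = output_growth,
    output_corr = output_corr, output_year_noise_sd = output_year_noise_sd,
    hedonic_targets = hedonic_targets,
    disposition_targets = disposition_targets,
    labor_base = labor_base, wage_growth = wage_growth,
    region_sd = region_sd, unit_value_noise_sd = unit_value_noise_sd,
    cpi_growth = cpi_growth, capital_weights = capital_weights,
    capital_cost_noise_sd = capital_cost_noise_sd,
    capital_component_noise_sd = capital_component_noise_sd,
    mean_total_cost = mean_total_cost,
    noise_sd_logcost = noise_sd_logcost, target_r2 = target_r2,
    share_noise_sd = share_noise_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  with(cfg, {
    if (er_coverage <= 0 || er_coverage > 1)
      stop("er_coverage must be in (0, 1]", call. = FALSE)
    if (any(output_targets$sd < 0) || any(hedonic_targets$sd < 0) ||
        any(disposition_targets$sd < 0))
      stop("target sds must be non-negative", call. = FALSE)
    if (any(output_targets$mean <= 0))
      stop("output moment targets must have positive means", call. = FALSE)
    if (any(output_targets$sd > output_targets$mean))
      stop("infeasible lognormal target: sd exceeds mean for ",
           paste(rownames(output_targets)[
             output_targets$sd > output_targets$mean], collapse = ", "),
           call. = FALSE)
    if (!is.null(target_n_obs) &&
        target_n_obs > n_hospitals * length(years))
      stop("target_n_obs exceeds the balanced panel size", call. = FALSE)
  })
  invisible(cfg)
}

# lognormal parameters hitting arithmetic mean m and sd s
.lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log1p((s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.truncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic hospital-year panel
#'
#' Draws a panel with the structure described in [sim_config()]: lognormal
#' cross-correlated service volumes, hedonic characteristics, ER
#' disposition shares, labor unit values with region/year structure, a CPI
#' path, capital components and capital costs.  Input prices are attached
#' through the package's own price-construction pipeline
#' ([labor_price_proxy()], [material_price_index()],
#' [capital_volume_index()], [capital_price()]).
#'
#' The column `er_visits_full` holds the complete ER counts used by cost
#' generation; `er_visits` and the disposition columns are masked to `NA`
#' outside the ER-coverage subsample, as in a survey with partial response.
#'
#' @param config A [sim_config()] object.
#' @return A hospital-year data frame (one row per kept hospital-year).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  outs <- hospital_outputs()
  H <- cfg$n_hospitals; yrs <- cfg$years; ref <- max(yrs)
  regions <- paste0("R", seq_len(cfg$region_count))

  # hospital-level draws -------------------------------------------------
  hosp <- data.frame(hospital_id = sprintf("H%03d", seq_len(H)),
                     region = sample(regions, H, replace = TRUE))
  lp <- lapply(outs, function(m)
    .lnorm_pars(cfg$output_targets[m, "mean"], cfg$output_targets[m, "sd"]))
  names(lp) <- outs
  sdlog <- vapply(lp, `[[`, 0, "sdlog")
  Sig <- diag(sdlog) %*% cfg$output_corr %*% diag(sdlog)
  base_log <- MASS::mvrnorm(H, mu = vapply(lp, `[[`, 0, "meanlog"),
                            Sigma = Sig)
  colnames(base_log) <- outs

  ht <- cfg$hedonic_targets
  hed <- data.frame(
    surgery_ortho = .truncnorm(H, ht["surgery_ortho", 1],
                               ht["surgery_ortho", 2], 0, 1),
    psych_beds = .truncnorm(H, ht["psych_beds", 1], ht["psych_beds", 2], 0),
    ic_beds = .truncnorm(H, ht["ic_beds", 1], ht["ic_beds", 2], 0),
    expected_los = .truncnorm(H, ht["expected_los", 1],
                              ht["expected_los", 2], 1),
    neurosurgery = .truncnorm(H, ht["neurosurgery", 1],
                              ht["neurosurgery", 2], 0, 1),
    cardiothoracic = .truncnorm(H, ht["cardiothoracic", 1],
                                ht["cardiothoracic", 2], 0, 1))
  names(hed) <- paste0("z_", hedonic_vars())

  # hospital-year frame ---------------------------------------------------
  panel <- merge(cbind(hosp, hed),
                 expand.grid(hospital_id = hosp$hospital_id, year = yrs,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
                 by = "hospital_id")
  panel <- panel[order(panel$hospital_id, panel$year), ]
  rownames(panel) <- NULL
  n <- nrow(panel)
  ih <- match(panel$hospital_id, hosp$hospital_id)
  for (m in outs) {
    g <- cfg$output_growth[[m]]
    jit <- if (cfg$output_year_noise_sd > 0)
      rnorm(n, 0, cfg$output_year_noise_sd) * (panel$year != ref) else 0
    panel[[m]] <- exp(base_log[ih, m] - g * (ref - panel$year) + jit)
  }

  # ER disposition shares -------------------------------------------------
  dt <- cfg$disposition_targets
  disp <- vapply(rownames(dt), function(k)
    pmax(.truncnorm(n, dt[k, "mean"], dt[k, "sd"]), 0.001), numeric(n))
  disp <- disp / rowSums(disp)
  colnames(disp) <- paste0("disp_", rownames(dt))
  panel <- cbind(panel, disp)

  # labor unit values and price proxies ----------------------------------
  cats <- names(cfg$labor_base)
  region_eff <- matrix(rnorm(cfg$region_count * length(cats), 0,
                             cfg$region_sd),
                       cfg$region_count, length(cats),
                       dimnames = list(regions, cats))
  fte_scale <- c(man_adm = 1 / 180, nursing = 1 / 40, paramedical = 1 / 400,
                 auxiliary = 1 / 150)
  uv_list <- lapply(cats, function(cat) {
    uv <- cfg$labor_base[[cat]] *
      exp(region_eff[panel$region, cat] +
            cfg$wage_growth * (panel$year - min(yrs)) +
            rnorm(n, 0, cfg$unit_value_noise_sd))
    fte <- pmax(panel$admissions * fte_scale[[cat]], 1)
    data.frame(hospital_id = panel$hospital_id, year = panel$year,
               region = panel$region, category = cat,
               unit_value = uv, fte = fte, cost = uv * fte)
  })
  uv_long <- labor_price_proxy(do.call(rbind, uv_list))
  for (cat in cats) {
    idx <- uv_long$category == cat
    panel[[paste0("w_", cat)]] <- uv_long$price[idx]
    panel[[paste0("unit_value_", cat)]] <- uv_long$unit_value[idx]
    panel[[paste0("fte_", cat)]] <- uv_long$fte[idx]
  }

  # material price: CPI path, base one in the first year ------------------
  cpi <- data.frame(year = yrs,
                    cpi = (1 + cfg$cpi_growth)^(yrs - min(yrs)))
  idx_mat <- material_price_index(cpi, base_year = min(yrs))
  panel$w_material <- idx_mat$index[match(panel$year, idx_mat$year)]

  # capital components, cost, volume and implicit price -------------------
  ks <- cfg$capital_component_noise_sd
  panel$beds <- pmax(panel$admissions / 110 * exp(rnorm(n, 0, ks)), 40)
  panel$ic_beds_n <- pmax(round(panel$beds * 0.025 *
                                  exp(rnorm(n, 0, 3 * ks))), 1)
  panel$radiotherapists <- if (ks > 0) stats::rpois(n, 1) else rep(1L, n)
  panel$theatres <- pmax(round(panel$beds / 40 *
                                 exp(rnorm(n, 0, 2.5 * ks))), 1)
  comp <- panel[, names(cfg$capital_weights)]
  panel$capital_cost <- drop(as.matrix(comp) %*% cfg$capital_weights) *
    exp(rnorm(n, 0, cfg$capital_cost_noise_sd))
  cv <- capital_volume_index(panel$capital_cost, comp)
  panel$capital_volume <- cv$volume
  panel$w_capital <- capital_price(panel$capital_cost, cv$volume)

  # unbalance and ER masking ----------------------------------------------
  if (!is.null(cfg$target_n_obs) && cfg$target_n_obs < n) {
    keep <- sort(sample.int(n, cfg$target_n_obs))
    panel <- panel[keep, ]
    rownames(panel) <- NULL
    n <- nrow(panel)
  }
  panel$er_visits_full <- panel$er_visits
  if (cfg$er_coverage < 1) {
    n_er <- round(cfg$er_coverage * n)
    masked <- setdiff(seq_len(n), sort(sample.int(n, n_er)))
    panel$er_visits[masked] <- NA_real_
    for (k in grep("^disp_", names(panel))) panel[[k]][masked] <- NA_real_
  }
  attr(panel, "sim_config") <- cfg
  panel
}

#' Calibrate the cost-equation noise SD to a target R-squared
#'
#' Computes the variance of the systematic standardized log cost over the
#' panel and returns the disturbance SD for which the population
#' cost-equation R-squared equals `target_r2`.
#'
#' @param panel A panel from [generate_panel()].
#' @param params The generating [translog_params()].
#' @param target_r2 Target cost-equation R-squared.
#' @param norm Normalization point; defaults to panel means.
#' @return Scalar noise SD (standardized log-cost units).
#' @export
calibrate_cost_noise <- function(panel, params, target_r2 = 0.98,
                                 norm = NULL) {
  norm <- norm %||% normalization_point(panel)
  f <- .panel_log_cost(panel, params, norm)
  sqrt(stats::var(f) * (1 - target_r2) / target_r2)
}

# vectorized standardized design pieces for a panel; `prefer_full` uses the
# generator's complete ER column when present (cost generation needs the
# true level for every row, observed or not)
.panel_vars <- function(panel, norm, outputs, prefer_full = TRUE) {
  outs <- outputs
  ycols <- if (prefer_full)
    ifelse(outs == "er_visits" & "er_visits_full" %in% names(panel),
           "er_visits_full", outs)
  else outs
  Y <- as.matrix(panel[, ycols, drop = FALSE]); colnames(Y) <- outs
  if (any(!is.finite(Y) | Y <= 0))
    stop("non-positive or missing service level in panel for the model's ",
         "services", call. = FALSE)
  Yh <- sweep(log(Y), 2, log(norm$y[outs]))
  W <- as.matrix(panel[, paste0("w_", hospital_inputs())])
  colnames(W) <- hospital_inputs()
  if (any(!is.finite(W) | W <= 0))
    stop("non-positive or missing input price in panel", call. = FALSE)
  Wh <- sweep(log(W), 2, log(norm$w))
  Zc <- if (length(norm$z)) {
    Z <- as.matrix(panel[, paste0("z_", names(norm$z))])
    colnames(Z) <- names(norm$z)
    sweep(Z, 2, norm$z)
  } else matrix(0, nrow(panel), 0)
  trend <- (panel$year - norm$base_year) / 10
  list(Yh = Yh, Wh = Wh, Zc = Zc, trend = trend)
}

.panel_year_effect <- function(panel, params) {
  ye <- params$year_effects
  if (!length(ye)) return(numeric(nrow(panel)))
  idx <- match(as.character(panel$year), names(ye))
  ifelse(is.na(idx), 0, ye[idx])
}

.panel_log_cost <- function(panel, params, norm) {
  v <- .panel_vars(panel, norm, params$outputs)
  thz <- if (length(params$theta))
    drop(v$Zc[, names(params$theta), drop = FALSE] %*% params$theta)
  else 0
  params$alpha0 + .panel_year_effect(panel, params) +
    drop(v$Yh %*% params$beta) +
    0.5 * rowSums((v$Yh %*% params$B) * v$Yh) +
    drop(v$Wh %*% params$gamma) +
    0.5 * rowSums((v$Wh %*% params$G) * v$Wh) +
    rowSums((v$Yh %*% params$delta) * v$Wh) +
    v$trend * drop(v$Wh %*% params$tau) +
    v$Yh[, "admissions"] * thz
}

.panel_shares <- function(panel, params, norm) {
  v <- .panel_vars(panel, norm, params$outputs)
  S <- matrix(rep(params$gamma, each = nrow(panel)), nrow(panel), 6)
  S <- S + v$Wh %*% params$G + v$Yh %*% params$delta +
    outer(v$trend, params$tau)
  colnames(S) <- hospital_inputs()
  S
}

#' Generate observed costs and cost shares from a known parameter set
#'
#' The data-generating twin of the estimated system: standardized log cost
#' is the translog surface plus Gaussian noise; observed shares are the
#' predicted shares plus mean-zero noise re-projected to satisfy adding-up
#' exactly (equivalent to dropping one equation in generation, preserving
#' the singular covariance structure the estimator assumes).
#'
#' @param panel A panel from [generate_panel()].
#' @param true_params Generating [translog_params()]; must satisfy the
#'   homogeneity invariants.
#' @param noise_sd Cost-equation disturbance SD; `NULL` calibrates to the
#'   config's `target_r2` via [calibrate_cost_noise()].
#' @param share_noise_sd Pre-projection share noise SD (scalar or length-6),
#'   default from the panel's config.
#' @param cost_mean Mean total cost anchoring levels, default from config.
#' @param seed RNG seed, default `config$seed + 1`.
#' @return The panel with columns `total_cost`, `share_<input>` and
#'   `cost_<input>` appended; attributes `norm` (the frozen normalization
#'   point), `true_params` and `noise_sd`.
#' @export
generate_costs <- function(panel, true_params, noise_sd = NULL,
                           share_noise_sd = NULL, cost_mean = NULL,
                           seed = NULL) {
  validate_translog_params(true_params)
  cfg <- attr(panel, "sim_config")
  share_noise_sd <- share_noise_sd %||% cfg$share_noise_sd %||% 0.01
  cost_mean <- cost_mean %||% cfg$mean_total_cost %||% 130e6
  seed <- seed %||% (cfg$seed %||% 0L) + 1L
  set.seed(seed)
  norm <- normalization_point(panel)
  norm$cost <- cost_mean
  n <- nrow(panel)
  f <- .panel_log_cost(panel, true_params, norm)
  noise_sd <- noise_sd %||%
    calibrate_cost_noise(panel, true_params, cfg$target_r2 %||% 0.98, norm)
  logc <- f + rnorm(n, 0, noise_sd)
  panel$total_cost <- cost_mean * exp(logc)
  S <- .panel_shares(panel, true_params, norm)
  if (length(share_noise_sd) == 1) share_noise_sd <- rep(share_noise_sd, 6)
  eta <- MASS::mvrnorm(n, mu = numeric(6), Sigma = diag(share_noise_sd^2))
  eta <- eta - rowMeans(eta)  # adding-up projection: rows of S + eta sum to 1
  S_obs <- S + eta
  for (i in seq_along(hospital_inputs())) {
    nm <- hospital_inputs()[i]
    panel[[paste0("share_", nm)]] <- S_obs[, i]
    panel[[paste0("cost_", nm)]] <- S_obs[, i] * panel$total_cost
  }
  attr(panel, "norm") <- norm
  attr(panel, "true_params") <- true_params
  attr(panel, "noise_sd") <- noise_sd
  panel
}
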