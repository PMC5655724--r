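# check that a parameter set and a point describe the same services
.match_outputs <- function(params, point) {
  outs <- params$outputs
  if (!all(outs %in% names(point$yhat)))
    stop("point lacks service levels for: ",
         paste(setdiff(outs, names(point$yhat)), collapse = ", "),
         call. = FALSE)
  outs
}

.year_effect <- function(params, point) {
  yr <- as.character(point$year)
  if (yr %in% names(params$year_effects)) params$year_effects[[yr]] else 0
}

#' Evaluate standardized log cost of the translog system
#'
#' Exact analytic evaluation of the translog log-cost surface at an
#' arbitrary point: intercept, year effect, first- and second-order output
#' terms, first- and second-order price terms, output-price interactions,
#' trend-price interactions and the admissions-hedonic interactions.
#'
#' @param params A [translog_params()] object.
#' @param point A [translog_point()] object.
#' @return Standardized log cost, \eqn{\log(C/\bar C)} (dimensionless).
#' @seealso [cost_level()] for cost in currency units,
#'   [cost_elasticity()], [predicted_shares()], [marginal_cost()].
#' @export
#' @examples
#' p <- translog_fixture("stage2")
#' translog_log_cost(p, mean_point(reference_norm()))  # the intercept, 0.191
translog_log_cost <- function(params, point) {
  outs <- .match_outputs(params, point)
  yh <- point$yhat[outs]
  wh <- point$what
  lc <- params$alpha0 + .year_effect(params, point) +
    sum(params$beta * yh) + 0.5 * drop(yh %*% params$B %*% yh) +
    sum(params$gamma * wh) + 0.5 * drop(wh %*% params$G %*% wh) +
    drop(yh %*% params$delta %*% wh) +
    point$trend * sum(params$tau * wh)
  if (length(params$theta)) {
    zc <- point$zc[names(params$theta)]
    lc <- lc + yh[["admissions"]] * sum(params$theta * zc)
  }
  unname(lc)
}

#' Total cost in currency units at a point
#'
#' Converts the standardized log-cost evaluation back to levels using the
#' stored mean total cost: \eqn{C = \bar C \exp(\log(C/\bar C))}.
#'
#' @inheritParams translog_log_cost
#' @return Total cost in the currency units of the normalization mean.
#' @export
cost_level <- function(params, point) {
  cbar <- point$norm$cost
  if (!is.finite(cbar) || cbar <= 0)
    stop("normalization point has no positive mean total cost", call. = FALSE)
  cbar * exp(translog_log_cost(params, point))
}

#' Cost elasticity of one service
#'
#' Analytic derivative of log cost with respect to the log level of service
#' `m`: \eqn{\beta_m + \sum_n B_{mn}\hat y_n + \sum_i \delta_{mi}\hat w_i}
#' (plus \eqn{\sum_k \theta_k z_k} for admissions).  At the normalization
#' point it equals the first-order coefficient \eqn{\beta_m}.
#'
#' @inheritParams translog_log_cost
#' @param m Service id(s) from [hospital_outputs()]; defaults to every
#'   service in the model.
#' @return Named numeric vector of dimensionless elasticities.
#' @export
#' @examples
#' p <- translog_fixture("stage2")
#' cost_elasticity(p, mean_point(reference_norm()))
cost_elasticity <- function(params, point, m = params$outputs) {
  outs <- .match_outputs(params, point)
  if (!all(m %in% outs))
    stop("unknown service id: ", paste(setdiff(m, outs), collapse = ", "),
         call. = FALSE)
  yh <- point$yhat[outs]
  e <- params$beta + drop(params$B %*% yh) + drop(params$delta %*% point$what)
  if (length(params$theta)) {
    zc <- point$zc[names(params$theta)]
    e["admissions"] <- e["admissions"] + sum(params$theta * zc)
  }
  e[m]
}

#' Predicted input cost shares
#'
#' The logarithmic price gradient of the cost function: by Shephard's lemma
#' \eqn{s_i = \partial \log c / \partial \log w_i = \gamma_i +
#' \sum_j G_{ij}\hat w_j + \sum_m \delta_{mi}\hat y_m + \tau_i t}.
#' Under the homogeneity invariants the shares sum to one identically.
#'
#' @inheritParams translog_log_cost
#' @return Named numeric vector of the six predicted cost shares.
#' @export
#' @examples
#' p1 <- translog_fixture("stage1")
#' predicted_shares(p1, mean_point(reference_norm()))  # the gammas
predicted_shares <- function(params, point) {
  outs <- .match_outputs(params, point)
  yh <- point$yhat[outs]
  params$gamma + drop(params$G %*% point$what) +
    drop(t(params$delta) %*% yh) + params$tau * point$trend
}

#' Marginal cost of one service, in currency units
#'
#' \eqn{MC_m = (\partial \log c/\partial \log y_m) \times C / y_m}, with
#' the cost level taken from the model surface at the point (or supplied).
#'
#' @inheritParams cost_elasticity
#' @param total_cost Total cost level in currency units; defaults to the
#'   model-predicted [cost_level()] at the point.
#' @return Named numeric vector, currency units per unit of service.
#' @export
marginal_cost <- function(params, point, m = params$outputs,
                          total_cost = NULL) {
  total_cost <- total_cost %||% cost_level(params, point)
  e <- cost_elasticity(params, point, m)
  ym <- point$y[m]
  .check_positive(ym, "y")
  e * total_cost / ym
}
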