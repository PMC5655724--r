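# Scale economics derived from a fitted (or fixed) cost system.  All
# incremental and marginal quantities are computed in cost LEVELS
# (currency units), converting from the standardized log surface with the
# stored mean total cost.

#' Overall (ray) scale elasticity
#'
#' The inverse of the sum of the cost elasticities over all services.
#' Equivalently, the ratio of total cost to the output-weighted sum of
#' marginal costs; both forms are computed and verified to agree.
#' Values above one indicate economies of scale, below one diseconomies.
#'
#' @inheritParams translog_log_cost
#' @return Scalar elasticity (dimensionless).
#' @export
#' @examples
#' p <- translog_fixture("stage2")
#' overall_scale_elasticity(p, mean_point(reference_norm()))  # ~0.952
overall_scale_elasticity <- function(params, point) {
  e <- cost_elasticity(params, point)
  s <- sum(e)
  if (s <= 0)
    stop("regularity violation: cost elasticities sum to ",
         format(s), " (must be positive)", call. = FALSE)
  v1 <- 1 / s
  if (is.finite(point$norm$cost)) {
    C <- cost_level(params, point)
    mc <- marginal_cost(params, point)
    v2 <- C / sum(point$y[params$outputs] * mc)
    stopifnot(abs(v1 - v2) <= 1e-10 * max(1, abs(v1)))
  }
  v1
}

#' Product-specific scale elasticity with minimum-output substitution
#'
#' The average incremental cost of producing service `m` at its current
#' level rather than at the lowest level observed in the data, divided by
#' its marginal cost — holding every other variable fixed:
#' \deqn{v(y_m \mid \cdot) = \frac{[c(y) - c(y; y_m \to y_m^{min})] /
#'   (y_m - y_m^{min})}{\partial c / \partial y_m}.}
#' Because the fixed costs of the minimum level remain in the
#' counterfactual, this is a conservative (lower-bound) reading of the
#' zero-production definition.  Values above one indicate product-specific
#' economies of scale.
#'
#' @inheritParams cost_elasticity
#' @param m A single service id.
#' @param y_min The minimum service level substituted for zero production
#'   (typically the sample minimum); must satisfy `0 < y_min < y_m`.
#' @return Scalar elasticity (dimensionless).
#' @export
product_scale_elasticity <- function(params, point, m, y_min) {
  stopifnot(length(m) == 1, m %in% params$outputs)
  ym <- point$y[[m]]
  if (!is.finite(y_min) || y_min <= 0)
    stop("`y_min` must be strictly positive", call. = FALSE)
  if (y_min >= ym)
    stop(sprintf("`y_min` (%.6g) must be below the evaluated level %.6g",
                 y_min, ym), call. = FALSE)
  C1 <- cost_level(params, point)
  C0 <- cost_level(params, .point_with_outputs(point, setNames(y_min, m)))
  aic <- (C1 - C0) / (ym - y_min)
  mc <- marginal_cost(params, point, m, total_cost = C1)
  unname(aic / mc)
}

#' A sequential-service chain
#'
#' Describes a pair of sequential services and their joint volume: `y12`
#' upstream events (e.g. ER visits) followed by the downstream service
#' (e.g. an inpatient admission).  The joint count is part of both
#' services' totals.
#'
#' @param upstream,downstream Service ids from [hospital_outputs()].
#' @param y12 Joint volume (count/year), strictly positive.
#' @return An object of class `chain_link`.
#' @export
chain_link <- function(upstream = "er_visits", downstream = "admissions",
                       y12) {
  stopifnot(upstream %in% hospital_outputs(),
            downstream %in% hospital_outputs(), upstream != downstream)
  if (!is.finite(y12) || y12 <= 0)
    stop("`y12` must be strictly positive", call. = FALSE)
  structure(list(upstream = upstream, downstream = downstream,
                 y12 = as.numeric(y12)), class = "chain_link")
}

#' Chain scale elasticity of two sequential services
#'
#' Economies of scale of the joint volume of two sequential services: the
#' average incremental cost of the `y12` joint units (removing `y12` from
#' both services in the counterfactual) divided by the sum of the two
#' marginal costs at the actual point,
#' \deqn{v_{12} = \frac{[c(y_1, y_2) - c(y_1 - y_{12}, y_2 - y_{12})] /
#'   y_{12}}{\partial c/\partial y_1 + \partial c/\partial y_2}.}
#' Values above one indicate chain economies.
#'
#' @inheritParams cost_elasticity
#' @param link A [chain_link()].
#' @return Scalar elasticity (dimensionless).
#' @export
chain_scale_elasticity <- function(params, point, link) {
  stopifnot(inherits(link, "chain_link"))
  y1 <- point$y[[link$upstream]]; y2 <- point$y[[link$downstream]]
  y12 <- link$y12
  if (y12 >= min(y1, y2))
    stop("`y12` must be below both service levels", call. = FALSE)
  if (y1 - y12 <= 0 || y2 - y12 <= 0)
    stop("counterfactual output non-positive; reduce `y12`", call. = FALSE)
  C1 <- cost_level(params, point)
  C0 <- cost_level(params, .point_with_outputs(
    point, setNames(c(y1 - y12, y2 - y12), c(link$upstream,
                                             link$downstream))))
  mc <- marginal_cost(params, point, c(link$upstream, link$downstream),
                      total_cost = C1)
  unname(((C1 - C0) / y12) / sum(mc))
}

#' Numeric derivative of a product-specific scale elasticity
#'
#' Central finite difference of [product_scale_elasticity()] for service
#' `m` with respect to the level of a conditioning service `n`.  A
#' negative value means the increasing returns to scale of `m` diminish as
#' `n` grows.
#'
#' @inheritParams product_scale_elasticity
#' @param n Conditioning service (level that is perturbed).
#' @param rel_step Relative step of the central difference.
#' @return Scalar derivative (per unit of service `n`).
#' @export
conditional_scale_derivative <- function(params, point, m, y_min, n,
                                         rel_step = 1e-4) {
  stopifnot(n %in% params$outputs)
  yn <- point$y[[n]]
  h <- rel_step * yn
  if (n == m && (yn - h) <= y_min)
    stop("finite-difference step crosses the `y_min` bound", call. = FALSE)
  vp <- product_scale_elasticity(
    params, .point_with_outputs(point, setNames(yn + h, n)), m, y_min)
  vm <- product_scale_elasticity(
    params, .point_with_outputs(point, setNames(yn - h, n)), m, y_min)
  (vp - vm) / (2 * h)
}

#' Quartile report of marginal costs and scale measures across hospitals
#'
#' Evaluates, at every hospital's observed point, the model-predicted
#' marginal costs, the overall scale elasticity, the product-specific
#' scale elasticities (minimum levels taken from the sample) and the chain
#' elasticities, and summarizes each measure by quartiles (linear
#' interpolation).  Hospitals failing regularity (a non-positive predicted
#' share or cost elasticity) are excluded from the quartiles and counted.
#'
#' @param fit A `translog_fit` (or a list with elements `params` and
#'   `norm`).
#' @param panel Hospital-year rows to evaluate (e.g. one cross-section
#'   year); must contain the model's services, prices and hedonics, and —
#'   for the chain rows — ER disposition shares.
#' @param links Chain definitions: a list of lists with `upstream`,
#'   `downstream` and `share_cols` (disposition columns whose sum, times
#'   the upstream volume, gives `y12`).  The default pairs ER visits with
#'   admissions (admission + IC/stroke/CCU dispositions) and with
#'   outpatient care.
#' @param y_min Named vector of minimum service levels; defaults to the
#'   sample minima of `panel`.
#' @return A data frame with columns `measure`, `service`, `q1`, `median`,
#'   `q3`, `n`, `n_excluded`.
#' @export
quartile_report <- function(fit, panel, links = NULL, y_min = NULL) {
  params <- fit$params; norm <- fit$norm
  stopifnot(inherits(params, "translog_params"),
            inherits(norm, "translog_norm"))
  outs <- params$outputs
  links <- links %||% list(
    list(upstream = "er_visits", downstream = "admissions",
         share_cols = c("disp_admission", "disp_ic")),
    list(upstream = "er_visits", downstream = "outpatients",
         share_cols = "disp_outpatient"))
  keep <- complete.cases(panel[, c(outs, paste0("w_", hospital_inputs()))])
  panel <- panel[keep, , drop = FALSE]
  n <- nrow(panel)
  if (!n) stop("no complete observations to evaluate", call. = FALSE)
  y_min <- y_min %||% vapply(outs, function(m) min(panel[[m]]), 0)
  pts <- lapply(seq_len(n), function(r) {
    z <- if (length(norm$z)) {
      zz <- as.numeric(panel[r, paste0("z_", names(norm$z))])
      names(zz) <- names(norm$z); zz
    } else NULL
    translog_point(setNames(as.numeric(panel[r, outs]), outs),
                   setNames(as.numeric(panel[r, paste0("w_",
                                                       hospital_inputs())]),
                            hospital_inputs()),
                   z, panel$year[r], norm)
  })
  regular <- vapply(pts, function(pt) {
    all(predicted_shares(params, pt) > 0) &&
      all(cost_elasticity(params, pt) > 0)
  }, TRUE)
  n_exc <- sum(!regular)
  ok <- which(regular)
  qrow <- function(x, measure, service) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    data.frame(measure = measure, service = service,
               q1 = q[1], median = q[2], q3 = q[3],
               n = sum(!is.na(x)), n_excluded = n_exc)
  }
  rows <- list()
  mc <- t(vapply(pts[ok], function(pt) marginal_cost(params, pt),
                 setNames(numeric(length(outs)), outs)))
  for (m in outs)
    rows[[length(rows) + 1L]] <- qrow(mc[, m], "marginal_cost", m)
  v <- vapply(pts[ok], function(pt) overall_scale_elasticity(params, pt), 0)
  rows[[length(rows) + 1L]] <- qrow(v, "overall_scale", "total")
  for (m in outs) {
    vm <- vapply(pts[ok], function(pt) {
      if (pt$y[[m]] <= y_min[[m]]) return(NA_real_)
      product_scale_elasticity(params, pt, m, y_min[[m]])
    }, 0)
    rows[[length(rows) + 1L]] <- qrow(vm, "product_scale", m)
  }
  for (lk in links) {
    if (!all(c(lk$upstream, lk$downstream) %in% outs)) next
    if (!all(lk$share_cols %in% names(panel))) next
    vals <- vapply(ok, function(r) {
      sh <- sum(as.numeric(panel[r, lk$share_cols]))
      up <- panel[[lk$upstream]][r]
      y12 <- round(sh * up)
      if (!is.finite(y12) || y12 < 1) return(NA_real_)
      pt <- pts[[r]]
      if (y12 >= min(pt$y[[lk$upstream]], pt$y[[lk$downstream]]))
        return(NA_real_)
      chain_scale_elasticity(params, pt,
                             chain_link(lk$upstream, lk$downstream, y12))
    }, 0)
    rows[[length(rows) + 1L]] <- qrow(
      vals, "chain_scale", paste(lk$upstream, lk$downstream, sep = "-"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
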