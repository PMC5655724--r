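# Regularity diagnostics of a fitted cost system: monotonicity (positive
# input demands, i.e. positive predicted shares) and concavity in prices
# (negative own substitution elasticities; negative semi-definite
# substitution-elasticity matrix), plus a run-level fit summary.

# evaluation points for every complete row of a panel
.panel_points <- function(params, norm, panel) {
  outs <- params$outputs
  keep <- complete.cases(panel[, c(outs, paste0("w_", hospital_inputs()))])
  panel <- panel[keep, , drop = FALSE]
  list(panel = panel,
       points = lapply(seq_len(nrow(panel)), function(r) {
         z <- if (length(norm$z)) {
           zz <- as.numeric(panel[r, paste0("z_", names(norm$z))])
           names(zz) <- names(norm$z); zz
         } else NULL
         translog_point(setNames(as.numeric(panel[r, outs]), outs),
                        setNames(as.numeric(
                          panel[r, paste0("w_", hospital_inputs())]),
                          hospital_inputs()),
                        z, panel$year[r], norm)
       }))
}

.fit_parts <- function(fit) {
  stopifnot(inherits(fit$params, "translog_params"),
            inherits(fit$norm, "translog_norm"))
  fit
}

#' Monotonicity check: positive predicted input demands
#'
#' Input demand is positive exactly when the predicted cost share is
#' positive; the check evaluates all six predicted shares at every
#' observation's point.
#'
#' @param fit A `translog_fit`, or any list with `params`
#'   ([translog_params()]) and `norm` ([normalization_point()]).
#' @param panel Hospital-year rows to check.
#' @return List with `ok` (per-observation logical), `fraction` (share of
#'   observations passing) and `shares` (the predicted share matrix).
#' @export
monotonicity_check <- function(fit, panel) {
  fit <- .fit_parts(fit)
  pp <- .panel_points(fit$params, fit$norm, panel)
  S <- t(vapply(pp$points,
                function(pt) predicted_shares(fit$params, pt),
                setNames(numeric(6), hospital_inputs())))
  ok <- apply(S > 0, 1, all)
  list(ok = ok, fraction = mean(ok), shares = S)
}

#' Allen substitution-elasticity matrix at a point
#'
#' For a translog cost function the Allen partial elasticities of
#' substitution are \eqn{\sigma_{ij} = (G_{ij} + s_i s_j)/(s_i s_j)} for
#' \eqn{i \ne j} and \eqn{\sigma_{ii} = (G_{ii} + s_i^2 - s_i)/s_i^2},
#' with \eqn{s} the predicted shares at the point.
#'
#' @inheritParams translog_log_cost
#' @return A 6 x 6 matrix of substitution elasticities.
#' @export
substitution_elasticities <- function(params, point) {
  s <- predicted_shares(params, point)
  if (any(s <= 0))
    stop("non-positive predicted share at this point ",
         "(monotonicity must pass before concavity can be assessed)",
         call. = FALSE)
  M <- params$G + tcrossprod(s) - diag(s)
  M / tcrossprod(s)
}

#' Concavity check: negativity and negative semi-definiteness
#'
#' Curvature regularity of the cost function in prices, evaluated per
#' observation: all own substitution elasticities negative, and the
#' substitution-elasticity matrix negative semi-definite.  Both are
#' equivalently checked on \eqn{M = G + s s' - \mathrm{diag}(s)}, which is
#' congruent to the price Hessian of the cost function (so shares the same
#' definiteness) and to the Allen matrix.
#'
#' @inheritParams monotonicity_check
#' @param tol Eigenvalue tolerance: eigenvalues up to `tol` count as
#'   non-positive, accommodating values "slightly greater than zero".
#' @param strict Use a zero tolerance.
#' @return List with per-observation logicals `own_negative` and `nsd`
#'   (`NA` where monotonicity fails), their summary fractions, and
#'   `max_eigenvalue` per observation.
#' @export
concavity_check <- function(fit, panel, tol = 1e-8, strict = FALSE) {
  if (strict) tol <- 0
  fit <- .fit_parts(fit)
  pp <- .panel_points(fit$params, fit$norm, panel)
  n <- length(pp$points)
  own <- nsd <- rep(NA, n)
  maxev <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    s <- predicted_shares(fit$params, pp$points[[r]])
    if (any(s <= 0)) next
    M <- fit$params$G + tcrossprod(s) - diag(s)
    own[r] <- all(diag(M) < 0)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    maxev[r] <- max(ev)
    nsd[r] <- maxev[r] <= tol
  }
  list(own_negative = own, nsd = nsd,
       fraction_own = mean(own, na.rm = TRUE),
       fraction_nsd = mean(nsd, na.rm = TRUE),
       max_eigenvalue = maxev)
}

#' Run-level fit summary
#'
#' Goodness of fit and convergence of a system estimate: per-equation
#' R-squared (the cost equation's is on standardized log cost), the share
#' of free coefficients significant at the 5% level (two-sided z-tests
#' from the ML-style covariance), and the convergence log.
#'
#' @param fit A `translog_fit` from [fit_system()].
#' @return List with `r2`, `cost_r2`, `share_significant`,
#'   `n_coefficients`, `iterations`, `converged`.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "translog_fit"))
  z <- fit$zstat
  list(r2 = fit$r2, cost_r2 = unname(fit$r2["cost"]),
       share_significant = mean(abs(z) > stats::qnorm(0.975)),
       n_coefficients = length(fit$coefficients),
       iterations = fit$iterations, converged = fit$converged)
}
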