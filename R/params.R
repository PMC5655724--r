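#' Translog cost-system parameters
#'
#' Container for every coefficient of the multiproduct translog cost system:
#' intercept, additive year effects, first- and second-order output terms,
#' first- and second-order price terms, output-price interactions,
#' trend-price interactions and the hedonic (case-mix) interactions with
#' admissions.
#'
#' @details
#' The standardized log-cost surface is
#' \deqn{\log c = \alpha_0 + d_t + \sum_m \beta_m \hat y_m +
#'   \tfrac12 \sum_{m,n} B_{mn} \hat y_m \hat y_n +
#'   \sum_i \gamma_i \hat w_i + \tfrac12 \sum_{i,j} G_{ij} \hat w_i \hat w_j +
#'   \sum_{m,i} \delta_{mi} \hat y_m \hat w_i +
#'   t \sum_i \tau_i \hat w_i + \hat y_{adm} \sum_k \theta_k z_k}
#' where \eqn{\hat y_m = \log(y_m/\bar y_m)} and
#' \eqn{\hat w_i = \log(w_i/\bar w_i)} are outputs and input prices
#' standardized at the sample arithmetic means, \eqn{z_k} are hedonic
#' characteristics centered at their means, \eqn{d_t} is the year effect
#' (zero in the base year) and \eqn{t} the linear trend (decades since the
#' base year, zero in the base year).
#'
#' Maintained invariants (checked when `validate = TRUE`):
#' symmetry \eqn{B = B'}, \eqn{G = G'}; linear homogeneity in prices
#' \eqn{\sum_i \gamma_i = 1}, \eqn{\sum_j G_{ij} = 0} for every \eqn{i},
#' \eqn{\sum_i \delta_{mi} = 0} for every \eqn{m}, \eqn{\sum_i \tau_i = 0}.
#' Homogeneity guarantees that predicted shares sum to one and that scaling
#' all prices by \eqn{k} shifts log cost by exactly \eqn{\log k}.
#'
#' @param alpha0 Intercept (standardized log cost of the mean hospital in
#'   the base year).
#' @param beta Named numeric vector of first-order output coefficients; the
#'   names define which services enter the model (a subset of
#'   [hospital_outputs()]).  At the normalization point each equals the cost
#'   elasticity of its service.
#' @param B Symmetric second-order output matrix (same names as `beta`), or
#'   a scalar 0 for none.
#' @param gamma Named numeric vector of first-order price coefficients over
#'   [hospital_inputs()]; sums to one.  Each equals the predicted cost share
#'   at the normalization point in the base year.
#' @param G Symmetric second-order price matrix with zero row sums, or 0.
#' @param delta Output-by-input interaction matrix with zero row sums, or 0.
#' @param tau Trend-price interaction vector summing to zero, or 0.
#' @param theta Named numeric vector of hedonic interaction coefficients
#'   (admissions x characteristic), possibly empty.
#' @param year_effects Named numeric vector of additive year effects, names
#'   are calendar years; the base year is omitted (implicitly zero).
#' @param validate Check symmetry/homogeneity invariants.
#' @param tol Tolerance for the invariant checks.
#'
#' @return An object of class `translog_params`.
#' @seealso [translog_fixture()] for the packaged published parameter sets,
#'   [read_translog_params()] / [write_translog_params()] for YAML
#'   serialization, [repair_homogeneity()].
#' @export
#' @examples
#' p <- translog_params(
#'   alpha0 = 0.2,
#'   beta   = c(admissions = 0.6, outpatients = 0.35, other_revenues = 0.05),
#'   gamma  = c(man_adm = 0.12, nursing = 0.34, paramedical = 0.05,
#'              auxiliary = 0.09, material = 0.30, capital = 0.10))
#' p
translog_params <- function(alpha0, beta, B = 0, gamma, G = 0, delta = 0,
                            tau = 0, theta = numeric(0),
                            year_effects = numeric(0),
                            validate = TRUE, tol = 1e-8) {
  outs <- names(beta)
  if (is.null(outs) || !all(outs %in% hospital_outputs()))
    stop("`beta` must be named with services from hospital_outputs()",
         call. = FALSE)
  ins <- hospital_inputs()
  beta <- .named_num(beta, outs, "beta")
  gamma <- .named_num(gamma, ins, "gamma")
  M <- length(outs)
  if (identical(B, 0)) B <- matrix(0, M, M, dimnames = list(outs, outs))
  if (identical(G, 0)) G <- matrix(0, 6, 6, dimnames = list(ins, ins))
  if (identical(delta, 0)) delta <- matrix(0, M, 6, dimnames = list(outs, ins))
  if (identical(tau, 0)) tau <- setNames(numeric(6), ins)
  B <- .named_mat(B, outs, outs, "B")
  G <- .named_mat(G, ins, ins, "G")
  delta <- .named_mat(delta, outs, ins, "delta")
  tau <- .named_num(tau, ins, "tau")
  if (length(theta)) {
    if (is.null(names(theta)) || !all(names(theta) %in% hedonic_vars()))
      stop("`theta` must be named with hedonic_vars() entries", call. = FALSE)
    theta <- .named_num(theta, names(theta), "theta")
  }
  if (length(year_effects)) {
    if (is.null(names(year_effects)))
      stop("`year_effects` must be named by calendar year", call. = FALSE)
    year_effects <- setNames(as.numeric(year_effects), names(year_effects))
  }
  obj <- structure(
    list(alpha0 = as.numeric(alpha0), year_effects = year_effects,
         beta = beta, B = B, gamma = gamma, G = G, delta = delta,
         tau = tau, theta = theta, outputs = outs),
    class = "translog_params")
  if (validate) validate_translog_params(obj, tol = tol)
  obj
}

#' Check the symmetry and homogeneity invariants of a parameter set
#'
#' @param params A [translog_params()] object.
#' @param tol Numerical tolerance.
#' @return Invisibly `params`; errors describing the first violated
#'   invariant otherwise.
#' @export
validate_translog_params <- function(params, tol = 1e-8) {
  with(params, {
    if (max(abs(B - t(B))) > tol) stop("B is not symmetric", call. = FALSE)
    if (max(abs(G - t(G))) > tol) stop("G is not symmetric", call. = FALSE)
    if (abs(sum(gamma) - 1) > tol)
      stop(sprintf("sum(gamma) = %.6f, must be 1 (price homogeneity)",
                   sum(gamma)), call. = FALSE)
    if (max(abs(rowSums(G))) > tol)
      stop("G row sums must be 0 (price homogeneity)", call. = FALSE)
    if (max(abs(rowSums(delta))) > tol)
      stop("delta row sums must be 0 (price homogeneity)", call. = FALSE)
    if (abs(sum(tau)) > tol)
      stop("sum(tau) must be 0 (price homogeneity)", call. = FALSE)
  })
  invisible(params)
}

#' Re-derive the capital column from the adding-up identities
#'
#' Rounded (e.g. printed) parameter sets typically violate linear price
#' homogeneity in the third decimal.  This recomputes the entries associated
#' with one reference input (capital, the conventionally dropped share
#' equation) from the identities \eqn{\gamma_r = 1 - \sum_{i\ne r}\gamma_i},
#' \eqn{G_{ir} = -\sum_{j\ne r} G_{ij}}, \eqn{\delta_{mr} = -\sum_{i \ne r}
#' \delta_{mi}}, \eqn{\tau_r = -\sum_{i\ne r}\tau_i}, leaving every other
#' coefficient untouched.
#'
#' @param params A `translog_params` object (possibly failing validation).
#' @param ref Reference input whose coefficients are re-derived.
#' @return A valid `translog_params` object.
#' @export
repair_homogeneity <- function(params, ref = "capital") {
  ins <- hospital_inputs()
  stopifnot(ref %in% ins)
  oth <- setdiff(ins, ref)
  p <- unclass(params)
  p$gamma[ref] <- 1 - sum(p$gamma[oth])
  p$G[oth, ref] <- -rowSums(p$G[oth, oth, drop = FALSE])
  p$G[ref, oth] <- p$G[oth, ref]
  p$G[ref, ref] <- -sum(p$G[ref, oth])
  p$delta[, ref] <- -rowSums(p$delta[, oth, drop = FALSE])
  p$tau[ref] <- -sum(p$tau[oth])
  translog_params(p$alpha0, p$beta, p$B, p$gamma, p$G, p$delta, p$tau,
                  p$theta, p$year_effects, validate = TRUE)
}

#' @export
print.translog_params <- function(x, ...) {
  cat("Translog cost-system parameters\n")
  cat("  services:", paste(x$outputs, collapse = ", "), "\n")
  cat("  alpha0  :", format(x$alpha0), "\n")
  cat("  beta    :", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                           collapse = ", "), "\n")
  cat("  gamma   :", paste(sprintf("%s=%.3f", names(x$gamma), x$gamma),
                           collapse = ", "), "\n")
  cat(sprintf("  %d year effects, %d hedonic interactions\n",
              length(x$year_effects), length(x$theta)))
  invisible(x)
}

# ---- flat key-value (YAML) serialization --------------------------------

# key grammar mirrors the published coefficient-table row labels:
#   constant, year_<yyyy>, <output>, <output>_x_<output>,
#   price_<input>, price_<input>_x_price_<input>,
#   <output>_x_price_<input>, trend_x_price_<input>,
#   admissions_x_<hedonic>

.flatten_params <- function(params) {
  out <- list(constant = params$alpha0)
  for (yr in names(params$year_effects))
    out[[paste0("year_", yr)]] <- unname(params$year_effects[yr])
  outs <- params$outputs
  for (m in outs) out[[m]] <- unname(params$beta[m])
  for (a in seq_along(outs)) for (b in a:length(outs)) {
    v <- params$B[outs[a], outs[b]]
    if (v != 0 || a == b)
      out[[paste0(outs[a], "_x_", outs[b])]] <- unname(v)
  }
  ins <- hospital_inputs()
  for (i in ins) out[[paste0("price_", i)]] <- unname(params$gamma[i])
  for (a in seq_along(ins)) for (b in a:length(ins))
    out[[paste0("price_", ins[a], "_x_price_", ins[b])]] <-
      unname(params$G[ins[a], ins[b]])
  for (m in outs) for (i in ins)
    out[[paste0(m, "_x_price_", i)]] <- unname(params$delta[m, i])
  for (i in ins)
    out[[paste0("trend_x_price_", i)]] <- unname(params$tau[i])
  for (k in names(params$theta))
    out[[paste0("admissions_x_", k)]] <- unname(params$theta[k])
  out
}

.unflatten_params <- function(kv, validate = TRUE, tol = 1e-8) {
  keys <- names(kv)
  ins <- hospital_inputs()
  get0n <- function(k) if (k %in% keys) as.numeric(kv[[k]]) else 0
  outs <- intersect(hospital_outputs(), keys)
  if (!length(outs)) stop("no first-order output coefficient found",
                          call. = FALSE)
  beta <- setNames(vapply(outs, get0n, 0), outs)
  M <- length(outs)
  B <- matrix(0, M, M, dimnames = list(outs, outs))
  for (a in seq_len(M)) for (b in a:M) {
    v <- get0n(paste0(outs[a], "_x_", outs[b])) +
      if (a != b) get0n(paste0(outs[b], "_x_", outs[a])) else 0
    B[a, b] <- B[b, a] <- v
  }
  gamma <- setNames(vapply(paste0("price_", ins), get0n, 0), ins)
  G <- matrix(0, 6, 6, dimnames = list(ins, ins))
  for (a in 1:6) for (b in a:6) {
    v <- get0n(paste0("price_", ins[a], "_x_price_", ins[b])) +
      if (a != b) get0n(paste0("price_", ins[b], "_x_price_", ins[a])) else 0
    G[a, b] <- G[b, a] <- v
  }
  delta <- matrix(0, M, 6, dimnames = list(outs, ins))
  for (m in outs) for (i in ins)
    delta[m, i] <- get0n(paste0(m, "_x_price_", i))
  tau <- setNames(vapply(paste0("trend_x_price_", ins), get0n, 0), ins)
  hk <- hedonic_vars()[paste0("admissions_x_", hedonic_vars()) %in% keys]
  theta <- if (length(hk))
    setNames(vapply(paste0("admissions_x_", hk), get0n, 0), hk)
  else setNames(numeric(0), character(0))
  yk <- keys[grepl("^year_[0-9]{4}$", keys)]
  year_effects <- setNames(vapply(yk, get0n, 0), sub("^year_", "", yk))
  translog_params(get0n("constant"), beta, B, gamma, G, delta, tau, theta,
                  year_effects, validate = validate, tol = tol)
}

#' Read and write translog parameter sets as flat YAML
#'
#' Parameter sets serialize to a flat key-value YAML file whose keys mirror
#' the row labels of a published coefficient table: `constant`,
#' `year_2004`, `admissions`, `admissions_x_outpatients`, `price_nursing`,
#' `price_nursing_x_price_capital`, `admissions_x_price_material`,
#' `trend_x_price_capital`, `admissions_x_expected_los`, and so on.
#'
#' @param path File path.
#' @param params A [translog_params()] object.
#' @param repair If `TRUE` (default) and the stored values violate price
#'   homogeneity (as rounded printed tables do), re-derive the capital
#'   column via [repair_homogeneity()]; if `FALSE`, load verbatim without
#'   validation.
#' @return `read_translog_params()` returns a `translog_params` object;
#'   `write_translog_params()` returns `path` invisibly.
#' @export
read_translog_params <- function(path, repair = TRUE) {
  kv <- yaml::read_yaml(path)
  p <- .unflatten_params(kv, validate = FALSE)
  if (repair) repair_homogeneity(p) else p
}

#' @rdname read_translog_params
#' @export
write_translog_params <- function(params, path) {
  yaml::write_yaml(.flatten_params(params), path, precision = 15)
  invisible(path)
}

#' Packaged published parameter fixtures
#'
#' Loads the parameter sets of the two-stage Dutch general-hospital cost
#' system shipped with the package.  Stage 1 is the three-service system
#' (admissions, outpatients, other revenues) estimated on the full panel;
#' stage 2 adds ER visits, re-estimating the output terms on the ER
#' subsample while the price, trend, year and hedonic terms are carried
#' over fixed from stage 1.
#'
#' @param stage `"stage1"` or `"stage2"`.
#' @param repair Re-derive the capital column so homogeneity holds exactly
#'   (see [repair_homogeneity()]); printed tables round to three decimals.
#' @return A [translog_params()] object.
#' @export
#' @examples
#' p2 <- translog_fixture("stage2")
#' p2$beta
translog_fixture <- function(stage = c("stage2", "stage1"), repair = TRUE) {
  stage <- match.arg(stage)
  path <- system.file("extdata", paste0("translog_", stage, ".yml"),
                      package = "chainscale", mustWork = TRUE)
  read_translog_params(path, repair = repair)
}
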