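# Joint estimation of the cost system: the cost equation plus input
# cost-share equations, with cross-equation parameter restrictions
# (symmetry by construction, linear price homogeneity by substitution of
# the capital column) and cross-equation correlated disturbances.  The
# minimum-distance estimator is realized as iterated feasible GLS on the
# stacked system; because observed shares add up to one, the six-equation
# share covariance is singular and one share equation is dropped — at
# convergence the estimates do not depend on which.

# ---- coefficient layout --------------------------------------------------

# ordered descriptor table of the full (unconstrained) coefficient vector
.layout <- function(outputs, years = integer(0), theta_names = character(0)) {
  ins <- hospital_inputs()
  rows <- list(data.frame(name = "constant", group = "alpha0",
                          i1 = NA, i2 = NA))
  add <- function(name, group, i1 = NA, i2 = NA)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, group = group,
                                             i1 = i1, i2 = i2)
  for (yr in years) add(paste0("year_", yr), "year_effects", as.character(yr))
  for (m in outputs) add(m, "beta", m)
  for (a in seq_along(outputs)) for (b in a:length(outputs))
    add(paste0(outputs[a], "_x_", outputs[b]), "B", outputs[a], outputs[b])
  for (i in ins) add(paste0("price_", i), "gamma", i)
  for (a in 1:6) for (b in a:6)
    add(paste0("price_", ins[a], "_x_price_", ins[b]), "G", ins[a], ins[b])
  for (m in outputs) for (i in ins)
    add(paste0(m, "_x_price_", i), "delta", m, i)
  for (i in ins) add(paste0("trend_x_price_", i), "tau", i)
  for (k in theta_names) add(paste0("admissions_x_", k), "theta", k)
  out <- do.call(rbind, rows)
  rownames(out) <- out$name
  attr(out, "outputs") <- outputs
  attr(out, "years") <- years
  attr(out, "theta_names") <- theta_names
  out
}

.params_to_full <- function(params, layout) {
  v <- numeric(nrow(layout))
  for (j in seq_len(nrow(layout))) {
    e <- layout[j, ]
    v[j] <- switch(e$group,
      alpha0 = params$alpha0,
      year_effects = if (e$i1 %in% names(params$year_effects))
        params$year_effects[[e$i1]] else 0,
      beta = if (e$i1 %in% names(params$beta)) params$beta[[e$i1]] else 0,
      B = if (all(c(e$i1, e$i2) %in% rownames(params$B)))
        params$B[e$i1, e$i2] else 0,
      gamma = params$gamma[[e$i1]],
      G = params$G[e$i1, e$i2],
      delta = if (e$i1 %in% rownames(params$delta))
        params$delta[e$i1, e$i2] else 0,
      tau = params$tau[[e$i1]],
      theta = if (e$i1 %in% names(params$theta)) params$theta[[e$i1]] else 0)
  }
  setNames(v, layout$name)
}

.full_to_params <- function(full, layout, validate = TRUE) {
  outs <- attr(layout, "outputs")
  kv <- as.list(full)
  names(kv) <- layout$name
  .unflatten_params(kv, validate = validate, tol = 1e-9)
}

# ---- constraint map: full = A %*% theta_free + b -------------------------

.constraint_map <- function(layout, spec, fixed_full) {
  K <- nrow(layout)
  ins <- hospital_inputs()
  ref <- "capital"  # homogeneity reference input
  status <- character(K)
  for (j in seq_len(K)) {
    e <- layout[j, ]
    g <- e$group
    fixed <- g %in% spec$fixed_groups ||
      (g == "B" && spec$B_mode == "none") ||
      (g == "B" && spec$B_mode == "own" && e$i1 != e$i2)
    derived <- !fixed && switch(g,
      gamma = e$i1 == ref,
      G = e$i1 == ref || e$i2 == ref,
      delta = e$i2 == ref,
      tau = e$i1 == ref,
      FALSE)
    status[j] <- if (fixed) "fixed" else if (derived) "derived" else "free"
  }
  free_idx <- which(status == "free")
  pos <- setNames(match(seq_len(K), free_idx), layout$name)  # full -> free
  A <- matrix(0, K, length(free_idx),
              dimnames = list(layout$name, layout$name[free_idx]))
  b <- setNames(numeric(K), layout$name)
  oth <- setdiff(ins, ref)
  put <- function(j, name, val) {
    p <- pos[[name]]
    if (!is.na(p)) A[j, p] <<- A[j, p] + val
    else b[j] <<- b[j] + val * fixed_full[[name]]
  }
  for (j in seq_len(K)) {
    e <- layout[j, ]
    switch(status[j],
      free = { A[j, pos[[e$name]]] <- 1 },
      fixed = { b[j] <- fixed_full[[e$name]] },
      derived = switch(e$group,
        gamma = { b[j] <- 1
          for (i in oth) put(j, paste0("price_", i), -1) },
        G = {
          if (e$i1 == ref && e$i2 == ref) {
            for (a in seq_along(oth)) for (bb in a:length(oth)) {
              nm <- paste0("price_", oth[a], "_x_price_", oth[bb])
              put(j, nm, if (a == bb) 1 else 2)
            }
          } else {
            i <- if (e$i1 == ref) e$i2 else e$i1
            for (jj in oth) {
              a <- ins[min(match(i, ins), match(jj, ins))]
              bb <- ins[max(match(i, ins), match(jj, ins))]
              put(j, paste0("price_", a, "_x_price_", bb), -1)
            }
          }
        },
        delta = for (i in oth) put(j, paste0(e$i1, "_x_price_", i), -1),
        tau = for (i in oth) put(j, paste0("trend_x_price_", i), -1)))
  }
  list(A = A, b = b, status = status,
       free_names = layout$name[free_idx])
}

# ---- design matrices -----------------------------------------------------

.cost_design <- function(v, layout, panel_year) {
  n <- nrow(v$Yh)
  X <- matrix(0, n, nrow(layout), dimnames = list(NULL, layout$name))
  for (j in seq_len(nrow(layout))) {
    e <- layout[j, ]
    X[, j] <- switch(e$group,
      alpha0 = 1,
      year_effects = as.numeric(panel_year == as.integer(e$i1)),
      beta = v$Yh[, e$i1],
      B = if (e$i1 == e$i2) 0.5 * v$Yh[, e$i1]^2
          else v$Yh[, e$i1] * v$Yh[, e$i2],
      gamma = v$Wh[, e$i1],
      G = if (e$i1 == e$i2) 0.5 * v$Wh[, e$i1]^2
          else v$Wh[, e$i1] * v$Wh[, e$i2],
      delta = v$Yh[, e$i1] * v$Wh[, e$i2],
      tau = v$trend * v$Wh[, e$i1],
      theta = v$Yh[, "admissions"] * v$Zc[, e$i1])
  }
  X
}

.share_design <- function(v, layout, input) {
  n <- nrow(v$Yh)
  ins <- hospital_inputs()
  X <- matrix(0, n, nrow(layout), dimnames = list(NULL, layout$name))
  for (j in seq_len(nrow(layout))) {
    e <- layout[j, ]
    X[, j] <- switch(e$group,
      gamma = if (e$i1 == input) rep(1, n) else 0,
      G = if (e$i1 == input && e$i2 == input) v$Wh[, input]
          else if (e$i1 == input) v$Wh[, e$i2]
          else if (e$i2 == input) v$Wh[, e$i1]
          else 0,
      delta = if (e$i2 == input) v$Yh[, e$i1] else 0,
      tau = if (e$i1 == input) v$trend else 0,
      0)
  }
  X
}

# ---- public surface ------------------------------------------------------

#' Specification of the estimated cost system
#'
#' Declares which services enter, which coefficient groups are free versus
#' fixed (with values taken from a supplied parameter set), which share
#' equation is dropped, and the convergence controls of the iterated-GLS
#' estimator.
#'
#' @param outputs Services entering the model (subset of
#'   [hospital_outputs()]).
#' @param drop_share Input whose share equation is eliminated (the share
#'   covariance is singular because shares add up to one).  The converged
#'   estimates are invariant to this choice; capital — the input with the
#'   smallest share variance — is the default.
#' @param fixed_groups Coefficient groups held fixed at the values in
#'   `fixed`: any of `"year_effects"`, `"gamma"`, `"G"`, `"tau"`,
#'   `"theta"`, `"beta"`, `"delta"`, `"alpha0"`.
#' @param fixed A [translog_params()] object supplying the fixed values
#'   (required when `fixed_groups` or restricted `B_mode` is used; missing
#'   entries default to zero).
#' @param B_mode `"all"` (full symmetric second-order output matrix),
#'   `"own"` (own-quadratic terms free, cross terms fixed) or `"none"`.
#' @param hedonics Include admissions-hedonic interaction terms.
#' @param year_effects Include additive year effects (base year zero).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum GLS iterations.
#' @return A list of class `system_spec`.
#' @export
system_spec <- function(outputs = hospital_outputs()[1:3],
                        drop_share = "capital",
                        fixed_groups = character(0), fixed = NULL,
                        B_mode = c("all", "own", "none"),
                        hedonics = TRUE, year_effects = TRUE,
                        tol = 1e-8, max_iter = 500L) {
  B_mode <- match.arg(B_mode)
  stopifnot(all(outputs %in% hospital_outputs()),
            drop_share %in% hospital_inputs())
  known <- c("alpha0", "year_effects", "beta", "gamma", "G", "delta",
             "tau", "theta")
  if (!all(fixed_groups %in% known))
    stop("unknown fixed group(s): ",
         paste(setdiff(fixed_groups, known), collapse = ", "), call. = FALSE)
  if ((length(fixed_groups) || B_mode != "all") && !is.null(fixed))
    validate_translog_params(fixed)
  structure(list(outputs = outputs, drop_share = drop_share,
                 fixed_groups = fixed_groups, fixed = fixed,
                 B_mode = B_mode, hedonics = hedonics,
                 year_effects = year_effects, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "system_spec")
}

#' Build the stacked system design
#'
#' Constructs, for a panel and a [system_spec()], the per-equation design
#' matrices of the cost equation and the retained share equations, with
#' symmetry and homogeneity imposed by reparameterization (an affine map
#' `full = A %*% free + b` from free parameters to the full coefficient
#' vector, in which the capital column is derived from the adding-up
#' identities and fixed coefficients enter the offset).
#'
#' @param panel Hospital-year data frame with outputs, `w_<input>` prices,
#'   `z_<hedonic>` columns, `share_<input>` observed shares, `total_cost`
#'   and `year`.
#' @param spec A [system_spec()].
#' @param norm Normalization point ([normalization_point()]); defaults to
#'   the panel's attached or recomputed means.
#' @return An object of class `translog_design`: per-equation reduced
#'   designs `Z`, adjusted responses `r` (dependent minus fixed-coefficient
#'   offset), raw responses `y`, the affine map (`A`, `b`), the coefficient
#'   `layout` and equation names.
#' @export
build_design <- function(panel, spec, norm = NULL) {
  norm <- norm %||% attr(panel, "norm") %||% normalization_point(panel)
  v <- .panel_vars(panel, norm, spec$outputs, prefer_full = FALSE)
  years <- sort(unique(panel$year))
  years <- if (spec$year_effects) setdiff(years, norm$base_year)
           else integer(0)
  theta_names <- if (spec$hedonics) names(norm$z) else character(0)
  layout <- .layout(spec$outputs, years, theta_names)
  fixed_full <- if (!is.null(spec$fixed))
    .params_to_full(spec$fixed, layout)
  else setNames(numeric(nrow(layout)), layout$name)
  cm <- .constraint_map(layout, spec, fixed_full)
  eq_inputs <- setdiff(hospital_inputs(), spec$drop_share)
  if (!"total_cost" %in% names(panel))
    stop("panel lacks `total_cost`", call. = FALSE)
  y <- c(list(cost = log(panel$total_cost / norm$cost)),
         lapply(setNames(eq_inputs, paste0("share_", eq_inputs)),
                function(i) panel[[paste0("share_", i)]]))
  X <- c(list(cost = .cost_design(v, layout, panel$year)),
         lapply(setNames(eq_inputs, paste0("share_", eq_inputs)),
                function(i) .share_design(v, layout, i)))
  Z <- lapply(X, function(x) x %*% cm$A)
  r <- Map(function(yy, x) yy - drop(x %*% cm$b), y, X)
  structure(list(Z = Z, r = r, y = y, A = cm$A, b = cm$b, layout = layout,
                 free_names = cm$free_names, eq_names = names(y),
                 n = nrow(panel), spec = spec, norm = norm),
            class = "translog_design")
}

#' Fit the cost system by iterated feasible GLS
#'
#' Minimum-distance (SUR) estimation of the stacked cost/share system.
#' Starting from the pooled least-squares solution, the cross-equation
#' residual covariance is re-estimated and the GLS solve repeated until the
#' largest coefficient change falls below the tolerance; the concentrated
#' Gaussian criterion is non-increasing along the way.  Coefficients of the
#' dropped share equation are recovered from the homogeneity identities.
#'
#' @inheritParams build_design
#' @return An object of class `translog_fit`: `params` (the full
#'   [translog_params()], restrictions holding exactly), free
#'   `coefficients` with `se` and `zstat`, `vcov` (ML-style, no
#'   degrees-of-freedom correction), per-equation `r2`, residual covariance
#'   `sigma`, `residuals`, convergence log, the [system_spec()] used and
#'   the frozen `norm`.
#' @export
fit_system <- function(panel, spec, norm = NULL) {
  norm <- norm %||% attr(panel, "norm") %||% normalization_point(panel)
  need <- c(spec$outputs, paste0("w_", hospital_inputs()), "total_cost",
            paste0("share_", setdiff(hospital_inputs(), spec$drop_share)))
  ok <- complete.cases(panel[, intersect(need, names(panel))])
  panel <- panel[ok, , drop = FALSE]
  d <- build_design(panel, spec, norm)
  E <- length(d$Z); n <- d$n; K <- length(d$free_names)
  if (n < K)
    stop(sprintf("fewer observations (%d) than free parameters (%d)", n, K),
         call. = FALSE)
  C <- lapply(d$Z, function(Ze) lapply(d$Z, function(Zf) crossprod(Ze, Zf)))
  Dv <- lapply(d$Z, function(Ze) lapply(d$r, function(rf) crossprod(Ze, rf)))
  W <- diag(E)
  theta <- NULL
  objective <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(d$spec$max_iter)) {
    M <- matrix(0, K, K); rhs <- numeric(K)
    for (e in 1:E) for (f in 1:E) if (W[e, f] != 0) {
      M <- M + W[e, f] * C[[e]][[f]]
      rhs <- rhs + W[e, f] * drop(Dv[[e]][[f]])
    }
    ch <- tryCatch(chol(M), error = function(err) NULL)
    if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) *
          max(diag(ch)))
      stop("system not identified: singular normal equations ",
           "(zero-variance or collinear regressors in the design)",
           call. = FALSE)
    theta_new <- drop(backsolve(ch, forwardsolve(t(ch), rhs)))
    U <- vapply(1:E, function(e) d$r[[e]] - drop(d$Z[[e]] %*% theta_new),
                numeric(n))
    Sig <- crossprod(U) / n
    if (mean(U^2) < 1e-18) {  # numerically exact fit: OLS is the answer
      theta <- theta_new; converged <- TRUE
      objective <- c(objective, -Inf)
      break
    }
    if (rcond(Sig) < 1e-12) {
      v_eq <- diag(Sig)
      stop("singular residual covariance; offending equations: ",
           paste(d$eq_names[v_eq < 1e-12 * max(v_eq)], collapse = ", "),
           " (did you include all six share equations?)", call. = FALSE)
    }
    objective <- c(objective, n / 2 * determinant(Sig)$modulus[1])
    if (!is.null(theta) && max(abs(theta_new - theta)) < d$spec$tol) {
      theta <- theta_new; converged <- TRUE
      break
    }
    theta <- theta_new
    W <- solve(Sig)
  }
  if (!converged)
    warning("iterated GLS did not converge within ", d$spec$max_iter,
            " iterations", call. = FALSE)
  names(theta) <- d$free_names
  U <- vapply(1:E, function(e) d$r[[e]] - drop(d$Z[[e]] %*% theta),
              numeric(n))
  colnames(U) <- d$eq_names
  Sig <- crossprod(U) / n
  # final-weight information matrix (ML-style covariance, no dof correction)
  W <- tryCatch(solve(Sig), error = function(e) NULL)
  vcov <- if (!is.null(W)) {
    M <- matrix(0, K, K)
    for (e in 1:E) for (f in 1:E) M <- M + W[e, f] * C[[e]][[f]]
    solve(M)
  } else matrix(NA_real_, K, K)
  dimnames(vcov) <- list(d$free_names, d$free_names)
  se <- sqrt(pmax(diag(vcov), 0))
  r2 <- vapply(1:E, function(e) {
    yy <- d$y[[e]]
    1 - sum(U[, e]^2) / sum((yy - mean(yy))^2)
  }, 0)
  names(r2) <- d$eq_names
  full <- drop(d$A %*% theta) + d$b
  params <- .full_to_params(full, d$layout)
  structure(list(params = params, coefficients = theta, se = se,
                 zstat = theta / se, vcov = vcov, sigma = Sig, r2 = r2,
                 residuals = U, iterations = iter, converged = converged,
                 objective = objective, spec = d$spec, norm = d$norm,
                 n = n, eq_names = d$eq_names, design_layout = d$layout),
            class = "translog_fit")
}

#' @export
print.translog_fit <- function(x, ...) {
  cat("Translog cost-system fit (iterated FGLS)\n")
  cat(sprintf("  n = %d, %d free coefficients, %d equations\n",
              x$n, length(x$coefficients), length(x$eq_names)))
  cat(sprintf("  converged: %s after %d iterations\n",
              x$converged, x$iterations))
  cat(sprintf("  cost-equation R2: %.4f\n", x$r2[["cost"]]))
  cat("  first-order output coefficients:\n")
  print(round(x$params$beta, 4))
  invisible(x)
}

#' Two-stage estimation: full panel, then the ER subsample
#'
#' Stage 1 estimates the three-service system (no ER variables) on every
#' observation.  Stage 2 re-estimates, on the subsample with observed ER
#' visits, the intercept, all first-order output terms, the own-quadratic
#' output terms and the output-price interactions — now including ER visits
#' — while fixing the price, trend, year-effect, hedonic and cross-output
#' second-order coefficients at their stage-1 values (ER cross terms fixed
#' at zero).  This implicitly assumes resource prices and services are
#' uncorrelated, which holds by construction for region/year-driven price
#' proxies.
#'
#' @param panel Full hospital-year panel; rows without ER data carry `NA`
#'   in `er_visits`.
#' @param er_subsample Logical vector or row indices selecting the
#'   ER-complete observations; defaults to `!is.na(panel$er_visits)`.
#' @param drop_share,tol,max_iter Passed to both stages' [system_spec()].
#' @param norm Normalization point frozen for both stages; defaults to the
#'   full-panel means (the ER mean is taken over the observed rows).
#' @return List with elements `stage1` and `stage2`, both `translog_fit`.
#' @export
two_stage_fit <- function(panel, er_subsample = NULL, drop_share = "capital",
                          tol = 1e-8, max_iter = 500L, norm = NULL) {
  norm <- norm %||% attr(panel, "norm") %||% normalization_point(panel)
  spec1 <- system_spec(outputs = setdiff(hospital_outputs(), "er_visits"),
                       drop_share = drop_share, tol = tol,
                       max_iter = max_iter)
  fit1 <- fit_system(panel, spec1, norm = norm)
  er_subsample <- er_subsample %||% !is.na(panel$er_visits)
  sub <- panel[er_subsample, , drop = FALSE]
  if (!nrow(sub)) stop("ER subsample is empty", call. = FALSE)
  ext <- .extend_params(fit1$params, hospital_outputs())
  spec2 <- system_spec(outputs = hospital_outputs(),
                       drop_share = drop_share,
                       fixed_groups = c("year_effects", "gamma", "G",
                                        "tau", "theta"),
                       fixed = ext, B_mode = "own",
                       tol = tol, max_iter = max_iter)
  fit2 <- fit_system(sub, spec2, norm = norm)
  list(stage1 = fit1, stage2 = fit2)
}

# zero-pad a parameter set to a larger service list (keeps homogeneity)
.extend_params <- function(params, outputs) {
  M <- length(outputs)
  beta <- setNames(numeric(M), outputs)
  beta[names(params$beta)] <- params$beta
  B <- matrix(0, M, M, dimnames = list(outputs, outputs))
  B[rownames(params$B), colnames(params$B)] <- params$B
  delta <- matrix(0, M, 6, dimnames = list(outputs, hospital_inputs()))
  delta[rownames(params$delta), ] <- params$delta
  translog_params(params$alpha0, beta, B, params$gamma, params$G, delta,
                  params$tau, params$theta, params$year_effects)
}

#' Nonparametric bootstrap of the system fit
#'
#' Refits the system on observation resamples (normalization point frozen
#' from the original sample, so coefficients are comparable across draws).
#'
#' @inheritParams fit_system
#' @param n_boot Number of bootstrap draws.
#' @param seed RNG seed.
#' @return Matrix of free coefficients, one row per successful draw, with
#'   attribute `"se"` (per-coefficient bootstrap SDs).
#' @export
bootstrap_fit <- function(panel, spec, n_boot = 200L, seed = 1L,
                          norm = NULL) {
  norm <- norm %||% attr(panel, "norm") %||% normalization_point(panel)
  set.seed(seed)
  out <- vector("list", n_boot)
  for (bdx in seq_len(n_boot)) {
    idx <- sample.int(nrow(panel), nrow(panel), replace = TRUE)
    out[[bdx]] <- tryCatch(
      fit_system(panel[idx, , drop = FALSE], spec, norm = norm)$coefficients,
      error = function(e) NULL)
  }
  ok <- !vapply(out, is.null, TRUE)
  if (!all(ok))
    warning(sum(!ok), " bootstrap draws failed and were skipped",
            call. = FALSE)
  res <- do.call(rbind, out[ok])
  attr(res, "se") <- apply(res, 2, sd)
  res
}
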