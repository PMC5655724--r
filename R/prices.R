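# Exogenous input-price construction.
#
# Observed unit values (cost per FTE) are partly endogenous: hospitals that
# pay more may do so because of unobserved case mix.  The proxies used in
# estimation therefore keep only the region-by-year variation of unit
# values; materials get a national CPI index; capital gets an implicit
# price, cost over a regression-weighted volume aggregate.

#' Exogenous labor price proxies from unit values
#'
#' For each labor category, regresses the observed unit value (cost per
#' FTE) on region and year indicator sets and returns the fitted values,
#' which vary only by region and year and serve as exogenous market-price
#' proxies.
#'
#' @param unit_values Data frame with columns `category`, `unit_value`
#'   (or `cost` and `fte`, from which it is computed), `region`, `year`,
#'   and any id columns, one row per hospital-year-category.
#' @return The input data frame with a `price` column of fitted values
#'   appended.
#' @export
#' @examples
#' uv <- expand.grid(region = c("N", "S"), year = 2003:2004,
#'                   category = "nursing", KEEP.OUT.ATTRS = FALSE)
#' uv$unit_value <- 40000 + 1000 * (uv$region == "N") + 500 * (uv$year - 2003)
#' labor_price_proxy(uv)$price  # reproduces the region-year structure
labor_price_proxy <- function(unit_values) {
  uv <- as.data.frame(unit_values)
  if (!"unit_value" %in% names(uv)) {
    if (!all(c("cost", "fte") %in% names(uv)))
      stop("need `unit_value` or both `cost` and `fte` columns",
           call. = FALSE)
    if (any(uv$fte <= 0 & uv$cost > 0, na.rm = TRUE))
      stop("FTE must be positive where cost is positive", call. = FALSE)
    uv$unit_value <- uv$cost / uv$fte
  }
  stopifnot(all(c("category", "region", "year") %in% names(uv)))
  uv$price <- NA_real_
  for (cat in unique(uv$category)) {
    idx <- uv$category == cat
    d <- uv[idx, , drop = FALSE]
    if (all(is.na(d$unit_value)))
      stop(sprintf("category '%s' has no observed unit values", cat),
           call. = FALSE)
    nr <- length(unique(d$region)); ny <- length(unique(d$year))
    fml <- if (nr > 1 && ny > 1) unit_value ~ factor(region) + factor(year)
      else if (nr > 1) unit_value ~ factor(region)
      else if (ny > 1) unit_value ~ factor(year)
      else unit_value ~ 1
    fit <- stats::lm(fml, data = d, na.action = stats::na.exclude)
    uv$price[idx] <- stats::predict(fit, newdata = d)
  }
  uv
}

#' Material price index from a CPI series
#'
#' Materials have no natural quantity unit; their price is set to one in
#' the base year and moved by the national consumer price index, with no
#' regional variation.
#'
#' @param cpi Data frame with columns `year` and `cpi` (or a named numeric
#'   vector, names = years).
#' @param base_year Year where the index equals one.
#' @return Data frame with columns `year` and `index`.
#' @export
material_price_index <- function(cpi, base_year) {
  if (is.numeric(cpi) && !is.null(names(cpi)))
    cpi <- data.frame(year = as.integer(names(cpi)), cpi = as.numeric(cpi))
  stopifnot(all(c("year", "cpi") %in% names(cpi)))
  b <- cpi$cpi[cpi$year == base_year]
  if (length(b) != 1 || !is.finite(b))
    stop("base year ", base_year, " not present in the CPI series",
         call. = FALSE)
  data.frame(year = cpi$year, index = cpi$cpi / b)
}

#' Capital volume index from a weighted aggregate of capital components
#'
#' Weights are the least-squares coefficients of an intercept-free
#' regression of capital cost on the components (beds, IC beds,
#' radiotherapists as an equipment proxy, operating theatres); the volume
#' is the weighted sum, rescaled to mean one so the implied capital price
#' is comparable to the cost level at the mean hospital.  The intercept is
#' excluded so a hospital with no capital components has no capital volume.
#'
#' @param capital_cost Numeric vector of capital costs per hospital-year.
#' @param components Data frame or matrix of non-negative component counts
#'   (same rows as `capital_cost`).
#' @return List with `weights` (named, per component; dropped collinear
#'   components get weight 0 with a warning) and `volume` (mean-one).
#' @export
capital_volume_index <- function(capital_cost, components) {
  X <- as.matrix(components)
  if (any(X < 0, na.rm = TRUE))
    stop("capital components must be non-negative", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("component", seq_len(ncol(X)))
  qrX <- qr(X)
  w <- setNames(numeric(ncol(X)), colnames(X))
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("collinear capital components dropped: ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X_use <- X[, keep, drop = FALSE]
  } else {
    keep <- seq_len(ncol(X))
    X_use <- X
  }
  fit <- stats::lm.fit(X_use, capital_cost)
  w[colnames(X)[keep]] <- coef(fit)
  raw <- unname(drop(X %*% w))
  if (mean(raw) <= 0)
    stop("capital volume aggregate has non-positive mean", call. = FALSE)
  list(weights = w, volume = raw / mean(raw))
}

#' Implicit capital price
#'
#' Cost of capital divided by the volume of capital.
#'
#' @param capital_cost Numeric vector of capital costs.
#' @param volume Capital volume index (see [capital_volume_index()]).
#' @return Numeric vector of capital prices.
#' @export
capital_price <- function(capital_cost, volume) {
  if (any(volume <= 0, na.rm = TRUE))
    stop("capital volume must be strictly positive", call. = FALSE)
  capital_cost / volume
}
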