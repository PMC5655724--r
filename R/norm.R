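#' Normalization point: sample arithmetic means of every model variable
#'
#' All variables of the cost system are standardized at their arithmetic
#' means before estimation, so first-order coefficients read directly as
#' elasticities (outputs) and cost shares (prices) of the "average"
#' hospital.  The means are frozen from the estimation sample and stored so
#' counterfactual evaluations reuse them.
#'
#' @param panel A hospital-year data frame with output columns
#'   ([hospital_outputs()]), price columns `w_<input>`, hedonic columns
#'   `z_<hedonic>`, a `total_cost` column and a `year` column.  Missing ER
#'   columns are averaged over the rows where they are observed.
#' @param base_year Base calendar year for year effects and the trend;
#'   defaults to the first year in the panel.
#' @return An object of class `translog_norm`: named lists of means `y`,
#'   `w`, `z`, scalar `cost`, and `base_year`.
#' @seealso [translog_point()], [reference_norm()]
#' @export
normalization_point <- function(panel, base_year = NULL) {
  outs <- intersect(hospital_outputs(), names(panel))
  y <- vapply(outs, function(v) mean(panel[[v]], na.rm = TRUE), 0)
  ins <- hospital_inputs()
  wcols <- paste0("w_", ins)
  if (!all(wcols %in% names(panel)))
    stop("panel must contain price columns ", paste(wcols, collapse = ", "),
         call. = FALSE)
  w <- setNames(vapply(wcols, function(v) mean(panel[[v]], na.rm = TRUE), 0),
                ins)
  zcols <- paste0("z_", hedonic_vars())
  z <- if (all(zcols %in% names(panel)))
    setNames(vapply(zcols, function(v) mean(panel[[v]], na.rm = TRUE), 0),
             hedonic_vars())
  else setNames(numeric(0), character(0))
  cost <- if ("total_cost" %in% names(panel))
    mean(panel$total_cost, na.rm = TRUE) else NA_real_
  structure(list(y = y, w = w, z = z, cost = cost,
                 base_year = as.integer(base_year %||% min(panel$year))),
            class = "translog_norm")
}

#' Manually assembled normalization point
#'
#' @param y,w,z Named vectors of means (services, inputs, hedonics).
#' @param cost Mean total cost (currency units).
#' @param base_year Base calendar year.
#' @return A `translog_norm` object.
#' @export
make_norm <- function(y, w, z = setNames(numeric(0), character(0)),
                      cost = NA_real_, base_year = 2003L) {
  y <- .named_num(y, intersect(hospital_outputs(), names(y)), "y")
  w <- .named_num(w, hospital_inputs(), "w")
  if (length(z)) z <- .named_num(z, names(z), "z")
  structure(list(y = y, w = w, z = z, cost = as.numeric(cost),
                 base_year = as.integer(base_year)),
            class = "translog_norm")
}

#' Packaged reference normalization point
#'
#' Means of the 2011 Dutch general-hospital cross-section for services,
#' hedonic characteristics and total cost, combined with synthetic input
#' price means (the published source reports no price levels; the price
#' means here are the package's generator defaults and are immaterial for
#' evaluation at the mean, where all standardized prices are zero).
#'
#' @return A `translog_norm` object.
#' @export
reference_norm <- function() {
  path <- system.file("extdata", "reference_norm.yml",
                      package = "chainscale", mustWork = TRUE)
  kv <- yaml::read_yaml(path)
  make_norm(
    y = unlist(kv$outputs), w = unlist(kv$prices), z = unlist(kv$hedonics),
    cost = kv$total_cost, base_year = kv$base_year)
}

#' @export
print.translog_norm <- function(x, ...) {
  cat("Normalization point (sample arithmetic means)\n")
  cat("  base year:", x$base_year, "\n")
  cat("  outputs  :", paste(sprintf("%s=%.0f", names(x$y), x$y),
                            collapse = ", "), "\n")
  cat("  cost mean:", format(x$cost, big.mark = ","), "\n")
  invisible(x)
}

#' Evaluation point of the translog system
#'
#' Bundles raw levels with their standardized transforms: outputs and
#' prices as logs of level over mean, hedonics centered at their means,
#' year effect key and trend (decades since the base year).
#'
#' @param y Named vector of service levels (subset of [hospital_outputs()]).
#' @param w Named vector of the six input prices.
#' @param z Named vector of hedonic characteristics in levels (optional).
#' @param year Calendar year (defaults to the base year of `norm`).
#' @param norm A `translog_norm` object.
#' @return An object of class `translog_point` with elements `y`, `w`, `z`,
#'   `year`, `yhat`, `what`, `zc` (centered hedonics), `trend`, `norm`.
#' @export
#' @examples
#' nrm <- reference_norm()
#' pt <- translog_point(nrm$y, nrm$w, nrm$z, norm = nrm)
#' max(abs(pt$yhat))  # 0: the mean hospital
translog_point <- function(y, w, z = NULL, year = NULL, norm) {
  stopifnot(inherits(norm, "translog_norm"))
  outs <- intersect(hospital_outputs(), names(y))
  y <- .named_num(y, outs, "y")
  w <- .named_num(w, hospital_inputs(), "w")
  .check_positive(y, "y")
  .check_positive(w, "w")
  if (!all(outs %in% names(norm$y)))
    stop("normalization point lacks means for: ",
         paste(setdiff(outs, names(norm$y)), collapse = ", "), call. = FALSE)
  yhat <- log(y / norm$y[outs])
  what <- log(w / norm$w)
  if (is.null(z)) z <- norm$z
  zc <- if (length(norm$z)) {
    z <- .named_num(z, names(norm$z), "z")
    z - norm$z
  } else setNames(numeric(0), character(0))
  year <- as.integer(year %||% norm$base_year)
  structure(list(y = y, w = w, z = z, year = year,
                 yhat = yhat, what = what, zc = zc,
                 trend = (year - norm$base_year) / 10, norm = norm),
            class = "translog_point")
}

#' @describeIn translog_point the point where every standardized variable
#'   is zero: all levels at their means, hedonics centered, base year.
#' @export
mean_point <- function(norm, year = NULL) {
  translog_point(norm$y, norm$w, norm$z, year = year, norm = norm)
}

# replace one or more service levels, keeping everything else fixed
.point_with_outputs <- function(point, y_new) {
  y <- point$y
  y[names(y_new)] <- y_new
  translog_point(y, point$w, point$z, point$year, point$norm)
}
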