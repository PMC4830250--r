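# Regression calibration: ordinary least squares of the planimetry
# reference on an A.B.C product turns the half-product heuristic into a
# data-driven linear variation (slope a, intercept b in mL).

#' Fit a linear calibration of reference volume on a product
#'
#' Plain OLS with intercept of `references` (y, mL) on `products`
#' (x, mL units, i.e. A.B.C/1000).
#'
#' @param products numeric vector, the per-case A.B.C products in mL
#'   units; must not be constant.
#' @param references numeric vector of planimetry volumes in mL, same
#'   length.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept_mL`, `r_squared`, `n`, and `residuals`.
#' @export
#' @examples
#' fit_linear_calibration(1:10, 2 * (1:10))  # slope 2, intercept 0
fit_linear_calibration <- function(products, references) {
  if (length(products) != length(references))
    stop("`products` and `references` must have equal length")
  if (length(products) < 3L) stop("at least 3 cases are required")
  if (anyNA(products) || anyNA(references)) stop("inputs must not contain NA")
  if (stats::sd(products) == 0) stop("`products` is constant: no fit possible")
  fit <- stats::lm(references ~ products)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((references - mean(references))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept_mL = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n = length(products),
                 residuals = res),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x %+.4f mL, R2 %.4f, n = %d\n",
              x$slope, x$intercept_mL, x$r_squared, x$n))
  invisible(x)
}

#' Package a fitted calibration as a variation
#'
#' @param fit a [fit_linear_calibration()] result.
#' @param length_source,name,depth_source forwarded to
#'   [variation_spec()].
#' @return a [variation_spec()] with the fitted slope and intercept.
#' @export
derive_variation <- function(fit, length_source, depth_source, name) {
  stopifnot(inherits(fit, "regression_fit"))
  variation_spec(name, fit$slope, fit$intercept_mL,
                 length_source = length_source, depth_source = depth_source)
}

#' Serialise a fit (plus its sources) to JSON
#'
#' @param fit a `regression_fit`.
#' @param name variation label.
#' @param length_source,depth_source the A/B and C selectors the fitted
#'   product came from.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, name, length_source, depth_source, path = NULL) {
  stopifnot(inherits(fit, "regression_fit"))
  x <- list(name = name, slope = fit$slope, intercept_mL = fit$intercept_mL,
            r_squared = fit$r_squared, n = fit$n,
            length_source = length_source, depth_source = depth_source)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Refit the four study calibrations on a cohort table
#'
#' Runs [fit_linear_calibration()] of planimetry on each of the four
#' products and derives the primed variations. The input is either a
#' cohort data frame with columns `planimetry` and product columns
#' `p_A1B1C0` ... (as produced by [load_study_fixture()] or
#' [cases_to_table()]).
#'
#' @param table cohort data frame.
#' @return named list of four elements (`1p`, `2p`, `3p`, `4p`), each
#'   holding `fit` (`regression_fit`) and `spec` ([variation_spec()]).
#' @export
calibrate_cohort <- function(table) {
  prods <- c(`1p` = "p_A1B1C0", `2p` = "p_A1B1C1",
             `3p` = "p_A2B2C0", `4p` = "p_A2B2C1")
  srcs <- list(`1p` = c("largest", "C0"), `2p` = c("largest", "C1"),
               `3p` = c("central", "C0"), `4p` = c("central", "C1"))
  missing_cols <- setdiff(c("planimetry", unname(prods)), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  out <- lapply(names(prods), function(nm) {
    fit <- fit_linear_calibration(table[[prods[[nm]]]], table$planimetry)
    list(fit = fit,
         spec = derive_variation(fit, srcs[[nm]][1L], srcs[[nm]][2L], nm))
  })
  names(out) <- names(prods)
  out
}
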