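#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize fitted variogram models
#'
#' `tidy()` returns one row per parameter of the winning model; `glance()`
#' one row with the family, parameters, weighted RSS, nugget/sill ratio and
#' spatial-dependence class.
#'
#' @param x A `variogram_fit` from [fit_variogram()].
#' @param ... Unused.
#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "psill", if (x$family == "periodic") "period" else "range"),
    estimate = c(x$nugget, x$psill, x$range)
  )
}

#' @rdname tidy.variogram_fit
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(family = x$family, nugget = x$nugget, psill = x$psill,
                 range = x$range, sill = x$nugget + x$psill,
                 nugget_sill_ratio = nugget_sill_ratio(x),
                 dependence = spatial_dependence_class(x),
                 wrss = x$wrss, converged = x$converged)
}

#' Summarize a kriging cross-validation report
#'
#' One row with the validation-point count, ASE, RMSE, normalized RMSE and
#' the observation standard deviation.
#'
#' @param x A `cv_report` from [loo_cross_validation()].
#' @param ... Unused.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(attribute = attr(x, "attribute"), n = attr(x, "N"),
                 ASE = attr(x, "ASE"), RMSE = attr(x, "RMSE"),
                 RMSE_r = attr(x, "RMSE_r"), S_z = attr(x, "S_z"))
}

#' Tidy and summarize a BIOENV search
#'
#' `tidy()` returns the best subset per size; `glance()` the single best
#' subset overall.
#'
#' @param x A `bioenv_result` from [bioenv()].
#' @param ... Unused.
#' @export
tidy.bioenv_result <- function(x, ...) attr(x, "best_by_size")

#' @rdname tidy.bioenv_result
#' @export
glance.bioenv_result <- function(x, ...) {
  b <- attr(x, "best")
  tibble::tibble(best_subset = b$subset, size = b$size,
                 correlation = b$correlation,
                 dissimilarity = attr(x, "dissimilarity"),
                 n_samples = attr(x, "n_samples"))
}
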