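#' Empirical (omnidirectional) semivariogram
#'
#' For every sample pair the cloud value is half the squared difference,
#' \eqn{(z_i - z_j)^2 / 2}, at lag \eqn{h_{ij}}. Pairs up to `max_lag` are
#' grouped into `n_bins` equal-width bins and the binned semivariance
#' \eqn{\hat\gamma(h)} is the mean of the cloud values in each bin — the
#' classical estimator \eqn{\gamma(h) = \frac{1}{2N(h)}\sum [Z(u) - Z(u+h)]^2}.
#' Empty bins are dropped.
#'
#' @param samples Data frame with `easting`, `northing` and the attribute.
#' @param attribute Name of the column to analyse.
#' @param n_bins Number of equal-width lag bins (default 12).
#' @param max_lag Maximum lag in metres, or `"half-max"` (default) for half
#'   the maximum pairwise distance.
#' @return An `empirical_variogram`: a tibble of bins (`h` bin centre,
#'   `gamma`, `np` pair count) with the cloud pairs in attribute `"cloud"`.
#' @export
empirical_variogram <- function(samples, attribute, n_bins = 12,
                                max_lag = "half-max") {
  if (nrow(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!attribute %in% names(samples)) {
    stop("attribute not found: ", attribute, call. = FALSE)
  }
  z <- samples[[attribute]]
  d <- pairwise_distances(samples)
  low <- which(lower.tri(d), arr.ind = TRUE)
  h <- d[low]
  v <- (z[low[, 1]] - z[low[, 2]])^2 / 2
  if (identical(max_lag, "half-max")) max_lag <- max(h) / 2
  cloud <- tibble::tibble(h = h, gamma = v)[h <= max_lag & h > 0, ]
  if (nrow(cloud) == 0) stop("no pairs within max_lag", call. = FALSE)
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(cloud$h, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, gamma = cloud$gamma), .data$bin),
    gamma = mean(.data$gamma), np = dplyr::n(), .groups = "drop"
  )
  out$h <- (breaks[out$bin] + breaks[out$bin + 1]) / 2
  out <- out[order(out$h), c("h", "gamma", "np")]
  structure(out, class = c("empirical_variogram", class(out)),
            cloud = cloud, attribute = attribute, max_lag = max_lag)
}

#' @rdname empirical_variogram
#' @param x An `empirical_variogram`.
#' @export
variogram_cloud <- function(x) attr(x, "cloud")

#' Variogram model
#'
#' A parametric semivariogram \eqn{\gamma(h)} with nugget `c0`, partial sill
#' `c` and range (or period, for the hole-effect model) `a`. Families:
#' \describe{
#'   \item{nugget}{\eqn{c_0} for \eqn{h > 0}}
#'   \item{spherical}{\eqn{c_0 + c(1.5 h/a - 0.5 (h/a)^3)} up to `a`, then sill}
#'   \item{exponential}{\eqn{c_0 + c(1 - e^{-3h/a})} (practical range `a`)}
#'   \item{gaussian}{\eqn{c_0 + c(1 - e^{-3h^2/a^2})}}
#'   \item{periodic}{hole-effect \eqn{c_0 + c(1 - \cos(2\pi h/a))}; `a` is the
#'     patch period and the curve returns to the nugget level at each multiple
#'     of it}
#' }
#' All families are 0 at exactly \eqn{h = 0}. The sill is taken as
#' \eqn{c_0 + c} for every family (for the non-monotone periodic model this is
#' the maximum semivariance level used in the nugget/sill ratio).
#'
#' @param family Model family name.
#' @param nugget Nugget \eqn{c_0 \ge 0}.
#' @param psill Partial sill \eqn{c \ge 0}.
#' @param range Range or period \eqn{a > 0} in metres.
#' @return A `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian",
                                       "periodic", "nugget"),
                            nugget = 0, psill = 1, range = 1) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget=%.4g psill=%.4g %s=%.4g (sill=%.4g)\n",
              x$family, x$nugget, x$psill,
              if (x$family == "periodic") "period" else "range",
              x$range, x$nugget + x$psill))
  invisible(x)
}

#' Evaluate a variogram model
#'
#' @param model A [variogram_model()].
#' @param h Vector of lags in metres, `>= 0`.
#' @return Semivariances \eqn{\gamma(h)}; exactly 0 at `h = 0`.
#' @export
model_curve <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"), all(h >= 0))
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$family,
    nugget = 0 * h + c0,
    spherical = ifelse(h <= a, c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3), c0 + c1),
    exponential = c0 + c1 * (1 - exp(-3 * h / a)),
    gaussian = c0 + c1 * (1 - exp(-3 * h^2 / a^2)),
    periodic = c0 + c1 * (1 - cos(2 * pi * h / a)),
    stop("unknown variogram family: ", model$family, call. = FALSE)
  )
  g[h == 0] <- 0
  g
}

#' Fit variogram models to an empirical semivariogram
#'
#' Weighted least squares over (nugget, partial sill, range) for each
#' candidate family, with a deterministic multi-start grid over the range and
#' box constraints (parameters `>= 0`, range `> 0`); the family with the
#' smallest weighted residual sum of squares wins. Default weights are the
#' `N(h)/h^2` scheme; `cressie` weights `N(h)/gamma_model(h)^2` and plain OLS
#' are available.
#'
#' @param emp An [empirical_variogram()] with at least 3 non-empty bins.
#' @param families Candidate families (default all five).
#' @param weighting `"npairs_over_h2"` (default), `"ols"` or `"cressie"`.
#' @return A `variogram_fit`: the winning [variogram_model()] with fields
#'   `wrss`, `converged`, `candidates` (per-family diagnostics tibble) and
#'   `empirical` (the input).
#' @export
fit_variogram <- function(emp,
                          families = c("spherical", "exponential", "gaussian",
                                       "periodic", "nugget"),
                          weighting = c("npairs_over_h2", "ols", "cressie")) {
  stopifnot(inherits(emp, "empirical_variogram"))
  weighting <- match.arg(weighting)
  families <- match.arg(families, several.ok = TRUE)
  h <- emp$h; g <- emp$gamma; np <- emp$np
  if (length(h) < 3) stop("need at least 3 non-empty bins", call. = FALSE)
  g_scale <- max(g, 1e-12)

  wts <- function(model_g) {
    switch(weighting,
      ols = rep(1, length(h)),
      npairs_over_h2 = np / h^2,
      cressie = np / pmax(model_g, 1e-6 * g_scale)^2
    )
  }
  obj <- function(par, family) {
    m <- variogram_model(family, nugget = par[1], psill = par[2], range = par[3])
    mg <- model_curve(m, h)
    sum(wts(mg) * (g - mg)^2)
  }

  fits <- purrr::map_dfr(families, function(fam) {
    if (fam == "nugget") {
      # flat model: weighted mean solves the WLS problem directly
      w <- if (weighting == "ols") rep(1, length(h)) else np / h^2
      c0 <- sum(w * g) / sum(w)
      if (weighting == "cressie") {
        for (i in 1:5) {
          w <- np / pmax(c0, 1e-6 * g_scale)^2
          c0 <- sum(w * g) / sum(w)
        }
      }
      return(tibble::tibble(family = fam, nugget = c0, psill = 0,
                            range = max(h), wrss = obj(c(c0, 0, max(h)), fam),
                            converged = TRUE))
    }
    starts_a <- unique(c(max(h) * c(0.1, 0.25, 0.5, 0.75, 1, 1.5),
                         stats::quantile(h, c(0.25, 0.5, 0.75), names = FALSE)))
    starts <- expand.grid(c0 = c(0, 0.1 * g_scale),
                          c1 = c(g_scale, 0.5 * g_scale),
                          a = starts_a)
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(as.numeric(starts[k, ]), obj, family = fam,
                     method = "L-BFGS-B",
                     lower = c(0, 0, 1e-6 * max(h)),
                     upper = c(Inf, Inf, 100 * max(h)),
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) {
      return(tibble::tibble(family = fam, nugget = NA_real_, psill = NA_real_,
                            range = NA_real_, wrss = Inf, converged = FALSE))
    }
    tibble::tibble(family = fam, nugget = best$par[1], psill = best$par[2],
                   range = best$par[3], wrss = best$value,
                   converged = best$convergence == 0)
  })

  ok <- fits[is.finite(fits$wrss), ]
  if (nrow(ok) == 0) {
    stop("variogram fit failed to converge for every family; diagnostics:\n",
         paste(utils::capture.output(print(fits)), collapse = "\n"), call. = FALSE)
  }
  win <- ok[which.min(ok$wrss), ]
  model <- variogram_model(win$family, nugget = win$nugget, psill = win$psill,
                           range = win$range)
  structure(c(model, list(wrss = win$wrss, converged = win$converged,
                          candidates = fits, empirical = emp)),
            class = c("variogram_fit", "variogram_model"))
}

#' Nugget/sill ratio and spatial-dependence class
#'
#' The ratio \eqn{c_0 / (c_0 + c)} classifies spatial dependence: `"high"`
#' below 0.25, `"medium"` from 0.25 to 0.75, `"low"` above 0.75.
#'
#' @param model A [variogram_model()] with positive sill.
#' @return For `nugget_sill_ratio()` the ratio; for
#'   `spatial_dependence_class()` one of `"high"`, `"medium"`, `"low"`.
#' @export
spatial_dependence_class <- function(model) {
  r <- nugget_sill_ratio(model)
  if (r < 0.25) "high" else if (r <= 0.75) "medium" else "low"
}

#' @rdname spatial_dependence_class
#' @export
nugget_sill_ratio <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  sill <- model$nugget + model$psill
  if (sill <= 0) stop("no spatial variance: sill is zero", call. = FALSE)
  model$nugget / sill
}
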