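#' Polygon helpers
#'
#' `polygon_area()` is the shoelace area of a simple vertex ring;
#' `point_in_polygon()` applies the even-odd ray-casting rule (points exactly
#' on an edge follow the crossing parity of the cast ray).
#'
#' @param polygon Data frame or matrix with columns `easting`, `northing`
#'   (metres); the ring needs no explicit closure.
#' @return `polygon_area()`: area in square metres.
#' @export
polygon_area <- function(polygon) {
  p <- .ring(polygon)
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @rdname polygon_area
#' @param x,y Coordinates of the query points.
#' @return `point_in_polygon()`: logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  p <- .ring(polygon)
  px <- p[, 1]; py <- p[, 2]
  n <- nrow(p)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.ring <- function(polygon) {
  p <- as.matrix(as.data.frame(polygon)[, c("easting", "northing")])
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  p
}

#' Build a square-pixel prediction grid over a polygon
#'
#' Lays an axis-aligned lattice of square cells of side `sqrt(pixel_area)`
#' over the polygon's bounding box, anchored at its lower-left corner, and
#' keeps the cells whose centres fall inside the polygon (even-odd rule).
#' Cells are ordered row-major from the south-west corner.
#'
#' @param polygon Vertex ring (`easting`, `northing` in metres).
#' @param pixel_area Cell area in square metres.
#' @return A `prediction_grid` tibble of cell centres (`easting`, `northing`)
#'   with attributes `pixel_area`, `polygon`, `polygon_area` and
#'   `n_cells_estimate` (`round(polygon area / pixel_area)`).
#' @export
build_prediction_grid <- function(polygon, pixel_area) {
  stopifnot(pixel_area > 0)
  area <- polygon_area(polygon)
  if (area <= 0) stop("degenerate polygon: area is zero", call. = FALSE)
  p <- .ring(polygon)
  side <- sqrt(pixel_area)
  x0 <- min(p[, 1]); y0 <- min(p[, 2])
  nx <- ceiling((max(p[, 1]) - x0) / side)
  ny <- ceiling((max(p[, 2]) - y0) / side)
  centers <- expand.grid(
    easting = x0 + (seq_len(nx) - 0.5) * side,
    northing = y0 + (seq_len(ny) - 0.5) * side
  )
  keep <- point_in_polygon(centers$easting, centers$northing, p)
  out <- tibble::as_tibble(centers[keep, ])
  structure(out, class = c("prediction_grid", class(out)),
            pixel_area = pixel_area, polygon = p, polygon_area = area,
            n_cells_estimate = round(area / pixel_area))
}

#' Ordinary kriging
#'
#' Solves, for every target location \eqn{s_0}, the ordinary-kriging system in
#' semivariance form with the unbiasedness constraint \eqn{\sum_i w_i = 1}
#' enforced through a Lagrange multiplier \eqn{\lambda_0}: the prediction is
#' \eqn{\hat Z(s_0) = \sum_i w_i z(s_i)} and the kriging variance
#' \eqn{\sigma^2(s_0) = \sum_i w_i \gamma(s_i, s_0) + \lambda_0}. All samples
#' participate (global neighbourhood).
#'
#' @param samples Data frame with `easting`, `northing` and the attribute.
#' @param attribute Column to predict.
#' @param model A [variogram_model()].
#' @param targets Data frame of target locations (`easting`, `northing`),
#'   e.g. a [build_prediction_grid()] result.
#' @param keep_weights Keep the full weight matrix (targets x samples) in
#'   attribute `"weights"`, plus `"lagrange"` (for audit).
#' @return A `kriging_result` tibble: `easting`, `northing`, `prediction`,
#'   `variance`.
#' @export
ordinary_kriging <- function(samples, attribute, model, targets,
                             keep_weights = FALSE) {
  stopifnot(inherits(model, "variogram_model"))
  z <- samples[[attribute]]
  if (is.null(z)) stop("attribute not found: ", attribute, call. = FALSE)
  xy <- as.matrix(samples[, c("easting", "northing")])
  if (nrow(xy) < 2) stop("need at least 2 sample locations", call. = FALSE)

  # duplicate-location policy: identical values deduplicated, else singular
  d <- as.matrix(stats::dist(xy))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    differ <- dup[z[dup[, 1]] != z[dup[, 2]], , drop = FALSE]
    if (nrow(differ) > 0) {
      stop(sprintf("singular system: samples %d and %d share a location but differ in '%s'",
                   differ[1, 1], differ[1, 2], attribute), call. = FALSE)
    }
    warning("dropping ", nrow(dup), " duplicate location(s) with identical values",
            call. = FALSE)
    drop <- unique(dup[, 2])
    xy <- xy[-drop, , drop = FALSE]; z <- z[-drop]
    d <- as.matrix(stats::dist(xy))
  }
  n <- nrow(xy)

  A <- rbind(cbind(model_curve(model, d), 1), c(rep(1, n), 0))
  tx <- as.matrix(as.data.frame(targets)[, c("easting", "northing")])
  d0 <- sqrt(outer(xy[, 1], tx[, 1], "-")^2 + outer(xy[, 2], tx[, 2], "-")^2)
  B <- rbind(matrix(model_curve(model, d0), nrow = n), 1)
  # smooth zero-nugget models (notably gaussian) can make the system
  # numerically singular; a vanishing nugget is added until it factorizes
  eps <- 0
  sol <- NULL
  scale <- max(A[seq_len(n), seq_len(n)], 1e-12)
  for (k in 0:4) {
    Ak <- A
    if (eps > 0) {
      off <- matrix(eps, n, n); diag(off) <- 0
      Ak[seq_len(n), seq_len(n)] <- Ak[seq_len(n), seq_len(n)] + off
    }
    sol <- tryCatch(solve(Ak, B), error = function(e) NULL)
    if (!is.null(sol)) break
    eps <- if (eps == 0) 1e-12 * scale else eps * 100
  }
  if (is.null(sol)) {
    stop("ordinary-kriging system is singular for this configuration",
         call. = FALSE)
  }
  W <- sol[seq_len(n), , drop = FALSE]
  lambda <- unname(sol[n + 1, ])
  pred <- as.numeric(crossprod(W, z))
  g0 <- matrix(model_curve(model, d0), nrow = n)
  var <- pmax(unname(colSums(W * g0) + lambda), 0)

  out <- tibble::tibble(easting = tx[, 1], northing = tx[, 2],
                        prediction = pred, variance = var)
  out <- structure(out, class = c("kriging_result", class(out)),
                   attribute = attribute, model = model)
  if (keep_weights) {
    attr(out, "weights") <- t(W)
    attr(out, "lagrange") <- lambda
  }
  out
}

#' Leave-one-out cross-validation of ordinary kriging
#'
#' Each sample in turn is removed and predicted by ordinary kriging from the
#' remaining samples with the same (globally fitted) variogram model — no
#' refit per fold. Summary errors over the \eqn{N} validation points:
#' \deqn{ASE = \sqrt{\tfrac1N \sum_j [Z'(s_j) - \bar{Z'}]^2}, \quad
#'       RMSE = \sqrt{\tfrac1N \sum_j [Z(s_j) - Z'(s_j)]^2}, \quad
#'       RMSE_r = RMSE / S_z,}
#' where \eqn{Z'} are the LOO estimates and \eqn{S_z} the standard deviation
#' (denominator \eqn{N-1}) of the observations.
#'
#' @inheritParams ordinary_kriging
#' @return A `cv_report` tibble with per-point `sample_id`, `observed`,
#'   `estimated`, `error`; metrics via [glance.cv_report()] or attributes
#'   `ASE`, `RMSE`, `RMSE_r`, `S_z`, `N`.
#' @export
loo_cross_validation <- function(samples, attribute, model) {
  n <- nrow(samples)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  z <- samples[[attribute]]
  est <- vapply(seq_len(n), function(j) {
    ordinary_kriging(samples[-j, ], attribute, model,
                     targets = samples[j, c("easting", "northing")])$prediction
  }, numeric(1))
  ids <- if ("sample_id" %in% names(samples)) samples$sample_id else
    as.character(seq_len(n))
  out <- tibble::tibble(sample_id = ids, observed = z, estimated = est,
                        error = z - est)
  ase <- sqrt(mean((est - mean(est))^2))
  rmse <- sqrt(mean((z - est)^2))
  sz <- stats::sd(z)
  structure(out, class = c("cv_report", class(out)),
            attribute = attribute, model = model,
            ASE = ase, RMSE = rmse, S_z = sz, RMSE_r = rmse / sz, N = n)
}

#' Kriging accuracy flags from a cross-validation report
#'
#' The interpolation is considered good when ASE and RMSE are similar
#' (relative gap at most `ase_rmse_rel_tol`), and the prediction accurate when
#' the normalized error RMSE_r is close to (at most about) 40%.
#'
#' @param cv A `cv_report` from [loo_cross_validation()].
#' @param ase_rmse_rel_tol Relative tolerance (default 0.2), used both for
#'   the ASE/RMSE gap and to widen the 40% RMSE_r bound.
#' @return A list with logicals `ase_rmse_similar` and `rmse_r_accurate`.
#' @export
prediction_accuracy_flag <- function(cv, ase_rmse_rel_tol = 0.2) {
  stopifnot(inherits(cv, "cv_report"))
  ase <- attr(cv, "ASE"); rmse <- attr(cv, "RMSE"); rr <- attr(cv, "RMSE_r")
  list(
    ase_rmse_similar = abs(ase - rmse) / max(ase, rmse, .Machine$double.eps) <=
      ase_rmse_rel_tol,
    rmse_r_accurate = rr <= 0.40 * (1 + ase_rmse_rel_tol)
  )
}
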