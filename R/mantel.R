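#' Mantel autocorrelogram
#'
#' For each geographic distance class, the standardized Mantel statistic
#' between the class-membership indicator of sample pairs and the value
#' dissimilarity of those pairs, with the sign flipped so that a positive
#' statistic means positive spatial autocorrelation (nearby pairs more similar
#' than average). Significance per class is a two-sided permutation test that
#' shuffles sample identities (simultaneous row/column permutation of the
#' dissimilarity matrix); \eqn{p = (\#exceedances + 1)/(n_{perm} + 1)}.
#'
#' @param values Numeric attribute vector (one value per sample; dissimilarity
#'   is `|z_i - z_j|`), or a ready-made symmetric dissimilarity matrix/`dist`.
#' @param samples Data frame with `easting`/`northing` (metres).
#' @param n_classes Number of equal-width distance classes (default 5).
#' @param n_perm Number of permutations (default 1000, minimum 99).
#' @param seed Integer seed for the permutations.
#' @param max_lag Upper bound of the last class; default the maximum pairwise
#'   distance, so the classes partition the whole lag range.
#' @return A `mantel_correlogram` tibble with columns `class` (centre),
#'   `lower`, `upper`, `np` (pairs in class), `statistic`, `p_value`. Classes
#'   with no pairs are dropped with a warning.
#' @export
mantel_correlogram <- function(values, samples, n_classes = 5, n_perm = 1000,
                               seed, max_lag = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (nrow(samples) < 5) stop("need at least 5 samples", call. = FALSE)
  n <- nrow(samples)
  geo <- pairwise_distances(samples)
  D <- if (inherits(values, "dist")) as.matrix(values)
       else if (is.matrix(values)) values
       else abs(outer(as.numeric(values), as.numeric(values), "-"))
  if (!all(dim(D) == n)) stop("dissimilarity does not match sample count", call. = FALSE)

  low <- which(lower.tri(geo), arr.ind = TRUE)
  hvec <- geo[low]
  if (is.null(max_lag)) max_lag <- max(hvec)
  breaks <- seq(0, max_lag, length.out = n_classes + 1)
  cls <- cut(hvec, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  np <- tabulate(cls, nbins = n_classes)
  if (any(np == 0)) {
    warning("dropping ", sum(np == 0), " distance class(es) with no pairs",
            call. = FALSE)
  }
  keep <- which(np > 0)
  # centred & scaled indicator columns, one per retained class
  I <- vapply(keep, function(k) as.numeric(!is.na(cls) & cls == k), numeric(length(hvec)))
  Ic <- scale(I, center = TRUE, scale = FALSE)
  In <- sqrt(colSums(Ic^2))

  stat_for <- function(dvec) {
    dc <- dvec - mean(dvec)
    dn <- sqrt(sum(dc^2))
    if (dn == 0) return(rep(0, length(keep)))
    -as.numeric(crossprod(Ic, dc)) / (In * dn)
  }

  obs <- stat_for(D[low])
  exceed <- integer(length(keep))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      dperm <- D[cbind(p[low[, 1]], p[low[, 2]])]
      exceed <- exceed + (abs(stat_for(dperm)) >= abs(obs))
    }
  })
  pval <- (exceed + 1) / (n_perm + 1)

  out <- tibble::tibble(
    class = (breaks[keep] + breaks[keep + 1]) / 2,
    lower = breaks[keep], upper = breaks[keep + 1],
    np = np[keep], statistic = obs, p_value = pval
  )
  structure(out, class = c("mantel_correlogram", class(out)),
            n_perm = n_perm, seed = seed)
}
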