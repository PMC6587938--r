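#' Read and validate georeferenced sample metadata
#'
#' The metadata CSV has the header
#' `sample_id,easting,northing,pH,EC,WC,org_C,inorg_C,sand,silt,clay`:
#' UTM coordinates in metres, pH unitless, EC (electrolytic conductivity) in
#' dS/m, WC (gravimetric water content) in percent, organic and inorganic C in
#' g/kg dry soil, and the texture fractions in percent.
#'
#' @param path CSV file path.
#' @return A validated tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_transect(df)
  df
}

#' @rdname read_sample_metadata
#' @param samples A data frame of transect samples.
#' @param texture_tol Tolerance for `sand + silt + clay = 100` (percent).
#' @export
validate_transect <- function(samples, texture_tol = 1.5) {
  need <- c("sample_id", "easting", "northing")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (any(!is.finite(samples$easting)) || any(!is.finite(samples$northing))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if ("EC" %in% names(samples) && any(samples$EC < 0, na.rm = TRUE)) {
    stop("EC must be >= 0", call. = FALSE)
  }
  if ("WC" %in% names(samples) &&
      any(samples$WC < 0 | samples$WC > 100, na.rm = TRUE)) {
    stop("WC must lie in [0, 100] percent", call. = FALSE)
  }
  tex <- c("sand", "silt", "clay")
  if (all(tex %in% names(samples))) {
    s <- rowSums(samples[, tex])
    bad <- which(abs(s - 100) > texture_tol)
    if (length(bad)) {
      stop("texture fractions of sample ", samples$sample_id[bad[1]],
           " sum to ", round(s[bad[1]], 2), ", not 100", call. = FALSE)
    }
  }
  invisible(samples)
}

#' Pairwise planar distances between samples
#'
#' Euclidean distance on (easting, northing); UTM coordinates are treated as
#' planar. Duplicate locations are allowed but flagged (they make a kriging
#' system singular).
#'
#' @param samples Data frame with `easting` and `northing` in metres (and
#'   optionally `sample_id` for labels).
#' @return A symmetric distance matrix in metres with zero diagonal, with
#'   logical attribute `"has_duplicates"`.
#' @export
pairwise_distances <- function(samples) {
  if (nrow(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  xy <- as.matrix(samples[, c("easting", "northing")])
  if (any(!is.finite(xy))) stop("non-finite coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(xy))
  ids <- if ("sample_id" %in% names(samples)) samples$sample_id else
    as.character(seq_len(nrow(samples)))
  dimnames(d) <- list(ids, ids)
  dup <- any(d[upper.tri(d)] == 0)
  if (dup) warning("duplicate sample coordinates present", call. = FALSE)
  attr(d, "has_duplicates") <- dup
  d
}
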