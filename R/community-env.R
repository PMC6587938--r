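#' Spearman correlations between taxa and soil variables
#'
#' Spearman rank correlation (average ranks for ties) between each taxon's
#' relative abundance and each environmental variable across the shared
#' samples, with a two-sided p-value from the t approximation on `n - 2`
#' degrees of freedom and significance tiers at the usual 0.05 / 0.01 cuts.
#' Constant vectors yield `r = NA` with tier `"ns"`.
#'
#' @param abundances Proportion (or abundance) matrix, taxa x samples, as from
#'   [relative_abundance()], or a long tibble with `taxon_id`, `sample_id`,
#'   and a value column.
#' @param env Data frame of samples with `sample_id` and environmental
#'   columns.
#' @param variables Environmental columns to use; default every numeric
#'   column except the coordinates.
#' @param alpha_tiers Two significance thresholds, default `c(0.05, 0.01)`.
#' @return A `correlation_table` tibble: `taxon`, `variable`, `r`, `p_value`,
#'   `tier` (`"ns"`, `"significant"`, `"highly_significant"`), `sign`.
#' @export
spearman_matrix <- function(abundances, env, variables = NULL,
                            alpha_tiers = c(0.05, 0.01)) {
  if (!is.matrix(abundances)) {
    df <- as.data.frame(abundances)
    val <- setdiff(names(df), c("taxon_id", "sample_id", "taxonomy"))[1]
    abundances <- stats::xtabs(stats::reformulate("taxon_id + sample_id", val),
                               data = df)
    abundances <- as(abundances, "matrix")
  }
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
    variables <- setdiff(variables, c("easting", "northing"))
  }
  shared <- intersect(colnames(abundances), env$sample_id)
  if (length(shared) < 4) stop("need at least 4 shared samples", call. = FALSE)
  A <- abundances[, shared, drop = FALSE]
  E <- env[match(shared, env$sample_id), , drop = FALSE]
  alpha_tiers <- sort(alpha_tiers, decreasing = TRUE)

  out <- tidyr::expand_grid(taxon = rownames(A), variable = variables)
  res <- purrr::pmap_dfr(out, function(taxon, variable) {
    x <- A[taxon, ]; y <- E[[variable]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(r = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- dplyr::bind_cols(out, res)
  out$tier <- dplyr::case_when(
    is.na(out$p_value) ~ "ns",
    out$p_value < alpha_tiers[2] ~ "highly_significant",
    out$p_value < alpha_tiers[1] ~ "significant",
    TRUE ~ "ns"
  )
  out$sign <- ifelse(is.na(out$r), NA_character_,
                     ifelse(out$r >= 0, "positive", "negative"))
  structure(out, class = c("correlation_table", class(out)),
            alpha_tiers = alpha_tiers)
}

#' Greedy collinearity screening of environmental variables
#'
#' While any variable pair correlates beyond `pairwise_threshold` in absolute
#' value, the member of the worst pair with the larger mean absolute
#' correlation to all other variables is dropped (ties broken by variable
#' name order). A simple screen for the least multicollinear variable set.
#'
#' @param env Data frame of samples; only the columns in `variables` enter.
#' @param variables Candidate columns; default all numeric except coordinates.
#' @param pairwise_threshold Absolute Pearson correlation cutoff (default 0.8).
#' @return Character vector of retained variable names.
#' @export
collinearity_filter <- function(env, variables = NULL, pairwise_threshold = 0.8) {
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
    variables <- setdiff(variables, c("easting", "northing"))
  }
  if (length(variables) < 2) return(variables)
  keep <- sort(variables)
  repeat {
    R <- abs(stats::cor(as.data.frame(env)[, keep]))
    diag(R) <- 0
    if (max(R) <= pairwise_threshold) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    burden <- rowMeans(R)[pair]
    drop <- if (burden[1] != burden[2]) pair[which.max(burden)] else sort(pair)[2]
    keep <- setdiff(keep, drop)
    if (length(keep) < 2) break
  }
  keep
}

#' BIOENV: exhaustive environmental subset selection
#'
#' Finds the subset of (internally standardized) environmental variables whose
#' between-sample Euclidean distances have the maximum Spearman rank
#' correlation with the community dissimilarities. Every non-empty subset up
#' to `max_subset_size` is evaluated; the best subset per size and overall are
#' reported.
#'
#' @param community An `otu_table` (dissimilarity computed on relative
#'   abundances), or a ready-made `dist`/matrix of community dissimilarities.
#' @param env Data frame with `sample_id` and environmental columns.
#' @param variables Candidate environmental columns; default all numeric
#'   except coordinates.
#' @param dissimilarity `"bray_curtis"` (default) or `"euclidean"`, used when
#'   `community` is an `otu_table`.
#' @param max_subset_size Largest subset size to search (default: all
#'   variables; clamped with a warning when larger).
#' @return A `bioenv_result`: tibble of every evaluated subset (`subset`,
#'   `size`, `correlation`), with `best_by_size` and `best` in attributes.
#' @export
bioenv <- function(community, env, variables = NULL,
                   dissimilarity = c("bray_curtis", "euclidean"),
                   max_subset_size = NULL) {
  dissimilarity <- match.arg(dissimilarity)
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
    variables <- setdiff(variables, c("easting", "northing"))
  }
  if (inherits(community, "otu_table")) {
    ra <- relative_abundance(community)
    comm_ids <- colnames(ra)
  } else {
    cd <- as.matrix(community)
    comm_ids <- if (!is.null(rownames(cd))) rownames(cd) else env$sample_id
  }
  shared <- intersect(comm_ids, env$sample_id)
  if (length(shared) < 5) stop("need at least 5 shared samples", call. = FALSE)

  if (inherits(community, "otu_table")) {
    method <- c(bray_curtis = "bray", euclidean = "euclidean")[[dissimilarity]]
    cdist <- vegan::vegdist(t(ra[, shared, drop = FALSE]), method = method)
  } else {
    cdist <- stats::as.dist(as.matrix(community)[shared, shared])
  }
  E <- scale(as.matrix(as.data.frame(env)[match(shared, env$sample_id),
                                          variables, drop = FALSE]))
  cvec <- as.numeric(cdist)

  p <- length(variables)
  if (is.null(max_subset_size)) max_subset_size <- p
  if (max_subset_size > p) {
    warning("max_subset_size clamped to the ", p, " available variables",
            call. = FALSE)
    max_subset_size <- p
  }
  subsets <- unlist(lapply(seq_len(max_subset_size), function(k)
    utils::combn(variables, k, simplify = FALSE)), recursive = FALSE)
  rho <- vapply(subsets, function(vars) {
    ed <- stats::dist(E[, vars, drop = FALSE])
    stats::cor(cvec, as.numeric(ed), method = "spearman")
  }, numeric(1))
  out <- tibble::tibble(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets),
    correlation = rho
  )
  best_by_size <- dplyr::slice_max(dplyr::group_by(out, .data$size),
                                   .data$correlation, n = 1, with_ties = FALSE)
  best <- out[which.max(out$correlation), ]
  structure(out, class = c("bioenv_result", class(out)),
            best_by_size = dplyr::ungroup(best_by_size), best = best,
            dissimilarity = dissimilarity, n_samples = length(shared))
}

#' @rdname bioenv
#' @param x A `bioenv_result`.
#' @export
bioenv_best <- function(x) attr(x, "best")
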