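#' Alpha diversity of a single sample
#'
#' Computes one diversity index from a vector of taxon counts. With
#' proportions \eqn{p_i} and observed richness \eqn{S}:
#' Shannon \eqn{H = -\sum p_i \log_b p_i}; Gini-Simpson \eqn{1 - \sum p_i^2};
#' reciprocal Simpson \eqn{1/\sum p_i^2} (effective number of taxa); Simpson
#' evenness \eqn{(1/\sum p_i^2)/S}; Good's coverage \eqn{1 - F_1/N} where
#' \eqn{F_1} is the number of singletons and \eqn{N} the total reads.
#'
#' @param counts Non-negative integer vector with at least one positive entry.
#' @param metric One of `"shannon"`, `"gini_simpson"`, `"simpson_evenness"`,
#'   `"reciprocal_simpson"`, `"goods_coverage"`.
#' @param log_base Logarithm base for Shannon (default 2).
#' @return A single numeric value.
#' @export
alpha_diversity <- function(counts,
                            metric = c("shannon", "gini_simpson", "simpson_evenness",
                                       "reciprocal_simpson", "goods_coverage"),
                            log_base = 2) {
  metric <- match.arg(metric)
  counts <- .check_counts(counts)
  p <- counts / sum(counts)
  D <- sum(p^2)
  switch(metric,
    shannon = -sum(p * log(p, base = log_base)),
    gini_simpson = 1 - D,
    reciprocal_simpson = 1 / D,
    simpson_evenness = (1 / D) / length(p),
    goods_coverage = 1 - sum(counts == 1) / sum(counts)
  )
}

.check_counts <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero", call. = FALSE)
  counts
}

#' Nonparametric richness estimators
#'
#' Chao1 (bias-corrected by default):
#' \eqn{S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))}, with \eqn{F_k} the number of
#' taxa observed exactly \eqn{k} times; the classic form
#' \eqn{S_{obs} + F_1^2/(2 F_2)} is available with `bias_corrected = FALSE`.
#' ACE splits taxa into rare (abundance `<= rare_cutoff`) and abundant classes
#' and extrapolates the rare class through its sample coverage.
#'
#' @inheritParams alpha_diversity
#' @param estimator `"chao1"` or `"ace"`.
#' @param rare_cutoff Rare/abundant split for ACE (default 10).
#' @param bias_corrected Use the bias-corrected Chao1 form (default), defined
#'   also when no doubletons exist.
#' @return A single numeric value, always `>=` observed richness.
#' @export
richness_estimate <- function(counts, estimator = c("chao1", "ace"),
                              rare_cutoff = 10, bias_corrected = TRUE) {
  estimator <- match.arg(estimator)
  counts <- .check_counts(counts)
  S_obs <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (estimator == "chao1") {
    if (bias_corrected) {
      S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))
    } else {
      if (F2 == 0) S_obs else S_obs + F1^2 / (2 * F2)
    }
  } else {
    rare <- counts[counts <= rare_cutoff]
    S_abund <- sum(counts > rare_cutoff)
    S_rare <- length(rare)
    if (S_rare == 0) return(S_obs)
    N_rare <- sum(rare)
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      # coverage undefined (all rare taxa are singletons); fall back to Chao1
      warning("ACE coverage is zero; falling back to bias-corrected Chao1",
              call. = FALSE)
      return(richness_estimate(counts, "chao1"))
    }
    k <- seq_len(rare_cutoff)
    Fk <- vapply(k, function(i) sum(rare == i), numeric(1))
    gamma2 <- max(S_rare / C_ace * sum(k * (k - 1) * Fk) /
                    (N_rare * (N_rare - 1)) - 1, 0)
    S_abund + S_rare / C_ace + F1 / C_ace * gamma2
  }
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the observed
#' tips to the root of a rooted tree.
#'
#' @param observed_taxa Character vector of observed tip labels.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Total branch length of the spanned subtree.
#' @export
faith_pd <- function(observed_taxa, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  observed_taxa <- unique(observed_taxa)
  missing <- setdiff(observed_taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(observed_taxa) == 0) return(0)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  used <- logical(max(tree$edge)) # node -> its parent edge is in the subtree
  for (tip in match(observed_taxa, tree$tip.label)) {
    node <- tip
    while (node != root && !used[node]) {
      used[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[used[tree$edge[, 2]]])
}

#' Per-sample diversity table after rarefaction
#'
#' Rarefies the OTU table to `depth` (dropping samples below it, see
#' [rarefy()]) and computes all diversity and richness metrics for every
#' retained sample. Faith's PD is included when a tree is supplied.
#'
#' @param x An `otu_table`.
#' @param depth Rarefaction depth.
#' @param seed Seed for the rarefaction draw.
#' @param tree Optional rooted `phylo` tree whose tips are taxon ids.
#' @param log_base Shannon log base.
#' @param rare_cutoff ACE rare/abundant cutoff.
#' @return A long tibble with columns `sample_id`, `metric`, `value`; the
#'   rarefaction log is carried in attribute `"rarefaction_log"`.
#' @export
diversity_table <- function(x, depth, seed, tree = NULL, log_base = 2,
                            rare_cutoff = 10) {
  rar <- rarefy(x, depth = depth, seed = seed)
  m <- rar$counts
  alpha_metrics <- c("shannon", "gini_simpson", "simpson_evenness",
                     "reciprocal_simpson", "goods_coverage")
  rows <- purrr::map_dfr(colnames(m), function(sid) {
    cnt <- m[, sid]
    vals <- c(
      observed_otus = sum(cnt > 0),
      vapply(alpha_metrics, function(met)
        alpha_diversity(cnt, met, log_base = log_base), numeric(1)),
      chao1 = richness_estimate(cnt, "chao1"),
      ace = richness_estimate(cnt, "ace", rare_cutoff = rare_cutoff)
    )
    if (!is.null(tree)) {
      vals <- c(vals, faith_pd = faith_pd(rownames(m)[cnt > 0], tree))
    }
    tibble::tibble(sample_id = sid, metric = names(vals), value = unname(vals))
  })
  attr(rows, "rarefaction_log") <- rarefaction_log(rar)
  rows
}

#' Ratios of diversity metrics between two domains
#'
#' For each sample present in both tables, the ratio of metric values (e.g.
#' Archaea over Bacteria), as used to contrast the two domains' diversity
#' along a transect.
#'
#' @param div_a,div_b Long diversity tables (`sample_id`, `metric`, `value`)
#'   as returned by [diversity_table()]; `div_a` is the numerator.
#' @param metric Metric name(s) to ratio; default all shared metrics.
#' @param digits Rounding for the reported ratio (default 2, `NULL` for none).
#' @return A tibble with `sample_id`, `metric`, `value_a`, `value_b`, `ratio`.
#' @export
domain_ratio <- function(div_a, div_b, metric = NULL, digits = 2) {
  if (!is.null(metric)) {
    div_a <- dplyr::filter(div_a, .data$metric %in% .env$metric)
    div_b <- dplyr::filter(div_b, .data$metric %in% .env$metric)
  }
  j <- dplyr::inner_join(div_a, div_b, by = c("sample_id", "metric"),
                         suffix = c("_a", "_b"))
  if (nrow(j) == 0) stop("no shared samples/metrics", call. = FALSE)
  if (any(j$value_b <= 0)) stop("denominator values must be > 0", call. = FALSE)
  j$ratio <- j$value_a / j$value_b
  if (!is.null(digits)) j$ratio <- round(j$ratio, digits)
  tibble::as_tibble(j[, c("sample_id", "metric", "value_a", "value_b", "ratio")])
}
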