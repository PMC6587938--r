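# shared fixtures and independent (naive) oracles used across test files

toy_otu <- function(counts = matrix(c(1L, 3L, 2L, 4L), 2, 2,
                                    dimnames = list(c("OTU1", "OTU2"),
                                                    c("S1", "S2"))),
                    taxonomy = NULL) {
  otu_table(counts, taxonomy = taxonomy)
}

random_otu <- function(n_taxa = 20, n_samp = 5, seed = 1, lambda = 8) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samp, lambda), n_taxa, n_samp,
                dimnames = list(paste0("OTU", seq_len(n_taxa)),
                                paste0("S", seq_len(n_samp))))
    phyla <- sample(c("p__A", "p__B", "p__C"), n_taxa, replace = TRUE)
    otu_table(m, taxonomy = paste0("k__K; ", phyla, "; g__G", seq_len(n_taxa)))
  })
}

transect_1d <- function(x, z = NULL) {
  out <- tibble::tibble(sample_id = paste0("P", seq_along(x)),
                        easting = x, northing = 0)
  if (!is.null(z)) out$z <- z
  out
}

# naive ordinary-kriging solver: builds and solves the (n+1) system with
# explicit loops, independent of the package's vectorized path
naive_ok <- function(xy, z, model, target) {
  n <- nrow(xy)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    A[i, j] <- model_curve(model, h)
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    b[i] <- model_curve(model, sqrt(sum((xy[i, ] - target)^2)))
  }
  b[n + 1] <- 1
  sol <- solve(A, b)
  list(pred = sum(sol[seq_len(n)] * z),
       var = sum(sol[seq_len(n)] * b[seq_len(n)]) + sol[n + 1],
       w = sol[seq_len(n)])
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

# naive exhaustive BIOENV: double loop over subsets, recomputing everything
naive_bioenv <- function(comm_dist, env, variables) {
  E <- scale(as.matrix(env[, variables, drop = FALSE]))
  best <- list(r = -Inf, subset = NULL)
  for (k in seq_along(variables)) {
    for (idx in utils::combn(length(variables), k, simplify = FALSE)) {
      ed <- as.numeric(dist(E[, idx, drop = FALSE]))
      r <- cor(as.numeric(comm_dist), ed, method = "spearman")
      if (r > best$r) best <- list(r = r, subset = variables[idx])
    }
  }
  best
}
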