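#' Simulate a Gaussian random field at fixed locations
#'
#' Draws one realization of a zero-mean-plus-`mean` Gaussian field whose
#' covariance between two points at lag \eqn{h} is \eqn{C(h) = sill -
#' \gamma(h)}, with \eqn{\gamma} the supplied variogram model, via Cholesky
#' factorization of the covariance among the points. A small diagonal jitter
#' (`1e-8 * sill`) keeps the factorization of borderline families (notably the
#' hole-effect/periodic model) positive definite.
#'
#' @param coords Data frame or matrix with `easting`, `northing` (metres).
#' @param model A [variogram_model()].
#' @param mean Field mean.
#' @param seed Integer seed; a fixed seed gives a bit-identical field.
#' @return Numeric vector, one value per location.
#' @export
simulate_gaussian_field <- function(coords, model, mean = 0, seed) {
  stopifnot(inherits(model, "variogram_model"))
  xy <- as.matrix(as.data.frame(coords)[, c("easting", "northing")])
  n <- nrow(xy)
  if (anyDuplicated(xy)) stop("coords must be distinct", call. = FALSE)
  sill <- model$nugget + model$psill
  if (sill == 0) return(rep(mean, n))
  C <- sill - model_curve(model, as.matrix(stats::dist(xy)))
  C <- C + diag(1e-8 * sill, n)
  L <- tryCatch(chol(C), error = function(e) {
    stop("covariance of the '", model$family,
         "' model is not positive semi-definite at these locations", call. = FALSE)
  })
  mean + as.numeric(withr::with_seed(seed, stats::rnorm(n)) %*% L)
}

#' Default per-property simulation specs
#'
#' The property set the transect generator emulates: near-constant alkaline
#' pH, log-scale EC spanning roughly an order of magnitude, variable WC and
#' organic/inorganic C, all with patchy (hole-effect) spatial structure and
#' high spatial dependence. Tweak and pass to [simulation_config()].
#'
#' @return Named list of property specs (`model`, `mean`, `transform`, `clip`).
#' @export
default_soil_properties <- function() {
  list(
    pH = list(model = variogram_model("periodic", nugget = 0.0004,
                                      psill = 0.0036, range = 70),
              mean = 10.45, transform = "identity", clip = c(0, 14)),
    EC = list(model = variogram_model("periodic", nugget = 0.06,
                                      psill = 0.55, range = 70),
              mean = 3.6, transform = "exp", clip = c(0, Inf)),
    WC = list(model = variogram_model("periodic", nugget = 10,
                                      psill = 95, range = 60),
              mean = 35, transform = "identity", clip = c(0, 100)),
    org_C = list(model = variogram_model("periodic", nugget = 2,
                                         psill = 23, range = 80),
                 mean = 15, transform = "identity", clip = c(0.1, Inf)),
    inorg_C = list(model = variogram_model("periodic", nugget = 0.4,
                                           psill = 3.6, range = 80),
                   mean = 8, transform = "identity", clip = c(0.1, Inf))
  )
}

.default_taxonomy <- function(n_taxa) {
  arch <- c("k__Archaea; p__Euryarchaeota; c__Halobacteria; o__Halobacteriales; f__Halobacteriaceae",
            "k__Archaea; p__Thaumarchaeota; c__Nitrososphaeria; o__Nitrososphaerales; f__Nitrososphaeraceae")
  bact <- c("k__Bacteria; p__Actinobacteria; c__Nitriliruptoria; o__Euzebyales; f__Euzebyaceae",
            "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Chromatiales; f__Ectothiorhodospiraceae",
            "k__Bacteria; p__Bacteroidetes; c__Rhodothermia; o__Rhodothermales; f__Rhodothermaceae",
            "k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Bacillaceae",
            "k__Bacteria; p__Gemmatimonadetes; c__Gemmatimonadetes; o__Gemmatimonadales; f__Gemmatimonadaceae",
            "k__Bacteria; p__Chlorobi; c__Ignavibacteria; o__Ignavibacteriales; f__Ignavibacteriaceae")
  half <- ceiling(n_taxa / 2)
  base <- c(rep_len(arch, half), rep_len(bact, n_taxa - half))
  paste0(base, "; g__Taxon", seq_len(n_taxa))
}

.default_effects <- function(n_taxa, covariates = c("EC", "WC", "pH", "org_C")) {
  B <- matrix(0, n_taxa, length(covariates),
              dimnames = list(NULL, covariates))
  # a few strong responders on the variable axes the transect actually has:
  # salinity (EC) and moisture (WC); the rest respond weakly or not at all
  idx <- seq_len(n_taxa)
  B[idx %% 5 == 1, "EC"] <- 1.2
  B[idx %% 5 == 2, "EC"] <- -1.0
  B[idx %% 5 == 3, "WC"] <- 0.8
  B[idx %% 7 == 4, "org_C"] <- 0.5
  B
}

#' Simulation configuration for synthetic transect fixtures
#'
#' Bundles everything the generator needs: sample locations along a short
#' transect, per-property variogram models with means, transforms and
#' physical clipping ranges, the compositional texture rule, and the
#' community model (taxa, log-linear effect matrix, sequencing-depth range).
#' The defaults emulate a 13-site, ~211 m saline lake-bed transect:
#' near-constant alkaline pH (~10.3-10.6), highly variable EC spanning
#' roughly 8-180 dS/m (log-scale field), WC around 13-56%, patchy (periodic)
#' spatial structure with high spatial dependence, and per-sample multinomial
#' sequencing depth drawn from a range wide enough that some samples fall
#' below a typical rarefaction threshold.
#'
#' @param n_samples Number of transect sites (default 13).
#' @param transect_length Transect length in metres (default 211).
#' @param coords Optional explicit data frame of `easting`/`northing`;
#'   overrides the two arguments above.
#' @param properties Named list of per-property specs (`model`, `mean`,
#'   `transform` = `"identity"`/`"exp"`, `clip = c(lo, hi)`).
#' @param texture_model Variogram model shared by the three latent texture
#'   fields (closed to sand+silt+clay = 100 by a softmax).
#' @param texture_base Log-scale baseline of the three texture fractions.
#' @param n_taxa Number of taxa in the simulated community (default 40).
#' @param baseline Per-taxon log-abundance baseline (default a fixed linear
#'   ramp giving an uneven rank-abundance curve).
#' @param effects Taxa x covariates log-linear effect matrix; columns name
#'   the soil covariates (default: strong EC responders, some WC/org_C).
#' @param depth_range Integer range of per-sample sequencing depths,
#'   `c(low, high)` (default `c(120, 1500)`).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 13, transect_length = 211,
                              coords = NULL,
                              properties = default_soil_properties(),
                              texture_model = variogram_model("periodic",
                                nugget = 0.005, psill = 0.045, range = 90),
                              texture_base = log(c(sand = 40, silt = 30, clay = 30)),
                              n_taxa = 40,
                              baseline = NULL,
                              effects = NULL,
                              depth_range = c(120, 1500),
                              seed = 1) {
  stopifnot(n_samples >= 2, transect_length > 0,
            length(depth_range) == 2, all(depth_range >= 1),
            depth_range[1] <= depth_range[2])
  if (is.null(baseline)) baseline <- seq(2, -2, length.out = n_taxa)
  if (is.null(effects)) effects <- .default_effects(n_taxa)
  stopifnot(length(baseline) == n_taxa, nrow(effects) == n_taxa,
            all(is.finite(effects)))
  for (p in properties) {
    stopifnot(inherits(p$model, "variogram_model"), p$clip[1] < p$clip[2])
  }
  structure(list(n_samples = n_samples, transect_length = transect_length,
                 coords = coords, properties = properties,
                 texture_model = texture_model, texture_base = texture_base,
                 n_taxa = n_taxa, baseline = baseline, effects = effects,
                 depth_range = as.integer(depth_range), seed = seed),
            class = "simulation_config")
}

#' Simulate georeferenced transect samples
#'
#' Sites are placed at lightly jittered regular intervals along a NW-SE
#' diagonal; each soil property is one Gaussian-field realization of its
#' configured variogram model, shifted/transformed to its mean and scale and
#' truncated to its physical range; sand/silt/clay come from three positive
#' latent fields closed to sum exactly 100.
#'
#' @param config A [simulation_config()].
#' @return A tibble of transect samples (validated by [validate_transect()]).
#' @export
simulate_transect <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  if (is.null(config$coords)) {
    s <- seq(0, config$transect_length, length.out = n)
    gap <- config$transect_length / (n - 1)
    s <- s + withr::with_seed(config$seed, stats::runif(n, -0.2, 0.2)) * gap
    s <- sort(s)
    coords <- tibble::tibble(easting = 501000 + s / sqrt(2),
                             northing = 2157550 - s / sqrt(2))
  } else {
    coords <- tibble::as_tibble(config$coords)
  }
  out <- tibble::tibble(sample_id = sprintf("Tx%03d", seq_len(nrow(coords))),
                        easting = coords$easting, northing = coords$northing)
  for (i in seq_along(config$properties)) {
    nm <- names(config$properties)[i]
    p <- config$properties[[i]]
    f <- simulate_gaussian_field(coords, p$model, mean = 0,
                                 seed = config$seed + 100 * i)
    v <- switch(p$transform,
                identity = p$mean + f,
                exp = exp(p$mean + f),
                stop("unknown transform: ", p$transform, call. = FALSE))
    out[[nm]] <- pmin(pmax(v, p$clip[1]), p$clip[2])
  }
  tex <- vapply(1:3, function(k) {
    exp(config$texture_base[k] +
          simulate_gaussian_field(coords, config$texture_model, mean = 0,
                                  seed = config$seed + 1000 + k))
  }, numeric(nrow(coords)))
  tex <- tex / rowSums(tex) * 100
  out$sand <- tex[, 1]; out$silt <- tex[, 2]; out$clay <- tex[, 3]
  validate_transect(out)
  out
}

#' Simulate an OTU table driven by soil covariates
#'
#' Per-sample taxon intensities are \eqn{\exp(baseline + B \cdot x)} with
#' \eqn{x} the standardized covariates named by the columns of the effect
#' matrix \eqn{B}; proportions are the normalized intensities and counts are
#' drawn multinomially at a per-sample depth sampled uniformly from the
#' configured range. Two-domain taxonomy lineages are attached.
#'
#' @param samples Transect samples from [simulate_transect()] (must contain
#'   every covariate named by the effect-matrix columns).
#' @param config A [simulation_config()].
#' @return An `otu_table` with taxonomy; attribute `"true_proportions"` holds
#'   the generating taxa x samples proportion matrix.
#' @export
simulate_community <- function(samples, config) {
  stopifnot(inherits(config, "simulation_config"))
  B <- config$effects
  covs <- colnames(B)
  miss <- setdiff(covs, names(samples))
  if (length(miss)) stop("samples lack covariate(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- scale(as.matrix(as.data.frame(samples)[, covs, drop = FALSE]))
  X[is.nan(X)] <- 0 # constant covariate standardizes to 0
  eta <- config$baseline + B %*% t(X) # taxa x samples
  if (any(!is.finite(exp(eta)))) stop("non-finite taxon intensity", call. = FALSE)
  P <- exp(eta)
  P <- sweep(P, 2, colSums(P), "/")
  n <- ncol(P)
  counts <- withr::with_seed(config$seed + 5000, {
    depths <- sample(seq(config$depth_range[1], config$depth_range[2]), n,
                     replace = TRUE)
    m <- vapply(seq_len(n), function(j)
      stats::rmultinom(1, size = depths[j], prob = P[, j])[, 1],
      numeric(config$n_taxa))
    m
  })
  dimnames(counts) <- list(paste0("OTU", seq_len(config$n_taxa)),
                           samples$sample_id)
  out <- otu_table(counts, taxonomy = .default_taxonomy(config$n_taxa))
  attr(out, "true_proportions") <- `dimnames<-`(P, dimnames(counts))
  out
}

#' Rectangular polygon around a transect
#'
#' A rotated rectangle aligned with the transect's principal direction, wide
#' enough to reach `area` square metres — a stand-in prediction polygon for
#' synthetic runs (the study-style use is a ~7,141 m2 ring around the
#' sampling line).
#'
#' @param samples Transect samples (`easting`, `northing`).
#' @param area Target polygon area in m2 (default 7141).
#' @return A tibble vertex ring (`easting`, `northing`), closed.
#' @export
transect_polygon <- function(samples, area = 7141) {
  xy <- as.matrix(samples[, c("easting", "northing")])
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))$v
  t1 <- xy %*% sv[, 1]
  len <- diff(range(t1)) * 1.05
  width <- area / len
  u <- sv[, 1]; v <- sv[, 2]
  mid <- ctr + u * (mean(range(t1)) - sum(ctr * u))
  corners <- rbind(
    mid + u * len / 2 + v * width / 2,
    mid + u * len / 2 - v * width / 2,
    mid - u * len / 2 - v * width / 2,
    mid - u * len / 2 + v * width / 2,
    mid + u * len / 2 + v * width / 2
  )
  tibble::tibble(easting = corners[, 1], northing = corners[, 2])
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the OTU table (TSV), sample metadata (CSV), prediction polygon
#' (CSV), the configuration echo (YAML) and a seed log, so a full pipeline
#' run needs no download.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Invisibly, a named vector of the written paths.
#' @export
write_fixture_bundle <- function(dir, config = simulation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- simulate_transect(config)
  otu <- simulate_community(samples, config)
  poly <- transect_polygon(samples)
  paths <- c(
    otu = file.path(dir, "otu_table.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    polygon = file.path(dir, "polygon.csv"),
    config = file.path(dir, "config.yml"),
    seed_log = file.path(dir, "seed.log")
  )
  write_otu_table(otu, paths[["otu"]], format = "tsv")
  readr::write_csv(samples, paths[["metadata"]])
  readr::write_csv(poly, paths[["polygon"]])
  cfg <- list(n_samples = config$n_samples,
              transect_length = config$transect_length,
              n_taxa = config$n_taxa,
              depth_range = config$depth_range, seed = config$seed,
              properties = lapply(config$properties, function(p)
                list(family = p$model$family, nugget = p$model$nugget,
                     psill = p$model$psill, range = p$model$range,
                     mean = p$mean, transform = p$transform)))
  yaml::write_yaml(cfg, paths[["config"]])
  writeLines(paste("master seed:", config$seed), paths[["seed_log"]])
  invisible(paths)
}
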