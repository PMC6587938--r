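#' Pipeline configuration
#'
#' Settings for a full end-to-end run: per-domain OTU tables, sample
#' metadata, prediction polygon, rarefaction depths, variogram and kriging
#' settings, correlation tiers and BIOENV settings.
#'
#' @param otu_tables Named list (one entry per domain, e.g. `archaea`,
#'   `bacteria`) of `otu_table` objects or file paths.
#' @param metadata Transect sample table or CSV path.
#' @param polygon Vertex-ring data frame or CSV path.
#' @param tree Optional rooted `phylo` or newick path (enables Faith PD).
#' @param otu_format Format used when OTU entries are paths.
#' @param rarefaction_depths Named integer vector, one depth per domain.
#' @param n_bins,max_lag,families,weighting Variogram settings, see
#'   [empirical_variogram()] and [fit_variogram()].
#' @param pixel_area Prediction-grid cell area in m2 (default 2.38).
#' @param krige_variables Soil variables to interpolate and cross-validate.
#' @param krige_rank Taxonomic rank at which taxa relative abundances are
#'   kriged (default `"phylum"`).
#' @param krige_n_taxa How many of the most abundant rank-level taxa per
#'   domain to krige (default 2).
#' @param correlation_rank Rank for the taxa-environment Spearman table.
#' @param alpha_tiers Significance tiers for correlations.
#' @param bioenv_variables Environmental columns for BIOENV (default all).
#' @param bioenv_max_size Largest BIOENV subset size (default all).
#' @param outdir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(otu_tables, metadata, polygon, tree = NULL,
                            otu_format = "tsv",
                            rarefaction_depths,
                            n_bins = 12, max_lag = "half-max",
                            families = c("spherical", "exponential", "gaussian",
                                         "periodic", "nugget"),
                            weighting = "npairs_over_h2",
                            pixel_area = 2.38,
                            krige_variables = c("EC", "WC", "pH"),
                            krige_rank = "phylum", krige_n_taxa = 2,
                            correlation_rank = "genus",
                            alpha_tiers = c(0.05, 0.01),
                            bioenv_variables = NULL, bioenv_max_size = NULL,
                            outdir, seed = 1) {
  stopifnot(is.list(otu_tables), length(names(otu_tables)) == length(otu_tables))
  stopifnot(all(names(otu_tables) %in% names(rarefaction_depths)),
            all(rarefaction_depths >= 1))
  structure(list(otu_tables = otu_tables, metadata = metadata, polygon = polygon,
                 tree = tree, otu_format = otu_format,
                 rarefaction_depths = rarefaction_depths,
                 n_bins = n_bins, max_lag = max_lag, families = families,
                 weighting = weighting, pixel_area = pixel_area,
                 krige_variables = krige_variables, krige_rank = krige_rank,
                 krige_n_taxa = krige_n_taxa,
                 correlation_rank = correlation_rank,
                 alpha_tiers = alpha_tiers,
                 bioenv_variables = bioenv_variables,
                 bioenv_max_size = bioenv_max_size,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

.load_otu <- function(x, format) {
  if (inherits(x, "otu_table")) x else read_otu_table(x, format = format)
}

#' Run the full analysis pipeline
#'
#' Executes, per domain: rarefaction and the diversity table (plus the
#' between-domain ratio table when two domains are given); per soil variable:
#' empirical semivariogram, model fit and spatial-dependence class; grid
#' construction and ordinary-kriging maps for the selected soil variables and
#' the most abundant rank-level taxa, each with leave-one-out
#' cross-validation and accuracy flags; the taxa-environment Spearman
#' correlation table; and a BIOENV report per domain. Every artifact is a CSV
#' under `outdir`, listed with its MD5 checksum in `manifest.csv`. The run is
#' fully deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest tibble (`file`, `md5`); stage results are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  results <- list()
  emit <- function(df, name) {
    path <- file.path(out, name)
    readr::write_csv(tibble::as_tibble(df), path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) {
        note <- tibble::tibble(file = basename(written),
                               md5 = unname(tools::md5sum(written)))
        readr::write_csv(note, file.path(out, "manifest_partial.csv"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  meta <- stage("metadata", {
    m <- if (is.character(config$metadata)) read_sample_metadata(config$metadata)
         else validate_transect(config$metadata)
    tibble::as_tibble(m)
  })
  poly <- stage("polygon", {
    p <- if (is.character(config$polygon))
      readr::read_csv(config$polygon, show_col_types = FALSE)
    else config$polygon
    tibble::as_tibble(p)
  })
  tree <- stage("tree", {
    if (is.null(config$tree)) NULL
    else if (inherits(config$tree, "phylo")) config$tree
    else ape::read.tree(config$tree)
  })
  domains <- names(config$otu_tables)
  otus <- stage("otu_input", {
    lapply(config$otu_tables, .load_otu, format = config$otu_format)
  })

  # -- diversity ---------------------------------------------------------
  divs <- list()
  for (dm in domains) {
    divs[[dm]] <- stage(paste0("diversity_", dm), {
      dt <- diversity_table(otus[[dm]], depth = config$rarefaction_depths[[dm]],
                            seed = config$seed, tree = tree)
      emit(dt, paste0("diversity_", dm, ".csv"))
      emit(attr(dt, "rarefaction_log"), paste0("rarefaction_log_", dm, ".csv"))
      dt
    })
  }
  results$diversity <- divs
  if (length(domains) == 2) {
    results$domain_ratios <- stage("domain_ratios", {
      dr <- domain_ratio(divs[[1]], divs[[2]])
      emit(dr, paste0("ratio_", domains[1], "_over_", domains[2], ".csv"))
      dr
    })
  }

  # -- responses to map: soil variables + rank-level taxa abundances -----
  resp <- meta
  taxa_cols <- character()
  for (dm in domains) {
    resp <- stage(paste0("taxa_abundance_", dm), {
      coll <- collapse_to_rank(otus[[dm]], config$krige_rank)
      ra <- relative_abundance(coll)
      top <- order(rowMeans(ra), decreasing = TRUE)
      top <- top[seq_len(min(config$krige_n_taxa, nrow(ra)))]
      shared <- intersect(resp$sample_id, colnames(ra))
      add <- as.data.frame(t(ra[top, shared, drop = FALSE]))
      short <- vapply(strsplit(rownames(ra)[top], "; ", fixed = TRUE),
                      function(p) sub("^[a-z]__", "", utils::tail(p, 1)),
                      character(1))
      names(add) <- paste0(dm, "_", make.names(short))
      taxa_cols <- c(taxa_cols, names(add))
      add$sample_id <- shared
      dplyr::left_join(resp, add, by = "sample_id")
    })
  }
  responses <- c(config$krige_variables, taxa_cols)

  # -- variograms + dependence classes (Supp-6-style report) -------------
  fits <- list()
  vreport <- stage("variograms", {
    rows <- purrr::map_dfr(responses, function(v) {
      ok <- stats::complete.cases(resp[, c("easting", "northing", v)])
      emp <- empirical_variogram(resp[ok, ], v, n_bins = config$n_bins,
                                 max_lag = config$max_lag)
      fit <- fit_variogram(emp, families = config$families,
                           weighting = config$weighting)
      fits[[v]] <<- fit
      tibble::tibble(variable = v, model = fit$family,
                     sill = fit$nugget + fit$psill, range = fit$range,
                     nugget = fit$nugget,
                     nugget_sill_ratio = nugget_sill_ratio(fit),
                     dependence = spatial_dependence_class(fit))
    })
    emit(rows, "variogram_models.csv")
    rows
  })
  results$variograms <- vreport

  # -- kriging maps + LOO CV (Supp-7-style report) -----------------------
  grid <- stage("grid", build_prediction_grid(poly, config$pixel_area))
  results$grid <- grid
  cv_rows <- list()
  for (v in responses) {
    stage(paste0("krige_", v), {
      ok <- stats::complete.cases(resp[, c("easting", "northing", v)])
      kr <- ordinary_kriging(resp[ok, ], v, fits[[v]], grid)
      emit(kr, paste0("kriging_", make.names(v), ".csv"))
      cv <- loo_cross_validation(resp[ok, ], v, fits[[v]])
      flags <- prediction_accuracy_flag(cv)
      cv_rows[[v]] <- tibble::tibble(
        variable = v, n = attr(cv, "N"), ASE = attr(cv, "ASE"),
        RMSE = attr(cv, "RMSE"), RMSE_r = attr(cv, "RMSE_r"),
        ase_rmse_similar = flags$ase_rmse_similar,
        rmse_r_accurate = flags$rmse_r_accurate)
    })
  }
  results$cv <- dplyr::bind_rows(cv_rows)
  emit(results$cv, "cross_validation.csv")
  emit(tibble::tibble(easting = resp$easting, northing = resp$northing,
                      resp[, responses]), "observed_points.csv")

  # -- taxa-environment correlations -------------------------------------
  results$correlations <- stage("correlations", {
    tabs <- purrr::map_dfr(domains, function(dm) {
      coll <- collapse_to_rank(otus[[dm]], config$correlation_rank)
      ra <- relative_abundance(coll)
      ct <- spearman_matrix(ra, meta, alpha_tiers = config$alpha_tiers)
      dplyr::mutate(ct, domain = dm, .before = 1)
    })
    emit(tabs, "spearman_correlations.csv")
    tabs
  })

  # -- BIOENV (Supp-8-style report) --------------------------------------
  results$bioenv <- stage("bioenv", {
    tabs <- purrr::map_dfr(domains, function(dm) {
      be <- bioenv(otus[[dm]], meta, variables = config$bioenv_variables,
                   max_subset_size = config$bioenv_max_size)
      dplyr::mutate(tibble::as_tibble(be), domain = dm, .before = 1)
    })
    emit(tabs, "bioenv.csv")
    tabs
  })

  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  readr::write_csv(manifest, file.path(out, "manifest.csv"))
  attr(manifest, "results") <- results
  invisible(manifest)
}
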