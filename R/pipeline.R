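#' Pipeline run configuration
#'
#' Collects every choice the full analysis pipeline makes: input paths (or
#' in-memory objects), normalization scope, aggregate mode, cluster count,
#' LISA parameters and Jenks class counts. A seed is required whenever a
#' stochastic stage (LISA permutation inference) is enabled.
#'
#' @param panel,criteria,geometry file paths (long CSV / criteria CSV /
#'   GeoJSON) or the corresponding in-memory objects.
#' @param bounds_scope,aggregate_mode see [wsa()].
#' @param k number of Ward clusters (default 4).
#' @param n_permutations,alpha LISA parameters (defaults 999, 0.05).
#' @param jenks_k natural-breaks classes per axis (default 4).
#' @param missing_policy see [validate_panel()].
#' @param seed integer RNG seed for the stochastic stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, criteria, geometry = NULL,
                            bounds_scope = "pooled",
                            aggregate_mode = "all_determinants",
                            k = 4, n_permutations = 999, alpha = 0.05,
                            jenks_k = 4, missing_policy = "error", seed) {
  if (missing(seed)) stopf("a seed is required (LISA permutation inference is stochastic)")
  structure(list(panel = panel, criteria = criteria, geometry = geometry,
                 bounds_scope = bounds_scope, aggregate_mode = aggregate_mode,
                 k = k, n_permutations = n_permutations, alpha = alpha,
                 jenks_k = jenks_k, missing_policy = missing_policy,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the same fields as [pipeline_config()]; `panel`,
#' `criteria` and `geometry` are file paths resolved relative to the YAML
#' file's directory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  pipeline_config(panel = resolve(y$panel), criteria = resolve(y$criteria),
                  geometry = resolve(y$geometry),
                  bounds_scope = y$bounds_scope %||% "pooled",
                  aggregate_mode = y$aggregate_mode %||% "all_determinants",
                  k = y$k %||% 4,
                  n_permutations = y$n_permutations %||% 999,
                  alpha = y$alpha %||% 0.05,
                  jenks_k = y$jenks_k %||% 4,
                  missing_policy = y$missing_policy %||% "error",
                  seed = y$seed)
}

load_stage <- function(x, loader, what) {
  if (is.character(x)) loader(x) else x
}

csv_with_hash <- function(df, path, hash, digits = NA) {
  if (!is.na(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates validate -> composite indices -> correlations -> change
#' tests -> Ward clustering -> LISA / bivariate classification -> share
#' table, writing every result table plus a machine-readable run manifest to
#' `out_dir`. Reruns under an identical configuration and seed are
#' byte-identical. Outputs (CSV unless noted): `indices.csv` (full
#' precision), `descriptive_stats.csv`, `correlation_<period>.csv` per
#' period, `category_vs_health.csv`, `change_tests.csv`,
#' `cluster_assignment.csv`, `cluster_profiles.csv`, `share_table.csv`,
#' `lisa.geojson` (when geometry is available), `manifest.json`. Correlation
#' and descriptive tables are rounded to 2 decimals and shares to 1 decimal
#' at write time only; computation is full precision throughout.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list of class `pipeline_result` with the in-memory
#'   stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), c("panel", "criteria", "geometry"))])

  panel <- load_stage(config$panel, read_panel, "panel")
  criteria <- load_stage(config$criteria, read_criteria, "criteria")
  geoms <- if (is.null(config$geometry)) NULL else
    load_stage(config$geometry, read_geometry, "geometry")
  panel <- validate_panel(panel, criteria, config$missing_policy)
  if (!is.null(geoms)) check_geometry_ids(geoms, panel)

  fit <- suppressWarnings(wsa(panel, criteria, config$bounds_scope,
                              config$aggregate_mode))
  periods <- panel$period_ids
  outputs <- character(0)
  put <- function(name) {
    outputs <<- c(outputs, name)
    file.path(out_dir, name)
  }

  csv_with_hash(as.data.frame(fit), put("indices.csv"), hash)
  csv_with_hash(as.data.frame(summary(fit)), put("descriptive_stats.csv"),
                hash, digits = 2)

  cors <- lapply(periods, function(p) correlation_matrix(fit, p, include_b1 = TRUE))
  names(cors) <- periods
  for (p in periods) {
    m <- as.data.frame(unclass(cors[[p]]))
    m <- cbind(index = rownames(m), m)
    csv_with_hash(m, put(sprintf("correlation_%s.csv", p)), hash, digits = 2)
  }
  has_b1 <- "B.1" %in% dimnames(fit$index)[[2]]
  if (has_b1) {
    acats <- grep("^A\\.", dimnames(fit$index)[[2]], value = TRUE)
    tab3 <- data.frame(category = acats)
    for (p in periods) tab3[[p]] <- unclass(cors[[p]])[acats, "B.1"]
    csv_with_hash(tab3, put("category_vs_health.csv"), hash, digits = 2)
  }

  pair <- period_pair(periods[1], periods[length(periods)], panel)
  tests <- change_test_suite(panel, pair, config$alpha)
  csv_with_hash(as.data.frame(tests), put("change_tests.csv"), hash)

  feats <- fit$index[, grep("^A\\.", dimnames(fit$index)[[2]], value = TRUE),
                     pair$later, drop = TRUE]
  tree <- ward_linkage(feats)
  assign <- cut_to_k(tree, config$k,
                     order_by = fit$index[, "aggregate", pair$later])
  prof <- cluster_profile(assign, fit, pair$later)
  csv_with_hash(data.frame(region = names(assign), period = pair$later,
                           cluster = as.integer(assign)),
                put("cluster_assignment.csv"), hash)
  prof_df <- data.frame(cluster = rep(rownames(prof), ncol(prof)),
                        category = rep(colnames(prof), each = nrow(prof)),
                        mean_z = as.vector(unclass(prof)[, ]))
  csv_with_hash(prof_df, put("cluster_profiles.csv"), hash)

  lisa_res <- NULL
  shares <- NULL
  if (has_b1) {
    classes <- lapply(periods, function(p) {
      bivariate_classify(fit$index[, "aggregate", p], fit$index[, "B.1", p],
                         config$jenks_k, config$jenks_k)
    })
    names(classes) <- periods
    shares <- share_table(classes, length(panel$region_ids))
    sh <- as.data.frame(unclass(shares))
    sh <- cbind(period = rownames(sh), sh)
    csv_with_hash(sh, put("share_table.csv"), hash, digits = 1)
  }
  if (!is.null(geoms)) {
    w <- row_standardize(suppressWarnings(queen_contiguity(geoms)))
    lisa_res <- lisa(fit$index[, "aggregate", pair$later], w,
                     config$n_permutations, config$seed, config$alpha)
    props <- data.frame(region_id = lisa_res$region,
                        aggregate_index = lisa_res$value,
                        local_moran = lisa_res$Ii,
                        pseudo_p = lisa_res$p,
                        lisa_label = lisa_res$label,
                        stringsAsFactors = FALSE)
    if (has_b1) {
      bc <- bivariate_classify(fit$index[, "aggregate", pair$later],
                               fit$index[, "B.1", pair$later],
                               config$jenks_k, config$jenks_k)
      props$bivariate_class <- bc$label
    }
    write_geometry(geoms, put("lisa.geojson"), props)
  }

  manifest <- list(package = "healthineq",
                   version = as.character(utils::packageVersion("healthineq")),
                   config = config[setdiff(names(config),
                                           c("panel", "criteria", "geometry"))],
                   config_hash = hash,
                   seed = config$seed,
                   n_regions = length(panel$region_ids),
                   n_indicators = length(panel$indicator_ids),
                   periods = periods,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(fit = fit, correlations = cors, tests = tests,
                           tree = tree, assignment = assign, profile = prof,
                           lisa = lisa_res, shares = shares,
                           manifest = manifest, out_dir = out_dir),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$manifest$n_regions, "regions,",
      x$manifest$n_indicators, "indicators\n")
  cat("  outputs in", x$out_dir, ":\n   ",
      paste(x$manifest$outputs, collapse = "\n    "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits the long panel CSV, the criteria CSV and the lattice GeoJSON that
#' [run_pipeline()] reads back.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @return (invisibly) named list of the three file paths.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syn <- sample_panel(cfg)
  paths <- list(panel = file.path(dir, "panel.csv"),
                criteria = file.path(dir, "criteria.csv"),
                geometry = file.path(dir, "regions.geojson"))
  write_panel(syn$panel, paths$panel)
  write_criteria(syn$criteria, paths$criteria)
  write_geometry(syn$geometry, paths$geometry)
  invisible(paths)
}
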