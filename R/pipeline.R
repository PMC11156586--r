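pipeline_defaults <- list(
  ds_fraction = 0.5, min_donors = 3L, intensity_fraction = 0.5,
  method = "dme", kernel = "normalized_angle", alpha = 1, k = 5L,
  n_perm = 5000L, n_spins = 5000L, seed = 1L,
  run_triplets = TRUE, min_shared_regions = 10L,
  strong_threshold = 0.5, score_convention = "average")

#' Pipeline configuration
#'
#' Every tunable of the pipeline in one validated object.  Defaults are the
#' reference analysis choices: differential-stability retain fraction 0.5,
#' donor-coverage threshold 3, DME with the normalized-angle kernel and
#' alpha 1, 5 components, 5000 permutations and 5000 spins.  Unknown keys
#' are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop_invalid("config overrides must be named")
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown) > 0L)
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults, over)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Serialize / load a pipeline configuration (JSON)
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# small polynomial content hash for provenance stamping
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline on a cohort
#'
#' Preprocess (probe filters, SRS normalization, DS gene filter, coverage
#' region filter, donor averaging), decompose, and optionally quantify
#' triplet generalizability; writes every artifact with a provenance header
#' (stage + config hash) and returns a manifest.
#'
#' @param config a [pipeline_config()].
#' @param cohort a `synthetic_cohort`, a donor list, or a cohort directory
#'   written by [write_cohort()].
#' @param out_dir output directory (created).
#' @return List of class `pipeline_result`: `fit` (`cortex_components`),
#'   `matrix`, `triplets` (or NULL), `manifest` (paths), `config`,
#'   `config_hash`, `log` (per-stage in/out counts).
#' @export
run_pipeline <- function(config, cohort, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  donors <- if (inherits(cohort, "synthetic_cohort")) cohort$donors else cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- function(stage) paste0("cortexcomp stage=", stage,
                                  " config=", hash, " seed=", config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log <- list(n_donors = length(donors),
              n_genes_in = ncol(donors[[1]]$values %||%
                                  donors[[1]]$probes$values))
  m <- stage("preprocess", preprocess_cohort(
    donors, ds_fraction = config$ds_fraction, min_donors = config$min_donors,
    intensity_fraction = config$intensity_fraction))
  log$n_genes_out <- ncol(m); log$n_regions_out <- nrow(m)
  fit <- stage("decompose", fit_components(
    m, k = config$k, method = config$method, kernel = config$kernel,
    alpha = config$alpha))
  manifest <- list()
  write_matrix(m, fp <- file.path(out_dir, "matrix.tsv"), stamp("preprocess"))
  manifest$matrix <- fp
  write_matrix(fit$scores, fp <- file.path(out_dir, "scores.tsv"),
               stamp("decompose"))
  manifest$scores <- fp
  write_matrix(fit$weights, fp <- file.path(out_dir, "weights.tsv"),
               stamp("decompose"))
  manifest$weights <- fp
  ve_df <- data.frame(component = colnames(fit$scores), ve = fit$ve,
                      ve_raw = fit$ve_raw)
  fp <- file.path(out_dir, "ve.csv")
  writeLines(c(paste0("# ", stamp("decompose")),
               "component,ve,ve_raw",
               sprintf("%s,%.15g,%.15g", ve_df$component, ve_df$ve,
                       ve_df$ve_raw)), fp)
  manifest$ve <- fp
  trip <- NULL
  if (isTRUE(config$run_triplets) &&
      length(donors) >= 4L && length(donors) %% 2L == 0L) {
    trip <- stage("triplets", generalizability(
      donors, ds_fraction = config$ds_fraction,
      min_donors = config$min_donors,
      intensity_fraction = config$intensity_fraction,
      method = config$method, k = config$k, kernel = config$kernel,
      alpha = config$alpha, min_shared_regions = config$min_shared_regions))
    fp <- file.path(out_dir, "generalizability.csv")
    writeLines(c(paste0("# ", stamp("triplets")), "component,g",
                 sprintf("%s,%.15g", names(trip$g), trip$g)), fp)
    manifest$generalizability <- fp
  }
  fp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                            files = lapply(manifest, basename), log = log),
                       fp, auto_unbox = TRUE, pretty = TRUE)
  manifest$manifest <- fp
  structure(list(fit = fit, matrix = m, triplets = trip, manifest = manifest,
                 config = config, config_hash = hash, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> config ", x$config_hash, "\n", sep = "")
  print(x$fit)
  if (!is.null(x$triplets)) print(x$triplets)
  invisible(x)
}
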