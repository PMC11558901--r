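## Shared I/O: dataset readers/writers, run configuration, manifests.
## Data travel as CSV with empty cells or "NA" marking missing values;
## configurations as YAML; run manifests and summaries as JSON. All
## randomness flows from the seed recorded in the manifest.

#' Run configuration
#'
#' Declares the variable roles and scales of a subject-level dataset plus
#' method settings. Exactly one outcome and one exposure are required;
#' every referenced column must carry a scale (`"binary"` or
#' `"continuous"`).
#'
#' @param outcome,exposure Column names (single strings).
#' @param confounders,auxiliaries Character vectors of column names.
#' @param scales Named character vector mapping every declared column to
#'   `"binary"` or `"continuous"`.
#' @param prior_mean,prior_variance Bias-parameter prior hyperparameters.
#' @param settings Named list of free-form method settings (S, K, burn-in,
#'   MCMC sizes, ...).
#' @param seed Integer seed recorded in manifests.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outcome, exposure, confounders, auxiliaries,
                       scales, prior_mean = 0, prior_variance = 100,
                       settings = list(), seed = 1L) {
  stopifnot(length(outcome) == 1, length(exposure) == 1)
  vars <- c(outcome, exposure, confounders, auxiliaries)
  if (anyDuplicated(vars)) stop("variable roles overlap")
  if (!all(vars %in% names(scales))) {
    stop("missing scale declaration for: ",
         paste(setdiff(vars, names(scales)), collapse = ", "))
  }
  if (!all(scales %in% c("binary", "continuous"))) {
    stop("scales must be 'binary' or 'continuous'")
  }
  structure(list(outcome = outcome, exposure = exposure,
                 confounders = confounders, auxiliaries = auxiliaries,
                 scales = scales[vars], prior_mean = prior_mean,
                 prior_variance = prior_variance, settings = settings,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with fields matching the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(outcome = y$outcome, exposure = y$exposure,
             confounders = unlist(y$confounders),
             auxiliaries = unlist(y$auxiliaries),
             scales = unlist(y$scales),
             prior_mean = y$prior_mean %||% 0,
             prior_variance = y$prior_variance %||% 100,
             settings = y$settings %||% list(),
             seed = y$seed %||% 1L)
}

#' Read a subject-level dataset
#'
#' Reads a CSV with a header row; empty cells and the string `"NA"` both
#' mark missing values. Columns declared binary are validated to contain
#' only 0/1 (or missing); a missingness indicator column `m_<lowercase
#' name>` is derived for every declared variable.
#'
#' @param path CSV file path.
#' @param config A [run_config()].
#' @return A data.frame of class `observed_dataset`.
#' @export
read_dataset <- function(path, config) {
  d <- utils::read.csv(path, na.strings = c("", "NA"),
                       check.names = FALSE)
  if (!nrow(d)) stop("empty dataset: ", path)
  vars <- names(config$scales)
  absent <- setdiff(vars, names(d))
  if (length(absent)) stop("unknown column(s) declared in config: ",
                           paste(absent, collapse = ", "))
  for (v in vars) {
    col <- d[[v]]
    if (!is.numeric(col)) stop("column ", v, " is not numeric")
    if (config$scales[[v]] == "binary") {
      bad <- which(!is.na(col) & !(col %in% c(0, 1)))
      if (length(bad)) {
        stop("binary column ", v, " contains non-0/1 value at row ", bad[1])
      }
    }
    d[[paste0("m_", tolower(v))]] <- as.numeric(is.na(col))
  }
  class(d) <- c("observed_dataset", "data.frame")
  d
}

#' Standardise continuous columns to observed mean 0, SD 1
#'
#' Means and SDs are computed over the observed entries only; missing
#' entries stay missing and inherit the transformation once imputed. The
#' scaling parameters are stored in the `"scaling"` attribute so reported
#' effects can be back-transformed.
#'
#' @param data A data.frame.
#' @param columns Continuous columns to standardise.
#' @return The transformed data.frame with attribute `scaling` (data.frame
#'   `column, center, scale`).
#' @export
standardize_continuous <- function(data, columns = c("X", "Z2")) {
  recs <- lapply(columns, function(v) {
    col <- data[[v]]
    if (sum(!is.na(col)) < 2) stop("fewer than 2 observed values in ", v)
    m <- mean(col, na.rm = TRUE); s <- stats::sd(col, na.rm = TRUE)
    if (s == 0) stop("zero observed standard deviation in ", v)
    data[[v]] <<- (col - m) / s
    data.frame(column = v, center = m, scale = s)
  })
  attr(data, "scaling") <- do.call(rbind, recs)
  data
}

#' Write results with a reproducibility manifest
#'
#' Writes each element of `results` that is a data.frame as
#' `<name>.csv` (missing entries as empty fields) and a `manifest.json`
#' recording the seed, a hash of the configuration, the package version and
#' a timestamp. Re-running with identical inputs reproduces identical CSVs;
#' the manifest's config hash changes exactly when the configuration content
#' changes.
#'
#' @param results Named list; data.frame elements become CSVs, scalar/list
#'   elements are embedded in the manifest under `summary`.
#' @param config The run configuration (any serialisable object) to hash.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed to record.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, config, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  is_df <- vapply(results, is.data.frame, TRUE)
  for (nm in names(results)[is_df]) {
    utils::write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("mnarpba")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = paste0(names(results)[is_df], ".csv"),
    summary = results[!is_df]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}

#' @rdname write_results
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  canon <- jsonlite::toJSON(strip_attrs(config), auto_unbox = TRUE,
                            digits = NA, force = TRUE, null = "null")
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

strip_attrs <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_attrs)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write an observed dataset as CSV plus JSON sidecar
#'
#' One row per subject, missing entries as empty fields, indicator columns
#' retained; the sidecar records the seed, generator kind and a parameter
#' hash.
#'
#' @param obs An `observed_dataset` (or any data.frame).
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @param seed,dgm,params Provenance recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(obs, path, seed = NULL, dgm = NULL, params = NULL) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "")
  sidecar <- list(seed = seed, dgm = dgm,
                  params_hash = if (!is.null(params)) config_hash(params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
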