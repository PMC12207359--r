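# Dataset and results I/O, checkpoints and run manifests.

#' Read a reaction table
#'
#' Reads the standard reaction CSV (UTF-8, comma-delimited, `.` decimal)
#' with columns `reaction_id, olefin_smiles, ligand_smiles,
#' solvent_smiles, metal, additive, temperature_c, pressure_bar,
#' loading_molpct, ee, year`.  Rows failing validation (ee outside
#' \[0, 100\], year before 1900, unknown metal, non-boolean additive,
#' missing numerics) are collected and reported with their row numbers;
#' the read aborts when more than `max_invalid_frac` of rows are
#' invalid, otherwise invalid rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @param max_invalid_frac tolerated fraction of invalid rows
#'   (default 0.01).
#' @return data frame of validated reaction records; attribute
#'   `"invalid"` lists dropped row numbers.
#' @export
read_reactions <- function(path, max_invalid_frac = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(REACTION_COLUMNS, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[REACTION_COLUMNS]
  n <- nrow(df)
  num_cols <- c("temperature_c", "pressure_bar", "loading_molpct", "ee",
                "year")
  problems <- character(0)
  bad <- logical(n)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    new_na <- is.na(v) & !is.na(df[[col]])
    if (any(new_na)) {
      problems <- c(problems, sprintf("row %d: unparseable %s (%s)",
                                      which(new_na), col,
                                      df[[col]][new_na]))
      bad <- bad | new_na
    }
    df[[col]] <- v
  }
  add <- df$additive
  if (is.character(add)) add <- toupper(trimws(add)) %in% c("TRUE", "T", "1")
  df$additive <- as.logical(add)
  chk <- function(cond, msg) {
    rows <- which(cond & !bad)
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
      bad[rows] <<- TRUE
    }
  }
  chk(is.na(df$ee) | df$ee < 0 | df$ee > 100, "ee outside [0, 100]")
  chk(is.na(df$year) | df$year < 1900, "year before 1900 or missing")
  chk(!(df$metal %in% DKMETA_METALS),
      sprintf("unknown metal (supported: %s)",
              paste(DKMETA_METALS, collapse = ", ")))
  chk(is.na(df$additive), "additive not interpretable as TRUE/FALSE")
  if (sum(bad) > max_invalid_frac * n) {
    stop(sprintf("%d of %d rows invalid:\n%s", sum(bad), n,
                 paste(utils::head(problems, 10), collapse = "\n")),
         call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("dropping %d invalid row(s):\n%s", sum(bad),
                    paste(problems, collapse = "\n")), call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "invalid") <- which(bad)
  out
}

#' Write a reaction table
#'
#' @param records reaction data frame ([read_reactions()] schema).
#' @param path output CSV path.
#' @export
write_reactions <- function(records, path) {
  stopifnot(all(REACTION_COLUMNS %in% names(records)))
  utils::write.csv(records[REACTION_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a per-repeat results table
#'
#' Deterministic column order; the raw per-repeat AUPRC values are kept
#' at full precision.
#'
#' @param results data frame from [run_experiment()].
#' @param path output CSV path.
#' @export
write_results <- function(results, path) {
  cols <- c("method", "split_mode", "combination", "support_size",
            "repeat_id", "auprc")
  stopifnot(all(cols %in% names(results)))
  utils::write.csv(results[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an aggregated results table
#'
#' Floats are rendered at 4 decimals in the aggregated view, matching
#' the reporting precision of the results tables.
#'
#' @param agg data frame from [aggregate_results()].
#' @param path output CSV path.
#' @export
write_aggregate <- function(agg, path) {
  out <- agg
  for (col in c("mean_auprc", "dispersion")) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table
#'
#' @param path CSV written by [write_results()].
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

CHECKPOINT_SCHEMA <- 1L

#' Save a trained model checkpoint
#'
#' Serializes a `dkmeta_model` (method, kernel, hyperparameters,
#' extractor architecture and weights at full precision, prior variance
#' for ADKF-prior, and the training configuration) as versioned JSON.
#'
#' @param fit a `dkmeta_model`.
#' @param path output `.json` path.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "dkmeta_model"))
  obj <- list(schema = CHECKPOINT_SCHEMA, package_version =
                as.character(utils::packageVersion("dkmeta")),
              method = fit$method, kernel = fit$kernel,
              theta_gp = as.list(fit$theta_gp),
              log_sigma2 = fit$log_sigma2,
              nn = if (!is.null(fit$nn)) list(dims = fit$nn$dims,
                                              flat = nn_flatten(fit$nn)),
              config = fit$config[!vapply(fit$config, is.function,
                                          TRUE)])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path JSON written by [save_checkpoint()].
#' @return a `dkmeta_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != CHECKPOINT_SCHEMA) {
    stop("unsupported checkpoint schema", call. = FALSE)
  }
  nn <- NULL
  if (!is.null(obj$nn) && length(obj$nn$dims)) {
    dims <- as.integer(obj$nn$dims)
    nn <- mlp_init(dims[1], dims[-c(1, length(dims))],
                   dims[length(dims)], seed = 1)
    nn <- nn_unflatten(nn, as.numeric(obj$nn$flat))
  }
  theta_gp <- NULL
  if (!is.null(obj$theta_gp)) {
    theta_gp <- do.call(gp_hyper, obj$theta_gp)
  }
  structure(list(method = obj$method, nn = nn, theta_gp = theta_gp,
                 log_sigma2 = obj$log_sigma2, kernel = obj$kernel,
                 config = obj$config, history = NULL),
            class = "dkmeta_model")
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds, package version and input-file
#' hashes of a run, sufficient to replay it exactly.
#'
#' @param path output JSON path.
#' @param config configuration list.
#' @param seed integer seed of the run.
#' @param inputs character vector of input file paths (hashed).
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  obj <- list(package = "dkmeta",
              version = as.character(utils::packageVersion("dkmeta")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = unclass(config),
              input_md5 = hashes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Structured JSON-lines logging used by the command-line interface.
log_event <- function(level = "INFO", event, ...) {
  rec <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
              level = level, event = event, ...)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n")
  invisible(NULL)
}
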