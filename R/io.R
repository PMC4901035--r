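# Table input/output with schema validation, plus the run manifest.
# All tables are plain UTF-8 CSV/TSV with a one-line header; units are
# documented in the schema objects, not embedded in headers.

#' Schemas for the pipeline's exchange tables
#'
#' Named character vectors mapping column name to type (`"character"`
#' or `"numeric"`), used by [read_table_checked()] /
#' [write_table_checked()].
#'
#' @format list of named character vectors.
#' @export
table_schemas <- function() {
  list(
    vessels = c(treatment = "character", vessel = "character",
                acetate = "numeric", propionate = "numeric",
                butyrate = "numeric", isobutyrate = "numeric",
                valerate = "numeric", isovalerate = "numeric",
                methane_mmol_d = "numeric", nan_mg_d = "numeric",
                ammonia_mg_d = "numeric", om_disappearance = "numeric",
                digesta_nan_enrichment = "numeric",
                bacterial_enrichment = "numeric",
                ammonia_enrichment = "numeric"),
    pressures = c(bottle_id = "character", is_blank = "logical",
                  time_h = "numeric", pressure_kpa = "numeric"),
    release = c(tube_id = "character", time_h = "numeric",
                released_pct = "numeric")
  )
}

#' Read a delimited table against a schema
#'
#' The file must contain every schema column (extra columns are kept);
#' typed columns are converted and any value that fails to parse is
#' reported with its column name. Decimal parsing is locale-independent
#' (C locale, `.` as decimal separator).
#'
#' @param path file path.
#' @param schema named character vector, column -> type (`"character"`,
#'   `"numeric"`, `"integer"`, `"logical"`).
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @return validated data.frame.
#' @export
read_table_checked <- function(path, schema, sep = ",") {
  if (!file.exists(path)) {
    stop_rusitecr(sprintf("input file not found: %s", path),
                  "rusitecr_missing_file")
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, colClasses = "character")
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop_rusitecr(paste("missing column(s):", paste(missing, collapse = ", ")),
                  "rusitecr_schema_error")
  }
  bad <- character(0)
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = df[[col]],
      logical = as.logical(df[[col]]),
      integer = suppressWarnings(as.integer(df[[col]])),
      numeric = suppressWarnings(as.numeric(df[[col]])),
      stop_rusitecr(sprintf("unknown schema type `%s`", schema[[col]]),
                    "rusitecr_schema_error"))
    if (schema[[col]] != "character" && anyNA(df[[col]])) bad <- c(bad, col)
  }
  if (length(bad)) {
    stop_rusitecr(paste("unparseable values in column(s):",
                        paste(bad, collapse = ", ")),
                  "rusitecr_schema_error")
  }
  df
}

#' Write a delimited table, checking it against a schema
#'
#' @param df data.frame to write.
#' @param path destination.
#' @param schema as in [read_table_checked()]; the written table must
#'   contain every schema column.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(df, path, schema = NULL, sep = ",") {
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop_rusitecr(paste("missing column(s):",
                          paste(missing, collapse = ", ")),
                    "rusitecr_schema_error")
    }
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, configuration hash, seed, input/output paths,
#' package version and timestamp alongside a run's outputs, so a run
#' is reproducible from its manifest (identical command + config + seed
#' + inputs give identical results; only the timestamp differs).
#'
#' @param outdir output directory (manifest.json is written inside).
#' @param command subcommand name.
#' @param config the configuration object used (hashed and embedded).
#' @param seed RNG seed used.
#' @param inputs,outputs character vectors of paths.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(outdir, command, config = NULL, seed = NULL,
                           inputs = character(0), outputs = character(0)) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("rusitecr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
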