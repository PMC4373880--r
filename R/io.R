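#' Read a 2x2 dataset from a delimited text file
#'
#' Expects a header with columns `a`, `b`, `y` (case-insensitive). Factor
#' levels may be `C`/`T`, `0`/`1` or `-1`/`1`; they are normalized to
#' `C`/`T`. The outcome must be numeric and every cell must contain at
#' least two rows.
#'
#' @param path Path to a delimited text file (delimiter is guessed unless
#'   given).
#' @param delim Optional field delimiter.
#' @param quiet Suppress the message reporting the inferred cell counts?
#' @return A tibble with columns `a`, `b` (factors `C`/`T`) and `y`.
#' @export
read_dataset <- function(path, delim = NULL, quiet = FALSE) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("a", "b", "y")) {
    if (!col %in% names(df)) abort(paste0("Missing column `", col, "` in ", path, "."))
  }
  if (!is.numeric(df$y)) abort("Column `y` must be numeric.")
  out <- tibble(a = .normalize_levels(df$a, "a"),
                b = .normalize_levels(df$b, "b"),
                y = as.double(df$y))
  cs <- .cell_stats(out)
  if (any(cs$n < 2)) {
    small <- c("(C,C)", "(C,T)", "(T,C)", "(T,T)")[cs$n < 2]
    abort(paste0("Cell ", paste(small, collapse = ", "),
                 " has fewer than 2 rows; no within-cell variance."))
  }
  if (!quiet) {
    message(sprintf("Read %d subjects; cell counts (n00, n01, n10, n11) = (%s).",
                    nrow(out), paste(cs$n, collapse = ", ")))
  }
  out
}

.normalize_levels <- function(x, name) {
  v <- trimws(as.character(x))
  u <- sort(unique(v))
  map <- NULL
  if (all(u %in% c("C", "T"))) map <- c(C = "C", T = "T")
  if (all(u %in% c("0", "1"))) map <- c(`0` = "C", `1` = "T")
  if (all(u %in% c("-1", "1"))) map <- c(`-1` = "C", `1` = "T")
  if (is.null(map)) {
    abort(paste0("Column `", name,
                 "` must use levels C/T, 0/1 or -1/1 (found: ",
                 paste(u, collapse = ", "), ")."))
  }
  factor(unname(map[v]), levels = c("C", "T"))
}

#' Write a 2x2 sample as CSV
#'
#' Writes columns `a`, `b` (levels `C`/`T`) and `y`; the file round-trips
#' through [read_dataset()].
#'
#' @param data A sample tibble (`a`, `b`, `y`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(data, path) {
  .cell_stats(data)
  out <- tibble(a = as.character(data$a), b = as.character(data$b),
                y = data$y)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write result tables as TSV and/or JSON
#'
#' TSV output prints floating-point columns with three decimals (the
#' precision at which rejection rates are conventionally reported); JSON
#' output keeps full precision. Column order is preserved, so identical
#' inputs yield byte-identical files.
#'
#' @param tables A data frame, or a named list of data frames (names become
#'   file stems).
#' @param dir Output directory (created if needed).
#' @param formats Any of `"tsv"`, `"json"`.
#' @param digits Decimals for floating-point columns in TSV.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, dir = ".", formats = c("tsv", "json"),
                         digits = 3) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.data.frame(tables)) tables <- list(report = tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a data frame or a *named* list of data frames.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    tbl <- as.data.frame(tables[[nm]])
    if ("tsv" %in% formats) {
      fmt <- tbl
      for (col in names(fmt)) {
        if (is.double(fmt[[col]])) {
          fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA_character_,
                               formatC(fmt[[col]], format = "f", digits = digits))
        }
      }
      p <- file.path(dir, paste0(nm, ".tsv"))
      readr::write_tsv(fmt, p, na = "")
      paths <- c(paths, p)
    }
    if ("json" %in% formats) {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(tbl, p, dataframe = "rows", digits = NA,
                           na = "null", pretty = TRUE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write the standard study tables and a reproducibility manifest
#'
#' Writes the full rejection-rate report, its mean-rate summary
#' ([summarize_means()]), the balanced-vs-unbalanced comparison
#' ([compare_to_balanced()]) and a JSON manifest holding the exact grid,
#' seed and parameters, so that rerunning with the manifest's seed
#' reproduces the files byte for byte.
#'
#' @param report A `power_report` from [run_study()].
#' @param dir Output directory.
#' @param formats Formats for the tables (the manifest is always JSON).
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(report, dir = ".", formats = c("tsv", "json")) {
  stopifnot(inherits(report, "power_report"))
  paths <- write_report(
    list(rejection_rates = report,
         mean_rates = summarize_means(report),
         balanced_comparison = compare_to_balanced(report)),
    dir = dir, formats = formats
  )
  manifest <- list(
    seed = attr(report, "seed"),
    replicates = attr(report, "replicates"),
    alpha = attr(report, "alpha"),
    coding = attr(report, "coding"),
    betas = as.list(attr(report, "betas")),
    beta3 = attr(report, "beta3"),
    construction = attr(report, "construction"),
    n_designs = length(unique(report$design_id)),
    n_rows = nrow(report)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

.config_defaults <- function() {
  list(
    replicates = 1000L, alpha = 0.05, beta3 = c(0, 4, 8),
    construction = c("zero_control", "equal_contribution"),
    beta0 = 10, beta1 = 4, beta2 = 4, sigma = 10,
    scale = 10L, seed = 1L, coding = "contrast",
    out_dir = "results", formats = c("tsv", "json"), verbose = TRUE
  )
}

#' Study configuration
#'
#' A validated bundle of every knob of the pipeline (grid, generator
#' parameters, seed, output choices). Serializes losslessly to a plain-text
#' YAML key/value file via [write_study_config()] / [read_study_config()];
#' unknown keys in a file are rejected by name.
#'
#' @param ... Named overrides of the defaults (see [run_study()] for the
#'   simulation parameters; `scale` feeds [study_designs()], `out_dir` and
#'   `formats` feed [write_study_tables()]).
#' @return An object of class `study_config`.
#' @examples
#' study_config(replicates = 200, beta3 = 4)
#' @export
study_config <- function(...) {
  defaults <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", "), "."))
  }
  cfg <- modifyList(defaults, over)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (cfg$replicates < 1) abort("`replicates` must be positive.")
  if (cfg$sigma <= 0) abort("`sigma` must be positive.")
  cfg$construction <- match.arg(cfg$construction,
                                c("zero_control", "equal_contribution"),
                                several.ok = TRUE)
  cfg$coding <- match.arg(cfg$coding, c("contrast", "treatment"))
  cfg$formats <- match.arg(cfg$formats, c("tsv", "json"), several.ok = TRUE)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path File path for the YAML config.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

#' Run the pipeline described by a configuration
#'
#' Convenience driver: builds the design grid at the configured scale, runs
#' the Monte-Carlo study and writes the standard tables and manifest to the
#' configured directory.
#'
#' @param config A [study_config()].
#' @return The `power_report`, invisibly.
#' @export
run_configured_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  report <- run_study(
    designs = study_designs(scale = config$scale),
    beta3 = config$beta3, construction = config$construction,
    beta0 = config$beta0, beta1 = config$beta1, beta2 = config$beta2,
    sigma = config$sigma, replicates = config$replicates,
    alpha = config$alpha, seed = config$seed, coding = config$coding,
    verbose = config$verbose
  )
  write_study_tables(report, dir = config$out_dir, formats = config$formats)
  invisible(report)
}
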