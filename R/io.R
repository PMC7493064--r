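#' Read a univariate series from disk
#'
#' Accepts either a plain text file with one numeric value per line, or a CSV
#' with a header from which one column is selected (by name or position; by
#' default the first numeric column). Parsing is strict: blank lines,
#' non-numeric entries and missing values are errors, never silently imputed,
#' and a usable series must contain at least two values.
#'
#' @param path File to read.
#' @param column Column name or position for CSV input.
#' @param header Logical; forces header interpretation for CSV input
#'   (default: `TRUE` for files that look like CSV).
#' @return Numeric vector.
#' @export
read_series <- function(path, column = NULL, header = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "wbs2sdll_input_error")
  }
  lines <- readr::read_lines(path)
  if (length(lines) && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]        # trailing newline is fine
  }
  if (!length(lines)) {
    abort("empty input file.", class = "wbs2sdll_input_error")
  }
  looks_csv <- grepl(",", lines[1], fixed = TRUE) ||
    grepl("\\.csv$", path, ignore.case = TRUE)
  if (looks_csv) {
    if (is.null(header)) header <- TRUE
    df <- readr::read_csv(I(lines), col_names = header, show_col_types = FALSE,
                          progress = FALSE)
    if (!is.null(column) && is.character(column) && !column %in% names(df)) {
      abort(sprintf("column '%s' not found in %s.", column, path),
            class = "wbs2sdll_input_error")
    }
    out <- as_series(as.data.frame(df), column)
  } else {
    if (any(!nzchar(trimws(lines)))) {
      abort("blank line in input; refusing to guess.",
            class = "wbs2sdll_input_error")
    }
    out <- suppressWarnings(as.numeric(trimws(lines)))
  }
  if (anyNA(out) || !all(is.finite(out))) {
    abort("non-numeric or missing values in input series.",
          class = "wbs2sdll_input_error")
  }
  check_series(out)
  out
}

#' Write and re-read a detection result
#'
#' `write_result()` serialises a [wbs_sdll()] fit. JSON output is lossless for
#' the result proper: estimated count, locations and magnitudes, the fitted
#' signal, noise scale and threshold, the full configuration echo and a run
#' manifest (package version, seed, input digest, elapsed time), and
#' `read_result()` restores it as a list. CSV output writes the change-point
#' table (`changepoint`, `magnitude`) to `path` and the length-`T` fitted
#' signal to a companion file `<path stem>_fitted.csv`.
#'
#' @param fit A `"wbs_sdll"` object.
#' @param path Output file.
#' @param format `"json"` or `"csv"`.
#' @return `write_result()` invisibly returns `path`; `read_result()` returns
#'   the deserialised list.
#' @export
write_result <- function(fit, path, format = c("json", "csv")) {
  stopifnot(inherits(fit, "wbs_sdll"))
  format <- match.arg(format)
  sorted <- fit$path
  cp_tab <- tibble::tibble(
    changepoint = fit$changepoints,
    magnitude = sorted$magnitude[match(fit$changepoints, sorted$location)]
  )
  if (format == "csv") {
    readr::write_csv(cp_tab, path, progress = FALSE)
    fitted_path <- paste0(tools::file_path_sans_ext(path), "_fitted.csv")
    readr::write_csv(tibble::tibble(fitted = fit$fitted), fitted_path,
                     progress = FALSE)
    return(invisible(path))
  }
  payload <- list(
    n_obs = fit$n_obs,
    q_hat = fit$q_hat,
    changepoints = fit$changepoints,
    magnitudes = cp_tab$magnitude,
    fitted = fit$fitted,
    sigma_hat = fit$sigma_hat,
    zeta = fit$zeta,
    sorted_magnitudes = fit$diagnostics$sorted_magnitudes,
    config = fit$config,
    manifest = run_manifest(fit)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

run_manifest <- function(fit) {
  list(package = "wbs2sdll",
       version = as.character(packageVersion("wbs2sdll")),
       seed = fit$config$seed,
       input_digest = rlang::hash(fit$x),
       n_obs = fit$n_obs,
       elapsed_seconds = fit$diagnostics$elapsed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
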