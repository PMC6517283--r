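#' Read and write panel data CSV files
#'
#' The panel CSV dialect has required columns `id` and `time` (decimal years,
#' strictly increasing within subject), one observed-state column per process
#' (integers `1..K`, blank = missing), and any number of covariate columns;
#' a header row is required. `write_panel()` writes missing states as blank
#' cells so files round-trip exactly.
#'
#' @param path CSV file path.
#' @param spec Optional [cmsm_spec()]; if supplied, state columns are
#'   validated against its processes and state count.
#' @return `read_panel()` returns a validated panel tibble; `write_panel()`
#'   returns `path` invisibly.
#' @examples
#' \dontrun{
#' panel <- read_panel("slicc_panel.csv", cmsm_spec(processes = c("eGFR", "PU")))
#' }
#' @export
read_panel <- function(path, spec = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_panel(data, spec)
}

#' @param panel A panel data frame.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  if (!is.data.frame(panel) || nrow(panel) == 0) abort("`panel` must be a nonempty data frame.")
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

#' Validate panel data
#'
#' Checks the panel layout used throughout the package: `id` and `time`
#' columns present, times strictly increasing within subject, no duplicated
#' `(id, time)` rows, and (when a spec is given) state columns present with
#' values in `1..K` or missing. Errors name the offending rows.
#'
#' @param data A data frame.
#' @param spec Optional [cmsm_spec()].
#' @return The validated tibble (with `id` as character), invisibly usable in
#'   a pipe.
#' @export
validate_panel <- function(data, spec = NULL) {
  if (!is.data.frame(data)) abort("panel data must be a data frame.")
  miss <- setdiff(c("id", "time"), names(data))
  if (length(miss))
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  data <- as_tibble(data)
  data$id <- as.character(data$id)
  if (!is.numeric(data$time) || anyNA(data$time) || any(data$time < 0))
    abort("`time` must be nonnegative years, with no missing values.")

  dup <- duplicated(data[, c("id", "time")])
  if (any(dup))
    abort(paste0("duplicated (id, time) rows: ",
                 paste(which(dup), collapse = ", ")))
  lag_same <- c(FALSE, data$id[-1] == data$id[-nrow(data)])
  bad <- which(lag_same & c(TRUE, diff(data$time) <= 0))
  if (length(bad))
    abort(paste0("times not strictly increasing within subject at row(s): ",
                 paste(bad, collapse = ", "),
                 " (id ", paste(unique(data$id[bad]), collapse = ", "), ")"))

  if (!is.null(spec)) {
    stopifnot(inherits(spec, "cmsm_spec"))
    missp <- setdiff(spec$processes, names(data))
    if (length(missp))
      abort(paste0("missing state column(s): ", paste(missp, collapse = ", ")))
    for (p in spec$processes) {
      st <- data[[p]]
      ok <- is.na(st) | (st == as.integer(st) & st >= 1 & st <= spec$n_states)
      if (!all(ok)) {
        rows <- which(!ok)
        abort(sprintf("state column `%s` outside 1..%d at row(s) %s (id %s).",
                      p, spec$n_states, paste(rows, collapse = ", "),
                      paste(unique(data$id[rows]), collapse = ", ")))
      }
      data[[p]] <- as.integer(st)
    }
  }
  data
}
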