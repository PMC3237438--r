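#' Read a field series from delimited text
#'
#' Expects a comma-separated file ("." decimal, UTF-8) with a header holding
#' at least `t` (wk) and `Y` (Mg/ha); any `<element>_u` columns are uptakes
#' in kg/ha and any `<element>_c` columns concentrations in g/kg. If both an
#' uptake and a concentration column are present for an element, the
#' concentration is validated against uptake/Y and a warning names rows off
#' by more than 0.5 g/kg.
#'
#' @param path path to the CSV file.
#' @return A field-series data frame with attribute `provenance = "user"`.
#'   A header-only file yields a valid zero-row series.
#' @export
read_field_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("t", "Y"))
    if (!col %in% names(df))
      stop("field series is missing required column '", col, "'",
           call. = FALSE)
  for (col in names(df)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1L],
             ": '", v[bad[1L]], "'", call. = FALSE)
      df[[col]] <- coerced
    }
  }
  elements <- sub("_u$", "", grep("_u$", names(df), value = TRUE))
  if (nrow(df)) {
    for (el in elements) {
      ccol <- paste0(el, "_c")
      if (!ccol %in% names(df)) next
      ok <- df$Y > 0
      dev <- abs(df[[ccol]][ok] - df[[paste0(el, "_u")]][ok] / df$Y[ok])
      off <- which(dev > 0.5)
      if (length(off))
        warning("column '", ccol, "' inconsistent with ",
                el, "_u / Y beyond 0.5 g/kg at row(s) ",
                paste(which(ok)[off], collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "provenance") <- "user"
  df
}

#' Write a field series as CSV
#'
#' @param series a field-series data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_lines <- function(fit) {
  num <- function(x) sprintf("%.17g", x)
  if (inherits(fit, "yield_fit")) {
    c("[yield_fit]",
      paste("A =", num(fit$A)),
      paste("b =", num(fit$b)),
      paste("r2 =", num(fit$r2)),
      paste("n =", fit$n_points),
      paste("with_intercept =", tolower(fit$with_intercept)),
      "# display (rounded)",
      sprintf("# Y_hat = %.2f + %.2f * Q (Mg/ha), r^2 = %.3f",
              fit$b, fit$A, fit$r2))
  } else if (inherits(fit, "phase_fit")) {
    c(sprintf("[phase_fit %s]", fit$element),
      paste("element =", fit$element),
      paste("N_um =", num(fit$N_um)),
      paste("K_y =", num(fit$K_y)),
      paste("slope =", num(fit$slope)),
      paste("intercept =", num(fit$intercept)),
      paste("r2 =", num(fit$r2_linear)),
      paste("n =", fit$n_points),
      "# display (rounded)",
      sprintf("# N_um = %.0f kg/ha, K_y = %.1f Mg/ha, r^2 = %.3f",
              fit$N_um, fit$K_y, fit$r2_linear))
  } else if (is.list(fit)) {
    unlist(lapply(fit, report_lines), use.names = FALSE)
  } else stop("don't know how to report an object of class ",
              paste(class(fit), collapse = "/"), call. = FALSE)
}

#' Write a structured fit report
#'
#' Serializes yield and phase fits (or lists of them) as plain text with a
#' deterministic field order: full-precision `key = value` lines per block,
#' followed by a commented display block rounded to the reporting precision
#' used in the field (whole kg/ha for uptake potentials, two decimals for
#' the yield line).
#'
#' @param fit a `"yield_fit"`, `"phase_fit"`, or list of such.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(fit, path) {
  lines <- report_lines(fit)
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write report to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a fit report
#'
#' Parses the `key = value` blocks written by [write_report()] into a named
#' list of named lists; numeric values round-trip exactly.
#'
#' @param path report path.
#' @return A named list, one element per `[block]`.
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  block <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      block <- gsub("^\\[|\\]$", "", trimws(ln))
      out[[block]] <- list()
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[block]][[key]] <- if (is.na(num)) val else num
    }
  }
  out
}
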