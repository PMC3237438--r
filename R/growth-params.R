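#' Growth-model parameter set
#'
#' Bundles the five parameters of the expanded growth model: the mean `mu`
#' and spread `sigma_sqrt2` (= sqrt(2)*sigma) of the Gaussian seasonal
#' solar-energy distribution, the aging coefficient `c`, the partition
#' coefficient `k` between light-gathering and structural biomass, and the
#' dimensionless initiation time `x_i`. All times are decimal weeks since
#' January 1 (northern hemisphere).
#'
#' The defaults are the `"florence-1982"` set calibrated for corn grown at
#' Florence, SC: mu = 26.0 wk, sigma_sqrt2 = 8 wk, c = 0.2 / wk, k = 5,
#' x_i = 0.
#'
#' @param mu time of the mean of the solar-energy distribution (wk).
#' @param sigma_sqrt2 time spread sqrt(2)*sigma of the distribution (wk); > 0.
#' @param c aging coefficient (1/wk); >= 0.
#' @param k dimensionless partition coefficient; >= 0.
#' @param x_i dimensionless initiation time.
#' @param label name of the parameter set, for reporting.
#' @return An object of class `"growth_params"`.
#' @seealso [initiation_time()], [quantifier_table()], [read_growth_params()]
#' @examples
#' p <- growth_params()
#' initiation_time(p)  # 19.6 wk
#' @export
growth_params <- function(mu = 26.0, sigma_sqrt2 = 8.0, c = 0.2, k = 5.0,
                          x_i = 0.0, label = NULL) {
  for (nm in c("mu", "sigma_sqrt2", "c", "k", "x_i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (sigma_sqrt2 <= 0) stop("'sigma_sqrt2' must be > 0", call. = FALSE)
  if (c < 0) stop("'c' must be >= 0", call. = FALSE)
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (is.null(label)) {
    default <- missing(mu) && missing(sigma_sqrt2) && missing(c) &&
      missing(k) && missing(x_i)
    label <- if (default) "florence-1982" else "custom"
  }
  structure(list(mu = mu, sigma_sqrt2 = sigma_sqrt2, c = c, k = k,
                 x_i = x_i, label = label),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth-model parameter set:", x$label, "\n")
  cat(sprintf("  mu          = %g wk   (mean of solar-energy distribution)\n", x$mu))
  cat(sprintf("  sigma_sqrt2 = %g wk   (time spread sqrt(2)*sigma)\n", x$sigma_sqrt2))
  cat(sprintf("  c           = %g /wk  (aging coefficient)\n", x$c))
  cat(sprintf("  k           = %g      (partition coefficient)\n", x$k))
  cat(sprintf("  x_i         = %g      (dimensionless initiation time)\n", x$x_i))
  cat(sprintf("  t_i         = %g wk   (derived initiation time)\n",
              initiation_time(x)))
  invisible(x)
}

as_growth_params <- function(p) {
  if (inherits(p, "growth_params")) return(p)
  if (is.character(p) && length(p) == 1L) {
    if (identical(p, "florence-1982")) return(growth_params())
    if (file.exists(p)) return(read_growth_params(p))
    stop("unknown parameter set '", p,
         "' (use \"florence-1982\" or a config file path)", call. = FALSE)
  }
  if (is.list(p))
    return(growth_params(p$mu, p$sigma_sqrt2, p$c, p$k,
                         if (is.null(p$x_i)) 0 else p$x_i,
                         label = if (is.null(p$label)) "custom" else p$label))
  stop("cannot interpret 'params' as a growth parameter set", call. = FALSE)
}

#' Calendar time of growth initiation
#'
#' Inverts the dimensionless-time map at `x = x_i`:
#' `t_i = mu + sigma_sqrt2 * (x_i - c*sigma_sqrt2/2)`. With the default
#' Florence set (x_i = 0) this gives 19.6 wk, i.e. the aging term shifts the
#' effective time origin from mu = 26.0 wk back by c*sigma_sqrt2^2/2 = 6.4 wk.
#'
#' @param p a [growth_params()] object (or a name / config path).
#' @return Initiation time t_i in weeks since Jan. 1.
#' @export
initiation_time <- function(p) {
  p <- as_growth_params(p)
  p$mu + p$sigma_sqrt2 * (p$x_i - p$c * p$sigma_sqrt2 / 2)
}

#' Read / write a growth parameter set as a flat config file
#'
#' The format is one `key = value` pair per line (keys mu, sigma_sqrt2, c, k,
#' x_i; optional label), `#` comments allowed. The Florence set ships in
#' `system.file("extdata", "florence-1982.params", package = "egm")`.
#'
#' @param path file path.
#' @return `read_growth_params()` returns a `"growth_params"` object;
#'   `write_growth_params()` returns `path` invisibly.
#' @export
read_growth_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed line in ", path, ": ", lines[bad][1L], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- c("mu", "sigma_sqrt2", "c", "k", "x_i", "label")
  if (any(!keys %in% known))
    stop("unknown key(s) in ", path, ": ",
         paste(setdiff(keys, known), collapse = ", "), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated key(s) in ", path, call. = FALSE)
  get_num <- function(key) {
    if (!key %in% keys) stop("missing key '", key, "' in ", path, call. = FALSE)
    v <- suppressWarnings(as.numeric(vals[keys == key]))
    if (is.na(v)) stop("non-numeric value for '", key, "' in ", path, call. = FALSE)
    v
  }
  label <- if ("label" %in% keys) vals[keys == "label"] else basename(path)
  growth_params(get_num("mu"), get_num("sigma_sqrt2"), get_num("c"),
                get_num("k"), get_num("x_i"), label = label)
}

#' @rdname read_growth_params
#' @param p a `"growth_params"` object to serialize.
#' @export
write_growth_params <- function(p, path) {
  p <- as_growth_params(p)
  lines <- c(
    paste("label =", p$label),
    sprintf("mu = %.17g", p$mu),
    sprintf("sigma_sqrt2 = %.17g", p$sigma_sqrt2),
    sprintf("c = %.17g", p$c),
    sprintf("k = %.17g", p$k),
    sprintf("x_i = %.17g", p$x_i)
  )
  writeLines(lines, path)
  invisible(path)
}
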