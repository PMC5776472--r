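# Delimited-text I/O for traces and rate tables.  All artifacts are comma
# separated with '#'-prefixed provenance header lines (version, seed,
# params hash) so re-running with identical configuration reproduces them.

.pkg_version <- function() {
  as.character(utils::packageVersion("photosulfide"))
}

# small stable content hash (31-bit polynomial rolling hash) over a
# serialized object; plain double arithmetic so no integer overflow
params_hash <- function(p) {
  s <- paste(deparse(unclass(p), control = "exact"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance_header <- function(seed = NA, params = NULL) {
  c(sprintf("# photosulfide %s", .pkg_version()),
    sprintf("# seed: %s", seed),
    if (!is.null(params)) sprintf("# params_hash: %s", params_hash(params)))
}

#' Write / read a microsensor trace as delimited text
#'
#' Comma-separated values with header `time_s,o2_uM,h2s_uM,pH` and
#' `#`-prefixed provenance lines.  The round trip is lossless at full
#' double precision (values are written with 17 significant digits).
#' A missing pH channel is written as `NA` and read back as absent.
#'
#' @param trace a [microsensor_trace()].
#' @param path file path.
#' @param seed,params optional provenance (seed, generating parameters).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `microsensor_trace`.  Malformed headers, non-monotone times and
#'   negative concentrations raise errors naming the offending line.
#' @export
write_trace <- function(trace, path, seed = NA, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, params), con)
  writeLines("time_s,o2_uM,h2s_uM,pH", con)
  lines <- sprintf("%.17g,%.17g,%.17g,%s",
                   trace$time_s, trace$o2_uM, trace$h2s_uM,
                   ifelse(is.na(trace$pH), "NA",
                          sprintf("%.17g", trace$pH)))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  offset <- which(!is_comment)   # original line numbers of the body
  if (!length(body) || body[1] != "time_s,o2_uM,h2s_uM,pH")
    stop("malformed header at line ", if (length(offset)) offset[1] else 1,
         ": expected 'time_s,o2_uM,h2s_uM,pH'")
  dat <- utils::read.csv(text = body, header = TRUE)
  if (nrow(dat) >= 2) {
    bad <- which(diff(dat$time_s) <= 0)
    if (length(bad))
      stop("non-monotone time at line ", offset[bad[1] + 2L])
  }
  neg <- which(dat$o2_uM < 0 | dat$h2s_uM < 0)
  if (length(neg))
    stop("negative concentration at line ", offset[neg[1] + 1L])
  ph <- if (all(is.na(dat$pH))) NULL else dat$pH
  microsensor_trace(dat$time_s, dat$o2_uM, dat$h2s_uM, ph)
}

#' Write / read extracted rate points as delimited text
#'
#' @param points a `rate_point` data.frame.
#' @param path file path.
#' @param seed optional provenance seed.
#' @return `write_rate_points()` returns `path` invisibly;
#'   `read_rate_points()` the data.frame.
#' @export
write_rate_points <- function(points, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  utils::write.csv(as.data.frame(points), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_points
#' @export
read_rate_points <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                      collapse = "\n"))
  class(out) <- c("rate_point", "data.frame")
  out
}

#' Serialize a fit result as structured text (YAML)
#'
#' @param fit a `fit_result` from [fit_model()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  yaml::write_yaml(list(
    version = .pkg_version(),
    seed = fit$seed,
    variant = fit$params$variant,
    null_model = fit$null_model,
    objective = fit$objective,
    convergence = fit$convergence,
    fitted = fit$params[fit$fit_par],
    unconstrained = as.list(fit$unconstrained),
    at_bounds = as.list(fit$at_bounds),
    params = unclass(fit$params)), path)
  invisible(path)
}
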