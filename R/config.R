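#' Write / read a flat key=value run configuration
#'
#' A run is reproducible from its config plus its inputs.  Values are
#' kept as strings on read (multi-valued entries comma-separated), so a
#' dump -> load -> dump cycle is byte-identical; use `as.numeric()` etc.
#' on access.
#'
#' @param config named list (or named character vector) of settings.
#' @param path output file.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a named character vector.
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("config entries must all be named")
  vals <- vapply(config, function(v)
    paste(format(v, trim = TRUE, scientific = FALSE), collapse = ","),
    character(1))
  ord <- order(keys)
  writeLines(sprintf("%s=%s", keys[ord], vals[ord]), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 1L))
    stop(sprintf("malformed config line: '%s'", lines[which(eq < 1L)[1L]]))
  stats::setNames(substring(lines, eq + 1L),
                  substring(lines, 1L, eq - 1L))
}
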