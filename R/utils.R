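# Internal helpers shared across the pipeline.

LN2 <- log(2)

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a subclass so callers (and the
#' command-line wrappers) can distinguish bad data from bad configuration.
#'
#' @param msg message text.
#' @param class condition subclass, e.g. "mirdose_invalid_input".
#' @noRd
abort_mirdose <- function(msg, class = "mirdose_invalid_input") {
  stop(structure(
    class = c(class, "mirdose_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_mirdose(sprintf("`%s` must be a positive finite number", name))
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_mirdose(sprintf("`%s` must be a non-negative finite number", name))
  }
  invisible(x)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Report tables use conventional "half-up" rounding (0.65 -> 0.7 at one
#' decimal), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.65, 1) # 0.7
#' round_half_up(1.094, 1) # 1.1
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Detect the field separator of a delimited text file (comma or tab) from the
# first non-comment line.
detect_sep <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_mirdose(sprintf("file '%s' contains no data rows", path),
                  class = "mirdose_schema_error")
  }
  if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0) "\t" else ","
}

# Parse "# key: value" metadata directives from a file's comment header.
parse_header_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#\\s*[A-Za-z_.]+\\s*:", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:", "", body))
    out[[tolower(key)]] <- val
  }
  out
}
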