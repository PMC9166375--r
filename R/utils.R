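`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up to a fixed number of decimals
#'
#' Base `round()` rounds half to even; reported percentages use the
#' conventional half-up rule instead (61.255 -> 61.26 at 2 decimals).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Read either a file path, a connection, or literal text into one string.
read_stream <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    return(paste(text, collapse = "\n"))
  }
  stopifnot(!is.null(file))
  paste(readLines(file, warn = FALSE), collapse = "\n")
}

split_lines <- function(x) {
  if (identical(x, "")) character(0) else strsplit(x, "\n", fixed = TRUE)[[1]]
}

# Split a vector of lines into blocks separated by blank lines.
split_blocks <- function(lines) {
  blank <- grepl("^\\s*$", lines)
  if (all(blank)) return(list())
  grp <- cumsum(blank)
  blocks <- split(lines[!blank], grp[!blank])
  unname(blocks[lengths(blocks) > 0L])
}

stop_malformed <- function(pmid, msg) {
  stop(sprintf("malformed record [%s]: %s", pmid, msg), call. = FALSE)
}
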