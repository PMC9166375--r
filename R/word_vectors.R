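#' Read word vectors in word2vec text dialect
#'
#' Each line is `word v1 v2 ... vD`, space separated; an optional first
#' header line `count dim` is recognized and skipped.
#'
#' @param file path (ignored when `text` given).
#' @param text literal text.
#' @return numeric matrix, one row per word, rownames = words.
#' @export
read_word_vectors <- function(file = NULL, text = NULL) {
  lines <- split_lines(read_stream(file, text))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("configuration error: empty word-vector stream", call. = FALSE)
  first <- strsplit(lines[1], "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]                      # header "count dim"
  }
  parts <- strsplit(lines, "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    stop("malformed word-vector stream: inconsistent dimensions", call. = FALSE)
  }
  words <- vapply(parts, `[`, "", 1)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(mat) <- words
  mat
}

#' Write word vectors in word2vec text dialect
#'
#' @param mat numeric matrix with rownames.
#' @param file optional path.
#' @param header write the `count dim` header line (default TRUE).
#' @return the text (invisibly when written to file).
#' @export
write_word_vectors <- function(mat, file = NULL, header = TRUE) {
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], formatC(mat[i, ], format = "g", digits = 8)),
          collapse = " ")
  }, character(1))
  lines <- c(if (header) sprintf("%d %d", nrow(mat), ncol(mat)), body)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
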