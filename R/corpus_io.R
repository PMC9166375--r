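#' @title PubTator corpus reader
#'
#' @description Reads a PubTator-dialect stream into a list of document
#' records. Each block holds a `PMID|t|title` line, a `PMID|a|abstract`
#' line, tab-separated mention lines
#' (`pmid begin end surface type concept`) and relation lines
#' (`pmid CID chemical disease`), with blank lines between documents.
#' Character offsets are 0-based, half-open, over `title + " " + abstract`
#' (single separator character, the PubTator convention).
#'
#' @param file path to a PubTator file (ignored when `text` is given).
#' @param text literal PubTator text, as one string or a character vector
#'   of lines.
#' @return list of `document_record` objects, each with fields `id`,
#'   `title`, `abstract`, `sent_spans` (data.frame `begin`,`end`; row 1 is
#'   the title), `mentions` (data.frame `begin`,`end`,`surface`,`type`,
#'   `concept`) and `relations` (data.frame `chemical`,`disease`).
#' @seealso [write_pubtator()], [align_mentions()]
#' @export
read_pubtator <- function(file = NULL, text = NULL) {
  lines <- split_lines(read_stream(file, text))
  blocks <- split_blocks(lines)
  lapply(blocks, parse_pubtator_block)
}

parse_pubtator_block <- function(block) {
  tl <- grep("^[^\t|]+\\|t\\|", block, value = TRUE)
  al <- grep("^[^\t|]+\\|a\\|", block, value = TRUE)
  pmid <- sub("\\|.*$", "", c(tl, al, block)[1])
  if (length(tl) != 1L) stop_malformed(pmid, "expected exactly one title line")
  if (length(al) != 1L) stop_malformed(pmid, "expected exactly one abstract line")
  title <- sub("^[^|]+\\|t\\|", "", tl)
  abstract <- sub("^[^|]+\\|a\\|", "", al)
  if (sub("\\|.*$", "", al) != pmid) stop_malformed(pmid, "pmid mismatch on abstract line")

  tabbed <- block[grepl("\t", block, fixed = TRUE)]
  fields <- strsplit(tabbed, "\t", fixed = TRUE)
  mentions <- list()
  relations <- list()
  for (f in fields) {
    if (f[1] != pmid) stop_malformed(pmid, sprintf("line pmid '%s' differs", f[1]))
    if (length(f) >= 6 && grepl("^[0-9]+$", f[2])) {
      mentions[[length(mentions) + 1L]] <-
        data.frame(begin = as.integer(f[2]), end = as.integer(f[3]),
                   surface = f[4], type = f[5], concept = f[6])
    } else if (length(f) == 4 && f[2] == "CID") {
      relations[[length(relations) + 1L]] <-
        data.frame(chemical = f[3], disease = f[4])
    } else {
      stop_malformed(pmid, sprintf("unparseable line: %s", paste(f, collapse = "\\t")))
    }
  }
  mentions <- if (length(mentions)) do.call(rbind, mentions) else
    data.frame(begin = integer(), end = integer(), surface = character(),
               type = character(), concept = character())
  relations <- if (length(relations)) do.call(rbind, relations) else
    data.frame(chemical = character(), disease = character())

  doc <- new_document_record(pmid, title, abstract, mentions, relations)
  doc
}

#' Construct and validate a document record
#'
#' @param id document identifier (pmid).
#' @param title,abstract document text; offsets run over
#'   `title + " " + abstract`.
#' @param mentions data.frame with columns `begin`, `end`, `surface`,
#'   `type` (`Chemical` or `Disease`), `concept`.
#' @param relations data.frame with columns `chemical`, `disease`
#'   (concept identifiers).
#' @param sent_spans optional data.frame of sentence character spans
#'   (row 1 = title); computed by [split_sentences()] when missing.
#' @return a `document_record`.
#' @export
new_document_record <- function(id, title, abstract, mentions, relations,
                                sent_spans = NULL) {
  text <- paste(title, abstract)
  if (is.null(sent_spans)) sent_spans <- split_sentences(title, abstract)

  if (nrow(mentions)) {
    bad_type <- !mentions$type %in% c("Chemical", "Disease")
    if (any(bad_type)) {
      stop_malformed(id, sprintf("unknown entity type '%s'",
                                 mentions$type[bad_type][1]))
    }
    if (any(mentions$begin >= mentions$end)) stop_malformed(id, "mention with begin >= end")
    if (any(mentions$end > nchar(text))) {
      stop_malformed(id, "mention offset outside document text")
    }
    got <- substring(text, mentions$begin + 1L, mentions$end)
    off <- got != mentions$surface
    if (any(off)) {
      stop_malformed(id, sprintf(
        "mention surface '%s' does not match text at [%d,%d) ('%s')",
        mentions$surface[off][1], mentions$begin[off][1],
        mentions$end[off][1], got[off][1]))
    }
  }
  if (nrow(relations)) {
    if (anyDuplicated(relations)) stop_malformed(id, "duplicate relation pair")
    known <- unique(mentions$concept)
    miss <- !(relations$chemical %in% known) | !(relations$disease %in% known)
    if (any(miss)) {
      stop_malformed(id, sprintf("relation concept pair (%s,%s) has no mention",
                                 relations$chemical[miss][1], relations$disease[miss][1]))
    }
  }
  # every mention must fall inside a single sentence span
  if (nrow(mentions)) {
    sent <- mention_sentence(mentions, sent_spans)
    if (anyNA(sent)) {
      i <- which(is.na(sent))[1]
      stop_malformed(id, sprintf("mention '%s' [%d,%d) crosses a sentence boundary",
                                 mentions$surface[i], mentions$begin[i], mentions$end[i]))
    }
  }
  structure(list(id = id, title = title, abstract = abstract,
                 sent_spans = sent_spans, mentions = mentions,
                 relations = relations),
            class = "document_record")
}

# sentence index (1-based over sent_spans rows, row 1 = title) containing
# each mention, or NA when no single sentence contains it
mention_sentence <- function(mentions, sent_spans) {
  vapply(seq_len(nrow(mentions)), function(i) {
    hit <- which(mentions$begin[i] >= sent_spans$begin &
                 mentions$end[i] <= sent_spans$end)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
}

#' Deterministic sentence splitter
#'
#' The title is always sentence 1 (index 0 of the document). The abstract
#' is split after `.`, `?` or `!` followed by whitespace and an uppercase
#' letter or digit. Spans are 0-based half-open over
#' `title + " " + abstract` and exclude the inter-sentence whitespace.
#'
#' @param title,abstract document text fields.
#' @return data.frame with columns `begin`, `end`.
#' @export
split_sentences <- function(title, abstract) {
  off <- nchar(title) + 1L   # abstract begins after the 1-char separator
  spans <- data.frame(begin = 0L, end = nchar(title))
  if (nchar(abstract) == 0) return(spans)
  m <- gregexpr("[.?!](?=\\s+[A-Z0-9])", abstract, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer(0) else as.integer(m)
  starts <- c(1L, vapply(cuts, function(p) {
    rest <- substring(abstract, p + 1L)
    p + attr(regexpr("^\\s+", rest), "match.length") + 1L
  }, integer(1)))
  ends <- c(cuts, nchar(abstract))
  rbind(spans, data.frame(begin = off + starts - 1L, end = off + ends))
}

#' Write document records in PubTator format
#'
#' Inverse of [read_pubtator()]: `read_pubtator(text = write_pubtator(x))`
#' reproduces `x` up to field ordering.
#'
#' @param records list of `document_record`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return the PubTator text, one string (invisibly when written to file).
#' @export
write_pubtator <- function(records, file = NULL) {
  blocks <- vapply(records, function(doc) {
    stopifnot(inherits(doc, "document_record"))
    # re-validate so invariant violations fail on write, too
    new_document_record(doc$id, doc$title, doc$abstract, doc$mentions,
                        doc$relations, doc$sent_spans)
    out <- c(sprintf("%s|t|%s", doc$id, doc$title),
             sprintf("%s|a|%s", doc$id, doc$abstract))
    if (nrow(doc$mentions)) {
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc$id,
                            doc$mentions$begin, doc$mentions$end,
                            doc$mentions$surface, doc$mentions$type,
                            doc$mentions$concept))
    }
    if (nrow(doc$relations)) {
      out <- c(out, sprintf("%s\tCID\t%s\t%s", doc$id,
                            doc$relations$chemical, doc$relations$disease))
    }
    paste(out, collapse = "\n")
  }, character(1))
  txt <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' CoNLL-U reader
#'
#' Reads sentence blocks with columns ID, FORM, LEMMA, UPOS, XPOS, FEATS,
#' HEAD, DEPREL, DEPS, MISC. XPOS is used as the POS tag when present,
#' otherwise UPOS. Document-absolute token character spans may be carried
#' in MISC as `TokenRange=begin:end` (0-based half-open); sentence spans
#' are derived from them. Dependency labels outside the 72-label inventory
#' are mapped to the reserved unknown row (the original string is kept in
#' `deprel_raw`). A `# doc = <id>` comment attaches the sentence to a
#' document; multiword-token and empty-node lines are skipped.
#'
#' @param file path to a CoNLL-U file (ignored when `text` is given).
#' @param text literal CoNLL-U text.
#' @param quiet suppress the message listing unknown dependency labels.
#' @return list of `parsed_sentence` objects with fields `doc`, `tokens`
#'   (data.frame `surface`,`pos`,`begin`,`end`), `heads` (0 = root),
#'   `deprels`, `deprels_raw`, `root`.
#' @export
read_conllu <- function(file = NULL, text = NULL, quiet = FALSE) {
  lines <- split_lines(read_stream(file, text))
  blocks <- split_blocks(lines)
  unknown <- character(0)
  out <- lapply(blocks, function(b) {
    s <- parse_conllu_block(b)
    unknown <<- c(unknown, setdiff(s$deprels_raw, dep_label_inventory()))
    s
  })
  if (!quiet && length(unknown)) {
    message("read_conllu: mapped unknown dependency labels to '",
            DEP_UNKNOWN_LABEL, "': ", paste(unique(unknown), collapse = ", "))
  }
  out
}

parse_conllu_block <- function(block) {
  comments <- grep("^#", block, value = TRUE)
  doc <- sub("^#\\s*doc\\s*=\\s*", "",
             grep("^#\\s*doc\\s*=", comments, value = TRUE))
  doc <- if (length(doc)) doc[1] else NA_character_
  rows <- grep("^[0-9]+\t", block, value = TRUE)   # skip ranges & empty nodes
  if (!length(rows)) stop("parse-structure error: sentence block with no tokens",
                          call. = FALSE)
  f <- strsplit(rows, "\t", fixed = TRUE)
  n <- length(f)
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else "_", character(1))
  ids <- as.integer(get(1))
  if (!identical(ids, seq_len(n))) {
    stop("parse-structure error: token IDs are not 1..n", call. = FALSE)
  }
  upos <- get(4); xpos <- get(5)
  pos <- ifelse(xpos != "_", xpos, upos)
  heads <- suppressWarnings(as.integer(get(7)))
  if (anyNA(heads)) stop("parse-structure error: missing HEAD", call. = FALSE)
  deprels_raw <- get(8)
  misc <- get(10)
  span <- regmatches(misc, regexec("TokenRange=([0-9]+):([0-9]+)", misc))
  begin <- vapply(span, function(m) if (length(m)) as.integer(m[2]) else NA_integer_,
                  integer(1))
  end <- vapply(span, function(m) if (length(m)) as.integer(m[3]) else NA_integer_,
                integer(1))
  new_parsed_sentence(
    doc = doc,
    tokens = data.frame(surface = get(2), pos = pos, begin = begin, end = end),
    heads = heads, deprels_raw = deprels_raw)
}

#' Construct and validate a parsed sentence
#'
#' Enforces the tree invariants: exactly one root (HEAD = 0), every
#' non-root token has exactly one in-sentence head, and following heads
#' from any token reaches the root (no cycles).
#'
#' @param tokens data.frame with `surface`, `pos`, and optional `begin`,
#'   `end` character spans.
#' @param heads integer vector of head token indices, 0 for the root.
#' @param deprels_raw dependency labels as emitted by the parser.
#' @param doc optional document id.
#' @return a `parsed_sentence`.
#' @export
new_parsed_sentence <- function(tokens, heads, deprels_raw, doc = NA_character_) {
  n <- nrow(tokens)
  stopifnot(length(heads) == n, length(deprels_raw) == n)
  roots <- which(heads == 0L)
  if (length(roots) != 1L) {
    stop(sprintf("parse-structure error: %d roots in sentence (expected 1)",
                 length(roots)), call. = FALSE)
  }
  if (any(heads < 0L | heads > n)) {
    stop("parse-structure error: HEAD index outside sentence", call. = FALSE)
  }
  if (any(heads == seq_len(n))) {
    stop("parse-structure error: token is its own head", call. = FALSE)
  }
  # cycle check: climb from every token; must hit 0 within n steps
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (heads[j] != 0L) {
      j <- heads[j]; steps <- steps + 1L
      if (steps > n) stop("parse-structure error: cycle in dependency arcs",
                          call. = FALSE)
    }
  }
  structure(list(doc = doc, tokens = tokens, heads = heads,
                 deprels = map_dep_label(deprels_raw),
                 deprels_raw = deprels_raw, root = roots),
            class = "parsed_sentence")
}

#' Write parsed sentences in CoNLL-U format
#'
#' @param parses list of `parsed_sentence`.
#' @param file optional path.
#' @return CoNLL-U text (invisibly when written to file).
#' @export
write_conllu <- function(parses, file = NULL) {
  blocks <- vapply(parses, function(s) {
    n <- nrow(s$tokens)
    misc <- ifelse(is.na(s$tokens$begin), "_",
                   sprintf("TokenRange=%d:%d", s$tokens$begin, s$tokens$end))
    hdr <- if (!is.na(s$doc)) sprintf("# doc = %s", s$doc) else character(0)
    rows <- sprintf("%d\t%s\t_\t%s\t%s\t_\t%d\t%s\t_\t%s",
                    seq_len(n), s$tokens$surface, s$tokens$pos, s$tokens$pos,
                    s$heads, s$deprels_raw, misc)
    paste(c(hdr, rows), collapse = "\n")
  }, character(1))
  txt <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Knowledge-base pair reader
#'
#' Reads a CTD-style tab-separated table
#' `chemical_id<TAB>disease_id<TAB>relation_code` and keeps only rows whose
#' code equals `code`.
#'
#' @param file path (ignored when `text` given).
#' @param text literal TSV text.
#' @param code relation code to keep (default `"M"`).
#' @return data.frame with columns `chemical`, `disease`, `code`.
#' @export
read_kb_pairs <- function(file = NULL, text = NULL, code = "M") {
  lines <- split_lines(read_stream(file, text))
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) {
    return(data.frame(chemical = character(), disease = character(),
                      code = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed KB row at line %d: expected 3 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  out <- data.frame(chemical = vapply(f, `[`, "", 1),
                    disease = vapply(f, `[`, "", 2),
                    code = vapply(f, `[`, "", 3))
  out[out$code == code, , drop = FALSE]
}

#' Coreference link reader
#'
#' Reads a tab-separated table
#' `sent_idx<TAB>begin<TAB>end<TAB>ant_sent_idx<TAB>ant_begin<TAB>ant_end`
#' where `sent_idx` is the 0-based sentence index (0 = title) and
#' `begin`/`end` are 1-based inclusive token index ranges within the
#' sentence. When `parses` is given, every location is checked to resolve
#' to tokens of the document.
#'
#' @param file path (ignored when `text` given).
#' @param text literal TSV text.
#' @param parses optional list of `parsed_sentence` for validation.
#' @return data.frame with columns `sent`, `begin`, `end`, `ant_sent`,
#'   `ant_begin`, `ant_end` (all integer).
#' @export
read_coref_links <- function(file = NULL, text = NULL, parses = NULL) {
  lines <- split_lines(read_stream(file, text))
  lines <- lines[!grepl("^\\s*$", lines)]
  cols <- c("sent", "begin", "end", "ant_sent", "ant_begin", "ant_end")
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(integer()), 6), cols))
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 6L)
  if (length(bad)) {
    stop(sprintf("malformed coreference row at line %d: expected 6 fields",
                 bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(f, as.integer))
  out <- stats::setNames(as.data.frame(m), cols)
  if (!is.null(parses)) validate_coref_links(out, parses)
  out
}

validate_coref_links <- function(links, parses) {
  n_sent <- length(parses)
  for (i in seq_len(nrow(links))) {
    for (side in list(c("sent", "begin", "end"), c("ant_sent", "ant_begin", "ant_end"))) {
      s <- links[[side[1]]][i]
      if (s < 0L || s >= n_sent) {
        stop(sprintf("coreference link %d references sentence %d outside document (0..%d)",
                     i, s, n_sent - 1L), call. = FALSE)
      }
      nt <- nrow(parses[[s + 1L]]$tokens)
      b <- links[[side[2]]][i]; e <- links[[side[3]]][i]
      if (b < 1L || e > nt || b > e) {
        stop(sprintf("coreference link %d references tokens [%d,%d] outside sentence %d (1..%d)",
                     i, b, e, s, nt), call. = FALSE)
      }
    }
  }
  invisible(links)
}

#' Align character-offset mentions to parsed tokens
#'
#' Maps each mention of a document to the tokens its character span
#' overlaps, and picks the mention head token: the token whose syntactic
#' head lies outside the mention token set; when no token or more than one
#' qualifies, the rightmost mention token. Token spans come from the
#' parses when present (`TokenRange`), otherwise tokens are matched
#' left-to-right against the document text.
#'
#' @param doc a `document_record`.
#' @param parses list of `parsed_sentence`, one per sentence of `doc`
#'   (element 1 = title).
#' @return data.frame with one row per mention: `mention` (row index into
#'   `doc$mentions`), `sent` (0-based sentence index), `head_tok` (token
#'   index within sentence), and list-column `tokens` (integer indices).
#' @export
align_mentions <- function(doc, parses) {
  if (length(parses) != nrow(doc$sent_spans)) {
    stop(sprintf("alignment error [%s]: %d parses for %d sentences",
                 doc$id, length(parses), nrow(doc$sent_spans)), call. = FALSE)
  }
  parses <- ensure_token_spans(doc, parses)
  men <- doc$mentions
  n <- nrow(men)
  out <- data.frame(mention = seq_len(n), sent = NA_integer_,
                    head_tok = NA_integer_)
  out$tokens <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- lapply(seq_along(parses), function(si) {
      tk <- parses[[si]]$tokens
      which(tk$begin < men$end[i] & tk$end > men$begin[i])
    })
    has <- which(lengths(hits) > 0L)
    if (length(has) == 0L) {
      stop(sprintf("alignment error [%s]: mention '%s' [%d,%d) overlaps no token",
                   doc$id, men$surface[i], men$begin[i], men$end[i]), call. = FALSE)
    }
    if (length(has) > 1L) {
      stop(sprintf("alignment error [%s]: mention '%s' spans a sentence boundary",
                   doc$id, men$surface[i]), call. = FALSE)
    }
    si <- has
    toks <- hits[[si]]
    heads <- parses[[si]]$heads[toks]
    outside <- which(!(heads %in% toks))
    head_tok <- if (length(outside) == 1L) toks[outside] else max(toks)
    out$sent[i] <- si - 1L
    out$head_tok[i] <- head_tok
    out$tokens[[i]] <- toks
  }
  out
}

# Fill missing token character spans by matching surfaces left-to-right
# inside each sentence's span of the document text.
ensure_token_spans <- function(doc, parses) {
  text <- paste(doc$title, doc$abstract)
  for (si in seq_along(parses)) {
    tk <- parses[[si]]$tokens
    if (!anyNA(tk$begin)) next
    cursor <- doc$sent_spans$begin[si]
    for (ti in seq_len(nrow(tk))) {
      hit <- regexpr(tk$surface[ti], substring(text, cursor + 1L), fixed = TRUE)
      if (hit == -1L) {
        stop(sprintf("alignment error [%s]: token '%s' not found in sentence %d text",
                     doc$id, tk$surface[ti], si - 1L), call. = FALSE)
      }
      tk$begin[ti] <- cursor + as.integer(hit) - 1L
      tk$end[ti] <- tk$begin[ti] + nchar(tk$surface[ti])
      cursor <- tk$end[ti]
    }
    parses[[si]]$tokens <- tk
  }
  parses
}

#' Group parses by document id
#'
#' @param parses list of `parsed_sentence` carrying `doc` ids.
#' @return named list: document id -> list of its sentences, in order.
#' @export
split_parses_by_doc <- function(parses) {
  ids <- vapply(parses, function(s) s$doc, character(1))
  if (anyNA(ids)) stop("parses without '# doc =' ids cannot be grouped", call. = FALSE)
  split(parses, factor(ids, levels = unique(ids)))
}
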