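#' Virtual-edge family configuration
#'
#' Toggles each virtual-edge family of the document subgraph
#' independently, so ablation grids can be run.
#'
#' @param next_sent,title,coref_sent,coref_to_title,coref_from_title,kb_ctd
#'   logical flags enabling each family.
#' @return named logical vector of class `edge_config`.
#' @export
edge_config <- function(next_sent = TRUE, title = TRUE, coref_sent = TRUE,
                        coref_to_title = TRUE, coref_from_title = TRUE,
                        kb_ctd = TRUE) {
  structure(c(`NEXT-SENT` = next_sent, `TITLE` = title,
              `COREF-sent` = coref_sent, `COREF-to-title` = coref_to_title,
              `COREF-from-title` = coref_from_title, `KB-CTD` = kb_ctd),
            class = "edge_config")
}

#' Enumerate sliding windows over the abstract sentences
#'
#' All length-`w` consecutive spans of abstract sentences, stride 1. The
#' title never slides: it is part of every window's subgraph. A document
#' with fewer than `w` abstract sentences yields a single window covering
#' all of them, so short abstracts still emit instances.
#'
#' @param n_sentences number of abstract sentences (title excluded).
#' @param w window width in sentences, between 1 and 5.
#' @return list of window specs: `start` (first abstract sentence, 1-based),
#'   `width`, and `sentences` (the abstract sentence indices covered).
#' @export
enumerate_windows <- function(n_sentences, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w > 5) {
    stop("configuration error: window width w must be in [1, 5]", call. = FALSE)
  }
  w <- as.integer(w)
  stopifnot(n_sentences >= 1)
  if (n_sentences < w) {
    return(list(list(start = 1L, width = as.integer(n_sentences),
                     sentences = seq_len(n_sentences))))
  }
  lapply(seq_len(n_sentences - w + 1L), function(s) {
    list(start = s, width = w, sentences = seq.int(s, s + w - 1L))
  })
}

#' Build a document subgraph for one window
#'
#' Merges the dependency trees of the title and the window's sentences
#' into one graph and injects the enabled virtual edges:
#' \describe{
#'   \item{syntactic}{directed, labeled head-to-dependent arcs of every
#'     sentence in the subgraph (all dependency labels kept).}
#'   \item{NEXT-SENT}{undirected, between the roots of consecutive window
#'     sentences.}
#'   \item{TITLE}{undirected, between the title root and the first window
#'     sentence's root (exactly one per subgraph).}
#'   \item{COREF-*}{undirected, per coreference link whose two locations
#'     both fall inside the subgraph; the subtype depends on whether the
#'     anaphor/antecedent sits in the title.}
#'   \item{KB-CTD}{undirected, between the head tokens of every in-window
#'     chemical/disease mention pair whose concept pair is listed in the
#'     knowledge-base table.}
#' }
#' Duplicate virtual edges (same endpoints and label) are collapsed.
#'
#' @param doc a `document_record`.
#' @param parses list of `parsed_sentence` (element 1 = title).
#' @param window a window spec from [enumerate_windows()].
#' @param config an [edge_config()].
#' @param coref optional coreference link table ([read_coref_links()]).
#' @param kb optional knowledge-base pair table ([read_kb_pairs()]).
#' @param alignment optional mention alignment ([align_mentions()]);
#'   computed on demand when KB edges are requested.
#' @return a `document_subgraph`: `window`, `nodes` (data.frame
#'   `sent`,`tok`,`surface`,`pos`), `edges` (data.frame `from`,`to`,
#'   `category`,`label`,`directed`), `roots` (named node ids per sentence),
#'   and `sentences` (0-based sentence indices in the subgraph).
#' @export
build_subgraph <- function(doc, parses, window, config = edge_config(),
                           coref = NULL, kb = NULL, alignment = NULL) {
  sents <- c(0L, window$sentences)            # 0 = title
  if (any(window$sentences + 1L > length(parses))) {
    stop(sprintf("window references sentence %d but only %d parses given",
                 max(window$sentences), length(parses) - 1L), call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(sents, function(s) {
    tk <- parses[[s + 1L]]$tokens
    data.frame(sent = s, tok = seq_len(nrow(tk)),
               surface = tk$surface, pos = tk$pos)
  }))
  rownames(nodes) <- NULL
  nid <- function(sent, tok) {
    match(paste(sent, tok), paste(nodes$sent, nodes$tok))
  }
  roots <- vapply(sents, function(s) nid(s, parses[[s + 1L]]$root), integer(1))
  names(roots) <- sents

  edges <- do.call(rbind, lapply(sents, function(s) {
    p <- parses[[s + 1L]]
    dep <- which(p$heads != 0L)
    if (!length(dep)) return(NULL)
    data.frame(from = nid(s, p$heads[dep]), to = nid(s, dep),
               category = "syntactic", label = p$deprels[dep],
               directed = TRUE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = integer(), to = integer(),
                        category = character(), label = character(),
                        directed = logical())
  }

  virt <- list()
  add_virtual <- function(from, to, label) {
    virt[[length(virt) + 1L]] <<-
      data.frame(from = from, to = to, category = "virtual",
                 label = label, directed = FALSE)
  }
  if (config[["TITLE"]]) {
    add_virtual(roots[["0"]], roots[[as.character(window$sentences[1])]], "TITLE")
  }
  if (config[["NEXT-SENT"]] && length(window$sentences) > 1L) {
    for (i in seq_len(length(window$sentences) - 1L)) {
      add_virtual(roots[[as.character(window$sentences[i])]],
                  roots[[as.character(window$sentences[i + 1L])]], "NEXT-SENT")
    }
  }
  if (!is.null(coref) && nrow(coref)) {
    validate_coref_links(coref, parses)
    for (i in seq_len(nrow(coref))) {
      s_an <- coref$sent[i]; s_ant <- coref$ant_sent[i]
      if (!(s_an %in% sents) || !(s_ant %in% sents)) next   # outside window: skip
      subtype <- if (s_ant == 0L && s_an != 0L) "COREF-to-title"
                 else if (s_an == 0L && s_ant != 0L) "COREF-from-title"
                 else "COREF-sent"
      if (!config[[subtype]]) next
      an_tok <- span_head_token(parses[[s_an + 1L]], coref$begin[i], coref$end[i])
      ant_tok <- span_head_token(parses[[s_ant + 1L]], coref$ant_begin[i], coref$ant_end[i])
      add_virtual(nid(s_an, an_tok), nid(s_ant, ant_tok), subtype)
    }
  }
  if (config[["KB-CTD"]] && !is.null(kb) && nrow(kb)) {
    if (is.null(alignment)) alignment <- align_mentions(doc, parses)
    men <- doc$mentions
    inw <- which(alignment$sent %in% sents)
    chem <- inw[men$type[inw] == "Chemical"]
    dis <- inw[men$type[inw] == "Disease"]
    for (ci in chem) {
      for (di in dis) {
        hit <- kb$chemical == men$concept[ci] & kb$disease == men$concept[di]
        if (any(hit)) {
          add_virtual(nid(alignment$sent[ci], alignment$head_tok[ci]),
                      nid(alignment$sent[di], alignment$head_tok[di]), "KB-CTD")
        }
      }
    }
  }
  if (length(virt)) {
    virt <- do.call(rbind, virt)
    # collapse duplicates under unordered endpoints + label
    key <- paste(pmin(virt$from, virt$to), pmax(virt$from, virt$to), virt$label)
    virt <- virt[!duplicated(key), , drop = FALSE]
    edges <- rbind(edges, virt)
  }
  rownames(edges) <- NULL
  structure(list(window = window, sentences = sents, nodes = nodes,
                 edges = edges, roots = roots),
            class = "document_subgraph")
}

# head token of a 1-based inclusive token range: the token whose head lies
# outside the range; ties or none -> rightmost
span_head_token <- function(parse, begin, end) {
  toks <- seq.int(begin, end)
  outside <- which(!(parse$heads[toks] %in% toks))
  if (length(outside) == 1L) toks[outside] else max(toks)
}

#' Look up a subgraph node id
#'
#' @param sg a `document_subgraph`.
#' @param sent 0-based sentence index.
#' @param tok token index within the sentence.
#' @return integer node id (row of `sg$nodes`), or `NA` if absent.
#' @export
subgraph_node <- function(sg, sent, tok) {
  match(paste(sent, tok), paste(sg$nodes$sent, sg$nodes$tok))
}

#' Export a subgraph as edge-list TSV
#'
#' One edge per line:
#' `sent:tok<TAB>sent:tok<TAB>category<TAB>label<TAB>direction`,
#' direction `->` for directed syntactic arcs and `--` for virtual edges.
#'
#' @param sg a `document_subgraph`.
#' @param file optional path.
#' @return the TSV text (invisibly when written to file).
#' @export
subgraph_to_tsv <- function(sg, file = NULL) {
  key <- function(id) sprintf("%d:%d", sg$nodes$sent[id], sg$nodes$tok[id])
  lines <- sprintf("%s\t%s\t%s\t%s\t%s",
                   key(sg$edges$from), key(sg$edges$to),
                   sg$edges$category, sg$edges$label,
                   ifelse(sg$edges$directed, "->", "--"))
  txt <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @export
print.document_subgraph <- function(x, ...) {
  cat(sprintf("<document_subgraph> window start=%d width=%d | %d nodes, %d edges (%d virtual)\n",
              x$window$start, x$window$width, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$category == "virtual")))
  invisible(x)
}
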