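#' Bounded breadth-first path enumeration between two subgraph nodes
#'
#' Enumerates simple paths (no node revisited) between two nodes of a
#' document subgraph in breadth-first order: paths come out in
#' nondecreasing node count, ties broken lexicographically by the node
#' coordinate sequence (sentence index, then token index). Virtual edges
#' are traversed exactly like syntactic edges. The search is bounded by
#' the maximum depth `md` (number of nodes on a path) and stops as soon as
#' `kmax` paths have been collected.
#'
#' @param sg a `document_subgraph`.
#' @param source,target node ids (rows of `sg$nodes`); must differ.
#' @param md maximum number of nodes per path (default 15).
#' @param kmax maximum number of paths collected (default 150).
#' @return list of `dg_path` objects: `nodes` (node id sequence),
#'   `edges` (data.frame `label`, `category`, `direction` with direction
#'   `with`/`against` relative to the stored arc orientation).
#' @export
find_paths <- function(sg, source, target, md = 15L, kmax = 150L) {
  n <- nrow(sg$nodes)
  if (is.na(source) || is.na(target) || source < 1L || source > n ||
      target < 1L || target > n) {
    stop("path search error: source/target node not in subgraph", call. = FALSE)
  }
  if (source == target) {
    stop("degenerate-pair error: source and target are the same node", call. = FALSE)
  }
  stopifnot(md >= 2, kmax >= 1)

  adj <- subgraph_adjacency(sg)
  # FIFO queue of partial paths; each entry: nodes, edge idx, edge dir
  queue <- vector("list", 64L)
  queue[[1L]] <- list(nodes = source, eidx = integer(0), edir = character(0))
  head_i <- 1L; tail_i <- 1L
  out <- list()

  while (head_i <= tail_i && length(out) < kmax) {
    cur <- queue[[head_i]]
    queue[head_i] <- list(NULL)
    head_i <- head_i + 1L
    last <- cur$nodes[length(cur$nodes)]
    if (length(cur$nodes) >= md) next
    nb <- adj[[last]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      nxt <- nb$nbr[j]
      if (nxt %in% cur$nodes) next        # never go back to passed nodes
      ext <- list(nodes = c(cur$nodes, nxt),
                  eidx = c(cur$eidx, nb$edge[j]),
                  edir = c(cur$edir, nb$dir[j]))
      if (nxt == target) {
        out[[length(out) + 1L]] <- as_dg_path(sg, ext)
        if (length(out) >= kmax) break
      } else {
        tail_i <- tail_i + 1L
        if (tail_i > length(queue)) length(queue) <- 2L * length(queue)
        queue[[tail_i]] <- ext
      }
    }
  }
  out
}

# adjacency list: per node a data.frame(nbr, edge, dir) sorted by the
# neighbour's (sent, tok) coordinates so expansion order is deterministic
subgraph_adjacency <- function(sg) {
  e <- sg$edges
  half <- data.frame(node = c(e$from, e$to), nbr = c(e$to, e$from),
                     edge = rep(seq_len(nrow(e)), 2L),
                     dir = rep(c("with", "against"), each = nrow(e)))
  ord <- order(half$node, sg$nodes$sent[half$nbr], sg$nodes$tok[half$nbr],
               half$edge)
  half <- half[ord, , drop = FALSE]
  out <- vector("list", nrow(sg$nodes))
  for (grp in split(seq_len(nrow(half)), half$node)) {
    out[[half$node[grp[1]]]] <- half[grp, c("nbr", "edge", "dir")]
  }
  out
}

as_dg_path <- function(sg, ext) {
  e <- sg$edges[ext$eidx, , drop = FALSE]
  structure(list(
    nodes = ext$nodes,
    edges = data.frame(label = e$label, category = e$category,
                       direction = ext$edir)),
    class = "dg_path")
}

#' Materialize a path's token and coordinate content
#'
#' @param sg the subgraph the path was mined from.
#' @param path a `dg_path`.
#' @return list with `tokens` (data.frame `sent`,`tok`,`surface`,`pos`),
#'   `edges` (label/category/direction), `pattern` (the lexical dedup
#'   key: surfaces, POS tags, edge labels and traversal directions), and
#'   `coords` (the node coordinate string used as deterministic
#'   tie-break).
#' @export
path_content <- function(sg, path) {
  tk <- sg$nodes[path$nodes, c("sent", "tok", "surface", "pos")]
  rownames(tk) <- NULL
  n <- nrow(tk)
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <- paste0(tk$surface, "/", tk$pos)
  if (n > 1L) {
    parts[seq(2L, 2L * n - 2L, by = 2L)] <-
      paste0(path$edges$label, "/", path$edges$direction)
  }
  list(tokens = tk, edges = path$edges,
       pattern = paste(parts, collapse = " "),
       coords = paste(sprintf("%d:%d", tk$sent, tk$tok), collapse = " "))
}

#' Minimal-span filtering of co-occurring mention pairs
#'
#' A co-occurrence (one chemical mention plus one disease mention of a
#' fixed concept pair, with its sentence span `[span_lo, span_hi]`) is
#' removed when another co-occurrence of the same pair overlaps it and has
#' a strictly contained sentence span: the relation, if present, is most
#' likely expressed where the mentions are closest.
#'
#' @param cooc data.frame of co-occurrences of one concept pair with
#'   integer columns `span_lo`, `span_hi`.
#' @return the surviving subset of `cooc` rows.
#' @export
minimal_span_filter <- function(cooc) {
  n <- nrow(cooc)
  if (n <= 1L) return(cooc)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      overlaps <- cooc$span_lo[j] <= cooc$span_hi[i] &&
                  cooc$span_lo[i] <= cooc$span_hi[j]
      strictly_inside <- cooc$span_lo[j] >= cooc$span_lo[i] &&
                         cooc$span_hi[j] <= cooc$span_hi[i] &&
                         (cooc$span_lo[j] > cooc$span_lo[i] ||
                          cooc$span_hi[j] < cooc$span_hi[i])
      if (overlaps && strictly_inside) { keep[i] <- FALSE; break }
    }
  }
  cooc[keep, , drop = FALSE]
}

#' Merge mined paths into one candidate instance per concept pair
#'
#' Pools the paths of all mention pairs and all windows of one
#' (document, chemical concept, disease concept) key into a single set,
#' removes repeated paths (identical lexical pattern: token surface form,
#' POS tag, edge label and traversal direction along the path), and
#' records each kept path's pre-deduplication multiplicity for the
#' frequency selection strategy. Paths are ordered by node count, then by
#' the coordinate tie-break.
#'
#' @param doc_id,chemical,disease instance key.
#' @param paths list of materialized paths ([path_content()] output).
#' @param label gold label, `"CID"` or `"NONE"`.
#' @return a `candidate_instance`: key fields, `label`, and `paths` (each
#'   with `tokens`, `edges`, `pattern`, `length`, `multiplicity`).
#' @export
merge_instances <- function(doc_id, chemical, disease, paths,
                            label = c("NONE", "CID")) {
  label <- match.arg(label)
  if (length(paths)) {
    patt <- vapply(paths, `[[`, "", "pattern")
    lens <- vapply(paths, function(p) nrow(p$tokens), integer(1))
    coords <- vapply(paths, `[[`, "", "coords")
    ord <- order(lens, coords, patt)
    paths <- paths[ord]; patt <- patt[ord]; lens <- lens[ord]
    mult <- as.integer(table(patt)[patt])
    first <- !duplicated(patt)
    kept <- paths[first]
    kept <- Map(function(p, m, l) {
      p$multiplicity <- m; p$length <- l; p
    }, kept, mult[first], lens[first])
  } else {
    kept <- list()
  }
  structure(list(doc = doc_id, chemical = chemical, disease = disease,
                 label = label, paths = kept),
            class = "candidate_instance")
}

#' Select the top-k paths of an instance
#'
#' Two strategies: `"shortest"` keeps the `k` paths with fewest nodes
#' (ties by the deterministic path ordering); `"most_frequent"` keeps the
#' `k` paths with highest pre-deduplication multiplicity (ties by shorter
#' length, then path ordering). Instances with fewer than `k` paths keep
#' all of them; padding happens downstream in the classifier.
#'
#' @param instance a `candidate_instance`.
#' @param k maximum paths kept (default 3; `Inf` keeps all).
#' @param strategy `"shortest"` or `"most_frequent"`.
#' @return the instance with at most `k` paths.
#' @export
select_top_k <- function(instance, k = 3, strategy = c("shortest", "most_frequent")) {
  strategy <- match.arg(strategy)
  stopifnot(k >= 1)
  p <- instance$paths
  if (length(p) <= k) return(instance)
  lens <- vapply(p, `[[`, integer(1), "length")
  coords <- vapply(p, `[[`, "", "coords")
  ord <- switch(strategy,
    shortest = order(lens, coords),
    most_frequent = order(-vapply(p, `[[`, integer(1), "multiplicity"),
                          lens, coords))
  instance$paths <- p[ord[seq_len(k)]]
  instance
}

#' Mine candidate instances for one document
#'
#' Full per-document mining pipeline: enumerate windows of width `w`,
#' build each window's subgraph, list the chemical-disease mention-pair
#' co-occurrences (a title mention co-occurs with every window), apply
#' minimal-span filtering per concept pair, run the bounded path search
#' between mention head tokens in every window containing the pair, and
#' merge per concept pair. Concept pairs with no co-occurrence in any
#' window are excluded (callers count them as uncovered).
#'
#' @param doc a `document_record`.
#' @param parses the document's parses.
#' @param w window width.
#' @param config an [edge_config()].
#' @param coref,kb optional virtual-edge inputs.
#' @param md,kmax path-search bounds.
#' @param top_k,strategy path selection (see [select_top_k()]).
#' @param alignment optional precomputed [align_mentions()] result.
#' @return list of `candidate_instance` (possibly with empty path sets
#'   when the search finds nothing within the bounds).
#' @export
mine_document <- function(doc, parses, w, config = edge_config(),
                          coref = NULL, kb = NULL, md = 15L, kmax = 150L,
                          top_k = 3, strategy = "shortest",
                          alignment = NULL) {
  if (is.null(alignment)) alignment <- align_mentions(doc, parses)
  men <- doc$mentions
  if (!nrow(men)) return(list())
  n_abs <- nrow(doc$sent_spans) - 1L
  if (n_abs < 1L) return(list())
  windows <- enumerate_windows(n_abs, w)
  sg_cache <- vector("list", length(windows))
  get_sg <- function(wi) {
    if (is.null(sg_cache[[wi]])) {
      sg_cache[[wi]] <<- build_subgraph(doc, parses, windows[[wi]], config,
                                        coref = coref, kb = kb,
                                        alignment = alignment)
    }
    sg_cache[[wi]]
  }
  in_window <- function(sent, win) sent == 0L | sent %in% win$sentences

  chem_m <- which(men$type == "Chemical")
  dis_m <- which(men$type == "Disease")
  if (!length(chem_m) || !length(dis_m)) return(list())

  # mention-pair co-occurrences and their window memberships
  grid <- expand.grid(ci = chem_m, di = dis_m)
  cooc <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    ci <- grid$ci[g]; di <- grid$di[g]
    cs <- alignment$sent[ci]; ds <- alignment$sent[di]
    wins <- which(vapply(windows, function(win)
      in_window(cs, win) && in_window(ds, win), logical(1)))
    if (!length(wins)) return(NULL)
    data.frame(ci = ci, di = di,
               chem = men$concept[ci], dis = men$concept[di],
               span_lo = min(cs, ds), span_hi = max(cs, ds),
               wins = I(list(wins)))
  }))
  if (is.null(cooc)) return(list())

  keys <- unique(cooc[, c("chem", "dis")])
  gold <- paste(doc$relations$chemical, doc$relations$disease)
  out <- lapply(seq_len(nrow(keys)), function(ki) {
    rows <- cooc[cooc$chem == keys$chem[ki] & cooc$dis == keys$dis[ki], ,
                 drop = FALSE]
    rows <- minimal_span_filter(rows)
    paths <- list()
    for (r in seq_len(nrow(rows))) {
      ci <- rows$ci[r]; di <- rows$di[r]
      for (wi in rows$wins[[r]]) {
        sg <- get_sg(wi)
        src <- subgraph_node(sg, alignment$sent[ci], alignment$head_tok[ci])
        tgt <- subgraph_node(sg, alignment$sent[di], alignment$head_tok[di])
        if (is.na(src) || is.na(tgt) || src == tgt) next
        found <- find_paths(sg, src, tgt, md = md, kmax = kmax)
        paths <- c(paths, lapply(found, function(p) path_content(sg, p)))
      }
    }
    label <- if (paste(keys$chem[ki], keys$dis[ki]) %in% gold) "CID" else "NONE"
    inst <- merge_instances(doc$id, keys$chem[ki], keys$dis[ki], paths, label)
    select_top_k(inst, k = top_k, strategy = strategy)
  })
  out
}

#' Dump candidate instances as JSON lines
#'
#' One JSON object per line: key, label, paths (each an alternating list
#' of token and edge elements) and multiplicities.
#'
#' @param instances list of `candidate_instance`.
#' @param file optional path.
#' @return character vector of JSON lines (invisibly when written).
#' @export
instances_to_jsonl <- function(instances, file = NULL) {
  lines <- vapply(instances, function(inst) {
    paths <- lapply(inst$paths, function(p) {
      n <- nrow(p$tokens)
      elems <- vector("list", 2L * n - 1L)
      for (i in seq_len(n)) {
        elems[[2L * i - 1L]] <- list(kind = "token",
                                     surface = p$tokens$surface[i],
                                     pos = p$tokens$pos[i],
                                     sent = p$tokens$sent[i],
                                     tok = p$tokens$tok[i])
        if (i < n) {
          elems[[2L * i]] <- list(kind = "edge", label = p$edges$label[i],
                                  category = p$edges$category[i],
                                  direction = p$edges$direction[i])
        }
      }
      list(elements = elems, multiplicity = p$multiplicity)
    })
    jsonlite::toJSON(list(doc = inst$doc, chemical = inst$chemical,
                          disease = inst$disease, label = inst$label,
                          paths = paths),
                     auto_unbox = TRUE)
  }, character(1))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.candidate_instance <- function(x, ...) {
  cat(sprintf("<candidate_instance> %s: %s-%s [%s], %d paths\n",
              x$doc, x$chemical, x$disease, x$label, length(x$paths)))
  invisible(x)
}
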