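#' Synthetic corpus generator specification
#'
#' Defines the study conditions of the synthetic chemical-disease corpus:
#' document count, sentence counts, concept inventories, the rate of
#' documents carrying a planted CID relation, the intra-sentence fraction
#' of those relations (default 0.7, mirroring the roughly 30% share of
#' inter-sentence relations in abstract-level corpora), and the trigger
#' lexicon placed on the dependency route of every positive pair.
#'
#' @param n_docs number of documents.
#' @param seed integer; fixes all randomness (same seed, same bytes).
#' @param sent_range integer range of abstract sentences per document.
#' @param n_chem,n_dis sizes of the chemical / disease concept inventories.
#' @param pos_rate fraction of documents carrying one planted relation.
#' @param intra_frac fraction of planted relations that are
#'   intra-sentence; the rest split evenly between title-routed and
#'   consecutive-sentence inter relations.
#' @param trigger_lexicon verbs marking causal evidence.
#' @param word_dim dimension of the synthetic pretrained word vectors.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_docs = 100L, seed = 1L, sent_range = c(4L, 7L),
                           n_chem = 25L, n_dis = 35L, pos_rate = 0.6,
                           intra_frac = 0.7,
                           trigger_lexicon = c("induced", "caused",
                                               "provoked", "triggered"),
                           word_dim = 20L) {
  stopifnot(pos_rate >= 0, pos_rate <= 1, intra_frac >= 0, intra_frac <= 1,
            sent_range[1] >= 3, n_chem >= 1, n_dis >= 2)
  structure(as.list(environment()), class = "generator_spec")
}

# background (control-substance) chemical lexicon; never in gold relations
BG_CHEMS <- c("placebo", "saline", "dextrose", "mannitol")

#' Sentence template library
#'
#' Fixed small dependency-tree shapes used by the generator. Slots
#' `CHEM`, `DIS` and `TRIG` are filled with sampled lexemes. Heads are
#' 1-based token indices (0 = root).
#'
#' @return named list of templates (`tokens`, `pos`, `heads`, `rels`, and
#'   optional slot positions `chem`, `dis`, `trig`).
#' @export
sentence_templates <- function() {
  list(
    title_bg = list(
      tokens = c("CHEM", "treatment", "reduced", "overall", "discomfort"),
      pos = c("NN", "NN", "VBD", "JJ", "NN"),
      heads = c(2L, 3L, 0L, 5L, 3L),
      rels = c("compound", "nsubj", "root", "amod", "dobj"),
      chem = 1L),
    title_active = list(
      tokens = c("CHEM", "modified", "several", "outcomes"),
      pos = c("NN", "VBD", "JJ", "NNS"),
      heads = c(2L, 0L, 4L, 2L),
      rels = c("nsubj", "root", "amod", "dobj"),
      chem = 1L),
    bridge = list(
      tokens = c("Exposure", "TRIG", "severe", "outcomes", "."),
      pos = c("NN", "VBD", "JJ", "NNS", "."),
      heads = c(2L, 0L, 4L, 2L, 2L),
      rels = c("nsubj", "root", "amod", "dobj", "punct"),
      trig = 2L),
    disease_report = list(
      tokens = c("Patients", "VERB", "DIS", "afterwards", "."),
      pos = c("NNS", "VBD", "NN", "RB", "."),
      heads = c(2L, 0L, 2L, 2L, 2L),
      rels = c("nsubj", "root", "dobj", "advmod", "punct"),
      dis = 3L, verb = 2L),
    intra_pos = list(
      tokens = c("The", "CHEM", "TRIG", "acute", "DIS", "."),
      pos = c("DT", "NN", "VBD", "JJ", "NN", "."),
      heads = c(2L, 3L, 0L, 5L, 3L, 3L),
      rels = c("det", "nsubj", "root", "amod", "dobj", "punct"),
      chem = 2L, dis = 5L, trig = 3L),
    intra_neg = list(
      tokens = c("The", "CHEM", "accompanied", "mild", "DIS", "."),
      pos = c("DT", "NN", "VBD", "JJ", "NN", "."),
      heads = c(2L, 3L, 0L, 5L, 3L, 3L),
      rels = c("det", "nsubj", "root", "amod", "dobj", "punct"),
      chem = 2L, dis = 5L),
    chem_trigger = list(
      tokens = c("The", "CHEM", "TRIG", "adverse", "reactions", "."),
      pos = c("DT", "NN", "VBD", "JJ", "NNS", "."),
      heads = c(2L, 3L, 0L, 5L, 3L, 3L),
      rels = c("det", "nsubj", "root", "amod", "dobj", "punct"),
      chem = 2L, trig = 3L),
    chem_plain = list(
      tokens = c("The", "CHEM", "remained", "stable", "."),
      pos = c("DT", "NN", "VBD", "JJ", "."),
      heads = c(2L, 3L, 0L, 3L, 3L),
      rels = c("det", "nsubj", "root", "acomp", "punct"),
      chem = 2L),
    filler = list(
      tokens = c("The", "clinical", "study", "continued", "normally", "."),
      pos = c("DT", "JJ", "NN", "VBD", "RB", "."),
      heads = c(3L, 3L, 4L, 0L, 4L, 4L),
      rels = c("det", "amod", "nsubj", "root", "advmod", "punct")),
    filler2 = list(
      tokens = c("Doctors", "recorded", "all", "measurements", "."),
      pos = c("NNS", "VBD", "DT", "NNS", "."),
      heads = c(2L, 0L, 4L, 2L, 2L),
      rels = c("nsubj", "root", "det", "dobj", "punct"))
  )
}

# neutral verbs used as roots of disease-report sentences
REPORT_VERBS <- c("developed", "showed", "exhibited", "reported")

#' Instantiate a sentence template as a parsed sentence
#'
#' Fills the `CHEM`/`DIS`/`TRIG`/`VERB` slots of a template and returns
#' the corresponding dependency tree (character spans unset; the corpus
#' assembler fills them).
#'
#' @param template a template from [sentence_templates()] or its name.
#' @param chem,dis,trig,verb slot fillers (surfaces).
#' @return a `parsed_sentence` plus attribute `slots` (the filled slot
#'   token indices).
#' @export
generate_parse <- function(template, chem = NULL, dis = NULL, trig = NULL,
                           verb = NULL) {
  if (is.character(template)) template <- sentence_templates()[[template]]
  stopifnot(is.list(template))
  toks <- template$tokens
  if (!is.null(template$chem) && !is.null(chem)) toks[template$chem] <- chem
  if (!is.null(template$dis) && !is.null(dis)) toks[template$dis] <- dis
  if (!is.null(template$trig) && !is.null(trig)) toks[template$trig] <- trig
  if (!is.null(template$verb) && !is.null(verb)) toks[template$verb] <- verb
  if (any(toks %in% c("CHEM", "DIS", "TRIG", "VERB"))) {
    stop("template slot left unfilled", call. = FALSE)
  }
  ps <- new_parsed_sentence(
    tokens = data.frame(surface = toks, pos = template$pos,
                        begin = NA_integer_, end = NA_integer_),
    heads = template$heads, deprels_raw = template$rels)
  attr(ps, "slots") <- template[intersect(names(template),
                                          c("chem", "dis", "trig", "verb"))]
  ps
}

chem_surface <- function(i) sprintf("chem%02d", i)
chem_concept <- function(i) sprintf("C%03d", i)
dis_surface <- function(i) sprintf("dis%02d", i)
dis_concept <- function(i) sprintf("D%03d", i)
bg_concept <- function(i) sprintf("C9%02d", i)

#' Generate a synthetic corpus with matching parses
#'
#' Emits a PubTator stream, a CoNLL-U stream (with `# doc` ids and
#' `TokenRange` offsets) and the ground-truth locus map. Every document's
#' title carries a chemical mention. Positive documents plant exactly one
#' CID pair whose evidence carries a trigger verb on the dependency route
#' between the mention heads:
#' \describe{
#'   \item{intra}{`chem TRIG disease` inside one sentence.}
#'   \item{title-routed inter}{chemical only in the title; a trigger
#'     bridge sentence S1 and the disease in S2, so the evidence runs
#'     title root - TITLE edge - bridge root - NEXT-SENT - disease.}
#'   \item{consecutive-sentence inter}{chemical sentence with trigger
#'     root, disease in the following sentence, evidence over the
#'     NEXT-SENT edge.}
#' }
#' Negative documents mirror the same surface statistics without
#' triggers (co-occurrence sentences, disease-only sentences, and
#' active-chemical titles without relations), so trigger-free routes are
#' never predictive of the positive class.
#'
#' @param spec a [generator_spec()].
#' @return list with `pubtator`, `conllu` (single strings), `locus`
#'   (data.frame `doc`, `chemical`, `disease`, `locus`, `route`), and
#'   `doc_ids`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n_docs == 0L) {
    return(list(pubtator = "", conllu = "",
                locus = data.frame(doc = character(), chemical = character(),
                                   disease = character(), locus = character(),
                                   route = character()),
                doc_ids = character()))
  }
  local_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    parses <- vector("list", spec$n_docs)
    locus <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- as.character(200000L + d)
      u <- stats::runif(1)
      kind <- if (u < spec$pos_rate) {
        if (stats::runif(1) < spec$intra_frac) "intra"
        else if (stats::runif(1) < 0.5) "title_route" else "next_sent"
      } else {
        if (stats::runif(1) < 0.5) "neg_bg" else "neg_title"
      }
      built <- build_synthetic_doc(spec, doc_id, kind)
      docs[[d]] <- built$doc
      parses[[d]] <- built$parses
      if (!is.null(built$locus)) locus[[length(locus) + 1L]] <- built$locus
    }
    locus <- if (length(locus)) do.call(rbind, locus) else
      data.frame(doc = character(), chemical = character(),
                 disease = character(), locus = character(),
                 route = character())
    list(pubtator = write_pubtator(docs),
         conllu = write_conllu(do.call(c, parses)),
         locus = locus,
         doc_ids = vapply(docs, `[[`, "", "id"))
  })
}

# build one synthetic document of the given kind
build_synthetic_doc <- function(spec, doc_id, kind) {
  n_sent <- sample(seq(spec$sent_range[1], spec$sent_range[2]), 1L)
  trig <- function() sample(spec$trigger_lexicon, 1L)
  rverb <- function() sample(REPORT_VERBS, 1L)
  chem_i <- sample.int(spec$n_chem, 1L)
  dis_pool <- sample.int(spec$n_dis, min(4L, spec$n_dis))
  bg_i <- sample.int(length(BG_CHEMS), 1L)
  sent <- vector("list", n_sent)          # parsed sentences
  ment <- vector("list", n_sent + 1L)     # per-sentence mention slot info
  add_ment <- function(si, ps) {
    slots <- attr(ps, "slots")
    rows <- NULL
    if (!is.null(slots$chem)) {
      surf <- ps$tokens$surface[slots$chem]
      conc <- if (surf %in% BG_CHEMS) bg_concept(match(surf, BG_CHEMS))
              else chem_concept(as.integer(sub("chem", "", surf)))
      rows <- rbind(rows, data.frame(tok = slots$chem, type = "Chemical",
                                     concept = conc))
    }
    if (!is.null(slots$dis)) {
      surf <- ps$tokens$surface[slots$dis]
      rows <- rbind(rows, data.frame(tok = slots$dis, type = "Disease",
                      concept = dis_concept(as.integer(sub("dis", "", surf)))))
    }
    ment[si + 1L] <<- list(rows)   # may be NULL; keep the slot
    ps
  }
  fill_rest <- function(free, extra_dis) {
    # place extra (unrelated) disease sentences, fillers elsewhere
    slots <- free
    picked <- head(slots, extra_dis)
    for (si in free) {
      if (si %in% picked) {
        di <- dis_pool[1L + (match(si, picked) %% length(dis_pool))]
        sent[[si]] <<- add_ment(si, generate_parse("disease_report",
                                                   dis = dis_surface(di),
                                                   verb = rverb()))
      } else {
        sent[[si]] <<- add_ment(si, generate_parse(
          sample(c("filler", "filler2"), 1L)))
      }
    }
  }
  gold <- NULL; loc <- NULL
  if (kind == "intra") {
    title <- add_ment(0L, generate_parse("title_bg", chem = BG_CHEMS[bg_i]))
    e <- sample.int(n_sent, 1L)
    di <- dis_pool[1]
    sent[[e]] <- add_ment(e, generate_parse("intra_pos",
                                            chem = chem_surface(chem_i),
                                            dis = dis_surface(di),
                                            trig = trig()))
    free <- setdiff(seq_len(n_sent), e)
    far <- free[abs(free - e) >= 2L]
    n_extra <- min(sample(0:2, 1L), length(far))
    for (si in free) {
      if (si %in% head(far, n_extra)) {
        dj <- dis_pool[1L + (match(si, head(far, n_extra)) %% length(dis_pool))]
        if (dj == di) dj <- dis_pool[length(dis_pool)]
        sent[[si]] <- add_ment(si, generate_parse("disease_report",
                                                  dis = dis_surface(dj),
                                                  verb = rverb()))
      } else {
        sent[[si]] <- add_ment(si, generate_parse(
          sample(c("filler", "filler2"), 1L)))
      }
    }
    gold <- data.frame(chemical = chem_concept(chem_i), disease = dis_concept(di))
    loc <- data.frame(doc = doc_id, chemical = gold$chemical,
                      disease = gold$disease, locus = "intra", route = "intra")
  } else if (kind == "title_route") {
    title <- add_ment(0L, generate_parse("title_active",
                                         chem = chem_surface(chem_i)))
    di <- dis_pool[1]
    sent[[1L]] <- add_ment(1L, generate_parse("bridge", trig = trig()))
    sent[[2L]] <- add_ment(2L, generate_parse("disease_report",
                                              dis = dis_surface(di),
                                              verb = rverb()))
    free <- setdiff(seq_len(n_sent), 1:2)
    n_extra <- min(sample(1:2, 1L), length(free))
    extras <- head(free, n_extra)
    for (si in free) {
      if (si %in% extras) {
        dj <- dis_pool[1L + (match(si, extras) %% length(dis_pool))]
        if (dj == di) dj <- dis_pool[length(dis_pool)]
        sent[[si]] <- add_ment(si, generate_parse("disease_report",
                                                  dis = dis_surface(dj),
                                                  verb = rverb()))
      } else {
        sent[[si]] <- add_ment(si, generate_parse(
          sample(c("filler", "filler2"), 1L)))
      }
    }
    gold <- data.frame(chemical = chem_concept(chem_i), disease = dis_concept(di))
    loc <- data.frame(doc = doc_id, chemical = gold$chemical,
                      disease = gold$disease, locus = "inter", route = "title")
  } else if (kind == "next_sent") {
    title <- add_ment(0L, generate_parse("title_bg", chem = BG_CHEMS[bg_i]))
    i <- sample.int(n_sent - 1L, 1L)
    di <- dis_pool[1]
    sent[[i]] <- add_ment(i, generate_parse("chem_trigger",
                                            chem = chem_surface(chem_i),
                                            trig = trig()))
    sent[[i + 1L]] <- add_ment(i + 1L, generate_parse("disease_report",
                                                      dis = dis_surface(di),
                                                      verb = rverb()))
    for (si in setdiff(seq_len(n_sent), c(i, i + 1L))) {
      sent[[si]] <- add_ment(si, generate_parse(
        sample(c("filler", "filler2"), 1L)))
    }
    gold <- data.frame(chemical = chem_concept(chem_i), disease = dis_concept(di))
    loc <- data.frame(doc = doc_id, chemical = gold$chemical,
                      disease = gold$disease, locus = "inter",
                      route = "nextsent")
  } else if (kind == "neg_bg") {
    title <- add_ment(0L, generate_parse("title_bg", chem = BG_CHEMS[bg_i]))
    e <- sample.int(n_sent, 1L)
    di <- dis_pool[1]
    sent[[e]] <- add_ment(e, generate_parse("intra_neg",
                                            chem = chem_surface(chem_i),
                                            dis = dis_surface(di)))
    free <- setdiff(seq_len(n_sent), e)
    if (length(free) && stats::runif(1) < 0.5) {
      sent[[free[1]]] <- add_ment(free[1], generate_parse(
        "chem_plain", chem = chem_surface(sample.int(spec$n_chem, 1L))))
      free <- free[-1]
    }
    fill_rest(free, min(sample(0:2, 1L), length(free)))
  } else {                               # neg_title
    title <- add_ment(0L, generate_parse("title_active",
                                         chem = chem_surface(chem_i)))
    fill_rest(seq_len(n_sent), min(sample(1:3, 1L), n_sent))
  }
  assembled <- assemble_doc(doc_id, title, sent, ment, gold)
  list(doc = assembled$doc, parses = assembled$parses, locus = loc)
}

# compute character offsets, build the document record and final parses
assemble_doc <- function(doc_id, title, sent, ment, gold) {
  all_ps <- c(list(title), sent)
  cursor <- 0L
  mention_rows <- list()
  texts <- character(length(all_ps))
  for (si in seq_along(all_ps)) {
    ps <- all_ps[[si]]
    surf <- ps$tokens$surface
    begins <- integer(length(surf)); ends <- integer(length(surf))
    pos <- cursor
    for (ti in seq_along(surf)) {
      begins[ti] <- pos
      ends[ti] <- pos + nchar(surf[ti])
      pos <- ends[ti] + 1L                 # single space between tokens
    }
    texts[si] <- paste(surf, collapse = " ")
    ps$tokens$begin <- begins
    ps$tokens$end <- ends
    ps$doc <- doc_id
    all_ps[[si]] <- ps
    mrows <- ment[[si]]
    if (!is.null(mrows)) {
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        begin = begins[mrows$tok], end = ends[mrows$tok],
        surface = surf[mrows$tok], type = mrows$type, concept = mrows$concept)
    }
    cursor <- ends[length(ends)] + 1L      # separator / inter-sentence space
  }
  mentions <- if (length(mention_rows)) do.call(rbind, mention_rows) else
    data.frame(begin = integer(), end = integer(), surface = character(),
               type = character(), concept = character())
  relations <- if (!is.null(gold)) gold else
    data.frame(chemical = character(), disease = character())
  doc <- new_document_record(doc_id, texts[1],
                             paste(texts[-1], collapse = " "),
                             mentions, relations)
  list(doc = doc, parses = all_ps)
}

#' Synthetic pretrained word vectors
#'
#' Produces class-structured vectors in word2vec text format for the
#' generator's full vocabulary: words of one lexical class (active
#' chemicals, control substances, diseases, trigger verbs, neutral verbs,
#' everything else) share a class mean plus small per-word noise,
#' emulating the cluster structure of real pretrained embeddings.
#'
#' @param spec a [generator_spec()].
#' @return word2vec text (single string).
#' @export
generate_word_vectors <- function(spec) {
  tpl <- sentence_templates()
  base <- unique(unlist(lapply(tpl, `[[`, "tokens")))
  base <- setdiff(base, c("CHEM", "DIS", "TRIG", "VERB"))
  vocab <- list(
    chem = chem_surface(seq_len(spec$n_chem)),
    bgchem = BG_CHEMS,
    disease = dis_surface(seq_len(spec$n_dis)),
    trigger = spec$trigger_lexicon,
    verb = unique(c(REPORT_VERBS, "reduced", "modified", "accompanied",
                    "remained", "continued", "recorded")),
    filler = setdiff(base, c(spec$trigger_lexicon, REPORT_VERBS,
                             "reduced", "modified", "accompanied",
                             "remained", "continued", "recorded")))
  local_seed(spec$seed + 7919L, {
    classes <- names(vocab)
    means <- lapply(classes, function(cl) stats::rnorm(spec$word_dim))
    names(means) <- classes
    rows <- list()
    for (cl in classes) {
      for (w in vocab[[cl]]) {
        rows[[w]] <- means[[cl]] + stats::rnorm(spec$word_dim, 0, 0.15)
      }
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- names(rows)
    write_word_vectors(mat)
  })
}
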