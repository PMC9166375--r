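#' Build labeled candidate instances for a corpus
#'
#' Runs the mining pipeline ([mine_document()]) over every document:
#' one instance per document-level (chemical concept, disease concept)
#' pair with at least one co-occurrence in some width-`w` window, labeled
#' CID when the pair is a gold relation. Gold pairs that never co-occur
#' (entities farther apart than the window allows) are excluded from the
#' instances and returned as `uncovered`; they count as misses at
#' evaluation time.
#'
#' @param docs list of `document_record`.
#' @param parses_by_doc named list: document id -> parses.
#' @param w window width.
#' @param config an [edge_config()].
#' @param coref_by_doc optional named list of coreference tables.
#' @param kb optional knowledge-base pair table.
#' @param md,kmax,top_k,strategy mining parameters.
#' @return list with `instances` (flat list of `candidate_instance`) and
#'   `uncovered` (data.frame `doc`, `chemical`, `disease`).
#' @export
build_instances <- function(docs, parses_by_doc, w, config = edge_config(),
                            coref_by_doc = NULL, kb = NULL, md = 15L,
                            kmax = 150L, top_k = 3, strategy = "shortest") {
  instances <- list()
  uncovered <- list()
  for (doc in docs) {
    parses <- parses_by_doc[[doc$id]]
    if (is.null(parses)) stop(sprintf("no parses for document %s", doc$id),
                              call. = FALSE)
    found <- mine_document(doc, parses, w, config = config,
                           coref = coref_by_doc[[doc$id]], kb = kb, md = md,
                           kmax = kmax, top_k = top_k, strategy = strategy)
    instances <- c(instances, found)
    if (nrow(doc$relations)) {
      covered <- vapply(found, function(x) paste(x$chemical, x$disease),
                        character(1))
      gp <- paste(doc$relations$chemical, doc$relations$disease)
      miss <- which(!(gp %in% covered))
      if (length(miss)) {
        uncovered[[length(uncovered) + 1L]] <- data.frame(
          doc = doc$id, chemical = doc$relations$chemical[miss],
          disease = doc$relations$disease[miss])
      }
    }
  }
  uncovered <- if (length(uncovered)) do.call(rbind, uncovered) else
    data.frame(doc = character(), chemical = character(), disease = character())
  list(instances = instances, uncovered = uncovered)
}

#' Classify a concept pair as intra- or inter-sentence
#'
#' A pair is intra-sentence when some single sentence (the title
#' included) contains mentions of both concepts; otherwise it is
#' inter-sentence.
#'
#' @param doc a `document_record`.
#' @param chemical,disease concept identifiers.
#' @return `"intra"` or `"inter"`.
#' @export
classify_relation_locus <- function(doc, chemical, disease) {
  men <- doc$mentions
  cs <- mention_sentence(men[men$concept == chemical, , drop = FALSE],
                         doc$sent_spans)
  ds <- mention_sentence(men[men$concept == disease, , drop = FALSE],
                         doc$sent_spans)
  if (!length(cs) || !length(ds)) {
    stop(sprintf("locus error [%s]: pair (%s, %s) has no mentions",
                 doc$id, chemical, disease), call. = FALSE)
  }
  if (length(intersect(cs, ds))) "intra" else "inter"
}

locus_for_keys <- function(docs, keys) {
  by_id <- stats::setNames(docs, vapply(docs, `[[`, "", "id"))
  keys$locus <- vapply(seq_len(nrow(keys)), function(i) {
    classify_relation_locus(by_id[[keys$doc[i]]], keys$chemical[i],
                            keys$disease[i])
  }, character(1))
  keys
}

report_triplet <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(tp = tp, fp = fp, fn = fn,
    precision = round_half_up(100 * p), recall = round_half_up(100 * r),
    f1 = round_half_up(100 * f1))
}

#' Micro-averaged evaluation with intra/inter split
#'
#' Compares predicted CID pairs against gold pairs over
#' (document, chemical, disease) keys. Precision = TP/(TP+FP),
#' recall = TP/(TP+FN) and F1 is their harmonic mean (0 when undefined),
#' reported in percent with two decimals (half-up). Gold pairs absent
#' from the predictions (e.g. uncovered pairs) count as false negatives.
#' The intra (inter) sub-report excludes all inter (intra) pairs from
#' both gold and predictions, using the supplied locus map.
#'
#' @param predictions data.frame `doc`, `chemical`, `disease`, `label`.
#' @param gold data.frame `doc`, `chemical`, `disease` (all relations).
#' @param locus data.frame `doc`, `chemical`, `disease`, `locus` covering
#'   every predicted-CID and gold key.
#' @return an `eval_report`: list `overall`, `intra`, `inter`, each with
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate <- function(predictions, gold, locus) {
  key <- function(df) paste(df$doc, df$chemical, df$disease)
  pred_cid <- unique(key(predictions[predictions$label == "CID", , drop = FALSE]))
  gold_k <- unique(key(gold))
  loc_map <- stats::setNames(locus$locus, key(locus))
  need <- setdiff(c(pred_cid, gold_k), names(loc_map))
  if (length(need)) {
    stop(sprintf("locus map is missing %d keys (first: %s)", length(need),
                 need[1]), call. = FALSE)
  }
  one <- function(filter_locus = NULL) {
    pk <- pred_cid; gk <- gold_k
    if (!is.null(filter_locus)) {
      pk <- pk[loc_map[pk] == filter_locus]
      gk <- gk[loc_map[gk] == filter_locus]
    }
    report_triplet(length(intersect(pk, gk)), length(setdiff(pk, gk)),
                   length(setdiff(gk, pk)))
  }
  structure(list(overall = one(), intra = one("intra"), inter = one("inter")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%-8s %6s %6s %6s %9s %9s %9s\n", "", "TP", "FP", "FN",
              "P(%)", "R(%)", "F1(%)"))
  for (nm in c("overall", "intra", "inter")) {
    v <- x[[nm]]
    cat(sprintf("%-8s %6d %6d %6d %9.2f %9.2f %9.2f\n", nm, v[["tp"]],
                v[["fp"]], v[["fn"]], v[["precision"]], v[["recall"]],
                v[["f1"]]))
  }
  invisible(x)
}

#' Strict-majority-vote ensemble of prediction runs
#'
#' A pair is predicted CID when strictly more than half of the runs
#' predict CID; ties go to NONE.
#'
#' @param runs list of prediction data.frames (`doc`, `chemical`,
#'   `disease`, `label`), all covering the same keys.
#' @return a prediction data.frame with the voted labels and `votes`.
#' @export
ensemble_vote <- function(runs) {
  stopifnot(length(runs) >= 1)
  key <- function(df) paste(df$doc, df$chemical, df$disease)
  k0 <- key(runs[[1]])
  votes <- integer(length(k0))
  for (run in runs) {
    if (!identical(sort(key(run)), sort(k0))) {
      stop("ensemble error: runs cover different instance keys", call. = FALSE)
    }
    m <- match(k0, key(run))
    votes <- votes + (run$label[m] == "CID")
  }
  out <- runs[[1]][, c("doc", "chemical", "disease")]
  out$label <- ifelse(votes > length(runs) / 2, "CID", "NONE")
  out$votes <- votes
  out
}

#' Run a full train/evaluate experiment
#'
#' Builds training instances with window width `w_train` (plus optional
#' distant-supervision documents, ingested through the same pipeline with
#' weight 1), development and test instances with `w_test`, trains the
#' shared-weight CNN (optionally as an n-run strict-majority ensemble),
#' and evaluates document-level predictions with the intra/inter split.
#' Uncovered gold pairs count as false negatives.
#'
#' @param train_docs,dev_docs,test_docs lists of `document_record`.
#' @param parses_by_doc named list: document id -> parses.
#' @param word_vectors word-vector matrix (see [read_word_vectors()]).
#' @param w_train,w_test window widths for training and testing.
#' @param config an [edge_config()]; the default enables only the TITLE
#'   and NEXT-SENT families.
#' @param enc_config,sw_config model configurations.
#' @param top_k,strategy,md,kmax mining parameters.
#' @param coref_by_doc,kb optional virtual-edge inputs.
#' @param distant_docs optional extra training documents.
#' @param n_runs ensemble size (1 = single run).
#' @param seed base seed; run i uses `seed + i - 1`.
#' @param verbose print training progress.
#' @return list with `report` (an `eval_report`), `predictions`,
#'   `models`, `locus`, `uncovered`, and the echoed `config`.
#' @export
run_experiment <- function(train_docs, dev_docs, test_docs, parses_by_doc,
                           word_vectors, w_train = 5L, w_test = 2L,
                           config = edge_config(coref_sent = FALSE,
                                                coref_to_title = FALSE,
                                                coref_from_title = FALSE,
                                                kb_ctd = FALSE),
                           enc_config = compact_encoder_config(
                             word_dim = ncol(word_vectors)),
                           sw_config = compact_swcnn_config(),
                           top_k = 3, strategy = "shortest", md = 15L,
                           kmax = 150L, coref_by_doc = NULL, kb = NULL,
                           distant_docs = NULL, n_runs = 1L, seed = 1L,
                           verbose = FALSE) {
  mine <- function(docs, w) {
    build_instances(docs, parses_by_doc, w, config = config,
                    coref_by_doc = coref_by_doc, kb = kb, md = md,
                    kmax = kmax, top_k = top_k, strategy = strategy)
  }
  train_set <- mine(c(train_docs, distant_docs), w_train)
  dev_set <- mine(dev_docs, w_test)
  test_set <- mine(test_docs, w_test)

  models <- list()
  runs <- list()
  for (i in seq_len(n_runs)) {
    model <- train_swcnn(train_set$instances, dev_set$instances,
                         parses_by_doc, word_vectors, enc_config, sw_config,
                         seed = seed + i - 1L, verbose = verbose)
    models[[i]] <- model
    runs[[i]] <- predict_swcnn(model, test_set$instances, parses_by_doc)
  }
  predictions <- if (n_runs > 1L) ensemble_vote(runs) else runs[[1]]

  gold <- do.call(rbind, lapply(test_docs, function(d) {
    if (!nrow(d$relations)) return(NULL)
    data.frame(doc = d$id, chemical = d$relations$chemical,
               disease = d$relations$disease)
  }))
  if (is.null(gold)) {
    gold <- data.frame(doc = character(), chemical = character(),
                       disease = character())
  }
  keys <- unique(rbind(predictions[, c("doc", "chemical", "disease")], gold))
  locus <- locus_for_keys(test_docs, keys)
  report <- evaluate(predictions, gold, locus)
  list(report = report, predictions = predictions, models = models,
       locus = locus, uncovered = test_set$uncovered,
       config = list(w_train = w_train, w_test = w_test,
                     edge_config = config, top_k = top_k,
                     strategy = strategy, md = md, kmax = kmax,
                     n_runs = n_runs, seed = seed,
                     enc_config = enc_config, sw_config = sw_config))
}

#' Synthetic-recovery experiment
#'
#' Generates a seeded synthetic corpus, splits it 70/15/15 into
#' train/development/test documents, and runs the standard experiment
#' (train with `w_train`, predict with `w_test`). Optionally repeats the
#' evaluation with `w = 1` for both training and testing, and with TITLE
#' edges disabled, to expose the window-width and title-routing effects.
#'
#' @param seed integer seed driving the generator and the model.
#' @param n_docs corpus size (default 500).
#' @param w_train,w_test window widths of the main run.
#' @param with_w1 also run the `w = 1` train/test condition.
#' @param with_title_ablation also run with TITLE edges disabled.
#' @param verbose print training progress.
#' @return list with `report`, `locus`, `result` (the main run), and
#'   optionally `report_w1`, `report_no_title`.
#' @export
run_synthetic_experiment <- function(seed = 1L, n_docs = 500L, w_train = 5L,
                                     w_test = 2L, with_w1 = FALSE,
                                     with_title_ablation = FALSE,
                                     verbose = FALSE) {
  spec <- generator_spec(n_docs = n_docs, seed = seed)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  parses_by_doc <- split_parses_by_doc(read_conllu(text = corpus$conllu,
                                                   quiet = TRUE))
  wv <- read_word_vectors(text = generate_word_vectors(spec))
  n <- length(docs)
  i_train <- seq_len(floor(0.7 * n))
  i_dev <- seq.int(floor(0.7 * n) + 1L, floor(0.85 * n))
  i_test <- seq.int(floor(0.85 * n) + 1L, n)
  run <- function(w_tr, w_te, cfg) {
    run_experiment(docs[i_train], docs[i_dev], docs[i_test], parses_by_doc,
                   wv, w_train = w_tr, w_test = w_te, config = cfg,
                   seed = seed, verbose = verbose)
  }
  cfg_main <- edge_config(coref_sent = FALSE, coref_to_title = FALSE,
                          coref_from_title = FALSE, kb_ctd = FALSE)
  main <- run(w_train, w_test, cfg_main)
  out <- list(report = main$report, locus = corpus$locus, result = main)
  if (with_w1) {
    out$report_w1 <- run(1L, 1L, cfg_main)$report
  }
  if (with_title_ablation) {
    cfg_nt <- edge_config(title = FALSE, coref_sent = FALSE,
                          coref_to_title = FALSE, coref_from_title = FALSE,
                          kb_ctd = FALSE)
    out$report_no_title <- run(w_train, w_test, cfg_nt)$report
  }
  out
}
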