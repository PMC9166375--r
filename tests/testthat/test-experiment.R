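test_that("instance building covers pairs by window and records uncovered gold", {
  td <- tiny_doc()
  parses <- list(`777` = td$parses)
  built <- build_instances(list(td$doc), parses, w = 2L)
  keys <- vapply(built$instances, function(x) paste(x$chemical, x$disease), "")
  expect_setequal(keys, c("C001 D001", "C001 D002"))
  expect_identical(nrow(built$uncovered), 0L)

  # brute-force pair-by-window enumeration oracle on generated documents
  spec <- generator_spec(n_docs = 12L, seed = 31L)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  pbd <- split_parses_by_doc(read_conllu(text = corpus$conllu, quiet = TRUE))
  for (w in c(1L, 3L)) {
    built <- build_instances(docs, pbd, w = w)
    got <- sort(vapply(built$instances, function(x)
      paste(x$doc, x$chemical, x$disease), ""))
    want <- character(0)
    for (doc in docs) {
      al <- align_mentions(doc, pbd[[doc$id]])
      men <- doc$mentions
      wins <- enumerate_windows(nrow(doc$sent_spans) - 1L, w)
      for (ci in which(men$type == "Chemical")) {
        for (di in which(men$type == "Disease")) {
          hit <- any(vapply(wins, function(win) {
            (al$sent[ci] == 0L || al$sent[ci] %in% win$sentences) &&
              (al$sent[di] == 0L || al$sent[di] %in% win$sentences)
          }, TRUE))
          if (hit) want <- c(want, paste(doc$id, men$concept[ci], men$concept[di]))
        }
      }
    }
    expect_identical(got, sort(unique(want)))
  }
})

test_that("a gold pair beyond the window span is excluded and reported", {
  pub <- paste(
    "88|t|study of chemq",
    "88|a|The chemq arm continued . A . B . C . D . Some disq appeared .",
    "88\t9\t14\tchemq\tChemical\tC005",
    "88\t19\t24\tchemq\tChemical\tC005",
    "88\t62\t66\tdisq\tDisease\tD005",
    "88\tCID\tC005\tD005",
    sep = "\n")
  con_sent <- function(doc, toks, heads, rels, poss, start) {
    rows <- character(0)
    pos <- start
    for (i in seq_along(toks)) {
      rows <- c(rows, sprintf("%d\t%s\t_\t%s\t%s\t_\t%d\t%s\t_\tTokenRange=%d:%d",
                              i, toks[i], poss[i], poss[i], heads[i], rels[i],
                              pos, pos + nchar(toks[i])))
      pos <- pos + nchar(toks[i]) + 1L
    }
    paste(c(sprintf("# doc = %s", doc), rows), collapse = "\n")
  }
  blocks <- c(
    con_sent("88", c("study", "of", "chemq"), c(0, 1, 2), c("root", "prep", "pobj"),
             c("NN", "IN", "NN"), 0L),
    con_sent("88", c("The", "chemq", "arm", "continued", "."), c(3, 3, 4, 0, 4),
             c("det", "compound", "nsubj", "root", "punct"), c("DT", "NN", "NN", "VBD", "."), 15L),
    con_sent("88", c("A", "."), c(0, 1), c("root", "punct"), c("NN", "."), 41L),
    con_sent("88", c("B", "."), c(0, 1), c("root", "punct"), c("NN", "."), 45L),
    con_sent("88", c("C", "."), c(0, 1), c("root", "punct"), c("NN", "."), 49L),
    con_sent("88", c("D", "."), c(0, 1), c("root", "punct"), c("NN", "."), 53L),
    con_sent("88", c("Some", "disq", "appeared", "."), c(2, 3, 0, 3),
             c("det", "nsubj", "root", "punct"), c("DT", "NN", "VBD", "."), 57L))
  doc <- read_pubtator(text = pub)[[1]]
  parses <- read_conllu(text = paste(blocks, collapse = "\n\n"), quiet = TRUE)
  pbd <- list(`88` = parses)

  # title mention keeps the pair coverable at any width; drop it to expose
  # the pure window bound (chemical in S1, disease in S6, 5 sentences apart)
  doc$mentions <- doc$mentions[-1, ]
  built <- build_instances(list(doc), pbd, w = 5L)
  expect_length(built$instances, 0L)
  expect_identical(built$uncovered,
                   data.frame(doc = "88", chemical = "C005", disease = "D005"))
})

test_that("relation locus distinguishes intra from inter pairs", {
  td <- tiny_doc()
  expect_identical(classify_relation_locus(td$doc, "C001", "D001"), "inter")
  expect_error(classify_relation_locus(td$doc, "C009", "D001"), "no mentions")

  pub <- paste("66|t|about chemr and disr",
               "66|a|Nothing else .",
               "66\t6\t11\tchemr\tChemical\tC007",
               "66\t16\t20\tdisr\tDisease\tD007", sep = "\n")
  doc <- read_pubtator(text = pub)[[1]]
  expect_identical(classify_relation_locus(doc, "C007", "D007"), "intra")

  # the generator's ground-truth locus map agrees with the classifier
  spec <- generator_spec(n_docs = 40L, seed = 17L)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  by_id <- stats::setNames(docs, vapply(docs, `[[`, "", "id"))
  for (i in seq_len(nrow(corpus$locus))) {
    row <- corpus$locus[i, ]
    expect_identical(classify_relation_locus(by_id[[row$doc]], row$chemical,
                                             row$disease), row$locus)
  }
})

test_that("evaluation computes micro P/R/F1 with the intra/inter split", {
  gold <- data.frame(doc = c("1", "1", "2"), chemical = c("C1", "C2", "C1"),
                     disease = c("D1", "D2", "D1"))
  locus <- rbind(cbind(gold, locus = c("intra", "inter", "intra")),
                 data.frame(doc = "2", chemical = "C9", disease = "D9",
                            locus = "inter"))
  perfect <- cbind(gold, label = "CID")
  r <- evaluate(perfect, gold, locus)
  expect_equal(unname(r$overall[c("precision", "recall", "f1")]),
               c(100, 100, 100))

  # TP=2, FP=1, FN=1 -> all three metrics 66.67
  mixed <- data.frame(doc = c("1", "1", "2"), chemical = c("C1", "C2", "C9"),
                      disease = c("D1", "D2", "D9"), label = "CID")
  r2 <- evaluate(mixed, gold, locus)
  expect_equal(unname(r2$overall[c("tp", "fp", "fn")]), c(2, 1, 1))
  expect_equal(unname(r2$overall[c("precision", "recall", "f1")]),
               c(66.67, 66.67, 66.67))

  # counts add across the locus split
  for (f in c("tp", "fp", "fn")) {
    expect_equal(r2$overall[[f]], r2$intra[[f]] + r2$inter[[f]])
  }

  none <- data.frame(doc = character(), chemical = character(),
                     disease = character(), label = character())
  r3 <- evaluate(none, gold, locus)
  expect_equal(unname(r3$overall[c("precision", "recall", "f1")]), c(0, 0, 0))
  expect_equal(unname(r3$overall["fn"]), 3)

  # metrics are invariant to row order
  r4 <- evaluate(mixed[3:1, ], gold[c(2, 3, 1), ], locus)
  expect_identical(r4, r2)
})

test_that("strict majority voting requires more than half of the runs", {
  keyframe <- data.frame(doc = "1", chemical = c("C1", "C2"),
                         disease = c("D1", "D2"))
  mk <- function(labels) cbind(keyframe, label = labels)
  runs20 <- c(replicate(20, mk(c("CID", "CID")), simplify = FALSE))
  expect_identical(ensemble_vote(runs20)$label, c("CID", "CID"))

  half <- c(replicate(10, mk(c("CID", "NONE")), simplify = FALSE),
            replicate(10, mk(c("NONE", "NONE")), simplify = FALSE))
  expect_identical(ensemble_vote(half)$label, c("NONE", "NONE"))

  # ensemble of identical runs equals the single run
  one <- mk(c("CID", "NONE"))
  expect_identical(ensemble_vote(replicate(7, one, simplify = FALSE))$label,
                   one$label)

  # random vote matrices against a counting oracle
  withr::with_seed(55L, {
    for (rep in 1:10) {
      n <- sample(3:9, 1)
      votes <- matrix(sample(c("CID", "NONE"), 2 * n, TRUE), 2, n)
      runs <- lapply(seq_len(n), function(j) mk(votes[, j]))
      want <- ifelse(rowSums(votes == "CID") > n / 2, "CID", "NONE")
      expect_identical(ensemble_vote(runs)$label, unname(want))
    }
  })

  bad <- list(mk(c("CID", "NONE")),
              cbind(data.frame(doc = "9", chemical = "CX", disease = "DX"),
                    label = "CID")[c(1, 1), ])
  expect_error(ensemble_vote(bad), "different instance keys")
})

test_that("a small end-to-end run recovers relations and obeys window bounds", {
  spec <- generator_spec(n_docs = 60L, seed = 3L)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  pbd <- split_parses_by_doc(read_conllu(text = corpus$conllu, quiet = TRUE))
  wv <- read_word_vectors(text = generate_word_vectors(spec))
  res <- run_experiment(docs[1:40], docs[41:50], docs[51:60], pbd, wv,
                        w_train = 3L, w_test = 2L, seed = 3L)
  expect_s3_class(res$report, "eval_report")
  expect_true(res$report$overall[["f1"]] > 0)
  # consecutive-sentence gold pairs are structurally uncovered at w = 1
  built1 <- build_instances(docs, pbd, w = 1L)
  ns <- corpus$locus[corpus$locus$route == "nextsent", ]
  expect_gt(nrow(ns), 0L)
  unc <- paste(built1$uncovered$doc, built1$uncovered$chemical,
               built1$uncovered$disease)
  expect_true(all(paste(ns$doc, ns$chemical, ns$disease) %in% unc))
  # coverage at the test width does not depend on the training width
  built2a <- build_instances(docs, pbd, w = 2L)
  expect_identical(built2a$uncovered, build_instances(docs, pbd, w = 2L)$uncovered)
})
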