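test_that("adjacent endpoints give the single-edge path first", {
  td <- tiny_doc()
  w1 <- enumerate_windows(2L, 1L)[[1]]
  sg <- build_subgraph(td$doc, td$parses, w1)
  src <- subgraph_node(sg, 0L, 1L)   # chemx
  tgt <- subgraph_node(sg, 0L, 2L)   # relieves (its head)
  paths <- find_paths(sg, src, tgt, md = 15L)
  expect_identical(paths[[1]]$nodes, c(src, tgt))
  expect_identical(paths[[1]]$edges$label, "nsubj")
  expect_identical(paths[[1]]$edges$direction, "against")
})

test_that("degenerate or out-of-graph endpoints raise errors", {
  g <- complete_test_graph(4L)
  expect_error(find_paths(g, 2L, 2L), "degenerate-pair")
  expect_error(find_paths(g, 1L, 99L), "not in subgraph")
})

test_that("search equals exhaustive enumeration on a complete graph", {
  g <- complete_test_graph(5L)
  got <- find_paths(g, 1L, 5L, md = 5L, kmax = 1000L)
  want <- brute_force_paths(g, 1L, 5L, md = 5L)
  expect_identical(sort(vapply(got, function(p) path_key(p$nodes), "")),
                   sort(vapply(want, path_key, "")))
  # breadth-first order: nondecreasing node counts, lexicographic ties
  lens <- vapply(got, function(p) length(p$nodes), 1L)
  expect_true(all(diff(lens) >= 0))
  keys <- vapply(got, function(p) path_key(p$nodes), "")
  for (l in unique(lens)) expect_false(is.unsorted(keys[lens == l]))
})

test_that("the path cap and depth bound are enforced", {
  # K7 holds 326 simple paths between two nodes; the cap keeps 150
  g <- complete_test_graph(7L)
  got <- find_paths(g, 1L, 7L, md = 15L, kmax = 150L)
  expect_length(got, 150L)
  # depth bound: all returned paths have at most md nodes
  got4 <- find_paths(g, 1L, 7L, md = 4L, kmax = 1000L)
  expect_true(all(vapply(got4, function(p) length(p$nodes), 1L) <= 4L))
  expect_identical(sort(vapply(got4, function(p) path_key(p$nodes), "")),
                   sort(vapply(brute_force_paths(g, 1L, 7L, md = 4L),
                               path_key, "")))
  # interior nodes never revisit the endpoints
  expect_true(all(vapply(got, function(p) {
    inner <- p$nodes[-c(1L, length(p$nodes))]
    !(1L %in% inner) && !(7L %in% inner)
  }, TRUE)))
})

test_that("search matches the enumeration oracle on random graphs", {
  withr::with_seed(404L, {
    for (rep in seq_len(30L)) {
      n <- sample(3:8, 1L)
      g <- random_test_graph(n, p = runif(1, 0.3, 0.8))
      got <- find_paths(g, 1L, n, md = 8L, kmax = 100000L)
      want <- brute_force_paths(g, 1L, n, md = 8L)
      expect_identical(sort(vapply(got, function(p) path_key(p$nodes), "")),
                       sort(vapply(want, path_key, "")))
    }
  })
})

test_that("search agrees with igraph's simple-path enumeration", {
  withr::with_seed(405L, {
    for (rep in seq_len(10L)) {
      n <- sample(4:8, 1L)
      g <- random_test_graph(n, p = 0.5)
      ig <- igraph::graph_from_edgelist(
        as.matrix(g$edges[, c("from", "to")]), directed = FALSE)
      if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
      want <- igraph::all_simple_paths(ig, 1, n)
      got <- find_paths(g, 1L, n, md = n, kmax = 100000L)
      expect_identical(sort(vapply(got, function(p) path_key(p$nodes), "")),
                       sort(vapply(want, function(p) path_key(as.integer(p)), "")))
    }
  })
})

test_that("minimal-span filtering drops co-occurrences with a strictly tighter rival", {
  single <- data.frame(span_lo = 2L, span_hi = 5L)
  expect_identical(minimal_span_filter(single), single)

  two <- data.frame(span_lo = c(1L, 2L), span_hi = c(4L, 3L))
  kept <- minimal_span_filter(two)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$span_lo, 2L)

  disjoint <- data.frame(span_lo = c(1L, 4L), span_hi = c(2L, 5L))
  expect_identical(nrow(minimal_span_filter(disjoint)), 2L)

  # equal spans: neither strictly contains the other, both stay
  equal <- data.frame(span_lo = c(1L, 1L), span_hi = c(3L, 3L))
  expect_identical(nrow(minimal_span_filter(equal)), 2L)

  # brute-force pairwise containment oracle on random span sets
  withr::with_seed(77L, {
    for (rep in 1:20) {
      n <- sample(2:6, 1L)
      cooc <- data.frame(span_lo = sample(0:5, n, TRUE))
      cooc$span_hi <- cooc$span_lo + sample(0:4, n, TRUE)
      keep <- vapply(seq_len(n), function(i) {
        !any(vapply(seq_len(n), function(j) {
          if (i == j) return(FALSE)
          inside <- cooc$span_lo[j] >= cooc$span_lo[i] &&
            cooc$span_hi[j] <= cooc$span_hi[i]
          strict <- inside && (cooc$span_lo[j] > cooc$span_lo[i] ||
                                 cooc$span_hi[j] < cooc$span_hi[i])
          overlap <- cooc$span_lo[j] <= cooc$span_hi[i] &&
            cooc$span_lo[i] <= cooc$span_hi[j]
          strict && overlap
        }, TRUE))
      }, TRUE)
      expect_identical(minimal_span_filter(cooc), cooc[keep, , drop = FALSE])
    }
  })
})

fake_path <- function(pattern, coords, len, ...) {
  list(pattern = pattern, coords = coords, tokens = data.frame(x = seq_len(len)),
       edges = NULL, ...)
}

test_that("instance merging deduplicates by lexical pattern and records multiplicity", {
  paths <- list(fake_path("a X b", "0:1 0:2", 2L),
                fake_path("a X b", "1:1 1:2", 2L),
                fake_path("a X b", "0:1 0:2", 2L),
                fake_path("a Y c Z b", "0:1 0:3 0:2", 3L))
  inst <- merge_instances("d1", "C1", "D1", paths, label = "CID")
  expect_length(inst$paths, 2L)
  expect_identical(vapply(inst$paths, `[[`, 1L, "multiplicity"), c(3L, 1L))
  expect_identical(inst$label, "CID")

  # merging an already-merged instance changes nothing
  again <- merge_instances("d1", "C1", "D1", inst$paths, label = "CID")
  expect_identical(vapply(again$paths, `[[`, "", "pattern"),
                   vapply(inst$paths, `[[`, "", "pattern"))
  expect_length(again$paths, 2L)
})

test_that("top-k selection honors both strategies and their tie rules", {
  mk <- function(lens, mults) {
    paths <- Map(function(l, m, i) {
      p <- fake_path(sprintf("p%d", i), sprintf("0:%d", i), l)
      p$length <- l; p$multiplicity <- m; p
    }, lens, mults, seq_along(lens))
    structure(list(doc = "d", chemical = "C", disease = "D", label = "NONE",
                   paths = paths), class = "candidate_instance")
  }
  few <- select_top_k(mk(c(3L, 4L), c(1L, 1L)), k = 3)
  expect_length(few$paths, 2L)

  inst <- mk(c(3L, 3L, 4L, 5L, 6L), c(1L, 1L, 1L, 1L, 1L))
  short <- select_top_k(inst, k = 3, strategy = "shortest")
  expect_identical(vapply(short$paths, `[[`, 1L, "length"), c(3L, 3L, 4L))

  inst2 <- mk(c(5L, 3L, 4L, 2L), c(4L, 2L, 2L, 1L))
  freq <- select_top_k(inst2, k = 2, strategy = "most_frequent")
  expect_identical(vapply(freq$paths, `[[`, 1L, "multiplicity"), c(4L, 2L))
  # the multiplicity-2 tie resolves to the shorter path
  expect_identical(freq$paths[[2]]$length, 3L)

  # k = Inf is the identity
  all_kept <- select_top_k(inst2, k = Inf)
  expect_identical(vapply(all_kept$paths, `[[`, "", "pattern"),
                   vapply(inst2$paths, `[[`, "", "pattern"))
})

test_that("document mining merges windows and repeats into one instance per pair", {
  spec <- generator_spec(n_docs = 10L, seed = 21L)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  parses <- split_parses_by_doc(read_conllu(text = corpus$conllu, quiet = TRUE))
  for (doc in docs[1:5]) {
    inst <- mine_document(doc, parses[[doc$id]], w = 3L)
    keys <- vapply(inst, function(x) paste(x$chemical, x$disease), "")
    expect_false(anyDuplicated(keys) > 0)
    # paths inside each instance are pairwise distinct under the dedup key
    for (x in inst) {
      patt <- vapply(x$paths, `[[`, "", "pattern")
      expect_false(anyDuplicated(patt) > 0)
      expect_true(all(vapply(x$paths, `[[`, 1L, "multiplicity") >= 1L))
    }
  }
})

test_that("instance JSON-lines dump is parseable and complete", {
  td <- tiny_doc()
  inst <- mine_document(td$doc, td$parses, w = 2L)
  lines <- instances_to_jsonl(inst)
  expect_length(lines, length(inst))
  parsed <- jsonlite::fromJSON(lines[[1]], simplifyVector = FALSE)
  expect_named(parsed, c("doc", "chemical", "disease", "label", "paths"),
               ignore.order = TRUE)
  expect_identical(parsed$paths[[1]]$elements[[1]]$kind, "token")
  expect_identical(parsed$paths[[1]]$elements[[2]]$kind, "edge")
})
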