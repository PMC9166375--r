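# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive recursive enumeration of simple paths from s to t with at
# most md nodes; written independently of the package's breadth-first
# search (depth-first, no ordering or cap).
brute_force_paths <- function(sg, s, t, md = 15L) {
  e <- sg$edges
  nbrs <- function(v) sort(unique(c(e$to[e$from == v], e$from[e$to == v])))
  res <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) >= md) return(invisible())
    for (nb in nbrs(last)) {
      if (!(nb %in% path)) rec(c(path, nb))
    }
  }
  rec(s)
  res
}

path_key <- function(nodes) paste(nodes, collapse = "-")

# random undirected-ish graph wrapped as a minimal subgraph object
random_test_graph <- function(n, p = 0.4) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  e <- pairs[, keep, drop = FALSE]
  labs <- dep_label_inventory()
  edges <- if (ncol(e)) {
    data.frame(from = e[1, ], to = e[2, ], category = "syntactic",
               label = sample(labs, ncol(e), replace = TRUE), directed = TRUE)
  } else {
    data.frame(from = integer(), to = integer(), category = character(),
               label = character(), directed = logical())
  }
  structure(list(
    nodes = data.frame(sent = 1L, tok = seq_len(n),
                       surface = letters[seq_len(n)], pos = "NN"),
    edges = edges, roots = c(`1` = 1L),
    window = list(start = 1L, width = 1L, sentences = 1L),
    sentences = 1L), class = "document_subgraph")
}

complete_test_graph <- function(n) {
  g <- random_test_graph(n, p = 2)     # every pair kept
  g
}

# hand-written two-sentence document (title + 2 abstract sentences) with
# one chemical and two disease mentions, plus its CoNLL-U parses
tiny_doc_text <- function() {
  pub <- paste(
    "777|t|chemx relieves pain",
    "777|a|Patients got disy quickly . Others got disz too .",
    "777\t0\t5\tchemx\tChemical\tC001",
    "777\t33\t37\tdisy\tDisease\tD001",
    "777\t59\t63\tdisz\tDisease\tD002",
    "777\tCID\tC001\tD001",
    sep = "\n")
  con <- paste(
    "# doc = 777",
    "1\tchemx\t_\tNN\tNN\t_\t2\tnsubj\t_\tTokenRange=0:5",
    "2\trelieves\t_\tVBZ\tVBZ\t_\t0\troot\t_\tTokenRange=6:14",
    "3\tpain\t_\tNN\tNN\t_\t2\tdobj\t_\tTokenRange=15:19",
    "",
    "# doc = 777",
    "1\tPatients\t_\tNNS\tNNS\t_\t2\tnsubj\t_\tTokenRange=20:28",
    "2\tgot\t_\tVBD\tVBD\t_\t0\troot\t_\tTokenRange=29:32",
    "3\tdisy\t_\tNN\tNN\t_\t2\tdobj\t_\tTokenRange=33:37",
    "4\tquickly\t_\tRB\tRB\t_\t2\tadvmod\t_\tTokenRange=38:45",
    "5\t.\t_\t.\t.\t_\t2\tpunct\t_\tTokenRange=46:47",
    "",
    "# doc = 777",
    "1\tOthers\t_\tNNS\tNNS\t_\t2\tnsubj\t_\tTokenRange=48:54",
    "2\tgot\t_\tVBD\tVBD\t_\t0\troot\t_\tTokenRange=55:58",
    "3\tdisz\t_\tNN\tNN\t_\t2\tdobj\t_\tTokenRange=59:63",
    "4\ttoo\t_\tRB\tRB\t_\t2\tadvmod\t_\tTokenRange=64:67",
    "5\t.\t_\t.\t.\t_\t2\tpunct\t_\tTokenRange=68:69",
    sep = "\n")
  list(pubtator = pub, conllu = con)
}

tiny_doc <- function() {
  txt <- tiny_doc_text()
  doc <- read_pubtator(text = txt$pubtator)[[1]]
  parses <- read_conllu(text = txt$conllu, quiet = TRUE)
  list(doc = doc, parses = parses)
}

# small word-vector matrix covering a vocabulary, deterministic
toy_word_vectors <- function(words, dim = 6L, seed = 11L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(m) <- words
  m
}

toy_state <- function(enc, sw, seed = 31L) {
  withr::with_seed(seed, docgraphRE:::init_swcnn_params(enc, sw))
}

# brute-force re-computation of the pooled convolution features: expand
# every window of every path explicitly and take per-filter maxima
oracle_convolve_pool <- function(encoded_paths, state, config) {
  out <- numeric(0)
  for (r in config$region_sizes) {
    W <- state[[sprintf("W_c%d", r)]]
    b <- state[[sprintf("b_c%d", r)]]
    vals <- matrix(NA_real_, 0, ncol(W))
    for (ep in encoded_paths) {
      n <- nrow(ep$x)
      if (n < r) next
      for (j in 1:(n - r + 1)) {
        v <- c()
        for (q in 0:(r - 1)) {
          v <- c(v, ep$x[j + q, ])
          if (q < r - 1) v <- c(v, ep$d[j + q, ])
        }
        vals <- rbind(vals, drop(v %*% W) + b)
      }
    }
    out <- c(out, if (nrow(vals)) apply(vals, 2, max) else rep(0, ncol(W)))
  }
  out
}

random_encoded_path <- function(n, xdim, ddim) {
  list(x = matrix(rnorm(n * xdim), n), d = matrix(rnorm((n - 1) * ddim), n - 1))
}

# tiny trained-model scaffolding: deterministic params for toy dims
toy_setup <- function(n_docs = 12L, seed = 7L, w = 2L) {
  spec <- generator_spec(n_docs = n_docs, seed = seed)
  corpus <- generate_corpus(spec)
  docs <- read_pubtator(text = corpus$pubtator)
  parses <- split_parses_by_doc(read_conllu(text = corpus$conllu, quiet = TRUE))
  wv <- read_word_vectors(text = generate_word_vectors(spec))
  enc <- compact_encoder_config(word_dim = ncol(wv))
  sw <- compact_swcnn_config(dropout = 0, noise_sd = 0)
  insts <- build_instances(docs, parses, w = w)$instances
  params <- init_encoder_params(enc, wv, seed = 3L)
  swp <- docgraphRE:::init_swcnn_params(enc, sw)
  theta <- docgraphRE:::trainable_theta(params, swp)
  list(spec = spec, docs = docs, parses = parses, wv = wv, enc = enc,
       sw = sw, insts = insts, params = params, theta = theta)
}
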