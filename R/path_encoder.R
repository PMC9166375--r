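sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

#' Path encoder configuration
#'
#' Dimensions and switches of the path representation. The defaults are
#' the tuned full-scale configuration: 72x150 dependency-type and 2x150
#' direction tables feeding a 150-dim dependency-unit vector; 300-dim
#' pretrained word vectors, 57x50 POS table (56 OntoNotes tags plus one
#' unknown row), an 85x50 character table with a 50-unit-per-direction
#' bidirectional LSTM, and a fixed 45-dim auxiliary lexical vector,
#' feeding a 595-dim token vector; a 32-dim base distance embedding and an
#' 832-dim child context scored by a single attention unit and filtered by
#' 100 kernel filters with the heuristic distance weight beta = -0.03.
#'
#' The child-context dimension is derived as
#' `(word + pos + dim_typ) + word + dist_dim`
#' (child word, child POS tag, child's incoming dependency-type row;
#' parent word; scaled distance embedding), which reproduces 832 under the
#' defaults.
#'
#' @param dim_typ,dim_dir dependency type / direction embedding dims.
#' @param dep_out dependency-unit vector dim (D).
#' @param word_dim pretrained word vector dim.
#' @param pos_dim,n_pos POS embedding dim and table rows.
#' @param use_char,char_vocab,char_dim,char_units character-level encoder:
#'   switch, table rows, char embedding dim, LSTM units per direction.
#' @param use_aux,aux_dim fixed auxiliary lexical vector switch and dim.
#' @param token_out token vector dim (X), used for both the intermediate
#'   and the final token representation.
#' @param dist_dim base distance embedding dim.
#' @param n_kernel kernel filters over child contexts (K).
#' @param beta heuristic attention weight (must be negative).
#' @param n_dep,n_virtual syntactic / virtual dependency label table rows.
#' @return an `encoder_config` list; `$child_dim` is the derived
#'   child-context dimension.
#' @export
encoder_config <- function(dim_typ = 150, dim_dir = 150, dep_out = 150,
                           word_dim = 300, pos_dim = 50, n_pos = 57,
                           use_char = TRUE, char_vocab = 85, char_dim = 50,
                           char_units = 50, use_aux = TRUE, aux_dim = 45,
                           token_out = 595, dist_dim = 32, n_kernel = 100,
                           beta = -0.03, n_dep = 72, n_virtual = 6) {
  stopifnot(beta < 0)
  cfg <- as.list(environment())
  cfg$token_in <- word_dim + pos_dim +
    (if (use_char) 2L * char_units else 0L) + (if (use_aux) aux_dim else 0L)
  cfg$child_dim <- (word_dim + pos_dim + dim_typ) + word_dim + dist_dim
  stopifnot(vapply(cfg, function(v) is.numeric(v) || is.logical(v), TRUE))
  structure(cfg, class = "encoder_config")
}

#' Compact encoder configuration for small-scale experiments
#'
#' Same architecture, scaled-down dimensions, character and auxiliary
#' features off: suitable for synthetic corpora and unit tests where the
#' vocabulary is tiny and training must run on one CPU in minutes.
#'
#' @param word_dim synthetic word vector dim.
#' @param ... overrides passed to [encoder_config()].
#' @return an `encoder_config`.
#' @export
compact_encoder_config <- function(word_dim = 20, ...) {
  encoder_config(dim_typ = 12, dim_dir = 4, dep_out = 12, word_dim = word_dim,
                 pos_dim = 8, use_char = FALSE, use_aux = FALSE,
                 token_out = 20, dist_dim = 4, n_kernel = 12, ...)
}

# Glorot (Xavier) uniform initialization
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform lookup tables and transforms. The word table is built
#' from the pretrained vectors and stays frozen during training;
#' out-of-vocabulary tokens map to a fallback row (the mean vector).
#' Character-encoder weights are initialized once and also stay fixed.
#'
#' @param config an [encoder_config()].
#' @param word_vectors matrix from [read_word_vectors()]; its column count
#'   must equal `config$word_dim`.
#' @param seed integer seed fixing the initialization.
#' @return named list of parameter arrays (`encoder_params`).
#' @export
init_encoder_params <- function(config, word_vectors, seed = 1L) {
  if (ncol(word_vectors) != config$word_dim) {
    stop(sprintf("configuration error: word vectors are %d-dim, config says %d",
                 ncol(word_vectors), config$word_dim), call. = FALSE)
  }
  local_seed(seed, {
    word_tab <- rbind(word_vectors, `<oov>` = colMeans(word_vectors))
    p <- list(
      word_tab = word_tab,
      pos_tab = glorot(config$n_pos, config$pos_dim),
      typ_tab = glorot(config$n_dep, config$dim_typ),
      virt_tab = glorot(config$n_virtual, config$dim_typ),
      dir_tab = glorot(2L, config$dim_dir),
      W_d = glorot(config$dim_typ + config$dim_dir, config$dep_out),
      b_d = numeric(config$dep_out),
      W_t = glorot(config$token_in, config$token_out),
      b_t = numeric(config$token_out),
      w_dist = stats::runif(config$dist_dim, -0.1, 0.1),
      W_e = glorot(config$child_dim, 1L),
      b_e = 0,
      W_f = glorot(config$child_dim, config$n_kernel),
      b_f = numeric(config$n_kernel),
      W_x = glorot(config$token_out + config$n_kernel, config$token_out),
      b_x = numeric(config$token_out)
    )
    if (config$use_char) {
      nin <- config$char_dim + config$char_units
      p$char_tab <- glorot(config$char_vocab, config$char_dim)
      p$char_W_fwd <- glorot(nin, 4L * config$char_units)
      p$char_b_fwd <- numeric(4L * config$char_units)
      p$char_W_bwd <- glorot(nin, 4L * config$char_units)
      p$char_b_bwd <- numeric(4L * config$char_units)
    }
    structure(p, class = "encoder_params")
  })
}

# run code under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

word_row_ids <- function(surfaces, word_tab) {
  i <- match(surfaces, rownames(word_tab))
  i[is.na(i)] <- nrow(word_tab)            # <oov> fallback row
  i
}

pos_row_ids <- function(tags, config) {
  inv <- pos_tag_inventory()
  i <- match(map_pos_tag(tags), inv)
  pmin(i, config$n_pos)
}

# combined dependency label row ids: 1..n_dep syntactic, then virtual
dep_row_ids <- function(labels, config) {
  virt <- virtual_label_inventory()
  is_virt <- labels %in% virt
  out <- integer(length(labels))
  out[is_virt] <- config$n_dep + match(labels[is_virt], virt)
  out[!is_virt] <- match(map_dep_label(labels[!is_virt]), dep_label_inventory())
  out
}

dir_row_ids <- function(directions) {
  match(directions, c("with", "against"))
}

dep_type_rows <- function(lab_ids, params, config) {
  rbind(params$typ_tab, params$virt_tab)[lab_ids, , drop = FALSE]
}

#' Encode dependency relations (type + direction)
#'
#' `d = tanh([d_typ (+) d_dir] W_d + b_d)`: the label row comes from the
#' 72-row syntactic table (unknown labels use the reserved row) or the
#' 6-row virtual-label table; the direction row distinguishes traversal
#' with versus against the stored arc.
#'
#' @param labels character vector of dependency or virtual edge labels.
#' @param directions `"with"` or `"against"`, recycled if length 1.
#' @param params `encoder_params`.
#' @param config `encoder_config`.
#' @return matrix, one `dep_out`-dim row per label; entries in (-1, 1).
#' @export
encode_dependency <- function(labels, directions, params, config) {
  if (length(directions) == 1L) directions <- rep(directions, length(labels))
  din <- cbind(dep_type_rows(dep_row_ids(labels, config), params, config),
               params$dir_tab[dir_row_ids(directions), , drop = FALSE])
  tanh(sweep(din %*% params$W_d, 2L, params$b_d, `+`))
}

# deterministic fixed auxiliary lexical vector per surface form
aux_features <- function(surfaces, dim) {
  h <- vapply(surfaces, function(w) {
    sum(utf8ToInt(w) * seq_len(nchar(w))) %% 10007L
  }, numeric(1))
  t(vapply(h, function(hi) sin(hi * seq_len(dim) * 0.7), numeric(dim))) * 0.1
}

# character-level biLSTM encoder: concatenation of the two final hidden
# states; weights are fixed after initialization
char_encode <- function(surfaces, params, config) {
  inv <- char_inventory()
  u <- config$char_units
  run <- function(ids, W, b) {
    h <- numeric(u); cc <- numeric(u)
    for (i in ids) {
      z <- drop(c(params$char_tab[i, ], h) %*% W) + b
      ig <- sigmoid(z[1:u]); fg <- sigmoid(z[(u + 1):(2 * u)])
      og <- sigmoid(z[(2 * u + 1):(3 * u)]); gg <- tanh(z[(3 * u + 1):(4 * u)])
      cc <- fg * cc + ig * gg
      h <- og * tanh(cc)
    }
    h
  }
  t(vapply(surfaces, function(w) {
    chars <- strsplit(w, "")[[1]]
    ids <- match(chars, inv)
    ids[is.na(ids)] <- length(inv)
    c(run(ids, params$char_W_fwd, params$char_b_fwd),
      run(rev(ids), params$char_W_bwd, params$char_b_bwd))
  }, numeric(2 * u)))
}

# raw token feature rows: word (+ pos) (+ char) (+ aux)
token_features <- function(surfaces, pos_tags, params, config) {
  out <- cbind(params$word_tab[word_row_ids(surfaces, params$word_tab), , drop = FALSE],
               params$pos_tab[pos_row_ids(pos_tags, config), , drop = FALSE])
  if (config$use_char) out <- cbind(out, char_encode(surfaces, params, config))
  if (config$use_aux) out <- cbind(out, aux_features(surfaces, config$aux_dim))
  rownames(out) <- NULL
  out
}

#' Encode tokens
#'
#' `t = tanh([t_word (+) t_pos (+ char + aux)] W_t + b_t)`. Word vectors
#' are the pretrained (frozen) table; out-of-vocabulary surfaces use the
#' fallback row.
#'
#' @param surfaces,pos_tags character vectors, same length.
#' @param params,config encoder parameters and configuration.
#' @return matrix, one `token_out`-dim row per token; entries in (-1, 1).
#' @export
encode_token <- function(surfaces, pos_tags, params, config) {
  feat <- token_features(surfaces, pos_tags, params, config)
  tanh(sweep(feat %*% params$W_t, 2L, params$b_t, `+`))
}

#' Child contexts of a token on its original dependency tree
#'
#' @param parse a `parsed_sentence`.
#' @param tok token index.
#' @return data.frame with one row per dependency-tree child: `surface`,
#'   `pos`, `deprel` (incoming label from the parent) and `dist` (signed
#'   token offset child - parent; never 0).
#' @export
child_contexts <- function(parse, tok) {
  ch <- which(parse$heads == tok)
  data.frame(surface = parse$tokens$surface[ch], pos = parse$tokens$pos[ch],
             deprel = parse$deprels[ch], dist = ch - tok)
}

build_child_context_matrix <- function(word_rows, pos_rows, typ_rows,
                                       parent_word_rows, dist, w_dist) {
  cbind(word_rows, pos_rows, typ_rows, parent_word_rows, outer(dist, w_dist))
}

#' Attentive weighting of child contexts
#'
#' Builds the child-context matrix (child word + POS + incoming
#' dependency-type row, parent word, scaled distance embedding), scores
#' each row with the single-unit self-attention transform
#' `alpha_s = sigmoid(cbar W_e + b_e)`, applies the heuristic distance
#' gate `alpha_h = sigmoid(beta d^2)`, and returns the doubly gated
#' context rows `alpha_h * alpha_s * cbar`.
#'
#' @param children data.frame from [child_contexts()].
#' @param parent_surface the parent token's surface form.
#' @param params,config encoder parameters and configuration.
#' @return list with `cbar` (M x child_dim), `alpha_s`, `alpha_h`
#'   (vectors in (0,1)) and `attended` (M x child_dim).
#' @export
child_attention <- function(children, parent_surface, params, config) {
  m <- nrow(children)
  stopifnot(m >= 1L)
  cw <- params$word_tab[word_row_ids(children$surface, params$word_tab), , drop = FALSE]
  cp <- params$pos_tab[pos_row_ids(children$pos, config), , drop = FALSE]
  ct <- params$typ_tab[dep_row_ids(children$deprel, config), , drop = FALSE]
  pw <- params$word_tab[rep(word_row_ids(parent_surface, params$word_tab), m), , drop = FALSE]
  cbar <- build_child_context_matrix(cw, cp, ct, pw, children$dist, params$w_dist)
  alpha_s <- drop(sigmoid(cbar %*% params$W_e + params$b_e))
  alpha_h <- sigmoid(config$beta * children$dist^2)
  list(cbar = cbar, alpha_s = alpha_s, alpha_h = alpha_h,
       attended = cbar * (alpha_s * alpha_h))
}

#' Augmented child information
#'
#' `F_i = ReLU(c_i W_f + b_f)` per attended child row, max-pooled per
#' filter over the children. Leaf tokens (no children) yield the zero
#' vector, the neutral ReLU output.
#'
#' @param attended matrix of gated child contexts (possibly 0 rows).
#' @param params encoder parameters.
#' @return numeric vector of length `n_kernel`, componentwise >= 0.
#' @export
augment <- function(attended, params) {
  k <- ncol(params$W_f)
  if (is.null(attended) || nrow(attended) == 0L) return(numeric(k))
  f <- relu(sweep(attended %*% params$W_f, 2L, params$b_f, `+`))
  apply(f, 2L, max)
}

#' Final token representation
#'
#' `x = tanh([t (+) a] W_x + b_x)`.
#'
#' @param t token vector (or matrix of rows).
#' @param a augmented-information vector (or matrix of rows).
#' @param params encoder parameters.
#' @return matrix of `token_out`-dim rows; entries in (-1, 1).
#' @export
finalize_token <- function(t, a, params) {
  t <- rbind(t); a <- rbind(a)
  tanh(sweep(cbind(t, a) %*% params$W_x, 2L, params$b_x, `+`))
}

#' Encode a mined path
#'
#' Produces the alternating multi-path representation: n final token
#' vectors `x_i` interleaved with n-1 dependency-unit vectors `d_i`.
#' Child contexts come from each token's original sentence tree (not the
#' subgraph), so a token is encoded identically on every path through it.
#'
#' @param path a materialized path ([path_content()] output).
#' @param parses the document's parses (element 1 = title).
#' @param params,config encoder parameters and configuration.
#' @return an `encoded_path`: `x` (n x token_out), `d`
#'   ((n-1) x dep_out).
#' @export
encode_path <- function(path, parses, params, config) {
  tk <- path$tokens
  n <- nrow(tk)
  t_mat <- encode_token(tk$surface, tk$pos, params, config)
  a_mat <- t(vapply(seq_len(n), function(i) {
    parse <- parses[[tk$sent[i] + 1L]]
    if (is.null(parse)) stop("token without parse on path", call. = FALSE)
    children <- child_contexts(parse, tk$tok[i])
    if (nrow(children) == 0L) return(numeric(config$n_kernel))
    att <- child_attention(children, tk$surface[i], params, config)
    augment(att$attended, params)
  }, numeric(config$n_kernel)))
  x <- finalize_token(t_mat, a_mat, params)
  d <- if (n > 1L) {
    encode_dependency(path$edges$label, path$edges$direction, params, config)
  } else {
    matrix(0, 0L, config$dep_out)
  }
  structure(list(x = x, d = d), class = "encoded_path")
}
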