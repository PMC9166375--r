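#' Shared-weight CNN configuration
#'
#' Classifier-side hyperparameters. Defaults follow the tuned full-scale
#' setup: up to `k_paths = 3` paths per instance, 128 filters for each
#' region size in {1, 2, 3} dependency units, two classes with class
#' weights 3:1 for CID:NONE, mini-batches of 128, Adam with Glorot
#' uniform initialization, dropout 0.5 after the embedding and CNN
#' layers, zero-mean Gaussian input noise with scale 0.001, max-norm
#' weight capping and early stopping on development F1.
#'
#' @param k_paths paths per instance (shorter instances are padded).
#' @param n_filters filters per region size (N).
#' @param region_sizes region sizes in dependency units.
#' @param class_weights named positive weights for `CID` and `NONE`.
#' @param lambda L2 regularization coefficient.
#' @param dropout dropout rate after embedding and CNN layers.
#' @param noise_sd Gaussian input-noise scale at training time.
#' @param batch_size mini-batch size.
#' @param lr Adam step size.
#' @param max_norm per-column weight norm cap.
#' @param patience early-stopping patience in epochs without a new best dev F1 (default 15).
#' @param epochs maximum training epochs.
#' @return an `swcnn_config` list.
#' @export
swcnn_config <- function(k_paths = 3L, n_filters = 128L, region_sizes = 1:3,
                         class_weights = c(CID = 3, NONE = 1),
                         lambda = 1e-4, dropout = 0.5, noise_sd = 0.001,
                         batch_size = 128L, lr = 1e-3, max_norm = 3,
                         patience = 15L, epochs = 50L) {
  stopifnot(k_paths >= 1, all(region_sizes >= 1), all(class_weights > 0),
            dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "swcnn_config")
}

#' Compact shared-weight CNN configuration
#'
#' Scaled-down filter count for synthetic-corpus experiments; everything
#' else keeps the defaults of [swcnn_config()].
#'
#' @param ... overrides passed to [swcnn_config()].
#' @return an `swcnn_config`.
#' @export
compact_swcnn_config <- function(...) {
  swcnn_config(n_filters = 16L, ...)
}

init_swcnn_params <- function(enc_config, sw_config) {
  xdim <- enc_config$token_out
  ddim <- enc_config$dep_out
  p <- list()
  for (r in sw_config$region_sizes) {
    p[[sprintf("W_c%d", r)]] <- glorot(r * xdim + (r - 1) * ddim,
                                       sw_config$n_filters)
    p[[sprintf("b_c%d", r)]] <- numeric(sw_config$n_filters)
  }
  p$W_y <- glorot(length(sw_config$region_sizes) * sw_config$n_filters, 2L)
  p$b_y <- numeric(2L)
  p
}

# parameter names subject to L2 and max-norm (weight arrays, not biases)
reg_param_names <- function(theta) {
  if (!length(theta)) return(character(0))
  names(theta)[!startsWith(names(theta), "b_")]
}

#' Convolution with filter-wise max pooling over an instance's paths
#'
#' For each region size r, slides windows of r tokens and r-1 dependency
#' units (advancing one dependency unit, i.e. token to token) over every
#' path, applies the shared filters, and pools each filter's responses to
#' a single maximum over all paths and positions. Paths shorter than r
#' contribute nothing to that region size; if no path reaches r tokens
#' the region's features are zero.
#'
#' @param encoded_paths list of [encode_path()] outputs (1 to k paths).
#' @param state model parameter list holding `W_c<r>`/`b_c<r>`.
#' @param config an [swcnn_config()].
#' @return feature vector of length
#'   `length(region_sizes) * n_filters`.
#' @export
convolve_pool <- function(encoded_paths, state, config) {
  stopifnot(length(encoded_paths) >= 1)
  out <- lapply(config$region_sizes, function(r) {
    W <- state[[sprintf("W_c%d", r)]]
    b <- state[[sprintf("b_c%d", r)]]
    best <- rep(-Inf, ncol(W))
    for (ep in encoded_paths) {
      n <- nrow(ep$x)
      if (n < r) next
      for (j in seq_len(n - r + 1L)) {
        v <- as.numeric(t(cbind(ep$x[j:(j + r - 1L), , drop = FALSE],
                                rbind(ep$d, 0)[j:(j + r - 1L), , drop = FALSE])))
        v <- v[seq_len(r * ncol(ep$x) + (r - 1L) * ncol(ep$d))]
        best <- pmax(best, drop(v %*% W) + b)
      }
    }
    best[!is.finite(best)] <- 0
    best
  })
  unlist(out)
}

#' Softmax classification of a pooled feature vector
#'
#' @param f feature vector (or matrix of rows).
#' @param state model parameters holding `W_y`, `b_y`.
#' @return probability rows over (CID, NONE); positive, summing to 1.
#' @export
classify <- function(f, state) {
  z <- sweep(rbind(f) %*% state$W_y, 2L, state$b_y, `+`)
  softmax_rows(z)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Weighted, regularized training loss for one example
#'
#' `L = -w_gold * log(yhat_gold) + lambda * ||theta||^2`, where the class
#' weight is 3 for CID and 1 for NONE under the defaults and the squared
#' norm runs over the weight arrays of `theta`. The log is floored at
#' 1e-12.
#'
#' @param yhat probability vector over (CID, NONE).
#' @param gold `"CID"` or `"NONE"`.
#' @param theta parameter list (may be empty for the bare cross-entropy).
#' @param config an [swcnn_config()].
#' @return nonnegative scalar (when `lambda >= 0`).
#' @export
swcnn_loss <- function(yhat, gold, theta = list(), config = swcnn_config()) {
  gi <- match(gold, c("CID", "NONE"))
  ce <- -config$class_weights[[gold]] * log(max(yhat[gi], 1e-12))
  reg <- 0
  for (nm in reg_param_names(theta)) reg <- reg + sum(theta[[nm]]^2)
  ce + config$lambda * reg
}

# ---------------------------------------------------------------------------
# Instance compilation: flatten instances into index structures so that a
# whole mini-batch is encoded with a handful of matrix operations.
# ---------------------------------------------------------------------------

#' Compile candidate instances for the trainer
#'
#' Flattens every path of every instance into global token/dependency/
#' child index tables, precomputes the frozen token feature block
#' (character encoder output and auxiliary lexical vector, when enabled)
#' and the convolution window index matrices for each region size.
#' Instances with zero paths are dropped here (they are predicted NONE).
#'
#' @param instances list of `candidate_instance`.
#' @param parses_by_doc named list: document id -> list of parses.
#' @param params `encoder_params` (for the word table and frozen blocks).
#' @param enc_config,sw_config configurations.
#' @return a `compiled_instances` list used by [train_swcnn()] /
#'   [predict_swcnn()].
#' @export
compile_instances <- function(instances, parses_by_doc, params,
                              enc_config, sw_config) {
  keep <- which(vapply(instances, function(x) length(x$paths) > 0L, TRUE))
  inst_meta <- data.frame(
    doc = vapply(instances, `[[`, "", "doc"),
    chemical = vapply(instances, `[[`, "", "chemical"),
    disease = vapply(instances, `[[`, "", "disease"),
    label = vapply(instances, `[[`, "", "label"))
  tok <- list(); dep <- list(); child <- list(); win <- list()
  for (r in sw_config$region_sizes) win[[as.character(r)]] <- list()
  n_tok <- 0L; n_dep <- 0L

  for (bi in seq_along(keep)) {
    oi <- keep[bi]
    inst <- instances[[oi]]
    parses <- parses_by_doc[[inst$doc]]
    if (is.null(parses)) stop(sprintf("no parses for document %s", inst$doc),
                              call. = FALSE)
    npaths <- min(length(inst$paths), sw_config$k_paths)
    for (p in seq_len(npaths)) {
      pt <- inst$paths[[p]]
      n <- nrow(pt$tokens)
      trow <- n_tok + seq_len(n)
      tokdf <- data.frame(
        inst = bi,
        word = word_row_ids(pt$tokens$surface, params$word_tab),
        pos = pos_row_ids(pt$tokens$pos, enc_config))
      tokdf$surface <- pt$tokens$surface
      tok[[length(tok) + 1L]] <- tokdf
      for (i in seq_len(n)) {
        parse <- parses[[pt$tokens$sent[i] + 1L]]
        ch <- child_contexts(parse, pt$tokens$tok[i])
        if (nrow(ch)) {
          child[[length(child) + 1L]] <- data.frame(
            tok = trow[i],
            word = word_row_ids(ch$surface, params$word_tab),
            pos = pos_row_ids(ch$pos, enc_config),
            typ = dep_row_ids(ch$deprel, enc_config),
            parent_word = word_row_ids(pt$tokens$surface[i], params$word_tab),
            dist = ch$dist)
        }
      }
      if (n > 1L) {
        drow <- n_dep + seq_len(n - 1L)
        dep[[length(dep) + 1L]] <- data.frame(
          inst = bi,
          lab = dep_row_ids(pt$edges$label, enc_config),
          dir = dir_row_ids(pt$edges$direction))
      } else {
        drow <- integer(0)
      }
      for (r in sw_config$region_sizes) {
        if (n < r) next
        js <- seq_len(n - r + 1L)
        wt <- vapply(seq_len(r), function(q) trow[js + q - 1L], integer(length(js)))
        wd <- if (r > 1L) {
          vapply(seq_len(r - 1L), function(q) drow[js + q - 1L], integer(length(js)))
        } else matrix(0L, length(js), 0L)
        win[[as.character(r)]][[length(win[[as.character(r)]]) + 1L]] <-
          list(inst = rep(bi, length(js)), tok = matrix(wt, nrow = length(js)),
               dep = matrix(wd, nrow = length(js)))
      }
      n_tok <- n_tok + n
      n_dep <- n_dep + (n - 1L)
    }
  }
  tok <- if (length(tok)) do.call(rbind, tok) else
    data.frame(inst = integer(), word = integer(), pos = integer(),
               surface = character())
  dep <- if (length(dep)) do.call(rbind, dep) else
    data.frame(inst = integer(), lab = integer(), dir = integer())
  child <- if (length(child)) do.call(rbind, child) else
    data.frame(tok = integer(), word = integer(), pos = integer(),
               typ = integer(), parent_word = integer(), dist = integer())

  # fixed-width child slot matrix for vectorized per-token max pooling
  mmax <- if (nrow(child)) max(table(child$tok)) else 0L
  child_slots <- matrix(NA_integer_, nrow(tok), max(mmax, 1L))
  if (nrow(child)) {
    ordc <- order(child$tok)
    child <- child[ordc, , drop = FALSE]
    pos_in_tok <- stats::ave(seq_len(nrow(child)), child$tok, FUN = seq_along)
    child_slots[cbind(child$tok, pos_in_tok)] <- seq_len(nrow(child))
  }

  # frozen extra token features (character encoder + auxiliary vector)
  extra <- NULL
  if (enc_config$use_char || enc_config$use_aux) {
    uniq <- unique(tok$surface)
    blocks <- NULL
    if (enc_config$use_char) blocks <- char_encode(uniq, params, enc_config)
    if (enc_config$use_aux) {
      aux <- aux_features(uniq, enc_config$aux_dim)
      blocks <- if (is.null(blocks)) aux else cbind(blocks, aux)
    }
    extra <- blocks[match(tok$surface, uniq), , drop = FALSE]
  }

  wins <- lapply(win, function(parts) {
    if (!length(parts)) {
      return(list(inst = integer(), tok = NULL, dep = NULL))
    }
    list(inst = unlist(lapply(parts, `[[`, "inst")),
         tok = do.call(rbind, lapply(parts, `[[`, "tok")),
         dep = do.call(rbind, lapply(parts, `[[`, "dep")))
  })
  structure(list(inst = inst_meta, kept = keep, tok = tok, dep = dep,
                 child = child, child_slots = child_slots, extra = extra,
                 win = wins),
            class = "compiled_instances")
}

# ---------------------------------------------------------------------------
# Vectorized forward and backward passes
# ---------------------------------------------------------------------------

# forward pass over a batch of compiled instance ids; returns loss, class
# probabilities and (when wanted) the cache needed for the backward pass
swcnn_forward <- function(theta, word_tab, comp, batch_ids, enc_config,
                          sw_config, train = FALSE, want_cache = FALSE) {
  B <- length(batch_ids)
  sel_tok <- which(comp$tok$inst %in% batch_ids)
  sel_dep <- which(comp$dep$inst %in% batch_ids)
  loc_tok <- integer(nrow(comp$tok)); loc_tok[sel_tok] <- seq_along(sel_tok)
  loc_dep <- integer(max(nrow(comp$dep), 1L)); loc_dep[sel_dep] <- seq_along(sel_dep)

  # --- token encoding -----------------------------------------------------
  Tin <- cbind(word_tab[comp$tok$word[sel_tok], , drop = FALSE],
               theta$pos_tab[comp$tok$pos[sel_tok], , drop = FALSE])
  if (!is.null(comp$extra)) Tin <- cbind(Tin, comp$extra[sel_tok, , drop = FALSE])
  if (train && sw_config$noise_sd > 0) {
    Tin <- Tin + stats::rnorm(length(Tin), 0, sw_config$noise_sd)
  }
  tmat <- tanh(sweep(Tin %*% theta$W_t, 2L, theta$b_t, `+`))

  # --- dependency-unit encoding ------------------------------------------
  typvirt <- rbind(theta$typ_tab, theta$virt_tab)
  Din <- cbind(typvirt[comp$dep$lab[sel_dep], , drop = FALSE],
               theta$dir_tab[comp$dep$dir[sel_dep], , drop = FALSE])
  if (train && sw_config$noise_sd > 0 && nrow(Din)) {
    Din <- Din + stats::rnorm(length(Din), 0, sw_config$noise_sd)
  }
  dmat <- tanh(sweep(Din %*% theta$W_d, 2L, theta$b_d, `+`))

  # --- attentive child augmentation --------------------------------------
  sel_child <- which(comp$child$tok %in% sel_tok)
  K <- enc_config$n_kernel
  nt <- length(sel_tok)
  A <- matrix(0, nt, K)
  amax <- matrix(NA_integer_, nt, K)
  ch_cache <- NULL
  if (length(sel_child)) {
    ch <- comp$child[sel_child, , drop = FALSE]
    Cbar <- build_child_context_matrix(
      word_tab[ch$word, , drop = FALSE],
      theta$pos_tab[ch$pos, , drop = FALSE],
      theta$typ_tab[ch$typ, , drop = FALSE],
      word_tab[ch$parent_word, , drop = FALSE],
      ch$dist, theta$w_dist)
    s <- drop(Cbar %*% theta$W_e) + theta$b_e
    as_ <- sigmoid(s)
    ah <- sigmoid(enc_config$beta * ch$dist^2)
    g <- as_ * ah
    CH <- Cbar * g
    Fpre <- sweep(CH %*% theta$W_f, 2L, theta$b_f, `+`)
    Fm <- relu(Fpre)
    loc_child <- integer(nrow(comp$child)); loc_child[sel_child] <- seq_along(sel_child)
    slots <- comp$child_slots[sel_tok, , drop = FALSE]
    slots_loc <- matrix(loc_child[slots], nrow = nt)
    slots_loc[slots_loc == 0L] <- NA_integer_
    for (k in seq_len(K)) {
      V <- matrix(Fm[, k][slots_loc], nrow = nt)
      Vn <- replace(V, is.na(V), -Inf)
      mx <- do.call(pmax, c(lapply(seq_len(ncol(Vn)), function(j) Vn[, j]),
                            list(na.rm = TRUE)))
      has <- is.finite(mx)
      A[has, k] <- mx[has]
      amax[has, k] <- slots_loc[cbind(which(has),
                                      max.col(Vn[has, , drop = FALSE],
                                              ties.method = "first"))]
    }
    ch_cache <- list(ch = ch, Cbar = Cbar, as_ = as_, ah = ah, g = g,
                     CH = CH, Fpre = Fpre)
  }

  # --- final token representation ----------------------------------------
  TA <- cbind(tmat, A)
  xmat <- tanh(sweep(TA %*% theta$W_x, 2L, theta$b_x, `+`))

  p_drop <- if (train) sw_config$dropout else 0
  mask_x <- mask_d <- NULL
  x_use <- xmat; d_use <- dmat
  if (p_drop > 0) {
    mask_x <- matrix(stats::rbinom(length(xmat), 1L, 1 - p_drop),
                     nrow(xmat)) / (1 - p_drop)
    x_use <- xmat * mask_x
    if (nrow(dmat)) {
      mask_d <- matrix(stats::rbinom(length(dmat), 1L, 1 - p_drop),
                       nrow(dmat)) / (1 - p_drop)
      d_use <- dmat * mask_d
    }
  }

  # --- shared-weight convolution + filter-wise pooling --------------------
  N <- sw_config$n_filters
  xdim <- enc_config$token_out; ddim <- enc_config$dep_out
  f <- NULL
  conv_cache <- list()
  for (r in sw_config$region_sizes) {
    wr <- comp$win[[as.character(r)]]
    sel_w <- which(wr$inst %in% batch_ids)
    f_r <- matrix(0, B, N)
    arg_r <- matrix(NA_integer_, B, N)
    cache_r <- NULL
    if (length(sel_w)) {
      tokm <- matrix(loc_tok[wr$tok[sel_w, , drop = FALSE]], nrow = length(sel_w))
      V <- matrix(0, length(sel_w), r * xdim + (r - 1L) * ddim)
      cp <- 0L
      depm <- NULL
      if (r > 1L) depm <- matrix(loc_dep[wr$dep[sel_w, , drop = FALSE]],
                                 nrow = length(sel_w))
      for (q in seq_len(r)) {
        V[, cp + seq_len(xdim)] <- x_use[tokm[, q], , drop = FALSE]
        cp <- cp + xdim
        if (q < r) {
          V[, cp + seq_len(ddim)] <- d_use[depm[, q], , drop = FALSE]
          cp <- cp + ddim
        }
      }
      Z <- sweep(V %*% theta[[sprintf("W_c%d", r)]], 2L,
                 theta[[sprintf("b_c%d", r)]], `+`)
      grp <- match(wr$inst[sel_w], batch_ids)
      for (b in seq_len(B)) {
        rows <- which(grp == b)
        if (!length(rows)) next
        zb <- Z[rows, , drop = FALSE]
        am <- max.col(t(zb), ties.method = "first")
        f_r[b, ] <- zb[cbind(am, seq_len(N))]
        arg_r[b, ] <- rows[am]
      }
      cache_r <- list(sel_w = sel_w, tokm = tokm, depm = depm, V = V, Z = Z)
    }
    f <- if (is.null(f)) f_r else cbind(f, f_r)
    conv_cache[[as.character(r)]] <- list(arg = arg_r, data = cache_r)
  }

  mask_f <- NULL
  f_use <- f
  if (p_drop > 0) {
    mask_f <- matrix(stats::rbinom(length(f), 1L, 1 - p_drop), nrow(f)) /
      (1 - p_drop)
    f_use <- f * mask_f
  }

  # --- classification -----------------------------------------------------
  logits <- sweep(f_use %*% theta$W_y, 2L, theta$b_y, `+`)
  probs <- softmax_rows(logits)
  labels <- comp$inst$label[comp$kept][batch_ids]
  gold <- match(labels, c("CID", "NONE"))
  wts <- unname(sw_config$class_weights[labels])
  ce <- -wts * log(pmax(probs[cbind(seq_len(B), gold)], 1e-12))
  reg <- 0
  for (nm in reg_param_names(theta)) reg <- reg + sum(theta[[nm]]^2)
  loss <- mean(ce) + sw_config$lambda * reg

  out <- list(loss = loss, probs = probs, f = f, gold = gold, wts = wts)
  if (want_cache) {
    out$cache <- list(sel_tok = sel_tok, sel_dep = sel_dep, Tin = Tin,
                      tmat = tmat, Din = Din, dmat = dmat, A = A, amax = amax,
                      ch_cache = ch_cache, sel_child = sel_child, TA = TA,
                      xmat = xmat, mask_x = mask_x, mask_d = mask_d,
                      mask_f = mask_f, f_use = f_use, conv = conv_cache,
                      B = B)
  }
  out
}

# backward pass; returns gradients for every trainable parameter
swcnn_backward <- function(theta, word_tab, comp, batch_ids, enc_config,
                           sw_config, fwd) {
  cc <- fwd$cache
  B <- cc$B
  K <- enc_config$n_kernel
  xdim <- enc_config$token_out; ddim <- enc_config$dep_out
  grad <- lapply(theta, function(v) array(0, dim = dim(v) %||% length(v)))
  grad <- lapply(grad, function(g) if (is.matrix(g)) g else as.numeric(g))

  # classification
  Y <- matrix(0, B, 2L); Y[cbind(seq_len(B), fwd$gold)] <- 1
  dlogits <- (fwd$probs - Y) * fwd$wts / B
  grad$W_y <- t(cc$f_use) %*% dlogits
  grad$b_y <- colSums(dlogits)
  df <- dlogits %*% t(theta$W_y)
  if (!is.null(cc$mask_f)) df <- df * cc$mask_f

  # convolution layers
  nt <- length(cc$sel_tok)
  dx <- matrix(0, nt, xdim)
  dd <- matrix(0, max(nrow(cc$dmat), 1L), ddim)
  col0 <- 0L
  N <- sw_config$n_filters
  for (r in sw_config$region_sizes) {
    df_r <- df[, col0 + seq_len(N), drop = FALSE]
    col0 <- col0 + N
    cache <- cc$conv[[as.character(r)]]
    if (is.null(cache$data)) next
    arg <- cache$arg
    Z <- cache$data$Z
    dZ <- matrix(0, nrow(Z), N)
    idx_b <- rep(seq_len(B), N)
    idx_k <- rep(seq_len(N), each = B)
    rows <- arg[cbind(idx_b, idx_k)]
    okk <- !is.na(rows)
    dZ[cbind(rows[okk], idx_k[okk])] <- as.vector(df_r)[okk]
    Wc <- sprintf("W_c%d", r); bc <- sprintf("b_c%d", r)
    grad[[Wc]] <- t(cache$data$V) %*% dZ
    grad[[bc]] <- colSums(dZ)
    dV <- dZ %*% t(theta[[Wc]])
    cp <- 0L
    for (q in seq_len(r)) {
      blk <- dV[, cp + seq_len(xdim), drop = FALSE]
      add <- rowsum(blk, cache$data$tokm[, q])
      tgt <- as.integer(rownames(add))
      dx[tgt, ] <- dx[tgt, , drop = FALSE] + add
      cp <- cp + xdim
      if (q < r) {
        blkd <- dV[, cp + seq_len(ddim), drop = FALSE]
        addd <- rowsum(blkd, cache$data$depm[, q])
        tgtd <- as.integer(rownames(addd))
        dd[tgtd, ] <- dd[tgtd, , drop = FALSE] + addd
        cp <- cp + ddim
      }
    }
  }
  if (!is.null(cc$mask_x)) dx <- dx * cc$mask_x
  if (!is.null(cc$mask_d) && nrow(cc$dmat)) dd <- dd * cc$mask_d

  # final token transform
  dxpre <- dx * (1 - cc$xmat^2)
  grad$W_x <- t(cc$TA) %*% dxpre
  grad$b_x <- colSums(dxpre)
  dTA <- dxpre %*% t(theta$W_x)
  dt <- dTA[, seq_len(xdim), drop = FALSE]
  dA <- dTA[, xdim + seq_len(K), drop = FALSE]

  # child augmentation
  if (!is.null(cc$ch_cache)) {
    chc <- cc$ch_cache
    nchd <- nrow(chc$Cbar)
    dFm <- matrix(0, nchd, K)
    idx_t <- rep(seq_len(nt), K)
    idx_k <- rep(seq_len(K), each = nt)
    rows <- cc$amax[cbind(idx_t, idx_k)]
    okk <- !is.na(rows)
    dFm[cbind(rows[okk], idx_k[okk])] <-
      dFm[cbind(rows[okk], idx_k[okk])] + as.vector(dA)[okk]
    dFpre <- dFm * (chc$Fpre > 0)
    grad$W_f <- t(chc$CH) %*% dFpre
    grad$b_f <- colSums(dFpre)
    dCH <- dFpre %*% t(theta$W_f)
    dg <- rowSums(dCH * chc$Cbar)
    ds <- dg * chc$ah * chc$as_ * (1 - chc$as_)
    dCbar <- dCH * chc$g + outer(ds, drop(theta$W_e))
    grad$W_e <- t(chc$Cbar) %*% matrix(ds)
    grad$b_e <- sum(ds)
    wdim <- enc_config$word_dim; pdim <- enc_config$pos_dim
    tdim <- enc_config$dim_typ
    blk_pos <- dCbar[, wdim + seq_len(pdim), drop = FALSE]
    blk_typ <- dCbar[, wdim + pdim + seq_len(tdim), drop = FALSE]
    blk_dist <- dCbar[, 2L * wdim + pdim + tdim + seq_len(enc_config$dist_dim),
                      drop = FALSE]
    addp <- rowsum(blk_pos, chc$ch$pos)
    grad$pos_tab[as.integer(rownames(addp)), ] <-
      grad$pos_tab[as.integer(rownames(addp)), , drop = FALSE] + addp
    addt <- rowsum(blk_typ, chc$ch$typ)
    grad$typ_tab[as.integer(rownames(addt)), ] <-
      grad$typ_tab[as.integer(rownames(addt)), , drop = FALSE] + addt
    grad$w_dist <- grad$w_dist + colSums(blk_dist * chc$ch$dist)
  }

  # token encoder
  dtpre <- dt * (1 - cc$tmat^2)
  grad$W_t <- t(cc$Tin) %*% dtpre
  grad$b_t <- colSums(dtpre)
  dTin <- dtpre %*% t(theta$W_t)
  pos_blk <- dTin[, enc_config$word_dim + seq_len(enc_config$pos_dim),
                  drop = FALSE]
  addp <- rowsum(pos_blk, comp$tok$pos[cc$sel_tok])
  grad$pos_tab[as.integer(rownames(addp)), ] <-
    grad$pos_tab[as.integer(rownames(addp)), , drop = FALSE] + addp

  # dependency encoder
  if (nrow(cc$dmat)) {
    ddpre <- dd * (1 - cc$dmat^2)
    grad$W_d <- t(cc$Din) %*% ddpre
    grad$b_d <- colSums(ddpre)
    dDin <- ddpre %*% t(theta$W_d)
    typ_blk <- dDin[, seq_len(enc_config$dim_typ), drop = FALSE]
    dir_blk <- dDin[, enc_config$dim_typ + seq_len(enc_config$dim_dir),
                    drop = FALSE]
    labs <- comp$dep$lab[cc$sel_dep]
    addl <- rowsum(typ_blk, labs)
    rid <- as.integer(rownames(addl))
    syn <- rid <= enc_config$n_dep
    if (any(syn)) {
      grad$typ_tab[rid[syn], ] <- grad$typ_tab[rid[syn], , drop = FALSE] +
        addl[syn, , drop = FALSE]
    }
    if (any(!syn)) {
      vr <- rid[!syn] - enc_config$n_dep
      grad$virt_tab[vr, ] <- grad$virt_tab[vr, , drop = FALSE] +
        addl[!syn, , drop = FALSE]
    }
    addd <- rowsum(dir_blk, comp$dep$dir[cc$sel_dep])
    grad$dir_tab[as.integer(rownames(addd)), ] <-
      grad$dir_tab[as.integer(rownames(addd)), , drop = FALSE] + addd
  }

  # L2 term
  lam <- sw_config$lambda
  if (lam > 0) {
    for (nm in reg_param_names(theta)) {
      grad[[nm]] <- grad[[nm]] + 2 * lam * theta[[nm]]
    }
  }
  grad
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

trainable_theta <- function(enc_params, sw_params) {
  keep <- setdiff(names(enc_params),
                  c("word_tab", "char_tab", "char_W_fwd", "char_b_fwd",
                    "char_W_bwd", "char_b_bwd"))
  c(enc_params[keep], sw_params)
}

adam_step <- function(theta, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(theta)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    theta[[nm]] <- theta[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(theta = theta, state = state)
}

max_norm_clip <- function(theta, cap) {
  if (is.null(cap) || !is.finite(cap)) return(theta)
  for (nm in names(theta)) {
    w <- theta[[nm]]
    if (!is.matrix(w) || !startsWith(nm, "W_")) next
    nrm <- sqrt(colSums(w^2))
    over <- nrm > cap
    if (any(over)) {
      w[, over] <- sweep(w[, over, drop = FALSE], 2L, cap / nrm[over], `*`)
      theta[[nm]] <- w
    }
  }
  theta
}

#' Train the shared-weight CNN
#'
#' Mini-batch Adam with Glorot-uniform initialization, class-weighted
#' cross-entropy with L2 regularization, dropout, Gaussian input noise,
#' per-column max-norm capping and early stopping on development-set F1.
#' Deterministic given `seed` and the configurations; returns the
#' best-development checkpoint.
#'
#' @param train_instances,dev_instances lists of `candidate_instance`.
#' @param parses_by_doc named list: document id -> parses.
#' @param word_vectors pretrained word-vector matrix.
#' @param enc_config,sw_config configurations.
#' @param seed integer seed for initialization, shuffling, dropout, noise.
#' @param verbose print per-epoch loss and dev F1.
#' @return an `swcnn_model`: parameters, configs, training `log`
#'   (per-epoch data.frame) and `best_epoch`.
#' @export
train_swcnn <- function(train_instances, dev_instances, parses_by_doc,
                        word_vectors, enc_config = compact_encoder_config(),
                        sw_config = compact_swcnn_config(), seed = 1L,
                        verbose = FALSE) {
  has_paths <- vapply(train_instances, function(x) length(x$paths) > 0L, TRUE)
  if (!length(train_instances) || !any(has_paths)) {
    stop("empty training set (no instances with paths)", call. = FALSE)
  }
  enc_params <- init_encoder_params(enc_config, word_vectors, seed = seed)
  local_seed(seed + 1L, {
    sw_params <- init_swcnn_params(enc_config, sw_config)
    theta <- trainable_theta(enc_params, sw_params)
    word_tab <- enc_params$word_tab
    comp <- compile_instances(train_instances, parses_by_doc, enc_params,
                              enc_config, sw_config)
    comp_dev <- if (length(dev_instances)) {
      compile_instances(dev_instances, parses_by_doc, enc_params,
                        enc_config, sw_config)
    }
    n_train <- length(comp$kept)
    adam <- list(m = lapply(theta, function(v) v * 0),
                 v = lapply(theta, function(v) v * 0))
    step <- 0L
    best <- list(f1 = -Inf, theta = theta, epoch = 0L)
    log <- data.frame(epoch = integer(), loss = numeric(), dev_f1 = numeric())
    stall <- 0L

    for (epoch in seq_len(sw_config$epochs)) {
      ord <- sample.int(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / sw_config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        fwd <- swcnn_forward(theta, word_tab, comp, bt, enc_config, sw_config,
                             train = TRUE, want_cache = TRUE)
        if (!is.finite(fwd$loss)) {
          stop(sprintf("training aborted: non-finite loss at epoch %d", epoch),
               call. = FALSE)
        }
        grad <- swcnn_backward(theta, word_tab, comp, bt, enc_config,
                               sw_config, fwd)
        step <- step + 1L
        upd <- adam_step(theta, grad, adam, sw_config$lr, step)
        theta <- max_norm_clip(upd$theta, sw_config$max_norm)
        adam <- upd$state
        ep_loss <- ep_loss + fwd$loss * length(bt)
      }
      ep_loss <- ep_loss / n_train
      dev_f1 <- NA_real_
      if (!is.null(comp_dev) && length(comp_dev$kept)) {
        pr <- predict_compiled(theta, word_tab, comp_dev, enc_config, sw_config)
        gold <- comp_dev$inst$label[comp_dev$kept] == "CID"
        pred <- pr == "CID"
        tp <- sum(pred & gold); fp <- sum(pred & !gold); fn <- sum(!pred & gold)
        dev_f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      }
      log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss,
                                   dev_f1 = dev_f1))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  dev F1 %s", epoch, ep_loss,
                        formatC(dev_f1, digits = 4, format = "f")))
      }
      if (!is.na(dev_f1) && dev_f1 > best$f1 + 1e-9) {
        best <- list(f1 = dev_f1, theta = theta, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (!is.null(comp_dev) && stall >= sw_config$patience) break
      }
    }
    final_theta <- if (is.finite(best$f1)) best$theta else theta
    structure(list(theta = final_theta, word_tab = word_tab,
                   enc_params = enc_params, enc_config = enc_config,
                   sw_config = sw_config, log = log,
                   best_epoch = if (is.finite(best$f1)) best$epoch else NA_integer_),
              class = "swcnn_model")
  })
}

predict_compiled <- function(theta, word_tab, comp, enc_config, sw_config,
                             chunk = 512L) {
  n <- length(comp$kept)
  probs <- matrix(NA_real_, n, 2L)
  for (part in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fwd <- swcnn_forward(theta, word_tab, comp, part, enc_config, sw_config,
                         train = FALSE)
    probs[part, ] <- fwd$probs
  }
  c("CID", "NONE")[max.col(probs, ties.method = "last")]
}

#' Predict labels for candidate instances
#'
#' Instances with zero mined paths are predicted `NONE` (no evidence can
#' be examined); all others are classified by the model. Batching does
#' not affect the result.
#'
#' @param model an `swcnn_model` from [train_swcnn()].
#' @param instances list of `candidate_instance`.
#' @param parses_by_doc named list: document id -> parses.
#' @return data.frame `doc`, `chemical`, `disease`, `label`, `p_cid`
#'   (`p_cid` is `NA` for zero-path instances).
#' @export
predict_swcnn <- function(model, instances, parses_by_doc) {
  out <- data.frame(
    doc = vapply(instances, `[[`, "", "doc"),
    chemical = vapply(instances, `[[`, "", "chemical"),
    disease = vapply(instances, `[[`, "", "disease"),
    label = "NONE", p_cid = NA_real_)
  if (!length(instances)) return(out)
  comp <- compile_instances(instances, parses_by_doc, model$enc_params,
                            model$enc_config, model$sw_config)
  if (!length(comp$kept)) return(out)
  n <- length(comp$kept)
  probs <- matrix(NA_real_, n, 2L)
  for (part in split(seq_len(n), ceiling(seq_len(n) / 512L))) {
    fwd <- swcnn_forward(model$theta, model$word_tab, comp, part,
                         model$enc_config, model$sw_config, train = FALSE)
    probs[part, ] <- fwd$probs
  }
  out$label[comp$kept] <- c("CID", "NONE")[max.col(probs, ties.method = "last")]
  out$p_cid[comp$kept] <- probs[, 1L]
  out
}

#' Per-component trainable parameter counts
#'
#' Reports the size of every named architecture component under a
#' configuration pair, using the same dimension bookkeeping as the
#' implementation: lookup tables are rows x dim; the biLSTM counts
#' 4 gates x ((input + units) x units + units) per direction; the
#' attention scorer maps the child context to a scalar with bias; kernel
#' filters and convolution filters count weights + biases; the softmax
#' layer includes its bias.
#'
#' @param enc_config an [encoder_config()] (default: full-scale).
#' @param sw_config an [swcnn_config()] (default: full-scale).
#' @return named numeric vector of component counts plus `total`.
#' @export
count_parameters <- function(enc_config = encoder_config(),
                             sw_config = swcnn_config()) {
  e <- enc_config; s <- sw_config
  out <- c(
    dependency_type = e$n_dep * e$dim_typ,
    dependency_direction = 2 * e$dim_dir,
    virtual_label = e$n_virtual * e$dim_typ,
    character_table = if (e$use_char) e$char_vocab * e$char_dim else 0,
    character_bilstm = if (e$use_char) {
      2 * 4 * ((e$char_dim + e$char_units) * e$char_units + e$char_units)
    } else 0,
    pos_tag = e$n_pos * e$pos_dim,
    base_distance = e$dist_dim,
    self_attention_score = e$child_dim + 1,
    kernel_filters = e$n_kernel * e$child_dim + e$n_kernel,
    dependency_transform = (e$dim_typ + e$dim_dir) * e$dep_out + e$dep_out,
    token_transform = e$token_in * e$token_out + e$token_out,
    final_token_transform = (e$token_out + e$n_kernel) * e$token_out + e$token_out,
    shared_cnn = sum(vapply(s$region_sizes, function(r) {
      (r * e$token_out + (r - 1) * e$dep_out) * s$n_filters + s$n_filters
    }, numeric(1))),
    softmax = length(s$region_sizes) * s$n_filters * 2 + 2
  )
  c(out, total = sum(out))
}

#' @export
print.swcnn_model <- function(x, ...) {
  cat(sprintf("<swcnn_model> %d epochs trained, best dev epoch %s\n",
              nrow(x$log), x$best_epoch))
  invisible(x)
}
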