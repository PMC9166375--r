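# minimal hand-sized parameter set for closed-form checks
toy_encoder <- function(word_dim = 2L, seed = 5L) {
  cfg <- encoder_config(dim_typ = 2L, dim_dir = 2L, dep_out = 2L,
                        word_dim = word_dim, pos_dim = 2L, use_char = FALSE,
                        use_aux = FALSE, token_out = 2L, dist_dim = 2L,
                        n_kernel = 3L)
  wv <- toy_word_vectors(c("alpha", "beta", "gamma", "delta"), dim = word_dim)
  params <- init_encoder_params(cfg, wv, seed = seed)
  list(cfg = cfg, params = params, wv = wv)
}

test_that("dependency encoding follows the tanh-affine closed form", {
  te <- toy_encoder()
  p <- te$params
  # zero-weight limit: every label collapses to tanh(b_d)
  p0 <- p; p0$W_d[] <- 0; p0$b_d <- c(0.3, -0.2)
  d <- encode_dependency(c("nsubj", "dobj", "TITLE"), "with", p0, te$cfg)
  expect_equal(d, matrix(tanh(c(0.3, -0.2)), 3, 2, byrow = TRUE))

  # opposite directions differ when the direction rows differ
  dw <- encode_dependency("nsubj", "with", p, te$cfg)
  da <- encode_dependency("nsubj", "against", p, te$cfg)
  expect_false(isTRUE(all.equal(dw, da)))

  # hand-computed 2-dim case
  row <- c(p$typ_tab[match("amod", dep_label_inventory()), ],
           p$dir_tab[2, ])
  want <- tanh(row %*% p$W_d + p$b_d)
  expect_equal(encode_dependency("amod", "against", p, te$cfg),
               want, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(abs(encode_dependency("conj", "with", p, te$cfg)) < 1))
})

test_that("token encoding is deterministic and matches its closed form", {
  te <- toy_encoder()
  p <- te$params
  p0 <- p; p0$W_t[] <- 0; p0$b_t <- c(-1, 2)
  t0 <- encode_token("alpha", "NN", p0, te$cfg)
  expect_equal(drop(t0), tanh(c(-1, 2)))

  t1 <- encode_token(c("beta", "beta"), c("JJ", "JJ"), p, te$cfg)
  expect_identical(t1[1, ], t1[2, ])

  feat <- c(p$word_tab["gamma", ], p$pos_tab[match("VBD", pos_tag_inventory()), ])
  expect_equal(drop(encode_token("gamma", "VBD", p, te$cfg)),
               drop(tanh(feat %*% p$W_t + p$b_t)), tolerance = 1e-6)

  # out-of-vocabulary surface falls back to the reserved row
  oov <- encode_token("zzz-unknown", "NN", p, te$cfg)
  feat_oov <- c(p$word_tab["<oov>", ], p$pos_tab[match("NN", pos_tag_inventory()), ])
  expect_equal(drop(oov), drop(tanh(feat_oov %*% p$W_t + p$b_t)))
})

test_that("heuristic attention follows sigmoid(beta d^2) exactly", {
  te <- toy_encoder()
  ch <- function(d) data.frame(surface = "beta", pos = "NN",
                               deprel = "dobj", dist = d)
  att0 <- child_attention(ch(0L), "alpha", te$params, te$cfg)
  expect_equal(att0$alpha_h, 0.5)

  att5 <- child_attention(ch(5L), "alpha", te$params, te$cfg)
  expect_equal(att5$alpha_h, 1 / (1 + exp(0.75)), tolerance = 1e-6)
  expect_equal(att5$alpha_h, 0.32082, tolerance = 1e-4)

  # strictly decreasing in |d|
  ah <- vapply(1:10, function(d) child_attention(ch(d), "alpha", te$params,
                                                 te$cfg)$alpha_h, 1)
  expect_true(all(diff(ah) < 0))
  expect_true(all(ah > 0 & ah < 1))
  expect_true(all(att5$alpha_s > 0 & att5$alpha_s < 1))
  # the gated row is the elementwise-scaled child context
  expect_equal(att5$attended, att5$cbar * (att5$alpha_s * att5$alpha_h))
})

test_that("augmentation is ReLU-filter max pooling with a zero leaf default", {
  te <- toy_encoder()
  p <- te$params
  children <- data.frame(surface = c("alpha", "beta", "gamma"),
                         pos = "NN", deprel = "dobj", dist = c(-2L, 1L, 3L))
  att <- child_attention(children, "delta", p, te$cfg)

  p0 <- p; p0$W_f[] <- 0; p0$b_f <- c(-1, 0.5, 2)
  expect_equal(augment(att$attended, p0), c(0, 0.5, 2))

  one <- child_attention(children[2, ], "delta", p, te$cfg)
  expect_equal(augment(one$attended, p),
               drop(pmax(one$attended %*% p$W_f + p$b_f, 0)))

  # exhaustive per-component max oracle over the three children
  fmat <- pmax(sweep(att$attended %*% p$W_f, 2, p$b_f, `+`), 0)
  want <- vapply(seq_len(ncol(fmat)), function(k) max(fmat[, k]), 1)
  expect_equal(augment(att$attended, p), want)
  expect_true(all(augment(att$attended, p) >= 0))

  expect_equal(augment(NULL, p), c(0, 0, 0))
  expect_equal(augment(att$attended[0, , drop = FALSE], p), c(0, 0, 0))
})

test_that("the final token transform matches its closed form", {
  te <- toy_encoder()
  p <- te$params
  p0 <- p; p0$W_x[] <- 0; p0$b_x <- c(0.7, -0.1)
  expect_equal(drop(finalize_token(c(0.1, 0.2), c(1, 0, 2), p0)),
               tanh(c(0.7, -0.1)))
  tvec <- c(0.3, -0.4); avec <- c(0.5, 0, 1)
  expect_equal(drop(finalize_token(tvec, avec, p)),
               drop(tanh(c(tvec, avec) %*% p$W_x + p$b_x)), tolerance = 1e-6)
})

test_that("path encoding alternates tokens and dependency units", {
  td <- tiny_doc()
  wv <- toy_word_vectors(c("chemx", "relieves", "pain", "Patients", "got",
                           "disy", "quickly", "."), dim = 4L)
  cfg <- compact_encoder_config(word_dim = 4L)
  params <- init_encoder_params(cfg, wv, seed = 2L)
  inst <- mine_document(td$doc, td$parses, w = 1L)
  cid <- inst[[which(vapply(inst, `[[`, "", "label") == "CID")]]
  ep <- encode_path(cid$paths[[1]], td$parses, params, cfg)
  n <- nrow(cid$paths[[1]]$tokens)
  expect_identical(dim(ep$x), as.integer(c(n, cfg$token_out)))
  expect_identical(dim(ep$d), as.integer(c(n - 1L, cfg$dep_out)))
  expect_true(all(abs(ep$x) < 1) && all(abs(ep$d) < 1))

  # a token is encoded identically on every path through it
  inst2 <- mine_document(td$doc, td$parses, w = 2L)
  keys <- vapply(inst2, function(x) paste(x$chemical, x$disease), "")
  p1 <- inst2[[which(keys == "C001 D001")]]$paths[[1]]
  p2 <- inst2[[which(keys == "C001 D002")]]$paths[[1]]
  e1 <- encode_path(p1, td$parses, params, cfg)
  e2 <- encode_path(p2, td$parses, params, cfg)
  expect_equal(e1$x[1, ], e2$x[1, ])          # shared chemical head token
})

test_that("path encoding equals an independent straight-line recomputation", {
  td <- tiny_doc()
  wv <- toy_word_vectors(c("chemx", "relieves", "pain", "Patients", "got",
                           "disy", "quickly", "."), dim = 4L)
  cfg <- compact_encoder_config(word_dim = 4L)
  p <- init_encoder_params(cfg, wv, seed = 2L)
  inst <- mine_document(td$doc, td$parses, w = 1L)
  cid <- inst[[which(vapply(inst, `[[`, "", "label") == "CID")]]
  path <- cid$paths[[1]]
  got <- encode_path(path, td$parses, p, cfg)

  inv_pos <- pos_tag_inventory(); inv_dep <- dep_label_inventory()
  sigm <- function(z) 1 / (1 + exp(-z))
  for (i in seq_len(nrow(path$tokens))) {
    surf <- path$tokens$surface[i]
    wrow <- if (surf %in% rownames(p$word_tab)) p$word_tab[surf, ] else
      p$word_tab["<oov>", ]
    tvec <- tanh(c(wrow, p$pos_tab[match(path$tokens$pos[i], inv_pos), ]) %*%
                   p$W_t + p$b_t)
    parse <- td$parses[[path$tokens$sent[i] + 1L]]
    kids <- which(parse$heads == path$tokens$tok[i])
    avec <- numeric(cfg$n_kernel)
    if (length(kids)) {
      fmax <- rep(-Inf, cfg$n_kernel)
      for (kid in kids) {
        ksurf <- parse$tokens$surface[kid]
        kw <- if (ksurf %in% rownames(p$word_tab)) p$word_tab[ksurf, ] else
          p$word_tab["<oov>", ]
        cbar <- c(kw, p$pos_tab[match(parse$tokens$pos[kid], inv_pos), ],
                  p$typ_tab[match(parse$deprels[kid], inv_dep), ],
                  wrow, (kid - path$tokens$tok[i]) * p$w_dist)
        gate <- sigm(drop(cbar %*% p$W_e) + p$b_e) *
          sigm(cfg$beta * (kid - path$tokens$tok[i])^2)
        fmax <- pmax(fmax, pmax(drop((gate * cbar) %*% p$W_f) + p$b_f, 0))
      }
      avec <- fmax
    }
    xvec <- tanh(c(tvec, avec) %*% p$W_x + p$b_x)
    expect_equal(got$x[i, ], drop(xvec), tolerance = 1e-10)
  }
  for (j in seq_len(nrow(path$edges))) {
    lab <- path$edges$label[j]
    typ <- if (lab %in% virtual_label_inventory()) {
      p$virt_tab[match(lab, virtual_label_inventory()), ]
    } else p$typ_tab[match(lab, inv_dep), ]
    dirrow <- p$dir_tab[if (path$edges$direction[j] == "with") 1L else 2L, ]
    expect_equal(got$d[j, ], drop(tanh(c(typ, dirrow) %*% p$W_d + p$b_d)),
                 tolerance = 1e-10)
  }
})

test_that("the full-scale configuration reproduces the published dimensions", {
  cfg <- encoder_config()
  expect_identical(cfg$child_dim, 832)
  expect_identical(cfg$token_in, 495L + 0)  # 300 + 50 + 100 + 45
  wv <- toy_word_vectors(c("alpha", "beta"), dim = 300L)
  p <- init_encoder_params(cfg, wv, seed = 1L)
  expect_identical(dim(p$typ_tab), c(72L, 150L))
  expect_identical(dim(p$virt_tab), c(6L, 150L))
  tok <- encode_token("alpha", "NN", p, cfg)
  expect_identical(ncol(tok), 595L)
  expect_true(all(abs(tok) < 1))
  ch <- char_encode(c("alpha", "Zz9!"), p, cfg)
  expect_identical(dim(ch), c(2L, 100L))
})
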