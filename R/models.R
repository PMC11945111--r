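# The three networks: a decoder-only autoregressive SMILES generator, a
# scaffold-conditioned encoder-decoder generator, and a two-layer Bi-LSTM
# discriminator over last-layer feature maps.

#' Generator architecture configuration
#'
#' Defaults follow the reference setting: 8 decoder layers (plus 8 encoder
#' layers for the scaffold-conditioned model), 8 attention heads and a model
#' dimension of 256. Positional information uses learned embeddings up to
#' `max_len`.
#'
#' @param vocab_size Size of the token vocabulary (including specials).
#' @param n_decoder_layers,n_encoder_layers,n_heads,model_dim Architecture
#'   sizes; `model_dim` must be divisible by `n_heads`.
#' @param max_len Maximum sequence length (positions with learned embeddings).
#' @param dropout Dropout fraction applied to attention and feed-forward
#'   residual branches during training.
#' @param ffn_mult Width multiplier of the position-wise feed-forward layer.
#' @return A `generator_config` list.
#' @export
generator_config <- function(vocab_size,
                             n_decoder_layers = 8L,
                             n_encoder_layers = 8L,
                             n_heads = 8L,
                             model_dim = 256L,
                             max_len = 128L,
                             dropout = 0.1,
                             ffn_mult = 4L) {
  stopifnot(
    vocab_size > 0L, n_decoder_layers > 0L, n_heads > 0L, model_dim > 0L,
    model_dim %% n_heads == 0L, max_len > 0L, dropout >= 0, dropout < 1
  )
  structure(
    list(
      vocab_size = as.integer(vocab_size),
      n_decoder_layers = as.integer(n_decoder_layers),
      n_encoder_layers = as.integer(n_encoder_layers),
      n_heads = as.integer(n_heads),
      model_dim = as.integer(model_dim),
      max_len = as.integer(max_len),
      dropout = dropout,
      ffn_mult = as.integer(ffn_mult)
    ),
    class = "generator_config"
  )
}

#' Tiny desk-scale preset of [generator_config()]
#'
#' 2 layers, 64 dimensions, 4 heads — enough capacity to learn the toy
#' grammar in minutes on one CPU.
#' @inheritParams generator_config
#' @export
tiny_generator_config <- function(vocab_size, max_len = 64L) {
  generator_config(
    vocab_size,
    n_decoder_layers = 2L, n_encoder_layers = 2L,
    n_heads = 4L, model_dim = 64L, max_len = max_len,
    dropout = 0.1, ffn_mult = 2L
  )
}

# run expr with a locally-set RNG, restoring the caller's stream
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rnorm_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

new_param_set <- function() new.env(parent = emptyenv())

add_param <- function(ps, name, value) assign(name, tn_param(value), envir = ps)

param_names <- function(model) sort(ls(model$params))

param_list <- function(model) {
  mget(param_names(model), envir = model$params)
}

#' Total trainable parameter count of a model
#' @param model A generator or discriminator object.
#' @return Integer scalar.
#' @export
n_parameters <- function(model) {
  sum(vapply(param_list(model), function(p) length(p$value), numeric(1)))
}

decoder_layer_params <- function(ps, prefix, d, ffn) {
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    add_param(ps, paste0(prefix, nm), rnorm_mat(d, d))
  }
  for (nm in c("bq", "bk", "bv", "bo")) {
    add_param(ps, paste0(prefix, nm), matrix(0, 1, d))
  }
  add_param(ps, paste0(prefix, "ln1_g"), matrix(1, 1, d))
  add_param(ps, paste0(prefix, "ln1_b"), matrix(0, 1, d))
  add_param(ps, paste0(prefix, "ln2_g"), matrix(1, 1, d))
  add_param(ps, paste0(prefix, "ln2_b"), matrix(0, 1, d))
  add_param(ps, paste0(prefix, "W1"), rnorm_mat(d, ffn))
  add_param(ps, paste0(prefix, "b1"), matrix(0, 1, ffn))
  add_param(ps, paste0(prefix, "W2"), rnorm_mat(ffn, d))
  add_param(ps, paste0(prefix, "b2"), matrix(0, 1, d))
}

cross_attn_params <- function(ps, prefix, d) {
  for (nm in c("Wqc", "Wkc", "Wvc", "Woc")) {
    add_param(ps, paste0(prefix, nm), rnorm_mat(d, d))
  }
  for (nm in c("bqc", "bkc", "bvc", "boc")) {
    add_param(ps, paste0(prefix, nm), matrix(0, 1, d))
  }
  add_param(ps, paste0(prefix, "lnc_g"), matrix(1, 1, d))
  add_param(ps, paste0(prefix, "lnc_b"), matrix(0, 1, d))
}

#' Create a from-scratch autoregressive generator
#'
#' A decoder-only transformer trained with next-token prediction over SMILES
#' tokens.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `smiles_generator` object with `$kind = "from_scratch"`.
#' @export
new_gpt_generator <- function(config, seed = 1L) {
  ps <- new_param_set()
  d <- config$model_dim
  ffn <- d * config$ffn_mult
  local_seed(seed, {
    add_param(ps, "tok_emb", rnorm_mat(config$vocab_size, d))
    add_param(ps, "pos_emb", rnorm_mat(config$max_len, d))
    for (l in seq_len(config$n_decoder_layers)) {
      decoder_layer_params(ps, sprintf("dec%02d_", l), d, ffn)
    }
    add_param(ps, "lnf_g", matrix(1, 1, d))
    add_param(ps, "lnf_b", matrix(0, 1, d))
    add_param(ps, "W_out", rnorm_mat(d, config$vocab_size))
    add_param(ps, "b_out", matrix(0, 1, config$vocab_size))
  })
  structure(
    list(params = ps, config = config, kind = "from_scratch", seed = seed),
    class = c("smiles_gpt", "smiles_generator")
  )
}

#' Create a scaffold-conditioned encoder-decoder generator
#'
#' A standard transformer: the encoder reads the scaffold SMILES (full
#' bidirectional attention) and the decoder generates the molecule token
#' stream with causal self-attention plus cross-attention into the encoder
#' states.
#'
#' @inheritParams new_gpt_generator
#' @return A `smiles_generator` object with `$kind = "scaffold_based"`.
#' @export
new_scaffold_generator <- function(config, seed = 2L) {
  ps <- new_param_set()
  d <- config$model_dim
  ffn <- d * config$ffn_mult
  local_seed(seed, {
    add_param(ps, "tok_emb", rnorm_mat(config$vocab_size, d))
    add_param(ps, "pos_emb", rnorm_mat(config$max_len, d))
    add_param(ps, "enc_pos_emb", rnorm_mat(config$max_len, d))
    for (l in seq_len(config$n_encoder_layers)) {
      decoder_layer_params(ps, sprintf("enc%02d_", l), d, ffn)
    }
    add_param(ps, "enc_lnf_g", matrix(1, 1, d))
    add_param(ps, "enc_lnf_b", matrix(0, 1, d))
    for (l in seq_len(config$n_decoder_layers)) {
      prefix <- sprintf("dec%02d_", l)
      decoder_layer_params(ps, prefix, d, ffn)
      cross_attn_params(ps, prefix, d)
    }
    add_param(ps, "lnf_g", matrix(1, 1, d))
    add_param(ps, "lnf_b", matrix(0, 1, d))
    add_param(ps, "W_out", rnorm_mat(d, config$vocab_size))
    add_param(ps, "b_out", matrix(0, 1, config$vocab_size))
  })
  structure(
    list(params = ps, config = config, kind = "scaffold_based", seed = seed),
    class = c("smiles_seq2seq", "smiles_generator")
  )
}

#' @export
print.smiles_generator <- function(x, ...) {
  cat(sprintf(
    "<%s SMILES generator: %d layers, %d heads, dim %d, vocab %d, %s parameters>\n",
    x$kind, x$config$n_decoder_layers, x$config$n_heads, x$config$model_dim,
    x$config$vocab_size, format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

## ---- packed ragged batches -----------------------------------------------

# Flatten a padded id matrix + mask into a ragged "packed" batch: one row per
# real token, with its sequence label and 1-based position. PAD tokens never
# enter the computation, so masking is structural.
pack_batch <- function(ids, mask) {
  stopifnot(is.matrix(ids), identical(dim(ids), dim(mask)))
  keep <- which(t(mask))                # row-major order: seq 1 tokens, seq 2 ...
  tid <- t(ids)
  pos_m <- t(matrix(rep(seq_len(ncol(ids)), each = nrow(ids)), nrow(ids)))
  seq_m <- t(matrix(rep(seq_len(nrow(ids)), times = ncol(ids)), nrow(ids)))
  list(
    ids = as.integer(tid[keep]),
    seq = as.integer(seq_m[keep]),
    pos = as.integer(pos_m[keep]),
    n_seq = nrow(ids)
  )
}

# index matrix (n_seq x max_len) mapping (sequence, position) -> packed row,
# 0 where no token exists; used to re-pad feature maps for the discriminator
packed_index_matrix <- function(packed) {
  L <- max(packed$pos)
  m <- matrix(0L, packed$n_seq, L)
  m[cbind(packed$seq, packed$pos)] <- seq_along(packed$ids)
  m
}

## ---- forward passes (tape) -----------------------------------------------

get_p <- function(model, nm, frozen = FALSE) {
  p <- get(nm, envir = model$params)
  if (frozen) tn_const(p$value) else p
}

linear <- function(x, W, b) tn_add(tn_matmul(x, W), b)

transformer_block <- function(x, P, prefix, seq_labels, n_heads, causal,
                              dropout, enc = NULL, enc_seq = NULL) {
  a <- tn_layernorm(x, P(paste0(prefix, "ln1_g")), P(paste0(prefix, "ln1_b")))
  q <- linear(a, P(paste0(prefix, "Wq")), P(paste0(prefix, "bq")))
  k <- linear(a, P(paste0(prefix, "Wk")), P(paste0(prefix, "bk")))
  v <- linear(a, P(paste0(prefix, "Wv")), P(paste0(prefix, "bv")))
  att <- tn_attention(q, k, v, seq_labels, seq_labels, n_heads, causal)
  att <- linear(att, P(paste0(prefix, "Wo")), P(paste0(prefix, "bo")))
  x <- tn_add(x, tn_dropout(att, dropout))
  if (!is.null(enc)) {
    c_in <- tn_layernorm(x, P(paste0(prefix, "lnc_g")), P(paste0(prefix, "lnc_b")))
    qc <- linear(c_in, P(paste0(prefix, "Wqc")), P(paste0(prefix, "bqc")))
    kc <- linear(enc, P(paste0(prefix, "Wkc")), P(paste0(prefix, "bkc")))
    vc <- linear(enc, P(paste0(prefix, "Wvc")), P(paste0(prefix, "bvc")))
    catt <- tn_attention(qc, kc, vc, seq_labels, enc_seq, n_heads, causal = FALSE)
    catt <- linear(catt, P(paste0(prefix, "Woc")), P(paste0(prefix, "boc")))
    x <- tn_add(x, tn_dropout(catt, dropout))
  }
  f <- tn_layernorm(x, P(paste0(prefix, "ln2_g")), P(paste0(prefix, "ln2_b")))
  ffn <- linear(tn_gelu(linear(f, P(paste0(prefix, "W1")), P(paste0(prefix, "b1")))),
                P(paste0(prefix, "W2")), P(paste0(prefix, "b2")))
  tn_add(x, tn_dropout(ffn, dropout))
}

embed_packed <- function(model, packed, P, pos_name = "pos_emb") {
  cfg <- model$config
  if (max(packed$pos) > cfg$max_len) {
    stop("sequence longer than config max_len", call. = FALSE)
  }
  if (max(packed$ids) > cfg$vocab_size) {
    stop("token id outside vocabulary", call. = FALSE)
  }
  tn_add(tn_embed(P("tok_emb"), packed$ids), tn_embed(P(pos_name), packed$pos))
}

#' Forward pass of the from-scratch generator (teacher-forced)
#'
#' @param model A `smiles_gpt` from [new_gpt_generator()].
#' @param packed A packed batch (internal representation from padded ids and
#'   masks); see [encode_smiles_batch()].
#' @param train Logical; apply dropout when `TRUE`.
#' @param frozen Logical; treat parameters as constants (no gradients).
#' @return A list with tensors `logits` (tokens x vocab), `feature_map`
#'   (tokens x model_dim, output of the last decoder layer before the
#'   vocabulary projection) and `source = "from_scratch"`.
#' @keywords internal
gpt_forward <- function(model, packed, train = FALSE, frozen = FALSE) {
  cfg <- model$config
  P <- function(nm) get_p(model, nm, frozen)
  drop_p <- if (train) cfg$dropout else 0
  x <- embed_packed(model, packed, P)
  for (l in seq_len(cfg$n_decoder_layers)) {
    x <- transformer_block(
      x, P, sprintf("dec%02d_", l), packed$seq, cfg$n_heads,
      causal = TRUE, dropout = drop_p
    )
  }
  h <- tn_layernorm(x, P("lnf_g"), P("lnf_b"))
  logits <- linear(h, P("W_out"), P("b_out"))
  list(logits = logits, feature_map = h, source = "from_scratch",
       seq = packed$seq)
}

encoder_forward <- function(model, packed, train = FALSE, frozen = FALSE) {
  cfg <- model$config
  P <- function(nm) get_p(model, nm, frozen)
  drop_p <- if (train) cfg$dropout else 0
  x <- embed_packed(model, packed, P, pos_name = "enc_pos_emb")
  for (l in seq_len(cfg$n_encoder_layers)) {
    x <- transformer_block(
      x, P, sprintf("enc%02d_", l), packed$seq, cfg$n_heads,
      causal = FALSE, dropout = drop_p
    )
  }
  tn_layernorm(x, P("enc_lnf_g"), P("enc_lnf_b"))
}

#' Forward pass of the scaffold-conditioned generator (teacher-forced)
#'
#' The encoder attends bidirectionally over scaffold tokens; the decoder is
#' causal over molecule tokens with cross-attention into the encoder states.
#'
#' @param model A `smiles_seq2seq` from [new_scaffold_generator()].
#' @param scaffold_packed,packed Packed scaffold and molecule batches with
#'   matching sequence labels.
#' @inheritParams gpt_forward
#' @return As [gpt_forward()], with `source = "scaffold_based"`.
#' @keywords internal
sg_forward <- function(model, scaffold_packed, packed, train = FALSE,
                       frozen = FALSE) {
  cfg <- model$config
  P <- function(nm) get_p(model, nm, frozen)
  drop_p <- if (train) cfg$dropout else 0
  enc <- encoder_forward(model, scaffold_packed, train = train, frozen = frozen)
  x <- embed_packed(model, packed, P)
  for (l in seq_len(cfg$n_decoder_layers)) {
    x <- transformer_block(
      x, P, sprintf("dec%02d_", l), packed$seq, cfg$n_heads,
      causal = TRUE, dropout = drop_p,
      enc = enc, enc_seq = scaffold_packed$seq
    )
  }
  h <- tn_layernorm(x, P("lnf_g"), P("lnf_b"))
  logits <- linear(h, P("W_out"), P("b_out"))
  list(logits = logits, feature_map = h, source = "scaffold_based",
       seq = packed$seq)
}

## ---- discriminator --------------------------------------------------------

#' Create the feature-map discriminator
#'
#' A two-layer bidirectional LSTM over per-token feature maps. The final
#' hidden states of both directions of the top layer are concatenated and
#' passed through an affine map and a logistic squash, yielding one
#' probability per sequence: the estimated probability that the features come
#' from the scaffold-conditioned generator.
#'
#' @param model_dim Feature-map dimension (input size; hidden size matches).
#' @param n_layers Number of stacked Bi-LSTM layers.
#' @param seed Integer seed for initialisation.
#' @return A `feature_discriminator` object.
#' @export
new_discriminator <- function(model_dim, n_layers = 2L, seed = 3L) {
  ps <- new_param_set()
  H <- as.integer(model_dim)
  local_seed(seed, {
    for (l in seq_len(n_layers)) {
      in_dim <- if (l == 1L) H else 2L * H
      for (dr in c("f", "b")) {
        prefix <- sprintf("l%d%s_", l, dr)
        add_param(ps, paste0(prefix, "Wx"), rnorm_mat(in_dim, 4L * H, sd = 0.05))
        add_param(ps, paste0(prefix, "Wh"), rnorm_mat(H, 4L * H, sd = 0.05))
        add_param(ps, paste0(prefix, "b"), matrix(0, 1, 4L * H))
      }
    }
    add_param(ps, "W_head", rnorm_mat(2L * H, 1L, sd = 0.05))
    add_param(ps, "b_head", matrix(0, 1, 1))
  })
  structure(
    list(params = ps, hidden = H, n_layers = as.integer(n_layers), seed = seed),
    class = "feature_discriminator"
  )
}

#' @export
print.feature_discriminator <- function(x, ...) {
  cat(sprintf(
    "<Bi-LSTM feature discriminator: %d layers, hidden %d, %s parameters>\n",
    x$n_layers, x$hidden, format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

lstm_cell <- function(x_t, h_prev, c_prev, Wx, Wh, b, H) {
  z <- tn_add(tn_add(tn_matmul(x_t, Wx), tn_matmul(h_prev, Wh)), b)
  i <- tn_sigmoid(tn_cols(z, 1:H))
  f <- tn_sigmoid(tn_cols(z, (H + 1):(2 * H)))
  g <- tn_tanh(tn_cols(z, (2 * H + 1):(3 * H)))
  o <- tn_sigmoid(tn_cols(z, (3 * H + 1):(4 * H)))
  c_new <- tn_add(tn_mul(f, c_prev), tn_mul(i, g))
  h_new <- tn_mul(o, tn_tanh(c_new))
  list(h = h_new, c = c_new)
}

# one direction of one layer over a list of timestep inputs; `masks` is a
# list of B x 1 {0,1} columns. Padded steps carry state through unchanged, so
# PAD positions cannot influence the verdict.
lstm_direction <- function(xs, masks, Wx, Wh, b, H, reverse) {
  B <- nrow(xs[[1]]$value)
  h <- tn_const(matrix(0, B, H))
  c <- tn_const(matrix(0, B, H))
  steps <- if (reverse) rev(seq_along(xs)) else seq_along(xs)
  outs <- vector("list", length(xs))
  for (t in steps) {
    cell <- lstm_cell(xs[[t]], h, c, Wx, Wh, b, H)
    m <- masks[[t]]
    keep <- tn_const(1 - m$value)
    h <- tn_add(tn_mul(cell$h, m), tn_mul(h, keep))
    c <- tn_add(tn_mul(cell$c, m), tn_mul(c, keep))
    outs[[t]] <- h
  }
  list(outputs = outs, final = h)
}

#' Discriminator verdict on a batch of feature-map sequences
#'
#' @param disc A [new_discriminator()] object.
#' @param feature_map Tensor of packed per-token features (tokens x dim).
#' @param index Integer matrix (sequences x positions) mapping into packed
#'   rows, 0 at padded positions (see internals of the training loop).
#' @param eps Verdicts are clamped to `[eps, 1 - eps]` so adversarial log
#'   terms stay finite.
#' @return Tensor of per-sequence probabilities (sequences x 1), each inside
#'   the open unit interval.
#' @keywords internal
discriminate <- function(disc, feature_map, index, eps = 1e-7) {
  H <- disc$hidden
  P <- function(nm) get(nm, envir = disc$params)
  L <- ncol(index)
  xs <- lapply(seq_len(L), function(t) tn_rows_pad(feature_map, index[, t]))
  masks <- lapply(seq_len(L), function(t) {
    tn_const(matrix(as.numeric(index[, t] > 0L), ncol = 1L))
  })
  finals <- NULL
  for (l in seq_len(disc$n_layers)) {
    fwd <- lstm_direction(xs, masks, P(sprintf("l%df_Wx", l)),
                          P(sprintf("l%df_Wh", l)), P(sprintf("l%df_b", l)),
                          H, reverse = FALSE)
    bwd <- lstm_direction(xs, masks, P(sprintf("l%db_Wx", l)),
                          P(sprintf("l%db_Wh", l)), P(sprintf("l%db_b", l)),
                          H, reverse = TRUE)
    xs <- lapply(seq_len(L), function(t) tn_cbind(fwd$outputs[[t]], bwd$outputs[[t]]))
    finals <- list(fwd = fwd$final, bwd = bwd$final)
  }
  summary_vec <- tn_cbind(finals$fwd, finals$bwd)
  logit <- tn_add(tn_matmul(summary_vec, P("W_head")), P("b_head"))
  tn_clamp(tn_sigmoid(logit), eps, 1 - eps)
}
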