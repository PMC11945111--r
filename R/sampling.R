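# Autoregressive SMILES sampling: unconditional from the fixed start token
# 'C', or conditioned on a scaffold consumed once by the encoder. Decoding
# runs in a tape-free numeric fast path with per-layer key/value caches;
# tests verify it reproduces the training-time forward pass exactly.

#' Sampling configuration
#'
#' @param n_samples Number of SMILES strings to draw.
#' @param max_len Maximum generated token count (excluding the BOS seed).
#' @param temperature Softmax temperature (> 0) applied to logits.
#' @param strategy `"multinomial"` (default) or `"greedy"`.
#' @param seed Integer seed; seeded runs are byte-reproducible.
#' @param start_token First generated token, fed as the first input and
#'   emitted as the first character of every sample (default the literal
#'   carbon token `"C"`). Set `NULL` to start from the non-emitting BOS.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(n_samples = 100L,
                            max_len = 64L,
                            temperature = 1.0,
                            strategy = c("multinomial", "greedy"),
                            seed = 1L,
                            start_token = "C") {
  strategy <- match.arg(strategy)
  stopifnot(n_samples >= 0L, max_len >= 1L, temperature > 0)
  structure(
    list(
      n_samples = as.integer(n_samples), max_len = as.integer(max_len),
      temperature = temperature, strategy = strategy,
      seed = as.integer(seed), start_token = start_token
    ),
    class = "sampling_config"
  )
}

## ---- numeric (tape-free) forward helpers ---------------------------------

pv <- function(model, nm) get(nm, envir = model$params)$value

ln_np <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc * inv, 2L, as.numeric(g), "*"), 2L, as.numeric(b), "+")
}

lin_np <- function(x, W, b) sweep(x %*% W, 2L, as.numeric(b), "+")

gelu_np <- function(x) x * stats::pnorm(x)

softmax_rows_np <- function(x) {
  z <- exp(x - apply(x, 1L, max))
  z / rowSums(z)
}

# full numeric encoder pass over one scaffold sequence (Ls x d)
encoder_forward_np <- function(model, scaf_ids) {
  cfg <- model$config
  Ls <- length(scaf_ids)
  x <- pv(model, "tok_emb")[scaf_ids, , drop = FALSE] +
    pv(model, "enc_pos_emb")[seq_len(Ls), , drop = FALSE]
  dh <- cfg$model_dim %/% cfg$n_heads
  for (l in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%02d_", l)
    a <- ln_np(x, pv(model, paste0(pre, "ln1_g")), pv(model, paste0(pre, "ln1_b")))
    q <- lin_np(a, pv(model, paste0(pre, "Wq")), pv(model, paste0(pre, "bq")))
    k <- lin_np(a, pv(model, paste0(pre, "Wk")), pv(model, paste0(pre, "bk")))
    v <- lin_np(a, pv(model, paste0(pre, "Wv")), pv(model, paste0(pre, "bv")))
    att <- matrix(0, Ls, cfg$model_dim)
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
      att[, cols] <- softmax_rows_np(S) %*% v[, cols, drop = FALSE]
    }
    x <- x + lin_np(att, pv(model, paste0(pre, "Wo")), pv(model, paste0(pre, "bo")))
    f <- ln_np(x, pv(model, paste0(pre, "ln2_g")), pv(model, paste0(pre, "ln2_b")))
    x <- x + lin_np(
      gelu_np(lin_np(f, pv(model, paste0(pre, "W1")), pv(model, paste0(pre, "b1")))),
      pv(model, paste0(pre, "W2")), pv(model, paste0(pre, "b2"))
    )
  }
  ln_np(x, pv(model, "enc_lnf_g"), pv(model, "enc_lnf_b"))
}

decoder_cache_init <- function(model, B, max_steps, enc_h = NULL) {
  cfg <- model$config
  n_l <- cfg$n_decoder_layers
  state <- list(
    t = 0L,
    K = replicate(n_l, array(0, c(B, max_steps, cfg$model_dim)), simplify = FALSE),
    V = replicate(n_l, array(0, c(B, max_steps, cfg$model_dim)), simplify = FALSE)
  )
  if (!is.null(enc_h)) {
    state$Kc <- lapply(seq_len(n_l), function(l) {
      pre <- sprintf("dec%02d_", l)
      lin_np(enc_h, pv(model, paste0(pre, "Wkc")), pv(model, paste0(pre, "bkc")))
    })
    state$Vc <- lapply(seq_len(n_l), function(l) {
      pre <- sprintf("dec%02d_", l)
      lin_np(enc_h, pv(model, paste0(pre, "Wvc")), pv(model, paste0(pre, "bvc")))
    })
  }
  state
}

# one decode step for token ids (length B) at the next position; returns the
# per-sample logits and the updated cache state
decoder_cache_step <- function(model, state, ids_t) {
  cfg <- model$config
  B <- length(ids_t)
  t <- state$t + 1L
  if (t > cfg$max_len) stop("decode exceeded config max_len", call. = FALSE)
  dh <- cfg$model_dim %/% cfg$n_heads
  x <- pv(model, "tok_emb")[ids_t, , drop = FALSE] +
    matrix(pv(model, "pos_emb")[t, ], B, cfg$model_dim, byrow = TRUE)
  cross <- !is.null(state$Kc)
  for (l in seq_len(cfg$n_decoder_layers)) {
    pre <- sprintf("dec%02d_", l)
    a <- ln_np(x, pv(model, paste0(pre, "ln1_g")), pv(model, paste0(pre, "ln1_b")))
    q <- lin_np(a, pv(model, paste0(pre, "Wq")), pv(model, paste0(pre, "bq")))
    k <- lin_np(a, pv(model, paste0(pre, "Wk")), pv(model, paste0(pre, "bk")))
    v <- lin_np(a, pv(model, paste0(pre, "Wv")), pv(model, paste0(pre, "bv")))
    state$K[[l]][, t, ] <- k
    state$V[[l]][, t, ] <- v
    att <- matrix(0, B, cfg$model_dim)
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- matrix(0, B, t)
      qh <- q[, cols, drop = FALSE]
      for (j in seq_len(t)) {
        S[, j] <- rowSums(qh * matrix(state$K[[l]][, j, cols], B, dh)) / sqrt(dh)
      }
      P <- softmax_rows_np(S)
      o <- matrix(0, B, dh)
      for (j in seq_len(t)) {
        o <- o + P[, j] * matrix(state$V[[l]][, j, cols], B, dh)
      }
      att[, cols] <- o
    }
    x <- x + lin_np(att, pv(model, paste0(pre, "Wo")), pv(model, paste0(pre, "bo")))
    if (cross) {
      c_in <- ln_np(x, pv(model, paste0(pre, "lnc_g")), pv(model, paste0(pre, "lnc_b")))
      qc <- lin_np(c_in, pv(model, paste0(pre, "Wqc")), pv(model, paste0(pre, "bqc")))
      catt <- matrix(0, B, cfg$model_dim)
      for (h in seq_len(cfg$n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Sc <- tcrossprod(qc[, cols, drop = FALSE],
                         state$Kc[[l]][, cols, drop = FALSE]) / sqrt(dh)
        catt[, cols] <- softmax_rows_np(Sc) %*% state$Vc[[l]][, cols, drop = FALSE]
      }
      x <- x + lin_np(catt, pv(model, paste0(pre, "Woc")), pv(model, paste0(pre, "boc")))
    }
    f <- ln_np(x, pv(model, paste0(pre, "ln2_g")), pv(model, paste0(pre, "ln2_b")))
    x <- x + lin_np(
      gelu_np(lin_np(f, pv(model, paste0(pre, "W1")), pv(model, paste0(pre, "b1")))),
      pv(model, paste0(pre, "W2")), pv(model, paste0(pre, "b2"))
    )
  }
  h <- ln_np(x, pv(model, "lnf_g"), pv(model, "lnf_b"))
  state$t <- t
  list(logits = lin_np(h, pv(model, "W_out"), pv(model, "b_out")), state = state)
}

draw_tokens <- function(logits, config) {
  if (config$strategy == "greedy") return(max.col(logits, ties.method = "first"))
  P <- softmax_rows_np(logits / config$temperature)
  u <- stats::runif(nrow(P))
  cs <- t(apply(P, 1L, cumsum))
  max.col(cs >= u - 1e-12, ties.method = "first")
}

decode_autoregressive <- function(model, vocab, config, enc_h = NULL) {
  B <- config$n_samples
  if (B == 0L) return(character(0))
  set.seed(config$seed)
  start_id <- NULL
  if (!is.null(config$start_token)) {
    start_id <- unname(vocab$token_to_index[config$start_token])
    if (is.na(start_id)) {
      stop("start token '", config$start_token, "' missing from vocabulary",
           call. = FALSE)
    }
  }
  max_steps <- min(config$max_len + 1L, model$config$max_len)
  state <- decoder_cache_init(model, B, max_steps, enc_h = enc_h)
  res <- decoder_cache_step(model, state, rep(vocab$bos_id, B))
  state <- res$state
  emitted <- matrix(0L, B, config$max_len)
  done <- rep(FALSE, B)
  lens <- rep(0L, B)
  k <- 0L
  if (!is.null(start_id)) {
    k <- 1L
    emitted[, 1L] <- start_id
    lens[] <- 1L
    res <- decoder_cache_step(model, state, rep(as.integer(start_id), B))
    state <- res$state
  }
  while (k < config$max_len && !all(done) && state$t < max_steps) {
    logits <- res$logits
    # PAD and BOS are structural tokens, never sampled; EOS terminates
    logits[, c(vocab$pad_id, vocab$bos_id)] <- -Inf
    tok <- draw_tokens(logits, config)
    tok[done] <- vocab$pad_id
    newly_done <- !done & tok == vocab$eos_id
    live <- !done & !newly_done
    k <- k + 1L
    emitted[live, k] <- tok[live]
    lens[live] <- k
    done <- done | newly_done
    if (all(done) || k >= config$max_len) break
    feed <- tok
    feed[done] <- vocab$eos_id
    res <- decoder_cache_step(model, state, as.integer(feed))
    state <- res$state
  }
  vapply(seq_len(B), function(i) {
    if (lens[i] == 0L) return("")
    smiles_detokenize(vocab$index_to_token[emitted[i, seq_len(lens[i])]])
  }, character(1))
}

as_gpt_model <- function(model) {
  if (inherits(model, "distill_fit")) return(model$gpt)
  stopifnot(inherits(model, "smiles_gpt"))
  model
}

as_sg_model <- function(model) {
  if (inherits(model, "distill_fit")) model <- model$second
  if (!inherits(model, "smiles_seq2seq")) {
    stop("scaffold-conditioned sampling needs a scaffold-based generator",
         call. = FALSE)
  }
  model
}

#' Sample SMILES strings unconditionally
#'
#' Each sample starts from the fixed start token (default `'C'`), extends by
#' temperature-scaled draws from the next-token distribution and stops at
#' EOS or `max_len`. Raw strings are returned: validity is a metric, not a
#' constraint.
#'
#' @param model A `distill_fit` or a from-scratch generator.
#' @param vocab The matching vocabulary (taken from a `distill_fit`
#'   automatically).
#' @param config A [sampling_config()].
#' @return Character vector of `n_samples` SMILES strings.
#' @export
sample_unconditional <- function(model, config = sampling_config(),
                                 vocab = NULL) {
  if (inherits(model, "distill_fit") && is.null(vocab)) vocab <- model$vocab
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  decode_autoregressive(as_gpt_model(model), vocab, config)
}

#' Sample SMILES strings conditioned on a scaffold
#'
#' The encoder consumes the scaffold once; decoding then proceeds as in
#' [sample_unconditional()]. An empty scaffold (`""`) is accepted and
#' encoded as the bare EOS.
#'
#' @param model A `distill_fit` (with a scaffold-based second model) or a
#'   `smiles_seq2seq` generator.
#' @param scaffold Scaffold SMILES string (possibly `""`).
#' @inheritParams sample_unconditional
#' @return Character vector of `n_samples` SMILES strings.
#' @export
sample_from_scaffold <- function(model, scaffold, config = sampling_config(),
                                 vocab = NULL) {
  if (inherits(model, "distill_fit") && is.null(vocab)) vocab <- model$vocab
  stopifnot(inherits(vocab, "smiles_vocabulary"), length(scaffold) == 1L)
  sg <- as_sg_model(model)
  toks <- if (nzchar(scaffold)) smiles_tokenize(scaffold) else character(0)
  scaf_ids <- c(tokens_to_ids(toks, vocab, context = "scaffold"), vocab$eos_id)
  enc_h <- encoder_forward_np(sg, scaf_ids)
  decode_autoregressive(sg, vocab, config, enc_h = enc_h)
}
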