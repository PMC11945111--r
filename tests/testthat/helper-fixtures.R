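# Shared desk-scale fixtures, built once per test run.

md <- asNamespace("moldistill")

# small corpus + vocabulary used across model/loss tests
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- generate_toy_corpus(fixture_spec(n_molecules = 24, seed = 3))
      vocab <- build_vocabulary(c(corpus$smiles, corpus$scaffold))
      cfg <- generator_config(
        md$vocab_size(vocab), n_decoder_layers = 2L, n_encoder_layers = 1L,
        n_heads = 2L, model_dim = 16L, max_len = 48L, dropout = 0, ffn_mult = 2L
      )
      enc <- encode_smiles_batch(corpus, vocab, max_len = cfg$max_len)
      cache <<- list(corpus = corpus, vocab = vocab, cfg = cfg, enc = enc)
    }
    cache
  }
})

tiny_batch <- function(rows = 1:8) {
  w <- tiny_world()
  md$teacher_forcing_batch(w$enc, rows, w$vocab)
}

# finite-difference gradient of `loss_fn()` (a closure re-evaluating the
# loss) w.r.t. one entry of parameter `pname` of `model`
fd_grad <- function(model, pname, idx, loss_fn, eps = 1e-5) {
  p <- get(pname, envir = model$params)
  v0 <- p$value[idx]
  p$value[idx] <- v0 + eps
  up <- loss_fn()$value
  p$value[idx] <- v0 - eps
  dn <- loss_fn()$value
  p$value[idx] <- v0
  as.numeric(up - dn) / (2 * eps)
}

param_grad_norm <- function(model) {
  sum(vapply(md$param_list(model), function(p) {
    if (is.null(p$grad)) 0 else sum(abs(p$grad))
  }, numeric(1)))
}

param_checksum <- function(model) {
  sum(vapply(md$param_list(model), function(p) sum(p$value), numeric(1)))
}
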