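# Generators and discriminator: contracts, causality, parameter accounting

test_that("config validation rejects inconsistent architectures", {
  expect_error(generator_config(10, n_heads = 3, model_dim = 16))
  expect_error(generator_config(0))
  cfg <- generator_config(30)
  expect_identical(cfg$n_decoder_layers, 8L)
  expect_identical(cfg$n_heads, 8L)
  expect_identical(cfg$model_dim, 256L)
})

test_that("parameter counts match the closed form implied by the config", {
  w <- tiny_world()
  cfg <- w$cfg
  d <- cfg$model_dim
  f <- d * cfg$ffn_mult
  V <- cfg$vocab_size
  layer <- 4 * d^2 + 4 * d + 4 * d + d * f + f + f * d + d
  gpt_expected <- V * d + cfg$max_len * d +
    cfg$n_decoder_layers * layer + 2 * d + d * V + V
  expect_identical(n_parameters(new_gpt_generator(cfg)), gpt_expected)

  cross <- 4 * d^2 + 4 * d + 2 * d
  sg_expected <- gpt_expected + cfg$max_len * d +          # encoder positions
    cfg$n_encoder_layers * layer + 2 * d +                 # encoder stack + LN
    cfg$n_decoder_layers * cross                           # cross-attention
  expect_identical(n_parameters(new_scaffold_generator(cfg)), sg_expected)

  H <- d
  disc_expected <- 2 * (H * 4 * H + H * 4 * H + 4 * H) +
    2 * (2 * H * 4 * H + H * 4 * H + 4 * H) + 2 * H + 1
  expect_identical(n_parameters(new_discriminator(d)), disc_expected)
})

test_that("decoder logits are causal: later tokens cannot affect earlier ones", {
  w <- tiny_world()
  gpt <- new_gpt_generator(w$cfg, seed = 9)
  batch <- tiny_batch(1:2)
  out <- md$gpt_forward(gpt, batch$packed)
  packed2 <- batch$packed
  pos_in_seq1 <- which(packed2$seq == 1L)
  stopifnot(length(pos_in_seq1) >= 4L)
  edit_at <- pos_in_seq1[4]
  packed2$ids[edit_at] <- if (packed2$ids[edit_at] == 4L) 5L else 4L
  out2 <- md$gpt_forward(gpt, packed2)
  before <- pos_in_seq1[1:3]
  expect_equal(out$logits$value[before, ], out2$logits$value[before, ],
               tolerance = 1e-12)
  at_after <- pos_in_seq1[4:length(pos_in_seq1)]
  expect_gt(max(abs(out$logits$value[at_after, ] - out2$logits$value[at_after, ])), 0)
})

test_that("batch order permutation permutes outputs identically", {
  w <- tiny_world()
  gpt <- new_gpt_generator(w$cfg, seed = 9)
  b12 <- tiny_batch(c(3L, 7L))
  b21 <- tiny_batch(c(7L, 3L))
  o12 <- md$gpt_forward(gpt, b12$packed)$logits$value
  o21 <- md$gpt_forward(gpt, b21$packed)$logits$value
  n1 <- sum(b12$packed$seq == 1L)
  expect_equal(o12[b12$packed$seq == 1L, ], o21[b21$packed$seq == 2L, ],
               tolerance = 1e-12)
  expect_equal(o12[b12$packed$seq == 2L, ], o21[b21$packed$seq == 1L, ],
               tolerance = 1e-12)
})

test_that("scaffold conditioning is live and shapes follow the molecule", {
  w <- tiny_world()
  sg <- new_scaffold_generator(w$cfg, seed = 4)
  batch <- tiny_batch(1:3)
  out <- md$sg_forward(sg, batch$scaf_packed, batch$packed)
  expect_identical(nrow(out$logits$value), length(batch$packed$ids))
  expect_identical(ncol(out$logits$value), w$cfg$vocab_size)
  expect_identical(ncol(out$feature_map$value), w$cfg$model_dim)

  # change one scaffold -> that sequence's logits move from position 0 on
  scaf2 <- batch$scaf_packed
  s1 <- which(scaf2$seq == 1L)
  scaf2$ids[s1[1]] <- if (scaf2$ids[s1[1]] == 4L) 5L else 4L
  out2 <- md$sg_forward(sg, scaf2, batch$packed)
  first_pos <- which(batch$packed$seq == 1L)[1]
  expect_gt(max(abs(out$logits$value[first_pos, ] - out2$logits$value[first_pos, ])), 0)

  # an empty scaffold ([EOS] only) is accepted, full-length output
  rec <- tibble::tibble(smiles = "CCO", scaffold = "")
  enc <- encode_smiles_batch(rec, w$vocab, max_len = 16L)
  b <- md$teacher_forcing_batch(enc, 1L, w$vocab)
  o <- md$sg_forward(sg, b$scaf_packed, b$packed)
  expect_identical(nrow(o$logits$value), 4L) # C C O EOS
})

test_that("discriminator verdicts are probabilities and ignore PAD", {
  w <- tiny_world()
  disc <- new_discriminator(w$cfg$model_dim, seed = 5)
  set.seed(6)
  feat <- md$tn_const(matrix(rnorm(7 * w$cfg$model_dim), 7))
  idx <- rbind(c(1L, 2L, 3L, 0L), c(4L, 5L, 6L, 7L))
  v <- md$discriminate(disc, feat, idx)
  expect_identical(dim(v$value), c(2L, 1L))
  expect_true(all(v$value > 0 & v$value < 1))

  # appending masked PAD columns leaves the verdict unchanged
  idx_padded <- cbind(idx, 0L, 0L)
  v2 <- md$discriminate(disc, feat, idx_padded)
  expect_equal(v$value, v2$value, tolerance = 1e-12)

  # a zero affine head gives exactly 0.5
  wh <- get("W_head", envir = disc$params)
  bh <- get("b_head", envir = disc$params)
  wh$value[] <- 0
  bh$value[] <- 0
  v3 <- md$discriminate(disc, feat, idx)
  expect_equal(as.numeric(v3$value), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("checkpoints round-trip parameters, config and vocabulary", {
  w <- tiny_world()
  corpus <- w$corpus[1:10, ]
  fit <- train_distillation(
    corpus, gen_config = w$cfg,
    config = train_config(epochs = 1L, batch_size = 5L, seed = 2L),
    vocab = w$vocab
  )
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(param_checksum(back$gpt), param_checksum(fit$gpt))
  expect_equal(param_checksum(back$second), param_checksum(fit$second))
  expect_identical(back$vocab, fit$vocab)
  s1 <- sample_unconditional(fit, sampling_config(n_samples = 5, seed = 3, max_len = 20))
  s2 <- sample_unconditional(back, sampling_config(n_samples = 5, seed = 3, max_len = 20))
  expect_identical(s1, s2)
})
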