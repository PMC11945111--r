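# Loss analytics: closed forms, KL hand values, stop-gradient and routing

test_that("cross-entropy hits its closed forms", {
  V <- 5L
  n <- 4L
  targets <- c(2L, 1L, 5L, 3L)
  # near-certain correct prediction -> ~0
  big <- matrix(-1e4, n, V)
  big[cbind(seq_len(n), targets)] <- 1e4
  expect_equal(as.numeric(md$cross_entropy_loss(md$tn_const(big), targets)$value),
               0, tolerance = 1e-9)
  # uniform logits -> ln V per position
  unif <- matrix(0, n, V)
  expect_equal(as.numeric(md$cross_entropy_loss(md$tn_const(unif), targets)$value),
               log(V), tolerance = 1e-12)
  # masking a position removes its contribution: oracle = mean of per-row NLL
  set.seed(8)
  logits <- matrix(rnorm(n * V), n, V)
  per_row <- -vapply(seq_len(n), function(i) {
    z <- logits[i, ]
    z[targets[i]] - log(sum(exp(z)))
  }, numeric(1))
  full <- as.numeric(md$cross_entropy_loss(md$tn_const(logits), targets)$value)
  expect_equal(full, mean(per_row), tolerance = 1e-12)
  drop3 <- as.numeric(md$cross_entropy_loss(md$tn_const(logits[-3, ]), targets[-3])$value)
  expect_equal(drop3, mean(per_row[-3]), tolerance = 1e-12)
  expect_error(md$cross_entropy_loss(md$tn_const(logits[0, , drop = FALSE]),
                                     integer(0)), "empty")
})

test_that("mutual loss is the discrete KL with a stop-gradient target", {
  z <- matrix(rnorm(6), 2, 3)
  expect_equal(as.numeric(md$mutual_loss(md$tn_const(z), md$tn_const(z))$value),
               0, tolerance = 1e-12)
  # P1 = (0.5, 0.5), P2 = (0.9, 0.1): KL = 0.5 ln(0.5/0.9) + 0.5 ln(0.5/0.1)
  z1 <- md$tn_param(matrix(c(0, 0), 1))
  z2 <- md$tn_param(matrix(log(c(0.9, 0.1)), 1))
  l <- md$mutual_loss(z1, z2)
  expect_equal(as.numeric(l$value), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-6)
  expect_equal(as.numeric(l$value), log(5 / 3), tolerance = 1e-12)
  md$tn_backward(l)
  expect_null(z2$grad)          # stop-gradient: the target never sees gradient
  expect_gt(max(abs(z1$grad)), 0)
  # KL asymmetry: swapping the arguments changes the value
  l_swap <- md$mutual_loss(md$tn_const(z2$value), md$tn_const(z1$value))
  expect_false(isTRUE(all.equal(as.numeric(l$value), as.numeric(l_swap$value))))
})

test_that("adversarial losses reproduce their closed forms and limits", {
  half <- md$tn_const(matrix(0.5, 1, 1))
  expect_equal(as.numeric(md$generator_adversarial_loss(half)$value), log(0.5),
               tolerance = 1e-12)
  eps <- md$tn_const(matrix(1e-7, 1, 1))
  expect_equal(as.numeric(md$generator_adversarial_loss(eps)$value), 0,
               tolerance = 1e-6)
  two <- md$tn_const(matrix(0.5, 2, 1))
  expect_equal(as.numeric(md$generator_adversarial_loss(two)$value), log(0.5),
               tolerance = 1e-12)

  expect_equal(as.numeric(md$discriminator_loss(half, half)$value), log(2),
               tolerance = 1e-12)
  near1 <- md$tn_const(matrix(1 - 1e-7, 1, 1))
  expect_equal(as.numeric(md$discriminator_loss(eps, near1)$value), 0,
               tolerance = 1e-6)
  mislabeled <- as.numeric(md$discriminator_loss(near1, eps)$value)
  expect_gt(mislabeled, 10)
})

test_that("the composite loss is the weighted sum with implicit unit weight", {
  s <- function(x) md$tn_const(matrix(x, 1, 1))
  w <- loss_weights(1.5, 1, 0.5)
  total <- md$total_generation_loss(s(0.1), s(2), s(3), s(0.4), w)
  expect_equal(as.numeric(total$value), 0.1 + 1.5 * 2 + 3 + 0.5 * 0.4,
               tolerance = 1e-12)
  zero_w <- md$total_generation_loss(s(0.7), s(2), s(3), s(0.4),
                                     loss_weights(0, 0, 0))
  expect_equal(as.numeric(zero_w$value), 0.7, tolerance = 1e-12)
  no_terms <- md$total_generation_loss(NULL, NULL, NULL, NULL, w)
  expect_equal(as.numeric(no_terms$value), 0)
  expect_error(loss_weights(-1, 1, 1))
})

test_that("feature-map KL matches the discrete-KL oracle and stops gradient", {
  h <- matrix(rnorm(8), 2, 4)
  expect_equal(as.numeric(md$feature_map_kl_loss(md$tn_const(h), md$tn_const(h))$value),
               0, tolerance = 1e-12)
  h1 <- md$tn_param(matrix(c(0, 0), 1))
  h2 <- md$tn_param(matrix(c(log(9), 0), 1))
  l <- md$feature_map_kl_loss(h1, h2)
  expect_equal(as.numeric(l$value), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  md$tn_backward(l)
  expect_null(h2$grad)
})

test_that("gradient routing under the full variant isolates each term", {
  w <- tiny_world()
  gpt <- new_gpt_generator(w$cfg, seed = 31)
  sg <- new_scaffold_generator(w$cfg, seed = 32)
  disc <- new_discriminator(w$cfg$model_dim, seed = 33)
  batch <- tiny_batch(1:6)
  idx <- md$packed_index_matrix(batch$packed)
  fwd <- function() {
    list(g = md$gpt_forward(gpt, batch$packed),
         s = md$sg_forward(sg, batch$scaf_packed, batch$packed))
  }
  reset <- function() {
    md$zero_grads(md$param_list(gpt))
    md$zero_grads(md$param_list(sg))
    md$zero_grads(md$param_list(disc))
  }

  # L_mutual: gradient reaches only the from-scratch generator
  o <- fwd(); reset()
  md$tn_backward(md$mutual_loss(o$g$logits, o$s$logits))
  expect_gt(param_grad_norm(gpt), 0)
  expect_identical(param_grad_norm(sg), 0)

  # L_gen: gradient reaches the from-scratch generator (and D's tape), not SG
  o <- fwd(); reset()
  md$tn_backward(md$generator_adversarial_loss(
    md$discriminate(disc, o$g$feature_map, idx)))
  expect_gt(param_grad_norm(gpt), 0)
  expect_identical(param_grad_norm(sg), 0)

  # L_CE2: gradient reaches only the scaffold generator
  o <- fwd(); reset()
  md$tn_backward(md$cross_entropy_loss(o$s$logits, batch$targets))
  expect_gt(param_grad_norm(sg), 0)
  expect_identical(param_grad_norm(gpt), 0)

  # L_d on detached features: gradient reaches only the discriminator
  o <- fwd(); reset()
  v1 <- md$discriminate(disc, md$tn_detach(o$g$feature_map), idx)
  v2 <- md$discriminate(disc, md$tn_detach(o$s$feature_map), idx)
  md$tn_backward(md$discriminator_loss(v1, v2))
  expect_gt(param_grad_norm(disc), 0)
  expect_identical(param_grad_norm(gpt), 0)
  expect_identical(param_grad_norm(sg), 0)
})
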