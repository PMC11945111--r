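# Co-training loop: both generators are teacher-forced on the same batch and
# updated simultaneously from the composite loss; the discriminator is
# updated on its own cadence (every `disc_update_period` steps) from the
# negated printed objective on detached feature maps.

#' Training configuration
#'
#' @param variant One of `"full"`, `"no_ml"` (drop the mutual KL term),
#'   `"no_ad"` (drop the adversarial pair and the discriminator), `"mf"`
#'   (replace the adversarial pair with a feature-map KL), `"dual_gpt"` (the
#'   second model is another from-scratch generator with a different
#'   parameter seed), `"offline_kd"` (the scaffold model is pre-trained with
#'   its cross-entropy alone, then frozen as a static teacher).
#' @param epochs Number of passes over the corpus.
#' @param batch_size Sequences per step (reference setting: 512 MOSES-style,
#'   300 GuacaMol-style).
#' @param generator_lr,discriminator_lr AdamW learning rates (reference:
#'   0.0006 and 0.0003).
#' @param adam_betas Length-2 AdamW betas (reference: 0.9, 0.98).
#' @param weight_decay AdamW decoupled weight decay.
#' @param disc_update_period The discriminator updates once every this many
#'   training steps (reference: 5).
#' @param grad_clip Global gradient-norm clip applied to the generators.
#' @param seed Integer seed covering shuffling, dropout and initialisation.
#' @param pretrain_epochs Teacher pre-training epochs for
#'   `variant = "offline_kd"` (defaults to `epochs`).
#' @return A `train_config` list.
#' @export
train_config <- function(variant = c("full", "no_ml", "no_ad", "mf",
                                     "dual_gpt", "offline_kd"),
                         epochs = 5L,
                         batch_size = 512L,
                         generator_lr = 6e-4,
                         discriminator_lr = 3e-4,
                         adam_betas = c(0.9, 0.98),
                         weight_decay = 0.01,
                         disc_update_period = 5L,
                         grad_clip = 1.0,
                         seed = 1L,
                         pretrain_epochs = NULL) {
  variant <- match.arg(variant)
  stopifnot(
    epochs >= 1L, batch_size >= 1L, generator_lr > 0, discriminator_lr > 0,
    length(adam_betas) == 2L, all(adam_betas > 0 & adam_betas < 1),
    disc_update_period >= 1L
  )
  structure(
    list(
      variant = variant,
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      generator_lr = generator_lr,
      discriminator_lr = discriminator_lr,
      adam_betas = adam_betas,
      weight_decay = weight_decay,
      disc_update_period = as.integer(disc_update_period),
      grad_clip = grad_clip,
      seed = as.integer(seed),
      pretrain_epochs = if (is.null(pretrain_epochs)) as.integer(epochs)
                        else as.integer(pretrain_epochs)
    ),
    class = "train_config"
  )
}

## ---- AdamW ----------------------------------------------------------------

new_adamw <- function(params, lr, betas, eps = 1e-8, weight_decay = 0.01) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$b1 <- betas[1]
  opt$b2 <- betas[2]
  opt$eps <- eps
  opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# global-norm gradient clipping over a parameter list
clip_grads <- function(params, max_norm) {
  total <- 0
  for (p in params) if (!is.null(p$grad)) total <- total + sum(p$grad^2)
  total <- sqrt(total)
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / (total + 1e-12)
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(total)
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - opt$lr * (mhat / (sqrt(vhat) + opt$eps) +
                                     opt$wd * p$value)
    p$grad <- NULL
  }
  invisible(NULL)
}

## ---- batch preparation ----------------------------------------------------

# teacher-forcing views of an encoded batch slice: decoder input rows are
# [BOS, tokens...]; targets are [tokens..., EOS]; both share the mol mask.
teacher_forcing_batch <- function(enc, rows, vocab) {
  ids <- enc$mol_ids[rows, , drop = FALSE]
  mask <- enc$mol_mask[rows, , drop = FALSE]
  L <- ncol(ids)
  inp <- cbind(matrix(vocab$bos_id, nrow(ids), 1L), ids[, -L, drop = FALSE])
  inp[!mask] <- vocab$pad_id
  packed <- pack_batch(inp, mask)
  targets <- {
    tid <- t(ids)
    as.integer(tid[t(mask)])
  }
  scaf_packed <- pack_batch(
    enc$scaf_ids[rows, , drop = FALSE],
    enc$scaf_mask[rows, , drop = FALSE]
  )
  list(packed = packed, targets = targets, scaf_packed = scaf_packed)
}

second_model_forward <- function(second, batch, variant, train) {
  if (variant == "dual_gpt") {
    gpt_forward(second, batch$packed, train = train)
  } else if (variant == "offline_kd") {
    sg_forward(second, batch$scaf_packed, batch$packed,
               train = FALSE, frozen = TRUE)
  } else {
    sg_forward(second, batch$scaf_packed, batch$packed, train = train)
  }
}

scalar <- function(x) if (is.null(x)) NA_real_ else as.numeric(x$value)

check_finite <- function(terms) {
  vals <- vapply(terms, scalar, numeric(1))
  bad <- names(vals)[!is.na(vals) & !is.finite(vals)]
  if (length(bad)) {
    stop("non-finite loss term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(vals)
}

## ---- main loop ------------------------------------------------------------

#' Train the online-distillation pair on a SMILES corpus
#'
#' Per step, both generators run teacher-forced on the same batch, the
#' variant-appropriate composite loss is formed, and both generators receive
#' one simultaneous AdamW update. Every `disc_update_period`-th step the
#' discriminator additionally updates on detached feature maps. Runs are
#' deterministic for a fixed seed on a single-threaded machine.
#'
#' @param records Corpus tibble with `smiles` and `scaffold` columns.
#' @param gen_config A [generator_config()]; defaults to the reference
#'   architecture sized to the corpus vocabulary.
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param vocab Optional pre-built [build_vocabulary()]; built from the
#'   corpus when `NULL`.
#' @param verbose Print per-epoch loss means.
#' @return A `distill_fit` object: trained models (`$gpt`, `$second`,
#'   `$disc`), the vocabulary, configs, the per-epoch `$report` tibble, and
#'   counters (`$steps`, `$disc_updates`).
#' @export
train_distillation <- function(records,
                               gen_config = NULL,
                               config = train_config(),
                               weights = loss_weights(),
                               vocab = NULL,
                               verbose = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (is.null(vocab)) vocab <- build_vocabulary(c(records$smiles, records$scaffold[nzchar(records$scaffold)]))
  if (is.null(gen_config)) gen_config <- generator_config(vocab_size = vocab_size(vocab))
  stopifnot(gen_config$vocab_size == vocab_size(vocab))
  variant <- config$variant

  set.seed(config$seed)
  gpt <- new_gpt_generator(gen_config, seed = config$seed)
  second <- if (variant == "dual_gpt") {
    new_gpt_generator(gen_config, seed = config$seed + 1L)
  } else {
    new_scaffold_generator(gen_config, seed = config$seed + 1L)
  }
  use_disc <- !variant %in% c("no_ad", "mf")
  disc <- if (use_disc) {
    new_discriminator(gen_config$model_dim, seed = config$seed + 2L)
  } else {
    NULL
  }

  enc <- encode_smiles_batch(records, vocab, max_len = gen_config$max_len)

  if (variant == "offline_kd") {
    second <- pretrain_scaffold_teacher(second, enc, vocab, config, verbose)
  }

  gpt_params <- param_list(gpt)
  second_params <- if (variant == "offline_kd") list() else param_list(second)
  gen_opt <- new_adamw(c(gpt_params, second_params), config$generator_lr,
                       config$adam_betas, weight_decay = config$weight_decay)
  disc_opt <- if (use_disc) {
    new_adamw(param_list(disc), config$discriminator_lr, config$adam_betas,
              weight_decay = config$weight_decay)
  } else {
    NULL
  }

  n <- nrow(records)
  step <- 0L
  disc_updates <- 0L
  report <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    acc <- list(ce1 = c(), ce2 = c(), mutual = c(), gen = c(), disc = c(),
                total = c())
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, n)]
      batch <- teacher_forcing_batch(enc, rows, vocab)
      step <- step + 1L

      out1 <- gpt_forward(gpt, batch$packed, train = TRUE)
      out2 <- second_model_forward(second, batch, variant, train = TRUE)

      l_ce1 <- cross_entropy_loss(out1$logits, batch$targets)
      l_ce2 <- cross_entropy_loss(out2$logits, batch$targets)
      l_mutual <- if (variant == "no_ml") NULL else {
        mutual_loss(out1$logits, out2$logits)
      }
      idx1 <- packed_index_matrix(batch$packed)
      l_gen <- NULL
      if (use_disc) {
        l_gen <- generator_adversarial_loss(discriminate(disc, out1$feature_map, idx1))
      } else if (variant == "mf") {
        l_gen <- feature_map_kl_loss(out1$feature_map, out2$feature_map)
      }

      total <- total_generation_loss(l_gen, l_ce1, l_ce2, l_mutual, weights)
      check_finite(list(l_gen = l_gen, l_ce1 = l_ce1, l_ce2 = l_ce2,
                        l_mutual = l_mutual, total = total))
      tn_backward(total)
      clip_grads(gen_opt$params, config$grad_clip)
      adamw_step(gen_opt)
      if (use_disc) zero_grads(disc_opt$params)

      l_d <- NA_real_
      if (use_disc && step %% config$disc_update_period == 0L) {
        v1 <- discriminate(disc, tn_detach(out1$feature_map), idx1)
        v2 <- discriminate(disc, tn_detach(out2$feature_map), idx1)
        ld <- discriminator_loss(v1, v2)
        check_finite(list(l_d = ld))
        tn_backward(ld)
        adamw_step(disc_opt)
        disc_updates <- disc_updates + 1L
        l_d <- scalar(ld)
      }

      acc$ce1 <- c(acc$ce1, scalar(l_ce1))
      acc$ce2 <- c(acc$ce2, scalar(l_ce2))
      acc$mutual <- c(acc$mutual, scalar(l_mutual))
      acc$gen <- c(acc$gen, scalar(l_gen))
      acc$disc <- c(acc$disc, l_d)
      acc$total <- c(acc$total, scalar(total))
    }
    report[[epoch]] <- tibble::tibble(
      epoch = epoch,
      loss_ce1 = mean(acc$ce1),
      loss_ce2 = mean(acc$ce2),
      loss_mutual = mean(acc$mutual),
      loss_gen = mean(acc$gen),
      loss_disc = mean(acc$disc, na.rm = TRUE),
      loss_total = mean(acc$total),
      steps = length(acc$total),
      seconds = proc.time()[["elapsed"]] - t0
    )
    if (verbose) {
      message(sprintf(
        "epoch %d/%d: CE1 %.4f CE2 %.4f mutual %.4f gen %.4f total %.4f (%.1fs)",
        epoch, config$epochs, report[[epoch]]$loss_ce1, report[[epoch]]$loss_ce2,
        report[[epoch]]$loss_mutual, report[[epoch]]$loss_gen,
        report[[epoch]]$loss_total, report[[epoch]]$seconds
      ))
    }
  }

  structure(
    list(
      gpt = gpt, second = second, disc = disc, vocab = vocab,
      gen_config = gen_config, train_config = config, weights = weights,
      report = dplyr::bind_rows(report), steps = step,
      disc_updates = disc_updates
    ),
    class = "distill_fit"
  )
}

# CE-only pre-training of the scaffold teacher for the offline-KD variant
pretrain_scaffold_teacher <- function(second, enc, vocab, config, verbose) {
  opt <- new_adamw(param_list(second), config$generator_lr, config$adam_betas,
                   weight_decay = config$weight_decay)
  n <- nrow(enc$mol_ids)
  for (epoch in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = config$batch_size)) {
      rows <- ord[s:min(s + config$batch_size - 1L, n)]
      batch <- teacher_forcing_batch(enc, rows, vocab)
      out <- sg_forward(second, batch$scaf_packed, batch$packed, train = TRUE)
      loss <- cross_entropy_loss(out$logits, batch$targets)
      check_finite(list(teacher_ce = loss))
      tn_backward(loss)
      clip_grads(opt$params, config$grad_clip)
      adamw_step(opt)
    }
    if (verbose) message(sprintf("teacher pre-training epoch %d done", epoch))
  }
  second
}

#' @export
print.distill_fit <- function(x, ...) {
  cat(sprintf(
    "<distill_fit: variant '%s', %d epochs, %d steps, %d discriminator updates>\n",
    x$train_config$variant, x$train_config$epochs, x$steps, x$disc_updates
  ))
  print(utils::tail(x$report, 1L))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-epoch training losses
#'
#' @param x A `distill_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `term`, `value`.
#' @method tidy distill_fit
#' @export
tidy.distill_fit <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$report, "epoch", dplyr::starts_with("loss_")),
    -"epoch", names_to = "term", values_to = "value",
    names_prefix = "loss_"
  )
}

#' One-row training summary
#'
#' @param x A `distill_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance distill_fit
#' @export
glance.distill_fit <- function(x, ...) {
  last <- utils::tail(x$report, 1L)
  tibble::tibble(
    variant = x$train_config$variant,
    epochs = x$train_config$epochs,
    steps = x$steps,
    disc_updates = x$disc_updates,
    n_parameters = n_parameters(x$gpt) +
      (if (x$train_config$variant == "offline_kd") 0 else n_parameters(x$second)) +
      (if (is.null(x$disc)) 0 else n_parameters(x$disc)),
    final_loss_ce1 = last$loss_ce1,
    final_loss_total = last$loss_total
  )
}

## ---- checkpoints ----------------------------------------------------------

#' Save a training checkpoint
#'
#' A single versioned archive holding the configs, vocabulary and all
#' network parameters.
#'
#' @param fit A `distill_fit`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  dump_params <- function(model) {
    if (is.null(model)) return(NULL)
    lapply(param_list(model), function(p) p$value)
  }
  obj <- list(
    format_version = 1L,
    gen_config = fit$gen_config,
    train_config = fit$train_config,
    weights = fit$weights,
    vocab = fit$vocab,
    report = fit$report,
    steps = fit$steps,
    disc_updates = fit$disc_updates,
    second_kind = fit$second$kind,
    params = list(
      gpt = dump_params(fit$gpt),
      second = dump_params(fit$second),
      disc = dump_params(fit$disc)
    )
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `distill_fit` with restored parameters.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported checkpoint format version", call. = FALSE)
  }
  if (obj$gen_config$vocab_size != vocab_size(obj$vocab)) {
    stop("checkpoint config/vocabulary mismatch", call. = FALSE)
  }
  restore <- function(model, values) {
    stopifnot(setequal(names(values), ls(model$params)))
    for (nm in names(values)) {
      p <- get(nm, envir = model$params)
      p$value <- values[[nm]]
    }
    model
  }
  gpt <- restore(new_gpt_generator(obj$gen_config), obj$params$gpt)
  second <- if (identical(obj$second_kind, "from_scratch")) {
    restore(new_gpt_generator(obj$gen_config), obj$params$second)
  } else {
    restore(new_scaffold_generator(obj$gen_config), obj$params$second)
  }
  disc <- if (!is.null(obj$params$disc)) {
    restore(new_discriminator(obj$gen_config$model_dim), obj$params$disc)
  } else {
    NULL
  }
  structure(
    list(
      gpt = gpt, second = second, disc = disc, vocab = obj$vocab,
      gen_config = obj$gen_config, train_config = obj$train_config,
      weights = obj$weights, report = obj$report, steps = obj$steps,
      disc_updates = obj$disc_updates
    ),
    class = "distill_fit"
  )
}
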