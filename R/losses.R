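# The four training losses: two teacher-forced cross-entropies, the
# one-directional logit KL (mutual learning), and the adversarial pair over
# last-layer feature maps, combined as
#
#   Loss = L_gen + lambda1 * L_CE1 + lambda2 * L_CE2 + lambda3 * L_mutual
#
# with the discriminator objective optimised separately on its own cadence.

#' Loss weights of the composite generation objective
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights of the from-scratch
#'   cross-entropy, the scaffold-model cross-entropy and the mutual (KL)
#'   term. Defaults are the reference setting (1.5, 1, 0.5).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1.5, lambda2 = 1, lambda3 = 0.5) {
  stopifnot(
    is.finite(lambda1), is.finite(lambda2), is.finite(lambda3),
    lambda1 >= 0, lambda2 >= 0, lambda3 >= 0
  )
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' Teacher-forced cross-entropy over unmasked positions
#'
#' Mean negative log-likelihood of the target token at each real (non-PAD)
#' position. Operates on packed tensors, so the mask is structural: PAD
#' positions are never present.
#'
#' @param logits Tensor of per-position logits (positions x vocab).
#' @param targets Integer vector of target ids, one per row of `logits`.
#' @return A scalar tensor (>= 0).
#' @keywords internal
cross_entropy_loss <- function(logits, targets) {
  if (!nrow(logits$value)) stop("cross-entropy over an empty mask", call. = FALSE)
  tn_nll(tn_log_softmax(logits), targets)
}

#' One-directional mutual-learning loss
#'
#' Per-position KL divergence from the from-scratch model's next-token
#' distribution to the scaffold model's, averaged over positions:
#' `mean_t KL(softmax(z1_t) || softmax(z2_t))`. The scaffold-side logits are
#' treated as a constant target (stop-gradient), so this term pulls only the
#' from-scratch generator.
#'
#' @param z1 Logit tensor of the from-scratch generator.
#' @param z2 Logit tensor of the scaffold-conditioned generator (detached
#'   internally).
#' @return A scalar tensor (>= 0).
#' @keywords internal
mutual_loss <- function(z1, z2) {
  stopifnot(identical(dim(z1$value), dim(z2$value)))
  lp1 <- tn_log_softmax(z1)
  lp2 <- tn_log_softmax(tn_detach(z2))
  # sum_v p1 * (log p1 - log p2), averaged over rows
  tn_mean_rowsums(tn_mul(tn_exp(lp1), tn_sub(lp1, lp2)))
}

#' Adversarial loss of the from-scratch generator
#'
#' `mean(log(1 - D(h1)))`: minimised when the discriminator is fooled into
#' scoring from-scratch feature maps as scaffold-derived (D -> 1). The
#' discriminator's parameters receive no update from this term.
#'
#' @param verdict_h1 Tensor of clamped per-sequence probabilities `D(h1)`.
#' @return A scalar tensor (<= 0 after clamping).
#' @keywords internal
generator_adversarial_loss <- function(verdict_h1) {
  tn_mean(tn_log(tn_sub(tn_const(matrix(1, nrow(verdict_h1$value), 1L)),
                        verdict_h1)))
}

#' Discriminator loss
#'
#' The negated average of the printed objective:
#' `-(log D(h2) + log(1 - D(h1))) / 2`, so that minimisation trains the
#' discriminator to emit 1 on scaffold-derived features and 0 on
#' from-scratch features (the standard GAN discriminator NLL). Both feature
#' maps must be detached from their generators.
#'
#' @param verdict_h1,verdict_h2 Clamped verdict tensors on the two feature
#'   maps.
#' @return A scalar tensor.
#' @keywords internal
discriminator_loss <- function(verdict_h1, verdict_h2) {
  one1 <- tn_const(matrix(1, nrow(verdict_h1$value), 1L))
  term <- tn_add(tn_log(verdict_h2), tn_log(tn_sub(one1, verdict_h1)))
  tn_scale(tn_mean(term), -0.5)
}

#' Composite generation loss
#'
#' `l_gen + lambda1 * l_ce1 + lambda2 * l_ce2 + lambda3 * l_mutual`; the
#' adversarial term carries implicit weight 1.
#'
#' @param l_gen,l_ce1,l_ce2,l_mutual Scalar tensors (or NULL for absent
#'   terms under ablation variants, treated as 0).
#' @param weights A [loss_weights()].
#' @return A scalar tensor.
#' @keywords internal
total_generation_loss <- function(l_gen, l_ce1, l_ce2, l_mutual, weights) {
  acc <- NULL
  add_term <- function(acc, term, w) {
    if (is.null(term) || w == 0) return(acc)
    scaled <- if (w == 1) term else tn_scale(term, w)
    if (is.null(acc)) scaled else tn_add(acc, scaled)
  }
  acc <- add_term(acc, l_gen, 1)
  acc <- add_term(acc, l_ce1, weights$lambda1)
  acc <- add_term(acc, l_ce2, weights$lambda2)
  acc <- add_term(acc, l_mutual, weights$lambda3)
  if (is.null(acc)) tn_const(matrix(0, 1, 1)) else acc
}

#' Feature-map KL loss (ablation variant "mf")
#'
#' Each per-token feature vector is softmax-normalised into a distribution
#' over dimensions; the loss is the mean per-position KL from the
#' from-scratch features to the (detached) scaffold-model features. Replaces
#' the adversarial pair when `variant = "mf"`.
#'
#' @param h1,h2 Feature-map tensors of matching shape.
#' @return A scalar tensor (>= 0).
#' @keywords internal
feature_map_kl_loss <- function(h1, h2) {
  stopifnot(identical(dim(h1$value), dim(h2$value)))
  lp1 <- tn_log_softmax(h1)
  lp2 <- tn_log_softmax(tn_detach(h2))
  tn_mean_rowsums(tn_mul(tn_exp(lp1), tn_sub(lp1, lp2)))
}
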