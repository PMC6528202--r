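# Adversarial, L1 and cycle objectives.  All logarithms are natural logs;
# adversarial losses are reported in nats.

check_probs <- function(p, what) {
  if (any(p <= 0) || any(p >= 1))
    stop(what, " must lie strictly in (0, 1)", call. = FALSE)
  invisible(p)
}

#' Discriminator binary cross-entropy loss
#'
#' `-mean(log p_real) - mean(log(1 - p_fake))`: the negation of the
#' maximized discriminator objective, i.e. cross-entropy against labels
#' real = 1, fake = 0.  Always non-negative; `2 ln 2` when both maps sit at
#' the uninformative 0.5.
#'
#' @param p_real,p_fake Probability maps with values strictly in (0, 1).
#' @return Scalar loss in nats.
#' @export
discriminator_loss <- function(p_real, p_fake) {
  check_probs(p_real, "p_real"); check_probs(p_fake, "p_fake")
  -mean(log(p_real)) - mean(log(1 - p_fake))
}

#' Generator adversarial loss
#'
#' The `"literal"` variant is the minimized generator term
#' `mean(log(1 - p_fake))` (negative when the generator fools the
#' discriminator); `"non_saturating"` is the standard reformulation
#' `-mean(log p_fake)` with the same fixed points but usable gradients when
#' the discriminator wins early, and is the training default.
#'
#' @param p_fake Probability map of discriminator outputs on generated
#'   images, strictly in (0, 1).
#' @param variant `"non_saturating"` or `"literal"`.
#' @return Scalar loss in nats.
#' @export
generator_adversarial_loss <- function(p_fake,
                                       variant = c("non_saturating",
                                                   "literal")) {
  variant <- match.arg(variant)
  check_probs(p_fake, "p_fake")
  switch(variant,
         literal = mean(log(1 - p_fake)),
         non_saturating = -mean(log(p_fake)))
}

#' Mean absolute error between images
#'
#' @param a,b Arrays of identical shape.
#' @return Non-negative scalar.
#' @export
l1_loss <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("l1_loss: shapes differ", call. = FALSE)
  mean(abs(a - b))
}

loss_breakdown <- function(adv_g = NA_real_, adv_d = NA_real_,
                           l1 = NA_real_, cycle = NA_real_,
                           total_g = NA_real_, total_d = NA_real_,
                           lambda_weight = NA_real_) {
  structure(list(adv_g = adv_g, adv_d = adv_d, l1 = l1, cycle = cycle,
                 total_g = total_g, total_d = total_d,
                 lambda_weight = lambda_weight),
            class = "loss_breakdown")
}

#' Combined paired-translation generator objective
#'
#' The paired (Pix2pix-style) generator loss: adversarial term plus a
#' globally weighted L1 reconstruction term,
#' `total_g = adv + lambda_weight * mean|target - generated|`.  The default
#' weight is 0.5.
#'
#' @param p_fake Discriminator probabilities on the generated image.
#' @param generated,target Images of identical shape, model scale.
#' @param lambda_weight Non-negative L1 weight.
#' @param variant Adversarial variant, see [generator_adversarial_loss()].
#' @return A `loss_breakdown` with `adv_g`, `l1`, `total_g`.
#' @export
pix2pix_generator_loss <- function(p_fake, generated, target,
                                   lambda_weight = 0.5,
                                   variant = c("non_saturating", "literal")) {
  if (lambda_weight < 0)
    stop("lambda_weight must be non-negative", call. = FALSE)
  adv <- generator_adversarial_loss(p_fake, variant)
  l1 <- l1_loss(generated, target)
  loss_breakdown(adv_g = adv, l1 = l1,
                 total_g = adv + lambda_weight * l1,
                 lambda_weight = lambda_weight)
}

#' Cycle-consistency loss
#'
#' `mean|a_cycled - a| + mean|b_cycled - b|` for pre-computed round trips
#' `a_cycled = G2(G1(a))` and `b_cycled = G1(G2(b))`.  Zero iff both cycles
#' are exact.
#'
#' @param a,a_cycled,b,b_cycled Image arrays; shapes must match within each
#'   domain.
#' @return Non-negative scalar.
#' @export
cycle_consistency_loss <- function(a, a_cycled, b, b_cycled) {
  l1_loss(a_cycled, a) + l1_loss(b_cycled, b)
}

#' Total unpaired-translation objective
#'
#' Sums the two adversarial objectives (one per translation direction, each
#' split into its generator and discriminator parts) with the weighted
#' cycle term: `total = advs + lambda_weight * cycle`.
#'
#' @param adv_g1,adv_g2 Generator adversarial terms for G1 (A to B) and G2
#'   (B to A).
#' @param adv_d1,adv_d2 Discriminator losses for D1 (domain A) and D2
#'   (domain B).
#' @param cycle Cycle-consistency term.
#' @param lambda_weight Non-negative cycle weight (default 10).
#' @return A `loss_breakdown` with `total_g = adv_g1 + adv_g2 +
#'   lambda_weight * cycle` and `total_d = adv_d1 + adv_d2`.
#' @export
cyclegan_total_loss <- function(adv_g1, adv_g2, adv_d1, adv_d2, cycle,
                                lambda_weight = 10) {
  if (lambda_weight < 0)
    stop("lambda_weight must be non-negative", call. = FALSE)
  vals <- c(adv_g1, adv_g2, adv_d1, adv_d2, cycle)
  if (any(!is.finite(vals)))
    stop("loss components must be finite", call. = FALSE)
  loss_breakdown(adv_g = adv_g1 + adv_g2, adv_d = adv_d1 + adv_d2,
                 cycle = cycle,
                 total_g = adv_g1 + adv_g2 + lambda_weight * cycle,
                 total_d = adv_d1 + adv_d2,
                 lambda_weight = lambda_weight)
}
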