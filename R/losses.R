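# Training objectives.  The public functions operate on plain numeric arrays
# and are thin forward-only wrappers around the same autodiff ops the training
# loops differentiate through, so the tested values and the trained values
# cannot drift apart.

as_batch <- function(x, what = "input") {
  if (!is.numeric(x)) stop_sym(what, " must be numeric")
  as_nhwc(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_sym(what, " must have identical shapes (",
             paste(dim(a), collapse = "x"), " vs ",
             paste(dim(b), collapse = "x"), ")")
}

# Internal ad-graph soft Dice:  1 - (2*sum(pq) + eps) / (sum p + sum q + eps),
# sums over pixels, mean over the batch.
ad_soft_dice <- function(p, q, eps = 1) {
  sp <- ad_sum_prod_hwc(p, q)
  num <- ad_vaffine(sp, 2, eps)
  den <- ad_vaffine(ad_vadd(ad_sum_hwc(p), ad_sum_hwc(q)), 1, eps)
  ad_vmean(ad_vaffine(ad_vdiv(num, den), -1, 1))
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*q) + eps) / (sum(p) + sum(q) + eps)`, with pixel sums taken
#' per image and the loss averaged over a batch.  Symmetric in its arguments;
#' the smoothing `eps` removes the empty-mask singularity.
#'
#' @param pred Probability map (values in `[0, 1]`), matrix or `[H,W,C,N]`
#'   array.
#' @param ref Reference map of the same shape (binary or probabilities).
#' @param eps Positive smoothing constant, default 1.
#' @return A scalar in `[0, 1)`.
#' @export
soft_dice_loss <- function(pred, ref, eps = 1) {
  pred <- as_batch(pred, "pred"); ref <- as_batch(ref, "ref")
  check_same_shape(pred, ref, "pred and ref")
  if (eps <= 0) stop_sym("eps must be positive")
  ad_soft_dice(ad_leaf(pred), ad_leaf(ref), eps)$value
}

clamp_scores <- function(s, what) {
  s <- as_batch(s, what)
  if (any(s < 0 | s > 1)) stop_sym(what, " must be realness scores in (0, 1)")
  s
}

# Discriminator objective shared by Eqs. for both domains:
# E[-log(1 - D^feat(fake))] + E[-log D^feat(real)] + same for D^pix.
discriminator_adv_loss <- function(dfeat_real, dfeat_fake, dpix_real,
                                   dpix_fake) {
  terms <- list(
    ad_bce_fake(ad_leaf(clamp_scores(dfeat_fake, "dfeat_fake"))),
    ad_bce_real(ad_leaf(clamp_scores(dfeat_real, "dfeat_real"))),
    ad_bce_fake(ad_leaf(clamp_scores(dpix_fake, "dpix_fake"))),
    ad_bce_real(ad_leaf(clamp_scores(dpix_real, "dpix_real"))))
  ad_lincomb(terms, rep(1, 4))$value
}

#' Source-domain adversarial loss (discriminator side)
#'
#' Sum of the feature-level and pixel-level discriminator cross-entropies for
#' the source domain: real scores come from genuine source images/features,
#' fake scores from the target-to-source translations.  Expectations are means
#' over batch and patch scores; scores are clamped away from 0 and 1 by 1e-7.
#'
#' @param dfeat_real,dfeat_fake Feature-discriminator scores in `(0, 1)`.
#' @param dpix_real,dpix_fake Pixel-discriminator scores in `(0, 1)`.
#' @return A non-negative scalar.
#' @export
adv_loss_source <- function(dfeat_real, dfeat_fake, dpix_real, dpix_fake)
  discriminator_adv_loss(dfeat_real, dfeat_fake, dpix_real, dpix_fake)

#' Target-domain adversarial loss (discriminator side)
#'
#' Mirror of [adv_loss_source()]: fakes are the source-to-target translations.
#' @inheritParams adv_loss_source
#' @return A non-negative scalar.
#' @export
adv_loss_target <- function(dfeat_real, dfeat_fake, dpix_real, dpix_fake)
  discriminator_adv_loss(dfeat_real, dfeat_fake, dpix_real, dpix_fake)

#' Generator adversarial loss (non-saturating form)
#'
#' `E[-log D^feat(fake)] + E[-log D^pix(fake)]`: the alternation counterpart
#' of the discriminator losses, minimized by the translators (and, for the
#' feature term, the segmenter encoders).
#'
#' @param dfeat_fake,dpix_fake Discriminator scores on generated samples.
#' @return A non-negative scalar.
#' @export
generator_adv_loss <- function(dfeat_fake, dpix_fake) {
  terms <- list(ad_bce_real(ad_leaf(clamp_scores(dfeat_fake, "dfeat_fake"))),
                ad_bce_real(ad_leaf(clamp_scores(dpix_fake, "dpix_fake"))))
  ad_lincomb(terms, c(1, 1))$value
}

#' Cycle-consistency loss
#'
#' Mean absolute error of the round-trip reconstructions, summed over both
#' translation directions.
#'
#' @param x_s,x_t Original source and target images.
#' @param recon_s Reconstruction `G_TS(G_ST(x_s))`.
#' @param recon_t Reconstruction `G_ST(G_TS(x_t))`.
#' @return A non-negative scalar; 0 iff both reconstructions are exact.
#' @export
cycle_loss <- function(x_s, x_t, recon_s, recon_t) {
  x_s <- as_batch(x_s); x_t <- as_batch(x_t)
  recon_s <- as_batch(recon_s); recon_t <- as_batch(recon_t)
  check_same_shape(x_s, recon_s, "x_s and recon_s")
  check_same_shape(x_t, recon_t, "x_t and recon_t")
  ad_lincomb(list(ad_mean_abs_diff(ad_leaf(recon_s), ad_leaf(x_s)),
                  ad_mean_abs_diff(ad_leaf(recon_t), ad_leaf(x_t))),
             c(1, 1))$value
}

#' Identity-mapping loss
#'
#' L1 penalty on a translator altering an image already in its output domain:
#' `E|G_TS(x_s) - x_s| + E|G_ST(x_t) - x_t|`.
#'
#' @param x_s,x_t Original source and target images.
#' @param iden_s Output of `G_TS(x_s)`.
#' @param iden_t Output of `G_ST(x_t)`.
#' @return A non-negative scalar.
#' @export
identity_loss <- function(x_s, x_t, iden_s, iden_t) {
  cycle_loss(x_s, x_t, iden_s, iden_t)
}

#' Supervised segmentation loss
#'
#' Sum of the soft Dice losses of the source branch on the source image and
#' the target branch on its translation, both against the source ground truth.
#'
#' @param pred_s Probability map `F_S(x_s)`.
#' @param pred_t_translated Probability map `F_T(G_ST(x_s))`.
#' @param gt_mask Binary ground-truth mask (must be present: source samples
#'   are labeled).
#' @param eps Dice smoothing.
#' @return A non-negative scalar.
#' @export
seg_supervised_loss <- function(pred_s, pred_t_translated, gt_mask, eps = 1) {
  if (is.null(gt_mask))
    stop_sym("gt_mask is missing: source samples must be labeled")
  soft_dice_loss(pred_s, gt_mask, eps) +
    soft_dice_loss(pred_t_translated, gt_mask, eps)
}

#' Cross-branch consistency loss
#'
#' Soft Dice disagreement between the target branch's prediction on a target
#' image and the source branch's prediction on its source-translated version;
#' the unlabeled branch is guided by the supervised one.
#'
#' @param pred_t Probability map `F_T(x_t)`.
#' @param pred_s_translated Probability map `F_S(G_TS(x_t))`.
#' @param eps Dice smoothing.
#' @return A non-negative scalar.
#' @export
consistency_loss <- function(pred_t, pred_s_translated, eps = 1) {
  soft_dice_loss(pred_t, pred_s_translated, eps)
}

#' Loss-term weights of the total objective
#'
#' Defaults are the published operating point: adversarial, cycle and
#' identity at 1, supervised Dice at 10, consistency at 2.
#'
#' @param lambda_adv,lambda_cycle,lambda_iden,lambda_seg,lambda_consis
#'   Non-negative finite weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_adv = 1, lambda_cycle = 1, lambda_iden = 1,
                         lambda_seg = 10, lambda_consis = 2) {
  w <- c(lambda_adv = lambda_adv, lambda_cycle = lambda_cycle,
         lambda_iden = lambda_iden, lambda_seg = lambda_seg,
         lambda_consis = lambda_consis)
  if (any(!is.finite(w)) || any(w < 0))
    stop_sym("all loss weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Weighted total loss and per-term report
#'
#' `total = lambda_adv*(adv_S + adv_T) + lambda_cycle*cycle +
#' lambda_iden*iden + lambda_seg*seg + lambda_consis*consis`.
#'
#' @param adv_s,adv_t,cycle,iden,seg,consis Scalar loss terms.
#' @param weights A [loss_weights()].
#' @return An object of class `loss_report` carrying every term and `total`.
#' @export
total_loss <- function(adv_s, adv_t, cycle, iden, seg, consis,
                       weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  terms <- c(adv_s = adv_s, adv_t = adv_t, cycle = cycle, iden = iden,
             seg = seg, consis = consis)
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad))
    stop_sym("non-finite loss term(s): ", paste(bad, collapse = ", "))
  total <- weights$lambda_adv * (adv_s + adv_t) +
    weights$lambda_cycle * cycle + weights$lambda_iden * iden +
    weights$lambda_seg * seg + weights$lambda_consis * consis
  structure(c(as.list(terms), list(total = total, weights = weights)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(paste0("<loss_report> total=%.4f  adv_s=%.4f adv_t=%.4f ",
                     "cycle=%.4f iden=%.4f seg=%.4f consis=%.4f\n"),
              x$total, x$adv_s, x$adv_t, x$cycle, x$iden, x$seg, x$consis))
  invisible(x)
}

loss_report_row <- function(report, stage, epoch, step) {
  data.frame(stage = stage, epoch = epoch, step = step,
             adv_s = report$adv_s, adv_t = report$adv_t,
             cycle = report$cycle, iden = report$iden, seg = report$seg,
             consis = report$consis, total = report$total)
}
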