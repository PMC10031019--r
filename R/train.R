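# Three-stage optimization schedule and the experiment runner.
#
# Stage 1 trains the translation module (translators + pixel discriminators)
# with adversarial + cycle + identity losses; stage 2 trains the two
# segmenters supervised on (x_s, GT) and (G_ST(x_s), GT) with translators
# frozen; stage 3 jointly refines everything under the weighted total loss,
# adding feature-level adversarial alignment and the cross-branch consistency
# term.  Discriminator updates and generator/segmenter updates alternate
# within every step, discriminators first on detached fakes.

#' Training schedule
#'
#' Epoch counts, learning rates and optimizer settings for the three stages.
#' None of these are reported in the original study; the defaults are desk
#' scale choices (few hundred optimization steps) documented in the methods
#' vignette.  Setting a stage's `epochs` to 0 skips that stage.
#'
#' @param stage1 List: `epochs`, `lr_translation`, `lr_discriminator`.
#' @param stage2 List: `epochs`, `lr_segmentation`.
#' @param stage3 List: `epochs`, `lr_all`, `weights` (a [loss_weights()]).
#' @param batch_size Images per optimization step.
#' @param betas Adam momentum coefficients.
#' @param augment_no_da If `TRUE`, the source-only baseline gets flip/rotate
#'   augmentation (the adaptation runs never do).
#' @param seed Default run seed.
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(stage1 = list(epochs = 4L, lr_translation = 1e-3,
                                         lr_discriminator = 2e-4),
                           stage2 = list(epochs = 6L, lr_segmentation = 2e-3),
                           stage3 = list(epochs = 2L, lr_all = 5e-4,
                                         weights = loss_weights()),
                           batch_size = 8L, betas = c(0.5, 0.999),
                           augment_no_da = FALSE, seed = 1L) {
  chk <- function(st, nm) {
    if (is.null(st$epochs) || st$epochs < 0)
      stop_sym(nm, "$epochs must be >= 0")
    lrs <- st[grep("^lr", names(st))]
    if (any(unlist(lrs) <= 0)) stop_sym(nm, " learning rates must be > 0")
  }
  chk(stage1, "stage1"); chk(stage2, "stage2"); chk(stage3, "stage3")
  if (is.null(stage3$weights)) stage3$weights <- loss_weights()
  stopifnot(inherits(stage3$weights, "loss_weights"), batch_size >= 1)
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 batch_size = as.integer(batch_size), betas = betas,
                 augment_no_da = isTRUE(augment_no_da),
                 seed = as.integer(seed)),
            class = "stage_schedule")
}

ablation_variants <- function() c("full", "no_translation", "no_feature_gan",
                                  "no_consistency", "no_da")

## ---- optimizer --------------------------------------------------------------

adam_new <- function(lr, betas = c(0.5, 0.999), eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- betas[1]; e$b2 <- betas[2]; e$eps <- eps
  e$t <- 0L; e$m <- list(); e$v <- list()
  e
}

adam_update <- function(opt, params, pnodes) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t; c2 <- 1 - opt$b2^opt$t
  for (nm in names(params)) {
    g <- pnodes[[nm]]$grad
    if (is.null(g)) next
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    m <- if (is.null(m)) (1 - opt$b1) * g else opt$b1 * m + (1 - opt$b1) * g
    gg <- g * g
    v <- if (is.null(v)) (1 - opt$b2) * gg else opt$b2 * v + (1 - opt$b2) * gg
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps)
  }
  params
}

## ---- batching ---------------------------------------------------------------

batch_indices <- function(n, batch_size, seed) {
  ord <- with_seed(seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) out[, , 1L, i] <- imgs[[i]]
  out
}

augment_flip_rotate <- function(img, mask, seed) {
  ops <- with_seed(seed, c(runif(2) < 0.5, sample(0:3, 1)))
  tf <- function(m) {
    if (ops[1]) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (ops[2]) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    k <- ops[3]
    if (k > 0) for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), ,
                                              drop = FALSE])
    m
  }
  list(image = tf(img), mask = tf(mask))
}

require_train_images <- function(ds, what) {
  if (sum(ds$split == "train") == 0L)
    stop_sym(what, " has an empty training split")
}

## ---- stage 1: translation ---------------------------------------------------

#' Train the image translation module (stage 1)
#'
#' Alternates pixel-level discriminator steps and generator steps (adversarial
#' + cycle + identity) on unlabeled images from both domains.  Segmenter and
#' feature-discriminator parameters are untouched.
#'
#' @param datasets List with `source` and `target` [generate_domain_dataset()]
#'   objects (masks are not needed).
#' @param models A [model_bundle_new()] bundle.
#' @param schedule A [stage_schedule()].
#' @param seed Run seed; defaults to `schedule$seed`.
#' @return List with updated `models` and a `history` data frame.
#' @export
train_stage1 <- function(datasets, models, schedule, seed = schedule$seed) {
  require_train_images(datasets$source, "source dataset")
  require_train_images(datasets$target, "target dataset")
  if (schedule$stage1$epochs == 0L)
    return(list(models = models, history = NULL))
  src <- dataset_images(datasets$source, "train")
  tgt <- dataset_images(datasets$target, "train")
  w <- schedule$stage3$weights
  # one optimizer per network: parameter names repeat across networks, so
  # sharing Adam state would mix their moment estimates
  opt <- list(g_st = adam_new(schedule$stage1$lr_translation, schedule$betas),
              g_ts = adam_new(schedule$stage1$lr_translation, schedule$betas),
              d_s = adam_new(schedule$stage1$lr_discriminator, schedule$betas),
              d_t = adam_new(schedule$stage1$lr_discriminator, schedule$betas))
  hist <- list(); step <- 0L
  for (ep in seq_len(schedule$stage1$epochs)) {
    bs <- batch_indices(length(src), schedule$batch_size,
                        derive_seed(seed, paste0("s1src", ep)))
    bt <- batch_indices(length(tgt), schedule$batch_size,
                        derive_seed(seed, paste0("s1tgt", ep)))
    for (k in seq_len(min(length(bs), length(bt)))) {
      step <- step + 1L
      x_s <- ad_leaf(stack_images(src[bs[[k]]]))
      x_t <- ad_leaf(stack_images(tgt[bt[[k]]]))
      ns <- dim(x_s$value)[4]; nt <- dim(x_t$value)[4]
      pg_st <- net_nodes(models$g_st); pg_ts <- net_nodes(models$g_ts)
      # batched translator passes: [x_s|x_t] through G_ST gives the fake and
      # the identity-mapping output in one execution; likewise for G_TS with
      # the cycle reconstruction appended
      outA <- fw_translate01(models$g_st, pg_st, ad_concat_n(list(x_s, x_t)))
      fake_t <- ad_slice_n(outA, 1L, ns)
      iden_t <- ad_slice_n(outA, ns + 1L, ns + nt)
      outB <- fw_translate01(models$g_ts, pg_ts,
                             ad_concat_n(list(x_t, x_s, fake_t)))
      fake_s <- ad_slice_n(outB, 1L, nt)
      iden_s <- ad_slice_n(outB, nt + 1L, nt + ns)
      recon_s <- ad_slice_n(outB, nt + ns + 1L, nt + 2L * ns)
      # discriminator step on detached fakes ([real; fake] in one pass)
      pd_s <- net_nodes(models$d_s_pix); pd_t <- net_nodes(models$d_t_pix)
      sc_s <- fw_pixel_disc(models$d_s_pix, pd_s,
                            ad_concat_n(list(x_s, ad_detach(fake_s))))
      d_s_loss <- ad_lincomb(list(
        ad_bce_real(ad_slice_n(sc_s, 1L, ns)),
        ad_bce_fake(ad_slice_n(sc_s, ns + 1L, ns + nt))), c(1, 1))
      sc_t <- fw_pixel_disc(models$d_t_pix, pd_t,
                            ad_concat_n(list(x_t, ad_detach(fake_t))))
      d_t_loss <- ad_lincomb(list(
        ad_bce_real(ad_slice_n(sc_t, 1L, nt)),
        ad_bce_fake(ad_slice_n(sc_t, nt + 1L, nt + ns))), c(1, 1))
      ad_backward(d_s_loss); ad_backward(d_t_loss)
      models$d_s_pix$params <- adam_update(opt$d_s, models$d_s_pix$params,
                                           pd_s)
      models$d_t_pix$params <- adam_update(opt$d_t, models$d_t_pix$params,
                                           pd_t)
      # generator step against the updated discriminators
      pd_s2 <- net_nodes(models$d_s_pix); pd_t2 <- net_nodes(models$d_t_pix)
      gadv <- ad_lincomb(list(
        ad_bce_real(fw_pixel_disc(models$d_s_pix, pd_s2, fake_s)),
        ad_bce_real(fw_pixel_disc(models$d_t_pix, pd_t2, fake_t))), c(1, 1))
      recon_t <- fw_translate01(models$g_st, pg_st, fake_s)
      cyc <- ad_lincomb(list(ad_mean_abs_diff(recon_s, x_s),
                             ad_mean_abs_diff(recon_t, x_t)), c(1, 1))
      iden <- ad_lincomb(list(ad_mean_abs_diff(iden_s, x_s),
                              ad_mean_abs_diff(iden_t, x_t)), c(1, 1))
      g_loss <- ad_lincomb(list(gadv, cyc, iden),
                           c(w$lambda_adv, w$lambda_cycle, w$lambda_iden))
      ad_backward(g_loss)
      models$g_st$params <- adam_update(opt$g_st, models$g_st$params, pg_st)
      models$g_ts$params <- adam_update(opt$g_ts, models$g_ts$params, pg_ts)
      rep <- total_loss(d_s_loss$value, d_t_loss$value, cyc$value,
                        iden$value, 0, 0, w)
      hist[[step]] <- loss_report_row(rep, "stage1", ep, step)
    }
  }
  list(models = models, history = do.call(rbind, hist))
}

## ---- stage 2: supervised segmentation --------------------------------------

#' Train the symmetric segmenters supervised (stage 2)
#'
#' With translators frozen, minimizes the supervised Dice objective: the
#' source branch on `(x_s, GT)` and the target branch on `(G_ST(x_s), GT)`.
#'
#' @inheritParams train_stage1
#' @return List with updated `models` and a `history` data frame.
#' @export
train_stage2 <- function(datasets, models, schedule, seed = schedule$seed) {
  require_train_images(datasets$source, "source dataset")
  if (schedule$stage2$epochs == 0L)
    return(list(models = models, history = NULL))
  idx <- which(datasets$source$split == "train")
  src <- dataset_images(datasets$source)[idx]
  msk <- dataset_masks(datasets$source)[idx]
  if (any(vapply(msk, is.null, logical(1))))
    stop_sym("every source-domain training sample must carry a mask")
  w <- schedule$stage3$weights
  opt_fs <- adam_new(schedule$stage2$lr_segmentation, schedule$betas)
  opt_ft <- adam_new(schedule$stage2$lr_segmentation, schedule$betas)
  hist <- list(); step <- 0L
  for (ep in seq_len(schedule$stage2$epochs)) {
    bs <- batch_indices(length(src), schedule$batch_size,
                        derive_seed(seed, paste0("s2", ep)))
    for (k in seq_along(bs)) {
      step <- step + 1L
      x_s <- ad_leaf(stack_images(src[bs[[k]]]))
      gt <- ad_leaf(stack_images(msk[bs[[k]]]))
      fake_t <- ad_leaf(pmin(pmax(
        fw_translate01(models$g_st, net_nodes(models$g_st), x_s)$value,
        0), 1))
      pf_s <- net_nodes(models$f_s); pf_t <- net_nodes(models$f_t)
      loss_s <- ad_soft_dice(fw_segmenter(models$f_s, pf_s, x_s)$probs, gt)
      loss_t <- ad_soft_dice(fw_segmenter(models$f_t, pf_t, fake_t)$probs, gt)
      ad_backward(loss_s); ad_backward(loss_t)
      models$f_s$params <- adam_update(opt_fs, models$f_s$params, pf_s)
      models$f_t$params <- adam_update(opt_ft, models$f_t$params, pf_t)
      rep <- total_loss(0, 0, 0, 0, loss_s$value + loss_t$value, 0, w)
      hist[[step]] <- loss_report_row(rep, "stage2", ep, step)
    }
  }
  list(models = models, history = do.call(rbind, hist))
}

## ---- stage 3: joint refinement ----------------------------------------------

#' Jointly refine the whole framework (stage 3)
#'
#' One optimization step alternates (1) the four discriminators on the
#' domain adversarial losses with detached fakes and (2) the translators and
#' segmenters on the remaining weighted total: non-saturating adversarial,
#' cycle, identity, supervised Dice and consistency terms.  `variant` removes
#' components for the ablation study; see the vignette for the exact reading
#' of each variant.
#'
#' @inheritParams train_stage1
#' @param variant One of `"full"`, `"no_translation"`, `"no_feature_gan"`,
#'   `"no_consistency"`, `"no_da"`.
#' @return List with updated `models` and a `history` data frame.
#' @export
train_stage3 <- function(datasets, models, schedule, variant = "full",
                         seed = schedule$seed) {
  variant <- match.arg(variant, ablation_variants())
  require_train_images(datasets$source, "source dataset")
  if (variant != "no_da") require_train_images(datasets$target,
                                               "target dataset")
  if (schedule$stage3$epochs == 0L)
    return(list(models = models, history = NULL))
  idx <- which(datasets$source$split == "train")
  src <- dataset_images(datasets$source)[idx]
  msk <- dataset_masks(datasets$source)[idx]
  if (any(vapply(msk, is.null, logical(1))))
    stop_sym("every source-domain training sample must carry a mask")
  tgt <- if (variant == "no_da") src else dataset_images(datasets$target,
                                                         "train")
  w0 <- schedule$stage3$weights
  w <- if (variant == "no_consistency")
    loss_weights(w0$lambda_adv, w0$lambda_cycle, w0$lambda_iden,
                 w0$lambda_seg, 0)
  else w0
  use_trans <- !(variant %in% c("no_translation", "no_da"))
  use_feat <- !(variant %in% c("no_feature_gan", "no_da"))
  use_pix <- use_trans
  use_consis <- w$lambda_consis > 0 && variant != "no_da"
  lr <- schedule$stage3$lr_all
  opts <- stats::setNames(lapply(bundle_net_names(), function(nm)
    adam_new(lr, schedule$betas)), bundle_net_names())
  hist <- list(); step <- 0L
  for (ep in seq_len(schedule$stage3$epochs)) {
    bs <- batch_indices(length(src), schedule$batch_size,
                        derive_seed(seed, paste0("s3src", ep, variant)))
    bt <- batch_indices(length(tgt), schedule$batch_size,
                        derive_seed(seed, paste0("s3tgt", ep, variant)))
    for (k in seq_len(min(length(bs), length(bt)))) {
      step <- step + 1L
      x_s <- ad_leaf(stack_images(src[bs[[k]]]))
      gt <- ad_leaf(stack_images(msk[bs[[k]]]))
      x_t <- ad_leaf(stack_images(tgt[bt[[k]]]))

      if (variant == "no_da") {
        # source-only supervised baseline: F_S alone
        if (schedule$augment_no_da) {
          b <- bs[[k]]
          aug <- Map(function(i, j) augment_flip_rotate(
            src[[i]], msk[[i]], derive_seed(seed, paste0("aug", ep, j))),
            b, seq_along(b))
          x_s <- ad_leaf(stack_images(lapply(aug, `[[`, "image")))
          gt <- ad_leaf(stack_images(lapply(aug, `[[`, "mask")))
        }
        pf_s <- net_nodes(models$f_s)
        seg <- ad_soft_dice(fw_segmenter(models$f_s, pf_s, x_s)$probs, gt)
        ad_backward(seg)
        models$f_s$params <- adam_update(opts$f_s, models$f_s$params, pf_s)
        rep <- total_loss(0, 0, 0, 0, seg$value, 0, w)
        hist[[step]] <- loss_report_row(rep, "stage3", ep, step)
        next
      }

      ns <- dim(x_s$value)[4]; nt <- dim(x_t$value)[4]
      pg_st <- net_nodes(models$g_st); pg_ts <- net_nodes(models$g_ts)
      pf_s <- net_nodes(models$f_s); pf_t <- net_nodes(models$f_t)
      iden_s <- NULL; iden_t <- NULL; recon_s <- NULL
      if (use_trans) {
        outA <- fw_translate01(models$g_st, pg_st,
                               ad_concat_n(list(x_s, x_t)))
        fake_t <- ad_slice_n(outA, 1L, ns)
        iden_t <- ad_slice_n(outA, ns + 1L, ns + nt)
        outB <- fw_translate01(models$g_ts, pg_ts,
                               ad_concat_n(list(x_t, x_s, fake_t)))
        fake_s <- ad_slice_n(outB, 1L, nt)
        iden_s <- ad_slice_n(outB, nt + 1L, nt + ns)
        recon_s <- ad_slice_n(outB, nt + ns + 1L, nt + 2L * ns)
      } else {
        fake_t <- x_s; fake_s <- x_t
      }
      need_aux <- use_consis || use_feat
      # batched segmenter passes: each branch sees its supervised input and,
      # when needed, the input of the consistency/feature-alignment path
      if (need_aux) {
        outS <- fw_segmenter(models$f_s, pf_s, ad_concat_n(list(x_s, fake_s)))
        seg_s <- list(probs = ad_slice_n(outS$probs, 1L, ns),
                      bottleneck = ad_slice_n(outS$bottleneck, 1L, ns))
        seg_s_fake <- list(probs = ad_slice_n(outS$probs, ns + 1L, ns + nt),
                           bottleneck = ad_slice_n(outS$bottleneck, ns + 1L,
                                                   ns + nt))
        outT <- fw_segmenter(models$f_t, pf_t, ad_concat_n(list(fake_t, x_t)))
        seg_t_fake <- list(probs = ad_slice_n(outT$probs, 1L, ns),
                           bottleneck = ad_slice_n(outT$bottleneck, 1L, ns))
        seg_t <- list(probs = ad_slice_n(outT$probs, ns + 1L, ns + nt),
                      bottleneck = ad_slice_n(outT$bottleneck, ns + 1L,
                                              ns + nt))
      } else {
        seg_s <- fw_segmenter(models$f_s, pf_s, x_s)
        seg_t_fake <- fw_segmenter(models$f_t, pf_t, fake_t)
        seg_t <- NULL; seg_s_fake <- NULL
      }

      # ---- discriminator step (detached fakes/features) ----
      adv_s_val <- 0; adv_t_val <- 0
      if (use_pix) {
        pd_s <- net_nodes(models$d_s_pix); pd_t <- net_nodes(models$d_t_pix)
        sc_s <- fw_pixel_disc(models$d_s_pix, pd_s,
                              ad_concat_n(list(x_s, ad_detach(fake_s))))
        d_s_pix_real <- ad_bce_real(ad_slice_n(sc_s, 1L, ns))
        d_s_pix_fake <- ad_bce_fake(ad_slice_n(sc_s, ns + 1L, ns + nt))
        sc_t <- fw_pixel_disc(models$d_t_pix, pd_t,
                              ad_concat_n(list(x_t, ad_detach(fake_t))))
        d_t_pix_real <- ad_bce_real(ad_slice_n(sc_t, 1L, nt))
        d_t_pix_fake <- ad_bce_fake(ad_slice_n(sc_t, nt + 1L, nt + ns))
      }
      if (use_feat) {
        pe_s <- net_nodes(models$d_s_feat); pe_t <- net_nodes(models$d_t_feat)
        fs_sc <- fw_feature_disc(models$d_s_feat, pe_s, ad_concat_n(list(
          ad_detach(seg_s$bottleneck), ad_detach(seg_s_fake$bottleneck))))
        d_s_ft_real <- ad_bce_real(ad_slice_n(fs_sc, 1L, ns))
        d_s_ft_fake <- ad_bce_fake(ad_slice_n(fs_sc, ns + 1L, ns + nt))
        ft_sc <- fw_feature_disc(models$d_t_feat, pe_t, ad_concat_n(list(
          ad_detach(seg_t$bottleneck), ad_detach(seg_t_fake$bottleneck))))
        d_t_ft_real <- ad_bce_real(ad_slice_n(ft_sc, 1L, nt))
        d_t_ft_fake <- ad_bce_fake(ad_slice_n(ft_sc, nt + 1L, nt + ns))
      }
      if (use_pix || use_feat) {
        s_terms <- list(); t_terms <- list()
        if (use_feat) {
          s_terms <- c(s_terms, list(d_s_ft_fake, d_s_ft_real))
          t_terms <- c(t_terms, list(d_t_ft_fake, d_t_ft_real))
        }
        if (use_pix) {
          s_terms <- c(s_terms, list(d_s_pix_fake, d_s_pix_real))
          t_terms <- c(t_terms, list(d_t_pix_fake, d_t_pix_real))
        }
        adv_s <- ad_lincomb(s_terms, rep(1, length(s_terms)))
        adv_t <- ad_lincomb(t_terms, rep(1, length(t_terms)))
        ad_backward(adv_s); ad_backward(adv_t)
        if (use_pix) {
          models$d_s_pix$params <- adam_update(opts$d_s_pix,
                                               models$d_s_pix$params, pd_s)
          models$d_t_pix$params <- adam_update(opts$d_t_pix,
                                               models$d_t_pix$params, pd_t)
        }
        if (use_feat) {
          models$d_s_feat$params <- adam_update(opts$d_s_feat,
                                                models$d_s_feat$params, pe_s)
          models$d_t_feat$params <- adam_update(opts$d_t_feat,
                                                models$d_t_feat$params, pe_t)
        }
        adv_s_val <- adv_s$value; adv_t_val <- adv_t$value
      }

      # ---- generator/segmenter step ----
      g_terms <- list(); g_wts <- numeric()
      if (use_pix) {
        pd_s2 <- net_nodes(models$d_s_pix); pd_t2 <- net_nodes(models$d_t_pix)
        g_terms <- c(g_terms, list(
          ad_bce_real(fw_pixel_disc(models$d_s_pix, pd_s2, fake_s)),
          ad_bce_real(fw_pixel_disc(models$d_t_pix, pd_t2, fake_t))))
        g_wts <- c(g_wts, w$lambda_adv, w$lambda_adv)
      }
      if (use_feat) {
        pe_s2 <- net_nodes(models$d_s_feat); pe_t2 <- net_nodes(models$d_t_feat)
        g_terms <- c(g_terms, list(
          ad_bce_real(fw_feature_disc(models$d_s_feat, pe_s2,
                                      seg_s_fake$bottleneck)),
          ad_bce_real(fw_feature_disc(models$d_t_feat, pe_t2,
                                      seg_t_fake$bottleneck))))
        g_wts <- c(g_wts, w$lambda_adv, w$lambda_adv)
      }
      cyc_val <- 0; iden_val <- 0
      if (use_trans) {
        recon_t <- fw_translate01(models$g_st, pg_st, fake_s)
        cyc <- ad_lincomb(list(ad_mean_abs_diff(recon_s, x_s),
                               ad_mean_abs_diff(recon_t, x_t)), c(1, 1))
        iden <- ad_lincomb(list(ad_mean_abs_diff(iden_s, x_s),
                                ad_mean_abs_diff(iden_t, x_t)), c(1, 1))
        g_terms <- c(g_terms, list(cyc, iden))
        g_wts <- c(g_wts, w$lambda_cycle, w$lambda_iden)
        cyc_val <- cyc$value; iden_val <- iden$value
      }
      seg <- ad_lincomb(list(ad_soft_dice(seg_s$probs, gt),
                             ad_soft_dice(seg_t_fake$probs, gt)), c(1, 1))
      g_terms <- c(g_terms, list(seg))
      g_wts <- c(g_wts, w$lambda_seg)
      consis_val <- 0
      if (use_consis) {
        consis <- ad_soft_dice(seg_t$probs, seg_s_fake$probs)
        g_terms <- c(g_terms, list(consis))
        g_wts <- c(g_wts, w$lambda_consis)
        consis_val <- consis$value
      }
      g_loss <- ad_lincomb(g_terms, g_wts)
      ad_backward(g_loss)
      if (use_trans) {
        models$g_st$params <- adam_update(opts$g_st, models$g_st$params,
                                          pg_st)
        models$g_ts$params <- adam_update(opts$g_ts, models$g_ts$params,
                                          pg_ts)
      }
      models$f_s$params <- adam_update(opts$f_s, models$f_s$params, pf_s)
      models$f_t$params <- adam_update(opts$f_t, models$f_t$params, pf_t)

      rep <- total_loss(adv_s_val, adv_t_val, cyc_val, iden_val, seg$value,
                        consis_val, w)
      hist[[step]] <- loss_report_row(rep, "stage3", ep, step)
    }
  }
  list(models = models, history = do.call(rbind, hist))
}

## ---- evaluation and experiment runner ---------------------------------------

#' Segment a dataset split and evaluate against its masks
#'
#' @param segmenter The segmenter to evaluate (target branch `f_t` for the
#'   adaptation variants, source branch `f_s` for the source-only baseline).
#' @param dataset A `domain_dataset` whose samples carry masks.
#' @param split Which split to evaluate, default `"test"`.
#' @param aggregation Passed to [evaluate_pairs()].
#' @return A `seg_metrics` object.
#' @export
evaluate_segmenter <- function(segmenter, dataset, split = "test",
                               aggregation = "per_image_mean") {
  imgs <- dataset_images(dataset, split)
  gts <- dataset_masks(dataset, split)
  if (length(imgs) == 0L) stop_sym("no samples in split '", split, "'")
  # batched inference, then split back into per-image masks
  preds <- list()
  for (b in split(seq_along(imgs), ceiling(seq_along(imgs) / 8))) {
    probs <- segment_probs(segmenter, stack_images(imgs[b]))
    for (j in seq_along(b))
      preds[[b[j]]] <- binarize(probs[, , 1L, j])
  }
  evaluate_pairs(preds, gts, aggregation)
}

variant_eval_branch <- function(variant) if (variant == "no_da") "f_s" else "f_t"

# Train all stages for one source->target pair and one variant, reusing
# cached stage-1/stage-2 models when several variants share them.
train_pipeline <- function(datasets, schedule, variant, seed,
                           cache = new.env(parent = emptyenv()),
                           net_args = list()) {
  key12 <- "stage12"
  hist <- list()
  if (variant == "no_da") {
    if (is.null(cache$no_da)) {
      models <- do.call(model_bundle_new,
                        c(list(seed = derive_seed(seed, "init")), net_args))
      # fair budget: the baseline gets the stage-2 + stage-3 epochs supervised
      sch <- schedule
      sch$stage2$epochs <- 0L
      sch$stage3$epochs <- schedule$stage2$epochs + schedule$stage3$epochs
      st3 <- train_stage3(datasets, models, sch, "no_da", seed)
      cache$no_da <- st3
    }
    return(cache$no_da)
  }
  if (is.null(cache[[key12]])) {
    models <- do.call(model_bundle_new,
                      c(list(seed = derive_seed(seed, "init")), net_args))
    st1 <- train_stage1(datasets, models, schedule, seed)
    st2 <- train_stage2(datasets, st1$models, schedule, seed)
    cache[[key12]] <- list(models = st2$models,
                           history = rbind(st1$history, st2$history))
  }
  base <- cache[[key12]]
  st3 <- train_stage3(datasets, base$models, schedule, variant, seed)
  list(models = st3$models, history = rbind(base$history, st3$history))
}

#' Run a full cross-domain experiment
#'
#' For every ordered pair of configured domains and every requested ablation
#' variant: generates the two phantom datasets, runs the three training
#' stages (stage-1/2 products are shared across variants of the same pair),
#' evaluates on the held-out target test split, and returns the result
#' tables.  With k domains this yields k*(k-1) source->target rows per
#' variant plus an Average row.
#'
#' @param config A list (or YAML file read into one) with entries:
#'   `phantom` (arguments for [phantom_config()]), `domains` (named list of
#'   [style_preset()] names or [domain_style()] argument lists), `n_train`,
#'   `n_test`, `schedule` (arguments for [stage_schedule()]), `variants`
#'   (character vector), `seed`, optional `pairs` (list of `c(src, tgt)`),
#'   optional `network` (overrides for [model_bundle_new()]).
#' @return A list with `tables` (one data frame per variant), `history`,
#'   and `models` (per pair/variant bundles).
#' @export
run_experiment <- function(config) {
  config <- validate_run_config(config)
  pc <- do.call(phantom_config, config$phantom)
  styles <- lapply(config$domains, function(s) {
    if (is.character(s)) style_preset(s) else do.call(domain_style, s)
  })
  dn <- names(styles)
  pairs <- config$pairs %||% {
    p <- list()
    for (a in dn) for (b in dn) if (a != b) p[[length(p) + 1L]] <- c(a, b)
    p
  }
  schedule <- do.call(stage_schedule, config$schedule)
  seed <- config$seed
  datasets_for <- function(name, domain_tag) {
    generate_domain_dataset(pc, styles[[name]], config$n_train + config$n_test,
                            test_count = config$n_test,
                            seed = derive_seed(seed, paste0("data_", name)),
                            domain = domain_tag)
  }
  tables <- list(); history <- list(); models_out <- list()
  rows <- stats::setNames(vector("list", length(config$variants)),
                          config$variants)
  for (pr in pairs) {
    ds <- list(source = datasets_for(pr[1], "source"),
               target = datasets_for(pr[2], "target"))
    cache <- new.env(parent = emptyenv())
    pair_seed <- derive_seed(seed, paste(pr, collapse = ">"))
    for (variant in config$variants) {
      fit <- train_pipeline(ds, schedule, variant, pair_seed, cache,
                            config$network %||% list())
      branch <- variant_eval_branch(variant)
      met <- evaluate_segmenter(fit$models[[branch]], ds$target, "test",
                                config$aggregation %||% "per_image_mean")
      rows[[variant]] <- c(rows[[variant]],
                           list(list(source = pr[1], target = pr[2],
                                     metrics = met)))
      key <- paste(pr[1], pr[2], variant, sep = "_")
      history[[key]] <- fit$history
      models_out[[key]] <- fit$models
    }
  }
  for (variant in config$variants) tables[[variant]] <- metrics_table(
    rows[[variant]])
  list(tables = tables, history = history, models = models_out)
}

#' Validate an experiment configuration
#'
#' Fills defaults, rejects unknown keys and checks types before any
#' computation.
#'
#' @param config A named list, typically read from YAML.
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  allowed <- c("phantom", "domains", "n_train", "n_test", "schedule",
               "variants", "seed", "pairs", "network", "aggregation",
               "out_dir", "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_sym("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$phantom <- config$phantom %||% list()
  if (is.null(config$domains) || length(config$domains) < 2L ||
      is.null(names(config$domains)))
    stop_sym("config$domains must be a named list of at least two styles")
  config$n_train <- as.integer(config$n_train %||% 50L)
  config$n_test <- as.integer(config$n_test %||% 10L)
  if (config$n_train < 1L || config$n_test < 1L)
    stop_sym("n_train and n_test must be positive")
  config$schedule <- config$schedule %||% list()
  config$variants <- config$variants %||% "full"
  bad <- setdiff(config$variants, ablation_variants())
  if (length(bad))
    stop_sym("unknown variant(s): ", paste(bad, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$pairs)) {
    config$pairs <- lapply(config$pairs, function(p) {
      if (length(p) != 2L || !all(p %in% names(config$domains)))
        stop_sym("each pair must name two configured domains")
      as.character(p)
    })
  }
  config
}
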