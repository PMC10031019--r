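# Training-loop unit tests run at micro scale (32x32, a dozen images, one
# epoch); convergence-level runs live in test-acceptance.R.

test_that("zero-epoch stages leave models bit-identical", {
  ds <- tiny_pair(n = 6)
  models <- model_bundle_new(seed = 1, trans_width = 4, seg_width = 4,
                             disc_width = 4)
  sch <- micro_schedule()
  sch$stage1$epochs <- 0L; sch$stage2$epochs <- 0L; sch$stage3$epochs <- 0L
  expect_identical(train_stage1(ds, models, sch)$models, models)
  expect_identical(train_stage2(ds, models, sch)$models, models)
  expect_identical(train_stage3(ds, models, sch, "full")$models, models)
})

test_that("each stage touches exactly its stated parameter set", {
  ds <- tiny_pair(n = 6)
  models <- model_bundle_new(seed = 2, trans_width = 4, seg_width = 4,
                             disc_width = 4)
  sch <- micro_schedule()
  h0 <- vapply(models[bundle_net_names()], param_hash, "")

  s1 <- train_stage1(ds, models, sch, seed = 3)$models
  h1 <- vapply(s1[bundle_net_names()], param_hash, "")
  changed1 <- names(h1)[h1 != h0]
  expect_setequal(changed1, c("g_st", "g_ts", "d_s_pix", "d_t_pix"))

  s2 <- train_stage2(ds, s1, sch, seed = 3)$models
  h2 <- vapply(s2[bundle_net_names()], param_hash, "")
  expect_setequal(names(h2)[h2 != h1], c("f_s", "f_t"))

  s3 <- train_stage3(ds, s2, sch, "full", seed = 3)$models
  h3 <- vapply(s3[bundle_net_names()], param_hash, "")
  expect_setequal(names(h3)[h3 != h2], bundle_net_names())

  # no_da: translators and discriminators never updated
  nda <- train_stage3(ds, s2, sch, "no_da", seed = 3)$models
  hn <- vapply(nda[bundle_net_names()], param_hash, "")
  expect_setequal(names(hn)[hn != h2], "f_s")
})

test_that("stage histories satisfy the weighted-sum decomposition", {
  ds <- tiny_pair(n = 6)
  models <- model_bundle_new(seed = 4, trans_width = 4, seg_width = 4,
                             disc_width = 4)
  sch <- micro_schedule()
  fit1 <- train_stage1(ds, models, sch, seed = 5)
  fit2 <- train_stage2(ds, fit1$models, sch, seed = 5)
  fit3 <- train_stage3(ds, fit2$models, sch, "full", seed = 5)
  w <- sch$stage3$weights
  for (h in list(fit1$history, fit2$history, fit3$history)) {
    expect_true(all(is.finite(as.matrix(h[, 4:10]))))
    recomputed <- w$lambda_adv * (h$adv_s + h$adv_t) +
      w$lambda_cycle * h$cycle + w$lambda_iden * h$iden +
      w$lambda_seg * h$seg + w$lambda_consis * h$consis
    expect_equal(h$total, recomputed, tolerance = 1e-6)
  }
})

test_that("ablation variants gate the right loss terms", {
  ds <- tiny_pair(n = 6)
  models <- model_bundle_new(seed = 6, trans_width = 4, seg_width = 4,
                             disc_width = 4)
  sch <- micro_schedule()
  base <- train_stage2(ds, train_stage1(ds, models, sch, 7)$models, sch,
                       7)$models
  h_nc <- train_stage3(ds, base, sch, "no_consistency", seed = 7)$history
  expect_true(all(h_nc$consis == 0))
  h_nf <- train_stage3(ds, base, sch, "no_feature_gan", seed = 7)$history
  expect_true(all(is.finite(h_nf$total)))
  nf <- train_stage3(ds, base, sch, "no_feature_gan", seed = 7)$models
  expect_identical(param_hash(nf$d_s_feat), param_hash(base$d_s_feat))
  nt <- train_stage3(ds, base, sch, "no_translation", seed = 7)
  expect_true(all(nt$history$cycle == 0) && all(nt$history$iden == 0))
  expect_identical(param_hash(nt$models$g_st), param_hash(base$g_st))
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_pair(n = 6)
  sch <- micro_schedule()
  run <- function() {
    m <- model_bundle_new(seed = 8, trans_width = 4, seg_width = 4,
                          disc_width = 4)
    f <- train_stage1(ds, m, sch, seed = 9)
    train_stage3(ds, f$models, sch, "full", seed = 9)$models
  }
  a <- run(); b <- run()
  expect_identical(vapply(a[bundle_net_names()], param_hash, ""),
                   vapply(b[bundle_net_names()], param_hash, ""))
})

test_that("training validates its preconditions", {
  ds <- tiny_pair(n = 6)
  # unlabeled source: strip masks
  unl <- ds
  unl$source$samples <- lapply(unl$source$samples, function(s) {
    s$mask <- NULL; s
  })
  models <- model_bundle_new(seed = 1, trans_width = 4, seg_width = 4,
                             disc_width = 4)
  sch <- micro_schedule()
  expect_error(train_stage2(unl, models, sch), "mask")
  empty <- ds
  empty$source$split[] <- "test"
  expect_error(train_stage1(empty, models, sch), "empty training split")
})

test_that("run_experiment produces pair tables and is reproducible", {
  cfg <- list(
    phantom = list(image_size = 32),
    domains = list(a = "site_a", b = "site_inverted"),
    n_train = 6, n_test = 2,
    schedule = list(stage1 = list(epochs = 1, lr_translation = 1e-3,
                                  lr_discriminator = 2e-4),
                    stage2 = list(epochs = 1, lr_segmentation = 2e-3),
                    stage3 = list(epochs = 1, lr_all = 5e-4),
                    batch_size = 4),
    network = list(trans_width = 4, seg_width = 4, disc_width = 4),
    variants = c("full", "no_da"),
    pairs = list(c("a", "b")),
    seed = 11)
  res <- run_experiment(cfg)
  expect_named(res$tables, c("full", "no_da"))
  tb <- res$tables$full
  expect_identical(tb$source[1], "a")
  expect_true(all(c("pa", "dsc", "tpr", "tnr") %in% names(tb)))
  expect_true(all(tb$pa >= 0 & tb$pa <= 1))
  res2 <- run_experiment(cfg)
  expect_identical(res$tables, res2$tables)
  # unknown keys and variants are rejected before any computation
  bad <- cfg; bad$typo <- 1
  expect_error(run_experiment(bad), "unknown config key")
  bad2 <- cfg; bad2$variants <- "nope"
  expect_error(validate_run_config(bad2), "unknown variant")
})

test_that("three domains yield six source->target rows plus an Average", {
  # schedule with zero epochs everywhere: evaluation of untrained nets is
  # enough to exercise the experiment matrix shape quickly
  cfg <- list(
    phantom = list(image_size = 32),
    domains = list(d1 = "site_a", d2 = "site_b", d3 = "site_inverted"),
    n_train = 4, n_test = 2,
    schedule = list(stage1 = list(epochs = 0, lr_translation = 1e-3,
                                  lr_discriminator = 2e-4),
                    stage2 = list(epochs = 0, lr_segmentation = 2e-3),
                    stage3 = list(epochs = 0, lr_all = 5e-4),
                    batch_size = 4),
    network = list(trans_width = 4, seg_width = 4, disc_width = 4),
    variants = "full", seed = 12)
  res <- run_experiment(cfg)
  tb <- res$tables$full
  expect_identical(nrow(tb), 7L)  # 6 ordered pairs + Average
  expect_identical(tb$source[7], "Average")
  expect_equal(tb$dsc[7], mean(tb$dsc[1:6]))
})
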