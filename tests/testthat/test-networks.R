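test_that("translator preserves shape and range, rejects bad sizes", {
  tr <- translator_new(width = 4, n_res = 1, seed = 1)
  img <- withr_seed(1, matrix(runif(64 * 64), 64, 64))
  out <- translate(tr, img)
  expect_identical(dim(out), c(64L, 64L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(translate(tr, matrix(0.5, 30, 30)), "divisible by 4")
  # symmetry: both directions share the constructor, not the parameters
  t2 <- translator_new(width = 4, n_res = 1, seed = 2)
  expect_identical(names(tr$params), names(t2$params))
  expect_false(identical(tr$params$stem.w, t2$params$stem.w))
})

test_that("segmenter emits probability maps and a stride-16 bottleneck", {
  f <- segmenter_new(width = 4, seed = 3)
  img <- withr_seed(2, matrix(runif(64 * 64), 64, 64))
  p <- segment_probs(f, img)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # untrained net on a constant input: spatially near-constant output
  pc <- segment_probs(f, matrix(0.5, 64, 64))
  expect_lt(max(pc) - min(pc), 0.5)
  z <- encode_bottleneck(f, img)
  expect_identical(dim(z)[1:3], c(4L, 4L, 32L))  # 64 / 2^4, 8 * width
  # deterministic forward
  expect_identical(encode_bottleneck(f, img), z)
  expect_error(segment_probs(f, matrix(0.5, 24, 24)), "divisible by 16")
  # style shift moves the untrained features
  shifted <- apply_domain_style(img, style_preset("site_inverted"), 1)
  expect_gt(mean(abs(encode_bottleneck(f, shifted) - z)), 0)
})

test_that("discriminators score in (0,1) with the expected patch geometry", {
  d <- pixel_discriminator_new(width = 4, seed = 4)
  img <- withr_seed(3, matrix(runif(64 * 64), 64, 64))
  s <- discriminate_pixel(d, img)
  expect_identical(dim(s)[1:2], c(8L, 8L))  # three stride-2 stages
  expect_true(all(s > 0 & s < 1))
  fd <- feature_discriminator_new(in_channels = 32, width = 8, seed = 5)
  f <- segmenter_new(width = 4, seed = 3)
  z <- encode_bottleneck(f, img)
  sf <- discriminate_feature(fd, z)
  expect_true(all(sf > 0 & sf < 1))
  expect_error(discriminate_feature(fd, array(0.1, c(4, 4, 7, 1))),
               "channels")
})

test_that("autodiff gradients match finite differences on a tiny net", {
  # double-precision GEMM so the finite-difference oracle is not drowned in
  # single-precision round-off
  withr::local_options(symsegda.precision = "double")
  tr <- translator_new(width = 2, n_res = 1, seed = 6)
  x <- withr_seed(4, array(runif(16 * 16), c(16, 16, 1, 1)))
  loss_of <- function(net) {
    mean(symsegda:::fw_translate01(net, symsegda:::net_nodes(net),
                                   symsegda:::ad_leaf(x))$value)
  }
  pn <- symsegda:::net_nodes(tr)
  out <- symsegda:::fw_translate01(tr, pn, symsegda:::ad_leaf(x))
  loss <- symsegda:::ad_vmean(symsegda:::ad_sum_hwc(out))
  scale <- 1 / prod(dim(out$value))
  symsegda:::ad_backward(loss)
  for (nm in c("stem.w", "res1a.w", "u1.w", "out.b", "d1.g")) {
    g_auto <- pn[[nm]]$grad[1] * scale  # loss used sum; rescale to mean
    h <- 1e-5
    tp <- tr; tp$params[[nm]][1] <- tp$params[[nm]][1] + h
    tm <- tr; tm$params[[nm]][1] <- tm$params[[nm]][1] - h
    g_num <- (loss_of(tp) - loss_of(tm)) / (2 * h)
    expect_equal(g_auto, g_num, tolerance = 1e-3)
  }
})

test_that("hybrid attention output equals channel-gated plus spatial-gated", {
  f <- segmenter_new(width = 4, seed = 7)
  x <- symsegda:::ad_leaf(withr_seed(5, array(runif(8 * 8 * 16 * 2),
                                              c(8, 8, 16, 2))))
  pn <- symsegda:::net_nodes(f)
  att <- symsegda:::fw_attention(x, pn, "att1")
  # instrument the two branches independently
  g <- symsegda:::ad_dense(symsegda:::ad_gap(x), pn[["att1.ca1.w"]],
                           pn[["att1.ca1.b"]])
  g <- symsegda:::ad_sigmoid(symsegda:::ad_dense(
    symsegda:::ad_relu(g), pn[["att1.ca2.w"]], pn[["att1.ca2.b"]]))
  chan <- symsegda:::ad_scale_channel(x, g)$value
  s <- symsegda:::ad_sigmoid(symsegda:::ad_conv(
    symsegda:::ad_channel_meanmax(x), pn[["att1.sa.w"]], pn[["att1.sa.b"]],
    1L, 3L))
  spat <- symsegda:::ad_scale_spatial(x, s)$value
  expect_equal(att$value, chan + spat, tolerance = 1e-12)
})

test_that("model bundle builds eight nets; checkpoints round-trip bitwise", {
  b <- model_bundle_new(scale = "tiny", seed = 1, trans_width = 4,
                        seg_width = 4, disc_width = 4)
  expect_s3_class(b, "model_bundle")
  # architectural symmetry between the paired networks
  expect_identical(b$f_s$arch, b$f_t$arch)
  expect_identical(b$g_st$arch, b$g_ts$arch)
  expect_false(identical(b$f_s$params, b$f_t$params))
  tmp <- withr::local_tempdir()
  ck <- file.path(tmp, "bundle.rds")
  save_checkpoint(b, ck)
  b2 <- load_checkpoint(ck, expected_config = b$config)
  img <- withr_seed(6, matrix(runif(64 * 64), 64, 64))
  expect_identical(segment_probs(b$f_t, img), segment_probs(b2$f_t, img))
  expect_identical(translate(b$g_st, img), translate(b2$g_st, img))
  other <- model_bundle_new(scale = "tiny", seed = 1, trans_width = 8)
  expect_error(load_checkpoint(ck, expected_config = other$config),
               "mismatch")
})

test_that("a full tiny forward+backward pass stays under a second", {
  b <- model_bundle_new(scale = "tiny", seed = 2)
  x <- symsegda:::ad_leaf(withr_seed(7, array(runif(64 * 64), c(64, 64, 1, 1))))
  t0 <- Sys.time()
  pn <- symsegda:::net_nodes(b$f_t)
  out <- symsegda:::fw_segmenter(b$f_t, pn, x)
  symsegda:::ad_backward(symsegda:::ad_vmean(symsegda:::ad_sum_hwc(out$probs)))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  t0 <- Sys.time()
  pn <- symsegda:::net_nodes(b$g_st)
  y <- symsegda:::fw_translate01(b$g_st, pn, x)
  symsegda:::ad_backward(symsegda:::ad_vmean(symsegda:::ad_sum_hwc(y)))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})
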