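# Network definitions.  A network is a plain list: a `kind`, an `arch`
# description (enough to rebuild it), and a named list of parameter arrays.
# Forward passes build an autodiff graph from parameter leaf nodes; the
# public inference functions wrap them and return plain arrays.

init_gan <- function(...) {
  d <- c(...)
  array(rnorm(prod(d), 0, 0.02), d)
}

init_he <- function(k1, k2, cin, cout) {
  array(rnorm(k1 * k2 * cin * cout, 0, sqrt(2 / (k1 * k2 * cin))),
        c(k1, k2, cin, cout))
}

# Parameter declaration helpers operating on a collecting environment
decl_conv <- function(pp, name, k, cin, cout, init = c("gan", "he"),
                      norm = TRUE) {
  init <- match.arg(init)
  pp$p[[paste0(name, ".w")]] <- if (init == "gan") init_gan(k, k, cin, cout)
    else init_he(k, k, cin, cout)
  pp$p[[paste0(name, ".b")]] <- numeric(cout)
  if (norm) {
    pp$p[[paste0(name, ".g")]] <- rep(1, cout)
    pp$p[[paste0(name, ".be")]] <- numeric(cout)
  }
}

decl_convt <- function(pp, name, k, cin, cout) {
  # transposed-conv weight uses the adjoint layout [kh, kw, cout, cin]
  pp$p[[paste0(name, ".w")]] <- init_gan(k, k, cout, cin)
  pp$p[[paste0(name, ".b")]] <- numeric(cout)
  pp$p[[paste0(name, ".g")]] <- rep(1, cout)
  pp$p[[paste0(name, ".be")]] <- numeric(cout)
}

decl_dense <- function(pp, name, cin, cout) {
  pp$p[[paste0(name, ".w")]] <- matrix(rnorm(cout * cin, 0, sqrt(2 / cin)),
                                       cout, cin)
  pp$p[[paste0(name, ".b")]] <- numeric(cout)
}

net_nodes <- function(net) lapply(net$params, ad_leaf)

# conv + instance norm + activation on graph nodes
blk <- function(x, pn, name, stride, pad, act = ad_relu) {
  h <- ad_conv(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
               stride, pad)
  h <- ad_instnorm(h, pn[[paste0(name, ".g")]], pn[[paste0(name, ".be")]])
  if (is.null(act)) h else act(h)
}

blkt <- function(x, pn, name, act = ad_relu) {
  h <- ad_convt(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]], 2L, 0L)
  h <- ad_instnorm(h, pn[[paste0(name, ".g")]], pn[[paste0(name, ".be")]])
  if (is.null(act)) h else act(h)
}

## ---- translator -------------------------------------------------------------

#' Create an image translator
#'
#' Encoder: one stride-1 convolution to `width` channels, two stride-2
#' downsampling blocks, `n_res` residual blocks.  Decoder: two trainable
#' transposed-convolution upsampling blocks and an output convolution with
#' tanh activation.  Instance normalization throughout.  Input and output are
#' same-size images; internally intensities live in (-1, 1).
#'
#' @param width Base channel width (desk-scale default 8).
#' @param n_res Number of residual blocks (clinical-scale 8; desk-scale 2).
#' @param seed Seed for weight initialization.
#' @return A network object of kind `"translator"`.
#' @export
translator_new <- function(width = 8L, n_res = 2L, seed = 1L) {
  pp <- new.env(); pp$p <- list()
  with_seed(seed, {
    decl_conv(pp, "stem", 3L, 1L, width)
    decl_conv(pp, "d1", 3L, width, 2L * width)
    decl_conv(pp, "d2", 3L, 2L * width, 4L * width)
    for (r in seq_len(n_res)) {
      decl_conv(pp, paste0("res", r, "a"), 3L, 4L * width, 4L * width)
      decl_conv(pp, paste0("res", r, "b"), 3L, 4L * width, 4L * width)
    }
    decl_convt(pp, "u1", 2L, 4L * width, 2L * width)
    decl_convt(pp, "u2", 2L, 2L * width, width)
    decl_conv(pp, "out", 3L, width, 1L, norm = FALSE)
  })
  structure(list(kind = "translator",
                 arch = list(width = as.integer(width),
                             n_res = as.integer(n_res)),
                 params = pp$p),
            class = c("symsegda_net", "translator"))
}

# x: node in [-1, 1]; returns node in (-1, 1)
fw_translator <- function(net, pn, x) {
  h <- blk(x, pn, "stem", 1L, 1L)
  h <- blk(h, pn, "d1", 2L, 1L)
  h <- blk(h, pn, "d2", 2L, 1L)
  for (r in seq_len(net$arch$n_res)) {
    t <- blk(h, pn, paste0("res", r, "a"), 1L, 1L)
    t <- blk(t, pn, paste0("res", r, "b"), 1L, 1L, act = NULL)
    h <- ad_add(h, t)
  }
  h <- blkt(h, pn, "u1")
  h <- blkt(h, pn, "u2")
  ad_tanh(ad_conv(h, pn$out.w, pn$out.b, 1L, 1L))
}

# [0,1] image node -> [0,1] image node
fw_translate01 <- function(net, pn, x01) {
  y <- fw_translator(net, pn, ad_affine(x01, 2, -1))
  ad_affine(y, 0.5, 0.5)
}

check_div <- function(image, by, what) {
  d <- dim(image)
  if (d[1] %% by != 0 || d[2] %% by != 0)
    stop_sym(what, " requires spatial size divisible by ", by, ", got ",
             d[1], "x", d[2])
}

#' Translate an image to the other domain
#'
#' @param t A translator network.
#' @param image Matrix (or `[H,W,1,N]` array) of intensities in `[0, 1]`;
#'   spatial size must be divisible by 4.
#' @return The translated image(s) in `[0, 1]`, same shape as the input.
#' @export
translate <- function(t, image) {
  stopifnot(inherits(t, "translator"))
  assert_image01(image)
  x <- as_nhwc(image)
  check_div(x, 4L, "translate")
  y <- fw_translate01(t, net_nodes(t), ad_leaf(x))$value
  as_image_out(pmin(pmax(y, 0), 1), image)
}

## ---- segmenter --------------------------------------------------------------

#' Create a segmentation network
#'
#' U-Net-style encoder-decoder with four stride-2 encoder stages (channel
#' widths `width * c(1, 2, 4, 8, 8)`), skip connections fusing each decoder
#' level with the matching encoder stage, and a hybrid attention block
#' (channel gate + spatial gate, summed) after every fusion.  The head is a
#' 1x1 convolution with sigmoid, so the output is an `H x W` probability map.
#' The deepest encoder output (stride 16) is the bottleneck exposed for
#' feature-level discrimination.
#'
#' The `"tiny"` mode (plain convolution stages, width 8) is the desk-scale
#' configuration; larger widths approximate the capacity of a pretrained
#' compound-scaled backbone, which is not available in this environment.
#'
#' @param width Base channel width.
#' @param mode `"tiny"` or `"clinical"` (the latter simply selects width 32).
#' @param seed Seed for weight initialization.
#' @return A network object of kind `"segmenter"`.
#' @export
segmenter_new <- function(width = 8L, mode = c("tiny", "clinical"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "clinical") width <- max(width, 32L)
  w <- as.integer(width)
  enc <- c(w, 2L * w, 4L * w, 8L * w, 8L * w)   # stem, e1..e4
  dec <- c(4L * w, 2L * w, w, w)                # fuse outputs, deep to shallow
  pp <- new.env(); pp$p <- list()
  decl_att <- function(name, c) {
    hid <- max(4L, c %/% 4L)
    decl_dense(pp, paste0(name, ".ca1"), c, hid)
    decl_dense(pp, paste0(name, ".ca2"), hid, c)
    decl_conv(pp, paste0(name, ".sa"), 7L, 2L, 1L, init = "he", norm = FALSE)
  }
  with_seed(seed, {
    decl_conv(pp, "stem", 3L, 1L, enc[1], init = "he")
    for (i in 1:4) {
      decl_conv(pp, paste0("e", i, "a"), 3L, enc[i], enc[i + 1], init = "he")
      decl_conv(pp, paste0("e", i, "b"), 3L, enc[i + 1], enc[i + 1],
                init = "he")
    }
    skips <- enc[4:1]
    ins <- c(enc[5] + skips[1], dec[1] + skips[2], dec[2] + skips[3],
             dec[3] + skips[4])
    for (i in 1:4) {
      decl_conv(pp, paste0("f", i), 3L, ins[i], dec[i], init = "he")
      decl_att(paste0("att", i), dec[i])
    }
    decl_conv(pp, "head", 1L, dec[4], 1L, init = "he", norm = FALSE)
  })
  structure(list(kind = "segmenter",
                 arch = list(width = w, mode = mode, enc = enc, dec = dec),
                 params = pp$p),
            class = c("symsegda_net", "segmenter"))
}

fw_attention <- function(x, pn, name) {
  g <- ad_dense(ad_gap(x), pn[[paste0(name, ".ca1.w")]],
                pn[[paste0(name, ".ca1.b")]])
  g <- ad_sigmoid(ad_dense(ad_relu(g), pn[[paste0(name, ".ca2.w")]],
                           pn[[paste0(name, ".ca2.b")]]))
  chan <- ad_scale_channel(x, g)
  s <- ad_sigmoid(ad_conv(ad_channel_meanmax(x), pn[[paste0(name, ".sa.w")]],
                          pn[[paste0(name, ".sa.b")]], 1L, 3L))
  spat <- ad_scale_spatial(x, s)
  ad_add(chan, spat)
}

# Returns list(probs = node, bottleneck = node); x in [0, 1]
fw_segmenter <- function(net, pn, x) {
  s0 <- blk(x, pn, "stem", 1L, 1L)
  e <- list(); h <- s0
  for (i in 1:4) {
    h <- blk(h, pn, paste0("e", i, "a"), 2L, 1L)
    h <- blk(h, pn, paste0("e", i, "b"), 1L, 1L)
    e[[i]] <- h
  }
  skips <- list(e[[3]], e[[2]], e[[1]], s0)
  for (i in 1:4) {
    h <- ad_concat_c(ad_upsample2(h), skips[[i]])
    h <- blk(h, pn, paste0("f", i), 1L, 1L)
    h <- fw_attention(h, pn, paste0("att", i))
  }
  probs <- ad_sigmoid(ad_conv(h, pn$head.w, pn$head.b, 1L, 0L))
  list(probs = probs, bottleneck = e[[4]])
}

#' Segment an image into a nodule probability map
#'
#' @param f A segmenter network.
#' @param image Matrix (or batch array) in `[0, 1]`; spatial size must be
#'   divisible by 16.
#' @return Probability map(s) in `(0, 1)`, same spatial shape; binarize with
#'   [binarize()] for a mask.
#' @export
segment_probs <- function(f, image) {
  stopifnot(inherits(f, "segmenter"))
  assert_image01(image)
  x <- as_nhwc(image)
  check_div(x, 16L, "segment_probs")
  y <- fw_segmenter(f, net_nodes(f), ad_leaf(x))$probs$value
  as_image_out(y, image)
}

#' Deepest encoder feature map of a segmenter
#'
#' The latent code used for feature-level adversarial alignment: the output
#' of the last (stride-16) encoder stage.
#'
#' @inheritParams segment_probs
#' @return A `[H/16, W/16, C, N]` feature array.
#' @export
encode_bottleneck <- function(f, image) {
  stopifnot(inherits(f, "segmenter"))
  assert_image01(image)
  x <- as_nhwc(image)
  check_div(x, 16L, "encode_bottleneck")
  fw_segmenter(f, net_nodes(f), ad_leaf(x))$bottleneck$value
}

## ---- discriminators ---------------------------------------------------------

#' Create a patch-level pixel discriminator
#'
#' Three stride-2 convolution stages followed by a 1-channel scoring
#' convolution with sigmoid: a 64x64 image yields an 8x8 map of patch
#' realness scores in (0, 1).
#'
#' @param width Base channel width.
#' @param seed Seed for weight initialization.
#' @return A network object of kind `"pixel_discriminator"`.
#' @export
pixel_discriminator_new <- function(width = 16L, seed = 1L) {
  w <- as.integer(width)
  pp <- new.env(); pp$p <- list()
  with_seed(seed, {
    decl_conv(pp, "c1", 4L, 1L, w, norm = FALSE)
    decl_conv(pp, "c2", 4L, w, 2L * w)
    decl_conv(pp, "c3", 4L, 2L * w, 4L * w)
    decl_conv(pp, "out", 3L, 4L * w, 1L, norm = FALSE)
  })
  structure(list(kind = "pixel_discriminator", arch = list(width = w),
                 params = pp$p),
            class = c("symsegda_net", "pixel_discriminator"))
}

fw_pixel_disc <- function(net, pn, x) {
  h <- ad_lrelu(ad_conv(x, pn$c1.w, pn$c1.b, 2L, 1L))
  h <- ad_lrelu(ad_instnorm(ad_conv(h, pn$c2.w, pn$c2.b, 2L, 1L),
                            pn$c2.g, pn$c2.be))
  h <- ad_lrelu(ad_instnorm(ad_conv(h, pn$c3.w, pn$c3.b, 2L, 1L),
                            pn$c3.g, pn$c3.be))
  ad_sigmoid(ad_conv(h, pn$out.w, pn$out.b, 1L, 1L))
}

#' Create a feature-level discriminator
#'
#' A 3-layer strided convolutional classifier on segmenter bottleneck feature
#' maps; outputs patch realness scores in (0, 1).
#'
#' @param in_channels Number of channels of the bottleneck features.
#' @param width Base channel width.
#' @param seed Seed for weight initialization.
#' @return A network object of kind `"feature_discriminator"`.
#' @export
feature_discriminator_new <- function(in_channels, width = 32L, seed = 1L) {
  w <- as.integer(width)
  pp <- new.env(); pp$p <- list()
  with_seed(seed, {
    decl_conv(pp, "c1", 3L, as.integer(in_channels), w, norm = FALSE)
    decl_conv(pp, "c2", 3L, w, 2L * w, norm = FALSE)
    decl_conv(pp, "out", 1L, 2L * w, 1L, norm = FALSE)
  })
  structure(list(kind = "feature_discriminator",
                 arch = list(in_channels = as.integer(in_channels),
                             width = w),
                 params = pp$p),
            class = c("symsegda_net", "feature_discriminator"))
}

fw_feature_disc <- function(net, pn, x) {
  h <- ad_lrelu(ad_conv(x, pn$c1.w, pn$c1.b, 2L, 1L))
  h <- ad_lrelu(ad_conv(h, pn$c2.w, pn$c2.b, 2L, 1L))
  ad_sigmoid(ad_conv(h, pn$out.w, pn$out.b, 1L, 0L))
}

#' Apply a pixel-level discriminator to an image
#' @param d A pixel discriminator.
#' @param image Image(s) in `[0, 1]`.
#' @return Patch score map(s) with values in (0, 1).
#' @export
discriminate_pixel <- function(d, image) {
  stopifnot(inherits(d, "pixel_discriminator"))
  x <- as_nhwc(image)
  check_div(x, 8L, "discriminate_pixel")
  fw_pixel_disc(d, net_nodes(d), ad_leaf(x))$value
}

#' Apply a feature-level discriminator to bottleneck features
#' @param d A feature discriminator.
#' @param features A `[h, w, C, N]` feature array with `C` matching the
#'   discriminator's `in_channels`.
#' @return Score map(s) with values in (0, 1).
#' @export
discriminate_feature <- function(d, features) {
  stopifnot(inherits(d, "feature_discriminator"))
  x <- as_nhwc(features)
  if (dim(x)[3] != d$arch$in_channels)
    stop_sym("feature discriminator expects ", d$arch$in_channels,
             " channels, got ", dim(x)[3])
  fw_feature_disc(d, net_nodes(d), ad_leaf(x))$value
}

## ---- model bundle -----------------------------------------------------------

#' Create the full model bundle
#'
#' Builds the eight networks of the framework: translators `g_st`
#' (source-to-target) and `g_ts`, symmetric segmenters `f_s` and `f_t`
#' (identical constructors, independent parameters), and the four
#' discriminators (`d_s_pix`, `d_t_pix`, `d_s_feat`, `d_t_feat`).
#'
#' @param scale `"tiny"` (desk scale, default) or `"clinical"` (full-size
#'   widths and 8 residual blocks).
#' @param seed Seed; each network derives its own initialization stream.
#' @param trans_width,n_res,seg_width,disc_width Optional width overrides.
#' @return An object of class `model_bundle`.
#' @export
model_bundle_new <- function(scale = c("tiny", "clinical"), seed = 1L,
                             trans_width = NULL, n_res = NULL,
                             seg_width = NULL, disc_width = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "tiny")
    list(trans_width = 8L, n_res = 2L, seg_width = 8L, disc_width = 16L)
  else
    list(trans_width = 64L, n_res = 8L, seg_width = 32L, disc_width = 64L)
  cfg <- list(scale = scale,
              trans_width = as.integer(trans_width %||% def$trans_width),
              n_res = as.integer(n_res %||% def$n_res),
              seg_width = as.integer(seg_width %||% def$seg_width),
              disc_width = as.integer(disc_width %||% def$disc_width))
  bott <- 8L * cfg$seg_width
  s <- function(tag) derive_seed(seed, tag)
  structure(list(
    config = cfg,
    g_st = translator_new(cfg$trans_width, cfg$n_res, s("g_st")),
    g_ts = translator_new(cfg$trans_width, cfg$n_res, s("g_ts")),
    f_s = segmenter_new(cfg$seg_width, seed = s("f_s")),
    f_t = segmenter_new(cfg$seg_width, seed = s("f_t")),
    d_s_pix = pixel_discriminator_new(cfg$disc_width, s("d_s_pix")),
    d_t_pix = pixel_discriminator_new(cfg$disc_width, s("d_t_pix")),
    d_s_feat = feature_discriminator_new(bott, cfg$disc_width, s("d_s_feat")),
    d_t_feat = feature_discriminator_new(bott, cfg$disc_width, s("d_t_feat"))),
    class = "model_bundle")
}

bundle_net_names <- function() c("g_st", "g_ts", "f_s", "f_t", "d_s_pix",
                                 "d_t_pix", "d_s_feat", "d_t_feat")

#' Save a model bundle checkpoint
#' @param bundle A `model_bundle`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model bundle checkpoint
#'
#' Refuses to load when `expected_config` (e.g. the config of the bundle the
#' parameters are destined for) does not match the stored architecture.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param expected_config Optional config list to validate against.
#' @return A `model_bundle`.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle"))
    stop_sym("file is not a model bundle checkpoint")
  if (!is.null(expected_config) && !identical(bundle$config, expected_config))
    stop_sym("checkpoint architecture mismatch: stored config differs from ",
             "the expected one")
  bundle
}
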