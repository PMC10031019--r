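test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(image_size = 8), "image_size")
  expect_error(phantom_config(nodule_contrast = 1.2), "nodule_contrast")
  expect_error(phantom_config(nodule_radius = c(0.3, 0.2)), "min <= max")
  expect_error(phantom_config(nodule_radius = c(0.2, 0.6)), "image bounds")
  expect_error(phantom_config(speckle_shape = 0), "speckle_shape")
})

test_that("generate_anatomy is deterministic, hypoechoic, and area-correct", {
  cfg <- tiny_config()
  a <- generate_anatomy(cfg, seed = 7)
  b <- generate_anatomy(cfg, seed = 7)
  expect_identical(a, b)
  expect_identical(dim(a$image), dim(a$mask))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_lt(mean(a$image[a$mask == 1]), mean(a$image[a$mask == 0]))

  # zero-contrast nodules are invisible
  c0 <- phantom_config(image_size = 64, nodule_contrast = 0)
  z <- generate_anatomy(c0, seed = 3)
  expect_lt(abs(mean(z$image[z$mask == 1]) - mean(z$image[z$mask == 0])), 0.01)

  # single circular nodule of radius 0.2: mask area ~ pi * (0.2 * S)^2
  cc <- phantom_config(image_size = 128, nodules_per_image = c(1, 1),
                       nodule_radius = c(0.2, 0.2),
                       boundary_irregularity = 0)
  areas <- vapply(1:10, function(s) sum(generate_anatomy(cc, s)$mask),
                  numeric(1))
  expected <- pi * (0.2 * 128)^2
  expect_true(all(abs(areas - expected) / expected < 0.2))
})

test_that("apply_speckle is multiplicative, unit-mean, and has a clean limit", {
  img <- matrix(0.5, 100, 100)
  noisy <- apply_speckle(img, 6, seed = 1)
  expect_identical(dim(noisy), dim(img))
  # unit-mean noise: Monte-Carlo mean of output/input near 1
  expect_true(mean(noisy / img) > 0.97 && mean(noisy / img) < 1.03)
  # noise-free limit
  clean <- apply_speckle(img, 1e7, seed = 1)
  expect_lt(max(abs(clean - img)), 0.01)
  # multiplicative: zero input stays zero
  expect_true(all(apply_speckle(matrix(0, 10, 10), 4, 1) == 0))
  expect_error(apply_speckle(img, -1), "speckle_shape")
})

test_that("neutral style is the identity and inversion is an involution", {
  img <- generate_anatomy(tiny_config(), seed = 2)$image
  expect_equal(apply_domain_style(img, domain_style(), seed = 1), img)
  inv <- domain_style(invert = TRUE)
  twice <- apply_domain_style(apply_domain_style(img, inv, 1), inv, 1)
  expect_equal(twice, img, tolerance = 1e-12)
  # gamma 2 on constant 0.5 image -> 0.25 pointwise
  half <- matrix(0.5, 32, 32)
  expect_equal(apply_domain_style(half, domain_style(gamma = 2), 1),
               matrix(0.25, 32, 32))
})

test_that("domain_style rejects out-of-range parameters", {
  expect_error(domain_style(gamma = -1), "gamma")
  expect_error(domain_style(brightness_shift = 0.5), "brightness_shift")
  expect_error(domain_style(blur_sigma = -0.1), "blur_sigma")
})

test_that("generate_domain_dataset splits, masks and reproduces exactly", {
  cfg <- tiny_config()
  ds <- generate_domain_dataset(cfg, style_preset("site_a"), 10,
                                test_fraction = 0.2, seed = 5)
  expect_s3_class(ds, "domain_dataset")
  expect_length(ds$samples, 10)
  expect_identical(sum(ds$split == "test"), 2L)
  expect_identical(sum(ds$split == "train"), 8L)
  # every sample has a mask of matching shape
  for (s in ds$samples) {
    expect_false(is.null(s$mask))
    expect_identical(dim(s$mask), dim(s$image))
  }
  ds2 <- generate_domain_dataset(cfg, style_preset("site_a"), 10,
                                 test_fraction = 0.2, seed = 5)
  expect_identical(ds, ds2)
  # explicit test counts and error cases
  expect_error(generate_domain_dataset(cfg, domain_style(), 5,
                                       test_count = 5), "smaller than n")
  expect_error(generate_domain_dataset(cfg, domain_style(), 1), "at least 2")
})

test_that("hypoechogenicity holds across generated samples", {
  cfg <- phantom_config(image_size = 64, nodule_contrast = 0.3)
  ds <- generate_domain_dataset(cfg, domain_style(), 30, test_count = 2,
                                seed = 9)
  darker <- vapply(ds$samples, function(s) {
    mean(s$image[s$mask == 1]) < mean(s$image[s$mask == 0])
  }, logical(1))
  expect_gte(mean(darker), 0.99)
})

test_that("distinct styles produce a measurable pixel-distribution gap", {
  cfg <- tiny_config()
  n <- 12
  pool <- function(style, seed) {
    ds <- generate_domain_dataset(cfg, style, n, test_count = 2, seed = seed)
    unlist(dataset_images <- lapply(ds$samples, `[[`, "image"))
  }
  a1 <- pool(style_preset("site_a"), 1)
  a2 <- pool(style_preset("site_a"), 2)
  b <- pool(style_preset("site_inverted"), 3)
  ks_same <- stats::ks.test(a1, a2)$statistic
  ks_diff <- stats::ks.test(a1, b)$statistic
  expect_gt(ks_diff, ks_same)
})
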