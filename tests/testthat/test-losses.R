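test_that("soft Dice loss: fixed points, closed form, symmetry", {
  m <- rand_mask(16, 0.4, 1)
  expect_lt(soft_dice_loss(m, m, eps = 1), 1e-3)
  # all-ones vs all-zeros on 16x16, eps = 1: 1 - 1/257
  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  expect_equal(soft_dice_loss(ones, zeros, eps = 1), 1 - 1 / 257,
               tolerance = 1e-12)
  for (i in 1:5) {
    a <- withr_seed(i, matrix(runif(64), 8, 8))
    b <- withr_seed(100 + i, matrix(runif(64), 8, 8))
    expect_equal(soft_dice_loss(a, b), soft_dice_loss(b, a))
    expect_gte(soft_dice_loss(a, b), 0)
    expect_lt(soft_dice_loss(a, b), 1)
  }
  expect_error(soft_dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(soft_dice_loss(m, m, eps = 0), "eps")
})

test_that("adversarial losses reproduce chance-level closed forms", {
  half <- matrix(0.5, 8, 8)
  expect_equal(adv_loss_source(half, half, half, half), 4 * log(2),
               tolerance = 1e-6)
  expect_equal(adv_loss_target(half, half, half, half), 4 * log(2),
               tolerance = 1e-6)
  expect_equal(generator_adv_loss(half, half), 2 * log(2), tolerance = 1e-6)
  # perfect-discriminator limit
  hi <- matrix(1 - 1e-9, 4, 4); lo <- matrix(1e-9, 4, 4)
  expect_lt(adv_loss_source(hi, lo, hi, lo), 1e-5)
  expect_lt(generator_adv_loss(hi, hi), 1e-5)
  expect_error(adv_loss_source(half, half, half, matrix(1.5, 2, 2)),
               "scores")
})

test_that("discriminator loss is monotone in real and fake scores", {
  base <- matrix(0.5, 4, 4)
  at <- function(r, f) adv_loss_source(r, f, base, base)
  lo <- matrix(0.3, 4, 4); hi <- matrix(0.7, 4, 4)
  expect_gt(at(lo, base), at(hi, base))      # decreasing in real scores
  expect_lt(at(base, lo), at(base, hi))      # increasing in fake scores
  expect_gt(generator_adv_loss(lo, base), generator_adv_loss(hi, base))
})

test_that("cycle and identity losses: fixed points and L1 arithmetic", {
  x_s <- withr_seed(1, matrix(runif(256), 16, 16))
  x_t <- withr_seed(2, matrix(runif(256), 16, 16))
  expect_equal(cycle_loss(x_s, x_t, x_s, x_t), 0)
  expect_equal(identity_loss(x_s, x_t, x_s, x_t), 0)
  expect_equal(cycle_loss(x_s, x_t, x_s + 0.1, x_t), 0.1, tolerance = 1e-12)
  # permutation invariance: L1 is pointwise
  p <- withr_seed(3, sample(256))
  perm <- function(m) matrix(as.vector(m)[p], 16, 16)
  expect_equal(cycle_loss(x_s, x_t, x_s + 0.1, x_t),
               cycle_loss(perm(x_s), perm(x_t), perm(x_s + 0.1), perm(x_t)))
  # identity translator G_TS = 1 - x on a constant 0.25 image;
  # the loss sums both directions, so the value is |1 - 2*0.25| = 0.5
  quarter <- matrix(0.25, 16, 16)
  expect_equal(identity_loss(quarter, x_t, 1 - quarter, x_t), 0.5)
  expect_gte(identity_loss(x_s, x_t, x_t, x_s), 0)
  expect_error(cycle_loss(x_s, x_t, matrix(0, 2, 2), x_t), "shape")
})

test_that("supervised segmentation loss is the sum of two Dice losses", {
  gt <- rand_mask(16, 0.4, 7)
  p1 <- withr_seed(4, matrix(runif(256), 16, 16))
  p2 <- withr_seed(5, matrix(runif(256), 16, 16))
  expect_equal(seg_supervised_loss(p1, p2, gt),
               soft_dice_loss(p1, gt) + soft_dice_loss(p2, gt))
  expect_lt(seg_supervised_loss(gt, gt, gt), 2e-3)
  # one branch perfect, the other fully wrong
  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  expect_equal(seg_supervised_loss(ones, ones, zeros),
               2 * (1 - 1 / 257), tolerance = 1e-9)
  expect_error(seg_supervised_loss(p1, p2, NULL), "labeled")
})

test_that("consistency loss mirrors Dice symmetry and fixed point", {
  p <- withr_seed(6, matrix(runif(256), 16, 16))
  q <- withr_seed(7, matrix(runif(256), 16, 16))
  # soft Dice self-distance vanishes only for confident (near-binary) maps
  conf <- rand_mask(16, 0.4, 8)
  expect_lt(consistency_loss(conf, conf), 1e-3)
  expect_equal(consistency_loss(p, q), consistency_loss(q, p))
  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  expect_equal(consistency_loss(ones, zeros), 1 - 1 / 257, tolerance = 1e-12)
})

test_that("total loss decomposes linearly with the published weights", {
  w <- loss_weights()
  expect_equal(unlist(w[c("lambda_adv", "lambda_cycle", "lambda_iden",
                          "lambda_seg", "lambda_consis")], use.names = FALSE),
               c(1, 1, 1, 10, 2))
  rep1 <- total_loss(1, 1, 1, 1, 1, 1, w)
  expect_equal(rep1$total, 16)
  # weighted-sum decomposition reproduced from the report itself
  expect_equal(rep1$total,
               w$lambda_adv * (rep1$adv_s + rep1$adv_t) +
                 w$lambda_cycle * rep1$cycle + w$lambda_iden * rep1$iden +
                 w$lambda_seg * rep1$seg + w$lambda_consis * rep1$consis)
  w0 <- loss_weights(0, 0, 0, 0, 0)
  expect_equal(total_loss(1, 2, 3, 4, 5, 6, w0)$total, 0)
  w2 <- loss_weights(2, 2, 2, 20, 4)
  expect_equal(total_loss(1, 1, 1, 1, 1, 1, w2)$total, 32)
  expect_error(total_loss(NaN, 0, 0, 0, 0, 0, w), "adv_s")
  expect_error(loss_weights(lambda_seg = -1), "weights")
})
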