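# Shared fixtures and small oracles.  Everything is generated in code; no
# binary fixtures on disk.

tiny_config <- function(...) phantom_config(image_size = 64L, ...)

rand_mask <- function(n = 16, p = 0.3, seed = 1) {
  withr_seed(seed, matrix(rbinom(n * n, 1, p), n, n))
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force per-pixel confusion oracle (independent of confusion_counts)
brute_confusion <- function(pred, gt) {
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == 1; g <- gt[i, j] == 1
    if (p && g) tp <- tp + 1L
    else if (!p && !g) tn <- tn + 1L
    else if (p && !g) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Flat-field hash of all parameters of a bundle, for stage-isolation checks
param_hash <- function(net) digest::digest(net$params)

# Small two-domain dataset pair for training smoke tests
tiny_pair <- function(n = 12, image_size = 32, seed = 42,
                      styleS = domain_style(gamma = 0.7),
                      styleT = domain_style(gamma = 1.5)) {
  pc <- phantom_config(image_size = image_size)
  list(source = generate_domain_dataset(pc, styleS, n, test_count = 2,
                                        seed = seed, domain = "source"),
       target = generate_domain_dataset(pc, styleT, n, test_count = 2,
                                        seed = seed + 1, domain = "target"))
}

micro_schedule <- function(...) {
  stage_schedule(stage1 = list(epochs = 1L, lr_translation = 1e-3,
                               lr_discriminator = 2e-4),
                 stage2 = list(epochs = 1L, lr_segmentation = 2e-3),
                 stage3 = list(epochs = 1L, lr_all = 5e-4,
                               weights = loss_weights()),
                 batch_size = 4L, ...)
}
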