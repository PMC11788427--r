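tiny_cfg <- function(seed = 7L, ...)
  model_config(h = 16L, n_layers = 2L, n_heads = 2L,
               max_transcript_length = 256L, seed = seed, ...)

test_that("count normalization: max-scaling, length fractions, empty input", {
  m <- read_count_matrix("t", 3L, pos = c(0L, 0L, 1L),
                         read_length = c(28L, 30L, 28L), count = c(3L, 1L, 4L))
  # raw counts per position: [4, 4, 0] -> c = [1, 1, 0]
  inp <- normalize_counts(m)
  expect_equal(inp$c, c(1, 1, 0))
  expect_equal(inp$l[1, 28 - 20 + 1], 0.75)
  expect_equal(inp$l[1, 30 - 20 + 1], 0.25)
  expect_equal(sum(inp$l[1, ]), 1)
  expect_equal(sum(inp$l[3, ]), 0)
  m2 <- read_count_matrix("t", 3L, pos = c(0L, 1L),
                          read_length = c(28L, 28L), count = c(2L, 4L))
  expect_equal(normalize_counts(m2)$c, c(0.5, 1, 0))
  # empty transcript is still valid model input
  m0 <- read_count_matrix("t", 5L)
  inp0 <- normalize_counts(m0)
  expect_equal(inp0$c, rep(0, 5))
  expect_true(all(inp0$l == 0))
  model <- new_model(tiny_cfg())
  ps <- score_transcript(model, m0)
  expect_length(ps$scores, 5L)
})

test_that("position embedding: one-hot selection, linearity, bound in c", {
  p <- init_params(tiny_cfg())
  one26 <- numeric(21); one26[26 - 20 + 1] <- 1
  expect_equal(embed_position(0, one26, p) - embed_position(0, numeric(21), p),
               unname(p$E[26 - 20 + 1, ]))
  one28 <- numeric(21); one28[9] <- 1
  one32 <- numeric(21); one32[13] <- 1
  mid <- 0.5 * one28 + 0.5 * one32
  expect_equal(embed_position(0.3, mid, p),
               0.5 * embed_position(0.3, one28, p) +
                 0.5 * embed_position(0.3, one32, p))
  # |e_c[j]| <= |e[j]| since |tanh| <= 1
  for (cc in c(0, 0.3, 1)) {
    ec <- embed_position(cc, numeric(21), p)
    expect_true(all(abs(ec) <= abs(p$e) + 1e-12))
  }
  expect_error(embed_position(0.5, rep(0.5, 21), p), "sum 0 or 1")
  expect_error(embed_position(1.5, numeric(21), p), "in \\[0,1\\]")
})

test_that("forward pass is deterministic, in range, and full-receptive-field", {
  cfg <- tiny_cfg()
  model <- new_model(cfg)
  set.seed(3)
  L <- 200L
  m <- read_count_matrix("t", L, pos = sample(0:(L - 1), 50),
                         read_length = sample(26:32, 50, replace = TRUE),
                         count = sample(1:5, 50, replace = TRUE))
  s1 <- score_transcript(model, m)
  s2 <- score_transcript(model, m)
  expect_identical(s1$scores, s2$scores)
  expect_length(s1$scores, L)
  expect_true(all(s1$scores >= 0 & s1$scores <= 1))
  # perturbing position 1 changes the score at the last position
  m2 <- m
  m2$counts[1, 9] <- m2$counts[1, 9] + 50
  s3 <- score_transcript(model, m2)
  expect_gt(abs(s3$scores[L] - s1$scores[L]), 0)
})

test_that("overlong transcripts are chunked or rejected, never truncated", {
  cfg <- tiny_cfg(chunk_overlong = FALSE)
  model <- new_model(cfg)
  m <- read_count_matrix("t", 300L, pos = 0L, read_length = 28L, count = 1L)
  expect_error(score_transcript(model, m), "max_transcript_length")
  cfg2 <- tiny_cfg(chunk_overlong = TRUE, chunk_overlap = 32L)
  model2 <- new_model(cfg2)
  ps <- score_transcript(model2, m)
  expect_length(ps$scores, 300L)
  expect_true(all(ps$scores >= 0 & ps$scores <= 1))
})

test_that("kernel-approximate attention tracks exact attention on short input", {
  cfg <- tiny_cfg()
  model <- new_model(cfg)
  set.seed(13)
  devs <- c()
  for (rep in 1:3) {
    L <- 120L
    m <- read_count_matrix("t", L, pos = sample(0:(L - 1), 40),
                           read_length = sample(26:32, 40, replace = TRUE),
                           count = sample(1:6, 40, replace = TRUE))
    exact <- score_transcript(model, m)$scores
    mk <- model; mk$config$attention_kind <- "kernel-approximate"
    approx <- score_transcript(mk, m)$scores
    devs <- c(devs, abs(exact - approx))
  }
  expect_lt(max(devs), 0.2)    # configured agreement tolerance
  expect_lt(mean(devs), 0.05)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(h = 8L, n_layers = 2L, n_heads = 2L,
                      max_transcript_length = 32L, seed = 3L)
  p <- init_params(cfg, head_width = 2L)
  set.seed(21)
  L <- 12L
  cv <- runif(L)
  lm <- matrix(0, L, 21); for (i in 1:L) lm[i, sample(1:21, 1)] <- 1
  y <- matrix(rbinom(L * 2, 1, 0.3), L, 2)
  mask <- c(3L, 7L)
  lossf <- function(params)
    bce_loss(nn_forward(params, cfg, cv, lm, mask_idx = mask)$logits, y)$loss
  fw <- nn_forward(p, cfg, cv, lm, mask_idx = mask, want_cache = TRUE)
  gr <- nn_backward(p, cfg, fw$cache, bce_loss(fw$logits, y)$dlogits)
  eps <- 1e-6
  set.seed(9)
  for (nm in names(p)) {
    n <- length(p[[nm]])
    for (ii in if (n <= 2) seq_len(n) else sample(n, 2)) {
      pa <- p; pa[[nm]][ii] <- pa[[nm]][ii] + eps
      pb <- p; pb[[nm]][ii] <- pb[[nm]][ii] - eps
      num <- (lossf(pa) - lossf(pb)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("d/d %s[%d]", nm, ii))
    }
  }
})

test_that("predict_sample routes transcripts by test fold and covers all", {
  set.seed(51)
  ta <- tx_simple(random_seq(60), id = "ta", chrom = "A")
  tb <- tx_simple(random_seq(60), id = "tb", chrom = "B")
  ann <- ann_of(ta, tb)
  alloc <- allocate_folds(c("A", "B"), "custom", custom = list(
    list(train = character(), val = character(), test = "A"),
    list(train = character(), val = character(), test = "B")))
  m1 <- new_model(tiny_cfg(seed = 1L)); m2 <- new_model(tiny_cfg(seed = 2L))
  prof <- structure(list(sample_id = "s", matrices = list(), qc = list()),
                    class = "SampleProfile")
  sc <- predict_sample(prof, list(m1, m2), alloc, ann)
  expect_setequal(names(sc), c("ta", "tb"))
  expect_equal(sc[["ta"]]$fold_model, 1L)
  expect_equal(sc[["tb"]]$fold_model, 2L)
  # same models, same profile: identical outputs across runs
  sc2 <- predict_sample(prof, list(m1, m2), alloc, ann)
  expect_identical(sc[["ta"]]$scores, sc2[["ta"]]$scores)
  # scores differ between differently-initialized models
  expect_false(identical(sc[["ta"]]$scores, sc[["tb"]]$scores))
  tc <- tx_simple(random_seq(60), id = "tc", chrom = "C")
  expect_error(predict_sample(prof, list(m1, m2), alloc, ann_of(ta, tb, tc)),
               "neither test fold")
})

test_that("checkpoints round-trip and refuse bad versions", {
  dir <- withr::local_tempdir()
  model <- new_model(tiny_cfg())
  pth <- file.path(dir, "ck.rds")
  save_checkpoint(model, pth)
  back <- load_checkpoint(pth)
  expect_equal(back$params, model$params)
  bad <- model; bad$version <- "elsewhere-9"
  saveRDS(bad, pth)
  expect_error(load_checkpoint(pth), "incompatible")
})
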