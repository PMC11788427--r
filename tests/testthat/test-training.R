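test_that("the human fold scheme allocates chromosomes as expected", {
  chroms <- c(as.character(1:22), "X", "Y", "KI270728.1")
  alloc <- allocate_folds(chroms, "human")
  m1 <- alloc$models[[1]]; m2 <- alloc$models[[2]]
  expect_true("3" %in% m1$train_chromosomes)
  expect_true("3" %in% m2$test_chromosomes)
  expect_setequal(m1$train_chromosomes, c("3", "5", "7", "11", "13", "15",
                                          "19", "21", "X"))
  expect_setequal(m1$val_chromosomes, c("1", "9", "17"))
  expect_setequal(m2$train_chromosomes, c("2", "6", "8", "10", "14", "16",
                                          "18", "22", "Y"))
  expect_setequal(m2$val_chromosomes, c("4", "12", "20"))
  # a chr-1 transcript is scored by the model for which 1 is in the test set
  expect_true("1" %in% m2$test_chromosomes)
  expect_false("1" %in% m1$test_chromosomes)
  # unlisted scaffolds land in exactly one test set (model 1's)
  expect_true("KI270728.1" %in% m1$test_chromosomes)
  expect_false("KI270728.1" %in% m2$test_chromosomes)
  # disjointness + coverage
  expect_length(intersect(m1$test_chromosomes, m2$test_chromosomes), 0)
  expect_setequal(c(m1$test_chromosomes, m2$test_chromosomes), chroms)
})

test_that("custom allocations are validated", {
  ok <- allocate_folds(c("A", "B"), "custom", custom = list(
    list(train = "A", test = "B"), list(train = "B", test = "A")))
  expect_s3_class(ok, "FoldAllocation")
  expect_error(allocate_folds(c("A", "B"), "custom", custom = list(
    list(train = "A", test = "A"), list(train = "B", test = "A"))),
    "more than one|both test")
  expect_error(allocate_folds(c("A", "B"), "custom", custom = list(
    list(test = "A"), list(test = "A"))), "both test")
  expect_error(allocate_folds(c("A", "B", "C"), "custom", custom = list(
    list(test = "A"), list(test = "B"))), "neither test")
})

test_that("pretraining labels apply the read-presence threshold", {
  m <- read_count_matrix("t", 20L, pos = c(10L, 11L),
                         read_length = c(28L, 30L), count = c(3L, 1L))
  lab <- make_pretrain_labels(m)
  expect_equal(lab[11, 28 - 20 + 1], 1)
  expect_equal(lab[11, 30 - 20 + 1], 0)
  expect_equal(sum(lab[1, ]), 0)                 # empty position: all-zero
  lab2 <- make_pretrain_labels(m, read_presence_threshold = 2L)
  expect_equal(lab2[12, 30 - 20 + 1], 0)         # count 1 under threshold 2
  expect_equal(lab2[11, 28 - 20 + 1], 1)
})

test_that("masking selects the configured fraction deterministically", {
  m1 <- mask_positions(1000L, 0.15, seed = 42L)
  expect_equal(length(m1), 150L)
  expect_identical(m1, mask_positions(1000L, 0.15, seed = 42L))
  expect_false(identical(m1, mask_positions(1000L, 0.15, seed = 43L)))
})

test_that("masked positions carry no function of the true inputs", {
  cfg <- model_config(h = 16L, n_layers = 2L, n_heads = 2L,
                      max_transcript_length = 64L, seed = 5L)
  p <- init_params(cfg, head_width = 21L)
  set.seed(1)
  L <- 40L
  cv <- runif(L); lm <- matrix(0, L, 21)
  for (i in 1:L) lm[i, sample(1:21, 1)] <- 1
  mask <- c(5L, 17L, 30L)
  out1 <- nn_forward(p, cfg, cv, lm, mask_idx = mask)$logits
  cv2 <- cv; lm2 <- lm
  cv2[mask] <- runif(3)
  for (i in mask) { lm2[i, ] <- 0; lm2[i, sample(1:21, 1)] <- 1 }
  out2 <- nn_forward(p, cfg, cv2, lm2, mask_idx = mask)$logits
  expect_identical(out1, out2)
})

test_that("supervised training respects fold hygiene and early stopping", {
  run <- run_recovery(recovery_seeds[1])
  fit <- run$fit
  alloc <- run$alloc
  ann <- run$sim$annotation
  # audited id sets: no training transcript is ever scored by its own model
  for (m in 1:2) {
    train_ids <- fit$train_ids[[m]]
    test_chroms <- alloc$models[[m]]$test_chromosomes
    test_ids <- names(ann$transcripts)[
      vapply(ann$transcripts, function(t) t$chromosome %in% test_chroms,
             logical(1))]
    expect_length(intersect(train_ids, test_ids), 0)
    train_chroms <- unique(vapply(train_ids, function(id)
      ann$transcripts[[id]]$chromosome, character(1)))
    expect_true(all(train_chroms %in% alloc$models[[m]]$train_chromosomes))
  }
  # the two test folds partition the transcriptome
  sc <- run$scores
  expect_setequal(names(sc), names(ann$transcripts))
  folds <- vapply(sc, `[[`, integer(1), "fold_model")
  expect_setequal(unique(folds), 1:2)
  # early stopping returned the best-validation checkpoint within the cap
  expect_true(all(fit$best_epoch <= fit$epochs_run))
  expect_true(all(fit$epochs_run <= recovery_train_config(1L)$max_epochs))
})

test_that("zero positive labels in a fold is an error", {
  set.seed(71)
  lnc <- tx_simple(random_seq(60), id = "l1", chrom = "A", tags = "lncRNA")
  cod <- tx_simple(paste0(random_seq(12), "ATG", "AAA", "TAA", random_seq(12)),
                   id = "c1", chrom = "B",
                   cds = list(tis_index = 12L, stop_index = 18L))
  ann <- ann_of(lnc, cod)
  alloc <- allocate_folds(c("A", "B"), "custom", custom = list(
    list(train = "A", test = "B"), list(train = "B", test = "A")))
  prof <- structure(list(sample_id = "s", matrices = list(), qc = list()),
                    class = "SampleProfile")
  expect_error(
    train_supervised(prof, ann, alloc,
                     train_config(max_epochs = 1L),
                     model_config(h = 8L, n_layers = 1L, n_heads = 1L,
                                  max_transcript_length = 64L)),
    "zero annotated TISs")
})
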