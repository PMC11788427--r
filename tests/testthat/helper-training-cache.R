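# Heavy, shareable computations (simulations and trained fold models) are
# memoized per test run so several test files can reuse the same experiment
# without retraining.

.riboscope_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .riboscope_cache)) {
    assign(key, builder(), envir = .riboscope_cache)
  }
  get(key, envir = .riboscope_cache)
}

# the parameter-recovery study conditions: ~300 transcripts, coverage 2
# reads/nt, in-frame fidelity 0.6, HHT-like TIS enrichment x5; ncORF plant
# rates zero because the supervised labels are annotated TISs only. The
# robustness cells that sweep fidelity/depth use 200 transcripts each.
recovery_sim_config <- function(seed, in_frame_prob = 0.6, coverage = 2,
                                n_transcripts = 300L) {
  simulation_config(
    seed = seed, n_transcripts = n_transcripts, n_chromosomes = 4L,
    lncrna_fraction = 0,
    utr5_range = c(24L, 45L), cds_codon_range = c(25L, 55L),
    utr3_range = c(36L, 60L),
    ncorf_rates = c(uORF = 0, uoORF = 0, intORF = 0, dORF = 0, doORF = 0),
    coverage = coverage, in_frame_prob = in_frame_prob, tis_enrichment = 5,
    background_rate = 0.05)
}

recovery_folds <- function() {
  allocate_folds(paste0("chrS", 1:4), "custom", custom = list(
    list(train = "chrS1", val = "chrS2", test = c("chrS3", "chrS4")),
    list(train = "chrS3", val = "chrS4", test = c("chrS1", "chrS2"))))
}

recovery_model_config <- function() {
  model_config(h = 32L, n_layers = 4L, n_heads = 1L,
               max_transcript_length = 400L, attention_kind = "exact")
}

recovery_train_config <- function(seed) {
  train_config(max_epochs = 12L, patience = 2L, seed = seed,
               learning_rate = 1e-3, batch_size = 4L, lr_decay = 0.93)
}

# simulate + train the two fold models; returns everything downstream tests
# need (held-out scores and PR AUC, fold audit, history)
run_recovery <- function(seed, in_frame_prob = 0.6, coverage = 2,
                         init = NULL, n_transcripts = 300L) {
  key <- sprintf("recovery_%d_%s_%s_%d_%s", seed, in_frame_prob, coverage,
                 n_transcripts, if (is.null(init)) "scratch" else "pretrained")
  cache_get(key, function() {
    scfg <- recovery_sim_config(seed, in_frame_prob, coverage, n_transcripts)
    sim <- cache_get(sprintf("sim_%d_%s_%s_%d", seed, in_frame_prob, coverage,
                             n_transcripts),
                     function() {
                       s <- simulate_transcriptome(scfg)
                       r <- simulate_reads(s$annotation, s$truth, scfg)
                       list(sim = s, reads = r)
                     })
    alloc <- recovery_folds()
    fit <- train_supervised(sim$reads$profile, sim$sim$annotation, alloc,
                            recovery_train_config(seed),
                            recovery_model_config(), init = init)
    scores <- predict_sample(sim$reads$profile,
                             list(fit$model1, fit$model2), alloc,
                             sim$sim$annotation)
    s <- c(); y <- c()
    for (id in names(scores)) {
      t <- sim$sim$annotation$transcripts[[id]]
      lab <- numeric(nchar(t$sequence))
      if (!is.null(t$cds)) lab[t$cds$tis_index + 1L] <- 1
      s <- c(s, scores[[id]]$scores); y <- c(y, lab)
    }
    list(fit = fit, scores = scores, heldout_pr = pr_auc(s, y),
         heldout_roc = roc_auc(s, y), sim = sim$sim, profile = sim$reads$profile,
         alloc = alloc)
  })
}

recovery_seeds <- c(101L, 202L, 303L)

# robustness cells (fidelity/depth sweeps) at the smaller desk-scale size
run_robustness <- function(seed, in_frame_prob = 0.6, coverage = 2) {
  run_recovery(seed, in_frame_prob, coverage, n_transcripts = 200L)
}
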