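# Pipeline orchestration: one entry point over the stages, driven by a YAML
# config, with deterministic seed fan-out and a run manifest.

sort_rec <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sort_rec)
  } else x
}

config_hash <- function(config) rlang::hash(sort_rec(config))

PIPELINE_SUBCOMMANDS <- c("simulate", "ingest", "pretrain", "finetune",
                          "predict", "call", "annotate", "benchmark",
                          "quantify")

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

validate_run_config <- function(config, subcommand) {
  if (!subcommand %in% PIPELINE_SUBCOMMANDS)
    stop("unknown subcommand: ", subcommand)
  blk <- config[[subcommand]] %||% list()
  thr <- blk$threshold
  if (!is.null(thr) && (thr < 0 || thr > 1))
    stop("invalid threshold: ", thr, " (must be in [0,1])")
  for (f in c("gtf", "fasta", "alignments", "profile", "scores", "library")) {
    pth <- blk[[f]]
    if (!is.null(pth) && !file.exists(pth))
      stop("input path does not exist: ", pth, " (", subcommand, "$", f, ")")
  }
  invisible(TRUE)
}

write_manifest <- function(out_dir, subcommand, config, outputs) {
  manifest <- list(subcommand = subcommand,
                   config_hash = config_hash(config),
                   outputs = outputs,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("riboscope")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (synthetic transcriptome + reads), `ingest`
#' (SAM/BAM to profile), `pretrain`, `finetune`, `predict`, `call`,
#' `annotate`, `benchmark`, `quantify`. Each stage reads its block of the
#' config, writes its artifacts plus a `manifest.json` (config hash stable
#' under key reordering, outputs, versions) into `out_dir`, and derives its
#' RNG seed from the global seed so stages are independently reproducible.
#'
#' @param subcommand One of the stage names.
#' @param config A YAML path or config list. Recognized top-level keys:
#'   `seed`, plus one block per subcommand.
#' @param out_dir Output directory.
#' @param seed Overrides `config$seed`.
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(subcommand, config, out_dir = ".", seed = NULL) {
  config <- read_run_config(config)
  validate_run_config(config, subcommand)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  blk <- config[[subcommand]] %||% list()
  outputs <- list()

  load_ann <- function(b) load_annotation(b$gtf, b$fasta)

  if (subcommand == "simulate") {
    sargs <- blk; sargs$seed <- derive_seed(seed, "simulate")
    scfg <- do.call(simulation_config, sargs)
    sim <- simulate_transcriptome(scfg)
    paths <- write_simulation(sim, out_dir)
    sam <- file.path(out_dir, "reads.sam")
    simulate_reads(sim$annotation, sim$truth, scfg, sam_path = sam)
    outputs <- c(as.list(paths), list(sam = sam))
  } else if (subcommand == "ingest") {
    ann <- load_ann(blk)
    prof <- ingest_alignments(blk$alignments, ann,
                              length_min = blk$length_min %||% RL_MIN,
                              length_max = blk$length_max %||% RL_MAX)
    pdir <- file.path(out_dir, "profile")
    write_sample_profile(prof, pdir)
    qc <- file.path(out_dir, "qc_summary.tsv")
    write.table(data.frame(sample_id = prof$sample_id,
                           mapped_reads = prof$qc$mapped_reads,
                           in_frame_occupancy = prof$qc$in_frame_occupancy),
                qc, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- list(profile = pdir, qc = qc)
  } else if (subcommand %in% c("pretrain", "finetune")) {
    ann <- load_ann(blk)
    prof <- read_sample_profile(blk$profile)
    alloc <- if (identical(blk$folds %||% "human", "human"))
      allocate_folds(ann$chromosomes, "human")
    else allocate_folds(ann$chromosomes, "custom", custom = blk$folds)
    tcfg <- do.call(train_config,
                    c(blk$train %||% list(), list(seed = derive_seed(seed, subcommand))))
    mcfg <- do.call(model_config, blk$model %||% list())
    if (subcommand == "pretrain") {
      ck <- pretrain(list(prof), ann, alloc, tcfg, mcfg)
      p1 <- file.path(out_dir, "pretrained_model1.rds")
      p2 <- file.path(out_dir, "pretrained_model2.rds")
      save_checkpoint(ck$model1, p1); save_checkpoint(ck$model2, p2)
      outputs <- list(model1 = p1, model2 = p2)
    } else {
      init <- if (!is.null(blk$init))
        list(load_checkpoint(blk$init[[1]]), load_checkpoint(blk$init[[2]]))
      else NULL
      fit <- train_supervised(list(prof), ann, alloc, tcfg, mcfg, init = init)
      p1 <- file.path(out_dir, "model1.rds"); p2 <- file.path(out_dir, "model2.rds")
      save_checkpoint(fit$model1, p1); save_checkpoint(fit$model2, p2)
      lg <- file.path(out_dir, "training_log.tsv")
      write_training_log(fit, lg)
      outputs <- list(model1 = p1, model2 = p2, log = lg)
    }
  } else if (subcommand == "predict") {
    ann <- load_ann(blk)
    prof <- read_sample_profile(blk$profile)
    models <- list(load_checkpoint(blk$models[[1]]), load_checkpoint(blk$models[[2]]))
    alloc <- if (identical(blk$folds %||% "human", "human"))
      allocate_folds(ann$chromosomes, "human")
    else allocate_folds(ann$chromosomes, "custom", custom = blk$folds)
    scores <- predict_sample(prof, models, alloc, ann)
    sp <- file.path(out_dir, "scores.tsv")
    write_scores(scores, sp)
    outputs <- list(scores = sp)
  } else if (subcommand == "call") {
    ann <- load_ann(blk)
    scores <- read_scores(blk$scores)
    calls <- call_orfs(scores, ann, threshold = blk$threshold %||% 0.15)
    calls <- annotate_calls(calls, ann)
    tsv <- file.path(out_dir, "calls.tsv"); bed <- file.path(out_dir, "calls.bed")
    write_calls(calls, ann, tsv_path = tsv, bed_path = bed)
    outputs <- list(calls = tsv, bed = bed)
  } else if (subcommand == "annotate") {
    ann <- load_ann(blk)
    calls <- read.table(blk$calls, header = TRUE, sep = "\t")
    calls <- annotate_calls(calls, ann)
    tsv <- file.path(out_dir, "annotated_calls.tsv")
    write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    cnt <- file.path(out_dir, "orf_type_counts.tsv")
    write.table(orf_type_counts(calls), cnt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <- list(calls = tsv, counts = cnt)
  } else if (subcommand == "benchmark") {
    scores <- read_scores(blk$scores)
    lib <- read_orf_library(blk$library)
    res <- benchmark_library(scores, lib)
    bp <- file.path(out_dir, "benchmark.tsv")
    write.table(data.frame(library = lib$provenance, roc_auc = res$roc_auc,
                           pr_auc = res$pr_auc),
                bp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- list(benchmark = bp)
  } else if (subcommand == "quantify") {
    calls <- read.table(blk$calls, header = TRUE, sep = "\t")
    profs <- lapply(blk$profiles, read_sample_profile)
    tpm <- tpm_quantify(calls, profs)
    tp <- file.path(out_dir, "tpm.tsv")
    write.table(data.frame(orf = rownames(tpm), tpm, check.names = FALSE),
                tp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- list(tpm = tp)
  }

  write_manifest(out_dir, subcommand, config, outputs)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  invisible(outputs)
}

#' Write / read per-position scores as TSV
#'
#' Long format: transcript, position, score, transcript length.
#'
#' @param scores Named list of `PositionScores`.
#' @param path TSV path.
#' @return `path` invisibly (writer); named list of `PositionScores`
#'   (reader).
#' @export
write_scores <- function(scores, path) {
  dt <- data.table::rbindlist(lapply(scores, function(ps)
    data.table::data.table(transcript_id = ps$transcript_id,
                           pos = seq_along(ps$scores) - 1L,
                           score = ps$scores)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  out <- list()
  for (id in unique(dt$transcript_id)) {
    sub <- dt[dt$transcript_id == id, ]
    out[[id]] <- structure(list(transcript_id = id,
                                scores = sub$score[order(sub$pos)]),
                           class = "PositionScores")
  }
  out
}
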