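# Fold allocation, masked self-supervised pretraining, supervised TIS
# training / fine-tuning, and early stopping.

HUMAN_FOLDS <- list(
  model1 = list(train = c("3", "5", "7", "11", "13", "15", "19", "21", "X"),
                val = c("1", "9", "17"),
                test = c("2", "4", "6", "8", "10", "12", "14", "16", "18",
                         "20", "22", "Y")),
  model2 = list(train = c("2", "6", "8", "10", "14", "16", "18", "22", "Y"),
                val = c("4", "12", "20"),
                test = c("1", "3", "5", "7", "9", "11", "13", "15", "17",
                         "19", "21", "X")))

#' Allocate chromosomes to two training folds
#'
#' Two models are trained on non-overlapping chromosome folds; their test
#' sets are disjoint and jointly cover every chromosome, so combined
#' predictions span the transcriptome without leakage. The `human` scheme
#' is the standard human-chromosome allocation (model 1: train 3,5,7,11,13,15,19,21,X,
#' validate 1,9,17, test the even chromosomes plus Y; model 2 the
#' complement); unlisted scaffolds are joined to model 1's test set.
#'
#' @param chromosomes Character vector of chromosome names present in the
#'   annotation (a `"chr"` prefix is tolerated for the human scheme).
#' @param scheme `"human"` (built-in human-chromosome allocation) or
#'   `"custom"`.
#' @param custom For `scheme="custom"`: a list of two lists, each with
#'   `train`, `val`, `test` character vectors.
#' @return A `FoldAllocation`.
#' @export
allocate_folds <- function(chromosomes, scheme = c("human", "custom"),
                           custom = NULL) {
  scheme <- match.arg(scheme)
  chromosomes <- unique(as.character(chromosomes))
  if (scheme == "human") {
    base_name <- sub("^chr", "", chromosomes)
    pick <- function(set) chromosomes[base_name %in% set]
    listed <- unlist(HUMAN_FOLDS, use.names = FALSE)
    scaffolds <- chromosomes[!base_name %in% listed]
    models <- list(
      model1 = list(train_chromosomes = pick(HUMAN_FOLDS$model1$train),
                    val_chromosomes = pick(HUMAN_FOLDS$model1$val),
                    test_chromosomes = c(pick(HUMAN_FOLDS$model1$test), scaffolds)),
      model2 = list(train_chromosomes = pick(HUMAN_FOLDS$model2$train),
                    val_chromosomes = pick(HUMAN_FOLDS$model2$val),
                    test_chromosomes = pick(HUMAN_FOLDS$model2$test)))
  } else {
    if (is.null(custom) || length(custom) != 2L)
      stop("scheme='custom' requires a list of two train/val/test lists")
    models <- lapply(custom, function(m)
      list(train_chromosomes = as.character(m$train %||% character()),
           val_chromosomes = as.character(m$val %||% character()),
           test_chromosomes = as.character(m$test %||% character())))
    names(models) <- c("model1", "model2")
  }
  for (i in 1:2) {
    m <- models[[i]]
    ov <- c(intersect(m$train_chromosomes, m$val_chromosomes),
            intersect(m$train_chromosomes, m$test_chromosomes),
            intersect(m$val_chromosomes, m$test_chromosomes))
    if (length(ov))
      stop(sprintf("model %d: chromosome(s) %s in more than one of train/val/test",
                   i, paste(unique(ov), collapse = ",")))
  }
  dup <- intersect(models[[1]]$test_chromosomes, models[[2]]$test_chromosomes)
  if (length(dup))
    stop("chromosome(s) in both test sets: ", paste(dup, collapse = ","))
  uncovered <- setdiff(chromosomes,
                       c(models[[1]]$test_chromosomes, models[[2]]$test_chromosomes))
  if (length(uncovered))
    stop("chromosome(s) in neither test set: ", paste(uncovered, collapse = ","))
  structure(list(models = models), class = "FoldAllocation")
}

#' @export
print.FoldAllocation <- function(x, ...) {
  for (i in 1:2) {
    m <- x$models[[i]]
    cat(sprintf("model %d: train {%s} val {%s} test {%s}\n", i,
                paste(m$train_chromosomes, collapse = ","),
                paste(m$val_chromosomes, collapse = ","),
                paste(m$test_chromosomes, collapse = ",")))
  }
  invisible(x)
}

#' Read-presence labels for masked pretraining
#'
#' `label[pos, len] = 1` iff at least `read_presence_threshold` reads of
#' that length map to that position. The default threshold 1 reads the
#' underlying rule as "a read is present"; set 2 for the strictly-more-than-
#' one reading.
#'
#' @param matrix A `ReadCountMatrix`.
#' @param read_presence_threshold Minimum count for a positive label.
#' @return A binary L x 21 matrix.
#' @export
make_pretrain_labels <- function(matrix, read_presence_threshold = 1L) {
  (as.matrix(matrix$counts) >= read_presence_threshold) * 1
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Transcripts per optimizer step.
#' @param mask_fraction Fraction of positions masked during pretraining.
#' @param patience Epochs without validation-loss improvement before stop.
#' @param max_epochs Hard epoch cap.
#' @param seed Seed controlling shuffling and masking.
#' @param lr_decay Multiplicative per-epoch learning-rate decay.
#' @param pos_weight Positive-class weight for the TIS loss; `NULL` uses the
#'   per-batch negatives/positives ratio.
#' @param read_presence_threshold See [make_pretrain_labels()].
#' @return A `TrainConfig` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8L,
                         mask_fraction = 0.15, patience = 3L,
                         max_epochs = 25L, seed = 1L, lr_decay = 0.95,
                         pos_weight = NULL,
                         read_presence_threshold = 1L) {
  stopifnot(mask_fraction > 0, mask_fraction < 1, patience >= 1L)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 mask_fraction = mask_fraction, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 lr_decay = lr_decay, pos_weight = pos_weight,
                 read_presence_threshold = as.integer(read_presence_threshold)),
            class = "TrainConfig")
}

# transcripts of a profile that sit on the given chromosomes; includes
# read-free transcripts of the annotation (zero-input is valid model input)
fold_transcripts <- function(profiles, annotation, chroms) {
  ids <- names(annotation$transcripts)[
    vapply(annotation$transcripts, function(t) t$chromosome %in% chroms,
           logical(1))]
  out <- list()
  for (p in seq_along(profiles)) {
    for (id in ids) out[[length(out) + 1L]] <- list(profile = p, id = id)
  }
  out
}

get_inputs <- function(profiles, annotation, item) {
  t <- annotation$transcripts[[item$id]]
  m <- profiles[[item$profile]]$matrices[[item$id]]
  if (is.null(m)) {
    L <- transcript_length(t)
    list(c = numeric(L), l = matrix(0, L, N_RL), L = L, t = t)
  } else {
    inp <- normalize_counts(m)
    list(c = inp$c, l = as.matrix(inp$l), L = length(inp$c), t = t)
  }
}

add_grads <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

mask_positions <- function(L, fraction, seed) {
  set.seed(seed)
  n <- max(1L, round(fraction * L))
  sort(sample.int(L, n))
}

#' Masked self-supervised pretraining
#'
#' At each step a seeded random `mask_fraction` of positions per transcript
#' have their inputs replaced by a learned mask embedding; the model is
#' optimized to predict read presence per read length (21-wide head, binary
#' cross-entropy) at the masked positions only. One model is trained per
#' fold, using the identical chromosome allocation as supervised training.
#' Transcripts shorter than 7 nt are skipped with a log message.
#'
#' @param profiles List of `SampleProfile`s (the pretraining corpus).
#' @param annotation A `GenomeAnnotation`.
#' @param allocation A `FoldAllocation`.
#' @param config A [train_config()].
#' @param model_cfg A [model_config()].
#' @return List of two `riboscope_model` checkpoints (21-wide heads) with a
#'   `history` attribute per model.
#' @export
pretrain <- function(profiles, annotation, allocation, config,
                     model_cfg = model_config()) {
  if (inherits(profiles, "SampleProfile")) profiles <- list(profiles)
  out <- list()
  for (midx in 1:2) {
    alloc <- allocation$models[[midx]]
    items <- fold_transcripts(profiles, annotation, alloc$train_chromosomes)
    vitems <- fold_transcripts(profiles, annotation, alloc$val_chromosomes)
    short <- 0L
    keep_long <- function(its) Filter(function(it)
      transcript_length(annotation$transcripts[[it$id]]) >= 7L, its)
    n0 <- length(items); items <- keep_long(items); vitems <- keep_long(vitems)
    if (n0 > length(items))
      rs_log(sprintf("pretrain fold %d: skipped %d transcript(s) shorter than 7 nt",
                     midx, n0 - length(items)))
    mcfg <- model_cfg; mcfg$seed <- derive_seed(config$seed, sprintf("pre_m%d", midx))
    model <- new_model(mcfg, head_width = N_RL)
    st <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    history <- list()
    eval_val <- function(params) {
      tot <- 0; n <- 0
      for (vi in seq_along(vitems)) {
        inp <- get_inputs(profiles, annotation, vitems[[vi]])
        midr <- mask_positions(inp$L, config$mask_fraction,
                               derive_seed(config$seed, paste0("valmask", vi)))
        lab <- matrix(0, inp$L, N_RL)
        m <- profiles[[vitems[[vi]]$profile]]$matrices[[vitems[[vi]]$id]]
        if (!is.null(m)) lab <- make_pretrain_labels(m, config$read_presence_threshold)
        w <- matrix(0, inp$L, N_RL); w[midr, ] <- 1
        fw <- nn_forward(params, mcfg, inp$c, inp$l, mask_idx = midr)
        tot <- tot + bce_loss(fw$logits, lab, w)$loss; n <- n + 1L
      }
      if (n == 0L) NA_real_ else tot / n
    }
    for (epoch in seq_len(config$max_epochs)) {
      set.seed(derive_seed(config$seed, sprintf("pre_ep%d_m%d", epoch, midx)))
      ord <- sample(seq_along(items))
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        gacc <- NULL
        for (bi in batch) {
          it <- items[[bi]]
          inp <- get_inputs(profiles, annotation, it)
          midr <- mask_positions(inp$L, config$mask_fraction,
                                 derive_seed(config$seed,
                                             sprintf("mask_e%d_i%d", epoch, bi)))
          m <- profiles[[it$profile]]$matrices[[it$id]]
          lab <- if (is.null(m)) matrix(0, inp$L, N_RL) else
            make_pretrain_labels(m, config$read_presence_threshold)
          w <- matrix(0, inp$L, N_RL); w[midr, ] <- 1
          fw <- nn_forward(model$params, mcfg, inp$c, inp$l, mask_idx = midr,
                           want_cache = TRUE)
          ls <- bce_loss(fw$logits, lab, w)
          g <- nn_backward(model$params, mcfg, fw$cache, ls$dlogits)
          gacc <- if (is.null(gacc)) g else add_grads(gacc, g)
        }
        for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / length(batch)
        up <- adam_step(model$params, gacc, st,
                        lr = config$learning_rate * config$lr_decay^(epoch - 1L))
        model$params <- up$params; st <- up$state
        i <- i + config$batch_size
      }
      vl <- eval_val(model$params)
      history[[epoch]] <- data.frame(epoch = epoch, val_loss = vl)
      if (!is.na(vl) && vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) break
    }
    model$params <- best$params
    attr(model, "history") <- do.call(rbind, history)
    attr(model, "best_epoch") <- best$epoch
    out[[sprintf("model%d", midx)]] <- model
  }
  out
}

#' Supervised TIS training (and fine-tuning)
#'
#' Binary cross-entropy over all transcript positions of the training-fold
#' chromosomes, with annotated TIS positions as the positive set and every
#' other position negative; the extreme class imbalance is countered by a
#' positive-class weight (default: per-batch negatives/positives ratio).
#' With `init` given, encoder weights are loaded from the pretraining
#' checkpoints and the 21-wide head is swapped for a fresh 1-wide TIS head
#' ("fine-tuning"). Early stopping monitors the validation PR AUC for TIS
#' detection (the validation loss is recorded too, but under desk-scale
#' class imbalance it is dominated by a handful of positives and tracks the
#' ranking quality poorly); the best-validation checkpoint is returned per
#' fold model, together with a per-epoch history (train loss, val loss, val
#' PR AUC) and an audit of the transcript ids used for training.
#'
#' @param profiles A `SampleProfile` or list of them.
#' @param annotation A `GenomeAnnotation`.
#' @param allocation A `FoldAllocation`.
#' @param config A [train_config()].
#' @param model_cfg A [model_config()].
#' @param init Optional list of two pretrained checkpoints (from
#'   [pretrain()]) or of two `riboscope_model`s.
#' @return List with `model1`, `model2` (trained `riboscope_model`s),
#'   `history` (per-model data.frame), `epochs_run`, `best_epoch`,
#'   `train_ids` (per-model transcript-id audit).
#' @export
train_supervised <- function(profiles, annotation, allocation, config,
                             model_cfg = model_config(), init = NULL) {
  if (inherits(profiles, "SampleProfile")) profiles <- list(profiles)
  res <- list(history = list(), epochs_run = integer(2), best_epoch = integer(2),
              train_ids = list())
  for (midx in 1:2) {
    alloc <- allocation$models[[midx]]
    items <- fold_transcripts(profiles, annotation, alloc$train_chromosomes)
    vitems <- fold_transcripts(profiles, annotation, alloc$val_chromosomes)
    npos <- sum(vapply(items, function(it)
      !is.null(annotation$transcripts[[it$id]]$cds), logical(1)))
    if (npos == 0L)
      stop(sprintf("fold model %d: zero annotated TISs in training chromosomes", midx))
    mcfg <- model_cfg
    if (!is.null(init)) {
      ck <- init[[midx]]
      stopifnot(inherits(ck, "riboscope_model"))
      if (ck$config$h != mcfg$h || ck$config$n_layers != mcfg$n_layers ||
          ck$config$n_heads != mcfg$n_heads)
        stop("init checkpoint architecture incompatible with model_cfg")
      mcfg <- ck$config
      model <- structure(list(config = mcfg,
                              params = swap_head(ck$params, mcfg, 1L),
                              head_width = 1L, version = ck$version),
                         class = "riboscope_model")
    } else {
      mcfg$seed <- derive_seed(config$seed, sprintf("sup_m%d", midx))
      model <- new_model(mcfg, head_width = 1L)
    }
    st <- adam_init(model$params)
    best <- list(metric = -Inf, params = model$params, epoch = 0L)
    history <- list()

    labels_of <- function(it) {
      t <- annotation$transcripts[[it$id]]
      y <- numeric(transcript_length(t))
      if (!is.null(t$cds)) y[t$cds$tis_index + 1L] <- 1
      y
    }
    tx_loss <- function(params, it, want_grad = FALSE, pw = 1) {
      inp <- get_inputs(profiles, annotation, it)
      y <- labels_of(it)
      w <- ifelse(y > 0, pw, 1)
      fw <- nn_forward(params, mcfg, inp$c, inp$l, want_cache = want_grad)
      ls <- bce_loss(fw$logits, matrix(y), matrix(w))
      if (!want_grad) return(list(loss = ls$loss))
      list(loss = ls$loss,
           grads = nn_backward(params, mcfg, fw$cache, ls$dlogits))
    }
    eval_val <- function(params) {
      if (!length(vitems)) return(list(loss = NA_real_, pr = NA_real_))
      tot <- 0; sc <- list(); lb <- list()
      for (vi in seq_along(vitems)) {
        it <- vitems[[vi]]
        inp <- get_inputs(profiles, annotation, it)
        y <- labels_of(it)
        fw <- nn_forward(params, mcfg, inp$c, inp$l)
        pw <- if (is.null(config$pos_weight))
          max(1, (length(y) - sum(y)) / max(1, sum(y))) else config$pos_weight
        w <- ifelse(y > 0, pw, 1)
        tot <- tot + bce_loss(fw$logits, matrix(y), matrix(w))$loss
        sc[[vi]] <- as.numeric(1 / (1 + exp(-fw$logits[, 1L])))
        lb[[vi]] <- y
      }
      s <- unlist(sc); l <- unlist(lb)
      pr <- if (length(unique(l)) == 2L) pr_auc(s, l) else NA_real_
      list(loss = tot / length(vitems), pr = pr)
    }

    for (epoch in seq_len(config$max_epochs)) {
      set.seed(derive_seed(config$seed, sprintf("sup_ep%d_m%d", epoch, midx)))
      ord <- sample(seq_along(items))
      ep_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        if (is.null(config$pos_weight)) {
          bp <- 0; bn <- 0
          for (bi in batch) {
            y <- labels_of(items[[bi]])
            bp <- bp + sum(y); bn <- bn + length(y) - sum(y)
          }
          pw <- max(1, bn / max(1, bp))
        } else pw <- config$pos_weight
        gacc <- NULL
        for (bi in batch) {
          r <- tx_loss(model$params, items[[bi]], want_grad = TRUE, pw = pw)
          ep_loss <- ep_loss + r$loss
          gacc <- if (is.null(gacc)) r$grads else add_grads(gacc, r$grads)
        }
        for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / length(batch)
        up <- adam_step(model$params, gacc, st,
                        lr = config$learning_rate * config$lr_decay^(epoch - 1L))
        model$params <- up$params; st <- up$state
        nb <- nb + length(batch)
        i <- i + config$batch_size
      }
      vv <- eval_val(model$params)
      monitor <- if (!is.na(vv$pr)) vv$pr else
        if (!is.na(vv$loss)) -vv$loss else -ep_loss / nb
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_loss = vv$loss, val_pr_auc = vv$pr)
      if (monitor > best$metric + 1e-6) {
        best <- list(metric = monitor, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) break
    }
    model$params <- best$params
    res[[sprintf("model%d", midx)]] <- model
    res$history[[midx]] <- do.call(rbind, history)
    res$epochs_run[midx] <- length(history)
    res$best_epoch[midx] <- best$epoch
    res$train_ids[[midx]] <- unique(vapply(items, `[[`, character(1), "id"))
  }
  res
}

#' Write per-epoch training history as TSV
#'
#' @param result Result of [train_supervised()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(result, path) {
  h1 <- cbind(model = 1L, result$history[[1]])
  h2 <- cbind(model = 2L, result$history[[2]])
  write.table(rbind(h1, h2), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
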