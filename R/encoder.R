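# User-facing encoder surface: position-wise input embedding, count
# normalization, per-transcript scoring, and fold-routed whole-sample
# prediction.
#
# The model consumes, per transcript position, only the (normalized) total
# read count c and the per-read-length fractions l over lengths 20-40 (21
# lengths): e_c = e (*) tanh(phi(c)) and e_l = sum_i E_i l_i, scored with a
# full-transcript attention encoder. No nucleotide sequence is used.

#' Normalize a count matrix into per-position model inputs
#'
#' Per position: raw count = reads summed over lengths; `c` = raw divided by
#' the transcript-wide maximum (all zeros for a read-free transcript); `l` =
#' per-length fractions (a zero vector at read-free positions).
#'
#' @param matrix A `ReadCountMatrix`.
#' @return List with `c` (length-L vector in `[0,1]`) and `l` (L x 21 matrix
#'   whose rows sum to 1 or 0).
#' @export
normalize_counts <- function(matrix) {
  m <- as.matrix(matrix$counts)
  raw <- rowSums(m)
  cmax <- max(raw)
  c_vec <- if (cmax > 0) raw / cmax else raw
  l <- m
  nz <- raw > 0
  l[nz, ] <- m[nz, , drop = FALSE] / raw[nz]
  l[!nz, ] <- 0
  list(c = c_vec, l = l)
}

#' Embed one transcript position
#'
#' Returns `e_c + e_l` with `e_c = e (*) tanh(phi(c))` and
#' `e_l = sum_i E_i * l_i`; at read-free positions (`sum(l) == 0`) `e_l` is
#' the zero vector.
#'
#' @param c Normalized count in `[0,1]`.
#' @param l Numeric 21-vector of read-length fractions (lengths 20-40),
#'   entries in `[0,1]` with sum 0 or 1.
#' @param params Model parameter list (see [init_params] via [new_model()]).
#' @return Numeric vector of width `h`.
#' @export
embed_position <- function(c, l, params) {
  stopifnot(length(l) == N_RL)
  if (any(l < 0) || !(abs(sum(l)) < 1e-6 || abs(sum(l) - 1) < 1e-6))
    stop("l must be non-negative with sum 0 or 1")
  if (c < 0 || c > 1) stop("c must be in [0,1]")
  z1 <- tanh(params$phi_W1 * c + params$phi_b1)
  z2 <- tanh(as.numeric(crossprod(params$phi_W2, z1)) + params$phi_b2)
  e_c <- params$e * z2
  e_l <- as.numeric(crossprod(params$E, l))
  e_c + e_l
}

#' Create an untrained encoder model
#'
#' @param config A [model_config()].
#' @param head_width Output head width (1 for the TIS task, 21 for the
#'   read-presence pretraining task).
#' @return A `riboscope_model`: `config`, `params`, `head_width`.
#' @export
new_model <- function(config = model_config(), head_width = 1L) {
  structure(list(config = config, params = init_params(config, head_width),
                 head_width = as.integer(head_width), version = "riboscope-ckpt-1"),
            class = "riboscope_model")
}

#' @export
print.riboscope_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("riboscope_model: h=%d, %d layer(s), %d head(s), %s attention, %d parameters\n",
              x$config$h, x$config$n_layers, x$config$n_heads,
              x$config$attention_kind, np))
  invisible(x)
}

#' Score every position of one transcript
#'
#' Deterministic at inference (dropout disabled); every position's score can
#' depend on every other position via full-transcript attention. Inputs
#' longer than `max_transcript_length` are scored in overlapping chunks when
#' `chunk_overlong` is set, otherwise raise an error.
#'
#' @param model A `riboscope_model` with a 1-wide head.
#' @param matrix A `ReadCountMatrix` (or `NULL` with `length` given, for a
#'   read-free transcript).
#' @param length Transcript length (required when `matrix` is `NULL`).
#' @return A `PositionScores`: `transcript_id`, `scores` (probabilities).
#' @export
score_transcript <- function(model, matrix, length = NULL) {
  if (is.null(matrix)) {
    stopifnot(!is.null(length))
    inp <- list(c = numeric(length), l = Matrix::Matrix(0, length, N_RL))
    id <- NA_character_
  } else {
    inp <- normalize_counts(matrix)
    id <- matrix$transcript_id
  }
  L <- base::length(inp$c)
  cfg <- model$config
  if (L <= cfg$max_transcript_length) {
    logits <- nn_forward(model$params, cfg, inp$c, as.matrix(inp$l))$logits
    scores <- as.numeric(1 / (1 + exp(-logits[, 1L])))
  } else if (!cfg$chunk_overlong) {
    stop(sprintf("transcript %s (%d nt) exceeds max_transcript_length=%d and chunking is disabled",
                 id, L, cfg$max_transcript_length))
  } else {
    w <- cfg$max_transcript_length; ov <- cfg$chunk_overlap
    step <- w - 2L * ov
    scores <- numeric(L); filled <- logical(L)
    s <- 1L
    while (s <= L) {
      e <- min(s + w - 1L, L)
      logits <- nn_forward(model$params, cfg, inp$c[s:e],
                           as.matrix(inp$l[s:e, , drop = FALSE]))$logits
      sc <- 1 / (1 + exp(-logits[, 1L]))
      lo <- if (s == 1L) s else s + ov
      hi <- if (e == L) e else e - ov
      scores[lo:hi] <- sc[(lo - s + 1L):(hi - s + 1L)]
      filled[lo:hi] <- TRUE
      if (e == L) break
      s <- s + step
    }
    stopifnot(all(filled))
  }
  structure(list(transcript_id = id, scores = scores), class = "PositionScores")
}

#' Combine two fold models into whole-sample predictions
#'
#' Each transcript is scored by the model whose *test* fold contains its
#' chromosome; the union of the two test folds covers the transcriptome, so
#' every transcript is scored exactly once and never by a model that saw its
#' chromosome in training.
#'
#' @param profile A `SampleProfile`.
#' @param models List of two `riboscope_model`s (fold model 1 and 2).
#' @param allocation A `FoldAllocation` (see [allocate_folds()]).
#' @param annotation A `GenomeAnnotation` (chromosome lookup; transcripts
#'   without reads are scored on empty input).
#' @return Named list of `PositionScores`, one per transcript.
#' @export
predict_sample <- function(profile, models, allocation, annotation) {
  stopifnot(length(models) == 2L)
  out <- list()
  for (t in annotation$transcripts) {
    ch <- t$chromosome
    m_idx <- which(vapply(1:2, function(i)
      ch %in% allocation$models[[i]]$test_chromosomes, logical(1)))
    if (length(m_idx) == 0L)
      stop("chromosome in neither test fold: ", ch)
    m_idx <- m_idx[1L]
    ps <- score_transcript(models[[m_idx]],
                           profile$matrices[[t$transcript_id]],
                           length = transcript_length(t))
    ps$transcript_id <- t$transcript_id
    ps$fold_model <- m_idx
    out[[t$transcript_id]] <- ps
  }
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the model config and a format version; loading refuses
#' incompatible versions, and fine-tuning refuses architecture mismatches.
#'
#' @param model A `riboscope_model`.
#' @param path Destination path (`.rds`).
#' @return `path` (writer); the model (reader).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "riboscope_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!identical(m$version, "riboscope-ckpt-1"))
    stop("incompatible checkpoint version: ", m$version %||% "<missing>")
  m
}
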