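# Scoring-quality metrics against ORF libraries, the benchmark harness, and
# ORF-level quantification.

#' ROC AUC by the rank (Mann-Whitney) method
#'
#' Equals `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("roc_auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' PR AUC as average precision (step-wise interpolation)
#'
#' Area under precision vs recall using right-continuous steps at each
#' distinct score threshold — the average-precision convention, which avoids
#' the optimism of trapezoidal interpolation.
#'
#' @inheritParams roc_auc
#' @return AUC in `[0,1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("pr_auc requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each distinct score (threshold = score)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Build an ORF library
#'
#' An ORF library is a labelled set of candidate ORFs — the custom
#' positive/negative evaluation set a caller works over.
#'
#' @param entries data.frame with columns `transcript_id`, `tis_index`,
#'   `stop_index`, `label` (`"positive"`/`"negative"`).
#' @param provenance Free-text origin of the library.
#' @return An `OrfLibrary`.
#' @export
orf_library <- function(entries, provenance = "unknown") {
  entries <- as.data.frame(entries)
  stopifnot(all(c("transcript_id", "tis_index", "stop_index", "label") %in%
                  names(entries)),
            all(entries$label %in% c("positive", "negative")))
  key <- paste(entries$transcript_id, entries$tis_index, entries$stop_index)
  if (anyDuplicated(key)) stop("duplicate library entries")
  structure(list(entries = entries, provenance = provenance),
            class = "OrfLibrary")
}

#' Read/write an ORF library as TSV
#' @param path TSV path.
#' @param provenance Provenance string for the reader.
#' @param library An `OrfLibrary` (writer).
#' @return An `OrfLibrary` (reader); `path` invisibly (writer).
#' @export
read_orf_library <- function(path, provenance = basename(path)) {
  orf_library(read.table(path, header = TRUE, sep = "\t"), provenance)
}

#' @rdname read_orf_library
#' @export
write_orf_library <- function(library, path) {
  write.table(library$entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Benchmark per-position scores against an ORF library
#'
#' Each library entry is scored by the model score at its TIS position;
#' labels come from the library (canonical CDSs form the positive set).
#' Entries on transcripts without scores are an error, never silently
#' dropped.
#'
#' @param scores Named list of `PositionScores` (from [predict_sample()]).
#' @param library An `OrfLibrary`.
#' @return Named list with `roc_auc` and `pr_auc`.
#' @export
benchmark_library <- function(scores, library) {
  e <- library$entries
  missing <- setdiff(unique(e$transcript_id), names(scores))
  if (length(missing))
    stop("library entries on unscored transcripts: ",
         paste(missing, collapse = ","))
  s <- vapply(seq_len(nrow(e)), function(i) {
    v <- scores[[e$transcript_id[i]]]$scores
    if (e$tis_index[i] < 0 || e$tis_index[i] >= length(v))
      stop(sprintf("library entry %s:%d outside scored positions",
                   e$transcript_id[i], e$tis_index[i]))
    v[e$tis_index[i] + 1L]
  }, numeric(1))
  y <- as.numeric(e$label == "positive")
  list(roc_auc = roc_auc(s, y), pr_auc = pr_auc(s, y))
}

#' TPM quantification of called ORFs
#'
#' Per ORF and sample: rate = reads with 5'-end in `[tis, stop+3)` divided
#' by the span length; TPM = rate over the sum of rates of all quantified
#' features, times 1e6.
#'
#' @param calls List or data.frame of ORF calls (needs `transcript_id`,
#'   `tis_index`, `stop_index`).
#' @param profiles Named list of `SampleProfile`s.
#' @return Matrix (ORFs x samples) of TPM values; rownames are
#'   `transcript:tis:stop` keys.
#' @export
tpm_quantify <- function(calls, profiles) {
  df <- as_call_frame(calls)
  if (inherits(profiles, "SampleProfile")) profiles <- list(profiles)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- vapply(profiles, function(p)
      p$sample_id %||% "sample", character(1))
  out <- matrix(0, nrow(df), length(profiles),
                dimnames = list(paste(df$transcript_id, df$tis_index,
                                      df$stop_index, sep = ":"),
                                names(profiles)))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    rate <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) {
      m <- p$matrices[[df$transcript_id[i]]]
      if (is.null(m)) { rate[i] <- 0; next }
      rate[i] <- reads_per_base(m, df$tis_index[i], df$stop_index[i] + 3L)
    }
    tot <- sum(rate)
    if (tot == 0) stop("zero total rate in sample ", names(profiles)[j])
    out[, j] <- rate / tot * 1e6
  }
  out
}

#' Spearman correlation between ncORF and CDS translation across samples
#'
#' For each stated (ncORF, CDS) pair of TPM rows, the two-sided Spearman
#' test across samples: ties mid-ranked; p-values via the asymptotic
#' approximation by default, with the exact small-sample option.
#'
#' @param tpm ORF x sample TPM matrix (rownames as in [tpm_quantify()]).
#' @param pairs data.frame with columns `ncorf` and `cds` naming TPM rows.
#' @param exact Passed to [stats::cor.test()].
#' @return data.frame with `ncorf`, `cds`, `rho`, `p`; `rho` is `NA` (with a
#'   warning) when a vector is constant.
#' @export
ncorf_cds_correlation <- function(tpm, pairs, exact = FALSE) {
  stopifnot(ncol(tpm) >= 4L)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- tpm[pairs$ncorf[i], ]; b <- tpm[pairs$cds[i], ]
    if (sd(a) == 0 || sd(b) == 0) {
      warning("constant TPM vector for pair ", i, "; rho undefined")
      return(data.frame(ncorf = pairs$ncorf[i], cds = pairs$cds[i],
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                    alternative = "two.sided", exact = exact))
    data.frame(ncorf = pairs$ncorf[i], cds = pairs$cds[i],
               rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
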