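# ORF calling: thresholding per-position TIS scores, ATG neighborhood
# correction, greedy stop-codon extension, start/stop filters, dedup, and
# multi-sample consensus.

as_call_frame <- function(calls) {
  if (is.data.frame(calls)) return(as.data.frame(calls))
  do.call(rbind, lapply(calls, function(x) as.data.frame(x[!vapply(x, is.null, logical(1))])))
}

#' Construct an ORF from a TIS by greedy stop-codon extension
#'
#' Scans codons `tis, tis+3, ...` and returns the ORF ending at the first
#' in-frame stop codon; `NULL` when no in-frame stop exists before the
#' transcript end (absence is a value, later removed by the stop filter).
#'
#' @param t A `TranscriptRecord`.
#' @param tis Transcript coordinate of the candidate start.
#' @return An `OrfCall` list (`transcript_id`, `tis_index`, `stop_index`,
#'   `start_codon`) or `NULL`.
#' @export
construct_orf <- function(t, tis) {
  L <- transcript_length(t)
  stopifnot(tis >= 0L, tis + 3L <= L)
  p <- tis + 3L
  while (p + 3L <= L) {
    if (is_stop_codon(codon_at(t, p)))
      return(list(transcript_id = t$transcript_id, tis_index = as.integer(tis),
                  stop_index = as.integer(p), start_codon = codon_at(t, tis)))
    p <- p + 3L
  }
  NULL
}

#' Correct a non-ATG candidate TIS to a nearby in-frame ATG
#'
#' If the codon at `tis` is not ATG, in-frame positions `tis +- 3k`
#' (k = 1..9 codons) are searched; when at least one ATG exists the nearest
#' one is returned, ties broken upstream (which yields the longer ORF).
#' ATG candidates and candidates with no in-frame ATG within range are
#' returned unchanged. Idempotent.
#'
#' @param t A `TranscriptRecord`.
#' @param tis Candidate TIS (transcript coordinate).
#' @param max_codons Search radius in codons.
#' @return The (possibly moved) TIS coordinate.
#' @export
neighborhood_correct <- function(t, tis, max_codons = 9L) {
  L <- transcript_length(t)
  if (codon_at(t, tis) == "ATG") return(as.integer(tis))
  for (k in seq_len(max_codons)) {
    up <- tis - 3L * k; dn <- tis + 3L * k
    if (up >= 0L && codon_at(t, up) == "ATG") return(as.integer(up))
    if (dn + 3L <= L && codon_at(t, dn) == "ATG") return(as.integer(dn))
  }
  as.integer(tis)
}

#' Start/stop filters for a constructed call
#'
#' Drops calls whose start codon does not match the N-T-G pattern
#' (ATG/CTG/GTG/TTG) and calls without an in-frame stop on the transcript.
#'
#' @param call An `OrfCall` list (possibly `NULL` = no stop found).
#' @return List with `keep` (logical) and `reason` (`"pass"`,
#'   `"no_stop_on_transcript"`, or `"invalid_start_codon"`).
#' @export
apply_filters <- function(call) {
  if (is.null(call) || is.null(call$stop_index) || is.na(call$stop_index))
    return(list(keep = FALSE, reason = "no_stop_on_transcript"))
  if (!grepl("^.TG$", call$start_codon))
    return(list(keep = FALSE, reason = "invalid_start_codon"))
  list(keep = TRUE, reason = "pass")
}

#' Call ORFs from per-position TIS scores
#'
#' Positions scoring above `threshold` become candidate TISs; each is passed
#' through ATG neighborhood correction, greedy stop-codon extension, and the
#' start/stop filters. The threshold applies to the original prediction (the
#' model's evidence); a corrected call keeps that score together with both
#' coordinates. Calls are deduplicated on (transcript, tis, stop), keeping
#' the maximum score.
#'
#' @param scores Named list of `PositionScores`.
#' @param annotation A `GenomeAnnotation`.
#' @param threshold Score threshold (default 0.15, exclusive).
#' @param correct_codons ATG-correction radius in codons (0 disables).
#' @param sample_id Optional label attached to the calls.
#' @return data.frame of calls: `transcript_id`, `tis_index`, `stop_index`,
#'   `start_codon`, `score`, `corrected_from` (NA when unmoved),
#'   `filter_reason` audit of dropped candidates is attached as the
#'   `"dropped"` attribute.
#' @export
call_orfs <- function(scores, annotation, threshold = 0.15,
                      correct_codons = 9L, sample_id = NA_character_) {
  rows <- list(); dropped <- list()
  for (id in names(scores)) {
    t <- annotation$transcripts[[id]]
    if (is.null(t)) next
    sc <- scores[[id]]$scores
    cand <- which(sc > threshold) - 1L
    cand <- cand[cand + 3L <= transcript_length(t)]
    for (tis0 in cand) {
      tis <- if (correct_codons > 0L)
        neighborhood_correct(t, tis0, max_codons = correct_codons) else tis0
      orf <- construct_orf(t, tis)
      if (!is.null(orf)) orf$start_codon <- codon_at(t, tis)
      fl <- apply_filters(orf)
      if (!fl$keep) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(transcript_id = id, tis_index = tis0, reason = fl$reason)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, tis_index = orf$tis_index,
        stop_index = orf$stop_index, start_codon = orf$start_codon,
        score = sc[tis0 + 1L],
        corrected_from = if (tis != tis0) tis0 else NA_integer_,
        sample_id = sample_id)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), tis_index = integer(),
               stop_index = integer(), start_codon = character(),
               score = numeric(), corrected_from = integer(),
               sample_id = character())
  if (nrow(calls)) {
    # dedup on the ORF key, keep max score
    key <- paste(calls$transcript_id, calls$tis_index, calls$stop_index)
    calls <- calls[order(key, -calls$score), ]
    calls <- calls[!duplicated(paste(calls$transcript_id, calls$tis_index,
                                     calls$stop_index)), ]
    rownames(calls) <- NULL
  }
  attr(calls, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(transcript_id = character(), tis_index = integer(),
               reason = character())
  calls
}

#' Multi-sample consensus call set
#'
#' Keeps ORFs (keyed by transcript, tis, stop) called in at least
#' `min_samples` samples, attaching the per-sample support count.
#'
#' @param call_sets List of per-sample call data.frames.
#' @param min_samples Minimum number of supporting samples.
#' @return data.frame of consensus calls with a `support` column (maximum
#'   score across supporting samples is retained).
#' @export
consensus_calls <- function(call_sets, min_samples = 2L) {
  if (min_samples > length(call_sets))
    stop(sprintf("min_samples=%d exceeds number of samples (%d)",
                 min_samples, length(call_sets)))
  all <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
    df <- as.data.frame(call_sets[[i]])
    if (!nrow(df)) return(NULL)
    df$.sample <- i
    df
  }))
  if (is.null(all) || !nrow(all))
    return(data.frame(transcript_id = character(), tis_index = integer(),
                      stop_index = integer(), support = integer()))
  dt <- data.table::as.data.table(all)
  agg <- dt[, list(support = data.table::uniqueN(.sample),
                   score = max(score),
                   start_codon = start_codon[1]),
            by = c("transcript_id", "tis_index", "stop_index")]
  out <- as.data.frame(agg[agg$support >= min_samples, ])
  rownames(out) <- NULL
  out
}

#' Write calls as TSV and BED12
#'
#' The BED12 uses genome coordinates via the transcript exon map: one BED
#' row per ORF spanning `[tis, stop+3)`, with blocks following the exon
#' structure.
#'
#' @param calls Call data.frame (optionally with `orf_type`, `support`).
#' @param annotation A `GenomeAnnotation`.
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @return Invisible list of written paths.
#' @export
write_calls <- function(calls, annotation, tsv_path = NULL, bed_path = NULL) {
  calls <- as.data.frame(calls)
  if (!is.null(tsv_path)) {
    df <- calls
    df$gene_id <- vapply(df$transcript_id, function(id)
      annotation$transcripts[[id]]$gene_id %||% NA_character_, character(1))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    lines <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      t <- annotation$transcripts[[calls$transcript_id[i]]]
      gr <- transcript_interval_to_granges(t, calls$tis_index[i],
                                           calls$stop_index[i] + 3L)
      st <- BiocGenerics::start(gr) - 1L; en <- BiocGenerics::end(gr)
      o <- order(st)
      st <- st[o]; en <- en[o]
      chromStart <- min(st); chromEnd <- max(en)
      lines[i] <- paste(t$chromosome, chromStart, chromEnd,
                        sprintf("%s:%d-%d", calls$transcript_id[i],
                                calls$tis_index[i], calls$stop_index[i] + 3L),
                        round(1000 * min(1, calls$score[i] %||% 0)), t$strand,
                        chromStart, chromEnd, "0",
                        length(st), paste0(paste(en - st, collapse = ","), ","),
                        paste0(paste(st - chromStart, collapse = ","), ","),
                        sep = "\t")
    }
    writeLines(lines, bed_path)
  }
  invisible(list(tsv = tsv_path, bed = bed_path))
}
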