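# ORF taxonomy: label each called ORF relative to the annotation.

ORF_TYPES <- c("annotated_CDS", "N_terminal_extension", "N_terminal_truncation",
               "uORF", "uoORF", "intORF", "dORF", "doORF", "lncRNA_ORF",
               "CDS_variant", "other")

#' Classify one ORF against the annotation
#'
#' Precedence: (1) `annotated_CDS` — TIS and stop equal the transcript's
#' annotated CDS; (2) `N_terminal_extension` — same stop, in frame, TIS
#' upstream; (3) `N_terminal_truncation` — same stop, in frame, TIS
#' downstream; (4) on a coding transcript: `uORF` (entirely 5' of the CDS),
#' `uoORF` (TIS 5' of the CDS, overlapping its start out of frame),
#' `intORF` (nested in the CDS span, out of frame), `dORF` (entirely 3'),
#' `doORF` (TIS strictly inside the CDS span, out of frame, stop 3' of it);
#' (5) on a non-coding transcript: `CDS_variant` when the ORF's genomic
#' start or stop coincides with any annotated CDS start/stop site, else
#' `lncRNA_ORF` when the transcript carries the lncRNA tag, else `other`.
#' In-frame nested ORFs without a shared stop are `other` (internal ORFs
#' are restricted to out-of-frame). Overlap is measured against the CDS
#' span `[tis, stop+3)` with half-open arithmetic.
#'
#' @param call An ORF call (list or one-row data.frame with
#'   `transcript_id`, `tis_index`, `stop_index`).
#' @param t The call's `TranscriptRecord`.
#' @param annotation A `GenomeAnnotation` (for the CDS site/interval index).
#' @return List with `label` and `evidence` (which rule fired).
#' @export
classify_orf <- function(call, t, annotation) {
  tis <- as.integer(call$tis_index); stp <- as.integer(call$stop_index)
  out <- function(label, evidence) list(label = label, evidence = evidence)
  if (!is.null(t$cds)) {
    ct <- t$cds$tis_index; cs <- t$cds$stop_index
    in_frame <- (tis - ct) %% 3L == 0L
    if (stp == cs) {
      if (tis == ct) return(out("annotated_CDS", "tis and stop match annotated CDS"))
      if (in_frame && tis < ct)
        return(out("N_terminal_extension", "shared stop, in-frame upstream TIS"))
      if (in_frame && tis > ct)
        return(out("N_terminal_truncation", "shared stop, in-frame downstream TIS"))
    }
    orf_end <- stp + 3L; cds_end <- cs + 3L
    if (orf_end <= ct)
      return(out("uORF", "ORF entirely upstream of CDS"))
    if (tis < ct && orf_end > ct && !in_frame)
      return(out("uoORF", "TIS upstream of CDS, overlaps CDS start out of frame"))
    if (tis >= ct && orf_end <= cds_end && !in_frame)
      return(out("intORF", "nested within CDS span out of frame"))
    if (tis >= cds_end)
      return(out("dORF", "ORF entirely downstream of CDS"))
    if (tis > ct && tis < cds_end && !in_frame && orf_end > cds_end)
      return(out("doORF", "TIS inside CDS span out of frame, stop downstream of CDS"))
    return(out("other", "coding transcript, no taxonomy rule matched"))
  }
  # non-coding transcript: check genomic start/stop coincidence with any CDS
  g_tis <- transcript_to_genomic(t, tis)
  g_stop <- transcript_to_genomic(t, stp)
  ss <- annotation$cds_start_sites; st <- annotation$cds_stop_sites
  shares <- any(ss$chromosome == t$chromosome & ss$gpos == g_tis) ||
    any(st$chromosome == t$chromosome & st$gpos == g_stop) ||
    any(st$chromosome == t$chromosome & st$gpos == g_tis) ||
    any(ss$chromosome == t$chromosome & ss$gpos == g_stop)
  if (shares)
    return(out("CDS_variant", "shares a genomic start/stop site with an annotated CDS"))
  if ("lncRNA" %in% t$biotype_tags)
    return(out("lncRNA_ORF", "lncRNA-tagged transcript, no shared CDS site"))
  out("other", "non-coding transcript without lncRNA tag")
}

#' Annotate a call set with taxonomy labels
#'
#' @param calls Call data.frame (from [call_orfs()] or
#'   [consensus_calls()]).
#' @param annotation A `GenomeAnnotation`.
#' @return The call data.frame with `orf_type` and `evidence` columns.
#' @export
annotate_calls <- function(calls, annotation) {
  calls <- as.data.frame(calls)
  labs <- character(nrow(calls)); ev <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    t <- annotation$transcripts[[calls$transcript_id[i]]]
    cl <- classify_orf(calls[i, ], t, annotation)
    labs[i] <- cl$label; ev[i] <- cl$evidence
  }
  calls$orf_type <- labs; calls$evidence <- ev
  calls
}

#' Summary counts of ORF types
#'
#' @param calls Annotated call data.frame (with `orf_type`).
#' @return data.frame of per-type counts over all taxonomy labels.
#' @export
orf_type_counts <- function(calls) {
  tab <- table(factor(calls$orf_type, levels = ORF_TYPES))
  data.frame(orf_type = names(tab), n = as.integer(tab))
}

#' Overlap profile of called lncRNA-ORFs
#'
#' For each lncRNA-ORF, tests (a) whether its genomic TIS lies inside an
#' annotated CDS interval, (b) whether it lies inside an exon of a
#' protein-coding transcript, and (c) whether it is intergenic (outside all
#' annotated exons of any *other* gene — a TIS necessarily lies in its own
#' transcript's exon). The three fractions are not mutually exclusive.
#'
#' @param calls Annotated call data.frame; only rows with
#'   `orf_type == "lncRNA_ORF"` are used.
#' @param annotation A `GenomeAnnotation`.
#' @return Named list of fractions: `tis_in_cds`, `tis_in_pc_exon`,
#'   `intergenic`, plus `n`.
#' @export
lncRNA_overlap_profile <- function(calls, annotation) {
  calls <- as.data.frame(calls)
  if ("orf_type" %in% names(calls))
    calls <- calls[calls$orf_type == "lncRNA_ORF", ]
  if (!nrow(calls)) stop("no lncRNA-ORF calls to profile")
  g <- vapply(seq_len(nrow(calls)), function(i) {
    t <- annotation$transcripts[[calls$transcript_id[i]]]
    transcript_to_genomic(t, calls$tis_index[i])
  }, integer(1))
  chrom <- vapply(calls$transcript_id, function(id)
    annotation$transcripts[[id]]$chromosome, character(1))
  tis_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(g + 1L, g + 1L))
  hits <- function(idx) {
    if (length(idx) == 0L) return(logical(nrow(calls)))
    suppressWarnings(IRanges::overlapsAny(tis_gr, idx, ignore.strand = TRUE))
  }
  in_cds <- hits(annotation$cds_ranges)
  in_pc <- hits(annotation$pc_exon_ranges)
  own_gene <- vapply(calls$transcript_id, function(id)
    annotation$transcripts[[id]]$gene_id, character(1))
  in_other <- vapply(seq_len(nrow(calls)), function(i) {
    ov <- suppressWarnings(IRanges::findOverlaps(tis_gr[i], annotation$exon_ranges,
                                ignore.strand = TRUE))
    genes <- S4Vectors::mcols(annotation$exon_ranges)$gene_id[
      S4Vectors::subjectHits(ov)]
    any(genes != own_gene[i])
  }, logical(1))
  list(tis_in_cds = mean(in_cds), tis_in_pc_exon = mean(in_pc),
       intergenic = mean(!in_other), n = nrow(calls))
}
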