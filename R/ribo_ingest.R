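# Ingestion of transcript-space RPF alignments.
#
# Only each read's 5'-end position and aligned reference length are kept; no
# P-site/A-site offsetting and no frame-based discarding is performed.

RL_MIN <- 20L
RL_MAX <- 40L
N_RL <- RL_MAX - RL_MIN + 1L   # 21 read lengths

#' Construct a per-transcript read-count matrix
#'
#' Counts of RPF 5'-ends at each transcript position for each read length
#' 20-40, stored as a sparse `positions x 21` matrix.
#'
#' @param transcript_id Transcript identifier.
#' @param length Transcript length in nt.
#' @param pos,read_length,count Parallel vectors of triplets (pos 0-based).
#' @return An object of class `ReadCountMatrix`.
#' @export
read_count_matrix <- function(transcript_id, length,
                              pos = integer(), read_length = integer(),
                              count = integer()) {
  stopifnot(length(pos) == length(read_length), length(pos) == length(count))
  if (length(pos)) {
    stopifnot(all(pos >= 0L), all(pos < length),
              all(read_length >= RL_MIN), all(read_length <= RL_MAX),
              all(count >= 0L))
  }
  m <- Matrix::sparseMatrix(i = pos + 1L, j = read_length - RL_MIN + 1L,
                            x = as.numeric(count), dims = c(length, N_RL))
  structure(list(transcript_id = transcript_id, counts = m,
                 total_reads = sum(count)),
            class = "ReadCountMatrix")
}

#' @export
print.ReadCountMatrix <- function(x, ...) {
  cat(sprintf("ReadCountMatrix %s: %d positions, %d reads\n",
              x$transcript_id, nrow(x$counts), x$total_reads))
  invisible(x)
}

# reference span consumed by a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1L] == -1L) return(NA_integer_)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Ingest transcript-space alignments into count matrices
#'
#' Reads a SAM or BAM whose reference names are transcript ids. For each
#' primary, forward-strand alignment with reference span within
#' `[length_min, length_max]`, the count at (5'-end position, read length)
#' is incremented. Reads on transcripts absent from the annotation are
#' counted and logged, not stored. Alignments whose reference names look
#' like chromosomes rather than transcripts trigger a hard error.
#'
#' @param bam_path Path to a transcript-space SAM or BAM file.
#' @param annotation A `GenomeAnnotation`.
#' @param length_min,length_max Accepted read-length bounds (defaults 20/40).
#' @param sample_id Sample label (defaults to the file name).
#' @return A `SampleProfile`: `matrices` (one `ReadCountMatrix` per
#'   transcript with reads), and `qc` (`mapped_reads`, accepted/dropped
#'   tallies, `in_frame_occupancy`).
#' @export
ingest_alignments <- function(bam_path, annotation,
                              length_min = RL_MIN, length_max = RL_MAX,
                              sample_id = basename(bam_path)) {
  force(sample_id)
  if (grepl("\\.sam$", bam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam_path <- tryCatch(Rsamtools::asBam(bam_path, destination = dest,
                                          indexDestination = FALSE),
                         error = function(e) stop("cannot read SAM file ",
                                                  bam_path, ": ", conditionMessage(e)))
  }
  res <- tryCatch(
    Rsamtools::scanBam(bam_path, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "cigar", "strand", "flag")))[[1]],
    error = function(e) stop("unreadable/corrupt alignment file ", bam_path,
                             ": ", conditionMessage(e)))
  rname <- as.character(res$rname); flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  primary <- !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  keep <- mapped & primary
  rname <- rname[keep]; pos1 <- res$pos[keep]; cigar <- res$cigar[keep]
  strand <- as.character(res$strand)[keep]

  known <- names(annotation$transcripts)
  if (length(rname) && !any(rname %in% known)) {
    if (any(rname %in% annotation$chromosomes))
      stop("alignments appear to be in GENOME space (reference names match ",
           "chromosomes, not transcripts); re-align with a transcriptome ",
           "quantification mode (e.g. STAR --quantMode TranscriptomeSAM)")
  }
  if (any(grepl("[SH]", cigar)))
    rs_log(sprintf("%d clipped alignment(s) seen; 5'-ends taken as aligned start",
                   sum(grepl("[SH]", cigar))), level = "WARN")

  rev_n <- sum(strand == "-")
  if (rev_n) rs_log(sprintf("dropped %d reverse-strand alignment(s)", rev_n))
  fwd <- strand != "-"
  rname <- rname[fwd]; pos1 <- pos1[fwd]; cigar <- cigar[fwd]

  rlen <- cigar_ref_span(cigar)
  inlen <- !is.na(rlen) & rlen >= length_min & rlen <= length_max
  rname <- rname[inlen]; pos1 <- pos1[inlen]; rlen <- rlen[inlen]

  on_known <- rname %in% known
  unknown_n <- sum(!on_known)
  if (unknown_n) rs_log(sprintf("%d read(s) on transcripts absent from annotation",
                                unknown_n))
  dt <- data.table::data.table(tx = rname[on_known], pos = pos1[on_known] - 1L,
                               len = rlen[on_known])
  agg <- dt[, .N, by = c("tx", "pos", "len")]
  matrices <- list()
  for (id in unique(agg$tx)) {
    sub <- agg[agg$tx == id, ]
    matrices[[id]] <- read_count_matrix(
      id, transcript_length(annotation$transcripts[[id]]),
      pos = sub$pos, read_length = sub$len, count = sub$N)
  }
  profile <- structure(list(sample_id = sample_id, matrices = matrices,
                            qc = list(mapped_reads = sum(on_known),
                                      dropped_reverse = rev_n,
                                      dropped_length = sum(!inlen),
                                      unknown_transcript = unknown_n)),
                       class = "SampleProfile")
  profile$qc$in_frame_occupancy <- in_frame_occupancy(profile, annotation)
  profile
}

#' @export
print.SampleProfile <- function(x, ...) {
  cat(sprintf("SampleProfile %s: %d transcripts, %d mapped reads, in-frame occupancy %s\n",
              x$sample_id, length(x$matrices), x$qc$mapped_reads,
              ifelse(is.na(x$qc$in_frame_occupancy), "NA",
                     sprintf("%.3f", x$qc$in_frame_occupancy))))
  invisible(x)
}

#' In-frame read occupancy of a sample
#'
#' Fraction of reads whose 5'-end lies within an annotated CDS at a position
#' congruent to the CDS start modulo 3, over all reads whose 5'-end lies
#' within a CDS — pooled (micro-averaged) across transcripts, giving one
#' sample-level QC number.
#'
#' @param profile A `SampleProfile`.
#' @param annotation A `GenomeAnnotation`.
#' @return A fraction in `[0,1]`, or `NA_real_` when no CDS reads exist
#'   (undefined, distinct from 0).
#' @export
in_frame_occupancy <- function(profile, annotation) {
  in_frame <- 0; total <- 0
  for (id in names(profile$matrices)) {
    t <- annotation$transcripts[[id]]
    if (is.null(t) || is.null(t$cds)) next
    m <- profile$matrices[[id]]$counts
    per_pos <- Matrix::rowSums(m)
    idx <- which(per_pos > 0)
    if (!length(idx)) next
    pos <- idx - 1L
    in_cds <- pos >= t$cds$tis_index & pos < t$cds$stop_index + 3L
    if (!any(in_cds)) next
    cnt <- per_pos[idx][in_cds]
    frame0 <- ((pos[in_cds] - t$cds$tis_index) %% 3L) == 0L
    total <- total + sum(cnt)
    in_frame <- in_frame + sum(cnt[frame0])
  }
  if (total == 0) return(NA_real_)
  in_frame / total
}

#' Reads-per-base over a transcript interval
#'
#' ORF abundance metric: total read count with 5'-end in `[start, stop)`
#' divided by the interval length.
#'
#' @param matrix A `ReadCountMatrix`.
#' @param start,stop Transcript coordinates, half-open.
#' @return Non-negative rate.
#' @export
reads_per_base <- function(matrix, start, stop) {
  L <- nrow(matrix$counts)
  if (!(start >= 0L && start < stop && stop <= L))
    stop(sprintf("invalid interval [%d,%d) on transcript %s (length %d)",
                 start, stop, matrix$transcript_id, L))
  sum(Matrix::rowSums(matrix$counts)[(start + 1L):stop]) / (stop - start)
}

#' Write / read a sample profile as a TSV container
#'
#' The profile is serialized as a directory holding `counts.tsv` (long
#' format: transcript, position, read length, count, transcript length) and
#' `qc.tsv`.
#'
#' @param profile A `SampleProfile`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly (writer); a `SampleProfile` (reader).
#' @export
write_sample_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (id in names(profile$matrices)) {
    m <- profile$matrices[[id]]
    tm <- Matrix::summary(m$counts)
    rows[[id]] <- data.frame(transcript_id = id, pos = tm$i - 1L,
                             read_length = tm$j + RL_MIN - 1L,
                             count = tm$x, tx_length = nrow(m$counts))
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), pos = integer(),
               read_length = integer(), count = numeric(), tx_length = integer())
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qc <- data.frame(metric = names(profile$qc),
                   value = vapply(profile$qc, function(v)
                     as.character(v %||% NA), character(1)))
  write.table(data.frame(sample_id = profile$sample_id), file.path(dir, "sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(qc, file.path(dir, "qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sample_profile
#' @export
read_sample_profile <- function(dir) {
  counts <- read.table(file.path(dir, "counts.tsv"), header = TRUE, sep = "\t")
  sample_id <- read.table(file.path(dir, "sample.tsv"), header = TRUE,
                          sep = "\t")$sample_id[1]
  qc_df <- read.table(file.path(dir, "qc.tsv"), header = TRUE, sep = "\t")
  matrices <- list()
  for (id in unique(counts$transcript_id)) {
    sub <- counts[counts$transcript_id == id, ]
    matrices[[id]] <- read_count_matrix(id, sub$tx_length[1], pos = sub$pos,
                                        read_length = sub$read_length,
                                        count = sub$count)
  }
  qc <- as.list(suppressWarnings(as.numeric(qc_df$value)))
  names(qc) <- qc_df$metric
  structure(list(sample_id = sample_id, matrices = matrices, qc = qc),
            class = "SampleProfile")
}
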