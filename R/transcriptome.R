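# Transcript annotation model.
#
# Internally every coordinate is 0-based, half-open, and strand-resolved:
# transcript position 0 is the 5' end of the mature transcript regardless of
# genomic strand. GTF/GFF3's 1-based closed convention is converted at the
# parser boundary only.

#' Construct a transcript record
#'
#' A `TranscriptRecord` holds one transcript: its spliced sequence (5'->3'),
#' the exon map to the genome, biotype tags, and (optionally) the annotated
#' CDS given as the transcript coordinates of the first base of the start
#' codon (`tis_index`) and of the first base of the stop codon
#' (`stop_index`).
#'
#' @param transcript_id,gene_id,chromosome Identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of genomic intervals (0-based half-open),
#'   ordered 5'->3' along the transcript (descending genomic start on the
#'   minus strand).
#' @param sequence Spliced sequence in transcript orientation; stored in the
#'   DNA alphabet (U is normalized to T).
#' @param biotype_tags Character vector of annotation tags.
#' @param cds `NULL`, or `list(tis_index=, stop_index=)` in transcript
#'   coordinates.
#' @param strict If `TRUE`, a CDS whose stop-codon invariants fail is an
#'   error; by default the record is kept and tagged (`cds_flags`).
#' @return An object of class `TranscriptRecord`.
#' @export
transcript_record <- function(transcript_id, gene_id, chromosome, strand,
                              exons, sequence, biotype_tags = character(),
                              cds = NULL, strict = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  sequence <- normalize_dna(sequence)
  if (sum(exons[, 2L] - exons[, 1L]) != nchar(sequence)) {
    stop(sprintf("transcript %s: exon lengths (%d) != sequence length (%d)",
                 transcript_id, sum(exons[, 2L] - exons[, 1L]), nchar(sequence)))
  }
  lens <- exons[, 2L] - exons[, 1L]
  if (any(lens <= 0L)) stop(sprintf("transcript %s: empty exon", transcript_id))
  rec <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    chromosome = chromosome, strand = strand,
    exons = exons, exon_cum = c(0L, cumsum(lens)),
    sequence = sequence, biotype_tags = as.character(biotype_tags),
    cds = NULL, cds_flags = character()
  ), class = "TranscriptRecord")
  if (!is.null(cds)) {
    tis <- as.integer(cds$tis_index); stp <- as.integer(cds$stop_index)
    span <- stp - tis
    flags <- character()
    if (span <= 0L || span %% 3L != 0L)
      flags <- c(flags, "cds_span_not_codon_multiple")
    if (stp + 3L > nchar(sequence) || !is_stop_codon(substr(sequence, stp + 1L, stp + 3L)))
      flags <- c(flags, "invalid_stop_codon")
    if (length(flags) && strict)
      stop(sprintf("transcript %s: invalid CDS (%s)", transcript_id,
                   paste(flags, collapse = ",")))
    rec$cds <- list(tis_index = tis, stop_index = stp)
    rec$cds_flags <- flags
  }
  rec
}

#' @export
print.TranscriptRecord <- function(x, ...) {
  cat(sprintf("TranscriptRecord %s (%s:%s) %d nt, %d exon(s)%s\n",
              x$transcript_id, x$chromosome, x$strand, nchar(x$sequence),
              nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", CDS [%d,%d)",
                                                  x$cds$tis_index, x$cds$stop_index + 3L)))
  invisible(x)
}

transcript_length <- function(t) nchar(t$sequence)

#' Map a transcript coordinate to its genomic coordinate
#'
#' Inverse of [genomic_to_transcript()]; both are 0-based.
#'
#' @param t A `TranscriptRecord`.
#' @param pos Transcript coordinate(s), `0 <= pos < length(sequence)`.
#' @return Integer genomic coordinate(s).
#' @export
transcript_to_genomic <- function(t, pos) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= transcript_length(t))) {
    stop(sprintf("transcript %s: position %s out of range [0, %d)",
                 t$transcript_id, paste(pos[pos < 0L | pos >= transcript_length(t)],
                                        collapse = ","), transcript_length(t)))
  }
  idx <- findInterval(pos, t$exon_cum, left.open = FALSE)
  off <- pos - t$exon_cum[idx]
  unname(if (t$strand == "+") t$exons[idx, 1L] + off
         else t$exons[idx, 2L] - 1L - off)
}

#' Map a genomic coordinate to a transcript coordinate
#'
#' @param t A `TranscriptRecord`.
#' @param gpos Genomic coordinate(s) (0-based); must fall on an exon.
#' @return Integer transcript coordinate(s).
#' @export
genomic_to_transcript <- function(t, gpos) {
  gpos <- as.integer(gpos)
  out <- integer(length(gpos))
  for (k in seq_along(gpos)) {
    g <- gpos[k]
    hit <- which(t$exons[, 1L] <= g & g < t$exons[, 2L])
    if (length(hit) != 1L)
      stop(sprintf("transcript %s: genomic position %d is not exonic",
                   t$transcript_id, g))
    off <- if (t$strand == "+") g - t$exons[hit, 1L] else t$exons[hit, 2L] - 1L - g
    out[k] <- t$exon_cum[hit] + off
  }
  out
}

#' Read the codon starting at a transcript position
#'
#' @param t A `TranscriptRecord` (or any object with a `sequence` field).
#' @param pos Transcript coordinate of the codon's first base.
#' @return Upper-case 3-mer with U normalized to T.
#' @export
codon_at <- function(t, pos) {
  L <- transcript_length(t)
  if (pos < 0L || pos + 3L > L)
    stop(sprintf("transcript %s: no complete codon at position %d (length %d)",
                 t$transcript_id, pos, L))
  substr(t$sequence, pos + 1L, pos + 3L)
}

# Project a transcript-coordinate interval [start, end) onto the genome as a
# GRanges (one range per intersected exon).
transcript_interval_to_granges <- function(t, start, end) {
  stopifnot(start >= 0L, end <= transcript_length(t), start < end)
  pieces <- list()
  n <- nrow(t$exons)
  for (i in seq_len(n)) {
    s <- max(start, t$exon_cum[i]); e <- min(end, t$exon_cum[i + 1L])
    if (s >= e) next
    if (t$strand == "+") {
      gs <- t$exons[i, 1L] + (s - t$exon_cum[i]); ge <- gs + (e - s)
    } else {
      ge <- t$exons[i, 2L] - (s - t$exon_cum[i]); gs <- ge - (e - s)
    }
    pieces[[length(pieces) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, pieces)
  GenomicRanges::GRanges(t$chromosome,
                         IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]),
                         strand = t$strand)
}

# ---------------------------------------------------------------------------
# GenomeAnnotation: keyed transcript collection + genomic interval indices.

build_annotation <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ","))
  names(transcripts) <- ids
  cds_gr <- list(); pc_exon_gr <- list(); exon_gr <- list()
  cds_starts <- list(); cds_stops <- list()
  for (t in transcripts) {
    eg <- GenomicRanges::GRanges(t$chromosome,
                                 IRanges::IRanges(t$exons[, 1L] + 1L, t$exons[, 2L]),
                                 strand = t$strand)
    S4Vectors::mcols(eg)$gene_id <- t$gene_id
    exon_gr[[length(exon_gr) + 1L]] <- eg
    is_pc <- "protein_coding" %in% t$biotype_tags || !is.null(t$cds)
    if (is_pc) pc_exon_gr[[length(pc_exon_gr) + 1L]] <- exon_gr[[length(exon_gr)]]
    if (!is.null(t$cds)) {
      gr <- transcript_interval_to_granges(t, t$cds$tis_index, t$cds$stop_index + 3L)
      S4Vectors::mcols(gr)$transcript_id <- t$transcript_id
      cds_gr[[length(cds_gr) + 1L]] <- gr
      cds_starts[[length(cds_starts) + 1L]] <-
        data.frame(chromosome = t$chromosome,
                   gpos = transcript_to_genomic(t, t$cds$tis_index))
      cds_stops[[length(cds_stops) + 1L]] <-
        data.frame(chromosome = t$chromosome,
                   gpos = transcript_to_genomic(t, t$cds$stop_index))
    }
  }
  cat_gr <- function(lst) if (length(lst)) suppressWarnings(do.call(c, lst)) else
    GenomicRanges::GRanges()
  structure(list(
    transcripts = transcripts,
    cds_ranges = cat_gr(cds_gr),
    pc_exon_ranges = cat_gr(pc_exon_gr),
    exon_ranges = cat_gr(exon_gr),
    cds_start_sites = if (length(cds_starts)) do.call(rbind, cds_starts) else
      data.frame(chromosome = character(), gpos = integer()),
    cds_stop_sites = if (length(cds_stops)) do.call(rbind, cds_stops) else
      data.frame(chromosome = character(), gpos = integer()),
    chromosomes = unique(vapply(transcripts, `[[`, character(1), "chromosome"))
  ), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  n_cds <- sum(!vapply(x$transcripts, function(t) is.null(t$cds), logical(1)))
  cat(sprintf("GenomeAnnotation: %d transcripts (%d with CDS) on %d chromosome(s)\n",
              length(x$transcripts), n_cds, length(x$chromosomes)))
  invisible(x)
}

sniff_gff_format <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no feature lines in ", path)
  attrs <- vapply(strsplit(lines, "\t", fixed = TRUE),
                  function(f) if (length(f) >= 9L) f[9L] else "", character(1))
  if (any(grepl("=", attrs, fixed = TRUE)) && !any(grepl("\\w+ \"", attrs))) "gff3" else "gtf"
}

#' Load a transcript annotation with sequences
#'
#' Reads a GTF or GFF3 (auto-detected by attribute syntax) together with a
#' FASTA of either the genome or the transcripts (auto-detected by whether
#' the FASTA names match chromosome or transcript ids). The start-codon
#' positive set is taken from `start_codon` features when present, otherwise
#' inferred from the 5'-most `CDS` feature; the stop-codon position comes
#' from `stop_codon` features or from the base following the 3'-most CDS
#' base (Ensembl convention: CDS excludes the stop codon). Minus-strand
#' transcripts are spliced then reverse-complemented. Transcripts shorter
#' than 3 nt or with zero exons are rejected with a logged count.
#'
#' @param gtf_path Path to a GTF/GFF3 file.
#' @param fasta_path Path to a FASTA file (genome or transcripts).
#' @param strict Passed to [transcript_record()] CDS validation.
#' @return A `GenomeAnnotation`.
#' @export
load_annotation <- function(gtf_path, fasta_path, strict = FALSE) {
  fmt <- sniff_gff_format(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  tx_id <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else {
    p <- as.character(mc$Parent)
    sub("^transcript:", "", p)
  }
  gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else
    rep(NA_character_, length(gr))
  ftype <- as.character(mc$type)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  exon_idx <- which(ftype == "exon" & !is.na(tx_id))
  by_tx <- split(exon_idx, tx_id[exon_idx])
  tx_mode <- all(names(by_tx) %in% names(seqs))

  biotype_cols <- intersect(
    c("transcript_biotype", "gene_biotype", "transcript_type", "gene_type",
      "biotype", "tag"), names(mc))

  skipped <- 0L; missing_seq <- character()
  transcripts <- list()
  for (id in names(by_tx)) {
    rows <- by_tx[[id]]
    strand <- as.character(BiocGenerics::strand(gr[rows[1L]]))
    chrom <- as.character(GenomicRanges::seqnames(gr[rows[1L]]))
    ex <- cbind(BiocGenerics::start(gr[rows]) - 1L, BiocGenerics::end(gr[rows]))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]              # ascending genomic
    total_len <- sum(ex[, 2L] - ex[, 1L])
    if (nrow(ex) == 0L || total_len < 3L) { skipped <- skipped + 1L; next }
    if (tx_mode) {
      seq <- as.character(seqs[[id]])
      if (nchar(seq) != total_len) { skipped <- skipped + 1L; next }
    } else {
      if (!chrom %in% names(seqs)) { missing_seq <- c(missing_seq, id); next }
      chrseq <- seqs[[chrom]]
      seq <- paste(vapply(seq_len(nrow(ex)), function(i)
        as.character(Biostrings::subseq(chrseq, ex[i, 1L] + 1L, ex[i, 2L])),
        character(1)), collapse = "")
      if (strand == "-") seq <- revcomp_chr(seq)
    }
    # exon map in transcript order
    ex_tx <- if (strand == "+") ex else ex[rev(seq_len(nrow(ex))), , drop = FALSE]

    tags <- character()
    for (col in biotype_cols) {
      v <- mc[[col]][rows]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      tags <- c(tags, as.character(v))
    }
    tags <- unique(tags[!is.na(tags)])

    rec <- transcript_record(id, gene_id[rows[1L]], chrom, strand, ex_tx, seq,
                             biotype_tags = tags)

    # CDS from start_codon/stop_codon features, else CDS features
    tx_rows_all <- which(tx_id == id)
    cds <- NULL
    five_most <- function(rr) {       # genomic coord of 5'-most base
      if (strand == "+") min(BiocGenerics::start(gr[rr])) - 1L
      else max(BiocGenerics::end(gr[rr])) - 1L
    }
    sc <- tx_rows_all[ftype[tx_rows_all] == "start_codon"]
    cd <- tx_rows_all[ftype[tx_rows_all] == "CDS"]
    st <- tx_rows_all[ftype[tx_rows_all] == "stop_codon"]
    tis <- NULL
    if (length(sc)) tis <- genomic_to_transcript(rec, five_most(sc))
    else if (length(cd)) tis <- genomic_to_transcript(rec, five_most(cd))
    if (!is.null(tis)) {
      stopv <- NULL
      if (length(st)) stopv <- genomic_to_transcript(rec, five_most(st))
      else if (length(cd)) {
        three_most <- if (strand == "+") max(BiocGenerics::end(gr[cd])) - 1L
                      else min(BiocGenerics::start(gr[cd])) - 1L
        stopv <- genomic_to_transcript(rec, three_most) + 1L
      }
      if (!is.null(stopv)) cds <- list(tis_index = tis, stop_index = stopv)
    }
    if (!is.null(cds)) {
      rec <- transcript_record(id, gene_id[rows[1L]], chrom, strand, ex_tx, seq,
                               biotype_tags = tags, cds = cds, strict = strict)
    }
    transcripts[[length(transcripts) + 1L]] <- rec
  }
  if (length(missing_seq))
    stop("missing chromosome sequence for transcripts: ",
         paste(missing_seq, collapse = ","))
  if (skipped > 0L)
    rs_log(sprintf("skipped %d transcript(s) (zero exons, <3 nt, or length mismatch)",
                   skipped), level = "WARN")
  build_annotation(transcripts)
}
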