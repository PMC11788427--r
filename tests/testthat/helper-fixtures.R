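# Shared fixtures and independent oracles.

options(riboscope.quiet = TRUE)

# single-exon plus-strand transcript from a raw sequence
tx_simple <- function(seq, id = "T1", chrom = "chr1", strand = "+",
                      g0 = 100L, cds = NULL, tags = "protein_coding",
                      strict = FALSE) {
  transcript_record(id, paste0("G_", id), chrom, strand,
                    rbind(c(g0, g0 + nchar(seq))), seq,
                    biotype_tags = tags, cds = cds, strict = strict)
}

# annotation from a list of records
ann_of <- function(...) build_annotation(list(...))

# random sequence with a guaranteed ATG...stop ORF planted at tis
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# --- independent oracles ---------------------------------------------------

# brute-force first-in-frame-stop scan over a precomputed codon vector
oracle_first_stop <- function(seq, tis) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  p <- tis + 3L
  while (p + 3L <= n) {
    if (substr(seq, p + 1L, p + 3L) %in% stops) return(p)
    p <- p + 3L
  }
  NA_integer_
}

# all-pairs ROC AUC
oracle_roc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# average precision by explicit threshold sweep
oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# write a toy SAM file from read tuples
write_toy_sam <- function(path, reads, tx_lengths) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(tx_lengths), tx_lengths))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    flag <- if (!is.null(reads$flag)) reads$flag[i] else 0L
    sprintf("r%03d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
            i, flag, reads$tx[i], reads$pos[i] + 1L, reads$len[i],
            paste(rep("A", reads$len[i]), collapse = ""))
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# oracle per-position scorer: 1 at given TIS positions, 0 elsewhere
oracle_scores <- function(annotation, tis_map) {
  out <- list()
  for (id in names(annotation$transcripts)) {
    L <- nchar(annotation$transcripts[[id]]$sequence)
    s <- numeric(L)
    if (id %in% names(tis_map)) s[tis_map[[id]] + 1L] <- 1
    out[[id]] <- structure(list(transcript_id = id, scores = s),
                           class = "PositionScores")
  }
  out
}

# hand-written taxonomy edge-case table (built in code; used by the unit
# tests and the acceptance suite)
taxonomy_fixture <- function() {
  set.seed(61)
  host <- tx_simple(random_seq(120), id = "host", g0 = 1000L,
                    cds = list(tis_index = 30L, stop_index = 57L))
  l1 <- tx_simple(random_seq(100), id = "l1", g0 = 2000L, tags = "lncRNA")
  l2 <- tx_simple(random_seq(120), id = "l2", g0 = 1000L, tags = "lncRNA")
  l3 <- tx_simple(random_seq(100), id = "l3", g0 = 1010L, tags = "lncRNA")
  l4 <- tx_simple(random_seq(100), id = "l4", g0 = 1020L, tags = "lncRNA")
  plain <- tx_simple(random_seq(100), id = "plain", g0 = 3000L,
                     tags = "misc_RNA")
  ann <- ann_of(host, l1, l2, l3, l4, plain)
  cases <- rbind(
    # --- coding transcript (CDS [30,60)) ---
    data.frame(tx = "host", tis = 30L, stop = 57L, want = "annotated_CDS"),
    data.frame(tx = "host", tis = 24L, stop = 57L, want = "N_terminal_extension"),
    data.frame(tx = "host", tis = 21L, stop = 57L, want = "N_terminal_extension"),
    data.frame(tx = "host", tis = 36L, stop = 57L, want = "N_terminal_truncation"),
    data.frame(tx = "host", tis = 54L, stop = 57L, want = "N_terminal_truncation"),
    data.frame(tx = "host", tis = 0L,  stop = 24L, want = "uORF"),
    data.frame(tx = "host", tis = 6L,  stop = 18L, want = "uORF"),
    # uORF/uoORF boundary: stop codon's last base is tis-1 -> still uORF
    data.frame(tx = "host", tis = 0L,  stop = 27L, want = "uORF"),
    data.frame(tx = "host", tis = 5L,  stop = 26L, want = "uORF"),
    data.frame(tx = "host", tis = 10L, stop = 40L, want = "uoORF"),
    data.frame(tx = "host", tis = 11L, stop = 41L, want = "uoORF"),
    data.frame(tx = "host", tis = 29L, stop = 44L, want = "uoORF"),
    data.frame(tx = "host", tis = 28L, stop = 55L, want = "uoORF"),
    # in-frame upstream overlap without shared stop: no class fits
    data.frame(tx = "host", tis = 27L, stop = 45L, want = "other"),
    data.frame(tx = "host", tis = 31L, stop = 43L, want = "intORF"),
    data.frame(tx = "host", tis = 32L, stop = 47L, want = "intORF"),
    # in-frame nested without shared stop is NOT an intORF
    data.frame(tx = "host", tis = 33L, stop = 45L, want = "other"),
    data.frame(tx = "host", tis = 60L, stop = 75L, want = "dORF"),
    data.frame(tx = "host", tis = 63L, stop = 78L, want = "dORF"),
    data.frame(tx = "host", tis = 40L, stop = 61L, want = "doORF"),
    data.frame(tx = "host", tis = 41L, stop = 62L, want = "doORF"),
    # doORF needs the TIS strictly inside: at the CDS start it is not
    data.frame(tx = "host", tis = 30L, stop = 63L, want = "other"),
    # last base inside the CDS span still counts as inside
    data.frame(tx = "host", tis = 59L, stop = 71L, want = "doORF"),
    data.frame(tx = "host", tis = 60L, stop = 72L, want = "dORF"),
    # --- non-coding transcripts ---
    data.frame(tx = "l1", tis = 10L, stop = 40L, want = "lncRNA_ORF"),
    # shares the host CDS genomic start (1030): CDS_variant beats lncRNA tag
    data.frame(tx = "l2", tis = 30L, stop = 57L, want = "CDS_variant"),
    data.frame(tx = "l3", tis = 20L, stop = 47L, want = "CDS_variant"),
    # shares only the genomic stop site (1057)
    data.frame(tx = "l4", tis = 7L, stop = 37L, want = "CDS_variant"),
    data.frame(tx = "plain", tis = 10L, stop = 25L, want = "other"))
  list(ann = ann, cases = cases)
}
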