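test_that("GTF loading splices exons and maps coordinates on both strands", {
  dir <- withr::local_tempdir()
  # 50-nt chromosome; two-exon transcripts on + and - using exons
  # [10,20) and [30,40) (0-based half-open)
  set.seed(4)
  chrom <- random_seq(50)
  fa <- file.path(dir, "g.fa")
  writeLines(c(">c1", chrom), fa)
  gtf <- file.path(dir, "a.gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'
  attr2 <- 'gene_id "g2"; transcript_id "t2"; transcript_biotype "protein_coding";'
  writeLines(c(
    sprintf("c1\tsrc\texon\t11\t20\t.\t+\t.\t%s", attr1),
    sprintf("c1\tsrc\texon\t31\t40\t.\t+\t.\t%s", attr1),
    sprintf("c1\tsrc\texon\t11\t20\t.\t-\t.\t%s", attr2),
    sprintf("c1\tsrc\texon\t31\t40\t.\t-\t.\t%s", attr2)), gtf)
  ann <- load_annotation(gtf, fa)
  t1 <- ann$transcripts[["t1"]]; t2 <- ann$transcripts[["t2"]]
  expect_equal(nchar(t1$sequence), 20L)
  expect_equal(genomic_to_transcript(t1, 15L), 5L)
  expect_equal(transcript_to_genomic(t1, 15L), 35L)
  # minus strand: transcript position 0 is the 3'-most genomic base
  expect_equal(transcript_to_genomic(t2, 0L), 39L)
  expect_equal(t2$sequence,
               paste0(revcomp_chr(substr(chrom, 31, 40)),
                      revcomp_chr(substr(chrom, 11, 20))))
})

test_that("start_codon features set the CDS TIS through the exon map", {
  dir <- withr::local_tempdir()
  # force ATG at genomic [30,33) so tis lands at transcript position 10,
  # and TAA one codon later at genomic [39,42)
  chrom <- paste0(random_seq(30), "ATG", random_seq(6), "TAA", random_seq(8))
  fa <- file.path(dir, "g.fa"); writeLines(c(">c1", chrom), fa)
  a <- 'gene_id "g1"; transcript_id "t1";'
  gtf <- file.path(dir, "a.gtf")
  writeLines(c(
    sprintf("c1\tsrc\texon\t11\t20\t.\t+\t.\t%s", a),
    sprintf("c1\tsrc\texon\t31\t48\t.\t+\t.\t%s", a),
    sprintf("c1\tsrc\tstart_codon\t31\t33\t.\t+\t.\t%s", a),
    sprintf("c1\tsrc\tstop_codon\t40\t42\t.\t+\t.\t%s", a)), gtf)
  ann <- load_annotation(gtf, fa)
  expect_equal(ann$transcripts[["t1"]]$cds$tis_index, 10L)
  expect_equal(ann$transcripts[["t1"]]$cds$stop_index, 19L)
  expect_length(ann$transcripts[["t1"]]$cds_flags, 0L)
})

test_that("transcript_to_genomic handles single exons and rejects bad input", {
  tp <- tx_simple(random_seq(100), g0 = 100L)
  expect_equal(transcript_to_genomic(tp, 0L), 100L)
  tm <- tx_simple(random_seq(100), g0 = 100L, strand = "-")
  expect_equal(transcript_to_genomic(tm, 0L), 199L)
  expect_error(transcript_to_genomic(tp, 100L), "out of range")
  expect_error(transcript_to_genomic(tp, -1L), "out of range")
})

test_that("codon_at uppercases, maps U to T, and needs 3 bases", {
  t <- tx_simple("GGATGAA")
  expect_equal(codon_at(t, 2L), "ATG")
  t2 <- tx_simple("auggcc")
  expect_equal(codon_at(t2, 0L), "ATG")
  expect_error(codon_at(t, nchar(t$sequence) - 2L), "codon")
})

test_that("coordinate maps round-trip on every exonic base (property)", {
  set.seed(11)
  cfg <- simulation_config(seed = 21, n_transcripts = 30,
                           lncrna_fraction = 0.2, multi_exon_fraction = 0.6)
  sim <- simulate_transcriptome(cfg)
  for (t in sim$annotation$transcripts) {
    L <- nchar(t$sequence)
    pos <- unique(c(0L, L - 1L, sample.int(L, min(25L, L)) - 1L))
    g <- transcript_to_genomic(t, pos)
    expect_equal(genomic_to_transcript(t, g), pos)
  }
})

test_that("annotated CDSs contain no internal in-frame stop codon", {
  cfg <- simulation_config(seed = 22, n_transcripts = 40)
  sim <- simulate_transcriptome(cfg)
  n_checked <- 0L; clean <- TRUE
  for (t in sim$annotation$transcripts) {
    if (is.null(t$cds)) next
    for (p in seq.int(t$cds$tis_index, t$cds$stop_index - 3L, by = 3L))
      clean <- clean && !codon_at(t, p) %in% c("TAA", "TAG", "TGA")
    clean <- clean && codon_at(t, t$cds$stop_index) %in% c("TAA", "TAG", "TGA")
    n_checked <- n_checked + 1L
  }
  expect_true(clean)
  expect_gt(n_checked, 20L)
})

test_that("invalid CDS records are tagged by default and rejected when strict", {
  seq <- paste0(random_seq(12), "ATG", "AAACCC", "GGG", random_seq(9))  # no stop
  expect_error(tx_simple(seq, cds = list(tis_index = 12, stop_index = 21),
                         strict = TRUE), "invalid CDS")
  t <- transcript_record("t", "g", "c", "+", rbind(c(0, nchar(seq))), seq,
                         cds = list(tis_index = 12, stop_index = 21))
  expect_true("invalid_stop_codon" %in% t$cds_flags)
})

test_that("loading fails with transcript ids when a chromosome is missing", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); writeLines(c(">other", random_seq(50)), fa)
  gtf <- file.path(dir, "a.gtf")
  writeLines('c1\tsrc\texon\t1\t30\t.\t+\t.\tgene_id "g"; transcript_id "tX";',
             gtf)
  expect_error(load_annotation(gtf, fa), "tX")
})
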