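test_that("the generator is bitwise-reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 101, n_transcripts = 25, lncrna_fraction = 0.2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_transcriptome(cfg), d1)
  p2 <- write_simulation(simulate_transcriptome(cfg), d2)
  expect_identical(readLines(p1["fasta"]), readLines(p2["fasta"]))
  expect_identical(readLines(p1["gtf"]), readLines(p2["gtf"]))
  cfg2 <- simulation_config(seed = 102, n_transcripts = 25, lncrna_fraction = 0.2)
  p3 <- write_simulation(simulate_transcriptome(cfg2), withr::local_tempdir())
  expect_false(identical(readLines(p1["fasta"]), readLines(p3["fasta"])))
})

test_that("ncORF plant rates behave binomially", {
  cfg <- simulation_config(seed = 103, n_transcripts = 1000,
                           lncrna_fraction = 0,
                           ncorf_rates = c(uORF = 0.3, uoORF = 0, intORF = 0,
                                           dORF = 0, doORF = 0))
  sim <- simulate_transcriptome(cfg)
  n_u <- sum(sim$truth$orfs$class == "uORF")
  # 300 +- 3 binomial SDs (sd ~ 14.5); plant failures are rare but allowed
  expect_gt(n_u, 300 - 3 * sqrt(1000 * 0.3 * 0.7) - 10)
  expect_lt(n_u, 300 + 3 * sqrt(1000 * 0.3 * 0.7))
  # all ncORF rates zero: only CDS truth rows remain
  cfg0 <- simulation_config(seed = 104, n_transcripts = 50, lncrna_fraction = 0,
                            ncorf_rates = c(uORF = 0, uoORF = 0, intORF = 0,
                                            dORF = 0, doORF = 0))
  sim0 <- simulate_transcriptome(cfg0)
  expect_true(all(sim0$truth$orfs$class == "CDS"))
  expect_equal(nrow(sim0$truth$orfs), 50L)
})

test_that("planted ORFs have clean reading frames in the emitted sequence", {
  cfg <- simulation_config(seed = 105, n_transcripts = 150,
                           lncrna_fraction = 0.2,
                           ncorf_rates = c(uORF = 0.3, uoORF = 0.2,
                                           intORF = 0.2, dORF = 0.2,
                                           doORF = 0.2))
  sim <- simulate_transcriptome(cfg)
  orfs <- sim$truth$orfs[!sim$truth$orfs$ambiguous, ]
  ok_start <- logical(nrow(orfs)); ok_stop <- logical(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    t <- sim$annotation$transcripts[[orfs$transcript_id[i]]]
    ok_start[i] <- codon_at(t, orfs$tis_index[i]) == "ATG"
    # designated stop is the FIRST in-frame stop (greedy-scan consistency)
    ok_stop[i] <- identical(oracle_first_stop(t$sequence, orfs$tis_index[i]),
                            orfs$stop_index[i])
  }
  expect_true(all(ok_start))
  expect_true(all(ok_stop))
})

test_that("in-frame fidelity 1.0 with no background yields occupancy 1.0", {
  cfg <- simulation_config(seed = 106, n_transcripts = 20, lncrna_fraction = 0,
                           in_frame_prob = 1.0, background_rate = 0,
                           ncorf_rates = c(uORF = 0, uoORF = 0, intORF = 0,
                                           dORF = 0, doORF = 0))
  sim <- simulate_transcriptome(cfg)
  rr <- simulate_reads(sim$annotation, sim$truth, cfg)
  expect_equal(rr$profile$qc$in_frame_occupancy, 1.0)
})

test_that("TIS enrichment concentrates footprints around the TIS", {
  cfg <- simulation_config(seed = 107, n_transcripts = 60, lncrna_fraction = 0,
                           tis_enrichment = 10, background_rate = 0,
                           coverage = 4,
                           ncorf_rates = c(uORF = 0, uoORF = 0, intORF = 0,
                                           dORF = 0, doORF = 0))
  sim <- simulate_transcriptome(cfg)
  rr <- simulate_reads(sim$annotation, sim$truth, cfg)
  win <- 0; rest <- 0; win_n <- 0; rest_n <- 0
  for (id in names(rr$profile$matrices)) {
    t <- sim$annotation$transcripts[[id]]
    per_pos <- Matrix::rowSums(rr$profile$matrices[[id]]$counts)
    tis <- t$cds$tis_index; stp <- t$cds$stop_index
    idx <- seq.int(tis + 1L, stp)      # CDS body, 1-based
    inwin <- idx <= tis + 31L
    win <- win + sum(per_pos[idx[inwin]]); win_n <- win_n + sum(inwin)
    rest <- rest + sum(per_pos[idx[!inwin]]); rest_n <- rest_n + sum(!inwin)
  }
  ratio <- (win / win_n) / (rest / rest_n)
  expect_gt(ratio, 8); expect_lt(ratio, 12)   # 10 +- 20%
})

test_that("empty configurations are rejected", {
  expect_error(simulation_config(cds_codon_range = c(1L, 1L)), "at least 2 codons")
  cfg <- simulation_config(seed = 1, n_transcripts = 5, coverage = 0,
                           background_rate = 0)
  sim <- simulate_transcriptome(cfg)
  expect_error(simulate_reads(sim$annotation, sim$truth, cfg), "empty sample")
})

test_that("SAM round-trip: ingestion reproduces the truth matrices exactly", {
  cfg <- simulation_config(seed = 108, n_transcripts = 50,
                           lncrna_fraction = 0.15)
  sim <- simulate_transcriptome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  rr <- simulate_reads(sim$annotation, sim$truth, cfg,
                       sam_path = file.path(dir, "r.sam"))
  ann <- suppressWarnings(load_annotation(paths["gtf"], paths["fasta"]))
  prof <- ingest_alignments(file.path(dir, "r.sam"), ann)
  expect_equal(prof$qc$mapped_reads, nrow(rr$reads))
  expect_setequal(names(prof$matrices), names(rr$profile$matrices))
  for (id in names(prof$matrices))
    expect_equal(as.matrix(prof$matrices[[id]]$counts),
                 as.matrix(rr$profile$matrices[[id]]$counts))
  expect_equal(prof$qc$in_frame_occupancy,
               rr$profile$qc$in_frame_occupancy)
})
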