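test_that("construct_orf stops at the first in-frame stop codon", {
  t <- tx_simple("GGATGAAATAAGG")
  orf <- construct_orf(t, 2L)
  expect_equal(orf$stop_index, 8L)
  expect_equal(orf$start_codon, "ATG")
  expect_null(construct_orf(tx_simple("ATGAAA"), 0L))
})

test_that("construct_orf agrees with the brute-force codon-scan oracle", {
  set.seed(17)
  bad <- 0L
  for (i in 1:10) {
    seq <- random_seq(500)
    t <- tx_simple(seq)
    for (tis in 0:(nchar(seq) - 3L)) {
      got <- construct_orf(t, tis)
      want <- oracle_first_stop(seq, tis)
      ok <- if (is.na(want)) is.null(got) else
        (!is.null(got) && got$stop_index == want)
      bad <- bad + !ok
    }
  }
  expect_identical(bad, 0L)
})

test_that("neighborhood correction finds the nearest in-frame ATG, ties upstream", {
  # CTG at 12, ATG planted at 18 (downstream, 2 codons)
  seq1 <- paste0(strrep("C", 12), "CTGCCC", "ATG", strrep("C", 20))
  expect_equal(neighborhood_correct(tx_simple(seq1), 12L), 18L)
  # no ATG within 9 codons: unchanged
  seq2 <- paste0(strrep("C", 60), "CTG", strrep("C", 60))
  expect_equal(neighborhood_correct(tx_simple(seq2), 60L), 60L)
  # ATG at both tis-3 and tis+3: upstream wins
  seq3 <- paste0(strrep("C", 12), "ATG", "CTG", "ATG", strrep("C", 12))
  expect_equal(neighborhood_correct(tx_simple(seq3), 15L), 12L)
  # ATG candidates pass through unchanged; correction is idempotent
  expect_equal(neighborhood_correct(tx_simple(seq3), 12L), 12L)
  t1 <- tx_simple(seq1)
  once <- neighborhood_correct(t1, 12L)
  expect_equal(neighborhood_correct(t1, once), once)
})

test_that("filters enforce *TG starts and on-transcript stops", {
  keep <- apply_filters(list(start_codon = "CTG", stop_index = 30L))
  expect_true(keep$keep)
  expect_true(apply_filters(list(start_codon = "TTG", stop_index = 30L))$keep)
  drop1 <- apply_filters(list(start_codon = "ATA", stop_index = 30L))
  expect_false(drop1$keep); expect_equal(drop1$reason, "invalid_start_codon")
  drop2 <- apply_filters(NULL)
  expect_false(drop2$keep); expect_equal(drop2$reason, "no_stop_on_transcript")
})

test_that("call_orfs thresholds, corrects, filters, and dedups", {
  # ATG at 2 with TAA at 8: one real ORF
  t <- tx_simple(paste0("GG", "ATG", "AAA", "TAA", "GGGGG"), id = "t1")
  ann <- ann_of(t)
  sc <- oracle_scores(ann, list())
  sc[["t1"]]$scores[3] <- 0.2
  calls <- call_orfs(sc, ann, threshold = 0.15)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tis_index, 2L)
  expect_equal(calls$stop_index, 8L)
  # all scores at/below threshold: empty
  sc[["t1"]]$scores[] <- 0.15
  expect_equal(nrow(call_orfs(sc, ann)), 0L)
})

test_that("calling with an oracle scorer recovers planted truth perfectly", {
  cfg <- simulation_config(seed = 33, n_transcripts = 40, lncrna_fraction = 0,
                           ncorf_rates = c(uORF = 0.3, uoORF = 0, intORF = 0,
                                           dORF = 0.2, doORF = 0))
  sim <- simulate_transcriptome(cfg)
  truth <- sim$truth$orfs
  sc <- oracle_scores(sim$annotation, split(truth$tis_index, truth$transcript_id))
  calls <- call_orfs(sc, sim$annotation, threshold = 0.15, correct_codons = 0L)
  got <- paste(calls$transcript_id, calls$tis_index, calls$stop_index)
  want <- paste(truth$transcript_id, truth$tis_index, truth$stop_index)
  expect_setequal(got, want)   # recall 1.0 and precision 1.0
})

test_that("lowering the threshold is monotone in the number of calls", {
  set.seed(55)
  t <- tx_simple(random_seq(300), id = "t1")
  ann <- ann_of(t)
  sc <- list(t1 = structure(list(transcript_id = "t1", scores = runif(300)),
                            class = "PositionScores"))
  n_calls <- vapply(c(1.01, 0.8, 0.5, 0.2, 0.0),
                    function(th) nrow(call_orfs(sc, ann, threshold = th)),
                    numeric(1))
  expect_equal(n_calls[1], 0)
  expect_true(all(diff(n_calls) >= 0))
})

test_that("corrected calls keep the original score and coordinate", {
  # CTG at 9 scores 0.9; in-frame ATG at 15; shared downstream stop
  seq <- paste0(strrep("C", 9), "CTG", "CCC", "ATG", "CCC", "TAA", strrep("C", 9))
  t <- tx_simple(seq, id = "t1")
  ann <- ann_of(t)
  sc <- oracle_scores(ann, list())
  sc[["t1"]]$scores[10] <- 0.9
  calls <- call_orfs(sc, ann)
  expect_equal(calls$tis_index, 15L)
  expect_equal(calls$corrected_from, 9L)
  expect_equal(calls$score, 0.9)
  expect_equal(calls$start_codon, "ATG")
})

test_that("consensus keeps ORFs supported by enough samples", {
  base <- data.frame(transcript_id = "t1", tis_index = 10L, stop_index = 40L,
                     start_codon = "ATG", score = 0.5)
  rare <- data.frame(transcript_id = "t2", tis_index = 5L, stop_index = 20L,
                     start_codon = "ATG", score = 0.9)
  sets <- c(replicate(5, base, simplify = FALSE), list(rbind(base, rare)))
  cons <- consensus_calls(sets, min_samples = 2L)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$support, 6L)
  # identical replicates: consensus equals the single-sample set
  cons2 <- consensus_calls(replicate(6, base, simplify = FALSE), min_samples = 2L)
  expect_equal(cons2[, c("transcript_id", "tis_index", "stop_index")],
               base[, c("transcript_id", "tis_index", "stop_index")])
  expect_error(consensus_calls(list(base), min_samples = 2L), "min_samples")
})

test_that("emitted calls satisfy the OrfCall invariants (property)", {
  cfg <- simulation_config(seed = 44, n_transcripts = 25, lncrna_fraction = 0.2)
  sim <- simulate_transcriptome(cfg)
  set.seed(10)
  sc <- lapply(sim$annotation$transcripts, function(t)
    structure(list(transcript_id = t$transcript_id,
                   scores = runif(nchar(t$sequence))^3),
              class = "PositionScores"))
  calls <- call_orfs(sc, sim$annotation, threshold = 0.5)
  expect_gt(nrow(calls), 5)
  for (i in seq_len(nrow(calls))) {
    t <- sim$annotation$transcripts[[calls$transcript_id[i]]]
    span <- calls$stop_index[i] - calls$tis_index[i]
    expect_gt(span, 0)
    expect_equal(span %% 3L, 0)
    expect_true(codon_at(t, calls$stop_index[i]) %in% c("TAA", "TAG", "TGA"))
    expect_equal(codon_at(t, calls$tis_index[i]), calls$start_codon[i])
    expect_match(calls$start_codon[i], "^.TG$")
    expect_gt(calls$score[i], 0)
  }
  # dedup key is unique
  expect_false(anyDuplicated(paste(calls$transcript_id, calls$tis_index,
                                   calls$stop_index)) > 0)
})
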