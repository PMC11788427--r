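# Synthetic Ribo-Seq generator.
#
# Emits a transcriptome (GTF + genome FASTA) with planted canonical CDSs and
# non-canonical ORFs of every taxonomy class, plus transcript-space RPF
# alignments with configurable in-frame 5'-end fidelity, TIS-proximal
# footprint enrichment (HHT-like), and background noise — with full ground
# truth, so every downstream module is testable without any download.

BASES <- c("A", "C", "G", "T")

all_codons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  paste0(g[, 3], g[, 2], g[, 1])
}
NONSTOP_CODONS <- setdiff(all_codons(), c("TAA", "TAG", "TGA"))

random_bases <- function(n) sample(BASES, n, replace = TRUE)

#' Simulation configuration
#'
#' Defaults describe a desk-scale sample: unimodal footprint lengths with
#' mode 28 on support 26-32, in-frame 5'-end fidelity 0.6 (mid-range of
#' occupancies seen in real tissue data, 36-75%), mean coverage 2 reads per
#' CDS nt, no TIS enrichment (DMSO-like; homoharringtonine-like samples use
#' a multiplier much greater than 1), and modest background on untranslated
#' positions. ncORF plant rates weight uORFs most heavily, mirroring their
#' dominance among called ncORFs in real data.
#'
#' @param seed Integer seed; the generator is bitwise-reproducible given it.
#' @param n_chromosomes,n_transcripts Transcriptome size.
#' @param utr5_range,utr3_range 5'/3' UTR length ranges (nt).
#' @param cds_codon_range CDS length range in codons (incl. start + stop).
#' @param lncrna_fraction Fraction of transcripts that are lncRNAs.
#' @param ncorf_rates Named per-class plant probabilities on coding
#'   transcripts (`uORF`, `uoORF`, `intORF`, `dORF`, `doORF`).
#' @param lncorf_rate Probability a lncRNA transcript carries a planted ORF.
#' @param lnc_overlap_fraction Fraction of (non-variant) lncRNA ORFs whose
#'   TIS is placed inside an annotated CDS genomic interval.
#' @param cds_variant_fraction Fraction of lncRNA transcripts that are exact
#'   CDS-sharing isoforms (exercising the CDS-variant label).
#' @param multi_exon_fraction,minus_strand_fraction Structural fractions.
#' @param coverage Mean reads per CDS nt.
#' @param ncorf_coverage_mult Coverage multiplier for planted ncORFs.
#' @param in_frame_prob Probability a footprint 5'-end falls at its codon's
#'   frame-0 position.
#' @param read_length_probs Named probability vector over lengths 20-40.
#' @param tis_enrichment Footprint-density multiplier within
#'   `tis_window` nt of a TIS (1 = DMSO-like, >>1 = HHT-like).
#' @param tis_window Half-width of the enrichment window (nt).
#' @param background_rate Poisson mean of background reads per nt.
#' @param gap_range Intergenic gap range (nt).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              n_transcripts = 300L,
                              utr5_range = c(30L, 60L),
                              cds_codon_range = c(30L, 80L),
                              utr3_range = c(45L, 75L),
                              lncrna_fraction = 0.1,
                              ncorf_rates = c(uORF = 0.15, uoORF = 0.05,
                                              intORF = 0.05, dORF = 0.1,
                                              doORF = 0.05),
                              lncorf_rate = 0.6,
                              lnc_overlap_fraction = 0.25,
                              cds_variant_fraction = 0.05,
                              multi_exon_fraction = 0.3,
                              minus_strand_fraction = 0.4,
                              coverage = 2,
                              ncorf_coverage_mult = 0.5,
                              in_frame_prob = 0.6,
                              read_length_probs = NULL,
                              tis_enrichment = 1,
                              tis_window = 30L,
                              background_rate = 0.05,
                              gap_range = c(150L, 300L)) {
  if (is.null(read_length_probs)) {
    read_length_probs <- setNames(rep(0, N_RL), as.character(RL_MIN:RL_MAX))
    read_length_probs[as.character(26:32)] <-
      c(0.05, 0.15, 0.35, 0.20, 0.12, 0.08, 0.05)
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_transcripts = as.integer(n_transcripts),
              utr5_range = utr5_range, cds_codon_range = cds_codon_range,
              utr3_range = utr3_range, lncrna_fraction = lncrna_fraction,
              ncorf_rates = ncorf_rates, lncorf_rate = lncorf_rate,
              lnc_overlap_fraction = lnc_overlap_fraction,
              cds_variant_fraction = cds_variant_fraction,
              multi_exon_fraction = multi_exon_fraction,
              minus_strand_fraction = minus_strand_fraction,
              coverage = coverage, ncorf_coverage_mult = ncorf_coverage_mult,
              in_frame_prob = in_frame_prob,
              read_length_probs = read_length_probs / sum(read_length_probs),
              tis_enrichment = tis_enrichment, tis_window = as.integer(tis_window),
              background_rate = background_rate, gap_range = gap_range)
  stopifnot(cfg$in_frame_prob >= 0, cfg$in_frame_prob <= 1,
            all(cfg$ncorf_rates >= 0), cfg$coverage >= 0,
            cfg$background_rate >= 0, cfg$tis_enrichment >= 0)
  if (cfg$cds_codon_range[1] < 2L)
    stop("infeasible config: CDS must be at least 2 codons (6 nt)")
  structure(cfg, class = "SimulationConfig")
}

# -- sequence plumbing ------------------------------------------------------

seq_write_codon <- function(seqv, pos, codon) {
  seqv[(pos + 1L):(pos + 3L)] <- strsplit(codon, "")[[1]]
  seqv
}
seq_codon <- function(seqv, pos) paste(seqv[(pos + 1L):(pos + 3L)], collapse = "")

# Enforce, jointly, for a set of ORFs on one transcript: ATG at tis, a stop
# codon at stop, and no in-frame stop strictly between. Overlapping plants
# can invalidate each other, so repairs iterate to a fixed point; returns
# NULL if no fixed point is found (caller drops the plant).
repair_orfs <- function(seqv, orfs, max_iter = 80L) {
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (o in orfs) {
      if (seq_codon(seqv, o$tis) != "ATG") {
        seqv <- seq_write_codon(seqv, o$tis, "ATG"); changed <- TRUE
      }
      if (!is_stop_codon(seq_codon(seqv, o$stop))) {
        seqv <- seq_write_codon(seqv, o$stop, sample(STOP_CODONS, 1)); changed <- TRUE
      }
      if (o$stop - o$tis >= 6L) for (p in seq.int(o$tis + 3L, o$stop - 3L, by = 3L)) {
        if (is_stop_codon(seq_codon(seqv, p))) {
          seqv <- seq_write_codon(seqv, p, sample(NONSTOP_CODONS, 1)); changed <- TRUE
        }
      }
    }
    if (!changed) return(seqv)
  }
  NULL
}

# -- transcriptome simulation -----------------------------------------------

rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

make_coding_transcript <- function(cfg) {
  u5 <- rint(cfg$utr5_range)
  ncod <- rint(cfg$cds_codon_range)
  u3 <- rint(cfg$utr3_range)
  L <- u5 + 3L * ncod + u3
  seqv <- random_bases(L)
  tis <- u5; stopi <- u5 + 3L * (ncod - 1L)
  orfs <- list(list(class = "CDS", tis = tis, stop = stopi))

  for (cls in names(cfg$ncorf_rates)) {
    if (runif(1) >= cfg$ncorf_rates[[cls]]) next
    cand <- switch(cls,
      uORF = {
        # entirely within the 5'UTR: stop + 3 <= tis
        k <- 2L:5L; k <- k[tis - 3L * k - 3L >= 3L]
        if (!length(k)) NULL else {
          kk <- sample(rep(k, 2L), 1L)
          a_max <- tis - 3L * kk - 3L
          a <- rint(c(0L, a_max))
          list(class = "uORF", tis = a, stop = a + 3L * kk)
        }
      },
      uoORF = {
        # TIS in 5'UTR, out of CDS frame, stop inside the CDS span
        offs <- c(1L, 2L)
        a_cand <- tis - sample(offs, 1L) - 3L * rint(c(1L, max(1L, tis %/% 3L - 2L)))
        if (a_cand < 0L) NULL else {
          smax <- stopi - 3L
          s_cand <- a_cand + 3L * (((tis + 6L - a_cand) %/% 3L) + rint(c(1L, 4L)))
          if (s_cand > smax || s_cand <= tis) NULL else
            list(class = "uoORF", tis = a_cand, stop = s_cand)
        }
      },
      intORF = {
        # nested inside the CDS span, out of frame
        if (stopi - tis < 36L) NULL else {
          a <- tis + sample(c(1L, 2L), 1L) + 3L * rint(c(1L, 3L))
          s <- a + 3L * rint(c(3L, max(3L, (stopi - 6L - a) %/% 3L)))
          if (s > stopi - 3L || s + 3L > stopi + 3L) NULL else
            list(class = "intORF", tis = a, stop = s)
        }
      },
      dORF = {
        # entirely 3' of the CDS
        a0 <- stopi + 3L + rint(c(2L, 8L))
        k <- (L - 6L - a0) %/% 3L
        if (k < 2L) NULL else {
          s <- a0 + 3L * rint(c(2L, min(k, 6L)))
          list(class = "dORF", tis = a0, stop = s)
        }
      },
      doORF = {
        # TIS strictly inside the CDS span, out of frame, stop 3' of the CDS
        a <- stopi - sample(c(1L, 2L), 1L) - 3L * rint(c(1L, 4L))
        if (a <= tis) NULL else {
          s <- a + 3L * (((stopi + 3L - a) %/% 3L) + rint(c(1L, 3L)))
          if (s + 3L > L || s <= stopi) NULL else
            list(class = "doORF", tis = a, stop = s)
        }
      })
    if (is.null(cand)) next
    # frame sanity for out-of-frame classes
    if (cand$class %in% c("uoORF", "intORF", "doORF") &&
        (cand$tis - tis) %% 3L == 0L) next
    if ((cand$stop - cand$tis) %% 3L != 0L || cand$stop <= cand$tis) next
    trial <- repair_orfs(seqv, c(orfs, list(cand)))
    if (!is.null(trial)) { seqv <- trial; orfs <- c(orfs, list(cand)) }
  }
  seqv <- repair_orfs(seqv, orfs)
  if (is.null(seqv)) return(make_coding_transcript(cfg))  # vanishing probability
  list(seqv = seqv, orfs = orfs, cds = list(tis_index = tis, stop_index = stopi))
}

#' Simulate a transcriptome with planted ORF ground truth
#'
#' Generates random transcripts with planted canonical CDSs and ncORFs of
#' each taxonomy class, lays them out on synthetic chromosomes (with a
#' configurable fraction of minus-strand and two-exon structures), plants
#' lncRNA transcripts including CDS-sharing isoforms (CDS-variant plants)
#' and lncRNA ORFs whose TISs overlap coding sequence, and guarantees that
#' no planted ORF contains an in-frame stop before its designated stop.
#'
#' @param config A [simulation_config()].
#' @return A list with `annotation` (a `GenomeAnnotation`), `truth` (a
#'   `SimulationTruth`: `orfs` data.table with planted classes and
#'   coordinates, plus the config), and `chrom_seqs` (named character vector
#'   of chromosome sequences).
#' @export
simulate_transcriptome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n_lnc <- round(cfg$n_transcripts * cfg$lncrna_fraction)
  n_cod <- cfg$n_transcripts - n_lnc
  chroms <- paste0("chrS", seq_len(cfg$n_chromosomes))

  cursor <- setNames(rep(1L, cfg$n_chromosomes), chroms)  # 0-based next free
  cursor[] <- 0L
  writes <- list()   # per chromosome: list of (start, bases)
  for (ch in chroms) writes[[ch]] <- list()
  records <- list(); truth_rows <- list()
  hosts <- list()    # single-exon plus-strand coding loci, for lnc plants

  add_truth <- function(id, cls, tis, stop, ambiguous = FALSE, tis_in_cds = NA) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      transcript_id = id, class = cls, tis_index = tis, stop_index = stop,
      ambiguous = ambiguous, tis_in_cds = tis_in_cds)
  }

  for (i in seq_len(n_cod)) {
    ch <- chroms[(i - 1L) %% cfg$n_chromosomes + 1L]
    ct <- make_coding_transcript(cfg)
    L <- length(ct$seqv)
    strand <- if (runif(1) < cfg$minus_strand_fraction) "-" else "+"
    two_exon <- runif(1) < cfg$multi_exon_fraction
    g0 <- cursor[[ch]]
    S <- paste(ct$seqv, collapse = "")
    if (two_exon) {
      sp <- rint(c(20L, L - 20L)); il <- rint(c(30L, 100L))
      s1 <- substr(S, 1L, sp); s2 <- substr(S, sp + 1L, L)
      if (strand == "+") {
        writes[[ch]] <- c(writes[[ch]], list(list(g0, s1), list(g0 + sp + il, s2)))
        exons <- rbind(c(g0, g0 + sp), c(g0 + sp + il, g0 + sp + il + (L - sp)))
      } else {
        e2 <- L - sp
        writes[[ch]] <- c(writes[[ch]], list(list(g0, revcomp_chr(s2)),
                                             list(g0 + e2 + il, revcomp_chr(s1))))
        exons <- rbind(c(g0 + e2 + il, g0 + e2 + il + sp), c(g0, g0 + e2))
      }
      span <- L + il
    } else {
      writes[[ch]] <- c(writes[[ch]],
                        list(list(g0, if (strand == "+") S else revcomp_chr(S))))
      exons <- rbind(c(g0, g0 + L))
      span <- L
    }
    id <- sprintf("TX%04d", i)
    rec <- transcript_record(id, sprintf("G%04d", i), ch, strand, exons, S,
                             biotype_tags = "protein_coding", cds = ct$cds)
    records[[length(records) + 1L]] <- rec
    for (o in ct$orfs) add_truth(id, o$class, o$tis, o$stop)
    if (!two_exon && strand == "+")
      hosts[[length(hosts) + 1L]] <- list(id = id, chrom = ch, g0 = g0, L = L,
                                          cds = ct$cds)
    cursor[[ch]] <- g0 + span + rint(cfg$gap_range)
  }

  # materialize chromosomes (coding layer), leaving room for lncRNAs
  lnc_per_chrom <- table(factor(chroms[(seq_len(max(n_lnc, 1L)) - 1L) %%
                                         cfg$n_chromosomes + 1L], levels = chroms))
  chrom_seqs <- list()
  for (ch in chroms) {
    len <- cursor[[ch]] + (if (n_lnc > 0) lnc_per_chrom[[ch]] * 700L else 0L) + 500L
    v <- random_bases(len)
    for (w in writes[[ch]]) {
      b <- strsplit(w[[2]], "")[[1]]
      v[(w[[1]] + 1L):(w[[1]] + length(b))] <- b
    }
    chrom_seqs[[ch]] <- v
  }

  if (n_lnc > 0) for (j in seq_len(n_lnc)) {
    id <- sprintf("LNC%04d", j)
    kind <- if (length(hosts) && runif(1) < cfg$cds_variant_fraction) "variant"
            else if (length(hosts) && runif(1) < cfg$lnc_overlap_fraction) "overlap"
            else "intergenic"
    made <- FALSE
    if (kind == "variant") {
      h <- hosts[[sample.int(length(hosts), 1L)]]
      v <- chrom_seqs[[h$chrom]]
      S <- paste(v[(h$g0 + 1L):(h$g0 + h$L)], collapse = "")
      rec <- transcript_record(id, sprintf("GL%04d", j), h$chrom, "+",
                               rbind(c(h$g0, h$g0 + h$L)), S,
                               biotype_tags = "lncRNA")
      records[[length(records) + 1L]] <- rec
      add_truth(id, "CDS_variant", h$cds$tis_index, h$cds$stop_index,
                tis_in_cds = TRUE)
      made <- TRUE
    } else if (kind == "overlap" && runif(1) < cfg$lncorf_rate) {
      h <- hosts[[sample.int(length(hosts), 1L)]]
      v <- chrom_seqs[[h$chrom]]
      gs <- h$g0 + h$cds$tis_index; ge <- h$g0 + h$cds$stop_index + 3L
      cand <- integer()
      for (p in (gs + 1L):(ge - 3L))
        if (paste(v[(p + 1L):(p + 3L)], collapse = "") == "ATG")
          cand <- c(cand, p)
      cand <- cand[cand != gs]
      if (length(cand)) {
        g <- cand[sample.int(length(cand), 1L)]
        u5off <- rint(c(10L, 30L))
        l0 <- max(0L, g - u5off)
        l1 <- min(length(v), h$g0 + h$L + rint(c(50L, 80L)))
        S <- paste(v[(l0 + 1L):l1], collapse = "")
        a <- g - l0
        # first in-frame stop; if none, plant one in the free tail
        Llnc <- l1 - l0
        s <- NA_integer_
        p <- a + 3L
        while (p + 3L <= Llnc) {
          if (is_stop_codon(substr(S, p + 1L, p + 3L))) { s <- p; break }
          p <- p + 3L
        }
        if (is.na(s)) {
          tail_start <- h$g0 + h$L - l0
          p0 <- a + 3L * ceiling((tail_start - a) / 3)
          if (p0 + 3L <= Llnc) {
            stopc <- sample(STOP_CODONS, 1)
            v <- chrom_seqs[[h$chrom]]
            v[(l0 + p0 + 1L):(l0 + p0 + 3L)] <- strsplit(stopc, "")[[1]]
            chrom_seqs[[h$chrom]] <- v
            S <- paste(v[(l0 + 1L):l1], collapse = "")
            s <- p0
          }
        }
        if (!is.na(s)) {
          rec <- transcript_record(id, sprintf("GL%04d", j), h$chrom, "+",
                                   rbind(c(l0, l1)), S, biotype_tags = "lncRNA")
          records[[length(records) + 1L]] <- rec
          # ambiguous if the ORF happens to share a genomic start/stop site
          amb <- (l0 + s) == (h$g0 + h$cds$stop_index)
          add_truth(id, "lncRNA_ORF", a, s, ambiguous = amb, tis_in_cds = TRUE)
          made <- TRUE
        }
      }
    }
    if (!made) {  # intergenic lncRNA
      ch <- chroms[(j - 1L) %% cfg$n_chromosomes + 1L]
      Llnc <- rint(c(150L, 300L))
      g0 <- cursor[[ch]]
      v <- chrom_seqs[[ch]]
      if (g0 + Llnc + 10L > length(v)) { v <- c(v, random_bases(Llnc + 500L)) }
      seqv <- v[(g0 + 1L):(g0 + Llnc)]
      has_orf <- runif(1) < cfg$lncorf_rate
      orf <- NULL
      if (has_orf) {
        a <- rint(c(10L, 40L)); k <- rint(c(8L, min(25L, (Llnc - 6L - a) %/% 3L)))
        orf <- list(class = "lncRNA_ORF", tis = a, stop = a + 3L * k)
        seqv2 <- repair_orfs(seqv, list(orf))
        if (is.null(seqv2)) orf <- NULL else seqv <- seqv2
      }
      v[(g0 + 1L):(g0 + Llnc)] <- seqv
      chrom_seqs[[ch]] <- v
      S <- paste(seqv, collapse = "")
      rec <- transcript_record(id, sprintf("GL%04d", j), ch, "+",
                               rbind(c(g0, g0 + Llnc)), S, biotype_tags = "lncRNA")
      records[[length(records) + 1L]] <- rec
      if (!is.null(orf)) add_truth(id, "lncRNA_ORF", orf$tis, orf$stop,
                                   tis_in_cds = FALSE)
      cursor[[ch]] <- g0 + Llnc + rint(cfg$gap_range)
    }
  }

  truth <- structure(list(
    orfs = data.table::as.data.table(do.call(rbind, truth_rows)),
    config = cfg), class = "SimulationTruth")
  list(annotation = build_annotation(records), truth = truth,
       chrom_seqs = vapply(chrom_seqs, paste, character(1), collapse = ""))
}

#' Write a simulated transcriptome to GTF + FASTA (+ truth tables)
#'
#' @param sim Result of [simulate_transcriptome()].
#' @param dir Output directory.
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  seqs <- Biostrings::DNAStringSet(sim$chrom_seqs)
  Biostrings::writeXStringSet(seqs, fa, width = 70L)

  lines <- character()
  fmt_attr <- function(t) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
    t$gene_id, t$transcript_id,
    if ("lncRNA" %in% t$biotype_tags) "lncRNA" else "protein_coding",
    if ("lncRNA" %in% t$biotype_tags) "lncRNA" else "protein_coding")
  emit <- function(t, type, gr) {
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    sprintf("%s\triboscope_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            t$chromosome, type, st, en, t$strand, fmt_attr(t))
  }
  for (t in sim$annotation$transcripts) {
    ex_gr <- GenomicRanges::GRanges(t$chromosome,
                                    IRanges::IRanges(t$exons[, 1] + 1L, t$exons[, 2]),
                                    strand = t$strand)
    lines <- c(lines, emit(t, "exon", ex_gr))
    if (!is.null(t$cds)) {
      cds_gr <- transcript_interval_to_granges(t, t$cds$tis_index, t$cds$stop_index)
      sc_gr <- transcript_interval_to_granges(t, t$cds$tis_index, t$cds$tis_index + 3L)
      st_gr <- transcript_interval_to_granges(t, t$cds$stop_index, t$cds$stop_index + 3L)
      lines <- c(lines, emit(t, "CDS", cds_gr), emit(t, "start_codon", sc_gr),
                 emit(t, "stop_codon", st_gr))
    }
  }
  writeLines(lines, gtf)

  truth_tsv <- file.path(dir, "truth.tsv")
  write.table(sim$truth$orfs, truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(list(config = unclass(sim$truth$config),
                            orfs = sim$truth$orfs),
                       truth_json, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, gtf = gtf, truth_tsv = truth_tsv, truth_json = truth_json)
}

# -- read simulation --------------------------------------------------------

sample_read_lengths <- function(n, probs) {
  if (n == 0L) return(integer())
  as.integer(sample(as.integer(names(probs)), n, replace = TRUE, prob = probs))
}

#' Simulate ribosome-protected-fragment reads
#'
#' For each translated ORF (the CDS at full coverage; planted ncORFs at
#' `ncorf_coverage_mult` of it), footprint counts per codon are Poisson with
#' mean `3 * coverage`, multiplied by `tis_enrichment` within `tis_window`
#' nt of the TIS. Each footprint's 5'-end falls on the codon's frame-0
#' position with probability `in_frame_prob`, else uniformly on frame 1/2;
#' its length is drawn from the configured length distribution. Background
#' reads are added at every position at `background_rate`. Reads that would
#' run off the transcript 3' end are dropped. Ground truth records realized
#' placements, so ingestion can be checked for exact round-trip.
#'
#' @param annotation,truth From [simulate_transcriptome()].
#' @param config The same [simulation_config()].
#' @param sam_path Optional path; when given, sorted transcript-space SAM is
#'   written there.
#' @param seed Seed for read placement (default derived from `config$seed`).
#' @return A list with `profile` (a `SampleProfile` built from the internal
#'   truth matrices), `reads` (data.table of realized placements), and
#'   `sam_path` (or `NULL`).
#' @export
simulate_reads <- function(annotation, truth, config, sam_path = NULL,
                           seed = NULL) {
  cfg <- config
  if (cfg$coverage == 0 && cfg$background_rate == 0)
    stop("empty sample: zero coverage and zero background")
  set.seed(seed %||% derive_seed(cfg$seed, "reads"))
  out <- list()
  for (t in annotation$transcripts) {
    id <- t$transcript_id
    L <- transcript_length(t)
    orfs <- truth$orfs[truth$orfs$transcript_id == id, ]
    pos_all <- integer(); len_all <- integer()
    if (nrow(orfs)) for (k in seq_len(nrow(orfs))) {
      mult <- if (orfs$class[k] == "CDS") 1 else cfg$ncorf_coverage_mult
      if (mult == 0 || cfg$coverage == 0) next
      tis <- orfs$tis_index[k]; stp <- orfs$stop_index[k]
      codons <- seq.int(tis, stp - 3L, by = 3L)
      lam <- rep(3 * cfg$coverage * mult, length(codons))
      lam[codons <= tis + cfg$tis_window] <- lam[codons <= tis + cfg$tis_window] *
        cfg$tis_enrichment
      n <- rpois(length(codons), lam)
      if (sum(n) == 0L) next
      cpos <- rep(codons, n)
      inf <- runif(length(cpos)) < cfg$in_frame_prob
      off <- integer(length(cpos))
      off[!inf] <- sample(c(1L, 2L), sum(!inf), replace = TRUE)
      pos_all <- c(pos_all, cpos + off)
    }
    if (cfg$background_rate > 0) {
      nb <- rpois(L, cfg$background_rate)
      if (sum(nb) > 0L) pos_all <- c(pos_all, rep(seq_len(L) - 1L, nb))
    }
    if (!length(pos_all)) next
    len_all <- sample_read_lengths(length(pos_all), cfg$read_length_probs)
    fit <- pos_all + len_all <= L
    pos_all <- pos_all[fit]; len_all <- len_all[fit]
    if (!length(pos_all)) next
    out[[id]] <- data.table::data.table(tx = id, pos = pos_all, len = len_all)
  }
  reads <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(tx = character(), pos = integer(), len = integer())

  matrices <- list()
  for (id in unique(reads$tx)) {
    sub <- reads[reads$tx == id, ]
    agg <- sub[, .N, by = c("pos", "len")]
    matrices[[id]] <- read_count_matrix(
      id, transcript_length(annotation$transcripts[[id]]),
      pos = agg$pos, read_length = agg$len, count = agg$N)
  }
  profile <- structure(list(sample_id = "simulated", matrices = matrices,
                            qc = list(mapped_reads = nrow(reads))),
                       class = "SampleProfile")
  profile$qc$in_frame_occupancy <- in_frame_occupancy(profile, annotation)

  if (!is.null(sam_path)) {
    ord <- order(reads$tx, reads$pos)
    reads_s <- reads[ord, ]
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             vapply(annotation$transcripts, function(t)
               sprintf("@SQ\tSN:%s\tLN:%d", t$transcript_id,
                       transcript_length(t)), character(1)))
    seqs <- vapply(seq_len(nrow(reads_s)), function(i) {
      t <- annotation$transcripts[[reads_s$tx[i]]]
      substr(t$sequence, reads_s$pos[i] + 1L, reads_s$pos[i] + reads_s$len[i])
    }, character(1))
    body <- sprintf("sim%07d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                    seq_len(nrow(reads_s)), reads_s$tx, reads_s$pos + 1L,
                    reads_s$len, seqs)
    writeLines(c(hdr, body), sam_path)
  }
  list(profile = profile, reads = reads, sam_path = sam_path)
}
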