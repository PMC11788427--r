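# riboscope

Detection of translated open reading frames (ORFs) from ribosome profiling
data, for transcriptomics researchers who want ORF calls — canonical CDSs
and non-canonical uORFs, uoORFs, intORFs, dORFs, doORFs and lncRNA-ORFs —
directly from transcript-space alignments of ribosome-protected fragments
(RPFs).

## The method

Instead of offsetting reads to ribosome P/A-sites and testing pre-built
candidate ORFs, `riboscope` scores **every transcript position** for being
a translation initiation site (TIS) and constructs ORFs afterwards. The
only inputs per position are the RPF 5'-end count and the read-length
composition over lengths 20–40. Each position is embedded as

    e_c + e_l,   e_c = e ⊙ tanh(φ(c)),   e_l = Σᵢ Eᵢ lᵢ

where `c ∈ [0,1]` is the per-transcript max-normalized count, `φ` a small
feed-forward map, and `l` the length-fraction 21-vector. A small
transformer encoder (learned absolute positional encodings plus a learned
relative-position attention bias; exact or Performer-style kernel
attention) maps the embedded sequence to per-position TIS probabilities.
Two models are trained on non-overlapping chromosome folds so that every
transcript is scored by a model that never saw its chromosome. Candidate
TISs (score > 0.15) are corrected to nearby in-frame ATGs (≤ 9 codons,
ties upstream), extended greedily to the first in-frame stop, filtered to
N-T-G starts with an on-transcript stop, and labelled against the
annotation (annotated CDS, N-terminal extension/truncation, uORF, uoORF,
intORF, dORF, doORF, lncRNA-ORF, CDS variant, other).

A bundled synthetic Ribo-Seq generator plants ORFs of every class with
ground truth and emulates in-frame read fidelity (36–75% range seen in
real data), a unimodal footprint-length distribution (mode 28), TIS-window
footprint enrichment (homoharringtonine-like), and background noise — so
the whole pipeline is testable offline.

## Worked example

```r
library(riboscope)

# 1. simulate a small transcriptome + reads with known truth
cfg <- simulation_config(seed = 7, n_transcripts = 60, lncrna_fraction = 0.2,
                         coverage = 2, in_frame_prob = 0.6, tis_enrichment = 5)
sim <- simulate_transcriptome(cfg)
paths <- write_simulation(sim, "sim")                  # genome.fa, annotation.gtf
rr <- simulate_reads(sim$annotation, sim$truth, cfg,
                     sam_path = "sim/reads.sam")

# 2. ingest the alignments (5'-end position + read length only)
ann <- load_annotation(paths["gtf"], paths["fasta"])
prof <- ingest_alignments("sim/reads.sam", ann)
prof
#> SampleProfile reads.sam: 60 transcripts, 32055 mapped reads, in-frame occupancy 0.594

# 3. train the two fold models and score the transcriptome
alloc <- allocate_folds(ann$chromosomes, "custom", custom = list(
  list(train = "chrS1", val = "chrS2", test = c("chrS3", "chrS4")),
  list(train = "chrS3", val = "chrS4", test = c("chrS1", "chrS2"))))
fit <- train_supervised(prof, ann, alloc, train_config(seed = 1),
                        model_config(h = 32, n_layers = 4, n_heads = 2,
                                     max_transcript_length = 600))
scores <- predict_sample(prof, list(fit$model1, fit$model2), alloc, ann)

# 4. call and annotate ORFs
calls <- annotate_calls(call_orfs(scores, ann, threshold = 0.15), ann)
orf_type_counts(calls)
```

The in-frame occupancy printed in step 2 is the sample QC statistic
(fraction of CDS-internal reads whose 5'-end falls in the reading frame);
with `in_frame_prob = 0.6` and a little uniform background the measured
0.594 is the expected value. The call table in step 4 carries one
row per ORF (transcript, TIS, stop, start codon, score, taxonomy label,
correction provenance).

A command-line wrapper over the same stages is installed at
`inst/scripts/riboscope`:

```sh
Rscript inst/scripts/riboscope simulate --config run.yaml --seed 7 --out out/
```

with subcommands `simulate | ingest | pretrain | finetune | predict | call
| annotate | benchmark | quantify`.

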