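---
title: "Calling translated ORFs from ribosome profiling counts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling translated ORFs from ribosome profiling counts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribosome profiling (Ribo-Seq) sequences the ~26–32 nt mRNA fragments
protected by translating ribosomes. Classical ORF callers first offset each
read 5'-end to an estimated ribosome P/A-site (per read length), then test
candidate ORFs against curated features such as triplet periodicity. Both
steps are brittle: offsets are not deterministic per read length, and
feature-based tests lose power on samples with low in-frame read occupancy
and on short ORFs.

`riboscope` takes the alternative route: it keeps the raw data — for each
transcript position, the count of read 5'-ends at that position for each
read length 20–40 — and trains a small transformer encoder to emit, per
nucleotide position, the probability that the position is a translation
initiation site (TIS). ORFs are *constructed afterwards* from high-scoring
TISs by greedy extension to the first in-frame stop codon, so every
possible ORF on the transcriptome is implicitly scored. No nucleotide
sequence and no ORF-level features (start codon identity, length) enter the
model; sequence only enters post-processing.

## The model

Per transcript position the model receives two inputs. The total read count
is normalized per transcript by its maximum, `c ∈ [0,1]`, and embedded as
`e_c = e ⊙ tanh(φ(c))` where `φ` is a two-layer feed-forward map `R → R^h`
and `e` is a learned vector. The read-length composition enters as the
fraction vector `l` over the 21 lengths 20–40 and is embedded linearly,
`e_l = Σ_i E_i l_i` with `E ∈ R^{21×h}`; at read-free positions `l` is the
zero vector, the natural limit of the sum-to-one constraint. The position's
input embedding is `e_c + e_l`.

The sequence encoder is a pre-norm transformer (default: width `h = 32`,
4 layers, attention heads dividing `h`, feed-forward expansion 2) with a
single-logit head and logistic output. Attention is exact by default; a
Performer-style kernel approximation (positive orthogonal random features)
is available for long inputs where the `L × L` attention matrix is the
memory bottleneck. Because it approximates the plain softmax kernel, the
kernel path cannot carry the additive relative-position bias (below) and
ignores it; agreement between the two paths is therefore checked at
initialization, where the bias is zero. On short inputs with 256 random
features we observe a maximum per-position deviation of about 0.1–0.15 in
the sigmoid outputs and a mean deviation well under 0.05 (sharp softmax
rows are the known weak spot of the approximation); the configured
tolerance in the test suite is 0.2 maximum / 0.05 mean.

### Positional information

A full-scale training regime (hundreds of thousands of transcripts) can
afford to learn positional structure from data alone. At desk scale we
found that content-only attention with independently initialized absolute
positional encodings cannot learn *relative* patterns ("is there read
density just upstream of me?") from under a hundred training transcripts —
held-out precision plateaus far below the achievable value even though a
hand-built "count minus upstream maximum" feature separates TISs almost
perfectly. The encoder therefore adds a learned relative-position attention
bias (one scalar per layer, head, and clipped offset within ±32 nt) on top
of the learned absolute encodings. The bias costs ~65 parameters per head
and makes local-neighborhood attention learnable from the first epoch; the
absolute encodings remain and can be disabled for ablation
(`use_positional = FALSE`). The bias is initialized with structure rather
than zeros: heads start attending to local ±15 nt windows, alternating
between upstream and downstream across heads and layers, with distant
offsets disfavoured. This is an
inductive-bias initialization, fully trainable away; with zero init the
upstream/downstream comparison a TIS boundary requires takes over a
hundred desk-scale epochs to emerge, with the structured init held-out
PR AUC saturates within ten.

A related initialization choice: `φ`'s first layer starts as a spread of
tanh ramps over `c ∈ [0,1]` (slopes ~4, staggered offsets), a soft binning
of the count scale. With small random init, layer norm at the encoder input
almost erases count *magnitude*, which is the dominant signal; the ramp
basis keeps count differences directional.

## Training

Two models are trained on non-overlapping chromosome folds; each transcript
is scored only by the model whose held-out *test* fold contains its
chromosome, so combined predictions cover the transcriptome with no
train/test leakage (asserted by id-set audits in the tests). For human-style
annotations the built-in `human` scheme trains on chromosomes
{3,5,7,11,13,15,19,21,X} / {2,6,8,10,14,16,18,22,Y}, validates on {1,9,17}
/ {4,12,20}, and tests on the complements, with unplaced scaffolds joined
to the first model's test fold. Synthetic experiments use a 4-chromosome
custom allocation of the same shape.

Supervised training treats every annotated TIS as positive and every other
transcript position as negative — roughly a 1:250 imbalance at typical
transcript lengths. The binary cross-entropy uses a positive-class weight
defaulting to the per-batch negatives/positives ratio. Optimization is Adam
(default learning rate 1e-3, per-epoch decay 0.95, batches of a few
transcripts). Early stopping monitors the *validation PR AUC* rather than
the validation loss: at desk scale the weighted loss is dominated by a
handful of validation positives and fluctuates wildly while the ranking
quality improves monotonically, so loss-based selection reliably returns a
premature checkpoint. The loss is still logged per epoch.

Masked self-supervised pretraining replaces the inputs of a random 15% of
positions per transcript with a learned mask token and predicts per-length
read presence (a 21-wide binary head) at the masked positions only. "Read
presence" defaults to count ≥ 1; the stricter `≥ 2` reading is available as
`read_presence_threshold = 2`. Fine-tuning loads the pretrained encoder and
swaps the 21-wide head for a fresh 1-wide TIS head. Masked positions carry
no function of their true inputs — substituting random values at masked
positions leaves the forward pass bit-identical, which the tests assert.

## Post-processing

Positions scoring above 0.15 (strictly) become candidate TISs. Candidates
whose codon is not ATG are moved to the nearest in-frame ATG within 9
codons, ties broken upstream (yielding the longer ORF); the model's score
at the original position is retained as the call's evidence, along with
both coordinates. Each candidate is extended to the first in-frame stop
codon. Calls failing the N-T-G start pattern (ATG/CTG/GTG/TTG) or lacking
an on-transcript stop are dropped with recorded reasons. Calls are
deduplicated on (transcript, TIS, stop) keeping the maximum score;
multi-sample consensus keeps ORFs called in at least `min_samples` samples.
The threshold applies before correction, matching the stated processing
order; no minimum ORF length is imposed beyond start plus stop.

Each call is labelled against the annotation with the precedence:
annotated CDS; N-terminal extension/truncation (shared stop, in frame);
then on coding transcripts uORF, uoORF, intORF, dORF, doORF (overlap
measured against the CDS span `[tis, stop+3)` with half-open arithmetic;
internal and downstream-overlapping classes require a frame difference, and
the doORF TIS must lie strictly inside the CDS span); on non-coding
transcripts, CDS-variant (genomic start or stop shared with any annotated
CDS) takes precedence over lncRNA-ORF (lncRNA biotype tag), else "other".
An in-frame ORF nested in the CDS without the shared stop is "other" — the
internal-ORF class is reserved for out-of-frame calls.

## The synthetic generator

The generator emulates exactly the data features the model exploits, with
planted ground truth: random transcripts with 5'UTR/CDS/3'UTR structure
(optionally two exons and either strand), planted ncORFs of every taxonomy
class with repaired reading frames (ATG start, designated first in-frame
stop, no earlier in-frame stop), lncRNA transcripts including CDS-sharing
isoforms and ORFs whose TIS overlaps coding sequence, footprints attached
to the codons of translated ORFs with: configurable in-frame 5'-end
fidelity (default 0.6, mid-range of the 36–75% occupancies reported for
real tissue samples), a unimodal read-length distribution with mode 28 on
support 26–32, mean coverage in reads per CDS nt (default 2), a TIS
enrichment multiplier within ±30 nt (1 = DMSO-like, ≫1 =
homoharringtonine-like), and Poisson background on all positions. The
emitted SAM/FASTA/GTF round-trip exactly: ingesting the alignments
reproduces the generator's internal count matrices bit for bit.

What the generator does *not* model — sequencing error, rRNA contamination,
multimapping ambiguity, UMI duplication, isoform sharing of genomic
regions, non-Poisson overdispersion, codon-level pausing structure — bounds
what passing tests can show: they validate the statistical machinery and
the post-processing rules, not performance on real libraries.

### Experiment sizes and defaults

The parameter-recovery experiments use 300 transcripts over 4 synthetic
chromosomes (75 per fold role), 5'UTRs of 24–45 nt, CDSs of 25–55 codons,
3'UTRs of 36–60 nt, coverage 2 reads per CDS nt, in-frame fidelity 0.6, TIS
enrichment 5, background 0.05 reads/nt. ncORF plant rates are zero in these
runs: supervised labels are annotated TISs only, so planted translated
ncORFs would be genuine signal labelled negative and would contaminate the
measured precision. The encoder is h = 32, 4 layers, 2 heads, exact
attention, trained up to 10 epochs (batch 4, learning-rate decay 0.93,
patience 3 on validation PR AUC). The robustness experiments vary in-frame fidelity over {0.4, 0.6,
0.75} at fixed depth and reduce coverage tenfold at fixed fidelity — the
expected direction, mirroring observations on real samples, is that
fidelity moves held-out PR AUC weakly while depth moves it strongly.
Default ncORF rates elsewhere weight uORFs most heavily (uORFs dominate
ncORF calls on real data), and the default lncRNA TIS-overlap fraction is
0.25, matching the reported ~25% of called lncRNA-ORFs whose TISs overlap
coding sequence.

## Numerical notes

- All gradients of the hand-written backward pass are verified against
  central finite differences to 1e-4 relative error in the test suite (the
  key-projection bias has an exactly-zero gradient by softmax shift
  invariance and is excluded from relative comparison).
- Logistic losses use the softplus form with clipping at 30 to avoid
  overflow; layer norm uses eps = 1e-5.
- Count normalization divides by the per-transcript maximum; a read-free
  transcript yields all-zero inputs, which are valid (the model scores
  them, typically near the base rate).
- Transcripts longer than `max_transcript_length` are scored in overlapping
  chunks (overlap 64 nt, centers kept) when `chunk_overlong = TRUE`,
  otherwise raise an error; they are never silently truncated.
- The read-length embedding matrix has exactly 21 rows, one per length in
  the closed range 20-40; formulations that write the range half-open
  ("20 to 41") or sum 22 terms are read as the same 21 lengths, and lengths
  outside the range are excluded at ingestion.
- Ties in ATG neighborhood correction break upstream; dedup keeps the
  maximum score; ORF keys are (transcript, TIS, stop).
- Seeds fan out from one global seed through a fixed affine map
  (`derive_seed`), so each pipeline stage is independently reproducible and
  two runs with the same seed produce byte-identical simulator output.

## Known limitations

- The desk-scale training recipe is tuned for the bundled simulator; real
  libraries need the full-scale regime (hundreds of thousands of
  transcripts, GPU training) that this package does not attempt.
- The kernel-attention path is inference-only and ignores the
  relative-position bias.
- No isoform collapsing across transcripts sharing genomic regions; NMD /
  retained-intron transcripts are tagged at load but not excluded.
- TPM quantification attributes reads to ORFs by 5'-end containment only;
  overlapping ORFs double-count reads.
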