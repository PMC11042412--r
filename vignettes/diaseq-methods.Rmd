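---
title: "diaseq: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diaseq: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(diaseq)
```

## The sequencing problem in DIA

Data-independent acquisition fragments all precursors inside sliding
isolation windows, so an MS2 scan mixes the b/y-family fragments of every
peptide co-isolated in its window.  De novo sequencing must therefore both
*read* a mass ladder (successive prefix masses differing by residue
masses) and *attribute* fragments to the right precursor.  diaseq couples
three sources of evidence per precursor feature: its elution profile (five
(intensity, RT) points nearest the retention-time apex), five binned MS2
spectra from its window and RT range, and the nearest MS1 scan.

## Data model and discretization

MS2 spectra are discretized to fixed-length vectors: bin index
`floor(mz / w)` with `w = 0.01` Da and `L = 150000` bins (so m/z 0–1500).
The printed model size fixes `w * L`; the split into width and ceiling is
our inference and both stay configurable.  Colliding peaks aggregate by
**max**, preserving the dominant fragment against noise splatter, and each
spectrum is divided by its own maximum ("normalized matrix"
underspecified; per-spectrum max gives run-scale invariance).  Isolation
windows are half-open `[low, high)` so a boundary m/z belongs to exactly
one window; RT-proximity ties break by ascending scan id; shortages (< 5
qualifying spectra, < 5 profile points) are closed by zero pads so every
context has identical shapes.

## The product-ion array

For decoding position *t*, candidate residue *a*, ion type *k* and
spectrum *s*, the theoretical fragment m/z of the cut at
`prefix_mass + mass(a)` is located on the bin grid and a 10-bin window
around it extracted: offsets cover `[center-5, center+4]` (a size-10
window cannot be symmetric; left-heavy is fixed and documented — the
center bin sits at 0-based offset 5).  The per-feature slice has shape
`(V, 8, 5, 10)`.  `V = 26` reconciles the published 26-slot candidate
axis with the 20-residue vocabulary: 20 residues (C carries the fixed
carbamidomethyl +57.02146 Da; no variable modifications), start/stop/pad,
and 3 reserved slots.  Massless slots and out-of-range ions contribute
zeros rather than masks, keeping the array dense and shape-stable.  A
prefix already heavier than the precursor's residue budget yields an
all-zero, flagged slice — termination support for the decoder.  Slices
are built lazily per position; the full `(positions, V, 8, 5, 10)` array
never materializes.

## Spectrum encoder and fusion

MS1 peaks embed as a fixed sinusoid of m/z (wavelengths geometrically
spaced 0.001–10,000 Da, so both sub-Dalton offsets and whole-peptide
differences are resolvable) plus a learned linear map of intensity.  The
profile maps 2 → d with one linear layer; the ion-array slice is
flattened, zero-padded to 64 equal chunks and mapped chunk → d (shapes
(5, 512) and (64, 512) at the published d = 512).

Three fusion mechanisms feed the transformer encoder:

* **concat** — streams appended, with a learned marker vector per stream
  (the sources are otherwise indistinguishable after projection; the
  reference description is silent here).  `concat_no_ms1` drops the MS1
  stream, isolating its contribution.
* **attention** — scores `e[t,i] = q_t · tanh(W_c h_i)`, softmax weights,
  context `c_t = Σ_i att[t,i] h_i`.  Roles are not assigned by the
  reference description; we take queries from the ion-array stream
  attending over MS1 + profile, and output `q_t + c_t` (a residual, so
  the position-specific ion evidence itself is never lost — with the
  pure context, `W_c = 0` would collapse all positions to one vector).
* **multihead** — standard concat-heads-then-project multi-head scaled
  dot-product attention, ion tokens as queries over all three streams,
  residual added.  The published combination formula (a sum of per-head
  outputs through per-head output matrices) conflicts with the
  accompanying text ("concatenating the outputs from all attention
  heads"); we implement the standard concatenate-then-project form.  The
  equation labelled as the concatenation step prints the per-head
  softmax attention; we read it as the per-head definition and guess no
  further.

## Decoder, training, inference

The decoder input at position 0 is the start-token embedding plus a
sinusoidal precursor embedding (sinusoid of neutral mass + sinusoid of
the integer charge, summed — pure sinusoids, no learned charge table).
Residue positions use a learned token embedding plus
sinusoidal position encoding.  Layers are pre-norm transformer blocks;
causal self-attention over the prefix; cross-attention at position *t*
attends the encoder memory built from the ion-array slice of *its own*
prefix mass — so the encoder runs once per position, and a teacher-forced
full pass is exactly equivalent to step-by-step decoding (tested to
1e-5).  During decoding, encoder memories are memoized by prefix mass, so
beam hypotheses sharing a mass reuse them.

Training minimizes token-level cross-entropy with teacher forcing.  The
output head starts at zero, so the initial loss is exactly log V.  The
optimizer is Adam (unstated in the reference; the printed learning rate
5e-4 is the paper-preset default) with linear warm-up — needed for
transformer stability and documented as an addition.  Depth is unstated;
the paper preset uses 9 + 9 layers at d = 512 with 8 heads (the lineage
this model extends), batch 32.  Data splits are peptide-level at
0.9/0.05/0.05 (the two printed variants conflict; the consistent one is
the default, the ratio is configurable), so no sequence is shared across
partitions.

Beam search keeps the k = 20 best hypotheses by cumulative
log-probability.  The precursor-mass constraint acts twice: branches
whose running residue mass exceeds the budget plus tolerance are pruned
during expansion (an efficiency reading of "terminates candidates"), and
stop-token hypotheses survive only if the full peptide mass is within the
tolerance on *both* sides (the low side is not addressed in the
reference; we filter symmetrically).  The default tolerance is 0.1 Da
absolute (unstated; ppm mode available).  Confidence is the mean
per-residue log-probability (formula unstated; the sum is available
behind a flag); equal scores order lexicographically for determinism.
Stop tokens compete for beam slots, which makes beam width 1 exactly
greedy decoding.

## Evaluation metrics

The one-sentence matching rule is operationalized as the mass-ladder
alignment standard in this lineage: walk both cumulative-mass ladders
left to right; residues match when prefix masses differ by < 0.5 Da and
residue masses by < 0.1 Da; on a failed residue check the lighter ladder
advances.  Because 0.5 Da is far below the smallest residue (57 Da), the
greedy walk is provably optimal; an exhaustive dynamic-programming oracle
confirms it on all short pairs.  A peptide is fully correct when every
residue matches and lengths are equal — Leu/Ile substitutions therefore
count as correct.  Precision–coverage curves rank predictions by
confidence (stable tie-break by feature id); AUC integrates by trapezoid
to the achieved maximum coverage, never extrapolated to 1.  Coverage
counts features, one prediction each.

## The synthetic-DIA generator

The simulator is the test bed standing in for real multiplexed runs.
Defaults: 12 m/z windows, co-isolation depth 3 (window-mates grouped into
clusters sharing an elution apex, so their fragments genuinely
multiplex), Gaussian elution with sigma = 6 s sampled on a 3 s cycle over
a 300 s gradient, amplitudes log-uniform over a 100-fold dynamic range,
50 uniform noise peaks per MS2 scan, per-scan fragment detection
probability 0.9, fragments at exact theoretical m/z (an optional jitter
sigma stresses the binning tolerance).  Clusters of the same window are
spread across the gradient; with a gradient long enough that each cluster
gets a slot of at least ~7 sigma, distinct clusters never co-elute, which
the depth-1 tests rely on.  A reduced 5-residue alphabet (G, A, S, P, V —
pairwise gaps > 1 Da) supports fast, isobaric-free overfit tests.

Ion-type intensities are b/y-**asymmetric** (y stronger, as in HCD
fragmentation): this is not cosmetic.  With symmetric weights, the
alphabet admits exact mirror degeneracies — e.g. S+2A and P+2G+H₂O share
an elemental composition — under which a reversed-ladder reading of a
peptide produces *identical* evidence to the true reading and no method
could separate them.  The asymmetry is both the realistic choice and the
physical basis on which forward readings win.

What the simulator does **not** emulate: learned intensity patterns,
retention-time prediction, isotope envelopes, chromatographic peak shapes
beyond a Gaussian, charge > 2 fragments, or real instrument noise
structure.  Tests passing on simulator output therefore validate the
pipeline's *mechanics* (mass arithmetic, geometry, learning machinery,
decoding semantics) — they do not certify accuracy on real DIA data,
which requires training at full scale on annotated runs.

## The model-free ladder readout

`ladder_readout()` is a sanity oracle requiring no trained model: at each
teacher-forced position it scores candidates by their ion-array window
intensity and takes the argmax.  Three refinements, all deterministic:
windows are weighted toward the center bin (a correct candidate's
fragment falls exactly there; near-miss mirror evidence lands a bin or
two off); ion types are weighted by the expected intensity template (a
matched filter — by the AM–GM inequality a mirrored reading, which sees
strong-y evidence in its b window and weak-b evidence in its y window,
scores strictly below the true reading); exact residual ties look one
rung ahead (the true ladder has a planted continuation); and the final
rung — whose cleavage has no interior fragment at all — is read from mass
closure, the only candidate completing the precursor's residue budget.

The readout is evaluated on noise-free, *singly-isolated* runs: it
validates that binning, feature assembly and ion-array windows are
geometrically consistent end to end.  It is deliberately not asked to
separate co-isolated precursors of very different abundance — a naive
intensity argmax cannot, and that separation is precisely the learned
model's job.  On multiplexed depth-3 runs, a weaker property is tested
instead: the true candidate's b and y windows contain planted intensity
at the center offset at virtually every position.

## Problem sizes and numerical choices

The test and demonstration configuration ("tiny" preset) is d = 64, 4
heads, 2 encoder + 2 decoder layers, feed-forward 128, 16 ion tokens,
batch 8, Adam at 1e-3 with 20 warm-up steps — sized so that the full
suite, including training a model to 100% training-set peptide accuracy
on 32 noise-free simulated features (reached around epoch 50) and the
exhaustive metric oracles, completes in a few minutes on one CPU.  The
learning-rate and batch choices are convergence choices for this model
size; the paper preset keeps the published values.  Layer normalization
uses eps = 1e-5; softmax subtracts row maxima; the greedy-accuracy
early-stop check runs every 10 epochs; all seeds (parameter
initialization, data order, simulation) are explicit arguments.

## Known limitations

* No GPU path and no minibatch parallelism: training beyond a few
  thousand features is impractical in this implementation.
* The paper-scale preset (9 + 9 layers, d = 512) is provided and
  shape-tested but not trained here; published benchmark-scale accuracy
  is out of reach without the original data and hardware.
* mzML input is not implemented; MGF (plus the feature CSV) is the
  canonical interchange format behind the reader contract.
* Fragment charges > 2, internal fragments, a/c/x/z ions and variable
  modifications are out of scope by design.
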