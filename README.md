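# diaseq

De novo peptide sequencing for data-independent acquisition (DIA) tandem
mass spectrometry, in R.

## The problem

In DIA, the mass spectrometer fragments *every* precursor ion inside
sliding isolation windows (e.g. 12 m/z wide), so each MS2 scan is a
multiplex of fragment ions from several co-isolated peptides.  That makes
DIA quantitatively reproducible — and makes de novo sequencing (reading a
peptide's residue sequence directly off its fragment spectrum, with no
sequence database) much harder than in data-dependent acquisition, where
each MS2 scan belongs to one precursor.

diaseq is for computational proteomics researchers who want a fully
inspectable, dependency-light implementation of attention-based DIA
sequencing: every stage — feature assembly, ion-array construction, the
transformer, beam search, evaluation — is plain R matrix code with tests,
plus a synthetic-DIA simulator so the whole pipeline runs and is verified
without any external data or GPUs.

## The model

For each detected precursor feature (m/z, charge z, retention-time center,
elution profile), three inputs are assembled:

* the **precursor profile** — the 5 (intensity, RT) samples nearest the RT
  center;
* **5 MS2 spectra** whose isolation window covers the feature m/z and whose
  RT is nearest the center, each discretized into a 150,000-bin intensity
  vector (0.01 Da bins, max-aggregated, per-spectrum max-normalized);
* the **MS1 scan** nearest the RT center, each peak embedded as
  sinusoid(m/z) + linear(intensity).

At decoding position *t* with prefix mass *m(prefix)*, the **product-ion
array** locates, for every candidate residue *a* and each of the 8 ion
types b, y, b²⁺, y²⁺, b−H₂O, y−H₂O, b−NH₃, y−NH₃, the theoretical
fragment of the cut at *m(prefix) + m(a)*:

    mz(b-family) = (m_prefix − loss + z·m_H⁺) / z
    mz(y-family) = (M_residues − m_prefix + m_H₂O − loss + z·m_H⁺) / z

and extracts a 10-bin intensity window around its bin in each of the 5
spectra, giving a (V=26, 8, 5, 10) array per position.  The three embedded
streams are fused by one of three mechanisms before the transformer
encoder:

* **concatenation** (with learned stream markers), optionally without the
  MS1 stream;
* **standard attention**: scores e₍t,i₎ = qₜ · tanh(W_c hᵢ), weights
  attₜ = softmax(eₜ), context cₜ = Σᵢ att₍t,i₎ hᵢ;
* **multi-head attention**: per head softmax(QWᵢᵠ (KWᵢᴷ)ᵀ/√d_k)·VWᵢⱽ,
  heads concatenated and projected.

A transformer decoder (causal self-attention over the residue prefix +
sinusoidal precursor (mass, charge) embedding, cross-attention over the
encoder memory) emits next-residue logits.  Beam search (default width 20)
expands the top-k hypotheses by cumulative log-probability, terminates
branches whose running residue mass exceeds the precursor budget plus the
tolerance (default 0.1 Da), accepts a hypothesis at the stop token only if
its full peptide mass matches the precursor neutral mass, and ranks
finished peptides by mean per-residue log-probability.

Evaluation follows the mass-ladder convention: a predicted residue matches
a truth residue when their cumulative prefix masses differ by < 0.5 Da and
their residue masses by < 0.1 Da (so Leu/Ile count as correct); amino-acid
precision/recall, peptide precision, and confidence-ranked
precision–coverage curves with AUC are reported.

## Worked example

```r
library(diaseq)

cfg <- sim_config(seed = 42, n_peptides = 8, length_range = c(7, 10),
                  alphabet = "reduced", noise_peaks = 0, detect_prob = 1,
                  co_isolation_depth = 1, rt_span = 400)
sim  <- simulate_dataset(cfg, dir = "demo")
ctxs <- sim_contexts(sim)
print(ctxs[[1]])

hits <- unlist(lapply(ctxs, ladder_readout, table = sim$table))
cat(sprintf("ladder readout: %d/%d residues recovered (%.1f%%)\n",
            sum(hits), length(hits), 100 * mean(hits)))

match_residues(residue_table(), "LES", "IES")
```

prints

```
feature_context F001: mass 541.2860 (z=3), 6 MS1 peaks, MS2 stack 5 x 150000
ladder readout: 64/64 residues recovered (100.0%)
[1] 3
```

The simulator wrote a labelled DIA run (134 MS1 + 804 MS2 scans as MGF, a
feature CSV, a manifest).  The assembled context for the first feature has
the model's input shapes; the model-free mass-ladder readout — score each
candidate residue by its matched-filter ion-window intensity — recovers all
64 residues on this clean run, confirming that binning, assembly and
ion-array geometry are consistent.  `match_residues` returns 3 because
Leu→Ile is mass-equivalent.  From here, `train_model()` /
`predict_features()` / `evaluate_predictions()` (or the
`inst/scripts/diaseq` command line: `simulate | train | predict |
evaluate`) run the learned pipeline.

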