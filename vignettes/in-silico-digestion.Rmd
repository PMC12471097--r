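---
title: "In silico digestion and characterization of bioactive peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico digestion and characterization of bioactive peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdigest)
```

## The problem

Plant antimicrobial oligopeptides — thionins, viscotoxins, cyclotides,
lunasin and relatives — are inactive reservoirs of much shorter bioactive
peptides. Passage through the gastrointestinal tract cuts them into di- and
tripeptides, some of which inhibit angiotensin-converting enzyme (ACE),
dipeptidyl peptidase IV and other peptidases, act as antioxidants, or have
neuropeptide activity. Whether such a fragment ever reaches its target
depends on two further questions: does it survive the proteases of gut
microorganisms, and do its physicochemical properties (charge, hydropathy,
solubility, stability) allow absorption and binding? `pepdigest` models
this whole chain — digestion, bioactivity annotation, microbial-resistance
screening and physicochemical characterization — as a deterministic,
configurable pipeline over a shipped 57-record reference dataset.

## The cleavage model and its assumptions

Each protease is a *bond-cleavage rule*: a set of P1 residues cleaved
C-terminally, optionally a set of ordered (P1, P1′) pairs, optional P1′
exclusions, and a substrate-length floor (`min_length`, default 2 — a
single residue has no bond). Digestion by a rule set is **simultaneous**:
every bond matched by any rule is cut in one pass. This is an equilibrium
abstraction — no enzyme kinetics, no partial or missed cleavage, no pH
dynamics — and it makes digestion idempotent: re-digesting any released
fragment changes nothing, which the test suite asserts as a fixed-point
property.

Bonds are indexed 0-based between residues internally; all user-facing
coordinates are 1-based inclusive.

The default gastrointestinal set is:

| enzyme | P1 set | note |
|---|---|---|
| pepsin (pH 1.3) | F, L | the classical pH 1.3 convention |
| trypsin | K, R | |
| chymotrypsin | F, Y, W, L, M, N, H | calibrated, see below |

Two deliberate departures from textbook specificity:

- **No proline exclusion.** The published fragment inventory requires
  cleavage before proline (PK from a ...DYPK tail needs Y|P; GL from a
  GLP... N-terminus needs L|P), so the classical "no cut before P" rule is
  off by default. It remains available per rule via `exclusions`.
- **Broadened chymotrypsin.** High-specificity chymotrypsin (F, Y, W)
  cannot release several attested fragments: TW needs N|T, IY needs N|I,
  QH needs H|Q. The shipped set {F, Y, W, L, M, N, H} is the smallest
  conventional superset under which every attested (fragment, source) pair
  is released from the reference dataset. Because the specificity is a
  calibration rather than a constant of nature, it lives in
  `inst/extdata/enzyme_rules.yaml`, never in code; users with a different
  view of chymotrypsin edit the config, not the package.

One record-keeping caveat: the published activity attributions cite one
source accession (AP01328) that is absent from the published 57-record
dataset itself. The annotation asset transcribes the attribution as
printed; tests that check attribution recovery necessarily exclude that
one id, since no digestion of the dataset can produce it.

## The resistance screen

Released di/tripeptides meet two proteases of small-intestine
microorganisms:

- **Oligopeptidase F** is modeled as inert on substrates shorter than four
  residues (`min_length = 4` with an empty specificity set). Every
  published outcome shows di/tripeptides intact under it, and its action
  on longer substrates is not part of this analysis, so encoding any P1
  set would invent cleavages without evidence.
- **Proteinase P1 (lactocepin, EC 3.4.21.96)** is an explicit cleaved-pair
  table: {PG, GL, IL, VF, PL, PK, PW, PF, QH, QL}. A pair table rather
  than a P1 set is forced by the data: GL is cleaved while GF and GK stay
  intact, PF is cleaved while TF and CF stay intact — no single-residue
  rule reproduces that. Pairs absent from the table default to resistant,
  which is the conservative reading (unknown ⇒ no predicted cleavage).

A fragment is `resistant_both` iff both product lists are the fragment
itself. On the 22 annotated fragments this yields 12 survivors.

## Physicochemical descriptors

All descriptors are computed on unrounded doubles; `format_physchem()`
applies the reporting convention (2 decimals, net charge 1 decimal), and
classification flags are always derived from unrounded values, so a
peptide sitting at 2.4849 never flips class through rounding.

- **GRAVY**: mean Kyte–Doolittle hydropathy; negative = hydrophilic.
- **Aliphatic index**: `100·(f_A + 2.9·f_V + 3.9·(f_I + f_L))`; range 0
  (no aliphatic residues) to 390 (pure I/L). Values above 100 are read as
  thermostability. (The alternative textual reading — instability index
  above 100 — contradicts the attested thermostable set, which is exactly
  the aliphatic-index-above-100 set, so the aliphatic reading is
  implemented.)
- **Boman index**: mean per-residue transfer free energy, kcal/mol, stored
  hydrophilic-positive so the reported index is literally the mean; above
  2.48 kcal/mol flags high protein-/membrane-binding potential.
- **Instability index**: `(10/L) Σ DIWV(x_i, x_{i+1})` over overlapping
  dipeptides, using the published Guruprasad weight matrix (unlisted pairs
  weigh 1.0); above 40 predicts in vitro instability. The terminal residue
  contributes no term; length-1 input is rejected rather than defined.
- **Net charge and pI**: Henderson–Hasselbalch sums over N-terminus,
  C-terminus and ionizable side chains (C, D, E, H, K, R, Y). Two pKa sets
  are shipped because the two published columns came from different
  calculators: the `"pi"` set (EMBOSS-style: N-term 8.6, C-term 3.6,
  C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1) reproduces every
  attested pI, and the `"charge"` set (identical but H 6.0) reproduces the
  attested pH-7 charges (QH +0.1, CF −0.1). The charge curve is strictly
  decreasing in pH — every group's contribution is — so the pI is the
  unique root on [0, 14]; bisection stops at |charge| < 1e−6 or interval
  < 1e−6, far inside the 2-decimal reporting precision. A peptide with no
  ionizable side chain lands exactly on the closed form
  (pKa_N + pKa_C)/2 = 6.10.
- **Water solubility**: `good` iff a charged side chain (D, E, K, R, H) is
  present. This simple rule reproduces the attested good/poor column
  exactly; no attempt is made to reverse-engineer proprietary calculator
  heuristics further.
- **PEPT1/PEPT2 transportability**: length ≤ 3, the standard proxy for the
  intestinal di/tripeptide transporters.

Known data inconsistencies are handled by computing, not copying: the GK
row of the published characterization (pI 6.70, charge 0, instability
−3745) disagrees with the method that reproduces every other row, which
gives 9.70, +1 and −37.45 (consistent with its PK/SK neighbours and with a
dropped decimal point); the package reports the computed values. The TW
Boman index computes to 0.12 against a printed 0.11, and QH to 5.10
against 5.09 — both inside the ±0.01 reproduction tolerance; the AR Boman
mean is exactly 6.555, an honest rounding half-way case.

## The synthetic generator

`random_peptides()` exists so every engine property can be tested without
external data: lengths uniform on a range (default 2–60, spanning released
fragments up to small-protein hosts), residues i.i.d. under a
configurable composition (default uniform over the 20 canonical residues),
all driven by one explicit integer seed through a local RNG that never
touches global state. `embed_motif()` plants a di/tripeptide so that
digestion provably releases it: the motif goes at the C-terminus behind a
flanking P1 residue, after checking that no bond inside the motif is
itself a cleavage site.

What the generator emulates is sequence-level structure only. Real plant
AMPs are cysteine-rich, disulfide-bonded, sometimes head-to-tail cyclic —
none of which the uniform model mimics, and none of which matters to a
purely sequence-based cleavage engine. Passing property tests on synthetic
cohorts therefore validates the combinatorics of the engine (concatenation
identity, oracle equivalence, monotonicity, motif recall), not the
biological realism of any particular digestion.

## Problem sizes and determinism

The property suites run on cohorts of 1,000 random peptides (engine
invariants, charge-curve monotonicity, |charge(pI)| < 1e−4) and 200
motif-bearing constructs (end-to-end recall), sizes at which every
combinatorial path through the predicate logic is exercised many times
over while the whole suite stays interactive. The full pipeline on the
57-record reference set is sub-second. All pipeline outputs are
byte-identical across reruns; run metadata records content fingerprints of
the dataset and rule set so a changed config is visible in the report.

## Limitations

- No cleavage kinetics, probabilities or missed-cleavage enumeration; the
  simultaneous model is the right abstraction for "what can be released",
  not for yields.
- Activity annotation is a static snapshot keyed on exact di/tripeptide
  identity; no prediction for unseen fragments, no potency.
- Oligopeptidase F on substrates of length ≥ 4 is out of scope (modeled
  as no action below the floor only).
- No structure: disulfides, cyclization and aggregation are invisible to
  the sequence-level model, and no half-life estimation is attempted.
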