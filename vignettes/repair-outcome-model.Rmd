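---
title: "Modelling repair outcomes of a Cas9 break in a CTG repeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling repair outcomes of a Cas9 break in a CTG repeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgbreak)
```

## The system being modelled

A SpCas9 double-strand break (DSB) is induced at the 3' end of a long CTG
trinucleotide repeat — the expanded microsatellite of myotonic dystrophy
type 1 — integrated in a suppressor-tRNA gene (*SUP4*) on yeast chromosome X.
The guide RNA targets the repeat itself, with the PAM (TGG) sitting at the
border between the tract and non-repeated DNA, so the blunt cut falls a
couple of triplets from the repeat's 3' end: the 5' DSB end carries almost
the whole structured tract while the 3' end is essentially non-repeated DNA.
Survivors of the break carry rearrangements ranging from small
guide-templated insertions to multi-kilobase deletions fusing dispersed Ty1
retrotransposon LTRs, classified into twelve types (I–XII) by a fixed
molecular decision procedure: Southern blot first, then one of two PCRs,
then junction sequencing.

`ctgbreak` rebuilds this entire analysis in silico. Because the deposited
sequencing data are not an input, the package is organised around a
synthetic locus plus a survivor-allele generator with known truth labels, so
that every downstream stage — assays, junction calling, type assignment,
statistics — can be tested end to end.

## The synthetic locus

`build_locus()` assembles a ~9.5 kb annotated sequence:

* **Repeat tract**: 80 CTG units (240 bp) by default, with the PAM
  immediately downstream. The cut site is `3 × cut_offset_triplets_3p` bp
  from the repeat 3' end (default 2 triplets, standard SpCas9 blunt-cut
  geometry of 3 bp 5' of the PAM); the second guide is represented as a
  2 nt shift of the cut toward the repeat end (`guide_id = "gRNA2"`).
* **Restriction sites**: four EcoRV sites flank the repeat, two per side.
  The proximal distances default to the values returned by
  `calibrate_distances(1145, 821, 80, 2)` — 911 bp upstream and 815 bp
  downstream — so the virtual digest reproduces the published 5' (1145 bp)
  and 3' (821 bp) DSB fragments and the 1966 bp parental fragment exactly.
  The distal sites sit at the published qPCR distances (1.88 kb from the 5'
  end, 2.94 kb from the 3' end of the tract). Two SspI sites support the
  survivor-blot enzyme track (~1 kb repeat fragment).
* **LTR family**: five 330 bp delta elements. delta19 and delta20 bracket
  the repeat most closely; delta16/delta17 are distal, ~4 kb upstream.
  Pairwise identity defaults to 0.85, implemented with disjoint per-copy
  mutation sets so every pairwise identity is deterministic
  (`1 − 2k/len`); a published value does not exist, and 0.85 gives
  realistic interrupted homology blocks for junction sampling.
* **Primers and probes**: su47/su48 flank the repeat (940 bp product);
  su23 sits between delta17 and delta18 and su42 between the probe region
  and *CDC8*, 5060 bp apart on the reference — deliberately just over the
  5 kb product cap, so the pair only amplifies after a large deletion. The
  survivor-typing probe lies ~300 bp downstream of the repeat. A second
  annotation, `probe_dsb`, spans the repeat and is used only for DSB-level
  quantification: the published time courses quantify both break fragments
  on one blot, which a strictly downstream probe could not do, so the two
  assays are given separate hybridisation targets.
* **Background**: seeded random sequence at GC 0.38 (yeast-like),
  rejection-sampled so no spurious EcoRV/SspI motif, primer match (either
  strand) or repeat-unit run of ≥ 3 units (which also removes
  PAM-adjacent guide matches) survives outside its sanctioned location.
  Identical (config, seed) pairs give byte-identical sequences.

Coordinates are 0-based half-open throughout, matching the BED output of
`write_locus()`; a single convention avoids off-by-one junction calls.

## The survivor generator

`generate_cohort()` draws event types from a configurable mix and simulates
each pathway:

* **Type I / I_expansion / II** — unchanged alleles and repeat resizing.
  Contractions draw a new length in `[3, n0 − 3]`: losses of one or two
  triplets are indistinguishable from natural microsatellite drift and are
  scored as type I by the classifier (threshold `type1_max_loss = 2`), so
  the generator does not emit them as contraction truth. Expansions are
  small (≤ 10 triplets), as observed.
* **Type III** — 1–8 nt insertions at the cut drawn from {C, T, G} only
  (the guide-encoded bases; no adenosine was ever observed among sequenced
  insertions). Draws whose product is sequence-identical to a pure
  repeat-length change (e.g. an in-frame CTG) are resampled: on sequence
  alone such events *are* length changes.
* **Type IV / V** — local deletions within 300 bp of the cut per side,
  always removing at least 13 bp of 5' flank so that the event genuinely
  leaves the PAM–repeat boundary window; type V adds an insertion,
  optionally templated from a donor cassette (modelling the published
  211 bp ectopic-capture event).
* **Types VI–X** — single-strand annealing between an upstream LTR and
  delta20: the junction is sampled from the identical blocks shared by the
  pair (weighted by block length), everything between the annealed
  positions is deleted, and one chimeric LTR remains. Pair weights default
  to favouring the repeat-proximal pairs, reflecting that resection reveals
  the nearest homologies first. Type X is the delta16/delta20 fusion with a
  captured fragment of a synthetic Ty1-internal sequence at the junction.
  A RAD52-independent variant (`mmej_deletion()`) anneals at short 8–9 nt
  exact matches near the LTRs instead.
* **Type XI** — very large deletions removing the su23 site and the probe
  target. The right bound is drawn beyond the viable window on purpose:
  draws hitting the essential *CDC8* gene (or its promoter margin) are
  inviable, logged as simulated mortality and resampled, so cohorts contain
  exactly `n` survivors — mirroring that only survivors are picked from
  plates. The promoter margin defaults to 180 bp, which makes the viability
  bound coincide exactly with the downstream edge of su42: emitted type XI
  deletions never extend past su42, encoding the essentiality argument as a
  hard constraint.
* **Type XII** — deletion from within delta18 into delta20 carrying an
  inverted (reverse-complemented) copy of a distal segment anchored at
  delta16, emitted as a single rearranged allele.

The default mix approximates the wild-type survivor spectrum (local
deletions ~16 %, LTR fusions ~63 %, very large deletions ~4 %). These are
descriptive survivor proportions, not mechanistic pathway rates — the true
generative probabilities are unobservable because only survivors are
sequenced.

**What the generator does not emulate**: sequencing reads (alleles are
emitted as full sequences), translocations, resection kinetics, checkpoint
signalling, Cas9 re-cutting of repaired alleles, or heterogeneity in colony
purity. Passing tests therefore demonstrate that the classifier implements
the decision procedure faithfully on clean single-allele inputs, not that it
would be robust to read-level noise.

## Virtual assays

`digest()` partitions a linear window at given cut positions (window edges
act as flanking virtual sites, so fragment sizes always sum to the window).
`southern()` reports one band per distinct probe-overlapping fragment size
with signal `fraction × overlap/probe length`, renormalised per lane;
fragments retaining less than `min_overlap = 50` bp of probe target are
dropped, modelling the published partial-deletion signal loss. The
gel-resolution proxy for band assignment is 30 bp. Band-signal noise is off
by default; the DSB-quantification round trip is exact at zero noise and
stays within ±0.02 at the default noise of 0.005 lane-fraction units.
`pcr()` is exact-match only — the bench assays report binary
product/no-product outcomes, so a mismatch model would add parameters
without adding testable behaviour. Product caps default to 3 kb (su47/su48)
and 5 kb (su23/su42), chosen so the reference locus behaves as the typing
rules require (one local product, no LTR-spanning product).

Fig-1-style time courses use the EcoRV track; survivor blots default to
SspI (the published survivor blots used SspI, with one EcoRV exception);
which track is active is an argument per assay.

## Junction calling and type assignment

`align_junction()` computes the longest exact prefix and suffix matches
between allele and reference. If they cover the allele, the event is a pure
deletion whose overhang is the annealed microhomology; otherwise the
unexplained middle is an insertion. All calls are **left-aligned**: extended
homology between LTR copies makes the exact breakpoint undeterminable in
principle, so a canonical placement is required, and "maximally left" is
declared. The invariants are: (i) every call recomposes its allele
byte-exactly, and (ii) the reported microhomology equals the brute-force
symmetric-extension oracle (`microhomology_oracle()`); the test suite
checks (ii) exhaustively over all deletion placements on 300 bp references
and on 2000 sampled placements on a 2 kb repeat-bearing reference — sizes
chosen to keep the suite fast while still covering tandem-repeat and
duplicated-block edge cases.

`classify_clone()` walks the published decision tree: Southern band → local
su47/su48 PCR → sequence (types I–V, falling back to su23/su42 when the
su48 site is deleted); no band → su23/su42 PCR (LTR fusions VI–X, inverted
duplication XII); no product at all → XI. The numeric boundaries the
published rules leave open are declared configurable defaults in
`classify_config()`: losses ≤ 2 triplets with unchanged flanks are type I;
a type III call requires both deletion and insertion ≤ 8 nt within a
±12 bp window around the tract; an LTR-fusion call with ≥ 10 nt of
junction insertion is the capture type X; an insertion of ≥ 30 nt whose
reverse complement matches the reference marks a type XII inverted
duplication.

One consequence of the default geometry is intrinsic to the assay logic,
not a classifier defect: fusions involving delta17 or delta16 delete the
su23 primer site, so no su23/su42 product forms and they are reported as
type XI — exactly as a bench workflow using these primers would score them.
`expected_call()` encodes this collapse, and the truth-recovery suite
(100 % on noise-free cohorts of 500 clones) is run over the assay-resolvable
types {I, I_expansion, II, III, IV, V, VI, VII, XI, XII}.

## Resection and copy-number estimators

A resected (single-stranded) EcoRV site resists digestion and remains
amplifiable. With `deltaCt = mean(Ct_digested) − mean(Ct_mock)` over
replicates (means, as specified for the bench protocol; no outlier
removal):

* raw resection `= 2 / (1 + 2^deltaCt)`, so `deltaCt = 0` means full
  resistance (raw 1) and "no amplification" in all digested wells means a
  fully double-stranded, fully digested site (raw 0) — no imputed cap cycle
  is invented;
* relative resection `= raw / DSB fraction`, the fraction of *broken*
  molecules resected at the site. Whether the published values were capped
  at 100 % is not stated; clamping at 1 is the declared choice here, with a
  warning up to 1.1 and an error beyond (values that far above 1 indicate
  inconsistent inputs, not sampling noise);
* copy number uses the standard `2^−ddCt` form.

`simulate_qpcr()` inverts the estimator exactly (planted fractions recovered
to 1e-9 at zero noise over a 0.05–1.0 grid) and, with the realistic Ct noise
of 0.1 cycles and triplicates, recovers planted fractions within ±0.05 in
≥ 95 % of trials. The mock baseline Ct of 22 is arbitrary (the estimator
depends only on the difference).

## Statistics

Survival is the CFU ratio galactose/glucose per plating replicate, with a
t-based 95 % CI across replicates (the published figures plot mean and
95 % CI; replicate counts are not printed, so the CI method is declared).
Strain comparisons use two-sample t-tests — Welch by default, since equal
variances across strains with 60-fold different survival would be a strong
assumption; the pooled test is a switch — with Bonferroni correction
`min(1, p·m)`. Type spectra are compared with Pearson chi-squared without
continuity correction (also switchable; the published convention is
unknown). Fisher's exact test and the Mann-Whitney-Wilcoxon test are thin
wrappers over the standard implementations.

`simulate_survival()` uses a plating efficiency of 0.85; the published
protocol plates "the same number of cells" on both media without stating an
efficiency, and the ratio estimator is efficiency-invariant, so this choice
only affects count magnitudes.

## Problem sizes and numerical choices

The shipped test suite uses cohorts of 150–500 clones, 1000-draw sampling
checks, 1000-trial parameter-recovery and type-I-error suites, exhaustive
junction enumeration at 300 bp and sampled enumeration at 2 kb — sizes at
which every property is comfortably resolved and the whole suite runs in a
few minutes. Degenerate inputs are defined rather than left to chance:
zero-length deletions are resampled, an all-zero type mix is an error,
empty Southern lanes are reported as zero bands (never renormalised from
zero), ties in PCR candidate products resolve to the shortest with a
warning, and the identical-allele junction call is the canonical empty call
at position 0.

## Known limitations

* The locus is synthetic: calibrated to every printed distance and fragment
  size, but its base composition is random, so sequence-specific artefacts
  of the real chromosome (cryptic homologies, secondary structure) are out
  of scope. A real sequence can be supplied via FASTA + BED.
* Types VIII–X are generated but not assay-resolvable with the default
  primer geometry (see above); resolving them would require a third primer
  pair upstream of delta16.
* The per-type mix is descriptive; the package cannot (and does not try to)
  infer mechanistic pathway probabilities from survivor spectra.
* Junction calling assumes one rearrangement per allele with intact outer
  flanks; translocations are flagged as unalignable rather than
  reconstructed.
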