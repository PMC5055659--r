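---
title: "Conservation-based modelling of cassette exon inclusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-based modelling of cassette exon inclusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

A cassette exon is an exon that is either included in or skipped from the
mature transcript between two constitutive neighbours (C1 and C2); its
inclusion level is quantified per tissue as the percent-spliced-in, PSI
(a fraction in [0, 1]).  Evolutionary conservation around the exon's two
alternative splice sites carries a surprising amount of information about
PSI.  This package implements, end to end, an analysis of that
relationship:

1. **Conservation features.** For each flanking intron, the *junction
   conservation* `J` is the per-base conservation score (phastCons-like,
   in [0, 1]) of the single first intronic base adjacent to the
   alternative exon's splice site, and the *average conservation* `A_w`
   is the mean score over the first `w` bp of the intron (default
   `w = 100`).  The central predictor is the ratio `R = J / A_100`
   ("Junc/Avg"), two features per exon (one per side).
2. **Conservation regimes.** Thresholding `J` and `A` at 0.5 partitions
   exons into Old- (old exon, few conserved cis elements: `J > 0.5`,
   `A <= 0.5`), Old+ (`J > 0.5`, `A > 0.5`), New (`J <= 0.5`,
   `A <= 0.5`), and a rare fourth corner, Other.  Old- exons are
   overwhelmingly included, New exons are mostly skipped, and Old+ exons
   split between high and low inclusion -- which is exactly why the ratio
   `R` outperforms either of its components: it assigns similarly low
   values to New and Old+, the two lower-inclusion groups.
3. **ISRE discovery.** Intronic splicing regulatory elements (enhancers,
   ISEs, and silencers, ISSs) are 6-mers whose presence in the *15-100 bp
   region* of a flanking intron shifts *residual PSI* -- tissue-averaged
   PSI after removing what mono- and di-nucleotide composition alone
   predicts.  The shift is assessed with a two-sided Mann-Whitney test
   (events containing vs not containing the 6-mer) and
   Benjamini-Hochberg FDR control at q < 0.05 over all 4096 6-mers of a
   side.
4. **k-mer conservation statistics.** Per 6-mer and side: *conservation
   enrichment* (mean conservation of instance-covered bases divided by
   the global region mean), *enrichment bias* B (Spearman correlation of
   per-event enrichment with residual PSI over containing events),
   *ISE/ISS character* X (Spearman correlation of count with residual PSI
   over containing events), the *meta-correlation* of X with B across
   eligible 6-mers, and a permutation test that re-draws PSI across
   exons, recomputing residuals inside every permutation.

The real dataset this style of analysis targets (RNA-Seq PSI for ~10^4
human cassette exons in 16 tissues, with genome-wide phastCons tracks) is
not redistributable, so the package ships a synthetic data generator with
planted ground truth: every downstream claim is validated as a *recovery*
problem on data whose true structure is known.

# The synthetic data generator

`sim_config()` / `simulate_splice_data()` generate event geometry, a
genome, mammalian and primate conservation tracks, and an events x
tissues PSI table.  The generator is the package's study design; its
defaults are chosen once, on the following grounds, and the tests are run
against them.

**Latent inclusion model.** PSI is logit-linear:

    logit PSI = regime intercept
              + effect_size_logit * (#planted ISE - #planted ISS occurrences)
              + gc_confound_beta * (region GC fraction - 0.5)
              + primate gain/loss effects + exon noise (+ tissue offsets)

A logit-linear model keeps effect sizes interpretable (one occurrence of
a planted silencer costs one logit of inclusion at `effect_size_logit =
1`) and makes recovery testable.  Regime intercepts are strongly bimodal
(`old_minus = +2.6`, `new = -2.2`, Old+ at `+/-3.0`): most exons are
clearly included or clearly skipped, matching the observation that ~99%
of real measurements are outside the intermediate PSI band.

**Old+ polarity is coupled to element load.**  Whether an Old+ exon is
included or skipped is drawn with probability
`plogis(polarity_slope * (mean target average conservation - 0.75))` of
being skipped: exons with more conserved cis elements tend to be skipped.
This graded load-to-inclusion coupling is the structural reason the ratio
`R` beats junction conservation alone; without it the two predictors tie,
because a binary Old+ split is symmetric for ranking purposes.

**Conservation tracks.**  Conservation is piecewise-constant: a low
background (0.02-0.08 per event) with "element" blocks at 0.85-1.0, so
per-event conservation enrichment is meaningful and bedGraph output
compresses well.  Junction conservation occupies offsets 0-2; the splice
consensus stretch (offsets 3-14) gets a moderate, regime-independent
value; element blocks in the ISRE region (offsets 15-100) realise a
per-side target region average drawn from `avg_high_dist` (Old+) or
`avg_low_dist` (Old-/New).  Beyond the region, *distal* elements are
drawn from the same magnitude distribution but independently of the
exon's regime and PSI (`distal_high_prob = 0.3`, matching the Old+
prevalence).  This last choice is what gives the window sweep its peak:
widening the averaging window beyond the regulatory depth admits
conservation with the same statistics but no relation to splicing, so the
correlation of `R_w` with PSI degrades.

**Motif planting and conservation coupling.**  Each planted 6-mer
receives `Binomial(2, motif_prob = 0.2)` instances per event, written at
non-overlapping random offsets of the 15-100 bp region in transcription
orientation.  Latent PSI uses the *realised* occurrence counts (including
chance background occurrences).  A planted instance is covered by a
conserved element with probability 0.9 when the motif's effect sign is
consistent with the exon's inclusion (ISE in an included exon, ISS in a
skipped one) and 0.2 otherwise.  This dataset-wide coupling encodes the
hypothesis under study -- silencers become conserved near exons whose
skipping is advantageous -- and is what the enrichment-bias and
meta-correlation statistics recover.

**Primate track.**  The primate track equals the mammalian track except
for element *loss* (a fraction of Old+ exons whose elements are absent in
primates; their PSI gains `+0.5` logits) and *birth* (a fraction of exons
gaining primate-only upstream elements; `-0.5` logits).  This yields the
expected contrast: within a mammalian regime, exons with high primate
average conservation have lower mean PSI.

**Measurement noise.**  Observed PSI is a [0, 1]-truncated normal around
latent PSI.  Confident measurements draw sigma from Unif(0.01, 0.02)
(`sigma_measurement = 0.015`); 30% of measurements are low-confidence
(sigma in 0.101-0.25) and are pruned by the `sigma <= 0.1` rule.  The
confident noise floor is deliberately below the 10% delta-PSI threshold:
the cross-tissue range of 16 noisy measurements is about 3.5 sigma, so a
floor near 0.05 would make the "substantial tissue difference" subset
(max cross-tissue |dPSI| > 10%) dominated by pure measurement noise and
unrecoverable by construction.

**What the generator does not emulate.**  No splice-site consensus
sequence model (sequences are i.i.d. at a per-exon GC propensity), no
phylogenetic simulation of alignments (conservation is painted directly),
no positional preference of motifs within the region, no correlated
motif co-occurrence, and no read-level PSI quantification noise model.
Passing recovery tests therefore shows that the *estimators* do what they
claim on data with the planted structure -- not that real introns have
that structure.

# Numerical and procedural choices

* **Coordinates** are 0-based, half-open, between-base (BED convention).
  Offset 0 is the first intronic base adjacent to the alternative exon's
  splice site; upstream region strings are stored 5'->3' of the pre-mRNA,
  i.e. with decreasing offset.
* **The 15-100 bp region** is offsets [15, 101): 86 bases, skipping the
  first 15 bases of splicing consensus next to the splice site.
* **Junc/Avg ratio**: `R = J / max(A, 1e-3)`, with `R = 0` whenever
  `J = 0`.  The epsilon floor keeps `R` finite on unconserved introns;
  the zero override keeps an unconserved junction from being rescued by
  an even less conserved intron.
* **Regime boundary**: values exactly at 0.5 go to the "low" side
  ("high" is strictly greater).
* **Missing conservation** (`missing_policy = "drop"` by default):
  uncovered bases are dropped from averages (shrinking the denominator),
  excluded from enrichment numerators, and any instance containing a
  missing base is dropped from conservation-weighted counts.  `"zero"`
  and `"error"` policies are available.
* **Mann-Whitney tests** use the normal approximation with tie and
  continuity corrections; the U statistic itself is exact (it equals
  pair enumeration), and direction (ISE vs ISS) is assigned from rank
  sums.  BH correction uses `n = 4096` per side even when some 6-mers are
  untestable.
* **k-mer counting** allows overlapping occurrences; bases covered by
  overlapping instances count once in enrichment numerators, while each
  instance contributes separately (its minimum base conservation) to
  weighted counts.
* **Composition regression**: OLS with intercept on both sides' mono- and
  overlapping-dinucleotide frequencies jointly (one reference column per
  frequency block is dropped; the blocks sum to 1 and would otherwise be
  collinear with the intercept).  A rank-deficient design falls back to
  ridge with a logged lambda.  Per-event enrichments are ranked at 12
  significant digits so values equal up to floating-point summation
  order tie instead of ranking on noise.
* **Per-event enrichment** uses the *global* region average as its
  denominator: per-event denominators are ratios of two small means and
  are numerically unstable.
* **The permutation test** permutes tissue-averaged PSI across exons and
  recomputes residual PSI through the fitted composition-regression
  projection inside every permutation, preserving the residualisation
  structure under the null; `p = #(|perm| > |observed|) / n_perm`.
* **Cross-validation** is grouped by exon (all tissues of an exon share a
  fold) to prevent tissue-level leakage, and ISRE discovery is re-run
  inside each training fold before the ISRE-count predictor is scored on
  held-out exons.  The reference classifier is L2-regularised logistic
  regression (`glmnet`, alpha 0, fixed small lambda): a linear scorer on
  two features is reproducible where a small neural network with
  unpublished hyperparameters is not.
* **Recovery scoring** (`score_isre_recovery()`): a called 6-mer counts
  as a correct discovery when it matches a planted 6-mer exactly or at a
  single-base shift (5 of 6 bases) with a consistent label -- the usual
  convention in motif-discovery evaluation.  Single-shift neighbours of a
  planted instance co-occur with it by construction (the flanking base is
  random, so each neighbour appears in ~25% of planted events), and a
  presence/absence test has no information to separate them from the
  motif itself.  Strict-match precision is also reported and is
  necessarily much lower (~0.25).
* **Tissue-specificity fraction** is evaluated over confident tissues
  only, among Old+ exons with confident measurements in at least half the
  tissues, and requires *every* confident measurement on one side of the
  1/3 / 2/3 cutpoints.

# Problem sizes used by the tests

The validation suite runs the recovery analyses at 3000 exons x 16
tissues (discovery, AUC ordering, tissue specificity), 20 replicate
datasets of 1500 exons for the window-sweep localisation, 2000 exons for
the null calibrations, and 200 replications x 99 permutations for the
permutation-p uniformity check.  These sizes were chosen so each check
has comfortable statistical resolution for the property it asserts;
`scripts/acceptance.R` re-runs the same computations from scratch at the
same sizes.

# Known limitations

* The delta-PSI evaluation of the Junc/Avg model is structurally
  degenerate: the model scores every tissue of an exon identically, so
  predicted tissue differences are all zero and the correlation is
  reported as undefined rather than as a small number.
* ISRE discovery power depends strongly on cohort size; at a few hundred
  exons the BH threshold over 4096 tests leaves most planted motifs
  uncalled.  The analysis scripts use 3000 exons.
* The meta-correlation of character with bias is intrinsically small
  (only planted motifs and their shift-neighbours carry aligned signal
  among hundreds of eligible 6-mers); its sign, not its magnitude, is the
  reproducible quantity.
* Conservation-track queries are held in memory per chromosome; the
  package targets simulated genomes of megabase scale, not whole-genome
  tracks.
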