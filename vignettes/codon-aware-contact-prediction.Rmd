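---
title: "Codon-aware correlated mutation analysis for contact prediction"
author: "codonCMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-aware correlated mutation analysis for contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonCMA)
```

## The problem and the model

Correlated mutation analysis (CMA) scores pairs of columns of a multiple
sequence alignment (MSA) for coevolution and ranks them as candidate
residue–residue contacts.  All classical scorers operate on amino-acid
alignments.  A correlation between two columns, however, can reflect
selection acting on the nucleotide sequence (RNA structure, splicing,
codon usage) or shared ancestry rather than a physical contact between
the encoded residues.  The signature of such confounding is visible one
level down: a pair that is correlated because of selection on the
*protein* contact should be correlated at the amino-acid level but only
weakly at the codon level (synonymous codons are interchangeable for a
contact), whereas a pair whose correlation survives at the codon level is
suspect.

`codonCMA` implements this idea end to end.  Every scorer is
alphabet-generic and runs both on the amino-acid alignment (q = 21
states: 20 residues + gap) and on the codon alignment obtained by
threading each record's coding sequence onto the protein alignment
(q = 65 states: 64 codons + gap).  The two score matrices are combined
per pair as

$$ S(i,j) \;=\; \frac{\max(S_{AA}(i,j), \varepsilon)^{\alpha}}
                     {\max(S_{C}(i,j), \varepsilon)} $$

which increases with the amino-acid-level correlation and decreases with
the codon-level correlation.  The power $\alpha > 0$ sets the relative
weight of the two levels and is fitted per method by maximising the
median percent AUC improvement over a family collection
(`fitAlpha()`), with random-split cross-validation
(`cvAlphaStability()`) to check that the fitted value is stable.  The
floor $\varepsilon = 10^{-10}$ keeps the ratio finite when a score is
zero or negative (possible for MIp and APC-corrected PSICOV); clamping
preserves the order of all positive scores.

## Scorers

* **OMES** — observed-minus-expected-squared counts,
  $\sum_{ab} (OBS_{ab} - EXP_{ab})^2$, no smoothing.
* **MI** — mutual information over all q states (gap included), natural
  logarithm; **MIp** subtracts the average product correction
  $APC(i,j) = \overline{MI}_i\,\overline{MI}_j / \overline{MI}$.
* **DCA** — mean-field direct coupling analysis: identity-based sequence
  reweighting at 80% (`computeWeights()`), pseudocount $\lambda =
  M_\mathrm{eff}$, connected correlation matrix over q − 1 states per
  site (gap is the gauge state), couplings $e = -C^{-1}$, per-pair
  two-site model fitted by iterative proportional fitting (tolerance
  1e-4, at most 500 iterations), direct information as the score.
* **PSICOV / PSICOV\*** — L1-penalised sparse precision matrix of the
  one-hot-encoded alignment (graphical lasso, penalty $\rho$ = 0.001),
  pair score $\sum_{ab} |\Theta_{(i,a),(j,b)}|$, APC subtracted for
  `PSICOV`, not for `PSICOV*`.  A diversity guard refuses alignments
  with $M_\mathrm{eff} < 125$ (configurable) the way the original tool
  refuses shallow alignments.

Design choices a user should know: the natural logarithm is used for MI
(a base change only rescales all scores uniformly); gaps are full
scoring states for OMES/MI/MIp but the dropped reference state for
DCA/PSICOV, matching the conventions of the methods each scorer
descends from; codon-alphabet DCA/PSICOV refuse problems with
$L(q-1) > 20{,}000$ unless the guard is raised, because the inverse
grows with the square of that number; sequence reweighting is computed
independently per alignment (amino-acid and codon), both at the 80%
identity threshold.

## Evaluation protocol

Contacts come from structures under three definitions: `cbeta`
(C$\beta$–C$\beta$ $\le$ 8 Å, C$\alpha$ for glycine — inclusive
threshold), `all_atom` (any heavy-atom pair $\le$ 8 Å) and `physical`
(any heavy-atom pair strictly < 3.5 Å).  Pairs separated by fewer than
5 residues are excluded everywhere; under that rule a 100-residue chain
has `nCandidatePairs(100, 5)` = 4560 candidate pairs.  Alignment columns
are mapped to structure residues by global pairwise alignment
(match +1, mismatch −1, gap open 5, extend 1 — the tooling's choice, as
only the procedure, not the parameters, is standard); structures
covering less than 80% of the domain are excluded.  Per family at most
30 unique-sequence structures with the best resolution are kept (ties
broken by smallest identifier) and accuracy curves are averaged across
them so deeply crystallised families are not over-represented.
Accuracy at N is the fraction of true contacts among the top N mapped
predictions; curves run over N = 1..L by default (the top-L convention;
the exact range is configurable because the upstream protocol does not
pin it down), AUC is trapezoidal, and the improvement of a variant is
$100\,(AUC - AUC_\mathrm{base})/AUC_\mathrm{base}$.

Statistical significance of per-family improvements uses two
nonparametric tests (two-sided by default; sidedness is a flag): an
exact binomial sign test, and a Wilcoxon signed-rank test whose exact
null is computed by a generating-function convolution over the $2^n$
sign assignments — exact even when tied absolute improvements receive
mid-ranks — for n $\le$ 25, with a tie- and continuity-corrected normal
approximation beyond.

## What the synthetic generator emulates

The package ships a seeded generator (`sampleFamily()`) because the
dissociation the combined score exploits must be a *measurable property
of data*, not an assumption.  Sequences are sampled by Gibbs sampling
(250 total sweeps per sequence: 50 burn-in + 200 equilibration) from a
pairwise model over the 61 sense codons with uniform fields:

* **Contact pairs** (default 26 on L = 30 sites, forming paths of
  maximum degree 2 so the contact set is geometrically realisable)
  couple the *translated amino acids* of the two sites through a random
  residue-pairing table with strength drawn per pair from
  Unif(0.8, 2.5).  Drawing a range of strengths makes some contacts
  marginal — exactly the pairs whose rank the codon channel can rescue.
* **Confound pairs** (default 8) couple the *synonymous index* of the
  two codons (which of its amino acid's codons each is) at strength 4,
  plus a weaker amino-acid term at strength 1.1.  They are correlated
  at both levels — strongly at the codon level, moderately at the
  amino-acid level — and are *not* contacts, the precise failure mode
  the combined score demotes.  `confoundDissociationCheck()` verifies
  per family that each confound's codon-level MI exceeds the 95th
  percentile of unplanted pairs while its amino-acid MI stays below the
  median of the planted contacts.

The default family size (M = 2000 sequences of L = 30 codons) mirrors
the alignment-depth regime in which coupling methods are usually
benchmarked, scaled to a length where the full pipeline runs in
seconds.  The number of planted contacts (26) plus confounds (8)
deliberately exceeds L: top-L precision can only respond to demotion if
true contacts and confounds actually compete for the last ranks.

A matching structure is produced by `makeSyntheticChain()`: single-atom
(C$\beta$-only) residues, planted pairs embedded closer than 6 Å and
all other pairs at separation $\ge$ 5 kept beyond 9 Å by constrained
rejection sampling, so the 8 Å contact map equals the planted set
exactly and all three contact definitions coincide.  Single-atom
residues isolate the evaluation logic from geometric detail.

What the generator does **not** emulate: phylogenetic relatedness
(sequences are i.i.d., so common-ancestry confounding is absent),
gaps, heterogeneous site conservation, real codon-usage bias, and
higher-order (beyond pairwise) constraints.  Passing the synthetic
acceptance checks therefore demonstrates that the machinery behaves as
specified under its own model — not that the same quantitative gains
appear on natural families, where ancestry and alignment noise matter.

## Numerical choices and degenerate inputs

* Ambiguous codons (any non-ACGT character) and unknown residues map to
  the gap state; a CDS may carry one trailing stop codon, which is
  stripped before threading.
* DCA without pseudocount on degenerate columns raises an error
  advising $\lambda > 0$ rather than silently regularising.
* The covariance matrix for PSICOV is shrunk toward its diagonal in 5%
  steps until positive definite; non-convergence of the graphical lasso
  is an error reporting the final criterion, never a silent result.
* Ranking ties break by ascending (i, j), making every ranking
  deterministic; equal-resolution structures tie-break by identifier.
* APC means are taken over all off-diagonal pairs (the background
  estimate uses every position, including pairs later excluded from
  ranking by the separation rule).
* `aucImprovement()` refuses a zero-AUC baseline; the sign and
  signed-rank tests refuse all-zero improvement vectors.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: oracle comparisons use 20-sequence alignments of 6–8 columns;
coupling recovery uses L = 12, M = 1000 with six planted pairs; the
core-claim check runs ten families at the generator defaults (L = 30,
M = 2000); type-I calibration uses 2000 replicates of 20–25 symmetric
deltas.  These sizes were chosen so the whole suite re-derives its
expectations from first principles in a couple of minutes on one core.

## Known limitations

* Mean-field DCA stores the full $(L(q-1))^2$ correlation matrix; codon
  alignments beyond a few hundred columns need the memory guard raised
  and corresponding memory.
* The PSICOV-style scorer uses a plain block-coordinate graphical
  lasso; it is exact but not tuned for alignments with thousands of
  columns.
* `readStructureChain()` keeps the highest-occupancy alternate
  conformation and drops hydrogens; insertion codes are honoured but
  heteroatoms are ignored entirely.
* The combined score is the ratio form only; other functionals
  (differences, regression residuals) are out of scope.
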