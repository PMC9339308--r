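---
title: "Detecting rate-limiting ribosome stalling with ribostall"
author: "ribostall maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rate-limiting ribosome stalling with ribostall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostall)
```

## The problem

When ribosome footprints on a transcript drop in a mutant relative to a
control, two very different mechanisms can be responsible: fewer ribosomes
are being loaded (reduced **initiation**), or ribosomes are loaded normally
but a rate-limiting **elongation** pause has appeared or been relieved.
Overall footprint abundance cannot distinguish the two, but the *shape* of
the footprint distribution can. A rate-limiting pause behaves like a road
bottleneck: ribosomes stack upstream of the pause site and thin out
downstream of it. A change in initiation rate, in contrast, rescales the
whole profile and leaves its shape untouched.

`ribostall` implements both halves of the argument: a biophysical traffic
simulator that generates footprint profiles whose rate-limiting step is
known by construction, and a detector that scores the redistribution of
footprints between two conditions.

## The traffic model

Translation is modelled as an inhomogeneous $\ell$-TASEP (totally
asymmetric simple exclusion process with extended particles). A transcript
is a lattice of $n$ codons. A ribosome occupies $\ell$ consecutive codons
(default $\ell = 10$, matching a ~30-nt footprint) and is identified by its
5'-most codon. Dynamics are continuous-time and simulated exactly with the
Gillespie algorithm:

* **initiation** at rate $\alpha$ when codons $0,\dots,\ell-1$ are vacant;
* **elongation** from codon $i$ to $i+1$ at rate $p_i$ when codon $i+\ell$
  is vacant;
* **termination** from the last codon at rate $\beta$.

We chose continuous time with exponential waiting times because it has an
unambiguous stationary distribution and no update-order artifacts, unlike
discrete-time sweeps. Per-codon occupancy (the fraction of time each codon
carries a ribosome 5'-edge) and the steady-state current are averaged after
a burn-in of three deterministic traversal times $3\sum_i 1/p_i$, over an
equally long sampling window — a conservative approach to stationarity for
free-flowing lattices (see Limitations for the jammed case).

The $\ell = 1$ special case has exact open-boundary phase results — low
density ($\rho = \alpha$, $J = \alpha(1-\alpha)$ for $\alpha < 1/2 \le
\beta$) and maximal current ($J = 1/4$) — which the test suite uses as
closed-form oracles, together with hard-exclusion and flux-conservation
invariants checked on every run.

Elongation rates are drawn i.i.d. from a gamma distribution (default shape
2, scale 0.5: mean 1, CV $\approx 0.7$), giving the skewed, strictly
positive codon-to-codon variation seen in elongation-rate estimates.
"Regime" has an operational definition here: the simulation is re-run with
the initiation rate, the single slowest elongation rate, and the
termination rate each increased by 10%, and the perturbation that raises
the current the most names the rate-limiting step (ties are flagged and
broken initiation > elongation > termination).

## From simulation to sequencing-like data

Finite sequencing depth is emulated by multinomial undersampling of the
stationary occupancy. The default cohort draws 10 reads per codon —
representative of well-covered transcripts, comfortably above the 0.5
reads/codon retention floor the detector applies; the known stalled genes
used to anchor the method in real datasets are all highly expressed.

A simulated cohort pairs each control transcript with a class-specific
mutant:

* *elongation-limited*: one interior elongation rate multiplied by 0.02 (a
  deep induced pause, kept $\ell$ codons away from both transcript ends);
* *initiation-limited*: $\alpha$ halved, elongation untouched (the
  loss-of-an-initiation-activator model);
* *termination-limited*: $\beta$ multiplied by 0.02;
* *null*: a second multinomial draw from the identical control density.

Transcript lengths are uniform on 150–2000 codons and every stream of
randomness derives from one master seed, so cohorts are byte-reproducible.

## The detector

Footprint profiles follow the published processing order exactly:

1. **P-site assignment** (for raw footprint tables): each read length gets
   a 3'-end offset, estimated as the modal distance from read 3' ends to
   the first CDS base over start-codon-spanning reads; the P-site codon is
   `floor((3'end - offset - cds_start)/3)` with 0-based half-open
   coordinates.
2. **Filtering**: a transcript is kept only if its CDS exceeds 100 codons
   and its mean density exceeds 0.5 reads/codon — strictly, and in *both*
   conditions, since the comparison is meaningless when either profile is
   undersampled. (The per-condition-vs-joint choice is not specified in the
   published description; joint filtering is the conservative reading.)
3. **Smoothing**: LOWESS — tricube-weighted local linear regression over
   the `span * n` nearest codons (default span 0.1, zero robustifying
   iterations), evaluated at every codon, negatives clamped to zero. The
   span default smooths codon-level sampling noise while preserving the
   upstream/downstream asymmetry a stall creates; much larger spans blur
   the jam boundary itself.
4. **Normalization**: division by the profile sum.
5. **Scoring**: the K–S statistic, the maximum absolute difference between
   the *cumulative* normalized densities of control and mutant, with the
   codon of maximal difference recorded. The published verbal description
   says "maximum absolute difference between the normalized read
   densities", but the accompanying displays are cumulative distribution
   plots and the K–S statistic is by definition a CDF distance; the
   cumulative form is therefore the default and a pointwise variant is
   available behind `cumulative = FALSE`.
6. **Grouping**: high ($> 0.3$), low ($< 0.15$), medium in between. The
   published group definition contains an evident typo ("$>0.3$ and
   $<0.15$" for medium); both boundaries are assigned to medium.
7. **Enrichment**: per group, the fraction of scored targets in the group
   over the fraction of scored nontargets in it, with a two-sided Fisher's
   exact test on the 2×2 table. Sidedness is not stated in the source
   description; two-sided is the neutral choice.

No p-value is attached to the K–S score itself: codon positions along a
profile are not i.i.d. samples, so the asymptotic K–S null distribution
does not apply. The score is used as a ranking/threshold statistic, which
is how it is validated on simulated regimes.

## Companion analyses

* **TPM / TE**: standard transcripts-per-million; translation efficiency is
  footprint TPM over mRNA TPM, undefined below an mRNA floor of 2 TPM.
  Genes are represented by their highest-expressed isoform (ties: longer
  CDS, then lexicographic id).
* **Length summaries**: set-vs-background medians and means of CDS, UTR and
  summed-intron lengths with Mann–Whitney tests (the published comparisons
  are box plots without a named test; Mann–Whitney is the standard
  distribution-free choice for such length data).
* **Motif scans**: degenerate IUPAC motifs (WGGA, ACUK, GAC, UAY) counted
  with overlaps over RNA or DNA spelling; the length-matched enrichment
  test bins the background by length quantiles (5 by default), compares
  per-bin motif densities one-sidedly, pools bins by Fisher's method, and
  runs random 4-mers through the identical machinery as negative controls.
* **Dosage table**: the packaged TSV of 62 translationally altered
  ASD-relevant genes with fold-changes, CLIP flags and ClinGen scores;
  "emerging/sufficient evidence" is operationalized as score $\ge 2$.
  Differential-TE significance testing itself is out of scope: fold-changes
  and adjusted p-values are ingested, not recomputed.

## Problem sizes and reproducibility

The shipped acceptance script simulates 50 control/mutant pairs per class
at full length range (150–2000 codons) and 10 reads/codon; the test suite
exercises the same machinery on reduced cohorts (6–20 pairs, lengths
120–800 codons) and on 200-codon homogeneous lattices for the closed-form
checks. All seeds are fixed; every cohort derives its substreams from a
single master seed.

## Known limitations

* **Natural bottlenecks dominate the default rate distribution on long
  transcripts.** A gamma(2, 0.5) rate profile places mass
  $\approx 2x^2$ below a small rate $x$, so the minimum over $n$ codons
  concentrates around $\sqrt{1/2n}$ — about 0.02–0.06 for 150–2000-codon
  transcripts, i.e. the same order as an induced pause (0.02 times a
  typical rate). With the default $\alpha = 0.5$ far above the lattice
  transport capacity, *control* transcripts are therefore already
  elongation-limited at their own natural slowest site, and profiles jam at
  that site in both conditions. Two consequences follow. First,
  "initiation-limited" cohort pairs still score very low K–S — halving
  $\alpha$ changes nothing about the shape, which is exactly the signature
  the detector keys on — so the negative control behaves correctly.
  Second, many "elongation-limited" pairs also score low: the induced
  pause often fails to out-compete the pre-existing natural bottleneck, or
  creates a jam in nearly the same place, so the minimum K–S over an
  elongation-limited cohort is far below the 0.3 threshold that clean
  separation would require. Clean separation needs controls that are
  genuinely initiation-limited (initiation rate below the lattice capacity
  and a rate distribution bounded away from zero); the defaults are kept as
  the package's declared study conditions rather than re-tuned, and the
  acceptance script reports the separation statistics as measured.
* **Burn-in in deeply jammed systems.** The $3\sum 1/p_i$ burn-in is
  generous for free-flowing lattices but the queue behind a deep bottleneck
  relaxes on a slower timescale $\sim (n/\ell)/\Delta J$ when the induced
  and natural bottleneck capacities are close. Spot checks with 5× longer
  windows showed stable profiles for the cohort defaults, but users
  simulating marginal double-bottleneck configurations should lengthen
  `burnInTime` explicitly.
* **What passing simulated tests does not show.** The generator emulates
  steady-state traffic with i.i.d. per-codon rates, multinomial sampling
  and perfect P-site assignment. Real ribosome profiling adds ligation and
  nuclease biases, frame ambiguity, multi-isoform averaging, UTR read-through
  and batch effects, none of which are modelled; simulated performance
  bounds the method's behaviour under its own assumptions only.
* The offset estimator assumes initiating-ribosome pileups at the start
  codon are the modal signal per read length; datasets treated with
  initiation inhibitors (or with heavy start-codon depletion) need an
  externally supplied offset table, which every entry point accepts.
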