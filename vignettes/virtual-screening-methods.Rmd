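---
title: "Methods: dynamics-aware ensemble pharmacophore screening for AChE inhibitors"
author: "achescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics-aware ensemble pharmacophore screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achescreen)
```

# The problem

Acetylcholinesterase (AChE) terminates cholinergic signalling by
hydrolysing acetylcholine; inhibiting it is an established symptomatic
strategy in Alzheimer's disease. Structure-based virtual screening
against AChE is complicated by the flexibility of the active-site gorge:
a single receptor conformation, or a single pharmacophore hypothesis
derived from it, misses ligands that bind other conformations of the
gorge. `achescreen` implements a screening cascade built around that
observation: known inhibitors are organised into structural families;
molecular-dynamics (MD) trajectories of representative complexes supply
both an ensemble of receptor conformations for docking and a
stable/unstable partition of the trajectory from which ensembles of
complex-based pharmacophore models are derived; and two bespoke metrics
— YN1 and YN2 — fuse computational and experimental evidence into
rankings.

The commercial engines surrounding the method (induced-fit and ensemble
docking, MD propagation, pharmacophore perception and 3D matching,
pocket-descriptor analysis) are *not* reimplemented. Their outputs are
consumed through declared plain-text contracts (docking-score tables,
RMSD/RMSF traces, molecule-by-model phase-score matrices), and a seeded
synthetic-data module fabricates statistically realistic instances of
each contract so the entire cascade runs, and is tested, end to end
without them.

# Inhibitor family clustering

Libraries of known inhibitors (SMILES with IC50 in nM) are compared by
circular fingerprints (ECFP-style, radius 2; Open Babel hashes into
4096 bits and we fold to 2048 by OR-ing halves — both parameters are
exposed) under Tanimoto similarity $|A \cap B| / |A \cup B|$. A pair of
molecules with no fingerprint bits at all (bond-less structures such as
methane) is defined to have similarity 0 against anything else and 1
against another empty fingerprint. Agglomerative clustering uses
unweighted average linkage on distance $1 - s$.

The cluster count is chosen with the Kelley–Gardner–Sutcliffe penalty:
at each cut level $k$, the mean within-cluster pairwise distance is
averaged over clusters with more than one member, the level spreads are
linearly rescaled onto $[1, n-1]$, and the penalty is the rescaled
spread plus $k$. The reported optimum is the smallest $k$ attaining the
minimum. Two properties of this scheme are worth knowing. First,
because $k = 1$ is outside the admissible range, a dataset consisting
of exactly *two* tight blobs has its elbow at an excluded level and the
profile drifts toward large $k$; three or more blobs give a sharp,
reliable elbow at the blob count. Second, exactly uniform distances
rescale to a constant, the penalty reduces to $1 + k$, and the range
floor $k = 2$ wins. We expose $k$ as an ordinary parameter throughout
rather than hard-wiring the penalty's argmin, since cluster-count
choice in practice also weighs downstream computational cost.

Per-cluster IC50 statistics use the sample (n−1) standard deviation;
singletons report a flagged standard deviation of 0. The four retention
criteria are strict inequalities — mean IC50 below 10,000 nM, standard
deviation under 14,900 nM, population exceeding 58 molecules,
coefficient of variation less than 1.7 — and a cluster is retained when
it meets at least three (configurable). The cluster representative is
the member minimising mean distance to the other members,
lexicographically tie-broken.

# Conformational sampling from trajectories

The backbone RMSD of the active-site residues is monitored along each
trajectory. Seven frames are extracted per trajectory by fixed-order
selectors: nearest the mean, nearest mean − 2sd, nearest mean + 2sd
(sample sd), then the two lowest and the two highest values. Each
selector takes the best *untaken* frame, ties resolved to the earliest
frame, which guarantees seven distinct frames for any trace of length
at least seven — the collision rule matters on flat or short traces and
is deliberately simple and deterministic.

The seven conformations are reduced to five by greedy maximin
diversity selection on their paired-RMSD matrix: seed with the globally
most distant pair, then repeatedly add the conformation whose minimum
distance to the chosen set is largest (ties to the smallest index).
Greedy maximin is deterministic and within-step optimal but not
globally or even swap-optimal — tests therefore verify it
step-for-step against an independent reimplementation rather than
asserting an optimality it does not have. Paired RMSD itself supports
optional Kabsch superposition (centroid translation + SVD rotation).

# Stable/unstable zone segmentation

For the long production trajectories the goal is to label time windows
as *stable* (the binding site fluctuates around one conformation) or
*unstable* (a transition is in progress). Per monitored RMSD series the
pipeline is:

1. exponential moving average with period $p$ (default 5,000 frames,
   one tenth of a 50,000-frame trajectory; $\alpha = 2/(p+1)$,
   initialised at the first observation),
2. min–max normalisation to $[0, 1]$,
3. absolute forward difference $|x_{i+1} - x_i|$ (last point copies its
   predecessor),
4. min–max normalisation of the derivative,
5. thresholding at 0.6.

The derivative is normalised before thresholding because the raw
per-frame derivative of a $[0,1]$ signal smoothed over thousands of
frames is of order $10^{-4}$ and could never cross a 0.6 threshold; a
raw mode is exposed for comparison. A frame whose normalised derivative
of the normalised moving average exceeds the threshold is flagged; the
moving average is by construction "in transit" exactly where its
derivative is large, so a single condition suffices. Flags are
OR-combined across the monitored series of a bundle.

Two morphological clean-ups turn flagged frames into contiguous
intervals. Runs of flagged frames shorter than one tenth of the
gap-merge window are discarded first: on a perfectly stationary noisy
trace the normalised derivative still attains 1 somewhere, so isolated
single-frame threshold crossings are inevitable and do not constitute
transitions. Remaining runs separated by gaps shorter than the
gap-merge window (default 1% of the trace) are then merged. The
surviving runs are the unstable intervals; the complement of the span
is stable. An exactly constant trace short-circuits through the
degenerate-normalisation flag to a single stable zone. On synthetic
traces (5,000 frames, EMA period 500 — the same 10:1 frame-to-period
ratio as the full-scale setting, scaled down so one hundred replicates
run in under a second) planted transitions are recovered within ±2% of
the span in 100/100 seeded replicates, with the exact
three-stable/two-unstable interval structure in 100/100.

Frame extraction from the zones is a declared simplified stand-in for
trajectory pocket-analysis tooling: per stable zone, k-means (k = 3 by
default) on per-frame feature vectors returns each cluster's medoid
frame; per unstable zone, frames whose within-zone descriptor z-score
magnitude exceeds 2 are returned as atypical.

# YN1 and YN2

Ligand efficiency is $LE_i = -\mathrm{XPGScore}_i / MW_i$, with the best
(most negative) score per molecule across the conformational ensemble;
molecules with no scored pose are "not recovered" and excluded. Within
a cluster,

$$
YN1_i = \frac{LE_i - LE_{\min}}{LE_{\max} - LE_{\min}}
      + 1 - \frac{\log_{10} IC50_i - \log_{10} IC50_{\min}}
                 {\log_{10} IC50_{\max} - \log_{10} IC50_{\min}}
$$

so $YN1 \in [0, 2]$, reaching 2 exactly for a molecule attaining both
the cluster's maximal ligand efficiency and minimal IC50. Normalisation
bounds are computed over exactly the molecules passed in (the recovered
ones). A cluster in which all ligand efficiencies (or all IC50s)
coincide has that term defined as 0 and flagged.

The *ensemble phase score* of a molecule is the maximum phase score it
obtains over all pharmacophore models in an ensemble, 0 if it matches
none. With $C$ counting matched models by origin,

$$
YN2_i = \frac{1}{3}\left(
  \frac{C^{stable}_i}{C^{stable}_{tot}} +
  \frac{C^{unstable}_i}{C^{unstable}_{tot}} +
  \widehat{Ph}_i\right),
\qquad
\widehat{Ph}_i = \frac{Ph_i - Ph_{\min}}{Ph_{\max} - Ph_{\min}},
$$

and $YN2_i = 0$ whenever $Ph_i < Ph_{\min}$, where $Ph_{\min}$ and
$Ph_{\max}$ are fitted from known actives during validation. Novel
screening libraries can exceed $Ph_{\max}$; the phase term is then
clamped at 1 and flagged rather than letting YN2 leave $[0, 1]$. A
degenerate $Ph_{\max} = Ph_{\min}$ defines the phase term as 1 at or
above the bound, flagged.

The YN2 activity threshold maximises recall + specificity over the
finite candidate set of observed YN2 values (a molecule is active when
its score is ≥ the threshold, so observed values exhaust the distinct
classifications; a dense grid can be added for comparison). Ties take
the smallest threshold, favouring recall. Ensemble validation in
"plain" mode uses the OR rule — one matching model makes a molecule
active — with ROC-AUC from the ensemble phase score; in "yn2" mode it
fits the parameters, optimises the threshold and reports metrics there.
On generated matrices with overlapping active/decoy score
distributions, YN2 mode improves specificity over the plain OR rule in
effectively all seeds at modest recall cost, which is the behaviour the
metric was designed for. Screening returns the top 500 (configurable)
YN2-ranked molecules at or above the threshold, ties broken by
molecule id for reproducibility.

ROC-AUC is computed as the normalised Mann–Whitney rank statistic with
tie averaging, balanced accuracy as the mean of recall and specificity.

# Family classifiers

Per family, actives are split 80/20 (test size `floor(n × 0.2)`,
uniform without replacement under a seed). Decoy generation is a
self-contained property-matched sampler standing in for DUDE-style
services: a pool molecule can serve as decoy for an active when it
falls inside physicochemical windows (MW ±25 g/mol, logP ±1, HBD/HBA
±1, rotatable bonds ±2) yet is structurally dissimilar (Tanimoto < 0.4
to *every* active); each pool molecule is used at most once and
shortfalls are reported.

Descriptor preparation removes constant columns, min–max scales the
rest, groups descriptors with $|r| \ge 0.9$ by transitive closure, and
keeps each group's highest-variance member (column order breaks ties).
Min–max scaling, not standardisation, precedes the variance
comparison: standardisation would force every variance to 1 and make
the rule vacuous. Training decoys are balanced by k-means with k equal
to the number of training actives, keeping the decoy nearest each
centroid.

Four classifiers — logistic regression, radial-kernel SVM, decision
tree, random forest — are tuned by stratified 5-fold cross-validation
maximising ROC-AUC over deliberately small, fixed grids (SVM: cost
{0.1, 1, 10} × gamma {0.01, 0.1, 1}; tree: cp {0.001, 0.01, 0.1};
forest: mtry {1, √d, d/3}, 300 trees; logistic regression has no tuned
hyperparameter), then refit on the full balanced set. Model selection
sums four equally weighted [0, 1] terms — test specificity, the
true-negative fraction on decoys excluded during balancing, family
recall, and non-family rejection — with ties resolved random forest >
SVM > logistic regression > decision tree.

# Assay analysis

Ellman-type kinetic reads (absorbance at 407 nm every 45 s over 15 min)
yield initial velocities as the least-squares slope over an early
window: every prefix of at least 3 points up to 5 minutes is scored by
R², the best R² wins and ties go to the longest prefix (a perfectly
flat trace is R² = 1 by convention, giving slope 0 over the full
window). Percent inhibition is
$(1 - V_0^{sample}/V_0^{control}) \times 100$ — the scale factor is
exposed for audit. IC50 defaults to log-linear interpolation between
the concentrations bracketing 50% inhibition (replicates averaged per
concentration first; an exact 50% observation is returned as-is), with
a four-parameter logistic fit as the robust alternative that falls back
to interpolation, flagged, on non-convergence. Mass concentrations
convert to molar as $c/MW \times 10^6$ (µg/mL → nM), optionally rounded
to the nearest 100 nM as assay tables conventionally report. On 200
seeded synthetic plates (1:1 dilutions from 450 downwards, 3
replicates, 2% velocity noise) the median relative IC50 recovery error
is under 10%.

# What the synthetic data does and does not show

The generators emulate the *statistical shape* of each consumed
contract: family-structured libraries built from ten fused-ring
scaffolds with short enumerated decorations (so within-family Tanimoto
exceeds between-family — short side chains matter, since long
decorations would dominate the fingerprints of small scaffolds);
log-normal within-family IC50s (sdlog 0.8, a typical within-series
assay spread; geometric means 500/5,000/20,000 nM by default);
piecewise-stationary Gaussian RMSD traces with linear transition ramps;
docking scores Gaussian around −6 kcal/mol with a −3 kcal/mol shift for
actives and a configurable unrecovered fraction; Bernoulli phase-score
matrices whose match probabilities and score means depend on origin and
label; and linear kinetic traces attenuated by a Hill curve. Every
generator is a pure function of its seed.

Passing recovery tests on these inputs demonstrates that the *methods*
behave as specified under known ground truth. It does not demonstrate
enrichment on real chemical libraries: real fingerprint spaces are not
clean blobs, real trajectories have correlated noise and drifting
baselines, and real phase scores are not conditionally independent
Bernoulli draws. Those claims would require the external engines and
databases that are out of scope here.

# Numerical choices and limitations

* Default test-scale problem sizes: 5,000-frame traces (EMA period
  500), libraries of tens of molecules per family, 100–200 seeded
  replicates for recovery suites. All full-scale defaults (50,000
  frames, period 5,000, 500-molecule screening lists) remain the
  package defaults.
* Degenerate normalisations (zero ranges) return flagged zeros rather
  than errors throughout, so constant inputs flow through the cascade
  as "no signal" rather than aborting it.
* k-means steps use seeded initialisation (`nstart` 5–10) and report
  medoids with smallest-id tie-breaks, making every clustered output
  reproducible under a seed.
* The rotatable-bond count is derived from the connection table
  (non-ring single bonds between non-terminal heavy atoms) and does not
  exclude amides; decoy windows of ±2 absorb the difference.
* The ligand-based pharmacophore stage of the cascade consumes an
  externally produced match table; only its filter logic (≥ 1
  hypothesis match) lives here. The final ensemble-docking + MMGBSA
  re-ranking of the top list is out of scope by design; the cascade
  terminates at the YN2-ranked list.
* Multi-family fan-out assigns a screening molecule to every family
  whose classifier accepted it; downstream stages then treat the
  families independently.
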