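---
title: "A constricted HMM for enhancer and promoter prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A constricted HMM for enhancer and promoter prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Active enhancers and promoters share a stereotyped chromatin architecture: a
nucleosome-free, accessible core (strong ATAC-seq or DNase-seq signal)
flanked on both sides by well-positioned nucleosomes carrying activating
histone marks. Enhancer flanks are rich in H3K4me1 and H3K27ac; promoter
flanks are distinguished chiefly by high H3K4me3 relative to H3K4me1.

`crehmm` encodes this architecture in a *constricted* hidden Markov model: a
22-state HMM whose transition matrix carries a boolean mask of allowed
moves. Ten background (BG) states absorb everything that is not an active
element. Each of the two foreground modules (enhancer E, promoter P) has six
states in three groups — two first-nucleosome states (N1), two
accessible-core states (A), two second-nucleosome states (N2) — and can only
be traversed in the order BG → N1 → A → N2 → BG. Self- and within-group
transitions let elements vary in length; transitions against the
directionality (A back to N1, N2 back to A, N1 skipping A) have probability
exactly zero. The payoff of the grammar is that every decoded element is
guaranteed to contain an accessible core with nucleosomal flanks — the
failure mode of unconstrained segmentations, which happily emit "enhancers"
that skip the nucleosome-free region, is structurally impossible.

Observations are per-bin read counts (default 100 bp bins) of the four
features in canonical order: accessibility, H3K27ac, H3K4me1, H3K4me3.
ChIP-seq reads are shifted 75 bp toward the fragment center (half the
expected 150 bp fragment); accessibility reads are not shifted because the
cut site itself is the signal. A pseudo-count of 1 keeps logarithms finite.

## Emissions

Given the state, features are independent and each pseudo-counted count
follows a log-normal distribution with parameters $(\mu, \sigma)$ on the
log scale. Fitting is by (weighted) moments of $\log v$: $\mu$ is the
weighted mean and $\sigma$ the reliability-weighted (unbiased) standard
deviation, which reduces to the usual $n-1$ form for unit weights.

Two numerical floors on $\sigma$ matter:

* `fit_lognormal()` floors $\sigma$ at $10^{-3}$, purely to keep the density
  proper when a state models a single coverage value (such states are
  assigned a Kolmogorov–Smirnov fit distance of 0 by convention).
* Unsupervised fitting (`fit_hmm_unsupervised()`, hence the 5-state
  foreground and 10-state background fits) floors $\sigma$ at 0.2 by
  default. Counts are integers, so the continuous log-normal likelihood is
  unbounded as a state collapses onto one count value; without a floor, EM
  reliably discovers these spikes and dedicates states to single values of
  the weakest feature instead of to chromatin states. A floor of 0.2 (about
  half a typical fitted $\sigma$) removes the spikes while still allowing
  near-constant states.

## Supervised construction

Foreground modules are built in two steps. First a conventional
(unconstrained) 5-state HMM is fitted to the training regions by
Baum–Welch, seeded by k-means on the log counts (seed exposed, default 0;
uniform transitions). Second, states are selected by their emission means
$e^{\mu + \sigma^2/2}$: the two states with the highest
accessibility/H3K27ac ratio become A-states; of the remaining three, the
two with the highest (enhancer) or lowest (promoter) H3K4me1/H3K4me3 ratio
become N-states; the fifth is discarded. The N-states are duplicated into
N1 and N2 groups (N2 emissions are exact copies) and arranged in the
directed order, with transition rows initialized from the 5-state fit
restricted to the mask.

The module is then refined by *Viterbi training* rather than Baum–Welch:
per iteration, each training region is decoded with the first bin
constrained to N1 roles and the last bin to N2 roles (training regions are
built to start and end at nucleosome positions), and transitions are
re-estimated from the hard path counts. Emissions are frozen throughout, so
states selected for a role cannot drift. The constraints are applied in the
Viterbi lattice (first/last-bin scores of other states set to $-\infty$),
not by modifying the model; the training initial distribution is uniform
over the allowed start states. Both constrained ends are an interpretation:
the construction forces regions to *end* in N2, and since training regions
are symmetric peak triplets we constrain the start to N1 as well. An
add-$\varepsilon$ count ($10^{-6}$) on every allowed transition prevents an
allowed move from collapsing to exactly zero on finite data. Ties in the
Viterbi argmax break toward the lowest state index, making decoding fully
deterministic.

The background model is a conventional 10-state HMM fitted the same
unsupervised way on an unbalanced training set meant to reflect genomic
proportions (10% enhancers, 5% active promoters, 5% inactive promoters, 10%
genic, 70% intergenic); regions annotated as enhancers or active promoters
are excluded and their quota re-allocated to genic/intergenic draws, so the
background never trains on foreground signal.

## Composition

The three sub-models are stacked into one 22-state model. Background rows
are rescaled by $1 - r_E - r_P$ where the entry rates are expected elements
per bin: with 399,124 enhancers and 70,292 promoters in a 3 Gb genome at
100 bp bins, $r_E = 399124 / 3\times10^7 = 1.33\%$ and $r_P = 0.23\%$
(computed exactly from the configuration, not hard-coded). Entry mass is
split between a module's two N1 states by the module's stationary occupancy
when defined; the refined module chain is absorbing in its N2 group, so in
practice the documented 50/50 fallback applies. Each N2 state's exit mass
to the background is set to the matching N1 state's total N1→A mass (N1 and
N2 stretches are expected to be equally long) and distributed over
background states by the background model's stationary distribution; N2
intra-group mass is rescaled to keep rows stochastic. The composed model is
not re-trained. No emission parameter is altered at any point after the
sub-model fits.

## Decoding and scoring

Genome-wide prediction uses Viterbi decoding — the globally most likely
path — which by construction respects the grammar and yields a definite
element set with no score threshold to choose. Posterior decoding is
deliberately not used for segmentation (it need not respect the grammar),
but the forward–backward posteriors provide a per-bin certainty score: the
summed posterior of the accessibility states, reported separately per
module (`score_enhancer`, `score_promoter`); the enhancer-module score is
the headline certainty. An element's score is the maximum per-bin
accessibility posterior inside it (posterior certainty peaks at element
centers, so the maximum is the natural summary). Chromosomes are decoded
independently, with the initial distribution applied per chromosome.

Cross-sample application uses quantile normalization: query counts are
replaced rank-wise by reference quantiles stored in the model (linear
interpolation between 1000 stored knots; tied query values receive the mean
of the spanned reference quantiles). The core map is continuous — rounding
inside the map would break its order preservation and idempotence — and the
`signal_matrix`-level wrapper rounds the result to non-negative integers so
downstream code sees ordinary counts. Normalization operates on raw counts
per feature, before pseudo-counting, and genome-wide rather than per
chromosome.

## The synthetic world

`default_truth_model()` states a complete 22-state generative model:
background states with assorted low-level signal (log-count means 0.25–1.1;
means below ~0.25 are avoided because integer rounding of the simulated
counts would distort them), enhancer modules whose N states are high in
H3K4me1/H3K27ac and whose A states are highly accessible, and promoter
modules marked by high H3K4me3. The two states of each foreground group are
given genuinely distinct profiles (e.g. one N flavor higher in H3K4me1, the
other in H3K27ac), since real elements are heterogeneous and a 5-state fit
is only identifiable if five distinct profiles exist. "Easy" separation
puts ≥ 2 log-units between discriminating means; "hard" compresses the
foreground-background contrast to ≤ 0.5. Entry rates equal the default
genome-composition rates; self-transitions of 0.6 per foreground state with
0.35 group-exit mass give mean group dwell near 3 bins, i.e. ~900 bp
elements.

`simulate_truth()` samples the state path and draws the pseudo-counted
value of each bin/feature as $\mathrm{round}(e^{N(\mu,\sigma)})$ clamped to
≥ 1 (counts are that value minus the pseudo-count), so `log(count + 1)`
follows the emission model exactly up to integer rounding. This matches the
emission family on purpose — recovery tests are then well-specified — and
is also the generator's main unrealism: real counts are overdispersed
mixtures with mappability artefacts, duplicate structure and
chromosome-scale covariates that the simulation does not model. A green
end-to-end test therefore establishes correctness of the estimation and
decoding machinery, not performance on real chromatin.

Synthetic training sets mirror the real protocol: foreground regions are
isolated truth elements (pairwise gap ≥ 2 kb, ≥ 5 bins long) and background
regions are random 2 kb windows that exclude all truth elements.

## Defaults and degenerate inputs

* bins 100 bp; ChIP shift 75 bp, accessibility 0; pseudo-count 1.
* Baum–Welch: `max_iter` 100, `tol` 1e-4 on the log-likelihood; Viterbi
  training: `max_iter` 50, stops at a path fixed point.
* k-means seeding falls back to deterministic per-feature quantile seeding
  when there are fewer distinct observation rows than states.
* Rows that receive no expected mass in an M-step keep their previous
  values; masked entries stay exactly zero through any number of updates.
* Bins never covered by reads keep a zero count (no masking of unmappable
  regions); regions or reads on unknown chromosomes are skipped with a
  warning.
* Neighbor removal drops *both* members of any pair closer than 2 kb
  (edge-to-edge), keeping only isolated training elements.
* The precision-recall area uses the average-precision (step) estimator,
  stated explicitly because estimator choice moves AUPRC by ~0.01.

## Known limitations

Exactly two foreground modules (enhancer, promoter) are supported. Emission
independence across features is an approximation; the model ignores strand
and replication timing; posterior scores are per-module rather than joint.
Whole-genome element counts on real data depend on the full input tracks
and cannot be validated from the synthetic world.
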