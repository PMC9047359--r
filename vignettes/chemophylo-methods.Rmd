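---
title: "Methods: from MS/MS spectra to chemical synapomorphies"
author: "chemophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MS/MS spectra to chemical synapomorphies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemophylo)
```

chemophylo turns untargeted LC–MS/MS metabolomics data collected across a
set of related taxa into phylogenetically interpretable characters. The
workflow has three layers: (i) spectral — clean MS/MS spectra, score their
pairwise similarity and group them into molecular families; (ii)
compositional — summarise feature abundances into chemical classes,
ordinate samples and test clade effects; (iii) evolutionary — code class
detections as binary genus-level characters and reconstruct their history
on a phylogeny under a one-rate Markov model. This vignette explains the
models, the defaults and the numerical choices, and what the synthetic
validation data do and do not establish.

## Spectral similarity and molecular networking

Spectra are cleaned with two standard filters before scoring. Fragment
ions within ±17 Da of the precursor m/z are removed (a closed interval on
both sides: residual precursor signal in QTOF data-dependent acquisition
can sit slightly above or below the recorded precursor). Each remaining
peak is kept only if it ranks among the top 6 by intensity within the
±50 Da window centred on its own m/z; intensity ties rank the lower-m/z
peak first so the filter is deterministic, and both filters are
idempotent.

The **modified cosine** score between two spectra treats each peak as a
weight $w = \sqrt{I}$, scaled per spectrum to unit Euclidean norm, and
allows a fragment pair $(i, j)$ to match either directly
($|m_i - m_j| \le 0.02$ Da) or offset by the precursor mass difference
$\Delta = M_a - M_b$ ($|m_i - m_j - \Delta| \le 0.02$ Da). The score is
the maximum of $\sum w_i w_j$ over one-to-one peak assignments. We solve
this assignment **exactly** (branch-and-bound over the sparse
candidate-pair list, which at 0.02 Da tolerances holds at most a handful
of conflicting pairs) rather than greedily: greedy matching by descending
weight product is a common implementation shortcut and is available via
`similarity_params(assignment = "greedy")`, but it can return a
sub-optimal sum when a high-product pair blocks two medium pairs, and we
want the reported score to be the defined maximum. Ties between equally
scoring assignments resolve toward the larger matched-peak count.

Network edges require cosine strictly above 0.7 **and** at least 4
matched peaks; library annotation uses the same thresholds plus a 0.02 Da
precursor gate, keeping the best-scoring hit (ties: more matched peaks,
then library order). Connected components of the resulting graph are the
molecular families. We deliberately apply no top-K neighbour pruning and
no maximum-component-size splitting; both exist in some networking
platforms but change the component structure, and the package's defaults
stay with the two stated thresholds. Blank subtraction is available as an
optional node filter (`blank_fraction`): features whose mean blank area
reaches that fraction of their mean sample area are dropped. There is no
universally accepted cutoff for "abundant in blanks", so the default
pipeline leaves it off.

## Ordination, PERMANOVA and two-group profiles

Sample dissimilarities use Bray–Curtis
($\sum|x_i-y_i| / \sum(x_i+y_i)$) for between-protocol comparisons and
Canberra ($\sum |x_i-y_i|/(x_i+y_i)$ over features not zero in both
samples) within subsets. Note the Canberra variant: terms with a zero
denominator are skipped and the sum is **not** divided by the number of
non-zero pairs, unlike some ecology toolkits that rescale by $1/NZ$;
distances here are therefore comparable across sample pairs with
different sparsity but not across datasets with different feature counts.

PCoA is classical metric scaling: eigendecomposition of
$-\tfrac12 J D^2 J$ with $J$ the centering matrix. Axes with negative
eigenvalues (possible for semimetric distances) are reported but carry no
coordinates, and no Lingoes/Cailliez correction is applied — the
proportion of variance explained is taken over positive eigenvalues only.
On Euclidean distances this reproduces PCA scores exactly up to axis
sign, which the tests exploit as an oracle.

PERMANOVA partitions squared distances in a one-way design:
$SS_T = \sum_{i<j} d_{ij}^2 / N$, $SS_W$ the analogous within-group sum,
pseudo-$F = \frac{(SS_T-SS_W)/(a-1)}{SS_W/(N-a)}$. Significance comes
from unrestricted permutation of group labels with
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$, 999 permutations by default,
seeded explicitly. The permutation stream is run inside the package (a
vectorised indicator-matrix computation over all permutations at once) so
large null calibrations stay cheap; the vegan implementation serves as an
independent cross-check in the test suite. On univariate Euclidean data
the pseudo-F equals the classic ANOVA F to machine precision. One caveat
baked into the definition: permutations that happen to reproduce the
observed partition (or its complement, in a balanced two-group design)
tie with the observed statistic, so the attained p can sit one or two
steps above the nominal floor of $1/(n_\pi+1)$.

The two chemical-profile groups that an analyst would read off a PCoA
plot are operationalised as 2-medoid partitioning (PAM) on the distance
matrix; the group containing the lexicographically first sample id is
labelled "A" so reruns are stable, and a non-positive mean silhouette
flags a low-separation (essentially arbitrary) split.

## Chemical classes and clade enrichment

Per-feature binary fingerprints are clustered by Euclidean distance with
average-linkage agglomeration into a rooted chemistry tree, then pruned
to leaves classified at the superclass level (degree-2 nodes contracted,
branch lengths summed, so leaf-to-leaf path lengths are preserved). The
linkage criterion is configurable (`ward.D2`, `complete`, ...) because no
single choice is canonical for fingerprint hierarchies; average linkage
is the default as the least shape-biased of the common options.
Fingerprints are treated as binary vectors, not probabilities — the
synthetic stand-ins are binary, and Euclidean distance on bits equals the
square root of the Hamming distance.

Class abundance per sample is the summed area of the class's features
divided by the sample's total area, so values lie in $[0,1]$ and
unclassified features dilute but never inflate a class. Enrichment
testing arcsine-square-root transforms these proportions
($y = \arcsin\sqrt{p}$, the classical variance-stabiliser with endpoints
$0 \mapsto 0$, $1 \mapsto \pi/2$), runs a one-way ANOVA per class across
the tested clades, adjusts p-values across classes with
Benjamini–Hochberg, and follows up with Tukey HSD pairwise contrasts.
Effect sizes are log2 fold changes of the **untransformed** mean relative
abundances per clade pair (antisymmetric by construction; infinite when a
class is entirely absent from one clade, which is reported as-is rather
than pseudocounted). Classes constant across all samples carry no
information for the F statistic and are skipped with a note. The heatmap
matrix keeps classes with adjusted p below 0.05.

## Character coding

Class detections become binary characters in three steps, each with a
strict-inequality threshold exposed: species presence (relative abundance
> `min_abundance`, default 0, in at least one sample), genus presence
(arithmetic mean of species presences > `threshold`, default 0 — i.e. any
sampled species suffices; with the default the mean-then-threshold rule
reduces to an OR, but raising the threshold lets a user require, say, a
majority of sampled species), and mode merging (logical OR of the
positive- and negative-mode matrices over the union of their characters,
with per-character provenance recording `pos`, `neg` or `both`). Merging
is commutative and idempotent. A separate one-character coding maps each
genus to the majority PCoA profile group of its samples, ties resolved to
the first sample's group and flagged.

## Mk1 ancestral state reconstruction

Characters evolve under the two-state symmetric Markov model with a
single rate $q$: over a branch of length $t$,
$P(\text{flip}) = \tfrac12 - \tfrac12 e^{-2qt}$. Likelihoods use
Felsenstein's pruning algorithm with per-node rescaling (so hundreds of
tips pose no underflow risk) and a uniform root prior — the stationary
distribution of the symmetric model, and the only prior that treats
presence and absence symmetrically. The rate is fitted per character by
default (each chemical class evolves at its own tempo; a shared-rate fit
across characters is available and is what the rate-recovery validation
uses, since a single binary character carries little information about
$q$). Optimisation is one-dimensional on $\log q$ over
$[10^{-8}, 100]$; characters invariant across tips sit at the lower
bound and are flagged rather than fitted. Zero-length input branches are
replaced by $10^{-8}$ with a warning so transition matrices stay
non-singular.

Marginal posterior state probabilities per node come from the standard
two-pass (up/down) algorithm; they sum to one at every node and match
brute-force enumeration over internal labellings on small trees to
$10^{-10}$. The maximum-a-posteriori (MAP) state labels every node, with
an exact 0.5 tie resolved to absence and flagged (ties are measure-zero
in practice). Gains are edges reconstructed $0 \to 1$ and losses
$1 \to 0$; the number of independent origins of a state additionally
counts the root if the root itself carries that state. A parsimony-style
labelling (Fitch sets with a parent-preference top-down refinement, root
ties toward absence) is available via `run_asr(method = "parsimony")`
for comparison with parsimony-based visualisers; it is a plain Fitch
refinement, not a full ACCTRAN edge resolution, and the ML MAP labelling
remains the default.

A character supports a clade as follows: the clade's tips must be
uniform for some state $s$; the clade's MRCA must be reconstructed as $s$
with its stem parent $\lnot s$ (a stem change); then a single origin of
$s$ on the whole tree makes the character a **synapomorphy** (present or
absent according to $s$), more than one makes it a **homoplasy**, and
anything else is uninformative. This is the standard cladistic reading;
the package applies it to ML reconstructions because no operational
definition is universal for probabilistic node states, and the
single-origin + stem-change rule is the strictest one that reduces to the
parsimony notion as $q \to 0$. Two consequences worth knowing: a clade
whose MRCA is the tree's root can never receive a call (it has no stem),
and a derived state shared by a clade spanning most of the tree tends to
be reconstructed as ancestral at the root under the uniform prior, again
yielding no call. Characters present in every genus are reported as
ubiquitous and excluded from clade calls.

## The synthetic study

The generator produces every input the pipeline consumes, with known
ground truth, under a single master seed that derives an independent
stream per stage (so any stage reruns identically in isolation).

* **Compound families**: each family is a base spectrum (default 12
  peaks, m/z uniform below precursor − 20 Da, lognormal intensities
  scaled to a maximum of 100) plus derivatives whose precursor and a
  random half of the peaks shift by a sampled neutral loss — defaults
  162.053 (hexoside), 146.058 (deoxyhexoside), 132.042 (pentoside) and
  18.011 Da (water), the glycosidic losses that make plant-metabolite
  families cohere in real networks. Within a family every peak aligns
  either directly or under the precursor shift, so the modified cosine
  stays near 1 (mild lognormal intensity jitter, sdlog 0.1); between
  families random peaks essentially never align within 0.02 Da.
* **Feature tables**: per-sample areas are lognormal (meanlog 11,
  sdlog 1 — peak areas in the 10^4–10^5 range typical of QTOF peak
  integration) with Bernoulli dropout (default 0.1). One class per
  configured clade is planted exclusively: nonzero in every sample of
  that clade, zero elsewhere. A second extraction solvent is an
  independent detection draw in which each feature is entirely missed
  with probability 0.25, emulating protocol selectivity.
* **Tree and clades**: a pure-birth tree over the genera, ultrametric
  with root age normalised to 1; clades are carved as monophyletic
  dendrogram cuts (or user-specified tip sets, with redraws until
  monophyletic).
* **Characters**: forward simulation of the same Mk1 model the inference
  assumes — uniform root state, per-branch flip probability
  $\tfrac12 - \tfrac12 e^{-2qt}$ — recording true node states and origin
  counts.

What passing on these data shows — and what it does not. The generator
matches the analysis assumptions by construction: families are exactly
neutral-loss-related, abundances are exactly lognormal with independent
dropout, characters evolve exactly under Mk1, and there is no
chromatographic structure, no isotopes or adducts, no instrument noise
model, and no model misspecification. Recovery of the planted structure
therefore validates the *implementation* (and the statistical power of
the stated thresholds under clean conditions), not the robustness of the
method to real instrument data, co-eluting isomers, batch effects or
violated evolutionary models.

## Validation problem sizes

The test suite checks the exact-assignment cosine against an exhaustive
matching oracle on 1,000 random spectrum pairs of up to 8 peaks; pruning
likelihoods against enumeration on every rooted topology of 2–5 tips
plus random 6-tip draws; PERMANOVA calibration over 500 null datasets of
20 samples with 999 permutations each; family recovery over 20 seeded
simulations of 3–10 families; rate recovery on a 32-tip tree at 100, 500
and 2,000 characters (15 replicates each, shared-rate fit); and
synapomorphy recovery over 50 seeded 12-genus studies with the planted
clade chosen at roughly a third of the tips, for the stem-adjacency
reason above. These sizes were chosen so each property is tested at the
smallest scale where its failure modes can appear.

## Known limitations

* MGF is the only spectral input format (no mzML/mzXML raw data; feature
  detection is upstream).
* Characters are strictly binary; no ambiguity codes, polymorphic tips
  or multistate characters.
* The Mk fit assumes the tree is correct and branch lengths meaningful;
  rate estimates from single characters are noisy and best interpreted
  jointly.
* Ionization modes are kept as separate tables end-to-end and only merge
  at the binary character stage; features absent from one mode's table
  are never zero-padded for cross-mode abundance comparisons.
* The annotation stage matches against a user-supplied MGF library only;
  no external spectral-library services are queried.
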