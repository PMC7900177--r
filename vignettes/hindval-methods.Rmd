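---
title: "Blocked indicator value analysis of compartmentalised gut communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked indicator value analysis of compartmentalised gut communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindval)
```

## The problem

Hindgut fermenters such as horses host distinct microbial communities in
each intestinal compartment, and the practical question is which features of
an easily collected fecal sample are informative about the inaccessible
upstream compartments. hindval implements the statistical core of that kind
of survey for a blocked design: each of `b` animals (horses, the blocks) is
sampled at each of `a` body sites — here cecum, right ventral colon, right
dorsal colon and feces, in proximal-to-distal order — and each sample is a
16S feature table column. Everything downstream of denoising and taxonomic
assignment is in scope: rank collapse, rarefaction, alpha and beta
diversity with permutation inference that respects the blocks, and the
indicator value analysis that names the taxa characterising each
compartment or group of compartments.

## The community table and rank collapse

Analyses run on abundances $y_{ijr}$ for body site $i$, horse $j$ and taxon
$r$ at a chosen rank, by default family. Collapsing sums feature counts
sharing a label at that rank; a feature with no family assignment keeps its
deepest assigned name plus a parenthesised rank letter — `Synergistales
(o)`, `Spirochaetes (p)`, `Anaerolineae (c)` — so partially classified
lineages remain distinct countable taxa instead of disappearing into an
"unclassified" pool. Assignment is prefix-closed (a rank can only be
assigned if every shallower rank is), which makes the count-weighted
classification rate monotonically non-increasing with rank depth. Family is
the default analysis rank because, in the kind of data this package
targets, roughly 60% of reads are family-assigned against ~38% at genus and
~27% at species. Abundances are numeric rather than integer so that
published per-sample *relative* abundances can be analysed too: with even
per-sample depths, faithfulness, exclusiveness and IndVal are invariant to
a common per-sample scale (this is tested).

## Rarefaction and diversity

Samples are subsampled without replacement to an even depth before
diversity comparison; samples below the depth are dropped with a warning.
The depth is a design choice of the study being analysed (the motivating
survey used 59,157, retaining 1,419,768 of 2,163,951 sequences, 65.61%,
across all 24 samples). Shannon diversity is reported in base 2 by default
— the convention of common upstream 16S platforms; published H values in
the 8-ish range for thousands of features do not disambiguate the base, so
it is a flag and is recorded with the result. Site effects on alpha
diversity are tested pairwise by tie-corrected Kruskal–Wallis, reported
raw.

Beta diversity uses square-root transformed abundances (damping the extreme
dynamic range of count data) and Bray–Curtis dissimilarity
$d(u,v)=\sum|u-v|/\sum(u+v)$, a semimetric bounded in $[0,1]$; the triangle
inequality is neither guaranteed nor asserted anywhere. Ordination is
classical PCoA on the Gower-centred $-D^2/2$ matrix; negative eigenvalues
are reported but excluded from coordinates and no additive correction is
applied, with the choice recorded in the result. Proportions explained are
taken against the sum of absolute eigenvalues so they sum to at most one.

## PERMANOVA and its permutation schemes

The pseudo-F partitions squared dissimilarities directly,
$SS_T=\sum_{u<v}d^2_{uv}/N$ and the within-group analogue per group, so no
Euclidean embedding is needed. Inference is by permutation under three
schemes:

* **free** — labels permuted across all samples; add-one p-value
  $(1+\#\{F^*\ge F\})/(1+n_{perm})$, default 9999 permutations. Used for
  the overall site test.
* **within_block** — labels shuffled independently inside each block;
  sampled, add-one p. Exposed because the blocked design makes restricted
  permutations defensible for the overall test as well; the pseudo-F itself
  is scheme-independent, only the p-value changes.
* **exhaustive_within_block** — for a pair of groups with one sample per
  group per block, all $2^b$ within-block swaps are enumerated and the
  p-value is the exact count including the identity. Swapping *every* block
  relabels without repartitioning, so statistics come in mirror pairs, the
  achievable p-values are even multiples of $2^{-b}$, and the smallest is
  $2/2^b$ — 0.03125 for six horses, which is exactly the value a pairwise
  comparison reports when the two compartments are maximally separated.
  Used for all pairwise site tests; pairwise p-values are reported raw, with
  no multiplicity correction.

Because PERMANOVA assumes comparable dispersions, `permdisp()` tests
homogeneity of group dispersions: samples are embedded by PCoA keeping the
"imaginary" part (squared distances to a group centre are the positive-axis
contribution minus the negative-axis magnitude, clamped at zero), a one-way
ANOVA F is computed on the distances to group centroids, and significance
comes from permuting those distances. Centroids are the default centre; a
spatial median (Weiszfeld, positive axes) is available, since the
literature uses both.

## The indicator value analysis

For taxon $r$ and site $i$, with $\bar y_{ir}$ the mean over horses and
$I_{ijr}$ the presence indicator:

$$F_{ir}=\frac{\sum_j I_{ijr}}{b},\qquad
  E_{ir}=\frac{\bar y_{ir}}{\sum_i \bar y_{ir}},\qquad
  IV_{ir}=\sqrt{E_{ir}F_{ir}}.$$

Faithfulness $F$ is constancy of presence across the blocks; exclusiveness
$E$ is the site's share of the taxon's across-site mean abundance (defined
as 0 for a taxon absent everywhere, so $\sum_i E_{ir}$ is 1 or 0 exactly).
A taxon's overall indicator value is the maximum of $IV_{ir}$ over
candidate groups, with the achieving group recorded; ties go to the first
group in site order and are flagged. Values near 1 mean the taxon is both
constant within and specific to the group.

For a *combination* $C$ of sites the package uses a merged-group reading:
$F_{Cr}$ is presence constancy over all $b|C|$ samples of $C$, and
$E_{Cr}=\bar y_{Cr}/(\bar y_{Cr}+\sum_{i\notin C}\bar y_{ir})$ with $\bar
y_{Cr}$ the mean over all samples in $C$. This is a design decision, not a
formula taken from elsewhere: it reduces exactly to the single-site
definitions when $|C|=1$ (tested), rewards taxa shared uniformly across the
combined compartments, and reproduces the expected ordering in which a
taxon shared by two adjacent compartments scores higher for the pair than
for either site alone. A combination of *all* sites is rejected, since
$E$ then degenerates to 1 by construction. The default combination list is
every contiguous run of 2 or 3 sites in anatomical order, the groups of
interest on either side of the pelvic flexure.

Significance uses a blocked Monte-Carlo randomization: in each of 9999
rounds (default) the site labels of each horse's samples are shuffled
independently within that horse, one relabelled table shared by all taxa,
and the full statistic — including the max-over-groups step — is
recomputed. The add-one convention gives p-values on a $10^{-4}$ lattice at
9999 rounds. Within each run (single-site and combined-site runs are
corrected separately, as they are separate analyses) Benjamini–Hochberg
controls the FDR at 0.05 by default; taxa absent everywhere are retained
with $IV=0$, $p=1$ for stable bookkeeping. An exhaustive enumeration is not
offered: with four sites and six blocks the group is $24^6 \approx 1.9
\times 10^8$ relabellings.

Numerical notes: permutation statistics are compared with a $10^{-12}$
margin so exact ties (a permutation that reassembles the observed grouping)
survive floating-point reordering of sums; the $E$ denominator is invariant
under within-block relabelling and is computed once; permutation rounds are
processed in batches of 512 through one indicator-matrix multiplication,
with squared IVs compared to avoid a matrix square root per round.

## The synthetic community generator

Every stage is testable without sequencing data through
`synthetic_design()` / `generate_study()`. The model: each site has a base
composition (rows summing to 1); each horse carries a log-normal block
effect, one $N(0,\sigma^2_h)$ log-scale factor per taxon *shared across
that horse's sites* — precisely the within-horse correlation the blocked
permutation tests assume; each (horse, site) cell draws its composition
from a Dirichlet centred on the effect-perturbed site composition with
total concentration $\theta$ (overdispersion; $\theta=\infty$ gives plain
multinomial), and counts are multinomial at a log-normal library size.
Defaults mirror the motivating study's shape: 6 horses, the four hindgut
sites, 87 families, mean library size 90,000. The library-size CV (0.3) is
a chosen, not inferred, value — the study reports no pre-rarefaction depth
spread — as are $\sigma_h=0.5$ and $\theta=200$ for the plain generator.
All draws flow from one seed through per-horse and per-(horse, site)
counter-based substreams, so a fixed seed is byte-reproducible and
enlarging one part of the design does not reshuffle unrelated draws.

Planted indicators make power measurable against ground truth: a planted
taxon receives mean relative abundance $a$ in its target sites and
$a(1-E^*)/(E^*n_{off})$ elsewhere — the remaining taxa are rescaled per
site so rows still sum to 1 — giving expected exclusiveness exactly $E^*$;
faithfulness is realised exactly by drawing $round(F^*b)$ carrier horses
per target site, so $F^*$ must be a multiple of $1/b$. Infeasible requests
(zero target abundance with positive $E^*$, $E^*<1$ with no off-target
site) fail before any sampling.

`pelvic_flexure_preset()` is a ready-made 87-family design reproducing the
motivating survey's headline structure: a Bacteroidetes aggregate of 0.50
proximally versus 0.30 distally, an Euryarchaeota fraction rising toward
the feces, near-identical compositions within the proximal and distal
pairs, and a taxonomy in which roughly 40% of expected reads are only
order-, class- or phylum-assigned. Its noise levels
($\sigma_h=0.3$, $\theta=300$) were chosen so a generated study shows the
qualitative behaviour of the real one — a dominant first PCoA axis
splitting the pairs at the pelvic flexure, a strongly significant overall
PERMANOVA with non-significant dispersion, and pairwise cecum comparisons
at the scheme's minimum p.

What the generator does *not* emulate: read-level artefacts (chimeras, PCR
bias), phylogenetic structure among taxa, longitudinal dynamics, and any
taxon-taxon interaction beyond the compositional constraint. Passing tests
therefore demonstrate correctness of the statistical machinery under a
plausible generative model, not robustness to those real-data features.

## Problem sizes used in the test suite

The suite regenerates all of its data. The calibration experiments use
2000 null communities (6 horses, 20 families, depth ~5000, 999
randomizations each) for the type-I rate of the blocked indicator test,
and 200 independent studies (30 families, depth $10^4$, 9999
randomizations) for recovery of a planted $E^*=0.9$, $F^*=1$ indicator;
consistency of $\hat E,\hat F$ is checked at 24 horses and depth $10^5$
with tolerance 0.05. End-to-end runs rarefy the preset's 24 samples at
depths of 20,000–30,000. These sizes are the package's own choices,
balancing Monte-Carlo resolution against a test suite that runs in
minutes.

## Known limitations

* The exhaustive pairwise scheme requires a complete paired design; with
  six blocks its resolution floor is p = 0.03125, so pairwise conclusions
  at conventional thresholds lean entirely on reaching that floor.
* BH is applied within each indicator run; no correction spans the
  single-site and combined-site analyses jointly.
* Bray–Curtis PCoA can produce negative eigenvalues; coordinates simply
  omit those axes, which is standard but makes `proportion_explained`
  conservative.
* The merged-group combination formula is one defensible reading of
  "modified for combined groups"; alternatives (e.g. max-based pooling)
  would order combinations differently.

## A minimal worked example

```{r example, eval = FALSE}
design <- pelvic_flexure_preset(seed = 42)
cfg <- run_config(design = design, depth = 30000, seed = 11,
                  out_dir = "hindval-report")
run <- run_pipeline(cfg)
run
indicator_table(run$indval_single)
plot(run$pcoa, groups = run$family_table$site)
```
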