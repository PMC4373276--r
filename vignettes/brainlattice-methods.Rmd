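---
title: "Methods: reverse-inference maps, the brain lattice, and author similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse-inference maps, the brain lattice, and author similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainlattice)
```

## The problem

Coordinate-based neuroimaging databases reduce each published fMRI study
to a table of activation peaks in MNI millimetre space, an ordered
author list, and the frequencies of behavioral terms in the study's
text.  From that raw material this package asks two questions about the
*people* behind the studies: what does a principal investigator's
published activation evidence look like as a brain map, and which other
investigators publish similar evidence — whether or not they actually
work together?

The pipeline has five stages: voxelize peaks into a study-by-voxel
activation matrix; compute a reverse-inference map per label (term or
author); train a self-organizing map (SOM) on the term maps — the
"brain lattice" — to give the high-dimensional maps a 2D behavioral
geography; project each PI's map onto that lattice and compare PIs by
their profiles of lattice match scores; and overlay the resulting
similarity groups on the co-authorship network.

## Voxelization

The field's databases record point coordinates, not images, so a rule
is needed to turn peaks into binary "activation present" calls per
voxel.  We mark every in-mask voxel whose centre lies within a
configurable radius (default 10 mm, the convention of upstream
coordinate-based tools) of any of a study's peaks, and OR across the
study's peaks.  Stamping is monotone in the radius, and a study's row
is invariant to the order its peaks are listed in.

Analyses run on any mask supplied as NIfTI; the package also provides a
synthetic ellipsoid mask (`ellipsoid_grid()`) used by the bundled demo
corpus and the test suite (8 mm isotropic, 14×17×14 field of view,
about 1,000 in-mask voxels), chosen so full pipeline runs complete in
seconds while leaving room for two well-separated foci.

## Reverse-inference maps

For a label (a behavioral term "present" in a study — frequency ≥ 0.001
by default, the documented default of the upstream tool — or an author
on the paper) and each voxel, we form the 2×2 table of activation
presence against label membership over all studies and compute the
Pearson chi-square statistic with 1 df, no continuity correction.
Omitting the correction is deliberate: it keeps the implementation
exactly equal to the textbook formula the tests recompute from the
marginals.  Tables with a zero marginal admit no test and are treated
as p = 1; tables with any expected cell below 1 are conservatively set
to p = 1 as well (the asymptotic reference distribution is not
trustworthy there), and the count of such voxels is logged.

P-values are Benjamini–Hochberg corrected *within each label's map*
over in-mask voxels — each map is its own testing family — at q = 0.05.
Surviving voxels whose association is positive (activation
preferentially present with the label, `sign(ad − bc) > 0`) receive

z = Φ⁻¹(1 − p_raw / 2),

a two-sided p mapped to a positive normal deviate; all other voxels are
zero.  Whether such z-scores should be signed or positive-only is
genuinely open; we keep positive-only as the default because the maps
are meant to show *preferential* association, and provide
`signed = TRUE` for the signed variant.  The raw p is floored at
1e-300 before the quantile transform so z stays finite (≈ 37 at the
floor).  The invariant `z ≠ 0 ⟺ (adjusted p ≤ q and direction
positive)` is asserted voxel-wise in the tests.

## The brain lattice (SOM)

The lattice is a rows × cols grid of nodes, each carrying a weight
vector of length `n_voxels`.  Training is classic online Kohonen
learning on the flattened term z-maps:

* neighborhood width: σ(t) = σ₀·exp(−t/λ);
* update, for every node within grid distance σ(t) of the best
  matching unit (BMU, the node nearest the sampled training vector in
  Euclidean distance): W(t+1) = W(t) + L(t)·(V(t) − W(t)).

The update applies the full learning rate uniformly inside the
neighborhood — exactly the printed rule — rather than the
Gaussian-falloff variant common in SOM libraries; the latter is
available behind `kernel = "gaussian"`.  The learning-rate schedule is
not pinned down by the rule above, so we use the same exponential
decay, L(t) = L₀·exp(−t/λ) with L₀ = 0.05.  Defaults resolved at
training time: σ₀ = max(rows, cols)/2; n_iter = 500 per training map
capped at 20,000; λ = n_iter / ln σ₀, which makes σ(n_iter) = 1 so the
schedule ends exactly when the neighborhood has contracted to the BMU
(training stops at the first t with σ(t) < 1, or at n_iter).  Weights
initialize uniformly inside the per-voxel min/max envelope of the
training data; since every update is a per-coordinate convex
combination with a training vector, weights provably never leave that
box — a property the tests assert.

Grid size may not exceed the number of training maps (each map can
claim a node without resampling) unless overridden.  When dimensions
are left unset the pipeline takes the largest near-square grid under
that constraint; at a full 525-term corpus this rule yields 22 × 23 =
506 nodes, and at the demo corpus's 6 terms it yields 2 × 3.  BMU ties
break to the lowest (row, col) lexicographically — with row-major node
storage that is simply the first minimum, making the rule cheap and
deterministic.

## Match scores, similar authors, clustering

Each author map vector A (the thresholded z-vector, zeros retained —
the comparison is about *significant* evidence, not subthreshold noise)
is compared with each node weight vector B by cosine similarity
Σᵢ AᵢBᵢ / (‖A‖‖B‖), giving the authors × nodes match matrix C.  An
author map with no significant voxels has an undefined angle; it gets a
zero row and is flagged rather than dropped.  Standardized scores Z
pool the mean and standard deviation over *all* entries of C (the
"top 2.5% of all match scores" convention; per-node standardization is
available as an option).  A node query returns authors with Z > 1.96,
ranked by raw cosine score, capped at 50.

Author-to-author distance is the Euclidean distance between rows of C
(matrix M); each author's ranked list starts with the author itself at
distance 0 and ascends.  Hierarchical clustering runs complete-linkage
agglomeration — the default of the standard `hclust` implementation the
procedure references — feeding M directly as the dissimilarity.  (The
alternative reading, re-deriving distances *between rows of M*, is noted
but not implemented: M already is the author dissimilarity.)  Trees are
cut both at fixed heights (1, 2, 2.5, 3, 3.5, 4) and at fixed group
counts (5–100); cut-by-k is exact, and cuts nest: a higher cut height
only merges groups from a lower one.

## Collaboration network and scores

PIs are authors in the last author position on at least two studies
(single-author papers count the sole author as last; identity is exact
string match with optional whitespace/case folding, since name
disambiguation is out of scope).  The network has one node per PI —
isolates retained — and an edge whenever two PIs share at least two
publications.  The same ≥ 2 rule defines "actual collaborator" in the
ranked lists (configurable down to ≥ 1): at rank r, the collaboration
score is the percentage of the top r similar authors the focal PI has
co-published with.  The fraction of edges joining same-group nodes is
reported as a diagnostic of whether similar-work groups align with
actual collaboration.

## The synthetic corpus

`synth_spec()` / `generate_corpus()` produce corpora in which every
downstream result has a knowable truth.  Each named focus (default:
two, at (±32, 0, 24) mm, radius 12 mm) is a research topic owning 10
studies, 2 cohort PIs and 2 behavioral terms; a focus study draws 90%
of its 5 peaks from an isotropic Gaussian (sd = radius/2) truncated to
the mask around the focus centre and the rest uniformly over in-mask
voxel centres.  The remaining 20 of the default 40 studies are
background: uniform peaks, a junior as last author at most once each
(so they never enter the PI roster).  These proportions were fixed by
a design power analysis, not by tuning against outcomes: with member
count m and corpus size n, the smallest expected cell of the 2×2 table
at a planted voxel is about `active·m/n`, and the conservative
small-cell guard would silently zero planted author signal unless each
PI has ≥ 5 member studies at ~25% condition prevalence.  Keeping
planted conditions rare relative to the corpus is also what makes
reverse inference identifiable in real databases, where any one topic
is a small fraction of the literature.

Middle author positions are filled from the junior pool only, so PI
pairs co-occur exactly through `planted_pairs` (PI b joins m of PI a's
studies as penultimate author); the manifest's joint-paper counts are
therefore exact, and the network stage must recover the planted pairs
with ≥ 2 papers and nothing else.  Condition terms get frequencies
uniform on (0.005, 0.05) — comfortably above the 0.001 presence
threshold — while absent terms are simply absent, placing studies on
both sides of the threshold; background terms appear in about half of
all studies with no spatial structure.

What the generator does *not* emulate: real text mining (frequencies
are drawn, not extracted), author-name ambiguity, heterogeneous peak
counts and reporting conventions across journals, spatially correlated
noise, and the long-tailed author productivity of real corpora.
Passing recovery tests therefore demonstrates the pipeline's
correctness on clean planted structure, not robustness to those
real-data pathologies.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default conditions above (40 studies, ≈ 1,000 voxels at 8 mm, 6 term
maps, 2 × 3 lattice, 4 PIs): focus recovery is evaluated over 20 seeds
and cohort clustering (k = 2 cut of M, Rand index against the manifest
cohorts) over 10 seeds.  One global seed fans out deterministically —
the corpus uses it directly, SOM training uses seed + 1 — and a
repeated run writes bit-identical artifacts, which `run_all()` verifies
by MD5 manifest.

## Known limitations

* Exact-name author identity inherits all splitting/merging errors of
  the source corpus.
* The chi-square asymptotics are weak exactly where the guard bites
  (small member counts); an exact test would be preferable for authors
  with very few papers, at real-database scale a substantial cost.
* The Talairach conversion is a single affine bridge; studies reporting
  other spaces are dropped.
* SOM training is online and seed-dependent; different seeds give
  different but comparably useful lattices, and no significance is
  attached to node positions.
* Cluster counts and cut heights are interactive choices; the package
  computes the standard grid of cuts and attaches no inferential claim
  to any particular cut.
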