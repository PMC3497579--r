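---
title: "Methods: models and design choices in mirevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in mirevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirevol)
```

mirevol is a pipeline for comparative analysis of microRNA family evolution
across many genomes. This vignette is the package's own account of the
models it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the places where a design was
genuinely open and a choice had to be made.

## The analysis in one paragraph

miRNA precursor loci from many species are grouped into homologous families
by sequence similarity, giving per-family phylogenetic profiles (which
species carry the family, and in how many copies). On a rooted binary
species tree these profiles support four inferences: (i) the node where
each family was gained and the branches where it was secondarily lost
(Dollo parsimony); (ii) clades where a family's copy number grew or shrank
faster than a neutral birth--death model of family size allows; (iii) pairs
of families (miRNA:miRNA or miRNA:protein) whose gains and losses are
correlated beyond what independent evolution predicts; and (iv) blocks of
conserved gene order (synteny) containing miRNA loci, classified by whether
they carry only proteins, only miRNAs, or both.

## Family attribution

Precursors are compared by global (Needleman--Wunsch) alignment under
affine gaps. The defining feature is the *seed*: positions 2--8 of the
mature miRNA are the primary target-recognition region and are far more
conserved than the rest of the precursor. Each precursor is therefore
re-coded over an expanded per-position alphabet — base plus a seed flag —
and a match between two seed-flagged positions scores `match * seed_mult`
(default 5 × 2) instead of `match`. Mismatches score `mismatch` (default
−4) regardless of flags, `N` never matches, and a gap of length `L` scores
`gap_open + L * gap_extend` (default −10 − 2L).

The numeric magnitudes are package defaults in the vicinity of standard
nucleotide scoring; what matters structurally is the doubling of in-seed
matches, and every value is configurable via `scoring_scheme()`. Two open
choices were resolved as follows and are exposed as options:

* the multiplier applies only when *both* aligned positions are
  seed-flagged (`seed_mode = "both"`); the more permissive either-side rule
  is available as `seed_mode = "either"`;
* gaps inside the seed are not penalised beyond the normal affine cost;
* scores are not length-normalised — the clustering threshold absorbs the
  scale.

Families are the connected components of the score graph at a threshold
(single-linkage clustering), and the threshold is chosen by minimising the
van Dongen split--join distance

$$d(A,B) = \Big(n - \sum_{C \in A}\max_{D \in B}|C \cap D|\Big) +
           \Big(n - \sum_{D \in B}\max_{C \in A}|D \cap C|\Big)$$

to a reference partition, over the grid of all distinct observed scores
(ties break toward the largest threshold, i.e. the most granular
partition). The split--join distance is a genuine metric; the test suite
checks identity, symmetry and the triangle inequality on random partitions
and the worked value $d(\{\{1,2\},\{3,4\}\}, \{\{1,2,3,4\}\}) = 2$.

## Dollo reconstruction

Under Dollo parsimony a family is gained exactly once and can only be lost
afterwards. This makes the most-parsimonious scenario fully determined, so
no search is needed: the gain node is the MRCA of the presence leaves, and
the losses are the maximal subtrees below the gain that contain no presence
leaf. That placement provably minimises the loss count among single-gain
scenarios — the suite verifies it against an exhaustive enumeration of all
internal-state assignments on hundreds of random trees. Two consequences
worth keeping in mind:

* families observed in a single species are retained as terminal-edge
  gains;
* reconstruction can only *deepen* a gain (a family whose early members
  were lost looks younger than it is never older); on simulated histories
  with losses the estimated gain clade is always nested in the true one.

Node age is the sum of branch lengths from the root, used as a proxy for
the evolutionary time of family birth. Per-node statistics report gains,
cumulative gains along the root path, losses, and — given genomic context —
the percentage of families gained at the node that are intronic or
clustered, where a family counts as intronic (clustered) if the majority of
its present-day loci are. In the rendered tree figure, branch width is
proportional to the number of families present among the leaves below the
branch, and the gain/loss colouring marks the top and bottom deciles of the
per-node net balance — a presentation threshold, not an inference.

## Genomic context

A locus is *intronic* iff it lies fully inside a protein-coding locus and
overlaps no exon; overlap by even one base, or straddling the gene
boundary, makes it intergenic, and nested hosts resolve to the shortest.
Host strand is ignored by default (`same_strand = FALSE` is a flag).
*Clusters* chain loci along a chromosome whenever the gap to the previous
locus is at most 10 kb — the same cutoff used to call miRNAs "distal" —
strand-agnostic and order-insensitive; singleton chains are solo loci. The
copy-number glyph maps 0 to white, 1--9 to a rainbow gradient (red through
violet) and ≥ 10 to black, with the bin table exported alongside.

## Family-size expansions

Family sizes evolve as a linear birth--death process with equal per-gene
birth and death rate $\lambda$. Over a branch of length $t$, with
$\alpha = \lambda t/(1+\lambda t)$,

$$P(c \mid s, t) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}\binom{s+c-j-1}{s-1}
\alpha^{s+c-2j} (1-2\alpha)^j .$$

Numerically this series alternates in sign once $\lambda t > 1$ and cancels
catastrophically for moderate sizes, so `bd_transition_matrix()` evaluates
it at a halved time until $\lambda t \le 0.9$ (all terms positive) and
squares the matrix back up via Chapman--Kolmogorov. Ancestral sizes are
truncated at `max_size` (default 100, which comfortably covers the largest
miRNA families of a few dozen members); rows near the cap leak mass past it
and are the price of truncation, which is why row-sum checks are asserted
for sizes well below the bound.

The likelihood of a family's observed sizes sums over ancestral sizes by
pruning, with a uniform root-size prior over `1..root_max` (default: the
largest observed size; settable, which also lets calibration experiments
match the generating prior exactly). Only families whose Dollo gain sits at
the subtree root are eligible — the model conditions on presence at the
root — and $\hat\lambda$ comes from bounded one-dimensional likelihood
maximisation. Because only $\lambda t$ is identified, doubling all branch
lengths halves $\hat\lambda$; the tests assert this invariance.

P-values are Monte-Carlo: `n_sim` (default 1000) null histories are
simulated under $\hat\lambda$ by explicit Gillespie events from the same
root prior, and a family's p-value is the fraction of null histories with
log-likelihood at most its own. On null data these p-values are uniform
(Kolmogorov--Smirnov checked in the suite). The reported branch per family
is the one with the lowest transition log-probability along the
max-product ancestral size assignment. The default report threshold is
p < 0.01, a package choice.

## Correlated gain/loss (phylogenetic profiles)

Two binary profiles evolve jointly as a 4-state continuous-time Markov
chain over (00, 01, 10, 11) with simultaneous double transitions forbidden.
The *independent* model has 4 rates (gain/loss per trait); the *dependent*
model frees all 8 single-step transitions and nests the independent one, so
$LR = 2(\ln L_{dep} - \ln L_{ind})$ measures correlated evolution, with
$\chi^2_4$ asymptotics as the default significance reference (the usual
caveat applies: rates on the boundary make the asymptotic null
conservative, which the calibration test tolerates by allowing up to 8%
exceedance of the 95% quantile).

Likelihoods use Felsenstein pruning with matrix exponentials of the rate
matrix (computed in compiled code; the dense Padé exponential is used
throughout, since eigendecomposition-based shortcuts are unreliable for the
non-symmetric generators that arise here). The root distribution defaults
to the stationary distribution of the fitted chain and can be set to
uniform or fixed. Zero-length branches are collapsed (length 1e-8) with a
warning. Fits are multi-start L-BFGS-B on log-rates bounded in
[1e-6, 100], default 5 restarts from seeded random starts; screening runs
of many pairs use 2 restarts as a documented speed/power trade-off.

`screen_pairs()` applies the filters before testing: traits fixed across
species are excluded, as are traits present — or absent — in fewer than 5
species (the "small numbers of species" filter; 5/5 is a package default),
with an optional exclusion list for pairs from the same synteny block.
Pairs are tested independently (no stepwise conditioning) and ranked by LR;
identical profiles are flagged as degenerate rather than dropped.

## Synteny blocks

Anchors are family-labelled loci (protein and miRNA) ordered along each
chromosome; exact duplicate records are removed and tandem repeats of the
same family collapse to one instance for detection (they remain visible to
the display alignment). The detector is deliberately a *simple collinear-run
detector*, not a reimplementation of a full synteny graph algorithm: per
genome pair it repeatedly extracts the longest chain of shared families
that appears in the same order (or exactly reversed) in both genomes,
allowing at most `max_mismatch_anchors` (default 10) intervening non-shared
anchors and physical gaps of at most `max_gap_length` (default 10 kb)
between consecutive shared anchors in either genome. Tie-breaking is total
and documented — maximum length, forward orientation before reversed,
lexicographically smallest match-pair sequence — which makes the output
deterministic, invariant to genome input order, and directly comparable to
a brute-force chain enumeration (the suite does exactly that comparison on
toy genomes). Runs with identical family sequences are merged across
genome pairs into blocks with ≥ `min_regions` (default 2) occurrences of ≥
`min_anchors` (default 2) families. A graph-simplification pass analogous
to heavier synteny tools has no counterpart here and is documented as
unimplemented; intra-genome duplicated blocks are likewise out of scope.

Note that the 10 kb default gap tolerance interacts with anchor spacing:
on the synthetic genomes, whose intergenic spacing is 25 kb, recovering
whole-chromosome runs requires raising `max_gap_length` accordingly (the
validation suite uses 60 kb there).

Blocks sharing a terminal anchor are chained when the shared terminal is
the *same anchor instance* (identical start coordinate) in every genome
where both blocks occur — the strictest reading of terminal-anchor
chaining, chosen because the exact adjacency conditions of the original
operating procedure are not public. Chaining is idempotent.

Blocks are classified protein-only / mixed / miRNA-only from their anchor
kinds. Occurrence lengths are reported raw and normalised by total genome
length; normalisation makes compact and expanded genomes with the same
block structure comparable, and the suite demonstrates this on a
compact-vs-scaled genome pair. For display, each occurrence's full anchor
sequence (including non-shared insertions) is aligned to the
anchor-richest occurrence by symbol-level Needleman--Wunsch (match +1,
mismatch −1, gap −1), genomes sorted alphabetically, proteins marked "P"
and intronic miRNA anchors "I".

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with planted ground truth for every stage:

* a Yule species tree (default 16 species, depth scaled to 1), or a fixed
  input tree;
* per family, one gain node drawn uniformly over nodes (optionally
  root-weighted) and independent per-branch loss below it (default
  probability 0.05); extinct draws are redrawn so planted families survive
  somewhere;
* one ancestral precursor per family (length 60--120, uniform ACGU),
  evolved down the tree by per-site, *per-branch* substitution at two
  rates — in-seed (default 0.01) below off-seed (default 0.05), encoding
  seed conservation. Substitution is per branch rather than per unit
  branch length: a deliberate simplification that keeps the within-family
  divergence analytically checkable
  ($E[\text{identity}] = \tfrac14 + \tfrac34(1-4p/3)^k$ after $k$
  branches);
* tandem copies per present species (1 + Poisson(0.3));
* genomes as an ancestral anchor order (40 single-copy protein families)
  with miRNA cluster groups (geometric size, mean 3) inserted between or —
  for a configurable fraction, default 0.5 — inside a host protein's
  intron; loci in a group sit 2 kb apart (a planted cluster under the
  10 kb rule), distinct groups are separated by 25 kb; optional per-species
  inversions and translocations scramble the anchor order;
* a separate Gillespie family-size simulator with birth = death = `lambda_sim`
  (default 0.5), used for expansion-model calibration; its defaults match
  the single-rate model fitted later, by design, so that parameter-recovery
  tests are well-posed.

Genome size is emergent (the span of the placed content) rather than a
dial, and is exposed where normalisation needs it. What the generator does
*not* emulate — and hence what green tests do not certify on real data —
includes hairpin secondary structure (irrelevant to every computation
here), indels (gap handling is exercised on hand-made fixtures instead),
repeat-driven family birth, assembly gaps and low-coverage genome
artefacts, and rate variation across lineages. All generators are pure
functions of `(config, seed)`; every stage derives its own stream from the
single master seed.

## Problem sizes and numerical conventions

The validation suite runs at desk scale by choice: 500 random trees of ≤ 8
leaves against the Dollo oracle, 200 random pairs of length ≤ 8 against the
alignment enumeration, family recovery on 20 species × 50 families at
off-seed rate 0.05 and in-seed 0, rate recovery from 200 families on a
16-leaf tree, 200-pair null calibrations for both the birth--death
p-values and the coevolution LR, and a full pipeline rerun compared file by
file for byte identity. Coordinates are 1-based inclusive everywhere
(BED converted on read); mature-arm offsets are precursor 5'→3' regardless
of strand; polytomies and negative branch lengths are hard errors; profile
matrices are written with lexicographic row/column order so that equal
content means equal bytes.

## Known limitations

The detector's greedy longest-chain-first extraction is deterministic but
not globally optimal when runs overlap; partial overlaps across genome
pairs are reported as separate blocks rather than reconciled. The
birth--death model uses a single global rate with birth = death; asymmetric
or per-family rates are out of scope. The coevolution test considers pairs
independently; no multiple-trait or stepwise model is attempted. None of
the real-data headline figures of large miRNA surveys (family counts,
intronic fractions, specific likelihood ratios) can be reproduced without
the underlying genome annotations; the package validates the machinery, on
data whose truth is known because it was planted.
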