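---
title: "Delimiting prophage species and integrating the host population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting prophage species and integrating the host population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surveys of temperate phages in bacterial pathogens routinely predict
thousands of prophages, but two questions are hard to answer from raw
predictions alone: *which prophages are the same phage species*, and *how do
those species distribute over the host's population structure* — its MLST
lineages (sequence types, STs), countries and source hosts? `prophagr`
implements an operational answer for *Acinetobacter baumannii*-style data:
phage species are clusters of sequences at **identity ≥ 95% and coverage ≥
90%** under fragment-based average nucleotide identity (ANI), obtained with
a **paraclique** graph-clustering strategy, and every downstream analysis
(host range, geography, polylysogeny, rarefaction) is computed per species.

## The procedure and its assumptions

1. **Quality control.** A prediction table (CheckV-style columns) is
   filtered: a prophage is kept iff its completeness *strictly exceeds* 50%
   and its source contig has *at least* 30,000 bp. The asymmetry is
   deliberate — the two rules are worded differently ("more than half
   complete", "at least 30 kb") and the boundary cases (completeness exactly
   50, contig exactly 30,000) resolve differently. Contigs with several
   prophage signals are resolved deterministically: overlapping intervals
   merge (union of coordinates, maximum completeness), disjoint signals stay
   separate, and every touched contig is reported. This replaces a manual
   curation step with the only automatable reading; the report preserves
   auditability.

2. **Fragment ANI.** Each query is cut into consecutive 1,020 bp fragments
   (a final fragment shorter than 100 bp is dropped); each fragment is
   locally aligned to the whole subject; a fragment is retained iff its best
   alignment covers ≥ 70% of the fragment at ≥ 30% identity. Pair identity
   is the alignment-length-weighted mean identity of retained fragments and
   pair coverage is the retained aligned query bases over the query length.
   These are the conventions of classic ANIb implementations. Two properties
   matter downstream: the matrices are **asymmetric** (fragments come from
   the query), and **unalignable pairs score 0**, not missing — the pooled
   intra-genome ANI means reported by the polylysogeny module are only
   meaningful under that convention.

3. **Aligner contract.** Any best-score affine-gap local aligner with match
   +1, mismatch −1, gap open 5, gap extend 1 (a gap of length L costs
   5 + L) satisfies the contract. The package ships two backends over the
   same exact dynamic-programming kernel: `"exact"` runs the full dynamic
   program over every diagonal and is the reference; `"seeded"` (default)
   first locates shared 21-mers, restricts the exact DP to the seeded
   diagonal band (±50 diagonals around the seeds), and skips pairs sharing
   no 21-mer. For sequence pairs that actually pass any of the thresholds
   studied here, the band always contains the optimal alignment, and the
   test suite asserts backend equality on small pairs; for deeply diverged
   pairs the seeded backend may report 0 where exhaustive DP would find a
   sub-threshold scrap of alignment — irrelevant at every threshold used.

4. **Species graph and paraclique clustering.** The two directed values of
   a pair are symmetrized before thresholding. The default takes the *mean*
   identity but the *minimum* coverage: coverage asymmetry is what lets a
   short sequence embed in a longer one, and taking the minimum prevents
   such embeddings from chaining distinct species together. Both means
   (`"mean-both"`) and either-direction acceptance (`"either"`) are
   available. Thresholds default to ≥ (non-strict) with a `strict` flag,
   since the operational species definition is stated with ≥ even where the
   methods prose writes >. Clustering then iterates: find a maximum clique
   (exact algorithm; ties broken by the lexicographically smallest sorted
   member list), grow it by absorbing any unassigned vertex adjacent to at
   least ⌈g·|C|⌉ current members (ties: smallest id), emit, remove, repeat
   until no edges remain; leftover vertices are singletons. The glom factor
   defaults to g = 0.9; the paraclique literature leaves it free, and at
   g = 1 the procedure reduces to exact maximum-clique partitioning, which
   is how the test suite checks the seed against brute-force enumeration.
   Species are named by size rank (`Ab_PS1` is the largest), with ties
   broken by the smallest member id.

5. **Host-population integration.** Host range is the set of STs of the
   genomes carrying a species' members; members without an ST are excluded
   from the range but counted. Allelic distance between two STs is the
   number of differing loci among the 7 housekeeping loci of the Pasteur
   scheme, a metric in 0–7; species means are taken over unordered pairs of
   distinct STs. Geographic dispersion counts countries per species, with
   outliers flagged by Tukey fences computed from *hinge* quartiles
   (`stats::fivenum()`), because "Tukey's method" names the hinge
   convention, not interpolated quantiles; the quartile method is the one
   deliberate numerical choice here and is asserted by example in the tests
   (for counts `1,1,1,2,2,3,20` the hinges are 1 and 2.5, the upper fence
   4.75).

6. **Polylysogeny.** Prophage counts per genome (zero-count genomes
   included when metadata lists them) are compared across host categories
   and STs with tie-corrected Kruskal–Wallis tests. Intra-genome divergence
   is the symmetrized identity of every unordered prophage pair within a
   genome, expressed as a *fraction* in [0, 1] — the scale on which pooled
   means of mostly-unrelated pairs are conventionally reported — with the
   global mean and sd pooled over pairs, not over per-genome means; only
   pair-pooling reproduces the published order of magnitude (~0.04 with sd
   ~0.11). Ties in the group tests are always corrected; the source
   analyses do not state whether they were, and correction is the defensible
   default.

7. **Diversity.** The species accumulation curve uses the exact site-based
   hypergeometric expectation
   E[Sₙ] = S − Σᵢ C(T−Tᵢ, n)/C(T, n),
   evaluated with log-gamma so T in the thousands cannot overflow, with the
   analytic variance including pairwise absence covariances. Because the
   field's standard tool implements "rarefaction" as the individual-based
   variant mapped back to sites, that mode is also provided (delegated to
   `vegan::specaccum`). The confidence band is expected ± 1.96·sd; the
   band construction in the original figure is unspecified, and a normal
   band on the analytic sd is the conventional default. Clusterings at
   95/90 and 70/70 are compared by a two-sample Kolmogorov–Smirnov test on
   their size distributions (asymptotic p at the sample sizes involved) and
   by a refinement check: the lenient graph has a superset of edges, so
   every strict cluster must sit inside exactly one lenient cluster.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage can be tested against known truth.
Its default configuration reproduces, at desk scale, the *shape* of a large
prophage survey: 40 species of which 72% are singletons; two designated
"cosmopolitan" species (30 and 15 members) spanning exactly 6 and 4 STs,
all other species confined to one ST; 100 genomes balanced over 12 STs,
8 countries, host mix human 0.70 / animal 0.25 / plant 0.05; ancestors of
30–60 kb; within-species substitution divergence 0.01 with indels at 5×10⁻⁴
per site (geometric lengths, mean 2, capped at 10). The divergence default
is a modeling choice, not an observed value — published species are defined
only by the ≥ 95% cutoff, so any within-species divergence comfortably
inside it (≤ 0.02) gives the same partition; 0.01 leaves the expected
pairwise identity near 98%, far from both the 95 and the 70 thresholds.
Completeness is 100 by default, with an option to inject sub-threshold rows
for filter testing. Placement honors superinfection exclusion by
construction (toggleable): no genome receives two members of one species.

Two deliberate simplifications define what passing tests do *not* show.
First, ancestors are independent uniform-random sequences, not a phage
phylogeny: between-species ANI is exactly 0, so the true partition is the
*unique* partition at 95/90 and recovery is a clean acceptance surface. Real
prophages share mosaics and gradients of homology; the synthetic tests
demonstrate correctness of the machinery, not robustness to borderline
biology. Second, intra-genome prophage pairs are between-species and hence
unrelated, so the pooled intra-genome ANI is ~0 on synthetic data, whereas
real surveys report small positive means — residual homology between
distinct phage species that random ancestors cannot emulate. Gene content,
GC bias, recombination and prediction false positives are out of scope.

## Numerical choices and degenerate inputs

- Sequences shorter than 100 bp yield zero fragments; such comparisons are
  reported as no-alignment (identity 0, coverage 0), never as missing.
- Self-comparisons give identity exactly 100; coverage is 100 only when the
  length is a multiple of 1,020 (a dropped tail can shave < 1%).
- All tie-breaks (clique choice, growth candidate, species naming) use
  locale-independent radix string order, making partitions byte-reproducible.
- Every stochastic operation takes an explicit seed; the pipeline derives
  per-stage sub-seeds from one master seed, and RNG state is restored after
  each seeded operation so seeded calls do not perturb the caller's stream.
- In the Kruskal–Wallis wrapper, all-identical values across groups return
  H = 0, p = 1 rather than an error.
- Allelic distances skip loci with missing alleles and report how many loci
  were compared.

## Problem sizes

The shipped tests and the acceptance script run the generator at its
default scale (~107 prophages of 30–60 kb, ~5,700 ordered ANI pairs of
which ~1,300 are within-species) and module-level tests on miniature
communities (ancestors of 3–6 kb); a full all-versus-all at default scale
takes on the order of a minute on one core. The exact accumulation formula
is validated on 20 sites × 15 species against 10,000 Monte-Carlo
orderings, and the clique seed against brute-force enumeration on graphs of
up to 10 vertices.

## Known limitations

- The paraclique variant implemented here follows the published paraclique
  literature (maximum-clique seed, proportional glom growth); equivalence
  with any particular in-house script used in past surveys cannot be
  asserted, and the glom factor is exposed for that reason.
- Whether study coverage values were query-referenced or symmetrized before
  thresholding is not documented in the sources this design follows; the
  symmetrization is therefore explicit and selectable, with mean-identity /
  min-coverage as the conservative default.
- ST assignment from assemblies (MLST calling) and lifestyle prediction of
  virulent phages are out of scope; the package consumes metadata tables.
- "Rather high" allelic distances are reported as means without a
  classification threshold, since no numeric cutoff is defined for them.
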