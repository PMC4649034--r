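---
title: "Distance-gap delimitation and fragment assignment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-gap delimitation and fragment assignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stygdist)
options(stygdist.quiet = TRUE)
```

## The problem

Anaerobic jakobids (Stygiellidae) are small heterotrophic flagellates of
anoxic marine habitats, known partly from cultured strains with proper
names and partly from anonymous environmental SSU rDNA sequences —
Sanger clone libraries and short next-generation amplicons of the V4,
V9 and V6–V8 hypervariable regions. Species in this group are
morphologically near-identical, so species boundaries rest on genetic
distance: within a species, SSU rDNA sequences stay close; between
species they are separated by a clear gap. This package operationalizes
that reasoning as an explicit, parameterized, testable pipeline:
delimit species-level clusters from a reference alignment, attach short
environmental reads to them, and compare what culturing and what
sequencing each managed to detect.

## The distance primitive

Everything rests on the uncorrected p-distance with **pairwise
deletion**. For two aligned rows, a column is *comparable* iff both rows
carry an unambiguous base (A, C, G or T); gaps, `N` and IUPAC ambiguity
codes are treated as missing data and excluded per pair. The distance is
the fraction of mismatches among comparable columns, and it is
**undefined** (NA) when fewer than `min_sites` columns are comparable.

Choices worth stating explicitly:

- *Pairwise* rather than complete deletion. Complete deletion discards a
  column if any row has a gap, which throws away almost everything once
  short fragments enter the alignment. Pairwise deletion maximizes the
  usable signal per pair and is the standard convention for p-distances.
  Which mode the original distance tables used is not documentable from
  the published text, so the mode is a stated package convention rather
  than a reconstruction.
- Ambiguity codes are missing data, not fractional matches. An `R`
  aligned to an `A` contributes nothing rather than half a match; this
  is simpler and conservative.
- `min_sites` defaults: 100 for full-length windows, 80 for V9-sized
  (130 nt) fragments. Distances on a handful of shared sites are noise;
  the guard turns them into an explicit `unassigned_low_overlap`
  outcome instead. Both are user-settable.
- Distances are *reported* to 4 decimals in TSV output but *compared*
  at full precision.

Coordinates are always 1-based inclusive positions on the ungapped
anchor row (the convention used for reference positions such as
545–1544 and 1645–1774), mapped to alignment columns through the
anchor's gap pattern. Rows shorter than a window simply overlap it
partially; no special casing happens at the mapping stage — the
`min_sites` rule downstream decides whether the overlap suffices.

## Delimitation by the barcoding gap

The delimitation model assumes a *barcoding gap*: a threshold
`t_intra` bounding intraspecific distances from above and a threshold
`t_inter` bounding interspecific distances from below, with
`t_intra < t_inter`. Defaults are `t_intra = 0.046` and
`t_inter = 0.067`, the published envelope for this family; both are
plain function arguments and CLI flags.

`delimit()` runs single-linkage clustering with linkage threshold
`t_intra` — implemented as connected components of the graph whose edges
are distances `<= t_intra`, which is exactly a single-linkage dendrogram
cut at that height. Single linkage is the right operationalization here
because the published reasoning is about *envelopes* (the largest
within-species and the smallest between-species distance), and chains of
small distances are precisely what "within the intraspecific range"
means; no algorithm was named in the source analysis, so this is a
design choice made explicit. Two audits accompany it:

- an error if one cluster contains cultured members with two different
  species labels (the data then contradict the envelope and no silent
  answer is right);
- a `gap_violations` report listing cluster pairs whose minimum
  inter-cluster distance falls strictly inside `(t_intra, t_inter)` —
  distances in the zone the model says should be empty.

Clusters with no cultured member become environmental clades labeled
`EC I, EC II, ...` by descending member count, ties broken by the
lexicographically smallest member id. The original EC numbering of this
family follows no stated rule, so ours is a documented convention (it
does agree with the intuition that EC I is the clone-richest clade), and
it makes relabeling deterministic under input permutation.

## OTU clustering

`otu_cluster()` is greedy, uclust-style: sequences in descending count
order (ties by ascending id) either join the first OTU whose
*representative* is within `identity = 1 - p_distance >= cutoff`
(default 0.97) or found a new OTU. Identity is computed on comparable
sites only — gap columns do not count toward or against identity, the
natural convention when the same p-distance machinery drives both
stages. There is no refinement pass; determinism and auditability are
worth more here than the last percent of cluster compactness.

## Fragment assignment by distance envelope

For a query fragment and each species `s`, the relevant quantity is
`d(q, s)`: the minimum distance from the query to any member of `s`
over the window. The decision rule:

1. if no reference shares `min_sites` comparable sites, the query is
   `unassigned_low_overlap`;
2. otherwise let `s*` minimize `d(q, s)`; the query is `assigned` to
   `s*` if `d(q, s*) <= max_intra(s*) + slack`, where `max_intra(s)` is
   the species' maximum intraspecific distance *computed over the same
   window* (0 for singletons);
3. if a second species also satisfies its envelope at a distance within
   `1e-9` of the best, the call is `ambiguous` — ties are reported,
   never silently broken;
4. otherwise the query enters the `founder_pool`.

`slack` (default 0.01 absolute) encodes "lower or only slightly higher
than intraspecific distances": on a 130-site V9 fragment, 1% is about
one substitution. The original margin was never quantified, so the
slack is an explicit stand-in, visible in every manifest.

Window-specific envelopes matter: a 130-nt window cannot be expected to
carry the full-length 4.6% envelope (the variance of a window-restricted
distance is far larger), and using full-length envelopes on window
distances would mix scales. Singleton species get envelope 0 — only the
slack admits queries — which is conservative for taxa like the two
single-sequence species in the motivating dataset.

`found_new_ecs()` handles the residue: founder-pool reads are
OTU-clustered; each OTU lying beyond `t_inter` from *every* existing
clade (wherever comparable at `min_sites`) is new-clade material; OTUs
that cannot be compared to some clade at all are founded but flagged
`overlap_incomplete` (the situation of a V9-only clade versus a clade
with no V9 coverage — the data admit no stronger statement, so the flag
preserves the caveat). Qualifying OTUs mutually within `t_intra` merge
into one EC, mirroring how a handful of near-identical OTUs can
constitute a single new clade; numbering continues after the existing
ECs.

The helix-27 signature check is deliberately dumb: given the two
alignment columns of the diagnostic pair (configuration — the package
does not predict secondary structure), each row is called `CG`, `AT` or
`other`. Reverse orientation (G:C) is `other` by a strict reading of the
pair's polarity; anything gapped or ambiguous is `other`.

## Survey tables and recovery

`tally()` sums records (species label, method, count) into a species ×
method matrix over the five methods (culture, clone, V4, V9, V6–V8
pyrotags). `recovery_fraction(table, methods)` is the share of a
*species universe* detected by at least one method of the subset. The
packaged fixture (`read_survey_fixture()`) encodes the published
incidence pattern; its universe is the ten species-level taxa with
culture or clone support — the V9-only clade EC V and the unresolved
pool are excluded, matching the published "at least 10 species" count.
Cells whose counts were never published are stored as the marker `NP`
(detected, count unknown): they participate in incidence and recovery,
but are excluded from count-level arithmetic, and
`relative_abundance()` therefore normalizes each column over its
*defined* cells only.

## The synthetic generator

`generate_references()` emulates the statistical structure the analysis
assumes, not the biology of rRNA evolution:

- a random ancestor (default 1800 nt, the scale of a near-full-length
  SSU gene) spawns `n_species` species ancestors by substitution at
  ~0.72 × (`d_inter_min` + `d_intra_max`) × L random sites each, giving
  expected pairwise ancestor distances ~35% above the required bound,
  with rejection sampling on the exact bound;
- strains mutate their species ancestor at up to
  `floor(d_intra_max/2 × L)` sites, bounding intraspecific distances by
  `d_intra_max` via the triangle inequality;
- the realized envelope is then **audited** by brute-force distance
  computation — over the full alignment *and* over the first configured
  window, the one delimitation runs on — and the whole community is
  redrawn on failure (bounded attempts). The audit on the delimitation
  window is essential: substitutions are uniform, so a community whose
  full-length distances respect the envelope can still violate it
  within a window. Short fragment windows are deliberately not
  intra-audited — a 130-site window essentially never carries the
  full-length envelope, and the assignment stage derives its own window
  envelopes, so no correctness claim depends on it.

The first `n_cultured` species carry labeled, culture-sourced strains;
the remaining species exist only as unlabeled environmental clones, so
the delimitation stage genuinely has to *discover* them as ECs.
`generate_fragments()` cuts fragments from the last configured window
(V9-like, 130 nt) of uniformly chosen strains, with independent
per-site substitution errors at `fragment_error` (default 0.002, a
conservative post-QC amplicon error rate). Per-species fragment counts
follow `abundance_profile` *deterministically* (default
200, 150, 80, 30, 15, 10, 6, 4, 3, 2 — a strongly skewed profile of a
few hyper-abundant and several rare species, summing to 500); making
the counts part of the configuration rather than a random draw keeps
power calculations and tests exactly reproducible.
`generate_survey_records()`'s `paper_mimic` preset withholds
environmental records for the two least-abundant cultured species,
reproducing the published incidence shape (6/10 cultured, 2 culture-only
species, 4 environmental-only clades — hence recovery 60% by culture,
80% environmentally).

What the generator does **not** emulate: indels are off by default (an
optional mode gaps random columns in non-anchor rows purely to exercise
pairwise deletion), there is no rate heterogeneity across sites, no
chimeras, no PCR or primer bias, and species are equidistant star-like
clades rather than a realistic phylogeny. Passing tests on this
generator therefore demonstrates that the *logic* — envelope in,
partition and assignments out — is correct under its stated
assumptions; it does not demonstrate robustness to alignment error or
to real rRNA mutational structure.

## Numerical and degenerate-input conventions

- Assignment tie tolerance `1e-9`; envelope comparisons otherwise at
  full double precision.
- Distance matrices carry a zero diagonal even for rows that are
  undefined against everything (an all-`N` row is still itself).
- `delimit()` on a single sequence returns one cluster; `otu_cluster()`
  on empty input returns an empty OTU set; `tally()` on zero records
  returns an all-zero table.
- All-gap rows inside a window are retained (flagged in the log) so
  that row sets never silently shrink.
- Every stochastic function takes its seed from `sim_config`; identical
  seed and configuration give byte-identical FASTA/TSV output.

## Problem sizes used in validation

The shipped test-and-validation suite works at desk scale, chosen so
the full suite runs in well under a minute: communities of 10 species ×
2–6 strains of 1800 nt; exact-recovery checks across 50 seeded
communities; assignment accuracy at 500 fragments per condition; the
p-distance oracle on 1000 random pairs up to 200 nt; and exhaustive
single-linkage enumeration on all inputs of ≤ 8 sequences (the full
partition lattice, Bell(8) = 4140 partitions, against which the
implementation must be the unique consistent answer). The published
envelope values themselves (4.6%, 6.7%, 6.8%) derive from a
supplementary distance table whose underlying sequence set is not
shipped here; they enter this package as defaults and generator
constraints, not as quantities the tests claim to re-derive. Likewise
OTU counts from the original pyrotag archives would require those
archives and are out of scope.

## Known limitations

- Queries must already be aligned into the reference coordinate system
  (or pre-sliced to the window); the package does not align fragments.
- Distance-based delimitation inherits the barcoding-gap assumption;
  lineages with intraspecific variation above `t_intra` (or young
  species pairs below `t_inter`) will be mis-delimited, and the
  `gap_violations` report is the tool's honest signal of that.
- The helix-27 check is a column lookup, not a structural analysis.
- No model-corrected distances (JC69, K2P) and no rarefaction or
  diversity statistics — deliberately outside the package's scope.
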