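---
title: "Structural cladistics of RNA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural cladistics of RNA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaclad)
```

## The evolutionary model

`rnaclad` treats an RNA secondary structure the way sequence
phylogenetics treats a sequence: as a string of homologous,
individually scorable components.  The components are substructures —
double-helical stems, hairpin loops, bulges and internal loops,
multiloop segments, joints between top-level stems, and the 5'/3'
free ends — and the characters are their geometries: stem lengths in
base pairs (optionally G:U wobble-pair counts per stem) and unpaired
lengths in nucleotides.  All structural characters are **linearly
ordered multistate** characters: changing a stem from 4 to 7 base
pairs costs three steps.  State symbols are alphanumeric, `0-9`,
`A-Z`, `a-z`, i.e. integers 0–61.

Two model assumptions do the real work:

* **Homology by kind and position.**  Only substructures of the same
  kind are compared, and the mapping from decomposed elements to
  canonical labels (P1, P12, …) is supplied by an explicit annotation.
  Coaxial tracts (e.g. a "P10-11" character) exist only because the
  annotation declares them; the decomposition itself never merges
  stems across an intervening bulge, since no pairing-only rule can
  decide where a composite tract ends.

* **Polarization towards molecular order.**  Ancestral states are the
  thermodynamically more stable ones: maximal for stabilizing
  characters (stems, G:U pairs), minimal (0) for de-stabilizing ones
  (all unpaired regions).  Operationally a hypothetical ancestor
  carrying these states per character joins the search as an ordinary
  leaf; minimal trees are rooted on its attachment branch and the
  leaf is pruned.  No outgroup is needed, which matters because at
  this depth of divergence no outgroup exists.

Because the matrix is just taxa × characters, transposing it (within
one character kind) and repeating the analysis yields a rooted **tree
of substructures**: basal leaves are the components accreted first.

## Parsimony machinery

Tree length uses cost `|i − j|` for ordered characters and 0/1 for
unordered ones (sequence columns in total-evidence matrices).  Two
scorers are implemented in C++ and cross-checked against each other
and against independent oracles in the test suite:

* a fast interval (Farris) scorer for binary trees, used inside all
  searches — interval propagation is exact for linear costs;
* a general Sankoff dynamic program over the full 62-state space with
  O(states) transitions, used for user-facing `tree_length()`; it
  accepts arbitrary, possibly multifurcating, rooted or unrooted
  trees, so consensus trees can be scored too.

Searches: `exhaustive` enumerates every unrooted binary topology via
stepwise insertion (≤ 10 leaves); `branch_and_bound` prunes partial
trees against a stepwise-addition upper bound (exact — adding a taxon
can never shorten a tree) and reports that initial bound;
`heuristic` runs random-addition starts followed by tree bisection
and reconnection (TBR), adopting the first improving neighbor and
otherwise pooling all equal-length trees (MULTREES behaviour).  All
tie-breaks flow from one integer seed.  The pool is capped by
`max_trees` (default 10,000); hitting the cap sets a `saturated` flag
rather than pretending the count is complete, since plateau sizes in
ordered-character data can be enormous.  Tree identity for
deduplication uses a canonical newick normal form (children sorted by
smallest leaf index).

Statistics: with per-character minimum conceivable steps `m_c` (state
range for ordered characters), realized steps `s_c`, and star-tree
(worst-case) steps `g_c`, the package reports `CI = Σm/Σs`, `CI`
excluding uninformative characters, `RI = (Σg − Σs)/(Σg − Σm)` and
`RC = CI × RI`.  A character is *parsimony-uninformative* exactly when
`g_c = m_c`: its steps are then the same on every topology.  `g1` is
the sample skewness (third standardized moment) of tree lengths over
uniformly sampled topologies — uniform sampling follows from random
stepwise addition with uniform edge choice.  The bootstrap follows
"fast" semantics: resample characters with replacement, build one
greedy stepwise-addition tree per replicate under a random taxon
order, no branch swapping, and tally clade frequencies; with a
polarized matrix the tallies are reported on the rooted ingroup side.

When the search includes the ancestor, reported tree lengths (and the
statistics above) include the ancestor leaf, matching how polarized
searches are conventionally run and reported.

## Node distances and chronologies

For each leaf of a rooted tree, `d` counts the internal nodes on the
root-to-leaf path.  The package normalizes

\[ nd = \frac{d - d_{\min}}{d_{\max} - d_{\min}} \]

so the basal-most leaf scores exactly 0 and the deepest leaves 1 on
*every* non-degenerate rooted tree.  When a leaf attaches directly at
the root — the typical shape of ancestor-rooted trees, and the shape
behind published chronologies whose basal substructure scores 0.00 —
this is identical to \((d-1)/(d_{\max}-1)\).  A tree whose leaves all
sit at one depth (a star, or a perfectly balanced tree) carries no
depth signal and returns 0 for every leaf.  On strict-consensus trees
polytomy nodes count once, so collapsing weakly supported nodes can
only reduce depths; by default nd is computed on the strict consensus
of all minimal trees (single-tree mode is just passing that tree),
because the consensus is the defensible summary when many minimal
trees exist.  Ancestry values are binned (default 10 classes over
[0, 1]) for cumulative accretion curves and for evolutionary heat
maps, which colour either a generated layout (label/x/y/shape table)
or an existing SVG template by element `id`; template elements
without an nd value are painted grey and listed in a warning.

## The synthetic-data generator

The generator exists so that every stage — decomposition, coding,
polarization, search, rooting, transposition, nd — can be tested
end-to-end against a known truth without any external data.  It
emulates the study conditions of the polarization model:

* a Yule (pure-birth) tree of molecules (`ape::rphylo`, birth 1);
* substructures born in a known order at positions along the spine
  (root → deepest tip); lineages diverging before a birth lack that
  substructure entirely (state 0) — this is what makes "basal =
  oldest" recoverable;
* stem characters starting at the maximal state (default 12, a
  realistic helix length that keeps states well inside the
  alphanumeric range) and taking `Pois(0.2)` change events per branch,
  each −1 with probability 0.9 (+1 otherwise), reflected into
  `[1, max]`; hairpin-loop characters start at 0 and drift upward in
  `[0, max]`;
* independent lineage-specific loss (default probability 0.05 per
  lineage per substructure).

Loop characters are tied one-to-one to stems (loop *i* is the hairpin
of stem *i*, born with it, lost with it).  This keeps simulated
molecules constructible: `simulate_molecules()` renders each present
stem as a hairpin module (`((((...))))`), emits the annotation and
homology scheme, and the round trip decompose → label → code
reproduces the simulated matrix bit for bit.  Stems reflect at 1, not
0, so "absent" (0) is reserved for true loss and the structures stay
internally consistent.

What the generator deliberately does **not** emulate: sequence
evolution (total-evidence columns are consumed, not simulated),
pseudoknot formation, convergent acquisition of substructures, or
rate variation across lineages.  Passing tests therefore demonstrate
that the machinery recovers the model's own signal under realistic
noise — not that real molecules evolve by this model.

## Numerical and design choices

* **Coordinates** are 0-based closed intervals internally; CT, bpseq
  and annotation files are 1-based on disk and converted at the
  boundary.
* **Pseudoknots**: dot-bracket layers `()[]{}<>`; pairs from any layer
  form ordinary stems (crossing is recorded but never changes length
  scoring), while unpaired-region classification uses the maximal
  non-crossing skeleton (first layer wins).  CT/bpseq input gets
  layers assigned greedily at parse time.
* **Lone pairs** (1-bp stems) are retained as stems; length coding
  handles them naturally.
* **State overflow** above 61 clamps to `z` with a warning, keeping
  the symbol alphabet closed.
* **G:U characters** are emitted only on request (`gu = TRUE`); which
  stems carry them is a property of the homology scheme in use, not
  hard-coded.
* **Alignment gaps** in total-evidence blocks are treated as missing
  (`?`), the conservative convention, and the ancestor is missing at
  every sequence column so sequences add grouping signal but no
  polarity.
* **The ancestor taxon** is named `ANC` (reserved) and excluded from
  consensus, bootstrap reporting and nd.
* **NEXUS**: DATA/ASSUMPTIONS/PAUP blocks with an `ANCSTATES` vector;
  per-character kind/domain/metric metadata ride in bracketed
  comments (legal NEXUS, ignored by other programs) so the round trip
  is lossless.  The character universe is data-driven — loaded from
  annotation/scheme files or matrix headers — never hard-coded,
  because published character censuses are distributed as data tables
  separate from any one piece of software.
* **Search reproducibility**: one integer seed drives addition orders,
  tie-breaks, bootstrap resampling and random-topology sampling; run
  directories include a JSON manifest echoing every setting.

## Problem sizes used in validation

The test suite and the acceptance script validate on sizes chosen to
exercise the machinery thoroughly at desk scale: 1,000 random ordered
matrices of 4–8 taxa × 2–12 characters for the search-equivalence
check (heuristic runs 20 random-addition starts there — a handful of
starts provably hits TBR local optima on a fraction of a percent of
matrices, while exact branch-and-bound agrees with exhaustive
enumeration on all of them); 100 replicates at 10 taxa × 24
characters for the polarity comparison; 20 simulations at 20 taxa ×
30 stem characters (change rate 0.2/branch) for accretion-order
recovery, with the minimal-tree pool capped at 10 trees per search —
consensus chronologies are insensitive to the cap well before that
point.

## Known limitations

* Heuristic search is exact only in the limit of many starts; the
  `saturated` flag and replicate lengths are exposed so users can
  judge plateau coverage.
* Homology is declarative: nothing infers P-numbering from sequence,
  and a wrong annotation yields a wrong (but internally consistent)
  matrix.
* Unordered characters are limited to 64 states in the search engine
  (ample for nucleotides); ordered characters use the full 0–61
  alphabet.
* The bootstrap implements only the fast stepwise-addition flavour;
  supports are comparable between runs of this package, not with
  swap-based bootstraps.
* `nd` is a topological age, not a time: it assumes node density
  tracks accretion order, which is exactly the polarization
  assumption — independent evidence is needed to calibrate it.
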