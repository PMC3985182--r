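---
title: "Models and algorithms in treerec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms in treerec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treerec)
```

`treerec` implements event-based reconciliation of rooted gene trees with a
rooted species tree: the canonical LCA mapping with duplication/loss
costing, minimum-cost evolutionary scenarios with horizontal transfers on a
time-sliced species tree, conditional supertree construction from many gene
trees, and paralogous binarization of polytomous gene trees. This vignette
explains the models, the tunable parameters, and the design decisions where
the underlying definitions left genuine freedom.

## Trees, tubes, and the mapping model

All trees are rooted and oriented downwards. Species-tree edges are called
*tubes* to distinguish them from gene-tree edges, and every tree carries an
auxiliary *superroot* whose single outgoing edge is the root edge (the root
tube for species trees). A tube is identified by its lower vertex, which
makes the tube set exactly the non-superroot vertex set — unambiguous
because every vertex except the superroot has exactly one incoming edge.
Gene leaves are labelled `id@species`, with the species name taken after
the last `@` (species names may contain any Newick-safe characters,
including underscores); a bare label is its own species.

A *mapping* f of a gene tree G into a species tree S assigns every gene
vertex to a vertex or tube of S: the superroot goes to the root tube, each
leaf to the species leaf of its species, images never increase along gene
edges, and a vertex imaged onto a species vertex must send its children
into the two distinct child subtrees. A vertex imaged in a tube is a
**duplication**, a nonleaf vertex imaged on a vertex is a **divergence**,
and a **loss** is a pair ⟨e, s⟩ of a gene edge and a species vertex lying
strictly between the images of the edge's termini. A loss at s is
**implicit** when the off-path child subtree of s contains no species
present in the gene tree — it records absence induced by the species tree
rather than by the family — and **explicit** otherwise.

The canonical mapping α sends g to LCA(g) unless some child of g has the
same LCA, in which case g goes to the tube above LCA(g). When divergence
costs less than duplication, α is the global cost minimum over all valid
mappings, and every other mapping has at least as many duplications and
strictly more losses. The test suite verifies this against
`enumerate_mappings()` — an exhaustive generator of all valid mappings —
over the complete census of gene/species tree pairs with up to four leaves
each plus 200 randomized five-leaf pairs.

## Event costs

`event_costs()` holds one nonnegative cost per event type; any cost may be
`Inf` to forbid the event. Defaults:

| parameter | event                      | default |
|-----------|----------------------------|---------|
| `div`     | divergence                 | 0       |
| `dup`     | duplication                | 2       |
| `los1`    | explicit loss              | 1       |
| `los2`    | implicit loss              | 0       |
| `tr_ret`  | transfer with retention    | 3       |
| `tr_nor`  | transfer without retention | 3       |
| `gain`    | gain (re-entry from the outgroup) | 1 |

Divergence is the null event of congruent speciation, so it is free by
default; implicit losses are also free so that a gene tree obtainable by
pruning the species tree reconciles at cost zero — the regime in which the
zero-cost supertree guarantee (below) is stated. Duplication 2 versus
explicit loss 1 is the classic duplication-loss weighting. Transfer costs
default above the duplication cost so lateral explanations must earn their
keep; all values are data-analysis choices the user should revisit.
`div < dup` is enforced (overridable with `check = FALSE`) because the
canonical-mapping optimality depends on it.

## Time slices and the scenario dynamic program

Transfers are only meaningful between contemporaneous lineages.
`assign_time_slices()` implements the uniform-depth policy: single-child
*subdivision vertices* are inserted so every root-to-leaf path carries the
same number h of tubes, and a tube's rank is its depth index. This
satisfies the required monotonicity (lower tubes never have a smaller
rank), puts all leaf tubes in one slice, and makes every rank a full cut of
the tree, so "same rank" means "contemporaries". Other ranking policies
satisfying monotonicity are conceivable; only uniform-depth is provided
because the dynamic program's transfer relation (distinct tubes, one slice)
relies on slices being cuts.

The scenario DP fills a table over pairs ⟨gene edge e, tube d⟩ — the
minimal cost of an *inner tree* describing one alternative evolution of
lineage e inside tube d — in the well-founded order (edges leaf-to-root;
within an edge, tubes by decreasing rank). The rules are: pass to the
single child tube (1); survive one side of a branching, losing the other
(2); duplicate in d (3); diverge at d's branching vertex (4, two child
assignments); duplicate with a transferred copy retained in d (5, all
contemporary recipients d′); and transfer without retention into d′
followed there by passing down, surviving one side, duplicating, diverging,
or re-transferring to a third tube d″ (6.1–6.5). The base case pairs a leaf
edge with a leaf tube: cost 0 in the species' own tube, one transfer
without retention otherwise (slice-legal under the uniform-depth policy, as
all leaf tubes are contemporaneous). Backtracking inserts single-child
vertices on gene edges — n insertions decode as n/2 transfers without
retention when n is even, one with retention plus (n−1)/2 without when odd
— and yields the mapping and localized event inventory.

Two deliberate choices:

* **Tie precedence.** The minimizer is not unique; backtracking follows the
  fixed precedence 4, 2, 1, 3, 3′, 5, 6.1–6.5, with auxiliary tubes scanned
  in increasing id. Preferring descent (rules 2 and 1) over duplication
  (rule 3) places tied events as low in the species tree as the canonical
  mapping does; with transfers forbidden the scenario then reproduces α's
  event multiset exactly, not just its cost. (Preferring duplication first
  would park tied duplications in subdivision tubes above the LCA — same
  cost, different localization.)
* **Reporting locations.** Events are recorded against sliced-tree ids and
  also mapped to the nearest original vertex (a subdivision tube reports
  against the original edge it subdivides), which is what
  `scenario_report()` tabulates.

Gene gain is modelled by an auxiliary outgroup lineage: with
`with_outgroup = TRUE` the slicing attaches a chain of h outgroup tubes
above the root, one per slice. In gain mode the root split into the
outgroup is free (rule 3′), losses at the root tube, duplications in
outgroup tubes and the divergence at the root vertex are free, recipients
d′/d″ are never outgroup tubes, and any transfer leaving an outgroup tube
is charged the gain cost and reported as a gain with its re-entry tube.
One underdetermined point: rule 6 describes the donor-copy loss in d
verbally but never charges it in the 6.1–6.5 cost sums; the implementation
follows the sums as written (no extra loss term).

The DP table has |edges(G)| × |tubes(S₀)| entries and the per-entry work is
at most quadratic in the slice width, cubic in the sliced species tree
overall. The test suite checks the DP against a plain recursive enumerator
of the rule set on every pair with up to three leaves per tree under five
randomized cost vectors.

## Conditional supertrees

The supertree problem is NP-complete unconstrained, so the search space is
restricted to species trees whose clades all belong to a *clade family* P —
at minimum the clades of the input gene trees (`default_clade_family()`
adds singletons and the full species set V₀). Phase 1 enumerates the
*basic* members of P (partitionable within P down to singletons) by
increasing cardinality and joins the best partition's trees under a new
root; the join's added cost counts exactly the events localized at the new
root vertex and root tube, via four censuses over all gene trees
(divergences q1, duplications q2, explicit losses q3′, implicit losses
q3″). Singletons cost `dup × Σ_j Par(G_j, s)`, the duplications any mapping
must place in the leaf tube of s (Par counts internal vertices of maximal
one-species subtrees). When V₀ is basic, S(V₀) is the exact conditional
optimum — verified in the tests against exhaustive (2n−3)!! tree search
with a powerset family. One reading decision: the duplication census q2
excludes the superroot, which by definition is never a duplication; with
the superroot included, the identity instance would count a spurious
duplication.

Phase 2 ("augmentation") assembles basic trees into one tree when V₀ is not
basic, or as a robustness device. A candidate tree's cost is the summed
canonical reconciliation cost of every basic tree (≥ 2 leaves) pruned to
the candidate's species. The base step scores all three topologies of every
3-subset; augmentation tries every unplaced species on every edge
(including the root edge). Per candidate, c is the best cost, c′ the
smallest cost strictly above it, R = (c′−c)/c′, and the score c·(2−R)
decides; ties fall to the lexicographically first species and then the
smallest insertion edge. A species whose insertion costs are all equal has
no c′; it is marked **unreliable** and excluded from the rest of the run —
permanently, as defined — so the output can legitimately omit species. The
modified Phase 1 (`modified_phase1()`) reruns the recursion on inputs
pruned to each family member, which can only gain basic sets (a set basic
for the original instance is basic for its pruned instance); its trees feed
`phase2()` unchanged.

**The zero-cost guarantee is conditional.** If every Phase-1 basic tree is
a pruning of a single tree over V₀ and implicit losses are free, the
augmentation ends at cost exactly 0 (and conversely). The hypothesis
matters: gene trees that are prunings of a reference do *not* by themselves
make it hold, because pruning manufactures clades the reference does not
have (a gene tree's root clade is the complement of what was pruned), and
for caterpillar-like references the reference's own root split can be
entirely absent from the family — Phase 1 is then forced to a
positive-cost S(V₀). Around a third of random 6-taxon instances are
affected. The fixture generator `pruning_fixture()` therefore draws a
reference and pruned gene trees, checks the hypothesis directly against
the known reference, and redraws from a seed-derived stream until it holds
(about 1.9 draws on average); the acceptance check then asserts the
guaranteed conclusion. Users applying `phase2()` to real data should read a
nonzero final cost as the analogous diagnostic: the gene trees are not
consistent enough for a perfect assembly under the given family.

## Polytomies and paralogous binarization

For a gene vertex g, d(g) denotes the tube entering LCA(g). An edge e
*enters* a tube d when d(e⁺) lies strictly above d and d lies weakly above
d(e₊). The printed form of this relation is garbled in two conflicting ways
in the source material; the implemented reading is the only one consistent
with the bundle machinery, including the convention that the superroot's
image lies strictly above every tube — so a root edge whose lower image is
the root tube enters exactly that tube and can parent a bundle for it,
which the bundle-parent bijection and the equality of the polytomous and
binary supertree censuses on binary input both require (both are tested).

A *bundle* for d is a maximal set of entering edges sharing their upper
terminus; p(G, d) counts bundles. No candidate binarization can send fewer
than p(G, d) edges into d, and the *paralogous binarization* G##, built by
the three-part child partition (children keeping d(g), children below the
first child tube, children below the second), attains that bound for every
tube simultaneously; all paralogous binarizations have equal reconciliation
cost. When only the first part is nonempty the split is genuinely
arbitrary; the implementation splits first child versus the rest, a
deterministic choice that the cost-invariance property makes harmless. The
leaf-tube duplication count generalizes to Par′(G, s) = L − p(G, d) with L
the leaves below the bundles' edges, and the supertree recursion acquires a
bundle-based census (`poly_q_counts()`): with n, n1, n2 bundles for the
join tube and the two half tubes and k the half-bundle pairs sharing a
parent, the join contributes k divergences, n1+n2−n−k duplications, and
n1′+n2′−2k′ explicit plus n1″+n2″−2k″ implicit losses. On binary input
these reproduce the binary censuses exactly. The optimal (non-paralogous)
binarization is not computed by an algorithm; the test suite enumerates all
candidate binarizations exhaustively on small trees as the oracle for the
minimality and invariance properties.

## The simulator and what passing tests mean

`evolve_gene_tree()` is a discrete forward process: one decision per
(lineage, tube) — duplicate, die, or transfer to a uniformly chosen
contemporary tube, else continue — with divergence forced at species
vertices. It is deliberately slice-aligned so that simulated transfers are
exactly the moves the scenario DP models, and ground truth stays discrete;
it is not a continuous-time birth-death process, has no rate heterogeneity
across lineages or branches, no incomplete lineage sorting, and no
reconstruction noise in the gene trees. Transferred lineages take no second
decision inside the recipient tube, so a lineage triggers at most one event
per tube visit. Recorded events are those recoverable from survivors
(duplications with both copies surviving, transfers whose lineage
survives); losses leave no observable subtree and are not reported.
Consequently, tests that recover simulated events certify the inference
machinery on data generated under its own event vocabulary — they say
nothing about model misspecification on real alignments, gene-tree
estimation error, or ILS.

## Numerical and degenerate-input choices

Costs are machine doubles; event counts are exact integers, so cost
comparisons are exact sums of products and no tolerance is applied inside
the algorithms. `Inf` costs propagate and an infinite optimum raises a
"no feasible scenario" error rather than returning a degenerate object.
Children are kept in input order; all set-valued outputs are sorted;
every tie-break in every module is deterministic, so identical inputs and
seeds give byte-identical outputs. Single-leaf gene trees, polytomous gene
trees (rejected by the DP with a pointer to `paralogous_binarization()`,
accepted everywhere else), gene families touching a strict subset of the
species, and empty event inventories are all exercised in the tests.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
exhaustive oracles stay exact: the full mapping census uses every
gene/species pair with ≤ 4 leaves each (tests) or ≤ 3 (script) plus 100–200
random five-leaf pairs; the DP-versus-enumeration check covers all pairs
with ≤ 3 leaves under 5 random cost vectors; Phase-1 optimality uses 4–5
taxa against all 15–105 rooted trees, 50 instances; the zero-cost assembly
uses 6 taxa and 4 gene families; binarization oracles enumerate all
candidate resolutions of ≤ 5-leaf polytomies. The algorithms themselves are
polynomial and handle larger trees; only the oracles are exponential.

## Known limitations

* Transfer-aware supertree construction is not provided (the conditional
  Phase 1 is proved optimal only for duplications and losses).
* Phase 2 is a heuristic; with contradictory inputs it may omit unreliable
  species, and its output then has no optimality guarantee.
* Species-tree-side polytomies are not supported: the species tree must be
  binary.
* Per-branch (reliability-weighted) event costs are not implemented; costs
  are per event type.
* Branch lengths are parsed and ignored; slicing is topological, not
  temporal.
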