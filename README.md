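# treerec

Event-based reconciliation of rooted gene trees with a rooted species tree,
and supertree construction from many gene trees.

When a gene family evolves inside a species phylogeny, its gene tree *G*
disagrees with the species tree *S* whenever the family underwent gene
duplication, gene loss, horizontal transfer, or gene gain. `treerec`
reconstructs those events. It is aimed at comparative genomicists who have
rooted gene trees (leaves labelled `geneID@species`) and want (i) the events
that explain each family on a known species tree, (ii) a species tree
assembled from many gene families when the species tree is unknown, or
(iii) well-founded resolutions of polytomous (non-binary) gene trees.

## What it computes

**Canonical reconciliation (duplications and losses).** The mapping α sends
each gene vertex *g* to LCA(*g*), the last common ancestor in *S* of the
species below *g*, or to the edge ("tube") above LCA(*g*) when a child of
*g* has the same LCA — the duplication case. Events are localized on *S*: a
vertex mapped into a tube is a duplication, a vertex mapped onto a vertex is
a divergence (speciation-congruent split), and a loss is a pair ⟨*e*, *s*⟩
of a gene edge and a species vertex lying strictly between the images of the
edge's ends; a loss is *implicit* when the off-path subtree contains no
species present in the gene tree. Each event type has a nonnegative cost;
with divergence cheaper than duplication, α is the global cost minimum over
all valid mappings (`compute_alpha()`, `infer_events()`,
`enumerate_mappings()` as the exhaustive oracle).

**Evolutionary scenarios with transfers and gains.** The species tree is cut
into time slices (ranks on tubes such that lower tubes never have a smaller
rank); horizontal transfer is legal only between distinct contemporaneous
tubes. A dynamic program over pairs ⟨gene edge *e*, tube *d*⟩ — the *inner
tree* of the pair — finds the minimum-cost scenario with duplications,
losses, divergences, transfers with/without retention of the donor copy,
and optionally gene gain routed through an auxiliary outgroup lineage
(`assign_time_slices()`, `build_inner_table()`, `best_scenario()`). With
transfers forbidden the scenario coincides with α, events included. The
table fill is polynomial (cubic in the sliced species tree).

**Conditional supertrees.** Given gene trees {*G<sub>j</sub>*} over a
species set V₀ and a clade family *P* (every clade of every *G<sub>j</sub>*
must belong to *P*), Phase 1 computes, for every *basic* member *V* of *P*
(recursively partitionable within *P* down to singletons), a minimum-cost
basic tree *S*(*V*) by the join recursion

    c(V, V1, V2) = c(V1) + c(V2) + c_div·q1 + c_dup·q2 + c_los1·q3' + c_los2·q3''

where the q's count, over all gene trees, the divergences and duplications
at the join root and the explicit/implicit losses there. If V₀ is basic,
*S*(V₀) is the global conditional optimum. Phase 2 assembles basic trees
into a full species tree by reliability-weighted augmentation: candidates
are scored c·(2−R) with R = (c′−c)/c′ from the best and second-best
insertion costs (`phase1()`, `phase2()`, `modified_phase1()`).

**Polytomy resolution.** For a polytomous gene tree, the *paralogous
binarization* G<sup>##</sup> resolves every polytomy so each species tube
receives the minimal possible number of entering gene edges (the bundle
count p(G, d)); all such resolutions have equal reconciliation cost, and the
supertree recursion has a bundle-based variant that works directly on
polytomous input (`paralogous_binarization()`, `bundles_for()`,
`poly_q_counts()`, `phase1_polytomous()`).

**Simulation.** A forward simulator evolves gene families along a sliced
species tree with per-tube duplication/loss/transfer probabilities and
returns the observable gene tree plus the recoverable true events
(`random_species_tree()`, `evolve_gene_tree()`, `pruning_fixture()`).

## Worked example

```r
library(treerec)

G <- parse_newick("((x@human,y@human),(z@mouse,rat));", "gene")
S <- parse_newick("((human,mouse),rat);", "species")
infer_events(G, S)
#> <event_inventory: 2 dup, 1 div, 3 expl loss, 0 impl loss, 0 transfer, 0 gain; cost 7>
```

The human in-paralogs force one duplication in the human leaf tube; the
(mouse, rat) grouping conflicts with ((human, mouse), rat), which costs a
second duplication in the root tube and three explicit losses; with the
default costs (duplication 2, explicit loss 1, divergence and implicit loss
free) the total is 2·2 + 3·1 = 7.

With transfers allowed, a patchy family can be explained laterally. Here a
gene present only in human and rat is cheaper to explain by transfers
(0.6 each) than by losing mouse (implicit loss set to 2):

```r
S0 <- assign_time_slices(S)
sc <- best_scenario(build_inner_table(parse_newick("(human,rat);", "gene"),
                                      S0, event_costs(los2 = 2, tr_nor = 0.6)))
sc
#> <scenario: cost 1.2>
#> <event_inventory: 0 dup, 1 div, 0 expl loss, 0 impl loss, 2 transfer, 0 gain; cost 1.2>
scenario_report(sc)$transfer_arcs
#>   donor recipient slice retention
#> 1     3         6     1     FALSE
#> 2     7         4     2     FALSE
```

Three gene families assemble into a supertree:

```r
Gjs <- list(parse_newick("((human,mouse),rat);", "gene"),
            parse_newick("((human,mouse),cow);", "gene"),
            parse_newick("((mouse,human),(rat,cow));", "gene"))
tab <- phase1(Gjs)
tab
#> <basic_table: 9/9 family members basic; V0 basic, cost 0>
write_newick(basic_trees(tab)[[tab$supertree_key]])
#> [1] "((cow,rat),(human,mouse));"
```

A command-line interface wrapping the same functions ships in
`inst/cli/treerec.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/treerec.R", package="treerec"))')" \
    alpha --gene gene.nwk --species species.nwk
```

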