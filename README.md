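# mulfold

Polyploid species phylogenies from multilabeled gene trees, under
incomplete lineage sorting.

## The problem

Allopolyploid species carry subgenomes inherited from different parental
lineages, so each nuclear gene is present in several homoeologous copies
and a rooted gene tree naturally has several leaves with the same taxon
label — a *MUL-tree*. The species history itself is a rooted
*phylogenetic network* whose reticulation nodes (in-degree ≥ 2) are the
polyploidization events. `mulfold` is for phylogeneticists who have a
collection of such rooted (MUL-)gene trees — typically hundreds to
thousands of loci — and want the species network without searching
network space, while tolerating the gene-tree discordance that the
multispecies coalescent (ILS) produces.

## The method

For gene trees G₁…Gₙ on leaf multiset L:

1. **Census.** Every internal node induces a cluster C (multiset of leaf
   labels below it); for each pair (C, m) the frequency s counts trees
   containing C at exactly multiplicity m.
2. **Selection (MWACC).** Records are vertices of a graph weighted
   w = m · s · |C|^0.65, joined when *approximately compatible* on L
   (C₁ ⊆ C₂, C₂ ⊆ C₁, or L ∖ m₁C₁ ⊇ m₂C₂, multiset arithmetic). An exact
   branch-and-bound finds the maximum-weight pairwise-compatible subset
   with at most one multiplicity per base cluster.
3. **Consensus.** Selected clusters are inserted, most frequent first,
   into a star tree on L (backtracking instance assignment); remaining
   multifurcations get a maximum-weight binary refinement.
4. **Folding.** Processing clades from the root height downward, clades
   with equal cluster multisets that are isomorphic — or within a
   normalized tree edit distance δ (default 0.3) — merge into a
   reticulation; the clade best supported by gene-tree frequencies
   survives as the representative.

A multispecies-coalescent simulator on species MUL-trees (with preset
1–3-reticulation scenarios and low/moderate/high ILS), MUL-tree and
network distances, and a CLI round out the package.

## Worked example

Simulate 500 gene trees from the 5-taxon, 1-reticulation preset at
moderate ILS (taxon B is the allopolyploid), infer, and compare to the
truth:

```r
library(mulfold)
sim <- cmd_simulate("D", "moderate", 500, "sim", run_config(seed = 7L))
inf <- cmd_infer("sim.genetrees.nwk", "run")
write_newick(inf$tree)
#> "((((A,B),(B,C)),D),O);"
write_enewick(inf$network)
#> "((((A,(B)#H1),(#H1,C)),D),O);"
cmd_compare("sim.network.enwk", "run.network.enwk")
#> network_distance	0
```

The consensus MUL-tree carries two copies of B — one per subgenome —
placed sister to A and to C respectively; folding merges them into the
reticulation `#H1`, and the path-multiplicity network distance of 0 says
the inferred network is isomorphic to the simulated truth. The run log
(`run.log`) records the census size (30 cluster records), the 6 selected
clusters with solver objective 5259.20, and every merge event with its
clade scores and δ test.

Equivalent shell form:

```sh
inst/cli/mulfold simulate -o sim --preset D --ils moderate -n 500 --seed 7
inst/cli/mulfold infer -i sim.genetrees.nwk -o run --delta 0.3
inst/cli/mulfold compare sim.network.enwk run.network.enwk
```

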