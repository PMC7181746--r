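---
title: "Inferring metastatic spreading routes from multi-lesion CCF data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metastatic spreading routes from multi-lesion CCF data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metroutes)
```

## The problem

When a colorectal cancer is resected together with its lymph node
metastases (LNMs) and, sometimes, liver metastases (LMs), each lesion
carries a genomic record of where its founding cells came from. Deep exome
sequencing plus PyClone-style clustering turns that record into, for every
mutation cluster and every lesion, a *cancer cell fraction* (CCF): the
fraction of the lesion's tumor cells carrying the cluster's mutations.
`metroutes` takes those per-mutation CCF estimates and reconstructs, per
patient:

1. the clone tree — which subclones descend from which;
2. the *metastatic map* — for every metastasis, the single lesion that
   seeded it, with a monoclonal/multiclonal classification of the seeding;
3. summary statistics over the five-layer network `T` (primary) → `P`
   (paracolic LNMs) → `I` (intermediate) → `C` (central) → `LM` (liver),
   including the three spread modes (inter-layer sequential, inter-layer
   skip, intra-layer).

## From reads to a cluster-by-lesion matrix

Lesions sampled in several regions (the primary, LMs) are analyzed as one
sample: a mutation's merged CCF is the depth-weighted mean over regions,
capped at 1,

$$\mathrm{CCF} = \min\Big(1,\ \frac{\sum_i \mathrm{CCF}_i\, d_i}{\sum_i d_i}\Big),$$

where $d_i$ is the sequencing depth of region $i$ (`merge_ccf()`). A
cluster's value in a lesion is then the arithmetic mean over its member
mutations; mutations with no call in a covered sample are imputed at CCF 0,
since under minimum-coverage calling rules absence of a call in a covered
region is evidence of absence. Ordering matters only with unequal depths;
we merge per mutation first because the depth weights are per-region
properties of each mutation's evidence.

Clonality per cluster and lesion is a three-way call with two thresholds:
**clonal** above 0.85 (strict), **absent** at or below 0.05, **subclonal**
between. The boundaries follow the inequalities as written, so exactly 0.85
is subclonal and exactly 0.05 is absent. Clusters with fewer than 5 member
mutations are dropped as potential false-positive calls. A "few
chromosomes" filter is available (`min_chromosomes`) but disabled by
default — there is no principled universal cutoff, so the choice is left to
the analyst.

## Clone-tree reconstruction by the pigeonhole principle

Cluster roles: the unique cluster clonal in *every* lesion is the **trunk**
(the most recent clone ancestor, MRCA); clusters present in two or more
lesions are **branches**; clusters private to one lesion are **leaves**,
which arose in situ and are excluded from route inference. A cluster that
is present everywhere but subclonal somewhere is a branch, not a trunk.
Zero or several all-clonal clusters is an error — a patient without an
unambiguous MRCA needs manual review, not silent repair.

The tree over trunk and branch clusters is the one consistent with four
per-lesion constraints, all compared with a tolerance $\varepsilon$
(default 0.05, the scale of the absence threshold):

* **nesting** — a child's CCF never exceeds its parent's by more than
  $\varepsilon$;
* **reversal ⇒ branching** — if two clusters' CCFs reverse order between
  lesions (each exceeding the other somewhere by more than $\varepsilon$),
  they are sister lineages and must not be nested;
* **sum ⇒ linear** — if two clusters' CCFs sum above 1 in some lesion,
  they cannot be disjoint lineages and must be nested;
* **joint bound** — two non-nested lineages can never jointly exceed the
  CCF of a common ancestor.

The last two compare a *sum of two estimates* against a third, so they use
a doubled tolerance $2\varepsilon$; single comparisons use $\varepsilon$.
This matters in practice because clonal clusters are estimated with a
downward bias (the cap at 1 truncates only the upper tail), so sister
subclones that truly fill a lesion routinely "exceed" their capped ancestor
by a hair. One-sided dominance without a reversal (cluster a at least as
large as b everywhere, strictly larger somewhere) is treated as *evidence*
of descent rather than a hard constraint: with tolerance-based comparisons
over sparse presence patterns it is frequently satisfied by true sister
lineages, and making it hard renders many correct branching structures
infeasible. The evidence instead drives the search preference below.
`pairwise_relation()` exposes the rule-level pair classification
(linear/branching/undetermined) directly.

`build_clone_tree()` searches parent assignments exhaustively (depth-first
with constraint pruning), so whenever the constraints single out one tree,
that tree is returned. Among several consistent trees the choice is
deterministic: each cluster takes the most derived feasible ancestor —
smallest maximum CCF across lesions, then smallest mean CCF, then smallest
cluster ID. The mean-CCF tie-break is needed because several ancestors are
often clonal somewhere and tie at a maximum of 1. Leaves attach under the
deepest cluster clonal in their lesion. Inconsistent matrices (e.g. a
reversal pair whose sum also exceeds 1) fail loudly with the offending
relations listed: such contradictions signal data problems that should not
be repaired silently.

## Route inference

Three model assumptions shape the search. Lymph flows outward only, so a
lymphatic lesion may be seeded from its own or a more proximal layer,
never from a more distal one; liver metastases may be seeded from any
layer but never seed back into the lymphatic network. Vanished clones are
not modeled: a source's present-day clone content stands in for its
history. Migrations are rare: each metastasis is founded by exactly one
seeding event, in which all subclones shared between the two lesions
migrated jointly.

The **seeding clone set** of a lesion is read off the clonality matrix and
the tree: every present non-leaf cluster that is subclonal, plus each
clonal cluster with no clonal descendant present. This is the
residual-cell reading of the nested-oval picture — a clone contributes
founding cells exactly when not all of its cells have acquired deeper
cluster mutations. A metastasis is **monoclonal** when every present
non-leaf cluster is clonal (a single founding clone), **multiclonal**
otherwise.

A lesion qualifies as a **candidate source** when it carries the target's
full seeding set and the layer constraint holds. Sources are then chosen
to minimize the number of metastasis-to-metastasis routes — the primary is
taken whenever it qualifies — and among metastasis candidates the one
sharing the deepest clone with the target wins, then the smallest lesion
ID. The formal objective is ours: the analysis it reproduces reasons
case-by-case, and an algorithm needs an explicit criterion. Every choice
and the rule that fired is written to the run log.

Candidate constraints can force cycles: a group of lesions bound together
by clones found nowhere else. The resolution reflects how such cases are
read by eye. If some member can be re-sourced externally by treating a few
of its *subclonal* clusters as having arisen in situ after seeding (clonal
founders must always be imported), the member minimizing the total number
of such in-situ originations for the whole group becomes the group's
entry point; a hypothesis that would make the same cluster originate in
two different lesions is rejected. If the group's members have *identical*
clonal composition, no data can orient the chain: the lexicographically
largest lesion ID is seeded externally and reseeds down the chain, and the
group is reported in `ambiguity_groups` so downstream consumers know the
internal ordering is conventional. Recovery scoring
(`evaluate_recovery()`) accordingly accepts any admissible ordering within
a flagged group.

Every returned map is verified acyclic, with exactly one route per
metastasis; the route color is the most-derived seeding clone, the
convention used to draw such maps.

## The synthetic-data generator

`simulate_patient()` produces datasets with a known answer. Its defaults
mirror the study design the package targets: seven mutation clusters of
5–40 mutations, a 2-region primary, three paracolic / two intermediate /
one central LNM and one 2-region liver metastasis, exome depth 264X,
purity 0.7, and about a third of metastases reseeded by an earlier
metastasis rather than the primary.

The primary receives all clones with Dirichlet-distributed residual
fractions; the trunk keeps a fixed residual of 0.30 so that no subclone
approaches clonality in the primary (which would create an ambiguous
MRCA), and every clone keeps a small floor residual so all clones remain
detectable above the absence threshold. Metastases are created in layer
order and seeded by 1–3 clones of one eligible source; founding fractions
are drawn with margins (e.g. 0.3–0.7 for two clones) so that clonality
calls are stable under read noise. A metastasis-to-metastasis event
carves, with probability `private_marker_probability` (default 1), a fresh
marker subclone out of the source, shared exclusively between source and
target; markers carved for earlier targets are excluded from later seeding
sets so each stays private to its own route. Identifiability is thus an
explicit configuration axis: without markers, reseeding is provably
indistinguishable from primary seeding and the parsimony objective will —
correctly — prefer the primary; tests must not treat that as failure. When
the source lacks residual clone mass to host a marker, the event falls
back to primary seeding and is logged. The recorded true seeding class is
derived from the lesion's final composition, so a monoclonally seeded
lesion that later spawns an in-situ marker is recorded (and inferred)
multiclonal — matching how such lesions are classified from observed data.

Observation noise is binomial read resampling: variant reads are drawn as
$\mathrm{Bin}(d,\ \mathrm{purity}\cdot\mathrm{CCF}/2)$ at diploid loci
with one mutated copy, then back-converted with `ccf_from_counts()`.
Multi-region lesions get per-region Dirichlet perturbations
(concentration 10) emulating spatial heterogeneity; `noise = "none"`
disables both channels and emits exact CCFs. All randomness flows from one
seed via R's global generator in a fixed draw order.

What the generator does **not** emulate: copy-number alterations and their
interaction with CCF estimation, purity variation between samples,
FFPE artifacts, PyClone mis-clustering (cluster assignments are taken as
given), and polyphyletic multi-event seeding of one lesion. Passing
recovery tests therefore demonstrate correctness of the inference logic
under the stated model, not robustness to every failure mode of real
pipelines.

## Numerical choices and degenerate inputs

* $\varepsilon = 0.05$ for single CCF comparisons, $2\varepsilon$ for
  two-estimate sums (rationale above).
* Percentages are reported to one decimal, halves rounded up, so published
  route counts reproduce bit-for-bit (38/61 → 62.3).
* All tie-breaks are lexicographic on cluster or lesion IDs and documented
  at each site; identical inputs always yield identical outputs.
* Degenerate inputs fail with informative errors rather than being
  repaired: no or multiple MRCA candidates, pigeonhole-inconsistent
  matrices, seeding sets no lesion can explain, empty post-filter cluster
  sets. Under read noise a few percent of simulated patients trip these
  checks; recovery benchmarks score them 0 rather than hiding them.
* Clusters absent in every lesion after clonality calling are dropped with
  a log entry before role classification (they are unobservable).

## Problem sizes used by the test suite

The suite validates the tree search against exhaustive enumeration on
1,000 random instances of up to 5 clusters and 4 lesions; the route
optimizer against exhaustive source assignment on 500 instances of up to 6
lesions; and end-to-end recovery on 100 noiseless plus 100 binomial-noise
synthetic patients at the default design. These sizes keep the full
enumeration spaces exact while exercising every code path.

## Worked example

```{r example}
res <- analyze_patient(example_patient8())
res$map
res$summary
```

## Known limitations

Chronological ordering of seeding events (which historical state of a
source existed at each seeding) is not modeled; only the final map is
inferred. Reverse lymphatic traffic is excluded by assumption, so a true
retrograde seeding would surface as an infeasibility error or a
misattributed source. Histories in which a reseeded lesion's composition
becomes indistinguishable from an alternative chain through its own
descendants are resolved by the documented conventions and, where truly
direction-free, flagged rather than decided.
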