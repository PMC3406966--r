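---
title: "Intra-breed diversity and exchange networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-breed diversity and exchange networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdnet)
```

## The problem

Endangered livestock breeds are often managed as a handful of small herds
whose gene pools are shaped mostly by drift and by the animals breeders
exchange with one another. When a cryobank has to pick donor animals, the
question is not how the breed differs from other breeds but how diversity is
distributed *within* it: which herds form coherent genetic groups, how much
of the structure is explained by the exchange network, and what can be said
about animals that were never genotyped.

`herdnet` implements that combined analysis for diploid microsatellite data:
classical diversity statistics per locus and herd, Weir–Cockerham
differentiation and Reynolds coancestry distances, Bayesian admixture
clustering with herd-level group assignment, exchange-network metrics, a
Mantel correlation between genetic and network distances, and a tiered donor
prioritization that degrades gracefully from genotype to pedigree to
network-only evidence. A forward-time drift-on-network simulator provides
data with known truth, because raw genotypes behind such surveys are rarely
deposited.

## Diversity statistics

For each analysis unit (herd of birth, breed, or genetic group) and locus
the package reports the observed heterozygosity Ho (fraction of heterozygous
typed individuals), Nei's unbiased expected heterozygosity

$$\hat H_e = \frac{2n}{2n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

and the inbreeding coefficient $F_{IS} = 1 - H_o/\hat H_e$ computed against
that small-sample $\hat H_e$ (a naive large-sample variant is available via
`fis = "naive"` for cross-checks). Monomorphic loci report
$H_o = H_e = 0$ and an undefined (NA) $F_{IS}$. Multi-locus unit values are
unweighted means over polymorphic loci: the weighting is a genuinely open
choice and the unweighted mean is the most transparent one; sample sizes per
locus barely differ within a unit, so the choice is second-order.

Allelic richness is the rarefied allele count: the expected number of
alleles among $g$ genes drawn without replacement,
$AR = \sum_a \bigl(1 - \binom{2N-N_a}{g}/\binom{2N}{g}\bigr)$, averaged over
loci. By default $g$ is the smallest gene count across units at the retained
loci, making units with unequal samples comparable.

Departures from Hardy–Weinberg proportions are tested with the exact
(probability) test estimated by the Guo–Thompson switch chain: two
individuals are drawn per step and a re-pairing of their four allele copies
is proposed, with a Metropolis–Hastings ratio that leaves Levene's
conditional distribution invariant. The p-value is the probability of
genotype tables no more probable than the observed one. Chain defaults (100
batches of 5000 steps, dememorization 10000) follow the conventional
settings of the field's software; the batch structure yields a Monte-Carlo
standard error. Familywise error over loci is controlled by the Bonferroni
rule, flagging $p_i \le \alpha/m$.

Null alleles are screened with Brookfield's first estimator
$r = (H_e - H_o)/(1 + H_e)$, flagged above a configurable threshold
(default 0.05) when $H_o < H_e$. This is deliberately a simple
homozygote-excess screen: only its binary outcome is used, to drop a marker
per breed from downstream analyses. Full scoring-error diagnostics are out
of scope. Note that genuine substructure (Wahlund effect) also produces
breed-wide homozygote excess; the clustering stage disambiguates.

## Differentiation

Wright's $F_{ST}$ is estimated by the Weir–Cockerham (1984) variance
components: per allele and locus the among-population ($a$), among
individual ($b$) and within-individual ($c$) components, combined as
$\hat\theta = \sum a / \sum (a+b+c)$ over alleles and loci. Small negative
estimates are left untruncated. The standard deviation comes from the
delete-one-locus jackknife,
$\mathrm{sd} = \sqrt{\frac{L-1}{L}\sum_l (\hat\theta_{(-l)} -
\bar\theta_{(\cdot)})^2}$, which needs at least three informative loci.

Between herds the package computes the Reynolds–Weir–Cockerham (1983)
least-squares coancestry $\hat\theta$ per pair (frequency-based with the
finite-sample correction; loci combined by summing numerators and
denominators, using only loci typed in both herds) and reports

$$D_r = -\ln(1 - \hat\theta),$$

which is approximately linear in drift time — the right scale for
short-divergence, drift-dominated structure. Negative $\hat\theta$ is
truncated to zero before the log; the untransformed $\hat\theta$ (negatives
preserved) is available via `return_theta = TRUE` since a correlation
analysis may legitimately use either form. Only herds with at least five
genotyped animals enter the matrix — below that the coancestry estimate is
dominated by sampling noise.

## Bayesian clustering and genetic groups

The clustering model is the admixture model: individual $i$ carries
membership vector $q_i$ over $K$ clusters, each cluster has its own allele
frequencies per locus, and every allele copy picks a cluster of origin with
probabilities $q_i$. The Gibbs sampler alternates origin assignments,
Dirichlet updates of cluster frequencies (independent Dirichlet(1) priors
per locus) and of $q_i$ (symmetric Dirichlet($\alpha$)), and a Metropolis
step for $\alpha$ under a uniform prior on (0, 10]. We use independent
allele-frequency priors rather than the correlated-frequency hierarchy:
for drift-scale group recovery the extra hierarchy changes little, and the
downstream assignment rule operates on herd means of $q$ regardless — this
is a documented modelling deviation from the reference implementation.
The sampler core is compiled (Rcpp) and fully reproducible under a seed.

The model log-probability is estimated as
$\widehat{\ln P} = \overline{\ln L} - \mathrm{var}(\ln L)/2$ over post
burn-in sweeps (the toolchain's conventional estimator; the plain mean is
available). Model order is suggested by Evanno's
$$\Delta K = \frac{\mathrm{mean}\,|L(K+1) - 2L(K) + L(K-1)|}{\mathrm{sd}\,[L(K)]}$$
over replicate runs per $K$; endpoints are NA and a zero sd yields Inf with
a warning. The argmax is reported, never auto-enforced: a finer $K$ than
the argmax can legitimately be preferred when it yields a finer
interpretable structure, so model order is exposed as a user decision.

Cluster labels are arbitrary per run; runs at one $K$ are aligned by greedy
matching on the correlation of $q$ columns and then averaged (a full
label-switching optimization is out of scope; greedy matching is exact in
the well-separated regime the assignment rule needs). Herd mean memberships
$\bar q$ are unweighted means over member individuals; a herd is assigned to
the cluster of its maximal $\bar q$ when that maximum reaches 0.7
(inclusive), ties going to the lowest cluster index, and is otherwise
unassigned. Herds sharing a cluster form a genetic group.

## Networks and the Mantel correlation

Exchange records become an undirected graph: herds are vertices and an edge
joins two herds with one or more recorded exchanges in either direction
(direction is retained in storage but never enters a metric; edge weights
are not modelled because per-herd animal counts are typically unavailable
from interviews). The headline metric is the average degree $AD = 2e/n$.
Shortest path lengths (SPL) are BFS geodesic distances; geodesic counts use
the standard path-counting recurrence
$\sigma(s,v) = \sum_{u \in \mathrm{pred}(v)} \sigma(s,u)$.

Metrics stratified by SPL take, for each $d \ge 1$, the pairs at geodesic
distance $d$; the stratum's vertex set is every herd in at least one such
pair and its edge set the induced edges, from which $n$, $e$ and $AD$
follow. Induced subgraphs are the one construction that is deterministic and
self-consistent ($AD = 2e/n$ bit-exactly from the emitted counts); published
per-stratum tables do not always document their construction, so exact
reproduction of any particular table's counts at $d \ge 2$ is not promised.

The genetic-vs-network association is a Mantel test: Pearson $r$ between
the lower triangles of the Reynolds and SPL matrices over a common herd
ordering, with the null distribution from jointly permuting rows and
columns of one matrix; $p = (\#\{\text{as or more extreme}\} + 1)/(B + 1)$.
The default tail is one-sided positive — the directional hypothesis is that
exchanging herds are genetically closer — with a two-sided option. SPL
enters untransformed (a log option exists but is off by default). The
analysis herd set keeps herds with at least five genotyped animals and
exchange information, then restricts to the largest connected component so
no infinite distances remain; exclusions are reported with reasons.

## Donor tiers

Candidates for a cryobank are ranked by evidence quality. Tier 1: genotyped
animals, assigned by their own $q$ (threshold 0.7 reused at the individual
level — one rule, one interpretation; configurable), kept in tier 1 even
when unassigned. Tier 2: non-genotyped animals whose dam and sire (or,
failing that, at least one grandparent) are genotyped; the putative group is
the relatives' common group, and any disagreement or unassigned relative
conservatively yields an unassigned tier-2 candidate. Tier 3: network-only
evidence — the natal herd's group when assigned, else the majority group
among the herd's direct exchange partners, ties yielding unassigned. The
majority rule is our own deterministic stand-in for a published procedure
whose exact rule is not printed; it uses only the information such a
procedure declares (exchange records). Candidates with no evidence are
reported as uncharacterizable rather than dropped. Within each tier the
ranking interleaves genetic groups round-robin so any prefix of the list is
group-balanced to within one animal.

## The simulator, and what passing tests mean

`simulate_scenario()` draws founder allele frequencies from a symmetric
Dirichlet (default 8 alleles at 19 loci), then iterates generations in
which each herd's gene pool first receives migrants — a fraction $m$ of the
pool replaced by the previous-generation pool of one uniformly chosen
network neighbour — and is then resampled at $2N$ genes (Wright–Fisher,
default $N = 20$). Final-generation pools are sampled into 5–15 diploid
animals per herd, the range a small endangered-breed survey realistically
achieves. Networks are random connected graphs at a target average degree
(spanning tree plus random extra edges), optionally in blocks joined by a
configurable number of bridges — isolated blocks create true ancestry
groups — plus optional islet components to exercise the isolation filter.
Migration acts on gene pools (island-model style) rather than moving named
individuals; named-animal structure needed by the donor tiers is layered on
top as non-genotyped offspring of sampled parents. Microsatellite mutation
is off by default: on the tens-of-generations timescales simulated here its
effect is negligible next to drift.

The simulator reproduces the qualitative laws the analysis relies on
(martingale allele frequencies, heterozygosity decay at rate $(1-1/2N)^t$,
$D_r$ growing with isolation time and shrinking with migration, lower $AD$
giving higher mean $D_r$ and a stronger SPL–$D_r$ correlation). It does not
emulate overlapping generations, selection, uneven herd sizes over time, or
interview noise in the exchange records, so passing recovery tests support
the estimators and the pipeline logic — not any claim about a particular
real breed.

## Numerical choices and scales

Test-suite and example problem sizes are chosen for desk-scale runtimes:
chains of a few hundred sweeps on ~50–110 individuals recover
block-separated structure comfortably; production settings (burn-in and
iterations of 1e5, 10 runs per K, 1e5 Mantel permutations, the 100×5000 HWE
chain) remain the configuration defaults where the field's conventions state
them. Frequencies are validated to sum to 1 within 1e-12; membership
vectors to within 1e-9; rarefaction uses log-binomials for stability; the
HWE chain refreshes its running log-probability every batch against float
drift; permutation p-values are +1-corrected so they are never zero; and
all samplers run off R's RNG so a single seed reproduces every artifact
byte-for-byte. Degenerate inputs (monomorphic loci, empty herds, all-missing
cells, disconnected herd pairs) yield NA or explicit errors, never silent
zeros.

## A worked miniature

```{r example, eval = FALSE}
cfg <- sim_config(n_herds = 9, n_loci = 19, network = "blocks",
                  n_blocks = 3, between_block_edges = 2,
                  migration_rate = 0.15, generations = 60, seed = 1)
sim <- simulate_scenario(cfg)

fst <- fst_jackknife(sim$gt, "herd")
dr  <- reynolds_matrix(sim$gt)

runs <- admixture_scan(sim$gt, K_range = 1:5, n_runs = 4,
                       burnin = 300, iters = 500, seed = 2)
evanno_delta_k(runs)

g   <- build_graph(sim$exchanges)
sel <- select_analysis_herds(sim$gt, g)
al  <- align_matrices(dr, shortest_path_lengths(
         build_graph(sim$exchanges, restrict_to = sel$herds)), sel$herds)
mantel_test(al$gen, al$spl, n_perm = 1e5, seed = 3)
```

The `analysis/` directory runs this workflow end to end on a simulated
12-herd, 3-group breed and writes every stage's tables under `results/`.

## Known limitations

The admixture sampler is the plain independent-frequency model: it will
merge weakly differentiated clusters sooner than the correlated-frequency
model would, and Evanno's criterion inherits its usual bias toward the
uppermost level of structure (the workflow therefore reports, not enforces,
the argmax). Reynolds distances assume drift-only divergence; with
substantial mutation or admixture from outside the breed they lose their
linear-in-time interpretation. The SPL stratification reflects one
documented construction. The donor tier-3 rule is a stand-in (see above).
Exchange networks built from interviews are snapshots: the package treats
them as error-free input.
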