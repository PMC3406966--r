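# herdnet

Herd-level analysis of intra-breed genetic diversity in livestock, combining
diploid microsatellite genotypes with the network of animal exchanges
between herds.

Small endangered breeds are structured mostly by drift inside herds and by
the rams and ewes breeders trade with each other. For a conservation program
(e.g. picking cryobank donors) the relevant questions are within-breed:
which herds form coherent genetic groups, how strongly the exchange network
predicts genetic distances between herds, and what can be inferred about
animals that were never genotyped. `herdnet` implements the full chain:

- **Diversity** — per-locus/per-herd allele numbers, observed and Nei's
  unbiased expected heterozygosity, F<sub>IS</sub>, rarefied allelic
  richness, Guo–Thompson Markov-chain exact tests for Hardy–Weinberg
  proportions with Bonferroni correction, and a Brookfield homozygote-excess
  screen for null alleles.
- **Differentiation** — Weir–Cockerham F<sub>ST</sub>
  (θ̂ = Σa / Σ(a+b+c) over alleles and loci) with a delete-one-locus
  jackknife sd, and Reynolds coancestry distances between herds,
  D<sub>r</sub> = −ln(1 − θ̂), linear in drift time.
- **Clustering** — admixture-model Bayesian clustering (Gibbs sampler,
  compiled core), Evanno's ΔK = mean|L(K+1) − 2L(K) + L(K−1)| / sd[L(K)]
  for model order, label-switching alignment across replicate runs, herd
  mean memberships q̄, and the q̄ ≥ 0.7 genetic-group assignment rule.
- **Networks** — undirected exchange graphs, average degree AD = 2e/n,
  shortest-path-length (SPL) matrices, geodesic counts, and per-SPL
  stratified metrics.
- **Correlation** — one-sided Mantel permutation test between the Reynolds
  and SPL matrices over herds with ≥ 5 genotyped animals in the largest
  connected component.
- **Donors** — tiered cryobank candidate ranking: own genotype, then
  genotyped parents/grandparents, then network-only presumption, balanced
  round-robin across genetic groups.
- **Simulator** — forward-time Wright–Fisher drift on an exchange network
  (migration only along edges), used by the test suite and the bundled
  analysis because raw genotypes behind such surveys are rarely deposited.

Genotypes are read/written in the 2- and 3-digit Genepop dialects and a
tabular format; exchanges, pedigrees and herd maps are plain TSV/CSV.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated 12-herd
breed with three ancestry blocks (19 microsatellites, 5–15 animals sampled
per herd, herds within a block exchanging animals, two bridges between
blocks):

```sh
Rscript analysis/01_simulate.R      # writes results/data/ (Genepop + TSV)
Rscript analysis/02_diversity.R
Rscript analysis/03_differentiation.R
Rscript analysis/04_clustering.R
Rscript analysis/05_network.R
Rscript analysis/06_mantel.R
Rscript analysis/07_donors.R
```

Stage output (abridged) from this repository's configuration:

```
theta = 0.1689 (jackknife sd 0.0150)
Reynolds distances over 12 herds: min 0.03, mean 0.19, max 0.40
delta-K argmax at K = 2
11 of 12 herds assigned to 3 genetic groups
full network: 12 herds, AD = 2.33
Mantel r = 0.92 (p = 1e-05): exchange distance predicts genetic distance
122 of 122 candidates characterized
```

Read: herds are strongly differentiated (multilocus Weir–Cockerham θ̂ of
0.17 means about a sixth of the genetic variance lies between herds); ΔK
favours the top split (K = 2) but K = 3 resolves the three simulated blocks
and 11 of 12 herds reach q̄ ≥ 0.7 for one cluster; on this sparse network
(average degree 2.33) the shortest-path distance between herds strongly
predicts their Reynolds distance (Mantel r = 0.92, one-sided p = 1e-05,
10⁵ permutations); and every candidate — genotyped or not — lands in a
donor tier.

## Layout

```
R/            package code (io, diversity, differentiation, clustering,
              network, correlate, donors, synthetic, pipeline)
src/          Rcpp core of the admixture Gibbs sampler
analysis/     numbered workflow drivers (write under results/)
scripts/      acceptance.R
tests/        testthat suite (unit, property and acceptance tests with
              independent brute-force oracles)
vignettes/    methods vignette: models, assumptions, parameter choices
```
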