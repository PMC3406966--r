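#!/usr/bin/env Rscript

# Stage 7 — cryobank donor characterization.
#
# Candidates are every genotyped animal plus the non-genotyped offspring
# with recorded parents. Tier 1: own genotype (assigned when max q >= 0.7).
# Tier 2: genotyped dam and sire, or grandparents, with a common group.
# Tier 3: network evidence only (natal herd's group, else the majority group
# of its direct exchange partners). Ranking ascends tiers and interleaves
# genetic groups round-robin so every group is represented early.

suppressPackageStartupMessages(library(herdnet))

gt <- read_genepop("results/data/genotypes.gen",
                   herd_map = "results/data/herd_map.tsv")
ex <- read_exchange_table("results/data/exchanges.tsv")
ped <- read_pedigree_table("results/data/pedigree.tsv")
off <- read.table("results/data/offspring_herds.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
qdf <- read.table("results/clustering/q_matrix.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
asg <- read.table("results/clustering/group_assignment.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
out <- "results/donors"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

q <- as.matrix(qdf[, grep("^C", names(qdf)), drop = FALSE])
rownames(q) <- qdf$individual
g <- build_graph(ex)

candidates <- c(gt$individuals, ped$animal)
rk <- rank_donors(candidates, gt, asg, q, ped, g,
                  natal_herd = setNames(off$herd, off$animal),
                  q_threshold = 0.7)
write.table(rk, file.path(out, "donor_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summ <- donor_summary(rk)
jsonlite::write_json(
  list(n_candidates = summ$n_candidates,
       n_characterized = summ$n_characterized,
       per_tier = as.list(setNames(as.integer(summ$per_tier),
                                   paste0("tier", names(summ$per_tier)))),
       per_group = as.list(setNames(as.integer(summ$per_group),
                                    names(summ$per_group)))),
  file.path(out, "donor_summary.json"), auto_unbox = TRUE, digits = NA)
message(sprintf("%d of %d candidates characterized", summ$n_characterized,
                summ$n_candidates))
print(summ$per_tier_group)
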