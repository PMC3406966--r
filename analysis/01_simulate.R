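#!/usr/bin/env Rscript

# Stage 1 — generate the study dataset.
#
# The raw microsatellite genotypes behind this kind of survey are rarely
# deposited, so the workflow runs on the bundled drift-on-network simulator:
# twelve herds in three ancestry blocks, herds within a block exchanging
# animals (migration homogenizes them), blocks joined by two bridge edges so
# the exchange network stays connected. Nineteen loci, 5-15 sampled animals
# per herd — the sampling design of a small endangered-breed survey.
# Everything downstream reads the files written here.

suppressPackageStartupMessages(library(herdnet))

seed <- 2026L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_herds = 12, herd_size = 20, n_loci = 19,
                  founder_alleles = 8, network = "blocks", n_blocks = 3,
                  between_block_edges = 2, migration_rate = 0.15,
                  generations = 60, sample_per_herd = c(5L, 15L),
                  pedigree_offspring = 1, target_ad = 2, seed = seed)
sim <- simulate_scenario(cfg)

write_genepop(sim$gt, file.path(out, "genotypes.gen"),
              herd_map = file.path(out, "herd_map.tsv"))
write.table(sim$exchanges, file.path(out, "exchanges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(animal = sim$pedigree$animal,
                       sire = ifelse(is.na(sim$pedigree$sire), "",
                                     sim$pedigree$sire),
                       dam = ifelse(is.na(sim$pedigree$dam), "",
                                    sim$pedigree$dam)),
            file.path(out, "pedigree.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(animal = names(sim$offspring_herd),
                       herd = sim$offspring_herd),
            file.path(out, "offspring_herds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(herd = names(sim$truth$block),
                       block = sim$truth$block),
            file.path(out, "truth_blocks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rep <- validate_dataset(sim$gt, sim$exchanges)
print(sim$gt)
print(rep)
message(sprintf("simulated %d animals in %d herds (seed %d); data in %s",
                length(sim$gt$individuals), cfg$n_herds, seed, out))
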