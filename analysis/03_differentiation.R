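#!/usr/bin/env Rscript

# Stage 3 — genetic differentiation between herds of birth.
#
# Weir-Cockerham multilocus Fst with a delete-one-locus jackknife standard
# deviation, and the Reynolds coancestry distance matrix D_r = -ln(1 - theta)
# between every pair of herds with at least five genotyped animals.

suppressPackageStartupMessages(library(herdnet))

gt <- read_genepop("results/data/genotypes.gen",
                   herd_map = "results/data/herd_map.tsv")
out <- "results/differentiation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fst <- fst_jackknife(gt, "herd")
print(fst)
write.table(data.frame(locus = names(fst$per_locus),
                       theta = fst$per_locus),
            file.path(out, "fst_per_locus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sprintf("multilocus_theta\t%.6f\nsd_jackknife\t%.6f",
                   fst$theta, fst$sd_jackknife),
           file.path(out, "fst_overall.tsv"))

dr <- reynolds_matrix(gt, min_animals = 5)
write_herd_matrix(dr, file.path(out, "reynolds_square.tsv"),
                  file.path(out, "reynolds_long.tsv"))
pairs <- dr$values[upper.tri(dr$values)]
message(sprintf(
  "Reynolds distances over %d herds: min %.2f, mean %.2f, max %.2f",
  length(dr$herds), min(pairs), mean(pairs), max(pairs)))
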