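test_that("allele frequencies match hand counts and count back to integers", {
  gt <- make_gt(rbind(c("1/1"), c("1/2")), herd = "H")
  fr <- allele_frequencies(gt, "herd")
  expect_equal(fr$H$L01$freq, c(`1` = 0.75, `2` = 0.25))
  expect_equal(fr$H$L01$n_genes, 4)

  gt2 <- make_gt(rbind(c("1/1", ""), c("1/2", "")), herd = "H")
  expect_null(allele_frequencies(gt2, "herd")$H$L02)

  set.seed(21)
  gt3 <- random_gt(list(A = c(.4, .3, .3), B = c(.6, .2, .2)),
                   list(A = 7, B = 9), n_loci = 4, missing_rate = 0.1)
  fr3 <- allele_frequencies(gt3, "herd")
  for (u in names(fr3)) for (cell in fr3[[u]]) {
    if (is.null(cell)) next
    counts <- cell$freq * cell$n_genes
    expect_equal(counts, round(counts), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(cell$freq), 1, tolerance = 1e-12)
  }
})

test_that("per-locus Ho/He/Fis match closed forms and a summation oracle", {
  gt <- make_gt(rbind("1/2", "1/2"), herd = "H")
  st <- per_locus_stats(gt, "herd")
  expect_equal(st$Ho, 1)
  expect_equal(st$He, (4 / 3) * 0.5)
  expect_equal(st$Fis, 1 - 1 / ((4 / 3) * 0.5))

  mono <- per_locus_stats(make_gt(rbind("5/5", "5/5"), herd = "H"), "herd")
  expect_equal(mono$Ho, 0); expect_equal(mono$He, 0)
  expect_true(is.na(mono$Fis))

  set.seed(22)
  for (rep in 1:5) {
    gt3 <- random_gt(list(U = c(.3, .3, .2, .2)), list(U = 8),
                     n_loci = 3, missing_rate = 0.1)
    st3 <- per_locus_stats(gt3, "herd")
    for (i in seq_len(nrow(st3))) {
      l <- match(st3$locus[i], gt3$loci)
      g1 <- gt3$a1[, l]; g2 <- gt3$a2[, l]
      ok <- !is.na(g1)
      al <- c(g1[ok], g2[ok])
      p <- table(al) / length(al)
      if (length(p) < 2) next
      ho <- sum(g1[ok] != g2[ok]) / sum(ok)
      he <- (2 * sum(ok) / (2 * sum(ok) - 1)) * (1 - sum(p^2))
      expect_equal(st3$Ho[i], ho, tolerance = 1e-10)
      expect_equal(st3$He[i], he, tolerance = 1e-10)
      expect_equal(st3$Fis[i], 1 - ho / he, tolerance = 1e-10)
    }
  }
})

test_that("Ho and He stay in [0,1] and He is near-unbiased for known freqs", {
  set.seed(23)
  p_true <- c(.5, .3, .2)
  he_hat <- replicate(400, {
    gt <- random_gt(list(U = p_true), list(U = 8), n_loci = 1)
    st <- per_locus_stats(gt, "herd")
    expect_true(all(st$Ho >= 0 & st$Ho <= 1))
    expect_true(all(st$He >= 0 & st$He <= 1))
    st$He
  })
  expect_equal(mean(he_hat, na.rm = TRUE), 1 - sum(p_true^2),
               tolerance = 0.015)
})

test_that("allelic richness obeys rarefaction identities and enumeration", {
  gt <- make_gt(cbind(rep("7/7", 4)), herd = "H")
  expect_equal(allelic_richness(gt, "herd", g = 2)$AR, 1)
  expect_equal(allelic_richness(gt, "herd", g = 8)$AR, 1)

  set.seed(24)
  gt2 <- random_gt(list(U = c(.4, .4, .2)), list(U = 5), n_loci = 3)
  # g = full gene count recovers the observed allele count
  full <- allelic_richness(gt2, "herd", g = 10)
  obs <- mean(vapply(seq_len(3), function(l)
    length(unique(c(gt2$a1[, l], gt2$a2[, l]))), 0))
  expect_equal(full$AR, obs, tolerance = 1e-12)

  # exhaustive subset enumeration oracle, and monotonicity in g
  prev <- 0
  for (g in c(2, 4, 6)) {
    ar <- allelic_richness(gt2, "herd", g = g)
    per <- attr(ar, "per_locus")
    for (l in seq_len(3)) {
      genes <- c(gt2$a1[, l], gt2$a2[, l])
      expect_equal(per["U", l], oracle_rarefaction(genes, g),
                   tolerance = 1e-10)
    }
    expect_gte(ar$AR + 1e-12, prev)
    prev <- ar$AR
  }
  expect_error(allelic_richness(gt2, "herd", g = 1), "g must be")
})

test_that("Bonferroni flags agree with the direct alpha/m comparison", {
  out <- bonferroni_adjust(c(0.001, 0.03), alpha = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE))
  expect_equal(attr(out, "threshold"), 0.025)
  # the rule is p <= alpha/m, inclusive
  expect_true(all(bonferroni_adjust(c(0.025, 0.02), 0.05)$significant))
  expect_equal(bonferroni_adjust(0.04, 0.05)$significant, TRUE)
  expect_equal(nrow(bonferroni_adjust(numeric(0))), 0L)
  set.seed(25)
  p <- runif(40)
  out2 <- bonferroni_adjust(p, 0.07)
  expect_equal(out2$significant, p <= 0.07 / 40)
})

test_that("null-allele screen matches closed forms and recovers a 10% null", {
  # Ho == He -> r = 0
  gt <- make_gt(rbind("1/2", "2/1", "1/2", "1/1", "2/2", "1/2"), herd = "H")
  st <- per_locus_stats(gt, "herd")
  r <- null_allele_estimate(gt, "herd", threshold = 0.05)
  expect_equal(r$null_freq, (st$He - st$Ho) / (1 + st$He))
  # heterozygote excess (Ho > He) must never be flagged
  expect_false(any(r$suspected[r$Ho >= r$He]))

  set.seed(26)
  p_null <- 0.1
  p_vis <- c(.45, .45)
  rs <- replicate(200, {
    n <- 80
    draw <- function() sample.int(3, n, TRUE, prob = c(p_vis, p_null))
    x1 <- draw(); x2 <- draw()
    # null allele (index 3) is invisible: null/a scores as a/a, null/null missing
    both_null <- x1 == 3 & x2 == 3
    v1 <- ifelse(x1 == 3, x2, x1); v2 <- ifelse(x2 == 3, x1, x2)
    v1[both_null] <- NA; v2[both_null] <- NA
    ids <- sprintf("i%02d", 1:n)
    g <- genotype_table(matrix(v1), matrix(v2), ids, "L1",
                        setNames(rep("H", n), ids),
                        setNames(rep("B", n), ids))
    null_allele_estimate(g, "herd")$null_freq
  })
  expect_lt(abs(mean(rs) - p_null), 0.05)
  expect_gt(mean(rs > 0.05), 0.5)  # a 10% null is usually suspected
})
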