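test_that("theta approaches 1 for fixed differences and 0 under a null split", {
  fixed <- random_gt(list(A = c(1, 0), B = c(0, 1)), list(A = 50, B = 50),
                     n_loci = 4)
  expect_gt(wc_fst(fixed, "herd")$theta, 0.99)

  set.seed(41)
  one <- random_gt(list(U = c(.4, .3, .3)), list(U = 200), n_loci = 8)
  split <- setNames(sample(c("X", "Y"), 200, TRUE), one$individuals)
  expect_lt(abs(wc_fst(one, split)$theta), 0.02)
})

test_that("theta equals the ANOVA-form variance-component oracle", {
  set.seed(42)
  for (rep in 1:6) {
    gt <- random_gt(list(A = list(c(.5, .5), c(.2, .5, .3), c(.7, .2, .1)),
                         B = list(c(.8, .2), c(.4, .3, .3), c(.3, .3, .4)),
                         C = list(c(.3, .7), c(.6, .2, .2), c(.1, .6, .3))),
                    list(A = 6, B = 9, C = 7), n_loci = 3,
                    missing_rate = 0.08)
    mine <- wc_fst(gt, "herd")
    oracle <- oracle_wc_theta(gt, gt$herd)
    expect_equal(mine$theta, oracle$theta, tolerance = 1e-10)
    expect_equal(mine$per_locus, oracle$per_locus, tolerance = 1e-10)
  }
})

test_that("jackknife sd matches the delete-one formula and degenerates to 0", {
  set.seed(43)
  gt <- random_gt(list(A = c(.6, .4), B = c(.3, .7)), list(A = 10, B = 10),
                  n_loci = 6)
  res <- fst_jackknife(gt, "herd")
  a <- res$components$a; abc <- res$components$abc
  used <- which(is.finite(a) & abc != 0)
  loo <- vapply(used, function(l)
    sum(a[setdiff(used, l)]) / sum(abc[setdiff(used, l)]), 0)
  L <- length(used)
  expect_equal(res$sd_jackknife,
               sqrt((L - 1) / L * sum((loo - mean(loo))^2)),
               tolerance = 1e-12)

  # identical information at every locus -> sd ~ 0
  one_locus <- random_gt(list(A = c(.6, .4), B = c(.2, .8)),
                         list(A = 12, B = 12), n_loci = 1)
  dup <- genotype_table(one_locus$a1[, c(1, 1, 1)], one_locus$a2[, c(1, 1, 1)],
                        one_locus$individuals, c("L1", "L2", "L3"),
                        one_locus$herd, one_locus$breed)
  expect_lt(fst_jackknife(dup, "herd")$sd_jackknife, 1e-12)

  expect_error(fst_jackknife(random_gt(list(A = c(.5, .5), B = c(.5, .5)),
                                       list(A = 8, B = 8), n_loci = 2),
                             "herd"),
               "at least 3")
})

test_that("theta +/- 2 sd brackets the replicate-mean theta most of the time", {
  thetas <- numeric(100); sds <- numeric(100)
  for (i in 1:100) {
    cfg <- sim_config(n_herds = 4, herd_size = 15, n_loci = 12,
                      founder_alleles = 4, migration_rate = 0.05,
                      generations = 15, sample_per_herd = 10,
                      target_ad = 2, seed = 4400 + i)
    res <- fst_jackknife(simulate_scenario(cfg)$gt, "herd")
    thetas[i] <- res$theta; sds[i] <- res$sd_jackknife
  }
  grand <- mean(thetas)
  hits <- mean(grand >= thetas - 2 * sds & grand <= thetas + 2 * sds)
  expect_gte(hits, 0.9)
})

test_that("duplicate-information loci give identical per-locus estimates", {
  set.seed(47)
  one <- random_gt(list(A = c(.6, .4), B = c(.2, .8)),
                   list(A = 12, B = 12), n_loci = 1)
  dup <- genotype_table(one$a1[, c(1, 1)], one$a2[, c(1, 1)],
                        one$individuals, c("La", "Lb"), one$herd, one$breed)
  pl <- wc_fst(dup, "herd")$per_locus
  expect_equal(unname(pl[1]), unname(pl[2]))
})

test_that("Reynolds distances: identical herds, transform, and oracle", {
  set.seed(45)
  base <- random_gt(list(A = list(c(.5, .5), c(.3, .4, .3))),
                    list(A = 6), n_loci = 2)
  # a herd paired with an exact copy of itself
  twin <- genotype_table(rbind(base$a1, base$a1), rbind(base$a2, base$a2),
                         c(base$individuals, paste0("c_", base$individuals)),
                         base$loci,
                         setNames(rep(c("A", "Acopy"), each = 6),
                                  c(base$individuals,
                                    paste0("c_", base$individuals))),
                         setNames(rep("B1", 12),
                                  c(base$individuals,
                                    paste0("c_", base$individuals))))
  dr <- reynolds_matrix(twin, min_animals = 5)
  expect_equal(dr$values["A", "Acopy"], 0, tolerance = 1e-12)

  gt <- random_gt(list(A = c(.7, .2, .1), B = c(.2, .3, .5),
                       C = c(.4, .4, .2)),
                  list(A = 7, B = 8, C = 6), n_loci = 5,
                  missing_rate = 0.05)
  th <- reynolds_matrix(gt, min_animals = 5, return_theta = TRUE)
  dm <- reynolds_matrix(gt, min_animals = 5)
  part <- gt$herd
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    r1 <- match(names(part)[part == pair[1]], gt$individuals)
    r2 <- match(names(part)[part == pair[2]], gt$individuals)
    expect_equal(th$values[pair[1], pair[2]],
                 oracle_reynolds_theta(gt, r1, r2), tolerance = 1e-10)
    # D_r = -ln(1 - theta) with truncation at 0
    expect_equal(dm$values[pair[1], pair[2]],
                 -log(1 - max(th$values[pair[1], pair[2]], 0)),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(dm$values))
  expect_true(all(diag(dm$values) == 0))
  expect_true(all(dm$values >= 0))

  small <- random_gt(list(A = c(.5, .5), B = c(.5, .5)),
                     list(A = 3, B = 8), n_loci = 2)
  expect_error(reynolds_matrix(small, herds = c("A", "B")), "threshold")
})

test_that("mean Reynolds distance grows with generations of isolation", {
  set.seed(46)
  means <- vapply(c(5, 25, 60), function(t) {
    m <- vapply(1:6, function(r) {
      cfg <- sim_config(n_herds = 4, herd_size = 15, n_loci = 8,
                        founder_alleles = 5, migration_rate = 0,
                        generations = t, sample_per_herd = 10,
                        target_ad = 2, seed = 460 + 17 * r + t)
      dr <- reynolds_matrix(simulate_scenario(cfg)$gt)
      mean(dr$values[upper.tri(dr$values)])
    }, 0)
    mean(m)
  }, 0)
  expect_true(all(diff(means) > 0))
})
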