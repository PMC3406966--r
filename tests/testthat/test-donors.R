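# shared fixture: 4 herds in two groups, individual q matrix, pedigree, graph
donor_fixture <- function() {
  set.seed(81)
  gt <- random_gt(list(H1 = c(1, 0), H2 = c(1, 0),
                       H3 = c(0, 1), H4 = c(0, 1)),
                  list(H1 = 3, H2 = 3, H3 = 3, H4 = 3), n_loci = 4)
  q <- rbind(matrix(rep(c(0.9, 0.1), each = 6), 6, 2),
             matrix(rep(c(0.1, 0.9), each = 6), 6, 2))
  # one deliberately ambiguous genotyped animal
  q[4, ] <- c(0.55, 0.45)
  rownames(q) <- gt$individuals
  qb <- herd_membership(q, gt$herd)
  asg <- assign_groups(qb, 0.7)
  g <- build_graph(exchange_records(
    c("H1", "H2", "H3", "H5", "H5", "H5", "H5"),
    c("H2", "H3", "H4", "H1", "H2", "H3", "H6")))
  list(gt = gt, q = q, asg = asg, g = g)
}

test_that("tiers carry the right evidence and assignments", {
  fx <- donor_fixture()
  ped <- pedigree_records(
    c("kid1", "kid2", "kid3"),
    c("H1_01", "H1_02", "H3_01"),
    c("H1_03", "H3_02", "H3_03"))
  cand <- c("H1_01", "H4_01", "kid1", "kid2", "net1", "lost1", "H1_02")
  rk <- rank_donors(cand, fx$gt, fx$asg, fx$q, ped, fx$g,
                    natal_herd = c(net1 = "H5", lost1 = "ZZ"))

  expect_setequal(rk$animal, cand)          # nothing dropped, nothing doubled
  expect_equal(anyDuplicated(rk$animal), 0L)

  r <- function(an) rk[rk$animal == an, ]
  expect_equal(r("H1_01")$tier, 1L)
  expect_equal(r("H1_01")$group, "G1")       # own q 0.9
  expect_equal(r("H4_01")$tier, 1L)
  expect_equal(r("H4_01")$group, "G2")
  expect_equal(r("kid1")$tier, 2L)           # both parents genotyped, G1
  expect_equal(r("kid1")$group, "G1")
  expect_equal(r("kid2")$tier, 2L)           # parents in different groups
  expect_equal(r("kid2")$group, "UNASSIGNED")
  expect_equal(r("net1")$tier, 3L)           # H5 unsampled: partner majority
  expect_equal(r("net1")$group, "G1")        # partners H1,H2 (G1) vs H3 (G2)
  expect_true(is.na(r("lost1")$tier))        # no evidence at all
  expect_equal(r("lost1")$group, "UNKNOWN")
})

test_that("ambiguous genotypes stay tier 1 unassigned; natal herd drives tier 3", {
  fx <- donor_fixture()
  rk <- rank_donors(c("H2_01_bad" = "H2_01", "n2" = "n2"), fx$gt, fx$asg,
                    {q <- fx$q; q["H2_01", ] <- c(0.6, 0.4); q},
                    ped = NULL, g = fx$g, natal_herd = c(n2 = "H3"))
  expect_equal(rk$tier[rk$animal == "H2_01"], 1L)
  expect_equal(rk$group[rk$animal == "H2_01"], "UNASSIGNED")
  # natal herd H3 is itself assigned -> its group, not partner majority
  expect_equal(rk$tier[rk$animal == "n2"], 3L)
  expect_equal(rk$group[rk$animal == "n2"], "G2")
})

test_that("grandparent fallback applies when parents are not genotyped", {
  fx <- donor_fixture()
  ped <- pedigree_records(
    c("gkid", "mid1", "mid2"),
    c("mid1", "H1_01", "H1_03"),
    c("mid2", "H1_02", NA))
  rk <- rank_donors("gkid", fx$gt, fx$asg, fx$q, ped, fx$g)
  expect_equal(rk$tier, 2L)
  expect_equal(rk$group, "G1")
  expect_match(rk$notes, "grandparents")
})

test_that("ranking ascends tiers and balances groups round-robin", {
  fx <- donor_fixture()
  cand <- fx$gt$individuals  # 12 genotyped animals, mostly assigned
  rk <- rank_donors(cand, fx$gt, fx$asg, fx$q, NULL, fx$g)
  expect_true(all(diff(rk$tier[!is.na(rk$tier)]) >= 0))
  grouped <- rk[rk$group != "UNASSIGNED", ]
  for (t in seq(2, min(10, nrow(grouped)), by = 2)) {
    counts <- table(grouped$group[1:t])
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("tier-2 putative groups usually match the simulated truth", {
  set.seed(84)
  cfg <- sim_config(n_herds = 6, herd_size = 15, n_loci = 10,
                    founder_alleles = 6, network = "blocks", n_blocks = 2,
                    between_block_edges = 0, migration_rate = 0,
                    generations = 60, sample_per_herd = 8, target_ad = 2,
                    pedigree_offspring = 2, seed = 8400)
  sim <- simulate_scenario(cfg)
  runs <- lapply(1:3, function(s)
    admixture_gibbs(sim$gt, K = 2, burnin = 200, iters = 400,
                    seed = 840 + s))
  al <- align_runs(runs)
  qb <- herd_membership(al$q, sim$gt$herd)
  asg <- assign_groups(qb, 0.7)
  g <- build_graph(sim$exchanges)
  rk <- rank_donors(sim$pedigree$animal, sim$gt, asg, al$q, sim$pedigree, g,
                    natal_herd = sim$offspring_herd)
  # truth: an offspring's source group is its natal herd's assigned group
  herd_group <- setNames(asg$group, asg$herd)
  ok <- rk$tier == 2L
  # parental confidence filter: both parents with max q >= 0.8
  conf <- vapply(rk$animal, function(an) {
    prow <- sim$pedigree[sim$pedigree$animal == an, ]
    if (!nrow(prow)) return(FALSE)
    all(apply(al$q[c(prow$sire, prow$dam), , drop = FALSE], 1, max) >= 0.8)
  }, TRUE)
  expected <- herd_group[rk$herd]
  sel <- ok & conf & !is.na(expected)
  expect_gte(sum(sel), 5)
  expect_gte(mean(rk$group[sel] == expected[sel]), 0.8)
})
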