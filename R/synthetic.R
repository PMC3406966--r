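#' Configuration for the drift-on-network simulator
#'
#' Defines a forward-time Wright-Fisher scenario: herds drift from a common
#' founder allele-frequency pool, with gene flow confined to the edges of an
#' exchange network. Defaults mirror the sampling design the analyses assume:
#' around 19 microsatellite loci, per-herd samples of 5-15 diploid animals,
#' and herd gene pools of a few tens of animals.
#'
#' @param n_herds number of herds (vertices).
#' @param herd_size diploid individuals per herd gene pool (Wright-Fisher N).
#' @param n_loci number of microsatellite loci.
#' @param founder_alleles alleles per locus in the founder pool.
#' @param founder_concentration symmetric Dirichlet concentration for founder
#'   frequencies (1 = uniform over the simplex).
#' @param network `"connected"` (random connected graph at a target average
#'   degree) or `"blocks"` (groups of herds densely connected within and
#'   joined by `between_block_edges` bridges; 0 bridges gives isolated
#'   ancestry groups).
#' @param target_ad target average degree 2e/n of the (within-block) network.
#' @param n_blocks,between_block_edges block structure (network = "blocks").
#' @param n_islets,islet_size extra small components appended to the exchange
#'   records (never to the main network) to exercise the isolation filter.
#' @param migration_rate per-generation fraction of a herd's gene pool
#'   replaced by genes from one uniformly chosen network neighbour.
#' @param generations generations of drift.
#' @param sample_per_herd integer range (length 2) or single count of
#'   genotyped animals per herd.
#' @param pedigree_offspring non-genotyped offspring per herd to emit in the
#'   pedigree (sire/dam drawn from that herd's genotyped animals).
#' @param seed integer seed; every source of randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_herds = 12L, herd_size = 20L, n_loci = 19L,
                       founder_alleles = 8L, founder_concentration = 1,
                       network = c("connected", "blocks"), target_ad = 3,
                       n_blocks = 3L, between_block_edges = 1L,
                       n_islets = 0L, islet_size = 2L,
                       migration_rate = 0.05, generations = 50L,
                       sample_per_herd = c(5L, 15L),
                       pedigree_offspring = 1L, seed = 1L) {
  network <- match.arg(network)
  cfg <- list(n_herds = as.integer(n_herds), herd_size = as.integer(herd_size),
              n_loci = as.integer(n_loci),
              founder_alleles = as.integer(founder_alleles),
              founder_concentration = founder_concentration,
              network = network, target_ad = target_ad,
              n_blocks = as.integer(n_blocks),
              between_block_edges = as.integer(between_block_edges),
              n_islets = as.integer(n_islets),
              islet_size = as.integer(islet_size),
              migration_rate = migration_rate,
              generations = as.integer(generations),
              sample_per_herd = as.integer(sample_per_herd),
              pedigree_offspring = as.integer(pedigree_offspring),
              seed = as.integer(seed))
  stopifnot(cfg$n_herds >= 2L, cfg$herd_size >= 2L, cfg$n_loci >= 1L,
            cfg$founder_alleles >= 1L, cfg$migration_rate >= 0,
            cfg$migration_rate <= 1, cfg$generations >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

# random connected graph on `ids` with e = round(ad*n/2) edges:
# uniform random spanning tree skeleton plus random extra non-edges
random_connected_edges <- function(ids, target_ad) {
  n <- length(ids)
  e_target <- round(target_ad * n / 2)
  e_max <- n * (n - 1) / 2
  if (n > 1L && (e_target < n - 1L || e_target > e_max))
    stop(sprintf(
      "target AD %.2f infeasible for %d herds (feasible range %.2f..%.2f)",
      target_ad, n, 2 * (n - 1) / n, n - 1))
  if (n == 1L) return(data.frame(a = character(0), b = character(0)))
  ord <- sample(n)
  a <- integer(0); b <- integer(0)
  for (v in 2:n) {  # attach each vertex to a random earlier one
    u <- ord[sample.int(v - 1L, 1L)]
    a <- c(a, min(u, ord[v])); b <- c(b, max(u, ord[v]))
  }
  have <- paste(a, b)
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keys <- paste(all_pairs[, 1], all_pairs[, 2])
  free <- which(!(keys %in% have))
  extra <- e_target - (n - 1L)
  if (extra > 0L) {
    pick <- free[sample.int(length(free), extra)]
    a <- c(a, all_pairs[pick, 1]); b <- c(b, all_pairs[pick, 2])
  }
  data.frame(a = ids[a], b = ids[b], stringsAsFactors = FALSE)
}

#' Simulate genotypes, exchanges and pedigree under drift on a network
#'
#' Founder allele frequencies are drawn once from a symmetric Dirichlet; each
#' generation every herd's gene pool first receives migrants (a
#' `migration_rate` fraction of its pool replaced by the previous-generation
#' pool of one uniformly chosen network neighbour) and is then resampled
#' binomially at size 2N (Wright-Fisher drift). The final generation is
#' sampled into diploid genotypes. Exchange records carry one row per network
#' edge with a random orientation (plus islet components, if requested,
#' disconnected from the main network). The returned truth object holds the
#' per-herd ancestry labels and realized allele-frequency trajectories for
#' recovery tests.
#'
#' @param cfg a [sim_config()].
#' @return A list with `gt` ([genotype_table()]), `exchanges`
#'   ([exchange_records()]), `pedigree` ([pedigree_records()]),
#'   `offspring_herd` (named vector: natal herd of the non-genotyped
#'   pedigree offspring), and `truth` (list: `block` herd labels,
#'   `founder_freq`, `final_freq`, `trajectories`, `edges`).
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  herds <- sprintf("H%02d", seq_len(cfg$n_herds))

  # network
  if (cfg$network == "connected") {
    edges <- random_connected_edges(herds, cfg$target_ad)
    block <- setNames(rep("B1", cfg$n_herds), herds)
  } else {
    blk <- sort(rep_len(seq_len(cfg$n_blocks), cfg$n_herds))
    block <- setNames(paste0("B", blk), herds)
    edges <- do.call(rbind, lapply(seq_len(cfg$n_blocks), function(bi)
      random_connected_edges(herds[blk == bi], cfg$target_ad)))
    if (cfg$between_block_edges > 0L && cfg$n_blocks > 1L) {
      for (i in seq_len(cfg$between_block_edges)) {
        bs <- sample.int(cfg$n_blocks, 2L)
        u <- sample(herds[blk == bs[1L]], 1L)
        v <- sample(herds[blk == bs[2L]], 1L)
        edges <- rbind(edges, data.frame(a = min(u, v), b = max(u, v)))
      }
      edges <- unique(edges)
    }
  }

  # founder pool and drift
  J <- cfg$founder_alleles
  founder <- lapply(seq_len(cfg$n_loci), function(l) {
    x <- rgamma(J, cfg$founder_concentration)
    x / sum(x)
  })
  nb <- lapply(herds, function(h)
    c(edges$b[edges$a == h], edges$a[edges$b == h]))
  names(nb) <- herds
  # freq[[h]] is an n_loci x J matrix
  freq <- setNames(lapply(herds, function(h)
    do.call(rbind, founder)), herds)
  traj <- list()
  two_n <- 2L * cfg$herd_size
  for (gen in seq_len(cfg$generations)) {
    prev <- freq
    for (h in herds) {
      p <- prev[[h]]
      if (cfg$migration_rate > 0 && length(nb[[h]])) {
        src <- if (length(nb[[h]]) == 1L) nb[[h]] else sample(nb[[h]], 1L)
        p <- (1 - cfg$migration_rate) * p + cfg$migration_rate * prev[[src]]
      }
      freq[[h]] <- t(apply(p, 1L, function(pl)
        as.numeric(rmultinom(1L, two_n, pl)) / two_n))
    }
    traj[[gen]] <- lapply(freq, function(m) m[1L, ])  # locus-1 trajectory
  }

  # sample genotypes
  spr <- cfg$sample_per_herd
  n_samp <- if (length(spr) == 2L)
    sample(seq(spr[1L], spr[2L]), cfg$n_herds, replace = TRUE)
  else rep(spr, cfg$n_herds)
  ids <- character(0); herd_of <- character(0)
  a1 <- NULL; a2 <- NULL
  allele_code <- 100L + 2L * seq_len(J)  # fragment-length-like codes
  for (hi in seq_along(herds)) {
    h <- herds[hi]
    m <- n_samp[hi]
    hid <- sprintf("%s_A%02d", h, seq_len(m))
    g1 <- matrix(0L, m, cfg$n_loci); g2 <- g1
    for (l in seq_len(cfg$n_loci)) {
      draws <- sample.int(J, 2L * m, replace = TRUE, prob = freq[[h]][l, ])
      g1[, l] <- allele_code[draws[seq_len(m)]]
      g2[, l] <- allele_code[draws[m + seq_len(m)]]
    }
    ids <- c(ids, hid); herd_of <- c(herd_of, rep(h, m))
    a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
  }
  gt <- genotype_table(a1, a2, ids, sprintf("LOC%02d", seq_len(cfg$n_loci)),
                       setNames(herd_of, ids),
                       setNames(rep("SIM", length(ids)), ids))

  # exchange records: one per edge, random orientation; plus islets
  flip <- runif(nrow(edges)) < 0.5
  src <- ifelse(flip, edges$a, edges$b)
  dst <- ifelse(flip, edges$b, edges$a)
  if (cfg$n_islets > 0L) {
    for (i in seq_len(cfg$n_islets)) {
      iher <- sprintf("ISL%d_%02d", i, seq_len(max(cfg$islet_size, 2L)))
      src <- c(src, iher[-length(iher)])
      dst <- c(dst, iher[-1L])
    }
  }
  exchanges <- exchange_records(src, dst)

  # pedigree: non-genotyped offspring of genotyped parents, per herd
  ped <- NULL; offspring_herd <- character(0)
  if (cfg$pedigree_offspring > 0L) {
    an <- sr <- dm <- character(0)
    for (h in herds) {
      members <- ids[herd_of == h]
      if (length(members) < 2L) next
      for (o in seq_len(cfg$pedigree_offspring)) {
        par <- sample(members, 2L)
        kid <- sprintf("%s_OFF%d", h, o)
        an <- c(an, kid); sr <- c(sr, par[1L]); dm <- c(dm, par[2L])
        offspring_herd[kid] <- h
      }
    }
    ped <- pedigree_records(an, sr, dm)
  }

  list(gt = gt, exchanges = exchanges, pedigree = ped,
       offspring_herd = offspring_herd,
       truth = list(block = block, founder_freq = founder,
                    final_freq = freq, trajectories = traj,
                    edges = edges, config = cfg))
}
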