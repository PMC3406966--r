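# independent reference implementations used only to check the package;
# written from the published formulas via a different route than R/

# Weir-Cockerham theta via the ANOVA (mean squares) formulation.
# gt: genotype_table; part: named vector animal -> unit
oracle_wc_theta <- function(gt, part) {
  part <- part[!is.na(part)]
  units <- unique(part)
  num <- 0; den <- 0
  per_locus <- stats::setNames(rep(NA_real_, length(gt$loci)), gt$loci)
  for (l in seq_along(gt$loci)) {
    # y[i][j] = copies of each allele per individual, per unit
    ys <- lapply(units, function(u) {
      rows <- match(names(part)[part == u], gt$individuals)
      g1 <- gt$a1[rows, l]; g2 <- gt$a2[rows, l]
      ok <- !is.na(g1)
      cbind(g1[ok], g2[ok])
    })
    ys <- ys[vapply(ys, nrow, 0L) > 0L]
    r <- length(ys)
    if (r < 2L) next
    alleles <- sort(unique(unlist(ys)))
    if (length(alleles) < 2L) next
    ns <- vapply(ys, nrow, 0L)
    ntot <- sum(ns)
    nc <- (ntot - sum(ns^2) / ntot) / (r - 1)
    l_num <- 0; l_den <- 0
    for (al in alleles) {
      y <- lapply(ys, function(m) rowSums(m == al))        # 0/1/2 per ind
      p_i <- vapply(y, function(v) sum(v) / (2 * length(v)), 0)
      pbar <- sum(ns * p_i) / ntot
      SSG <- sum(vapply(y, function(v) sum(v == 1L), 0)) / 2
      SSI <- sum(unlist(mapply(function(v, p) (v - 2 * p)^2 / 2, y, p_i,
                               SIMPLIFY = FALSE)))
      SSP <- sum(2 * ns * (p_i - pbar)^2)
      MSG <- SSG / ntot
      MSI <- SSI / (ntot - r)
      MSP <- SSP / (r - 1)
      s2G <- MSG
      s2I <- (MSI - MSG) / 2
      s2P <- (MSP - MSI) / (2 * nc)
      num <- num + s2P; den <- den + s2P + s2I + s2G
      l_num <- l_num + s2P; l_den <- l_den + s2P + s2I + s2G
    }
    if (l_den != 0) per_locus[l] <- l_num / l_den
  }
  list(theta = num / den, per_locus = per_locus)
}

# Reynolds 1983 pairwise coancestry, explicit per-locus loops
oracle_reynolds_theta <- function(gt, rows1, rows2) {
  top <- 0; bot <- 0
  for (l in seq_along(gt$loci)) {
    take <- function(rows) {
      x <- c(gt$a1[rows, l], gt$a2[rows, l])
      x[!is.na(x)]
    }
    x1 <- take(rows1); x2 <- take(rows2)
    n1 <- length(x1) / 2; n2 <- length(x2) / 2
    if (n1 < 1 || n2 < 1) next
    als <- sort(unique(c(x1, x2)))
    sumsq <- 0; het1 <- 1; het2 <- 1
    for (a in als) {
      p1 <- sum(x1 == a) / length(x1)
      p2 <- sum(x2 == a) / length(x2)
      sumsq <- sumsq + (p1 - p2)^2
      het1 <- het1 - p1^2; het2 <- het2 - p2^2
    }
    shared <- n1 * het1 + n2 * het2
    denom_c <- 4 * n1 * n2 * (n1 + n2 - 1)
    top <- top + sumsq / 2 - (n1 + n2) * shared / denom_c
    bot <- bot + sumsq / 2 + (4 * n1 * n2 - n1 - n2) * shared / denom_c
  }
  top / bot
}

# all-pairs shortest paths by Floyd-Warshall on the 0/1 adjacency matrix
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# number of geodesics between i and j by depth-limited simple-path DFS
oracle_count_geodesics <- function(adj, i, j, d) {
  if (!is.finite(d)) return(0)
  if (d == 0) return(1)
  count <- 0L
  dfs <- function(v, depth, visited) {
    if (depth == d) {
      if (v == j) count <<- count + 1L
      return(invisible(NULL))
    }
    for (w in which(adj[v, ] == 1)) {
      if (!visited[w]) {
        visited[w] <- TRUE
        dfs(w, depth + 1L, visited)
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, nrow(adj)); visited[i] <- TRUE
  dfs(i, 0L, visited)
  count
}

# rarefied allele count by exhaustive enumeration of g-subsets of genes
oracle_rarefaction <- function(genes, g) {
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# exact HWE test, full enumeration, 2 alleles (Levene's distribution)
oracle_hwe_exact2 <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  nA <- 2 * n11 + n12
  het_vals <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logpr <- vapply(het_vals, function(h) {
    h11 <- (nA - h) / 2; h22 <- n - h11 - h
    lgamma(n + 1) - lgamma(h11 + 1) - lgamma(h + 1) - lgamma(h22 + 1) +
      h * log(2)
  }, 0)
  pr <- exp(logpr - max(logpr)); pr <- pr / sum(pr)
  obs <- pr[het_vals == n12]
  sum(pr[pr <= obs + 1e-12])
}

# Mantel p by exhaustive enumeration over all n! relabelings
oracle_mantel_exhaustive <- function(m1, m2) {
  n <- nrow(m1)
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt])
  perms <- all_perms(n)
  stats_all <- vapply(perms, function(p)
    stats::cor(m1[lt], m2[p, p][lt]), 0)
  mean(stats_all >= r_obs - 1e-12)
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
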