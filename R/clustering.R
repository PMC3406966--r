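#' Bayesian admixture clustering by Gibbs sampling
#'
#' Fits the admixture model: each individual's genome is a mixture over K
#' clusters with cluster-specific allele frequencies. Cluster frequencies get
#' independent Dirichlet(lambda = 1) priors per locus; individual admixture
#' proportions get a symmetric Dirichlet(alpha) prior whose scalar alpha is
#' updated by a Metropolis step under a uniform prior on (0, 10]. Allele-copy
#' origins are sampled conditionally each sweep; no prior population labels
#' are used. The membership matrix q is the posterior mean of the admixture
#' proportions over post-burn-in sweeps, and lnP is the conventional model
#' log-probability estimate mean(lnL) - var(lnL)/2 of the data log-likelihood
#' (the posterior-mean-only alternative is exposed via `lnp`).
#'
#' Default chain lengths are deliberately short for desk-scale work; raise
#' `burnin` and `iters` (e.g. to 1e5 each) for production runs.
#'
#' @param gt a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param burnin,iters warm-up and retained sweeps.
#' @param seed integer seed; same seed and parameters give bit-identical
#'   results.
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param alpha0,alpha_sd,alpha_max initial value, proposal sd and prior
#'   upper bound for alpha.
#' @param lnp `"harmonic"` (mean - var/2, default) or `"mean"`.
#' @return A list of class `admixture_run`: `K`, `seed`, `lnP`, `q`
#'   (individuals x K, rows summing to 1), `alpha`, `mean_lnL`, `var_lnL`.
#' @export
admixture_gibbs <- function(gt, K, burnin = 10000L, iters = 10000L,
                            seed = NULL, lambda = 1, alpha0 = 1,
                            alpha_sd = 0.25, alpha_max = 10,
                            lnp = c("harmonic", "mean")) {
  stopifnot(inherits(gt, "genotype_table"))
  lnp <- match.arg(lnp)
  if (K < 1L) stop("K must be >= 1")
  if (K > length(gt$individuals)) stop("K larger than number of individuals")
  enc <- encode_alleles(gt)
  if (!is.null(seed)) set.seed(seed)
  res <- .admixture_gibbs_cpp(enc$a1, enc$a2, enc$n_alleles, as.integer(K),
                              as.integer(burnin), as.integer(iters),
                              lambda, alpha0, alpha_sd, alpha_max)
  if (K > 1L && res$alpha_reject_rate > 0.98)
    warning("alpha barely moved (reject rate ",
            round(res$alpha_reject_rate, 3), "); check chain settings")
  q <- res$q
  dimnames(q) <- list(gt$individuals, paste0("C", seq_len(K)))
  structure(list(K = as.integer(K), seed = seed,
                 lnP = if (lnp == "harmonic") res$lnP else res$mean_lnL,
                 q = q, alpha = res$alpha,
                 mean_lnL = res$mean_lnL, var_lnL = res$var_lnL),
            class = "admixture_run")
}

# 0-based allele index matrices and per-locus allele counts
encode_alleles <- function(gt) {
  L <- length(gt$loci)
  a1 <- matrix(-1L, nrow(gt$a1), L); a2 <- a1
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    n_alleles[l] <- max(length(alleles), 1L)
    i1 <- match(gt$a1[, l], alleles) - 1L
    i2 <- match(gt$a2[, l], alleles) - 1L
    a1[, l] <- ifelse(is.na(i1), -1L, i1)
    a2[, l] <- ifelse(is.na(i2), -1L, i2)
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles)
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: K = %d, lnP = %.2f, alpha = %.3f, %d individuals\n",
              x$K, x$lnP, x$alpha, nrow(x$q)))
  invisible(x)
}

#' Replicated admixture runs over a range of K
#'
#' Runs [admixture_gibbs()] `n_runs` times per K with per-run seeds derived
#' from `seed` by a fixed counter scheme (seed + 1000*K + run), so any single
#' run can be reproduced in isolation.
#'
#' @inheritParams admixture_gibbs
#' @param K_range integer vector of K values (e.g. `1:10`).
#' @param n_runs runs per K (default 10).
#' @param seed base seed.
#' @return A list of `admixture_run` objects, class `admixture_scan`.
#' @export
admixture_scan <- function(gt, K_range = 1:10, n_runs = 10L,
                           burnin = 10000L, iters = 10000L, seed = 1L, ...) {
  runs <- list()
  for (K in K_range) for (r in seq_len(n_runs)) {
    runs[[length(runs) + 1L]] <-
      admixture_gibbs(gt, K, burnin = burnin, iters = iters,
                      seed = seed + 1000L * K + r, ...)
  }
  class(runs) <- "admixture_scan"
  runs
}

#' Evanno's delta-K model-order criterion
#'
#' delta K = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K)), computed from the
#' per-run model log-probabilities lnP grouped by K: the numerator is the
#' mean over runs at K of the absolute second difference of the per-K mean
#' lnP, the denominator the standard deviation of lnP over runs at K.
#' Endpoint K values get `NA`; a zero standard deviation yields `Inf` with a
#' warning. The most probable K is the argmax of delta K over interior K,
#' but model-order choice remains a user decision: a finer K than the argmax
#' may legitimately be preferred.
#'
#' @param runs an `admixture_scan` or list of `admixture_run` objects
#'   covering a contiguous K range with >= 2 runs per K.
#' @return A data.frame with columns `K`, `n_runs`, `mean_lnP`, `sd_lnP`,
#'   `delta_k`, plus attribute `best_k`.
#' @export
evanno_delta_k <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, 0L)
  lnPs <- vapply(runs, function(r) r$lnP, 0)
  Kvals <- sort(unique(Ks))
  if (length(Kvals) < 3L) stop("need a contiguous K range of length >= 3")
  if (any(diff(Kvals) != 1L)) stop("K range must be contiguous")
  mean_lnP <- vapply(Kvals, function(K) mean(lnPs[Ks == K]), 0)
  sd_lnP <- vapply(Kvals, function(K) sd(lnPs[Ks == K]), 0)
  n_runs <- vapply(Kvals, function(K) sum(Ks == K), 0L)
  if (any(n_runs < 2L)) stop("need >= 2 runs per K")
  m <- length(Kvals)
  delta <- rep(NA_real_, m)
  for (i in seq(2L, m - 1L)) {
    num <- abs(mean_lnP[i + 1L] - 2 * mean_lnP[i] + mean_lnP[i - 1L])
    if (sd_lnP[i] == 0) {
      warning("zero sd of lnP at K = ", Kvals[i], "; delta K is infinite")
      delta[i] <- Inf
    } else delta[i] <- num / sd_lnP[i]
  }
  out <- data.frame(K = Kvals, n_runs = n_runs, mean_lnP = mean_lnP,
                    sd_lnP = sd_lnP, delta_k = delta)
  interior <- which(!is.na(delta))
  attr(out, "best_k") <- if (length(interior))
    Kvals[interior[which.max(delta[interior])]] else NA_integer_
  out
}

#' Align cluster labels across runs and average memberships
#'
#' Cluster labels are arbitrary per run (label switching). Runs at a fixed K
#' are aligned to the first run by greedy matching on the correlation between
#' q columns, then averaged.
#'
#' @param runs list of `admixture_run` objects, all at the same K, same
#'   individuals.
#' @return A list with `q` (averaged aligned membership matrix), `runs_q`
#'   (list of aligned per-run matrices), `agreement` (mean absolute
#'   difference between aligned runs and their average).
#' @export
align_runs <- function(runs) {
  Ks <- unique(vapply(runs, function(r) r$K, 0L))
  if (length(Ks) != 1L) stop("runs must share one K")
  K <- Ks
  ref <- runs[[1L]]$q
  aligned <- lapply(runs, function(r) {
    q <- r$q
    if (K == 1L) return(q)
    perm <- greedy_column_match(ref, q)
    q[, perm, drop = FALSE]
  })
  qbar <- Reduce(`+`, aligned) / length(aligned)
  colnames(qbar) <- paste0("C", seq_len(K))
  agree <- mean(vapply(aligned, function(q) mean(abs(q - qbar)), 0))
  list(q = qbar, runs_q = aligned, agreement = agree)
}

# permutation p such that q[, p] best matches ref, greedily by correlation
greedy_column_match <- function(ref, q) {
  K <- ncol(ref)
  cors <- suppressWarnings(cor(ref, q))
  cors[!is.finite(cors)] <- -2  # constant columns match last
  perm <- integer(K)
  for (step in seq_len(K)) {
    best <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    perm[best[1L]] <- best[2L]
    cors[best[1L], ] <- -Inf
    cors[, best[2L]] <- -Inf
  }
  perm
}

#' Herd-level mean membership coefficients
#'
#' q-bar(herd) = unweighted mean of the member individuals' q vectors.
#' Animals with unknown birth herd are excluded; empty herds are dropped.
#'
#' @param q membership matrix (individuals x K) with animal rownames, e.g.
#'   from an `admixture_run` or [align_runs()].
#' @param herd named character vector animal -> herd (e.g. `gt$herd`).
#' @return A matrix herds x K of q-bar vectors (rows sum to 1).
#' @export
herd_membership <- function(q, herd) {
  h <- as.character(herd)[match(rownames(q), names(herd))]
  keep <- !is.na(h)
  q <- q[keep, , drop = FALSE]; h <- h[keep]
  herds <- unique(h)
  out <- t(vapply(herds, function(u)
    colMeans(q[h == u, , drop = FALSE]), numeric(ncol(q))))
  rownames(out) <- herds
  out
}

#' Assign herds to genetic groups by the q-bar threshold rule
#'
#' A herd whose maximum mean membership q-bar reaches the threshold (default
#' 0.7, applied as >=) is assigned to that cluster; herds sharing a cluster
#' form one genetic group. Otherwise the herd is unassigned. Exact ties at or
#' above the threshold go to the lowest cluster index. Rows are ordered by
#' group and, within a group, by decreasing maximum q-bar (the convention
#' used for reporting).
#'
#' @param q_bars herds x K matrix from [herd_membership()].
#' @param threshold assignment threshold (default 0.7).
#' @return A data.frame with columns `herd`, `max_qbar`, `group`
#'   (`"G<k>"` or `NA` for unassigned), `cluster` (index or `NA`), ordered
#'   for reporting; attribute `q_bars` carries the input.
#' @export
assign_groups <- function(q_bars, threshold = 0.7) {
  stopifnot(is.matrix(q_bars))
  mx <- apply(q_bars, 1L, max)
  cl <- apply(q_bars, 1L, which.max)  # ties -> lowest index
  assigned <- mx >= threshold
  out <- data.frame(herd = rownames(q_bars), max_qbar = mx,
                    cluster = ifelse(assigned, cl, NA_integer_),
                    group = ifelse(assigned, paste0("G", cl), NA_character_),
                    stringsAsFactors = FALSE)
  out <- out[order(!assigned, out$cluster, -out$max_qbar), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q_bars") <- q_bars
  attr(out, "threshold") <- threshold
  out
}

#' Write a Q-matrix TSV (individual, herd, q_1..q_K)
#'
#' @param q membership matrix with animal rownames.
#' @param herd named herd vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(q, herd, path) {
  df <- data.frame(individual = rownames(q),
                   herd = as.character(herd)[match(rownames(q), names(herd))],
                   q, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
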