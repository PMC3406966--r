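#' Exact test for Hardy-Weinberg proportions (Guo-Thompson Markov chain)
#'
#' Estimates the exact probability test for HWE at one locus within one
#' analysis unit: the probability, under Levene's conditional distribution
#' given the observed allele counts, of genotype tables no more probable than
#' the observed one. The estimate comes from the Guo-Thompson switch chain:
#' at each step two individuals are drawn and a re-pairing of their four
#' allele copies is proposed, accepted by a Metropolis-Hastings ratio that
#' leaves the conditional distribution invariant. The chain is run for
#' `dememorization` warm-up steps and then `batches` batches of
#' `iters_per_batch` steps; the p-value is the mean of the batch proportions
#' and the Monte-Carlo standard error is their standard deviation over
#' sqrt(batches). Defaults follow the Genepop convention (100 batches of
#' 5000, dememorization 10000).
#'
#' @param gt a [genotype_table()].
#' @param unit unit label within the partition given by `partition`.
#' @param locus locus name.
#' @param partition `"herd"`, `"breed"`, or named vector (see
#'   [allele_frequencies()]).
#' @param batches,iters_per_batch,dememorization chain parameters.
#' @param seed optional integer seed for reproducibility.
#' @return A list with `p`, `se`, `n_ind`, `n_alleles`, and `reason` when the
#'   test is undefined (monomorphic locus), in which case `p` is `NA`.
#' @export
hwe_exact_test <- function(gt, unit, locus, partition = "herd",
                           batches = 100L, iters_per_batch = 5000L,
                           dememorization = 10000L, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  part <- resolve_partition(gt, partition)
  rows <- match(names(part)[part == unit], gt$individuals)
  l <- match(locus, gt$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  g1 <- gt$a1[rows, l]; g2 <- gt$a2[rows, l]
  ok <- !is.na(g1)
  g1 <- g1[ok]; g2 <- g2[ok]
  hwe_exact_mc(g1, g2, batches, iters_per_batch, dememorization, seed)
}

#' @rdname hwe_exact_test
#' @param g1,g2 integer vectors of the two allele codes per typed individual
#'   (the genotype-vector interface used internally and by the simulator).
#' @export
hwe_exact_mc <- function(g1, g2, batches = 100L, iters_per_batch = 5000L,
                         dememorization = 10000L, seed = NULL) {
  n <- length(g1)
  alleles <- sort(unique(c(g1, g2)))
  J <- length(alleles)
  if (J < 2L || n < 2L)
    return(list(p = NA_real_, se = NA_real_, n_ind = n, n_alleles = J,
                reason = "monomorphic or too few individuals"))
  if (!is.null(seed)) set.seed(seed)
  a <- match(g1, alleles); b <- match(g2, alleles)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  cellkey <- function(x, y) (pmin(x, y) - 1L) * J + pmax(x, y)
  f <- integer(J * J)
  tab <- table(cellkey(a, b))
  f[as.integer(names(tab))] <- as.integer(tab)
  h <- sum(a != b)
  logpi <- function(f, h) h * log(2) - sum(lgamma(f[f > 0L] + 1))
  lp_obs <- logpi(f, h)
  lp <- lp_obs

  total_steps <- dememorization + batches * iters_per_batch
  hits <- numeric(batches)
  step_in_batch <- 0L; batch <- 0L; count <- 0L
  # pre-draw randomness in blocks to keep the R loop lean
  blk <- 20000L
  ri <- rj <- ru <- racc <- NULL; bpos <- blk
  for (step in seq_len(total_steps)) {
    if (bpos >= blk) {
      m <- min(blk, total_steps - step + 1L)
      ri <- sample.int(n, m, replace = TRUE)
      rj <- sample.int(n, m, replace = TRUE)
      ru <- runif(m); racc <- runif(m)
      bpos <- 0L
    }
    bpos <- bpos + 1L
    i <- ri[bpos]; j <- rj[bpos]
    if (i != j) {
      aa <- a[i]; bb <- b[i]; cc <- a[j]; dd <- b[j]
      if (ru[bpos] < 0.5) { ni1 <- aa; ni2 <- cc; nj1 <- bb; nj2 <- dd }
      else                { ni1 <- aa; ni2 <- dd; nj1 <- bb; nj2 <- cc }
      A <- cellkey(aa, bb); B <- cellkey(cc, dd)
      C <- cellkey(ni1, ni2); D <- cellkey(nj1, nj2)
      same <- (A == C && B == D) || (A == D && B == C)
      if (!same) {
        # pi ratio via the (at most four) affected cells, removal before
        # addition so overlapping cells are handled exactly
        cells <- unique(c(A, B, C, D))
        fold <- f[cells]; fnew <- fold
        fnew[match(A, cells)] <- fnew[match(A, cells)] - 1L
        fnew[match(B, cells)] <- fnew[match(B, cells)] - 1L
        fnew[match(C, cells)] <- fnew[match(C, cells)] + 1L
        fnew[match(D, cells)] <- fnew[match(D, cells)] + 1L
        dh <- (ni1 != ni2) + (nj1 != nj2) - (aa != bb) - (cc != dd)
        dlp <- dh * log(2) + sum(lgamma(fold + 1) - lgamma(fnew + 1))
        # proposal correction: pair counts and rearrangement multiplicity
        np_fwd <- if (A == B) f[A] * (f[A] - 1) / 2 else f[A] * f[B]
        fC <- fnew[match(C, cells)]; fD <- fnew[match(D, cells)]
        np_rev <- if (C == D) fC * (fC - 1) / 2 else fC * fD
        w_fwd <- if (aa == bb || cc == dd) 1 else 0.5
        w_rev <- if (ni1 == ni2 || nj1 == nj2) 1 else 0.5
        ratio <- exp(dlp) * (np_rev * w_rev) / (np_fwd * w_fwd)
        if (racc[bpos] < ratio) {
          f[cells] <- fnew
          a[i] <- min(ni1, ni2); b[i] <- max(ni1, ni2)
          a[j] <- min(nj1, nj2); b[j] <- max(nj1, nj2)
          h <- h + dh
          lp <- lp + dlp
        }
      }
    }
    if (step > dememorization) {
      if (lp <= lp_obs + 1e-9) count <- count + 1L
      step_in_batch <- step_in_batch + 1L
      if (step_in_batch == iters_per_batch) {
        batch <- batch + 1L
        hits[batch] <- count / iters_per_batch
        count <- 0L; step_in_batch <- 0L
        lp <- logpi(f, h)  # refresh against float drift
      }
    }
  }
  p <- mean(hits)
  se <- if (batches > 1L) sd(hits) / sqrt(batches) else NA_real_
  list(p = max(p, 1 / (batches * iters_per_batch)), se = se,
       n_ind = n, n_alleles = J, reason = NA_character_)
}

#' HWE exact tests across units and loci with Bonferroni correction
#'
#' Convenience wrapper running [hwe_exact_test()] for every unit x locus cell
#' and flagging familywise significance with [bonferroni_adjust()].
#'
#' @inheritParams hwe_exact_test
#' @param alpha familywise error rate for the Bonferroni step.
#' @return A data.frame with columns `unit`, `locus`, `p`, `se`, `p_adj`,
#'   `significant`.
#' @export
hwe_scan <- function(gt, partition = "breed", batches = 20L,
                     iters_per_batch = 500L, dememorization = 1000L,
                     alpha = 0.05, seed = NULL) {
  part <- resolve_partition(gt, partition)
  units <- unique(part)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (u in units) for (l in gt$loci) {
    res <- hwe_exact_test(gt, u, l, partition = partition, batches = batches,
                          iters_per_batch = iters_per_batch,
                          dememorization = dememorization, seed = NULL)
    rows[[length(rows) + 1L]] <- data.frame(unit = u, locus = l,
                                            p = res$p, se = res$se)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  adj <- bonferroni_adjust(out$p[ok], alpha)
  out$p_adj <- NA_real_; out$significant <- NA
  out$p_adj[ok] <- adj$p_adj
  out$significant[ok] <- adj$significant
  out
}
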