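#' Weir-Cockerham Fst (theta) over a partition
#'
#' Variance-component estimator of Wright's Fst: for every allele at every
#' locus the among-population (a), among-individual-within-population (b) and
#' within-individual (c) components are computed from sample sizes, allele
#' frequencies and observed heterozygote frequencies; the multilocus estimate
#' is sum(a) / sum(a+b+c) over all alleles and loci. Small negative estimates
#' are a normal property of the estimator and are not truncated. Loci
#' monomorphic across all units carry no information and are skipped.
#'
#' @param gt a [genotype_table()].
#' @param unit partition as in [allele_frequencies()] (herds, breeds, or
#'   genetic groups).
#' @return A list of class `fst_result` with `theta` (multilocus),
#'   `per_locus` (named vector), `components` (per-locus sums of a and
#'   a+b+c), `units`, `n_loci_used`.
#' @export
wc_fst <- function(gt, unit = "herd") {
  stopifnot(inherits(gt, "genotype_table"))
  part <- resolve_partition(gt, unit)
  units <- unique(part)
  if (length(units) < 2L) stop("need at least 2 units for Fst")
  idx <- lapply(units, function(u) match(names(part)[part == u], gt$individuals))
  comp <- vapply(seq_along(gt$loci), function(l)
    wc_locus_components(gt$a1[, l], gt$a2[, l], idx), numeric(2))
  used <- is.finite(comp[1, ]) & is.finite(comp[2, ]) & comp[2, ] != 0
  if (!any(used)) stop("no polymorphic locus informative for Fst")
  per_locus <- setNames(rep(NA_real_, length(gt$loci)), gt$loci)
  per_locus[used] <- comp[1, used] / comp[2, used]
  structure(list(theta = sum(comp[1, used]) / sum(comp[2, used]),
                 per_locus = per_locus,
                 components = list(a = setNames(comp[1, ], gt$loci),
                                   abc = setNames(comp[2, ], gt$loci)),
                 units = units, n_loci_used = sum(used)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham Fst over %d units, %d informative loci\n",
              length(x$units), x$n_loci_used))
  cat(sprintf("theta = %.4f", x$theta))
  if (!is.null(x$sd_jackknife))
    cat(sprintf(" (jackknife sd %.4f)", x$sd_jackknife))
  cat("\n")
  invisible(x)
}

# per-locus sums of variance components a and a+b+c over alleles.
# idx: list of row-index vectors, one per unit. Returns c(sum_a, sum_abc).
wc_locus_components <- function(g1, g2, idx) {
  stats_u <- lapply(idx, function(rows) {
    x1 <- g1[rows]; x2 <- g2[rows]
    ok <- !is.na(x1)
    list(x1 = x1[ok], x2 = x2[ok], n = sum(ok))
  })
  stats_u <- stats_u[vapply(stats_u, function(s) s$n > 0L, TRUE)]
  r <- length(stats_u)
  if (r < 2L) return(c(NA_real_, NA_real_))
  alleles <- sort(unique(unlist(lapply(stats_u, function(s) c(s$x1, s$x2)))))
  if (length(alleles) < 2L) return(c(NA_real_, NA_real_))
  ns <- vapply(stats_u, function(s) s$n, 0)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  sum_a <- 0; sum_abc <- 0
  for (al in alleles) {
    p_i <- vapply(stats_u, function(s)
      (sum(s$x1 == al) + sum(s$x2 == al)) / (2 * s$n), 0)
    h_i <- vapply(stats_u, function(s)
      mean((s$x1 == al) != (s$x2 == al)), 0)
    pbar <- sum(ns * p_i) / (r * nbar)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  c(sum_a, sum_abc)
}

#' Jackknife standard deviation of multilocus Fst
#'
#' Delete-one-locus jackknife over the loci that entered the multilocus
#' estimate: sd = sqrt((L-1)/L * sum((theta_(-l) - mean(theta_(-l)))^2)).
#'
#' @param gt a [genotype_table()].
#' @param unit partition as in [wc_fst()].
#' @return The `fst_result` from [wc_fst()] with `sd_jackknife` and
#'   `theta_loo` (leave-one-out estimates) added.
#' @export
fst_jackknife <- function(gt, unit = "herd") {
  res <- wc_fst(gt, unit)
  a <- res$components$a; abc <- res$components$abc
  used <- which(is.finite(a) & is.finite(abc) & abc != 0)
  L <- length(used)
  if (L < 3L) stop("jackknife needs at least 3 informative loci")
  loo <- vapply(used, function(l) {
    keep <- setdiff(used, l)
    sum(a[keep]) / sum(abc[keep])
  }, 0)
  res$theta_loo <- setNames(loo, names(a)[used])
  res$sd_jackknife <- sqrt((L - 1) / L * sum((loo - mean(loo))^2))
  res
}

#' Reynolds' coancestry distance matrix between herds
#'
#' For each herd pair the least-squares coancestry estimate theta-hat
#' (frequency-based, with the small-sample correction): per locus, with
#' sample sizes n1, n2 (typed individuals) and allele frequencies p1, p2,
#' and g_i = 1 - sum(p_i^2),
#'
#'   num_l = sum((p1-p2)^2)/2 - (n1+n2)(n1 g1 + n2 g2) /
#'           (4 n1 n2 (n1+n2-1))
#'   den_l = sum((p1-p2)^2)/2 + (4 n1 n2 - n1 - n2)(n1 g1 + n2 g2) /
#'           (4 n1 n2 (n1+n2-1))
#'
#' loci are combined by summing numerators and denominators, and the distance
#' is D_r = -ln(1 - theta-hat), linear in drift time for short divergence;
#' negative theta-hat is truncated to 0 before the log. Only loci typed in
#' both herds of a pair enter its estimate.
#'
#' @param gt a [genotype_table()].
#' @param herds herd ids to include; default all birth herds with at least
#'   `min_animals` genotyped animals.
#' @param min_animals herd-size threshold (default 5).
#' @param return_theta if `TRUE` the matrix holds theta-hat itself (not
#'   log-transformed, negatives kept) instead of D_r.
#' @return A list of class `herd_matrix` with `herds` (ordered ids),
#'   `values` (symmetric matrix, zero diagonal), `kind = "reynolds"` (or
#'   `"reynolds_theta"`).
#' @export
reynolds_matrix <- function(gt, herds = NULL, min_animals = 5L,
                            return_theta = FALSE) {
  stopifnot(inherits(gt, "genotype_table"))
  hs <- herd_sizes(gt)
  if (is.null(herds)) herds <- names(hs)[hs >= min_animals]
  else {
    small <- herds[is.na(hs[herds]) | hs[herds] < min_animals]
    if (length(small))
      stop("herd(s) below the ", min_animals, "-animal threshold: ",
           paste(small, collapse = ", "))
  }
  if (length(herds) < 2L) stop("need at least 2 qualifying herds")
  part <- resolve_partition(gt, "herd")
  idx <- lapply(herds, function(h) match(names(part)[part == h], gt$individuals))
  H <- length(herds)
  vals <- matrix(0, H, H, dimnames = list(herds, herds))
  for (i in seq_len(H - 1L)) for (j in seq(i + 1L, H)) {
    th <- reynolds_theta_pair(gt, idx[[i]], idx[[j]])
    v <- if (return_theta) th else -log(1 - max(th, 0))
    vals[i, j] <- vals[j, i] <- v
  }
  structure(list(herds = herds, values = vals,
                 kind = if (return_theta) "reynolds_theta" else "reynolds"),
            class = "herd_matrix")
}

# pairwise Reynolds 1983 least-squares coancestry over shared typed loci
reynolds_theta_pair <- function(gt, rows1, rows2) {
  num <- 0; den <- 0; any_locus <- FALSE
  for (l in seq_along(gt$loci)) {
    x1 <- c(gt$a1[rows1, l], gt$a2[rows1, l]); x1 <- x1[!is.na(x1)]
    x2 <- c(gt$a1[rows2, l], gt$a2[rows2, l]); x2 <- x2[!is.na(x2)]
    n1 <- length(x1) / 2; n2 <- length(x2) / 2
    if (n1 < 1 || n2 < 1 || n1 + n2 < 1.5) next
    alleles <- sort(unique(c(x1, x2)))
    p1 <- vapply(alleles, function(a) mean(x1 == a), 0)
    p2 <- vapply(alleles, function(a) mean(x2 == a), 0)
    ssd <- sum((p1 - p2)^2) / 2
    g1 <- 1 - sum(p1^2); g2 <- 1 - sum(p2^2)
    corr <- (n1 * g1 + n2 * g2) / (4 * n1 * n2 * (n1 + n2 - 1))
    num <- num + ssd - (n1 + n2) * corr
    den <- den + ssd + (4 * n1 * n2 - n1 - n2) * corr
    any_locus <- TRUE
  }
  if (!any_locus || den == 0) return(NA_real_)
  num / den
}

#' @export
print.herd_matrix <- function(x, ...) {
  cat(sprintf("%s matrix over %d herds\n", x$kind, length(x$herds)))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a herd-pair matrix as square and long-format TSV
#'
#' @param m a `herd_matrix` (from [reynolds_matrix()] or
#'   [shortest_path_lengths()]).
#' @param square_path,long_path output paths (either may be `NULL`).
#' @return Invisibly, the long-format data.frame.
#' @export
write_herd_matrix <- function(m, square_path = NULL, long_path = NULL) {
  stopifnot(inherits(m, "herd_matrix"))
  if (!is.null(square_path)) {
    df <- data.frame(herd = m$herds, m$values, check.names = FALSE)
    write.table(df, square_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pairs <- which(upper.tri(m$values), arr.ind = TRUE)
  long <- data.frame(herd_i = m$herds[pairs[, 1]],
                     herd_j = m$herds[pairs[, 2]],
                     value = m$values[pairs])
  names(long)[3] <- m$kind
  if (!is.null(long_path))
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
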