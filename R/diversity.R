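#' Allele frequencies per analysis unit and locus
#'
#' Frequencies are computed over observed alleles within each unit (herd,
#' breed, or an arbitrary partition) at each locus, together with the gene
#' count (2 x typed individuals). A unit with no typed individual at a locus
#' yields an `NA` cell, never a zero-frequency table.
#'
#' @param gt a [genotype_table()].
#' @param unit `"herd"`, `"breed"`, or a named character vector
#'   animal -> unit label (animals with `NA` labels are dropped).
#' @return A list keyed by unit; each element a list keyed by locus with
#'   fields `freq` (named numeric vector summing to 1), `n_ind`, `n_genes`,
#'   or `NULL` for an all-missing cell.
#' @export
allele_frequencies <- function(gt, unit = "herd") {
  stopifnot(inherits(gt, "genotype_table"))
  part <- resolve_partition(gt, unit)
  units <- unique(part)
  idx_all <- match(names(part), gt$individuals)
  out <- lapply(units, function(u) {
    rows <- idx_all[part == u]
    per_locus <- lapply(seq_along(gt$loci), function(l) {
      al <- c(gt$a1[rows, l], gt$a2[rows, l])
      al <- al[!is.na(al)]
      if (!length(al)) return(NULL)
      tab <- table(al)
      list(freq = setNames(as.numeric(tab) / length(al), names(tab)),
           n_ind = length(al) / 2, n_genes = length(al),
           counts = setNames(as.integer(tab), names(tab)))
    })
    setNames(per_locus, gt$loci)
  })
  setNames(out, units)
}

#' Per-locus diversity statistics within analysis units
#'
#' For each unit and locus: typed individuals, allele count, observed
#' heterozygosity Ho (fraction of heterozygous typed individuals), Nei's
#' unbiased expected heterozygosity He = 2n/(2n-1) * (1 - sum p_i^2), and the
#' inbreeding coefficient Fis = 1 - Ho/He using that small-sample He (the
#' naive large-sample variant 1 - Ho/(1 - sum p_i^2) is available for
#' cross-checking). Monomorphic loci report Ho = He = 0 and Fis = NA.
#'
#' @param gt a [genotype_table()].
#' @param unit partition as in [allele_frequencies()].
#' @param fis one of `"unbiased"` (default) or `"naive"`.
#' @return A data.frame with columns `unit`, `locus`, `n_ind`, `n_alleles`,
#'   `Ho`, `He`, `Fis`.
#' @export
per_locus_stats <- function(gt, unit = "herd", fis = c("unbiased", "naive")) {
  fis <- match.arg(fis)
  part <- resolve_partition(gt, unit)
  units <- unique(part)
  idx_all <- match(names(part), gt$individuals)
  rows <- list()
  for (u in units) {
    ridx <- idx_all[part == u]
    for (l in seq_along(gt$loci)) {
      g1 <- gt$a1[ridx, l]; g2 <- gt$a2[ridx, l]
      ok <- !is.na(g1)
      n <- sum(ok)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit = u, locus = gt$loci[l], n_ind = 0L, n_alleles = NA_integer_,
          Ho = NA_real_, He = NA_real_, Fis = NA_real_)
        next
      }
      al <- c(g1[ok], g2[ok])
      p <- as.numeric(table(al)) / (2 * n)
      k <- length(p)
      if (k == 1L) {
        ho <- 0; he <- 0; f <- NA_real_
      } else {
        ho <- mean(g1[ok] != g2[ok])
        gd <- 1 - sum(p^2)
        he <- 2 * n / (2 * n - 1) * gd
        denom <- if (fis == "unbiased") he else gd
        f <- if (denom > 0) 1 - ho / denom else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, locus = gt$loci[l], n_ind = n, n_alleles = k,
        Ho = ho, He = he, Fis = f)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multilocus diversity summary per unit
#'
#' Unweighted means of Ho, He and allele number over polymorphic loci (the
#' breed-level single values reported alongside per-locus tables).
#'
#' @param stats output of [per_locus_stats()].
#' @return A data.frame with columns `unit`, `n_loci`, `mean_A`, `Ho`, `He`,
#'   `Fis` (mean over loci with defined Fis).
#' @export
unit_diversity_summary <- function(stats) {
  sp <- split(stats, stats$unit)
  out <- do.call(rbind, lapply(sp, function(d) {
    poly <- d[!is.na(d$n_alleles) & d$n_alleles > 1L, , drop = FALSE]
    data.frame(unit = d$unit[1L], n_loci = nrow(poly),
               mean_A = mean(d$n_alleles, na.rm = TRUE),
               Ho = mean(poly$Ho), He = mean(poly$He),
               Fis = mean(poly$Fis, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a standardized subsample of `g` genes,
#' comparable across unequal sample sizes: per locus
#' AR = sum_a (1 - choose(2N - N_a, g) / choose(2N, g)) where N is the number
#' of typed individuals and N_a the count of allele a; the unit value is the
#' mean over loci. By default `g` is the smallest gene count over units and
#' retained loci (the Fstat convention).
#'
#' @param gt a [genotype_table()].
#' @param unit partition as in [allele_frequencies()].
#' @param g rarefaction size in genes (>= 2); `NULL` for the default.
#' @param loci optional subset of locus names to retain.
#' @return A data.frame with columns `unit`, `g`, `AR` plus attribute
#'   `per_locus` (unit x locus matrix).
#' @export
allelic_richness <- function(gt, unit = "herd", g = NULL, loci = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(loci)) loci <- gt$loci
  fr <- allele_frequencies(gt, unit)
  gene_counts <- vapply(fr, function(u)
    min(vapply(u[loci], function(cell)
      if (is.null(cell)) Inf else cell$n_genes, 0)), 0)
  if (is.null(g)) g <- min(gene_counts)
  if (!is.finite(g) || g < 2) stop("rarefaction size g must be >= 2")
  if (g > min(gene_counts))
    stop(sprintf("g = %d exceeds the smallest gene count (%d)",
                 as.integer(g), as.integer(min(gene_counts))))
  per <- matrix(NA_real_, length(fr), length(loci),
                dimnames = list(names(fr), loci))
  for (u in names(fr)) for (l in loci) {
    cell <- fr[[u]][[l]]
    if (is.null(cell)) next
    per[u, l] <- rarefied_allele_count(cell$counts, g)
  }
  out <- data.frame(unit = names(fr), g = as.integer(g),
                    AR = rowMeans(per, na.rm = TRUE))
  rownames(out) <- NULL
  attr(out, "per_locus") <- per
  out
}

# expected allele count in a random subsample of g genes, hypergeometric form
rarefied_allele_count <- function(counts, g) {
  n2 <- sum(counts)
  if (g > n2) stop("g exceeds gene count")
  # 1 - C(2N - Na, g)/C(2N, g), on log scale for stability
  miss <- ifelse(n2 - counts >= g,
                 exp(lchoose(n2 - counts, g) - lchoose(n2, g)), 0)
  sum(1 - miss)
}

#' Bonferroni correction for a family of tests
#'
#' Flags test i significant iff p_i <= alpha / m over the m supplied p-values,
#' and reports the Bonferroni-adjusted p-values.
#'
#' @param pvalues numeric vector of p-values.
#' @param alpha familywise error rate in (0, 1).
#' @return A data.frame with columns `p`, `p_adj`, `significant`, plus
#'   attribute `threshold` = alpha/m.
#' @export
bonferroni_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- length(pvalues)
  if (m == 0L) {
    out <- data.frame(p = numeric(0), p_adj = numeric(0),
                      significant = logical(0))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  out <- data.frame(p = pvalues,
                    p_adj = p.adjust(pvalues, method = "bonferroni"),
                    significant = pvalues <= alpha / m)
  attr(out, "threshold") <- alpha / m
  out
}

#' Null-allele screening by homozygote excess
#'
#' Brookfield's estimator 1, r = (He - Ho) / (1 + He), per unit and locus; a
#' locus is flagged suspected when r exceeds `threshold` and Ho < He. This is
#' a deliberately simple homozygote-excess screen whose binary outcome drives
#' the optional per-breed marker exclusion.
#'
#' @param gt a [genotype_table()].
#' @param unit partition as in [allele_frequencies()].
#' @param threshold suspicion threshold on r (default 0.05).
#' @return A data.frame with columns `unit`, `locus`, `Ho`, `He`,
#'   `null_freq`, `suspected`.
#' @export
null_allele_estimate <- function(gt, unit = "breed", threshold = 0.05) {
  st <- per_locus_stats(gt, unit)
  r <- ifelse(is.na(st$He) | st$He == 0, NA_real_,
              (st$He - st$Ho) / (1 + st$He))
  data.frame(unit = st$unit, locus = st$locus, Ho = st$Ho, He = st$He,
             null_freq = r,
             suspected = !is.na(r) & r > threshold & st$Ho < st$He)
}
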