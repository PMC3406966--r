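#' Diploid microsatellite genotype table
#'
#' The central data container: diploid allele calls (positive integer codes,
#' typically fragment lengths) for a set of individuals at a set of loci,
#' together with each animal's herd of birth and breed label. Missing
#' genotypes are stored as `NA` in both allele slots; a partially scored
#' genotype is treated as missing. Allele order within a call carries no
#' meaning.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of each call; `NA` marks a missing call. Dimnames are taken from
#'   `individuals` and `loci`.
#' @param individuals character vector of animal identifiers (opaque strings).
#' @param loci character vector of locus names.
#' @param herd named character vector mapping every animal to its herd of
#'   birth; `NA` flags an unknown birth herd (such animals are kept but are
#'   excluded from herd-level analyses).
#' @param breed named character vector mapping every animal to a breed label.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, individuals, loci, herd, breed) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individuals); L <- length(loci)
  if (anyDuplicated(individuals)) stop("duplicate animal identifiers")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  # partial calls (one allele scored) collapse to missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  herd <- as.character(herd)[match(individuals, names(herd))]
  breed <- as.character(breed)[match(individuals, names(breed))]
  if (length(breed) != n || all(is.na(breed)))
    stop("breed map must cover all individuals")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(individuals = as.character(individuals), loci = as.character(loci),
         a1 = a1, a2 = a2,
         herd = setNames(herd, individuals),
         breed = setNames(breed, individuals)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  nh <- length(unique(x$herd[!is.na(x$herd)]))
  cat(sprintf("genotype_table: %d individuals, %d loci, %d birth herds, breeds: %s\n",
              length(x$individuals), length(x$loci), nh,
              paste(unique(x$breed), collapse = ", ")))
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  per_herd <- table(object$herd, useNA = "ifany")
  list(n_individuals = length(object$individuals),
       n_loci = length(object$loci),
       herd_sizes = per_herd,
       missing_rate = mean(is.na(object$a1)))
}

#' Subset a genotype table by individuals
#'
#' @param gt a [genotype_table()].
#' @param individuals character vector of animal ids to keep (order preserved).
#' @return A `genotype_table` restricted to those animals.
#' @export
subset_individuals <- function(gt, individuals) {
  stopifnot(inherits(gt, "genotype_table"))
  keep <- match(individuals, gt$individuals)
  if (anyNA(keep)) stop("unknown individuals: ",
                        paste(individuals[is.na(keep)], collapse = ", "))
  genotype_table(gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE],
                 gt$individuals[keep], gt$loci,
                 gt$herd[keep], gt$breed[keep])
}

#' Number of genotyped animals per herd of birth
#'
#' Animals with unknown herd of birth are excluded.
#'
#' @param gt a [genotype_table()].
#' @return Named integer vector, herd id -> count.
#' @export
herd_sizes <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  h <- gt$herd[!is.na(gt$herd)]
  tab <- table(h)
  setNames(as.integer(tab), names(tab))
}

# resolve a partition of individuals into analysis units.
# `unit` is "herd", "breed", or a named character vector animal -> unit label.
# Individuals with NA unit are dropped.
resolve_partition <- function(gt, unit) {
  if (is.character(unit) && length(unit) == 1L && unit %in% c("herd", "breed")) {
    p <- if (unit == "herd") gt$herd else gt$breed
  } else {
    p <- as.character(unit)[match(gt$individuals, names(unit))]
    p <- setNames(p, gt$individuals)
  }
  p[!is.na(p)]
}
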