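# fixture builders shared across test files; everything is generated in code

# genotype table from a character matrix of "a/b" calls ("" or NA = missing)
make_gt <- function(calls, herd, breed = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(n))
  if (is.null(loci)) loci <- colnames(calls)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  a1 <- matrix(NA_integer_, n, L); a2 <- a1
  for (j in seq_len(L)) {
    v <- calls[, j]
    ok <- !is.na(v) & nzchar(v)
    parts <- strsplit(v[ok], "/", fixed = TRUE)
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2))
  }
  if (length(herd) == 1L) herd <- rep(herd, n)
  if (is.null(breed)) breed <- rep("B1", n)
  if (length(breed) == 1L) breed <- rep(breed, n)
  herdnet::genotype_table(a1, a2, ids, loci,
                          stats::setNames(herd, ids),
                          stats::setNames(breed, ids))
}

# genotype table drawn from given per-unit allele frequencies (HWE within unit)
random_gt <- function(freqs_per_unit, n_per_unit, n_loci = 5L,
                      missing_rate = 0) {
  units <- names(freqs_per_unit)
  ids <- character(0); herd <- character(0)
  a1 <- NULL; a2 <- NULL
  for (u in units) {
    p <- freqs_per_unit[[u]]
    m <- n_per_unit[[u]]
    g1 <- matrix(0L, m, n_loci); g2 <- g1
    for (l in seq_len(n_loci)) {
      pl <- if (is.list(p)) p[[l]] else p
      g1[, l] <- sample.int(length(pl), m, TRUE, prob = pl)
      g2[, l] <- sample.int(length(pl), m, TRUE, prob = pl)
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(m * n_loci) < missing_rate, m, n_loci)
      g1[drop] <- NA_integer_; g2[drop] <- NA_integer_
    }
    uid <- sprintf("%s_%02d", u, seq_len(m))
    ids <- c(ids, uid); herd <- c(herd, rep(u, m))
    a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
  }
  herdnet::genotype_table(a1, a2, ids, sprintf("L%02d", seq_len(n_loci)),
                          stats::setNames(herd, ids),
                          stats::setNames(rep("B1", length(ids)), ids))
}

# Erdos-Renyi herd graph (possibly disconnected), herds named V01..Vn
random_herd_graph <- function(n, p_edge = 0.3) {
  ids <- sprintf("V%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep))
    return(herdnet::build_graph(
      herdnet::exchange_records(character(0), character(0)),
      restrict_to = ids))
  herdnet::build_graph(
    herdnet::exchange_records(ids[pairs[1, keep]], ids[pairs[2, keep]]),
    restrict_to = ids)
}

# random symmetric distance-like matrix with zero diagonal
random_sym_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  m
}

# toy Genepop file content, 2 pops x 2 loci
toy_genepop <- function(path, digits = 2) {
  enc <- function(a, b) {
    f <- paste0("%0", digits, "d")
    paste0(sprintf(f, a), sprintf(f, b))
  }
  writeLines(c(
    "toy data",
    "LocA", "LocB",
    "POP",
    paste0("a1 , ", enc(1, 1), " ", enc(2, 2)),
    paste0("a2 , ", enc(1, 2), " ", enc(0, 0)),
    "POP",
    paste0("b1 , ", enc(2, 2), " ", enc(1, 1)),
    paste0("b2 , ", enc(2, 1), " ", enc(1, 2))
  ), path)
  path
}
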