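#' Select the herd set for the genetic-vs-network correlation
#'
#' Keeps herds with at least `min_animals` genotyped animals that also have
#' exchange information, then drops isolated sub-networks: only the largest
#' connected component of the graph restricted to qualifying herds survives,
#' avoiding infinite shortest-path distances. Excluded herds are reported
#' with a reason.
#'
#' @param gt a [genotype_table()].
#' @param g a `herd_graph` built over all herds with identified exchanges.
#' @param min_animals herd-size threshold (default 5).
#' @return A list with `herds` (retained, sorted), `excluded` (data.frame
#'   herd/reason).
#' @export
select_analysis_herds <- function(gt, g, min_animals = 5L) {
  stopifnot(inherits(gt, "genotype_table"), inherits(g, "herd_graph"))
  hs <- herd_sizes(gt)
  excluded <- data.frame(herd = character(0), reason = character(0))
  drop <- function(h, why) rbind(excluded, data.frame(herd = h, reason = why))
  small <- names(hs)[hs < min_animals]
  if (length(small)) excluded <- drop(small, "below threshold")
  no_net <- setdiff(names(hs)[hs >= min_animals], g$herds)
  if (length(no_net)) excluded <- drop(no_net, "no exchange information")
  qual <- intersect(names(hs)[hs >= min_animals], g$herds)
  if (length(qual) >= 1L) {
    sub <- igraph::induced_subgraph(g$graph, qual)
    comp <- igraph::components(sub)
    main <- which.max(comp$csize)
    keep <- igraph::V(sub)$name[comp$membership == main]
    islet <- setdiff(qual, keep)
    if (length(islet)) excluded <- drop(islet, "isolated network")
  } else keep <- character(0)
  if (length(keep) < 3L)
    stop("fewer than 3 herds survive selection; Mantel analysis undefined")
  list(herds = sort(keep), excluded = excluded)
}

#' Mantel test between two herd-pair matrices
#'
#' Pearson correlation r over the strict lower triangle of two symmetric
#' matrices sharing one herd ordering, with a permutation p-value: the herd
#' labels of the second matrix are permuted jointly on rows and columns
#' `n_perm` times and p = (number of permuted statistics at least as extreme
#' + 1) / (n_perm + 1), so p is never 0. The default tail is one-sided
#' positive (the directional hypothesis that exchanging herds are more
#' genetically similar); `"two.sided"` compares |r|.
#'
#' @param m1,m2 `herd_matrix` objects (or plain symmetric matrices) with
#'   identical herd ordering and no non-finite entries.
#' @param n_perm number of permutations (default 1e5).
#' @param seed optional integer seed.
#' @param tail `"greater"` (default) or `"two.sided"`.
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm`, `n_herds`,
#'   `tail`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 100000L, seed = NULL,
                        tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  v1 <- if (inherits(m1, "herd_matrix")) m1$values else m1
  v2 <- if (inherits(m2, "herd_matrix")) m2$values else m2
  if (inherits(m1, "herd_matrix") && inherits(m2, "herd_matrix") &&
      !identical(m1$herds, m2$herds))
    stop("herd orderings differ between the two matrices")
  if (!all(dim(v1) == dim(v2))) stop("matrix dimension mismatch")
  if (!all(is.finite(v1)) || !all(is.finite(v2)))
    stop("non-finite entries (disconnected herd pairs?) in Mantel input")
  n <- nrow(v1)
  if (n < 3L) stop("need at least 3 herds")
  lt <- lower.tri(v1)
  x <- v1[lt]
  if (sd(x) == 0 || sd(v2[lt]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- cor(x, v2[lt])
  if (!is.null(seed)) set.seed(seed)
  stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    stat[b] <- cor(x, v2[perm, perm][lt])
  }
  extreme <- if (tail == "greater") sum(stat >= r_obs - 1e-12)
             else sum(abs(stat) >= abs(r_obs) - 1e-12)
  structure(list(r = r_obs, p = (extreme + 1) / (n_perm + 1),
                 n_perm = n_perm, n_herds = n, tail = tail, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d herds): r = %.3f, p = %.4g (%d permutations)\n",
              x$tail, x$n_herds, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Align a Reynolds matrix and an SPL matrix on a common herd set
#'
#' @param gen,spl `herd_matrix` objects.
#' @param herds herd ids to keep (must be present in both).
#' @return A list with the two re-ordered matrices.
#' @export
align_matrices <- function(gen, spl, herds) {
  herds <- sort(herds)
  for (m in list(gen, spl))
    if (!all(herds %in% m$herds))
      stop("herd(s) missing from a matrix: ",
           paste(setdiff(herds, m$herds), collapse = ", "))
  re <- function(m) {
    m$values <- m$values[herds, herds]; m$herds <- herds; m
  }
  list(gen = re(gen), spl = re(spl))
}

#' Pairwise scatter data for genetic distance vs shortest path length
#'
#' @param gen,spl aligned `herd_matrix` objects.
#' @return A data.frame with columns `herd_i`, `herd_j`, `reynolds`, `spl`.
#' @export
pair_scatter <- function(gen, spl) {
  stopifnot(identical(gen$herds, spl$herds))
  ut <- which(upper.tri(gen$values), arr.ind = TRUE)
  data.frame(herd_i = gen$herds[ut[, 1]], herd_j = gen$herds[ut[, 2]],
             reynolds = gen$values[ut], spl = spl$values[ut])
}
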