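#' Tiered characterization and ranking of cryobank donor candidates
#'
#' Combines every available evidence source into a priority ordering:
#'
#' * Tier 1 - genotyped candidates carry their own assignment: the cluster of
#'   their maximal individual membership q when it reaches `q_threshold`
#'   (default 0.7, the herd rule reused at the individual level), otherwise
#'   unassigned but still tier 1.
#' * Tier 2 - non-genotyped candidates with a genotyped dam and sire
#'   (preferred) or at least one genotyped grandparent: the putative group is
#'   the relatives' common group; relatives that disagree, or are themselves
#'   unassigned, yield an unassigned tier-2 candidate.
#' * Tier 3 - candidates with network evidence only: the group of the natal
#'   herd when that herd is assigned, otherwise the majority group among the
#'   natal herd's direct exchange partners (ties yield unassigned).
#'
#' Candidates with no usable evidence are reported as uncharacterizable,
#' never dropped. Ranking is tier-ascending; within a tier, candidates are
#' interleaved round-robin across genetic groups so that every group is
#' represented as evenly as possible, unassigned candidates last.
#'
#' @param candidates character vector of animal ids.
#' @param gt a [genotype_table()].
#' @param assignments herd-group table from [assign_groups()].
#' @param q individual membership matrix (animals x K) with rownames, e.g.
#'   the aligned average from [align_runs()].
#' @param ped a [pedigree_records()] data.frame (or `NULL`).
#' @param g a `herd_graph` (or `NULL`).
#' @param natal_herd named character vector animal -> herd for non-genotyped
#'   candidates (genotyped candidates use their birth herd in `gt`).
#' @param q_threshold individual-level assignment threshold.
#' @return A data.frame of class `donor_ranking`: `rank`, `animal`, `herd`,
#'   `tier`, `evidence`, `group`, `notes`.
#' @export
rank_donors <- function(candidates, gt, assignments, q, ped = NULL, g = NULL,
                        natal_herd = NULL, q_threshold = 0.7) {
  stopifnot(inherits(gt, "genotype_table"))
  herd_group <- setNames(assignments$group, assignments$herd)

  indiv_group <- function(animal) {
    # individual-level threshold rule on the membership matrix
    if (is.null(q) || !animal %in% rownames(q)) return(NA_character_)
    qi <- q[animal, ]
    if (max(qi) >= q_threshold) paste0("G", which.max(qi)) else NA_character_
  }

  rows <- lapply(candidates, function(an) {
    genotyped <- an %in% gt$individuals
    herd <- if (genotyped) unname(gt$herd[an])
            else if (!is.null(natal_herd) && an %in% names(natal_herd))
              unname(natal_herd[an])
            else NA_character_
    if (genotyped) {
      grp <- indiv_group(an)
      return(data.frame(animal = an, herd = ifelse(is.na(herd), "", herd),
                        tier = 1L, evidence = "direct",
                        group = ifelse(is.na(grp), "UNASSIGNED", grp),
                        notes = ifelse(is.na(grp),
                                       "max q below threshold", "own genotype"),
                        stringsAsFactors = FALSE))
    }
    # pedigree evidence: genotyped dam+sire, else genotyped grandparents
    if (!is.null(ped) && an %in% ped$animal) {
      prow <- ped[ped$animal == an, ]
      parents <- c(prow$sire, prow$dam)
      parents <- parents[!is.na(parents)]
      gpar <- setdiff(ancestors_depth2(ped, an), parents)
      rel <- if (length(parents) == 2L && all(parents %in% gt$individuals))
        list(set = parents, what = "dam and sire")
      else {
        gg <- gpar[gpar %in% gt$individuals]
        if (length(gg)) list(set = gg, what = "grandparents") else NULL
      }
      if (!is.null(rel)) {
        grps <- vapply(rel$set, indiv_group, "")
        grp <- if (anyNA(grps) || length(unique(grps)) != 1L) NA_character_
               else unique(grps)
        return(data.frame(animal = an, herd = ifelse(is.na(herd), "", herd),
                          tier = 2L, evidence = "pedigree",
                          group = ifelse(is.na(grp), "UNASSIGNED", grp),
                          notes = ifelse(is.na(grp),
                                         paste("genotyped", rel$what, "disagree"),
                                         paste("putative via", rel$what)),
                          stringsAsFactors = FALSE))
      }
    }
    # network-only evidence
    if (!is.na(herd)) {
      if (!is.na(herd_group[herd] %||% NA)) {
        return(data.frame(animal = an, herd = herd, tier = 3L,
                          evidence = "network",
                          group = unname(herd_group[herd]),
                          notes = "natal herd assigned",
                          stringsAsFactors = FALSE))
      }
      if (!is.null(g) && herd %in% g$herds) {
        partners <- igraph::V(g$graph)$name[
          as.integer(igraph::neighbors(g$graph, herd))]
        pg <- herd_group[intersect(partners, names(herd_group))]
        pg <- pg[!is.na(pg)]
        if (length(pg)) {
          tab <- sort(table(pg), decreasing = TRUE)
          grp <- if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_
                 else names(tab)[1L]
          note <- ifelse(is.na(grp), "exchange partners tie",
                         "majority of exchange partners")
        } else {
          grp <- NA_character_
          note <- "no informative exchange partners"
        }
        return(data.frame(animal = an, herd = herd, tier = 3L,
                          evidence = "network",
                          group = ifelse(is.na(grp), "UNASSIGNED", grp),
                          notes = note, stringsAsFactors = FALSE))
      }
    }
    data.frame(animal = an, herd = ifelse(is.na(herd), "", herd),
               tier = NA_integer_, evidence = "none", group = "UNKNOWN",
               notes = "no genotype, pedigree or network evidence",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  # within-tier round-robin over groups; uncharacterizable candidates last
  ordered <- list()
  for (ti in sort(unique(out$tier[!is.na(out$tier)]))) {
    sub <- out[!is.na(out$tier) & out$tier == ti, , drop = FALSE]
    grps <- sort(unique(sub$group[sub$group != "UNASSIGNED"]))
    buckets <- lapply(grps, function(gn)
      sub[sub$group == gn, , drop = FALSE])
    if (any(sub$group == "UNASSIGNED"))
      buckets <- c(buckets, list(sub[sub$group == "UNASSIGNED", ,
                                     drop = FALSE]))
    while (any(vapply(buckets, nrow, 0L) > 0L)) {
      for (bi in seq_along(buckets)) {
        if (nrow(buckets[[bi]])) {
          ordered[[length(ordered) + 1L]] <- buckets[[bi]][1L, , drop = FALSE]
          buckets[[bi]] <- buckets[[bi]][-1L, , drop = FALSE]
        }
      }
    }
  }
  unchar <- out[is.na(out$tier), , drop = FALSE]
  out <- rbind(do.call(rbind, c(ordered, list(unchar[0, ]))), unchar)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("donor_ranking", "data.frame")
  out[, c("rank", "animal", "herd", "tier", "evidence", "group", "notes")]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Per-tier and per-group donor summary
#'
#' @param ranking a `donor_ranking` from [rank_donors()].
#' @return A list with `per_tier` and `per_group` count tables and
#'   `n_characterized`.
#' @export
donor_summary <- function(ranking) {
  char <- ranking[!is.na(ranking$tier), , drop = FALSE]
  list(n_candidates = nrow(ranking),
       n_characterized = nrow(char),
       per_tier = table(tier = char$tier),
       per_group = table(group = char$group),
       per_tier_group = table(tier = char$tier, group = char$group))
}
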