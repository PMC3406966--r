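#' Read a Genepop genotype file
#'
#' Parses the Genepop dialect used throughout the microsatellite software
#' family: a title line, locus names (one per line or comma-separated on one
#' line), then `POP`-delimited samples with 2- or 3-digit diploid allele
#' encoding where `00`/`000` codes a missing allele. POP blocks become herds
#' (`P1`, `P2`, ...) unless an explicit animal-to-herd map overrides them —
#' the herd label carried into all analyses is the herd of *birth*, which
#' Genepop's residence-based blocks cannot express.
#'
#' @param path path to a Genepop file.
#' @param herd_map optional path to a delimited file with columns `animal`,
#'   `herd` and optionally `breed`; overrides POP-block herds. An empty herd
#'   field flags an unknown birth herd.
#' @param breed default breed label applied when no map provides one.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, herd_map = NULL, breed = "unknown") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("Genepop file too short: ", path)
  body <- lines[-1L]  # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP line found in ", path)
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found in ", path)

  sample_lines <- body[seq(first_pop, length(body))]
  pop_idx <- cumsum(grepl("^\\s*pop\\s*$", sample_lines, ignore.case = TRUE))
  rows <- sample_lines[!grepl("^\\s*pop\\s*$", sample_lines, ignore.case = TRUE)]
  row_pop <- pop_idx[!grepl("^\\s*pop\\s*$", sample_lines, ignore.case = TRUE)]
  if (!length(rows)) stop("no sample rows found in ", path)

  ids <- character(length(rows)); fields <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed sample row (no comma) at line: ", rows[i])
    ids[i] <- trimws(parts[1L])
    gen <- trimws(paste(parts[-1L], collapse = " "))
    f <- strsplit(gen, "\\s+")[[1L]]
    if (length(f) != length(loci))
      stop(sprintf("ragged genotype row for '%s': %d fields, expected %d loci",
                   ids[i], length(f), length(loci)))
    fields[[i]] <- f
  }
  if (anyDuplicated(ids)) {
    # Genepop permits repeated row labels; disambiguate deterministically
    ids <- make.unique(ids, sep = "_")
  }
  widths <- unique(nchar(unlist(fields)))
  if (!length(widths) == 1L || !widths %in% c(4L, 6L))
    stop("unknown allele encoding width (expect uniform 4 or 6 characters), saw: ",
         paste(widths, collapse = ", "))
  w <- widths / 2L
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    x1 <- as.integer(substr(f, 1L, w))
    x2 <- as.integer(substr(f, w + 1L, 2L * w))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  herd <- setNames(paste0("P", row_pop), ids)
  breed_v <- setNames(rep(breed, n), ids)
  if (!is.null(herd_map)) {
    hm <- read_herd_map(herd_map)
    idx <- match(ids, hm$animal)
    if (anyNA(idx))
      stop("herd map missing animals: ",
           paste(head(ids[is.na(idx)], 5L), collapse = ", "))
    herd <- setNames(hm$herd[idx], ids)
    if (!is.null(hm$breed)) breed_v <- setNames(hm$breed[idx], ids)
  }
  genotype_table(a1, a2, ids, loci, herd, breed_v)
}

#' Write a genotype table in Genepop format
#'
#' Herds become POP blocks (in first-appearance order); animals with an
#' unknown birth herd are emitted in a final block. Because Genepop itself
#' cannot store herd or breed labels, an optional sidecar map preserves them
#' for an exact round trip through [read_genepop()].
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @param digits allele encoding width, 2 or 3 digits per allele.
#' @param herd_map optional path for a sidecar `animal`/`herd`/`breed` table.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, digits = 3L, herd_map = NULL,
                          title = "herdnet genotype export") {
  stopifnot(inherits(gt, "genotype_table"), digits %in% c(2L, 3L))
  mx <- max(c(gt$a1, gt$a2), na.rm = TRUE)
  if (mx >= 10^digits)
    stop(sprintf("allele code %d does not fit a %d-digit encoding", mx, digits))
  fmt <- function(x) {
    out <- sprintf(paste0("%0", digits, "d"), ifelse(is.na(x), 0L, x))
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  # animals with unknown birth herd form their own trailing POP block
  herd_f <- ifelse(is.na(gt$herd), "__UNKNOWN_HERD__", gt$herd)
  blocks <- unique(herd_f)
  for (b in blocks) {
    writeLines("POP", con)
    for (i in which(herd_f == b)) {
      g <- paste0(fmt(gt$a1[i, ]), fmt(gt$a2[i, ]))
      writeLines(paste0(gt$individuals[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  if (!is.null(herd_map)) write_herd_map(gt, herd_map)
  invisible(path)
}

#' Read or write an animal-to-herd map
#'
#' Delimited table with columns `animal`, `herd`, optional `breed`. An empty
#' herd field means the birth herd is unknown.
#'
#' @param path file path.
#' @return A data.frame with columns `animal`, `herd` and possibly `breed`.
#' @export
read_herd_map <- function(path) {
  df <- read_delim_auto(path)
  need_col(df, "animal", path); need_col(df, "herd", path)
  df$animal <- as.character(df$animal)
  df$herd <- as.character(df$herd)
  df$herd[!nzchar(df$herd) | is.na(df$herd)] <- NA_character_
  if (anyDuplicated(df$animal)) stop("duplicate animal rows in herd map ", path)
  if (!is.null(df$breed)) df$breed <- as.character(df$breed)
  df
}

#' @param gt a [genotype_table()] (for the writer).
#' @rdname read_herd_map
#' @export
write_herd_map <- function(gt, path) {
  df <- data.frame(animal = gt$individuals,
                   herd = ifelse(is.na(gt$herd), "", gt$herd),
                   breed = gt$breed, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the tabular genotype dialect
#'
#' One row per animal: columns `animal`, `herd`, `breed`, then one column per
#' locus holding `a1/a2` (positive integer allele codes) or an empty field for
#' a missing call.
#'
#' @param path file path.
#' @return [read_genotypes_table()]: a [genotype_table()].
#' @export
read_genotypes_table <- function(path) {
  df <- read_delim_auto(path)
  for (cn in c("animal", "herd", "breed")) need_col(df, cn, path)
  loci <- setdiff(names(df), c("animal", "herd", "breed"))
  if (!length(loci)) stop("no locus columns in ", path)
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    v <- as.character(df[[loci[j]]])
    ok <- !is.na(v) & nzchar(v)
    parts <- strsplit(v[ok], "/", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed call (expect a1/a2) in column ", loci[j])
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1L))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  herd <- as.character(df$herd)
  herd[!nzchar(herd) | is.na(herd)] <- NA_character_
  genotype_table(a1, a2, as.character(df$animal), loci,
                 setNames(herd, df$animal),
                 setNames(as.character(df$breed), df$animal))
}

#' @param gt a [genotype_table()] (for the writer).
#' @rdname read_genotypes_table
#' @export
write_genotypes_table <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- matrix("", length(gt$individuals), length(gt$loci))
  ok <- !is.na(gt$a1)
  calls[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  df <- data.frame(animal = gt$individuals,
                   herd = ifelse(is.na(gt$herd), "", gt$herd),
                   breed = gt$breed, stringsAsFactors = FALSE)
  df[gt$loci] <- as.data.frame(calls, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an animal-exchange table
#'
#' Delimited text with source and destination herd columns (`source`/`dest`,
#' `source_herd`/`dest_herd` or `from`/`to`). Each row records that one or
#' more animals moved between two herds. Self-loops are rejected. Herds that
#' appear only here and were never genotyped are retained: exchange networks
#' legitimately include non-sampled herds. Duplicate records between a pair
#' are kept here and collapse to one undirected edge in [build_graph()].
#'
#' @param path file path.
#' @return A data.frame of class `exchange_records` with columns
#'   `source`, `dest`, `direction_known`.
#' @export
read_exchange_table <- function(path) {
  df <- read_delim_auto(path)
  nm <- names(df)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (!length(hit)) stop("no ", cands[1L], " column in ", path,
                           " (saw: ", paste(nm, collapse = ", "), ")")
    hit[1L]
  }
  src <- as.character(df[[pick(c("source", "source_herd", "from"))]])
  dst <- as.character(df[[pick(c("dest", "dest_herd", "to"))]])
  if (any(src == dst))
    stop("self-loop exchange record(s): ",
         paste(unique(src[src == dst]), collapse = ", "))
  dk <- if ("direction_known" %in% nm) as.logical(df$direction_known)
        else rep(TRUE, nrow(df))
  exchange_records(src, dst, dk)
}

#' Construct exchange records in code
#'
#' @param source,dest character vectors of herd ids (source != dest rowwise).
#' @param direction_known logical vector; `FALSE` when the interview only
#'   established that an exchange occurred, not its direction.
#' @return A data.frame of class `exchange_records`.
#' @export
exchange_records <- function(source, dest, direction_known = TRUE) {
  source <- as.character(source); dest <- as.character(dest)
  if (length(source) != length(dest)) stop("source/dest length mismatch")
  if (any(source == dest)) stop("self-loop exchange record")
  df <- data.frame(source = source, dest = dest,
                   direction_known = rep_len(as.logical(direction_known),
                                             length(source)),
                   stringsAsFactors = FALSE)
  class(df) <- c("exchange_records", "data.frame")
  df
}

#' Read a pedigree table
#'
#' Delimited text with columns `animal`, `sire`, `dam`; an empty parent field
#' codes an unknown parent. Duplicate animal rows are an error, as is any
#' animal that is its own ancestor within depth 2 (the depth the donor
#' characterization uses).
#'
#' @param path file path.
#' @return A data.frame of class `pedigree_records`.
#' @export
read_pedigree_table <- function(path) {
  df <- read_delim_auto(path)
  for (cn in c("animal", "sire", "dam")) need_col(df, cn, path)
  pedigree_records(as.character(df$animal),
                   as.character(df$sire), as.character(df$dam))
}

#' Construct pedigree records in code
#'
#' @param animal,sire,dam character vectors; `NA` or `""` = unknown parent.
#' @return A data.frame of class `pedigree_records`.
#' @export
pedigree_records <- function(animal, sire, dam) {
  blank_na <- function(x) { x <- as.character(x); x[is.na(x) | !nzchar(x)] <- NA; x }
  animal <- as.character(animal)
  if (anyDuplicated(animal))
    stop("duplicate animal rows in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  df <- data.frame(animal = animal, sire = blank_na(sire), dam = blank_na(dam),
                   stringsAsFactors = FALSE)
  # no animal its own ancestor to depth 2
  for (i in seq_len(nrow(df))) {
    anc <- ancestors_depth2(df, df$animal[i])
    if (df$animal[i] %in% anc)
      stop("pedigree cycle within depth 2 at animal ", df$animal[i])
  }
  class(df) <- c("pedigree_records", "data.frame")
  df
}

# parents and grandparents of `animal` according to `ped`
ancestors_depth2 <- function(ped, animal) {
  row <- ped[ped$animal == animal, , drop = FALSE]
  if (!nrow(row)) return(character(0))
  par <- c(row$sire, row$dam)
  par <- par[!is.na(par)]
  gp <- unlist(lapply(par, function(p) {
    r <- ped[ped$animal == p, , drop = FALSE]
    if (nrow(r)) c(r$sire, r$dam) else character(0)
  }))
  unique(c(par, gp[!is.na(gp)]))
}

#' Cross-validate a genotype table against an exchange table
#'
#' Report-only consistency summary: genotyped animals per herd, herds below
#' the five-animal analysis threshold, herds present only in the exchange
#' records (network-only herds), per-locus missingness, and the undirected
#' edge count. Inputs are never modified.
#'
#' @param gt a [genotype_table()].
#' @param ex an [exchange_records()] data.frame (may have zero rows).
#' @param min_animals herd-size threshold used by the downstream analyses.
#' @return A list of class `validation_report`.
#' @export
validate_dataset <- function(gt, ex, min_animals = 5L) {
  stopifnot(inherits(gt, "genotype_table"))
  hs <- herd_sizes(gt)
  geno_herds <- names(hs)
  ex_herds <- unique(c(ex$source, ex$dest))
  und <- unique_undirected_pairs(ex)
  rep <- list(
    herd_counts = hs,
    below_threshold = names(hs)[hs < min_animals],
    network_only_herds = setdiff(ex_herds, geno_herds),
    genotype_only_herds = setdiff(geno_herds, ex_herds),
    unknown_birth_herd = sum(is.na(gt$herd)),
    locus_missingness = colMeans(is.na(gt$a1)),
    n_exchange_records = nrow(ex),
    n_undirected_edges = nrow(und),
    min_animals = min_animals)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("herds genotyped: %d (%d below %d-animal analysis threshold)\n",
              length(x$herd_counts), length(x$below_threshold), x$min_animals))
  if (length(x$below_threshold))
    cat("  below threshold:", paste(x$below_threshold, collapse = ", "), "\n")
  cat(sprintf("network-only herds: %d\n", length(x$network_only_herds)))
  cat(sprintf("exchange records: %d (%d undirected edges)\n",
              x$n_exchange_records, x$n_undirected_edges))
  if (x$n_undirected_edges == 0L) cat("  note: zero edges\n")
  cat(sprintf("animals with unknown birth herd: %d\n", x$unknown_birth_herd))
  invisible(x)
}

# unique unordered herd pairs from exchange records
unique_undirected_pairs <- function(ex) {
  if (!nrow(ex)) return(data.frame(a = character(0), b = character(0)))
  a <- pmin(ex$source, ex$dest); b <- pmax(ex$source, ex$dest)
  unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}

# delimiter-sniffing reader for TSV/CSV with a header row
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", na.strings = NULL, quote = "\"",
             comment.char = "")
}

need_col <- function(df, col, path) {
  if (!col %in% names(df))
    stop("missing column '", col, "' in ", path,
         " (saw: ", paste(names(df), collapse = ", "), ")")
  invisible(TRUE)
}
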