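#' Haplotype variable-site table
#'
#' Compact representation of an alignment: the strictly increasing 1-based
#' positions of the variable sites, a reference state row, the per-haplotype
#' states at those sites, and per-population haplotype counts. This is the
#' in-memory form of a printed "variable sites of haplotypes" table.
#'
#' @param positions Strictly increasing integer vector of 1-based site
#'   positions (nt).
#' @param ref_states Character vector of reference states, one per position.
#' @param states Character matrix, haplotypes x positions; rownames are
#'   haplotype names.
#' @param counts Integer matrix, haplotypes x populations, of sampled copies.
#' @param region_of Optional named character vector, population -> region.
#' @return An object of class `haplotype_table`.
#' @export
haplotype_table <- function(positions, ref_states, states, counts,
                            region_of = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be strictly increasing")
  if (length(ref_states) != length(positions)) stop("ref_states/positions length mismatch")
  states <- as.matrix(states)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (ncol(states) != length(positions)) stop("states/positions mismatch")
  if (nrow(states) != nrow(counts)) stop("states/counts row mismatch")
  if (is.null(rownames(states)))
    rownames(states) <- paste0("Hap_", seq_len(nrow(states)))
  rownames(counts) <- rownames(states)
  if (anyDuplicated(apply(states, 1L, paste, collapse = "")))
    stop("two haplotypes share an identical state vector")
  if (any(counts < 0L)) stop("negative haplotype count")
  invariant <- vapply(seq_along(positions), function(j) {
    s <- unique(c(states[, j], ref_states[j]))
    length(s[!s %in% MISSING_STATES]) < 2L
  }, logical(1))
  if (any(invariant))
    stop("position(s) not variable: ", paste(positions[invariant], collapse = ", "))
  structure(list(positions = positions, ref_states = as.character(ref_states),
                 states = states, counts = counts, region_of = region_of),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$states), "haplotypes,",
      length(x$positions), "variable sites, n =", sum(x$counts),
      "over", ncol(x$counts), "population(s)\n")
  invisible(x)
}

#' Collapse an alignment to its haplotype table
#'
#' Identical sequences are collapsed to one haplotype; the variable columns
#' become the table's positions, and the first haplotype encountered (input
#' order) supplies the reference state row. Haplotypes are named `Hap_k` in
#' order of first appearance.
#'
#' @param a A [seq_alignment].
#' @return A [haplotype_table] whose counts preserve the per-population
#'   sample sizes of `a`.
#' @export
collapse_haplotypes <- function(a) {
  key <- a$seqs
  ord <- !duplicated(key)
  haps <- key[ord]
  idx <- match(key, haps)
  pops <- unique(a$pop)
  counts <- matrix(0L, nrow = length(haps), ncol = length(pops),
                   dimnames = list(paste0("Hap_", seq_along(haps)), pops))
  for (i in seq_along(idx))
    counts[idx[i], a$pop[i]] <- counts[idx[i], a$pop[i]] + 1L
  pos <- variable_sites(a)
  hm <- do.call(rbind, strsplit(haps, ""))
  states <- hm[, pos, drop = FALSE]
  rownames(states) <- rownames(counts)
  colnames(states) <- pos
  if (length(pos) == 0L) {     # monomorphic alignment: single haplotype
    return(structure(list(positions = integer(0), ref_states = character(0),
                          states = states, counts = counts,
                          region_of = a$region_of),
                     class = "haplotype_table"))
  }
  haplotype_table(pos, states[1L, ], states, counts, a$region_of)
}

#' Expand a haplotype table back into a full alignment
#'
#' Inverse of [collapse_haplotypes()]: emits `count` copies of each haplotype
#' per population, filling the invariant columns with a fixed state, so the
#' published variable-site table can drive every downstream analysis.
#' Collapsing the result recovers the table (positions, states, counts) up to
#' the choice of reference row.
#'
#' @param t A [haplotype_table].
#' @param total_length Alignment length in nt; must be at least
#'   `max(positions)`.
#' @param fill Single state used for all invariant columns (default `"A"`).
#' @return A [seq_alignment] of `sum(t$counts)` sequences.
#' @export
expand_table <- function(t, total_length, fill = "A") {
  if (length(t$positions) && max(t$positions) > total_length)
    stop("total_length smaller than the largest variable position")
  if (anyNA(t$counts)) stop("counts missing for a population")
  base <- rep(fill, total_length)
  hap_seq <- apply(t$states, 1L, function(s) {
    v <- base; v[t$positions] <- s; paste(v, collapse = "")
  })
  ids <- character(0); seqs <- character(0); pop <- character(0)
  for (p in colnames(t$counts)) {
    for (h in rownames(t$counts)) {
      k <- t$counts[h, p]
      if (k > 0L) {
        ids <- c(ids, paste(h, p, seq_len(k), sep = "_"))
        seqs <- c(seqs, rep(hap_seq[h], k))
        pop <- c(pop, rep(p, k))
      }
    }
  }
  names(seqs) <- ids
  seq_alignment(seqs, pop, t$region_of)
}

#' Rebuild a sequence multiset from published haplotype frequencies
#'
#' Studies often print haplotype frequencies rather than deposit every
#' sequence; multiplying each frequency by the reported sample size and
#' rounding recovers the original multiset. Rounded counts that do not sum to
#' `total_n` are reconciled by largest-remainder adjustment with first-listed
#' precedence (the earliest-listed haplotype keeps its copy on ties).
#'
#' @param recs Data frame with columns `haplotype` and `frequency` (fractions
#'   in `[0,1]`), optionally `population`.
#' @param seqs Named character vector supplying the sequence of every
#'   haplotype named in `recs`.
#' @param total_n Total reported sample size.
#' @return A [seq_alignment] with an attribute `counts` (the realised
#'   per-haplotype copy numbers).
#' @examples
#' regenerate_from_frequencies(
#'   data.frame(haplotype = "H1", frequency = 0.8),
#'   c(H1 = "ACGT"), total_n = 291)  # 233 copies, as 0.8 * 291 rounds to
#' @export
regenerate_from_frequencies <- function(recs, seqs, total_n) {
  f <- recs$frequency
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  if (abs(sum(f) - 1) > 0.01)
    stop("frequencies sum to ", format(sum(f)), ", more than 1% from 1")
  if (!all(recs$haplotype %in% names(seqs)))
    stop("sequence missing for haplotype(s): ",
         paste(setdiff(recs$haplotype, names(seqs)), collapse = ", "))
  exact <- f * total_n
  counts <- round(exact)
  deficit <- total_n - sum(counts)
  if (deficit != 0L) {
    resid <- exact - counts
    if (deficit > 0) {       # add to the most under-counted, earliest first
      ord <- order(-resid, seq_along(resid))
      counts[ord[seq_len(deficit)]] <- counts[ord[seq_len(deficit)]] + 1
    } else {                 # remove from the most over-counted, latest first
      ord <- order(resid, -seq_along(resid))
      counts[ord[seq_len(-deficit)]] <- counts[ord[seq_len(-deficit)]] - 1
    }
    message("largest-remainder adjustment applied to ", abs(deficit), " count(s)")
  }
  if (any(counts < 0)) stop("adjustment produced a negative count")
  pop <- if ("population" %in% names(recs)) recs$population else
    rep("pooled", nrow(recs))
  keep <- counts > 0
  ids <- unlist(lapply(which(keep), function(i)
    paste(recs$haplotype[i], seq_len(counts[i]), sep = "_")))
  out <- stats::setNames(
    rep(unname(seqs[recs$haplotype[keep]]), counts[keep]), ids)
  a <- seq_alignment(out, rep(pop[keep], counts[keep]))
  attr(a, "counts") <- stats::setNames(as.integer(counts), recs$haplotype)
  a
}

#' Find fixed-difference (diagnostic) sites for a group of populations
#'
#' A site is diagnostic for a focal group when every sampled sequence of the
#' group carries one and the same non-missing state and no sequence outside
#' the group carries that state. These are the "categorical" differences that
#' separate, e.g., the Northern from the Southern Hemisphere samples.
#'
#' @param t A [haplotype_table].
#' @param focal Character vector of population names forming the focal group.
#' @param other Populations forming the comparison group; defaults to all
#'   remaining populations with sampled sequences.
#' @return Data frame with columns `position` (1-based site) and `state`
#'   (the state fixed in the focal group).
#' @export
find_diagnostic_sites <- function(t, focal, other = NULL) {
  pops <- colnames(t$counts)
  if (!all(focal %in% pops)) stop("unknown focal population(s)")
  if (is.null(other)) other <- setdiff(pops, focal)
  fw <- rowSums(t$counts[, focal, drop = FALSE])
  ow <- rowSums(t$counts[, other, drop = FALSE])
  if (sum(fw) == 0L) stop("focal group has no sampled sequences")
  if (sum(ow) == 0L) stop("comparison group has no sampled sequences")
  hit <- logical(length(t$positions)); st <- character(length(t$positions))
  for (j in seq_along(t$positions)) {
    sf <- unique(t$states[fw > 0L, j]); sf <- sf[!sf %in% MISSING_STATES]
    so <- unique(t$states[ow > 0L, j]); so <- so[!so %in% MISSING_STATES]
    if (length(sf) == 0L)
      stop("only missing data in the focal group at position ", t$positions[j])
    if (length(sf) == 1L && !(sf %in% so)) { hit[j] <- TRUE; st[j] <- sf }
  }
  data.frame(position = t$positions[hit], state = st[hit])
}

#' Write a haplotype table in dot-notation report form
#'
#' One row per haplotype with `.` for states matching the reference row, plus
#' `haplotype`, `population`, `region` and `count` columns; the header row
#' carries the 1-based site positions. Populations with positive counts for a
#' haplotype each get a row. The format round-trips through
#' [read_haplotype_table()].
#'
#' @param t A [haplotype_table].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_haplotype_report <- function(t, path) {
  dots <- t$states
  for (j in seq_len(ncol(dots)))
    dots[dots[, j] == t$ref_states[j], j] <- "."
  lines <- c(paste(c("haplotype", "population", "region", "count",
                     t$positions), collapse = "\t"),
             paste(c("reference", ".", ".", "0", t$ref_states),
                   collapse = "\t"))
  for (h in rownames(t$counts)) for (p in colnames(t$counts)) {
    if (t$counts[h, p] > 0L) {
      reg <- if (is.null(t$region_of)) "." else unname(t$region_of[p])
      lines <- c(lines, paste(c(h, p, reg, t$counts[h, p], dots[h, ]),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a dot-notation haplotype table
#'
#' Parses the TSV format written by [write_haplotype_report()] (and shipped
#' as the packaged COI reference table): a header of 1-based positions, a
#' reference state row, then per-haplotype rows with `.` for identity.
#'
#' @param path TSV path.
#' @return A [haplotype_table].
#' @export
read_haplotype_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  meta <- c("haplotype", "population", "region", "count")
  if (!all(meta %in% names(raw)[1:4])) stop("not a haplotype report: ", path)
  positions <- as.integer(names(raw)[-(1:4)])
  ri <- which(raw$haplotype == "reference")
  if (length(ri) != 1L) stop("expected exactly one reference row")
  ref <- as.character(raw[ri, -(1:4)])
  body <- raw[-ri, , drop = FALSE]
  haps <- unique(body$haplotype)
  pops <- unique(body$population)
  states <- matrix(NA_character_, length(haps), length(positions),
                   dimnames = list(haps, positions))
  counts <- matrix(0L, length(haps), length(pops), dimnames = list(haps, pops))
  for (i in seq_len(nrow(body))) {
    s <- as.character(body[i, -(1:4)])
    s[s == "."] <- ref[s == "."]
    states[body$haplotype[i], ] <- s
    counts[body$haplotype[i], body$population[i]] <-
      counts[body$haplotype[i], body$population[i]] + as.integer(body$count[i])
  }
  region_of <- NULL
  if (any(body$region != ".")) {
    u <- !duplicated(body$population)
    region_of <- stats::setNames(body$region[u], body$population[u])
  }
  haplotype_table(positions, ref, states, counts, region_of)
}

#' The packaged yellowtail kingfish COI haplotype table
#'
#' The published variable-site table for the 604 nt COI fragment of 244
#' Pacific *Seriola lalandi*: 15 haplotypes scored at 28 polymorphic
#' positions, with region-level sample counts (NW Pacific n = 15, NE Pacific
#' n = 102, South Pacific n = 127; haplotype frequencies were converted to
#' counts against n = 244). Per-country compositions inside the NE and South
#' Pacific regions were not published, so the table resolves populations at
#' region level only; the NW Pacific region is a single population (Japan).
#'
#' @return A [haplotype_table].
#' @examples
#' t <- coi_haplotype_table()
#' nrow(t$states)            # 15 haplotypes
#' length(t$positions)       # 28 variable sites
#' @export
coi_haplotype_table <- function() {
  read_haplotype_table(system.file("extdata", "coi_haplotypes.tsv",
                                   package = "seriolapop", mustWork = TRUE))
}
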