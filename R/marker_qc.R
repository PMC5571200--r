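#' SNP / dominant marker matrix with tag metadata
#'
#' Holds reduced-representation genotyping calls: either dominant
#' presence/absence scores in `{0, 1}` (silicoDArT-style) or biallelic SNP
#' genotypes in `{0, 1, 2}`, with `NA` for missing. Each marker belongs to a
#' sequence-tag locus of fixed length; several markers can share a locus
#' (which downstream QC removes).
#'
#' @param calls Integer matrix, samples x markers; dimnames give sample and
#'   marker ids.
#' @param pop Character vector of population labels, one per sample.
#' @param locus_of Character vector mapping each marker to its tag locus id;
#'   defaults to one locus per marker.
#' @param tag_length Tag length in nt (default 70).
#' @param type `"dominant"` for presence/absence, `"snp"` for 0/1/2
#'   genotypes.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, pop, locus_of = NULL, tag_length = 70,
                          type = c("dominant", "snp")) {
  type <- match.arg(type)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  hi <- if (type == "dominant") 1L else 2L
  if (any(calls < 0L | calls > hi, na.rm = TRUE))
    stop("calls outside {0..", hi, ", NA} for type '", type, "'")
  if (length(pop) != nrow(calls)) stop("one population label per sample needed")
  if (is.null(locus_of)) locus_of <- colnames(calls)
  if (length(locus_of) != ncol(calls)) stop("locus_of must cover every marker")
  names(locus_of) <- colnames(calls)
  structure(list(calls = calls, pop = as.character(pop),
                 locus_of = locus_of, tag_length = tag_length, type = type),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix (", x$type, "): ", nrow(x$calls), " samples x ",
      ncol(x$calls), " markers; tag ", x$tag_length, " nt; ",
      length(unique(x$pop)), " population(s)\n", sep = "")
  invisible(x)
}

subset_markers <- function(m, keep) {
  m$calls <- m$calls[, keep, drop = FALSE]
  m$locus_of <- m$locus_of[keep]
  m
}

#' Drop markers with excessive missingness in any population
#'
#' Removes every marker whose missing-call fraction exceeds `max_frac` in at
#' least one population (the per-population rule guards against population-
#' specific dropout). The threshold is inclusive: exactly `max_frac` is kept.
#'
#' @param m A [marker_matrix].
#' @param max_frac Maximum tolerated per-population missing fraction
#'   (default 0.05).
#' @return The filtered [marker_matrix]; dropped marker ids are recorded in
#'   attribute `dropped`.
#' @export
filter_loci_by_missingness <- function(m, max_frac = 0.05) {
  worst <- apply(m$calls, 2L, function(col)
    max(tapply(is.na(col), m$pop, mean)))
  keep <- worst <= max_frac
  out <- subset_markers(m, keep)
  attr(out, "dropped") <- colnames(m$calls)[!keep]
  out
}

#' Drop all markers on multi-marker loci
#'
#' Tags carrying more than one called SNP violate the single-SNP-per-tag
#' assumption behind the homology statistic and HWE-style treatment, so
#' every marker sharing a locus with another marker is removed.
#'
#' @param m A [marker_matrix].
#' @return The filtered [marker_matrix] (attribute `dropped` lists removals).
#' @export
filter_multisnp_loci <- function(m) {
  tab <- table(m$locus_of)
  keep <- tab[m$locus_of] == 1L
  out <- subset_markers(m, keep)
  attr(out, "dropped") <- colnames(m$calls)[!keep]
  out
}

#' Drop samples with too many missing marker calls
#'
#' Removes samples missing calls at strictly more than `max_missing` markers
#' ("more than" is strict: a sample missing exactly `max_missing` is kept).
#'
#' @param m A [marker_matrix].
#' @param max_missing Maximum tolerated missing-call count (default 100).
#' @return The filtered [marker_matrix] (attribute `dropped` lists removed
#'   sample ids). Emptying a population entirely is an error.
#' @export
filter_samples_by_missingness <- function(m, max_missing = 100) {
  nm <- rowSums(is.na(m$calls))
  keep <- nm <= max_missing
  gone <- setdiff(unique(m$pop), unique(m$pop[keep]))
  if (length(gone))
    stop("sample filter would empty population(s): ", paste(gone, collapse = ", "))
  out <- m
  out$calls <- m$calls[keep, , drop = FALSE]
  out$pop <- m$pop[keep]
  attr(out, "dropped") <- rownames(m$calls)[!keep]
  out
}

#' Full marker QC chain
#'
#' Applies the three filters in order: per-population marker missingness,
#' multi-SNP loci, then sample missingness. Each filter is idempotent and the
#' chain is a fixed point (re-running it removes nothing further).
#'
#' @param m A [marker_matrix].
#' @param max_marker_missing Per-population marker missingness threshold.
#' @param max_sample_missing Per-sample missing-call threshold.
#' @return The filtered [marker_matrix] with attribute `qc_log`, a list of
#'   the ids dropped by each rule.
#' @export
qc_markers <- function(m, max_marker_missing = 0.05, max_sample_missing = 100) {
  s1 <- filter_loci_by_missingness(m, max_marker_missing)
  s2 <- filter_multisnp_loci(s1)
  s3 <- filter_samples_by_missingness(s2, max_sample_missing)
  attr(s3, "qc_log") <- list(loci_missingness = attr(s1, "dropped"),
                             multisnp_loci = attr(s2, "dropped"),
                             samples = attr(s3, "dropped"))
  s3
}

#' Population-unique (diagnostic) markers
#'
#' A marker is unique to a focal population (or set of populations) when it
#' is present in at least `min_focal` of the focal individuals (pooled) and
#' in at most `max_other` of the individuals of every other population,
#' checked population by population. The per-population form of the 5% rule
#' is the one under which very small reference samples (e.g. a two-fish
#' population) still veto markers that are in fact shared: pooling would let
#' a fixed marker of a small population slip under the 5% slack of a large
#' pooled remainder. Presence means a call of at least 1; fractions are
#' computed over non-missing calls, and a marker with only missing calls in
#' the focal group is ineligible (an other population with only missing
#' calls cannot veto). The `"absence"` polarity applies the same rule to
#' inverted calls, so markers diagnostic by their absence are also found;
#' `"both"` returns the union.
#'
#' @param m A [marker_matrix] (run [qc_markers()] first).
#' @param focal Population name(s) forming the focal group.
#' @param min_focal Minimum focal presence fraction (inclusive, default
#'   0.95).
#' @param max_other Maximum non-focal presence fraction (inclusive, default
#'   0.05).
#' @param polarity `"presence"`, `"absence"`, or `"both"`.
#' @return Character vector of marker ids.
#' @export
unique_markers <- function(m, focal, min_focal = 0.95, max_other = 0.05,
                           polarity = c("presence", "absence", "both")) {
  polarity <- match.arg(polarity)
  if (!all(focal %in% m$pop)) stop("unknown focal population(s)")
  if (polarity == "both") {
    return(union(unique_markers(m, focal, min_focal, max_other, "presence"),
                 unique_markers(m, focal, min_focal, max_other, "absence")))
  }
  pres <- m$calls >= 1L
  if (polarity == "absence") pres <- !pres
  f <- m$pop %in% focal
  frac <- function(rows) colMeans(pres[rows, , drop = FALSE], na.rm = TRUE)
  ff <- frac(f)
  hit <- !is.nan(ff) & ff >= min_focal
  for (p in setdiff(unique(m$pop), focal)) {
    of <- frac(m$pop == p)
    hit <- hit & (is.nan(of) | of <= max_other)
  }
  colnames(m$calls)[hit]
}

#' Read a marker matrix from CSV plus a metadata sidecar
#'
#' The CSV has samples as rows (`id`, `population`, then one column per
#' marker with values 0/1(/2) or `NA`); the optional TSV sidecar has columns
#' `marker`, `locus`, `tag_length`.
#'
#' @param path Marker CSV path.
#' @param meta Optional metadata TSV path.
#' @param type Marker type, `"dominant"` or `"snp"`.
#' @return A [marker_matrix].
#' @export
read_markers <- function(path, meta = NULL, type = c("dominant", "snp")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "population") %in% names(d)))
    stop("marker table needs 'id' and 'population' columns")
  calls <- as.matrix(d[, setdiff(names(d), c("id", "population")), drop = FALSE])
  rownames(calls) <- d$id
  locus_of <- NULL; tl <- 70
  if (!is.null(meta)) {
    md <- utils::read.delim(meta, stringsAsFactors = FALSE)
    locus_of <- stats::setNames(md$locus, md$marker)[colnames(calls)]
    if ("tag_length" %in% names(md)) tl <- md$tag_length[1]
  }
  marker_matrix(calls, d$population, locus_of, tl, match.arg(type))
}

#' Write a marker matrix as CSV plus a metadata sidecar
#'
#' @param m A [marker_matrix].
#' @param path Marker CSV path.
#' @param meta Optional metadata TSV path.
#' @return Invisibly, `path`.
#' @export
write_markers <- function(m, path, meta = NULL) {
  utils::write.csv(data.frame(id = rownames(m$calls), population = m$pop,
                              m$calls, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta))
    utils::write.table(data.frame(marker = colnames(m$calls),
                                  locus = unname(m$locus_of),
                                  tag_length = m$tag_length),
                       meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
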