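#' Pairwise sequence divergence (p-distance)
#'
#' One minus sequence identity: the fraction of differing sites among the
#' positions where both sequences carry a non-missing state.
#'
#' @param a,b Equal-length sequences (strings or character vectors).
#' @return Fraction in `[0, 1]`.
#' @examples
#' p_divergence(strrep("A", 604), paste0(strrep("A", 603), "G"))  # 1/604
#' @export
p_divergence <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- !(a %in% MISSING_STATES) & !(b %in% MISSING_STATES)
  if (!any(ok)) stop("no comparable sites")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Average pairwise divergence within and between population groups
#'
#' Count-weighted mean p-distance over all cross-group sequence pairs for
#' each pair of groups, and over all within-group pairs on the diagonal —
#' the matrix behind a "percent sequence divergence between populations"
#' table.
#'
#' @param t A [haplotype_table].
#' @param length Alignment length in nt.
#' @param groups Named list mapping group name to a character vector of
#'   population names; defaults to one group per population.
#' @return An object of class `divergence_matrix`: a symmetric matrix of
#'   divergences in percent (diagonal = within-group mean over `C(n,2)`
#'   pairs, `NA` for single-sequence groups).
#' @export
population_divergence <- function(t, length, groups = NULL) {
  if (length <= 0) stop("a positive alignment length is required")
  if (is.null(groups)) {
    groups <- as.list(colnames(t$counts))
    names(groups) <- colnames(t$counts)
  }
  d <- hap_dist(t$states) / length
  cnt <- lapply(groups, function(pp) {
    if (!all(pp %in% colnames(t$counts))) stop("unknown population in group")
    rowSums(t$counts[, pp, drop = FALSE])
  })
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in i:k) {
    ci <- cnt[[i]]; cj <- cnt[[j]]
    ni <- sum(ci); nj <- sum(cj)
    if (ni == 0L || nj == 0L) stop("empty group: ", names(groups)[if (ni == 0) i else j])
    if (i == j) {
      if (ni < 2L) next                      # within-group mean needs >= 2 seqs
      tot <- as.numeric(ci %*% d %*% ci) / 2
      out[i, i] <- tot / (ni * (ni - 1) / 2)
    } else {
      out[i, j] <- out[j, i] <- as.numeric(ci %*% d %*% cj) / (ni * nj)
    }
  }
  structure(out * 100, class = c("divergence_matrix", "matrix"))
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("Pairwise divergence (%):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' SNP-tag sequence homology
#'
#' For genotyping-by-sequencing markers that carry a single SNP on a
#' fixed-length consensus tag, the sequence homology across a set of
#' compared allele pairs is `H_s = 1 - sum(s_v) / (2 n l)`: one minus the
#' total number of varying SNPs over both alleles, divided by the number of
#' aligned allele pairs (`2n`, two per marker comparison) times the tag
#' length.
#'
#' @param s_v Total count of varying SNPs across the compared allele pairs.
#' @param n Number of single-SNP marker comparisons (each contributes two
#'   aligned allele pairs).
#' @param l Tag length in nt (default 70).
#' @return Homology `H_s` in `[0, 1]`; dissimilarity is `1 - H_s`.
#' @examples
#' eq1_homology(1, n = 1)          # 1 - 1/140
#' eq1_homology(14, n = 2)         # 0.95
#' @export
eq1_homology <- function(s_v, n, l = 70) {
  if (n < 1 || l <= 0) stop("need n >= 1 and l > 0")
  if (s_v < 0 || s_v > 2 * n * l) stop("corrupt input: s_v outside [0, 2nl]")
  1 - s_v / (2 * n * l)
}

#' Population-level SNP-tag dissimilarity matrix
#'
#' For every unordered pair of samples, counts the varying SNPs across both
#' alleles of the co-called single-SNP markers (`|g_i - g_j|` per marker for
#' genotypes coded 0/1/2: opposite homozygotes contribute 2, heterozygote vs
#' homozygote 1), converts to a tag-homology dissimilarity
#' `s_v / (2 n' l)` with `n'` the co-called marker count, and averages the
#' pairwise dissimilarities within and between populations.
#'
#' @param m A [marker_matrix] with `type = "snp"` and a known `tag_length`.
#' @return An object of class `divergence_matrix`: dissimilarity in percent,
#'   diagonal = within-population mean (NA for single-sample populations).
#'   Sample pairs with no co-called markers are excluded with a warning.
#' @export
population_homology <- function(m) {
  if (!identical(m$type, "snp"))
    stop("population_homology needs biallelic SNP genotypes (type = 'snp')")
  l <- m$tag_length
  calls <- m$calls
  n <- nrow(calls)
  pops <- unique(m$pop)
  acc <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  cntp <- acc
  dropped <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    if (!any(ok)) { dropped <- dropped + 1L; next }
    diss <- sum(abs(calls[i, ok] - calls[j, ok])) / (2 * sum(ok) * l)
    pi_ <- m$pop[i]; pj <- m$pop[j]
    acc[pi_, pj] <- acc[pi_, pj] + diss
    cntp[pi_, pj] <- cntp[pi_, pj] + 1L
    if (pi_ != pj) { acc[pj, pi_] <- acc[pi_, pj]; cntp[pj, pi_] <- cntp[pi_, pj] }
  }
  if (dropped > 0L)
    warning(dropped, " sample pair(s) with no co-called markers excluded")
  out <- 100 * acc / cntp
  out[cntp == 0L] <- NA_real_
  structure(out, class = c("divergence_matrix", "matrix"))
}

#' Molecular-clock divergence dating
#'
#' Converts a percent sequence divergence into a divergence time using a
#' constant-rate calibration, by default the conventional mtDNA clock of 2%
#' divergence per million years.
#'
#' @param divergence_percent Pairwise divergence in percent (e.g. 2.43 for
#'   2.43%).
#' @param rate Calibration in percent divergence per million years
#'   (default 2).
#' @return Divergence time in millions of years (MYA).
#' @examples
#' clock_date(2.43)   # ~1.2 MYA
#' @export
clock_date <- function(divergence_percent, rate = 2.0) {
  if (any(divergence_percent < 0)) stop("negative divergence")
  if (rate <= 0) stop("rate must be positive")
  divergence_percent / rate
}

#' Mitochondrial vs nuclear substitution-rate ratio
#'
#' @param mt_divergence,nuc_divergence Divergences on a common scale (e.g.
#'   percent) for the same population pair.
#' @return The ratio `mt / nuc`.
#' @examples
#' rate_ratio(2.42, 0.58)  # ~4.2
#' @export
rate_ratio <- function(mt_divergence, nuc_divergence) {
  if (any(nuc_divergence <= 0)) stop("nuclear divergence must be positive")
  mt_divergence / nuc_divergence
}

#' Write a divergence matrix as a square TSV in percent
#'
#' @param dm A `divergence_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_divergence <- function(dm, path) {
  utils::write.table(cbind(population = rownames(dm), round(unclass(dm), 4)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
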