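#' Unbiased haplotype (gene) diversity with its standard deviation
#'
#' Nei's unbiased estimator `h = n (1 - sum p_i^2) / (n - 1)`, the probability
#' that two sequences drawn without replacement carry different haplotypes,
#' with the standard deviation from Nei's sampling-variance formula.
#'
#' @param counts Non-negative integer vector of per-haplotype sample counts;
#'   total sample size must be at least 2.
#' @return Named numeric vector `c(h =, h_sd =)`.
#' @examples
#' haplotype_diversity(c(12, 3))   # h = 0.343 for the NW Pacific sample
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, h_sd = sqrt(max(v, 0)))
}

# pairwise non-missing differences between two state vectors
pair_diff <- function(x, y) {
  ok <- !(x %in% MISSING_STATES) & !(y %in% MISSING_STATES)
  sum(x[ok] != y[ok])
}

# haplotype x haplotype difference matrix over the variable positions
hap_dist <- function(states) {
  H <- nrow(states)
  d <- matrix(0, H, H, dimnames = list(rownames(states), rownames(states)))
  if (H >= 2L) for (i in 1:(H - 1L)) for (j in (i + 1L):H)
    d[i, j] <- d[j, i] <- pair_diff(states[i, ], states[j, ])
  d
}

#' Nucleotide diversity and mean pairwise differences
#'
#' `k` is the average number of nucleotide differences over all `C(n,2)`
#' sequence pairs (haplotype counts weight the pairs) and `pi = k / length`
#' is its per-site version, following the classical DnaSP-style definitions.
#'
#' @param x A [haplotype_table] or [seq_alignment].
#' @param length Alignment length in nt (required for a table; taken from the
#'   alignment otherwise).
#' @return Named numeric vector `c(pi =, k =)`; `pi` is a fraction (multiply
#'   by 100 for the conventional percent form).
#' @export
nucleotide_diversity <- function(x, length = NULL) UseMethod("nucleotide_diversity")

#' @rdname nucleotide_diversity
#' @export
nucleotide_diversity.haplotype_table <- function(x, length = NULL) {
  if (is.null(length) || length <= 0) stop("a positive alignment length is required")
  cnt <- rowSums(x$counts)
  n <- sum(cnt)
  if (n < 2) stop("need at least 2 sequences")
  d <- hap_dist(x$states)
  tot <- as.numeric(cnt %*% d %*% cnt) / 2    # within-haplotype pairs differ at 0 sites
  k <- tot / (n * (n - 1) / 2)
  c(pi = k / length, k = k)
}

#' @rdname nucleotide_diversity
#' @export
nucleotide_diversity.seq_alignment <- function(x, length = NULL) {
  nucleotide_diversity(collapse_haplotypes(x), length %||% x$length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-locus codominant diversity summaries
#'
#' For each locus within one population: allele count `N_a`, observed
#' heterozygosity `H_O`, Nei's unbiased expected heterozygosity
#' `H_E = 2n/(2n-1) (1 - sum q_a^2)` (also reported as gene diversity `g`),
#' and the inbreeding coefficient `F_IS = (H_E - H_O)/H_E`. A monomorphic
#' locus has undefined `F_IS`, reported as 0 with `fis_defined = FALSE`.
#'
#' @param g A [genotype_matrix].
#' @param pop Population to summarise; `NULL` pools all individuals.
#' @return List with `loci` (a per-locus data frame) and `means` (across-locus
#'   means of `g`, `N_a`, `H_O`, `H_E`, `F_IS`); loci with no called
#'   genotypes are skipped with a warning.
#' @export
locus_summaries <- function(g, pop = NULL) {
  keep <- if (is.null(pop)) rep(TRUE, nrow(g$a1)) else g$pop == pop
  if (!any(keep)) stop("no individuals in population ", pop)
  a1 <- g$a1[keep, , drop = FALSE]; a2 <- g$a2[keep, , drop = FALSE]
  res <- lapply(seq_len(ncol(a1)), function(j) {
    x <- a1[, j]; y <- a2[, j]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) return(NULL)
    x <- x[ok]; y <- y[ok]; n <- length(x)
    q <- table(c(x, y)) / (2 * n)
    he <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(q^2)) else NA_real_
    ho <- mean(x != y)
    fis_defined <- !is.na(he) && he > 0
    data.frame(locus = colnames(a1)[j], n = n, N_a = length(q),
               H_O = ho, H_E = he, g = he,
               F_IS = if (fis_defined) (he - ho) / he else 0,
               fis_defined = fis_defined)
  })
  skipped <- vapply(res, is.null, logical(1))
  if (any(skipped))
    warning("locus with no called genotypes skipped: ",
            paste(colnames(a1)[skipped], collapse = ", "))
  loci <- do.call(rbind, res[!skipped])
  means <- c(g = mean(loci$g, na.rm = TRUE), N_a = mean(loci$N_a),
             H_O = mean(loci$H_O), H_E = mean(loci$H_E, na.rm = TRUE),
             F_IS = mean(loci$F_IS[loci$fis_defined]))
  list(loci = loci, means = means)
}

#' Monte-Carlo Hardy-Weinberg equilibrium test
#'
#' Shuffles the pooled alleles of a locus into new diploid genotypes and
#' compares the observed heterozygote count against the permutation null.
#' The two-sided statistic is the absolute deviation of the heterozygote
#' count from its exact permutation expectation
#' `E = n (1 - sum n_a (n_a - 1) / (2n (2n-1)))`; the p-value uses the
#' add-one rule and counts ties as extreme (conservative).
#'
#' @param g A [genotype_matrix].
#' @param pop Population to test.
#' @param locus Locus name or index.
#' @param n_perm Number of allele-shuffling permutations.
#' @param seed Integer seed (mandatory; the test is exactly reproducible).
#' @return List with `p.value`, `observed_het`, `expected_het`, `n`,
#'   `n_perm` and `monomorphic`.
#' @export
hwe_permutation_test <- function(g, pop, locus, n_perm = 999, seed) {
  keep <- g$pop == pop
  x <- g$a1[keep, locus]; y <- g$a2[keep, locus]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 5) stop("need at least 5 called genotypes")
  alleles <- c(x, y)
  na <- table(alleles)
  if (length(na) < 2L)
    return(list(p.value = 1, observed_het = 0, expected_het = 0, n = n,
                n_perm = n_perm, monomorphic = TRUE))
  e_het <- n * (1 - sum(na * (na - 1)) / (2 * n * (2 * n - 1)))
  obs <- sum(x != y)
  stat_obs <- abs(obs - e_het)
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s <- sample(alleles)
      abs(sum(s[1:n] != s[(n + 1):(2 * n)]) - e_het) >= stat_obs
    }, logical(1))
  })
  list(p.value = (sum(hits) + 1) / (n_perm + 1), observed_het = obs,
       expected_het = e_het, n = n, n_perm = n_perm, monomorphic = FALSE)
}
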