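#' Pairwise individual-level distance matrices
#'
#' Builds the distance substrate for AMOVA and F_ST from any of the three
#' marker systems: sequences (count of differing non-missing sites),
#' codominant genotypes (allele mismatches per locus, 0/1/2, summed over
#' co-called loci), or SNP/dominant marker matrices (summed genotype
#' differences for `snp` calls in 0/1/2; simple mismatch for dominant
#' presence/absence). Missing data are pairwise-deleted; a pair with no
#' comparable data is an error.
#'
#' @param x A [seq_alignment], [genotype_matrix] or [marker_matrix].
#' @param ... Unused.
#' @return Symmetric numeric matrix with individual ids as dimnames and an
#'   attribute `metric` naming the distance used.
#' @export
pairwise_distance <- function(x, ...) UseMethod("pairwise_distance")

#' @rdname pairwise_distance
#' @export
pairwise_distance.seq_alignment <- function(x, ...) {
  uniq <- unique(x$seqs)
  ui <- match(x$seqs, uniq)
  um <- do.call(rbind, strsplit(uniq, ""))
  um[um %in% MISSING_STATES] <- NA
  U <- nrow(um)
  du <- matrix(0, U, U)
  if (U >= 2L) for (i in 1:(U - 1L)) for (j in (i + 1L):U) {
    ok <- !is.na(um[i, ]) & !is.na(um[j, ])
    if (!any(ok)) {
      a <- names(x$seqs)[match(i, ui)]; b <- names(x$seqs)[match(j, ui)]
      stop("no comparable sites between '", a, "' and '", b, "'")
    }
    du[i, j] <- du[j, i] <- sum(um[i, ok] != um[j, ok])
  }
  d <- du[ui, ui, drop = FALSE]
  dimnames(d) <- list(names(x$seqs), names(x$seqs))
  attr(d, "metric") <- "hamming_nt"
  d
}

#' @rdname pairwise_distance
#' @param unit For codominant genotypes: `"allele"` (default) treats each of
#'   the two allele copies of an individual as the exchangeable unit — the
#'   matrix has `2N` rows (`id|1`, `id|2`) and carries the expanded
#'   population labels in attribute `populations`, which [amova()] and
#'   [pairwise_fst()] pick up automatically. This is the unit under which
#'   the Phi_ST of a two-level analysis estimates allele-level F_ST
#'   (genotype-level units would estimate `2F/(1+F)` instead, since the
#'   among-population mean difference then enters with both allele copies).
#'   The sums of squares are invariant to the arbitrary phase of the stored
#'   copies. `"individual"` returns the per-pair allele-mismatch count
#'   (0/1/2 per locus) between individuals.
#' @export
pairwise_distance.genotype_matrix <- function(x, unit = c("allele", "individual"),
                                              ...) {
  unit <- match.arg(unit)
  if (unit == "allele") {
    n <- nrow(x$a1)
    al <- rbind(x$a1, x$a2)[rep(seq_len(n), each = 2L) + c(0L, n), , drop = FALSE]
    rownames(al) <- paste(rep(rownames(x$a1), each = 2L), 1:2, sep = "|")
    m <- nrow(al)
    d <- matrix(0, m, m, dimnames = list(rownames(al), rownames(al)))
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      ok <- !is.na(al[i, ]) & !is.na(al[j, ])
      if (!any(ok))
        stop("no comparable loci between '", rownames(al)[i], "' and '",
             rownames(al)[j], "'")
      d[i, j] <- d[j, i] <- sum(al[i, ok] != al[j, ok])
    }
    attr(d, "populations") <- rep(x$pop, each = 2L)
  } else {
    n <- nrow(x$a1)
    d <- matrix(0, n, n, dimnames = list(rownames(x$a1), rownames(x$a1)))
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(x$a1[i, ]) & !is.na(x$a1[j, ])
      if (!any(ok))
        stop("no comparable loci between '", rownames(x$a1)[i], "' and '",
             rownames(x$a1)[j], "'")
      m1 <- (x$a1[i, ok] == x$a1[j, ok]) + (x$a2[i, ok] == x$a2[j, ok])
      m2 <- (x$a1[i, ok] == x$a2[j, ok]) + (x$a2[i, ok] == x$a1[j, ok])
      d[i, j] <- d[j, i] <- sum(2 - pmax(m1, m2))
    }
  }
  attr(d, "metric") <- "allele_mismatch"
  d
}

#' @rdname pairwise_distance
#' @export
pairwise_distance.marker_matrix <- function(x, ...) {
  calls <- x$calls
  n <- nrow(calls)
  snp <- identical(x$type, "snp")
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    if (!any(ok))
      stop("no co-called markers between '", rownames(calls)[i], "' and '",
           rownames(calls)[j], "'")
    d[i, j] <- d[j, i] <- if (snp) sum(abs(calls[i, ok] - calls[j, ok]))
                          else sum(calls[i, ok] != calls[j, ok])
  }
  attr(d, "metric") <- if (snp) "allele_mismatch" else "binary_mismatch"
  d
}

# within-group sum-of-squares term: sum_g (1/n_g) sum_{i<j in g} e2_ij
ss_within <- function(e2, f) {
  f <- as.character(f)
  m <- rowsum(e2, f, reorder = FALSE)
  s <- rowsum(t(m), f, reorder = FALSE)       # group x group total sums
  ng <- as.vector(table(f)[rownames(s)])      # sizes in the same group order
  sum(diag(s) / (2 * ng))
}

# ratio that treats completely homogeneous data (0/0) as "no structure"
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

amova_2level <- function(e2, pop) {
  n <- length(pop); np <- table(pop); p <- length(np)
  ss_tot <- sum(e2) / (2 * n)
  ss_wp <- ss_within(e2, pop)
  ss_ap <- ss_tot - ss_wp
  df_ap <- p - 1; df_wp <- n - p
  sig_w <- ss_wp / df_wp
  n0 <- (n - sum(np^2) / n) / (p - 1)
  sig_a <- (ss_ap / df_ap - sig_w) / n0
  list(df = c(df_ap, df_wp), ss = c(ss_ap, ss_wp), sigma = c(sig_a, sig_w),
       phi_st = safe_ratio(sig_a, sig_a + sig_w))
}

amova_3level <- function(e2, pop, reg) {
  n <- length(pop)
  np <- table(pop); p <- length(np)
  nr <- table(reg); g <- length(nr)
  pop_region <- tapply(reg, pop, function(r) r[1])
  ss_tot <- sum(e2) / (2 * n)
  ss_wp <- ss_within(e2, pop)
  ss_wg <- ss_within(e2, reg)
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp
  df <- c(g - 1, p - g, n - p)
  sig_c <- ss_wp / df[3]
  # sum over regions of (sum_{pops in r} n_p^2) / n_r
  pr <- pop_region[names(np)]
  sum_np2 <- tapply(as.vector(np)^2, pr, sum)
  s_r <- sum_np2 / as.vector(nr[names(sum_np2)])
  n1 <- (n - sum(s_r)) / (p - g)
  n2 <- (sum(s_r) - sum(np^2) / n) / (g - 1)
  n3 <- (n - sum(nr^2) / n) / (g - 1)
  sig_b <- (ss_ap / df[2] - sig_c) / n1
  sig_a <- (ss_ag / df[1] - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(df = df, ss = c(ss_ag, ss_ap, ss_wp), sigma = c(sig_a, sig_b, sig_c),
       phi = c(Phi_CT = safe_ratio(sig_a, tot),
               Phi_SC = safe_ratio(sig_b, sig_b + sig_c),
               Phi_ST = safe_ratio(sig_a + sig_b, tot)))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Excoffier-style hierarchical decomposition of squared pairwise distances
#' into among-region, among-population-within-region and within-population
#' variance components, with Phi-statistics and permutation p-values.
#' Permutation schemes follow the standard conventions: individuals are
#' shuffled across the whole sample for `Phi_ST`, among populations within
#' regions for `Phi_SC`, and whole populations are shuffled among regions for
#' `Phi_CT`. p-values use the add-one rule `(b + 1)/(B + 1)`.
#'
#' @param d Symmetric distance matrix (see [pairwise_distance()]).
#' @param populations Character vector of population labels, one per row of
#'   `d`; defaults to the `populations` attribute of `d` when present (as
#'   set by the allele-level codominant distance).
#' @param regions Optional named character vector mapping population name to
#'   region; supplying it switches to the three-level design.
#' @param n_perm Number of permutations for p-values (0 skips them).
#' @param seed Integer seed; mandatory whenever `n_perm > 0`.
#' @param squared If `TRUE` (default) the entries of `d` are already the
#'   squared distances the sums of squares operate on — the convention for
#'   pairwise-difference counts; set `FALSE` to square raw distances first.
#' @return An object of class `amova`: a data frame `table` (level, df, SS,
#'   variance component, percent of variation), the `statistics` vector of
#'   Phi values, permutation `p_values`, and the call parameters. Individual
#'   variance components may be negative; percentages sum to 100.
#' @export
amova <- function(d, populations = NULL, regions = NULL, n_perm = 1000,
                  seed = NULL, squared = TRUE) {
  populations <- populations %||% attr(d, "populations")
  if (is.null(populations)) stop("population labels are required")
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(populations) != n) stop("one population label per individual needed")
  populations <- as.character(populations)
  if (length(unique(populations)) < 2L)
    stop("degenerate design: need at least 2 populations")
  if (any(table(populations) == 1L))
    warning("population(s) with a single individual: ",
            paste(names(which(table(populations) == 1L)), collapse = ", "))
  if (n_perm > 0 && is.null(seed)) stop("a seed is required when permuting")
  e2 <- if (squared) d else d^2
  if (is.null(regions)) {
    obs <- amova_2level(e2, populations)
    tab <- data.frame(
      level = c("among_populations", "within_populations"),
      df = obs$df, SS = obs$ss, variance = obs$sigma,
      percent = 100 * obs$sigma / sum(obs$sigma))
    stats <- c(Phi_ST = obs$phi_st)
    p <- c(Phi_ST = NA_real_)
    if (n_perm > 0) {
      hits <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b)
        amova_2level(e2, sample(populations))$phi_st >= obs$phi_st, logical(1)))
      p["Phi_ST"] <- (sum(hits) + 1) / (n_perm + 1)
    }
  } else {
    reg <- unname(regions[populations])
    if (anyNA(reg)) stop("region missing for some population(s)")
    if (length(unique(reg)) < 2L) stop("need at least 2 regions")
    obs <- amova_3level(e2, populations, reg)
    tab <- data.frame(
      level = c("among_regions", "among_populations_within_regions",
                "within_populations"),
      df = obs$df, SS = obs$ss, variance = obs$sigma,
      percent = 100 * obs$sigma / sum(obs$sigma))
    stats <- obs$phi
    p <- c(Phi_CT = NA_real_, Phi_SC = NA_real_, Phi_ST = NA_real_)
    if (n_perm > 0) {
      pops <- unique(populations)
      pop_reg <- regions[pops]
      idx_by_reg <- split(seq_len(n), reg)
      perm <- withr::with_seed(seed, {
        res <- matrix(FALSE, n_perm, 3L)
        for (b in seq_len(n_perm)) {
          # Phi_ST: individuals across the whole design (joint pop/region slots)
          ord <- sample(n)
          st <- amova_3level(e2, populations[ord], reg[ord])
          # Phi_SC: individuals among populations within regions
          pp <- populations
          for (ii in idx_by_reg) pp[ii] <- sample(populations[ii])
          sc <- amova_3level(e2, pp, reg)
          # Phi_CT: whole populations among regions
          rmap <- stats::setNames(sample(pop_reg), pops)
          ct <- amova_3level(e2, populations, unname(rmap[populations]))
          res[b, ] <- c(ct$phi["Phi_CT"] >= obs$phi["Phi_CT"],
                        sc$phi["Phi_SC"] >= obs$phi["Phi_SC"],
                        st$phi["Phi_ST"] >= obs$phi["Phi_ST"])
        }
        res
      })
      p[] <- (colSums(perm) + 1) / (n_perm + 1)
    }
  }
  structure(list(table = tab, statistics = stats, p_values = p,
                 n_perm = n_perm, seed = seed),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (", nrow(x$table), "-level design)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  for (s in names(x$statistics))
    cat(sprintf("%s = %.4f (p = %s, %d permutations)\n", s, x$statistics[s],
                format(x$p_values[s], digits = 3), x$n_perm))
  invisible(x)
}

#' Pairwise Phi_ST between all population pairs
#'
#' Runs a two-population AMOVA for every pair, with label-permutation
#' p-values. Negative estimates are reported as computed, not truncated.
#'
#' @inheritParams amova
#' @return An object of class `pairwise_fst`: symmetric matrices `phi_st`
#'   and `p` with populations as dimnames.
#' @export
pairwise_fst <- function(d, populations = NULL, n_perm = 1000, seed = NULL,
                         squared = TRUE) {
  populations <- populations %||% attr(d, "populations")
  if (is.null(populations)) stop("population labels are required")
  d <- as.matrix(d)
  pops <- unique(as.character(populations))
  if (length(pops) < 2L) stop("need at least 2 populations")
  k <- length(pops)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(phi) <- 0
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    keep <- populations %in% pops[c(i, j)]
    res <- amova(d[keep, keep, drop = FALSE], populations[keep],
                 n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else seed + i * k + j,
                 squared = squared)
    phi[i, j] <- phi[j, i] <- res$statistics["Phi_ST"]
    p[i, j] <- p[j, i] <- res$p_values["Phi_ST"]
  }
  structure(list(phi_st = phi, p = p, n_perm = n_perm, seed = seed),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise Phi_ST (upper: p-values from", x$n_perm, "permutations)\n")
  m <- x$phi_st
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 4))
  invisible(x)
}

#' Write an AMOVA result as TSV
#'
#' @param res An [amova] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_amova <- function(res, path) {
  tab <- res$table
  tab$statistic <- NA_character_; tab$p <- NA_real_
  for (i in seq_along(res$statistics)) {
    tab$statistic[i] <- names(res$statistics)[i]
    tab$p[i] <- res$p_values[i]
  }
  tab$statistic_value <- c(res$statistics, rep(NA, nrow(tab) - length(res$statistics)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
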