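#' Simulation configuration
#'
#' One seeded configuration object drives all three generators. Defaults
#' mirror the Pacific yellowtail kingfish study design: six populations in
#' three regions for the COI and microsatellite data (Japan 15, USA 26,
#' Mexico 76, Chile 50, NSW 48, SA 29; 604 nt fragment; 5 hemisphere-level,
#' 5 NW-level and 3 NE-level planted fixed differences), and the five-
#' population DArTseq design (Japan 2, Mexico 38, Chile 20, NSW 48, SA 44;
#' 70 bp tags) with planted population-unique markers 3/3/20/2 for
#' Japan/Mexico/Northern/Southern.
#'
#' @param seed Integer master seed (mandatory); each generator draws from an
#'   independent stream derived from it.
#' @param coi,msat,markers Named lists overriding individual fields of the
#'   corresponding generator block (see the defaults in the function body).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, coi = list(), msat = list(), markers = list()) {
  if (missing(seed)) stop("a seed is mandatory")
  base_coi <- list(
    pops = c(Japan = 15, USA = 26, Mexico = 76, Chile = 50, NSW = 48, SA = 29),
    region_of = c(Japan = "NW", USA = "NE", Mexico = "NE",
                  Chile = "SP", NSW = "SP", SA = "SP"),
    hemisphere_of = c(NW = "Northern", NE = "Northern", SP = "Southern"),
    seq_length = 604,
    n_diag = c(hemisphere = 5, NW = 5, NE = 3),
    n_private = c(NW = 1, NE = 3, SP = 8),
    mu = 0.003, root_freq = 0.7)
  base_msat <- list(
    pops = c(Japan = 15, USA = 26, Mexico = 76, Chile = 50, NSW = 48, SA = 29),
    n_loci = 9, n_alleles = 8, fst_target = 0.2)
  base_markers <- list(
    pops = c(Japan = 2, Mexico = 38, Chile = 20, NSW = 48, SA = 44),
    hemisphere = list(Northern = c("Japan", "Mexico"),
                      Southern = c("Chile", "NSW", "SA")),
    n_markers = 500, tag_length = 70, missing_rate = 0.01,
    fst_between = 0.2, fst_within = 0.05,
    planted = c(Japan = 3, Mexico = 3, Northern = 20, Southern = 2),
    n_bad_markers = 12, n_multi_loci = 8, n_bad_samples = 2,
    bad_missing = 150)
  cfg <- list(seed = as.integer(seed),
              coi = utils::modifyList(base_coi, coi),
              msat = utils::modifyList(base_msat, msat),
              markers = utils::modifyList(base_markers, markers))
  rates <- c(cfg$coi$mu, cfg$markers$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

stream_seed <- function(seed, k) (seed %% 20000L) * 100003L + k

mutate_at <- function(seq, pos, rng_states = c("A", "C", "G", "T")) {
  for (p in pos) {
    alt <- setdiff(rng_states, seq[p])
    seq[p] <- alt[sample.int(length(alt), 1L)]
  }
  seq
}

#' Simulate a region-structured COI alignment
#'
#' Builds a root sequence, plants the configured numbers of fixed differences
#' for the hemisphere, NW and NE partitions (mirroring a 5/5/3 categorical
#' pattern), derives low-frequency private haplotypes within each region by
#' mutating additional sites (mutation count per haplotype is
#' `max(1, Binomial(seq_length, mu))`; `mu = 0` suppresses private variation
#' entirely), and samples haplotype copies multinomially with every haplotype
#' guaranteed at least one copy so planted structure is recoverable by
#' construction.
#'
#' @param cfg A [sim_config].
#' @return List with `alignment` (a [seq_alignment]) and `truth` (planted
#'   diagnostic positions per partition, private positions, and the
#'   haplotype spectrum per region).
#' @export
simulate_coi <- function(cfg) {
  cc <- cfg$coi
  withr::with_seed(stream_seed(cfg$seed, 1L), {
    L <- cc$seq_length
    if (sum(cc$n_diag) > L) stop("diagnostic sites exceed sequence length")
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pool <- sample.int(L)
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    diag_pos <- list(hemisphere = sort(take(cc$n_diag[["hemisphere"]])),
                     NW = sort(take(cc$n_diag[["NW"]])),
                     NE = sort(take(cc$n_diag[["NE"]])))
    regions <- unique(cc$region_of)
    north <- names(cc$hemisphere_of)[cc$hemisphere_of == "Northern"]
    region_root <- list()
    for (r in regions) {
      s <- root
      if (r %in% north) s <- mutate_at(s, diag_pos$hemisphere)
      if (r == "NW") s <- mutate_at(s, diag_pos$NW)
      if (r == "NE") s <- mutate_at(s, diag_pos$NE)
      region_root[[r]] <- s
    }
    # Northern regions must share the hemisphere-derived states
    if (all(c("NW", "NE") %in% regions))
      region_root$NE[diag_pos$hemisphere] <- region_root$NW[diag_pos$hemisphere]
    private_pos <- list(); spectra <- list()
    for (r in regions) {
      haps <- list(region_root[[r]])
      ppos <- integer(0)
      n_priv <- if (cc$mu == 0) 0L else cc$n_private[[r]]
      if (n_priv > 0L) for (k in seq_len(n_priv)) {
        nmut <- max(1L, stats::rbinom(1L, L, cc$mu))
        pos <- take(nmut)
        haps[[k + 1L]] <- mutate_at(region_root[[r]], pos)
        ppos <- c(ppos, pos)
      }
      private_pos[[r]] <- sort(ppos)
      spectra[[r]] <- haps
    }
    seqs <- character(0); pop <- character(0); ids <- character(0)
    for (r in regions) {
      rpops <- names(cc$pops)[cc$region_of[names(cc$pops)] == r]
      n_r <- sum(cc$pops[rpops])
      H <- length(spectra[[r]])
      if (n_r < H) stop("region ", r, " has fewer samples than haplotypes")
      probs <- c(cc$root_freq, rep((1 - cc$root_freq) / max(H - 1L, 1L), H - 1L))
      counts <- rep(1L, H)
      if (n_r > H)
        counts <- counts + as.integer(stats::rmultinom(1L, n_r - H, probs))
      hap_of <- sample(rep(seq_len(H), counts))
      pop_of <- rep(rpops, cc$pops[rpops])
      seqs <- c(seqs, vapply(hap_of, function(h)
        paste(spectra[[r]][[h]], collapse = ""), character(1)))
      pop <- c(pop, pop_of)
      ids <- c(ids, paste0(r, "_", seq_len(n_r)))
    }
    names(seqs) <- ids
    aln <- seq_alignment(seqs, pop, cc$region_of)
    list(alignment = aln,
         truth = list(diagnostic_positions = diag_pos,
                      private_positions = private_pos,
                      n_haplotypes = sum(lengths(spectra)),
                      root = paste(root, collapse = "")))
  })
}

# Dirichlet draw, alpha vector
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate island-model microsatellite genotypes
#'
#' Ancestral allele frequencies per locus are Dirichlet(1,...,1); population
#' frequencies follow the multi-allele Balding-Nichols model,
#' `Dirichlet(p (1 - F)/F)` with `F = fst_target` (`fst_target = 0` gives
#' panmixia), and diploid genotypes are drawn under Hardy-Weinberg
#' equilibrium within populations.
#'
#' @param cfg A [sim_config].
#' @return List with `genotypes` (a [genotype_matrix]) and `truth`
#'   (`fst_target` and the per-population allele frequencies).
#' @export
simulate_msat <- function(cfg) {
  mc <- cfg$msat
  withr::with_seed(stream_seed(cfg$seed, 2L), {
    A <- mc$n_alleles
    allele_codes <- 100L + 2L * seq_len(A)
    N <- sum(mc$pops)
    a1 <- a2 <- matrix(NA_integer_, N, mc$n_loci,
                       dimnames = list(paste0("ind", seq_len(N)),
                                       paste0("loc", seq_len(mc$n_loci))))
    pop <- rep(names(mc$pops), mc$pops)
    freqs <- list()
    for (j in seq_len(mc$n_loci)) {
      anc <- rdirichlet1(rep(1, A))
      fr <- sapply(names(mc$pops), function(p) {
        if (mc$fst_target <= 0) anc
        else rdirichlet1(anc * (1 - mc$fst_target) / mc$fst_target)
      })
      freqs[[j]] <- fr
      for (p in names(mc$pops)) {
        rows <- which(pop == p)
        a1[rows, j] <- allele_codes[sample.int(A, length(rows), TRUE, fr[, p])]
        a2[rows, j] <- allele_codes[sample.int(A, length(rows), TRUE, fr[, p])]
      }
    }
    list(genotypes = genotype_matrix(a1, a2, pop),
         truth = list(fst_target = mc$fst_target, freqs = freqs))
  })
}

#' Simulate SNP and dominant (DArT-style) marker matrices
#'
#' Background biallelic frequencies follow a hierarchical Balding-Nichols
#' model (hemisphere level `fst_between`, population level `fst_within`,
#' intermediate ancestral frequencies). Diploid SNP genotypes (0/1/2) are
#' drawn under HWE; dominant presence/absence calls score carriage of the
#' alternate allele. The generator plants the configured counts of
#' population-unique markers (fixed present in the focal group, absent
#' elsewhere, fully called), a block of high-missingness markers, a few
#' multi-marker loci, and some high-missingness samples so every QC rule is
#' exercised; remaining calls go missing at `missing_rate`.
#'
#' @param cfg A [sim_config].
#' @return List with `snp` and `dart` (two [marker_matrix] objects sharing
#'   samples and loci) and `truth` (planted unique-marker ids per group,
#'   high-missingness marker/sample ids, multi-locus marker ids, and the F
#'   parameters).
#' @export
simulate_markers <- function(cfg) {
  kc <- cfg$markers
  withr::with_seed(stream_seed(cfg$seed, 3L), {
    pops <- kc$pops
    N <- sum(pops)
    pop <- rep(names(pops), pops)
    ids <- paste0(rep(names(pops), pops), "_",
                  unlist(lapply(pops, seq_len)))
    n_planted <- sum(kc$planted)
    if (n_planted > kc$n_markers) stop("planted counts exceed n_markers")
    n_bg <- kc$n_markers - n_planted
    bn <- function(p, f) if (f <= 0) p else
      stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    geno <- matrix(NA_integer_, N, kc$n_markers)
    anc <- stats::runif(n_bg, 0.3, 0.7)
    for (h in names(kc$hemisphere)) {
      ph <- bn(anc, kc$fst_between)
      for (p in kc$hemisphere[[h]]) {
        pp <- bn(ph, kc$fst_within)
        rows <- which(pop == p)
        draw <- vapply(pp, function(q) stats::rbinom(length(rows), 2L, q),
                       integer(length(rows)))
        geno[rows, seq_len(n_bg)] <- matrix(draw, nrow = length(rows))
      }
    }
    # planted unique markers: present throughout the focal group (minus one
    # carrier when the group is large enough, so a single-population set
    # never also clears the 95% bar of a wider group it belongs to), absent
    # everywhere else, fully called
    planted_ids <- list(); col <- n_bg
    marker_ids <- sprintf("M%04d", seq_len(kc$n_markers))
    for (g in names(kc$planted)) {
      focal_pops <- if (g %in% names(kc$hemisphere)) kc$hemisphere[[g]] else g
      cols <- col + seq_len(kc$planted[[g]])
      geno[, cols] <- 0L
      rows <- which(pop %in% focal_pops)
      if ((length(rows) - 1) / length(rows) >= 0.95) {
        big <- focal_pops[which.max(pops[focal_pops])]
        rows <- setdiff(rows, which(pop == big)[1L])
      }
      geno[rows, cols] <- 2L
      planted_ids[[g]] <- marker_ids[cols]
      col <- col + kc$planted[[g]]
    }
    # background missingness (planted markers stay fully called)
    if (kc$missing_rate > 0 && n_bg > 0) {
      mk <- matrix(stats::runif(N * n_bg) < kc$missing_rate, N, n_bg)
      geno[, seq_len(n_bg)][mk] <- NA_integer_
    }
    # high-missingness markers: missing in 20% of the first population
    bad_markers <- character(0)
    if (kc$n_bad_markers > 0 && n_bg >= kc$n_bad_markers) {
      bm <- seq_len(kc$n_bad_markers)
      p1 <- names(pops)[which.max(pops >= 5)]
      rows <- which(pop == p1)
      hit <- rows[seq_len(max(1L, ceiling(0.2 * length(rows))))]
      geno[hit, bm] <- NA_integer_
      bad_markers <- marker_ids[bm]
    }
    # high-missingness samples (placed in the largest population)
    bad_samples <- character(0)
    if (kc$n_bad_samples > 0) {
      big <- names(pops)[which.max(pops)]
      rows <- utils::tail(which(pop == big), kc$n_bad_samples)
      free <- setdiff(seq_len(n_bg), seq_len(kc$n_bad_markers))
      for (r in rows) geno[r, sample(free, kc$bad_missing)] <- NA_integer_
      bad_samples <- ids[rows]
    }
    # loci: a few tags carry two markers each (removed by QC)
    locus_of <- sprintf("L%04d", seq_len(kc$n_markers))
    multi <- character(0)
    if (kc$n_multi_loci > 0) {
      free <- setdiff(seq_len(n_bg), seq_len(kc$n_bad_markers))
      pick <- sample(free, 2L * kc$n_multi_loci)
      pairs <- matrix(pick, ncol = 2L)
      locus_of[pairs[, 2L]] <- locus_of[pairs[, 1L]]
      multi <- marker_ids[as.vector(pairs)]
    }
    dimnames(geno) <- list(ids, marker_ids)
    names(locus_of) <- marker_ids
    snp <- marker_matrix(geno, pop, locus_of, kc$tag_length, "snp")
    dom <- marker_matrix(ifelse(is.na(geno), NA_integer_,
                                as.integer(geno >= 1L)),
                         pop, locus_of, kc$tag_length, "dominant")
    list(snp = snp, dart = dom,
         truth = list(planted = planted_ids, bad_markers = bad_markers,
                      bad_samples = bad_samples, multi_locus_markers = multi,
                      fst_between = kc$fst_between,
                      fst_within = kc$fst_within))
  })
}

#' Write a simulation to disk in the formats the analysis functions read
#'
#' COI simulations are written as FASTA + population map, microsatellites as
#' a wide genotype CSV, marker simulations as SNP and dominant CSVs plus the
#' locus metadata sidecar; the recorded ground truth always goes to
#' `<prefix>_truth.json`.
#'
#' @param sim Result of [simulate_coi()], [simulate_msat()] or
#'   [simulate_markers()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(s) file.path(dir, paste0(prefix, s))
  files <- character(0)
  if (!is.null(sim$alignment)) {
    write_alignment(sim$alignment, fp(".fasta"), fp("_popmap.tsv"))
    files <- c(files, fp(".fasta"), fp("_popmap.tsv"))
  }
  if (!is.null(sim$genotypes)) {
    write_genotypes(sim$genotypes, fp("_genotypes.csv"))
    files <- c(files, fp("_genotypes.csv"))
  }
  if (!is.null(sim$snp)) {
    write_markers(sim$snp, fp("_snp.csv"), fp("_markers_meta.tsv"))
    write_markers(sim$dart, fp("_dart.csv"))
    files <- c(files, fp("_snp.csv"), fp("_dart.csv"), fp("_markers_meta.tsv"))
  }
  jsonlite::write_json(sim$truth, fp("_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, fp("_truth.json")))
}
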