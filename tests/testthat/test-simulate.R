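test_that("generators are reproducible from the seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(simulate_coi(cfg)$alignment$seqs,
                   simulate_coi(cfg)$alignment$seqs)
  expect_identical(simulate_msat(cfg)$genotypes$a1,
                   simulate_msat(cfg)$genotypes$a1)
  expect_identical(simulate_markers(cfg)$snp$calls,
                   simulate_markers(cfg)$snp$calls)
  # different seeds give different data
  expect_false(identical(simulate_coi(sim_config(seed = 12))$alignment$seqs,
                         simulate_coi(cfg)$alignment$seqs))
})

test_that("planted COI diagnostics are recovered exactly", {
  sim <- simulate_coi(sim_config(seed = 21))
  t <- collapse_haplotypes(sim$alignment)
  north <- c("Japan", "USA", "Mexico")
  got <- list(
    hemisphere = sort(find_diagnostic_sites(t, focal = north)$position),
    NW = sort(find_diagnostic_sites(t, focal = "Japan")$position),
    NE = sort(find_diagnostic_sites(t, focal = c("USA", "Mexico"))$position))
  expect_equal(got$hemisphere, sim$truth$diagnostic_positions$hemisphere)
  expect_equal(got$NW, sim$truth$diagnostic_positions$NW)
  expect_equal(got$NE, sim$truth$diagnostic_positions$NE)
  expect_equal(nrow(t$states), sim$truth$n_haplotypes)

  # mu = 0 with no planted sites: a monomorphic alignment, h = 0
  flat <- simulate_coi(sim_config(seed = 21, coi = list(
    mu = 0, n_diag = c(hemisphere = 0, NW = 0, NE = 0))))
  tf <- collapse_haplotypes(flat$alignment)
  expect_equal(nrow(tf$states), 1)
  expect_length(tf$positions, 0)
  expect_equal(unname(haplotype_diversity(rowSums(tf$counts))["h"]), 0)
})

test_that("island-model genotypes recover their target F_ST", {
  # panmixia: Phi_ST and F_IS both near zero
  pan <- simulate_msat(sim_config(seed = 31, msat = list(
    pops = c(A = 60, B = 60), n_loci = 30, fst_target = 0)))
  d <- pairwise_distance(pan$genotypes)
  expect_lt(abs(amova(d, n_perm = 0)$statistics["Phi_ST"]), 0.02)
  expect_lt(abs(locus_summaries(pan$genotypes, "A")$means["F_IS"]), 0.05)

  # monotonicity: higher target, higher mean estimate
  est <- vapply(c(0.05, 0.2, 0.4), function(f) {
    mean(vapply(1:2, function(r) {
      g <- simulate_msat(sim_config(seed = 40 + r, msat = list(
        pops = c(A = 30, B = 30), n_loci = 40, fst_target = f)))$genotypes
      unname(amova(pairwise_distance(g), n_perm = 0)$statistics["Phi_ST"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("marker simulation exercises every QC rule and stays recoverable", {
  cfg <- sim_config(seed = 51)
  sim <- simulate_markers(cfg)
  truth <- sim$truth
  q <- qc_markers(sim$dart)
  log <- attr(q, "qc_log")
  # the seeded bad markers, multi-marker loci and bad samples all fall
  expect_true(all(truth$bad_markers %in% log$loci_missingness))
  expect_true(all(setdiff(truth$multi_locus_markers, log$loci_missingness)
                  %in% log$multisnp_loci))
  expect_setequal(log$samples, truth$bad_samples)
  # no planted marker is lost
  expect_true(all(unlist(truth$planted) %in% colnames(q$calls)))

  # with no background missingness the QC chain only removes seeded blocks
  clean <- simulate_markers(sim_config(seed = 51,
                                       markers = list(missing_rate = 0)))
  qc <- qc_markers(clean$dart)
  logc <- attr(qc, "qc_log")
  expect_setequal(logc$loci_missingness, clean$truth$bad_markers)
  expect_setequal(logc$multisnp_loci, clean$truth$multi_locus_markers)
  expect_setequal(logc$samples, clean$truth$bad_samples)

  # between-hemisphere tag dissimilarity exceeds within-hemisphere values
  ph <- population_homology(qc_markers(sim$snp))
  north <- c("Japan", "Mexico"); south <- c("Chile", "NSW", "SA")
  between <- ph[north, south]
  within <- c(ph[north, north][upper.tri(diag(2))],
              ph[south, south][upper.tri(diag(3))])
  expect_gt(min(between), max(within))
})

test_that("simulations round-trip through their file formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 61)
  coi <- simulate_coi(cfg)
  write_simulation(coi, dir, "coi")
  a <- read_alignment(file.path(dir, "coi.fasta"),
                      file.path(dir, "coi_popmap.tsv"))
  expect_equal(a$seqs, coi$alignment$seqs)
  expect_equal(a$pop, coi$alignment$pop)

  ms <- simulate_msat(sim_config(seed = 61, msat = list(pops = c(A = 8, B = 8))))
  write_simulation(ms, dir, "msat")
  g <- read_genotypes(file.path(dir, "msat_genotypes.csv"))
  expect_equal(unname(g$a1), unname(ms$genotypes$a1))

  mk <- simulate_markers(cfg)
  write_simulation(mk, dir, "mk")
  m <- read_markers(file.path(dir, "mk_snp.csv"),
                    file.path(dir, "mk_markers_meta.tsv"), type = "snp")
  expect_equal(unname(m$calls), unname(mk$snp$calls))
  expect_equal(unname(m$locus_of), unname(mk$snp$locus_of))
  truth <- jsonlite::read_json(file.path(dir, "mk_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$planted$Northern, mk$truth$planted$Northern)
})
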