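test_that("pairwise distances count mismatches per marker system", {
  t <- coi_haplotype_table()
  a <- expand_table(t, 604)
  d <- pairwise_distance(a)
  # the two NW haplotypes differ by a single substitution
  i <- grep("^Hap_1_NW_1$", rownames(d)); j <- grep("^Hap_2_NW_1$", rownames(d))
  expect_equal(d[i, j], 1)
  # identical sequences are at distance zero
  expect_equal(d[i, grep("^Hap_1_NW_2$", rownames(d))], 0)

  # binary rows 10110 vs 10011 differ at two markers
  m <- marker_matrix(rbind(a = c(1, 0, 1, 1, 0), b = c(1, 0, 0, 1, 1)),
                     pop = c("P", "P"))
  expect_equal(unname(pairwise_distance(m)["a", "b"]), 2)

  # codominant, individual units: 0/1/2 allele mismatches per locus
  g <- genotype_matrix(a1 = cbind(L1 = c(100L, 100L), L2 = c(100L, 104L)),
                       a2 = cbind(L1 = c(102L, 100L), L2 = c(102L, 106L)),
                       pop = c("P", "P"))
  di <- pairwise_distance(g, unit = "individual")
  expect_equal(unname(di[1, 2]), 1 + 2)  # AB/AA at L1, AB/CD at L2
  # allele units expand to 2N rows with matching population labels
  da <- pairwise_distance(g)
  expect_equal(nrow(da), 4)
  expect_equal(attr(da, "populations"), rep("P", 4))

  # a pair with no comparable data is an error naming the pair
  mm <- marker_matrix(rbind(a = c(1L, NA), b = c(NA, 0L)), pop = c("P", "P"))
  expect_error(pairwise_distance(mm), "a.*b")
})

test_that("variance components match the brute-force moment equations", {
  for (s in 1:3) {
    withr::with_seed(s, {
      n <- 12
      pop <- rep(c("P1", "P2", "P3"), each = 4)
      x <- matrix(rnorm(n * 3), n)
      e2 <- as.matrix(dist(x))^2
    })
    obs <- amova(e2, pop, n_perm = 0)
    exp2 <- brute_amova2(e2, pop)
    expect_equal(obs$table$variance, exp2$sigma, tolerance = 1e-10)
    expect_equal(unname(obs$statistics["Phi_ST"]), exp2$phi_st,
                 tolerance = 1e-10)
    # percentages always total 100 even with negative components
    expect_equal(sum(obs$table$percent), 100, tolerance = 1e-8)

    reg <- c(P1 = "R1", P2 = "R1", P3 = "R2")
    obs3 <- amova(e2, pop, regions = reg, n_perm = 0)
    exp3 <- brute_amova3(e2, pop, unname(reg[pop]))
    expect_equal(obs3$table$variance, unname(exp3$sigma), tolerance = 1e-10)
    expect_equal(obs3$statistics, exp3$phi, tolerance = 1e-10)
    expect_equal(sum(obs3$table$percent), 100, tolerance = 1e-8)
  }
})

test_that("Phi_ST hits its boundary cases", {
  # no within-population variance, constant between: Phi_ST = 1; with six
  # individuals per population a random relabeling essentially never
  # reproduces the split, so the permutation p sits at its floor
  d <- matrix(4, 12, 12); d[1:6, 1:6] <- 0; d[7:12, 7:12] <- 0; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("i", 1:12)
  res <- amova(d, rep(c("A", "B"), each = 6), n_perm = 99, seed = 1)
  expect_equal(unname(res$statistics["Phi_ST"]), 1)
  expect_equal(unname(res$p_values["Phi_ST"]), 1 / 100)

  # one panmictic sample split into two labels: Phi_ST near zero
  withr::with_seed(5, {
    x <- matrix(rnorm(40), 20)
    e2 <- as.matrix(dist(x))^2
  })
  res0 <- amova(e2, rep(c("A", "B"), 10), n_perm = 0)
  expect_lt(abs(res0$statistics["Phi_ST"]), 0.2)

  expect_error(amova(d, rep("A", 12), n_perm = 0), "degenerate")
  expect_warning(amova(d[1:3, 1:3], c("A", "A", "B"), n_perm = 0), "single")
})

test_that("pairwise Phi_ST separates fixed pairs from identical pairs", {
  # fixed difference between A and B; C duplicates A's structure
  seqs <- c(setNames(rep("AAAA", 10), paste0("a", 1:10)),
            setNames(rep("TTTT", 10), paste0("b", 1:10)),
            setNames(rep("AAAA", 10), paste0("c", 1:10)))
  a <- seq_alignment(seqs, rep(c("A", "B", "C"), each = 10))
  pf <- pairwise_fst(pairwise_distance(a), a$pop, n_perm = 199, seed = 3)
  expect_equal(pf$phi_st["A", "B"], 1)
  expect_lte(pf$p["A", "B"], 1 / 200 + 1e-12)
  # identical populations: estimate at/below zero is reported as computed
  expect_lte(pf$phi_st["A", "C"], 0.01)
  expect_gt(pf$p["A", "C"], 0.05)
})

test_that("permutation p-values are uniform under a true null", {
  # continuous distances, no real structure: p over replicates ~ U(0,1)
  B <- 99; nrep <- 200
  pvals <- withr::with_seed(17, vapply(seq_len(nrep), function(r) {
    x <- matrix(rnorm(32), 16)
    e2 <- as.matrix(dist(x))^2
    amova(e2, rep(c("A", "B"), each = 8), n_perm = B,
          seed = sample.int(1e6, 1))$p_values[["Phi_ST"]]
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
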