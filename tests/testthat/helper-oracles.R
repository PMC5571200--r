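# Independent oracles: literal, loop-based transcriptions of the textbook
# formulas, kept deliberately separate from the package implementation.

# Excoffier-style 2-level AMOVA moment equations, squared distances e2
brute_amova2 <- function(e2, pop) {
  n <- length(pop)
  pops <- unique(pop)
  ss_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + e2[i, j]
  ss_tot <- ss_tot / n
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    acc <- 0
    if (length(idx) >= 2)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + e2[idx[a], idx[b]]
    ss_wp <- ss_wp + acc / length(idx)
  }
  ss_ap <- ss_tot - ss_wp
  df_ap <- length(pops) - 1; df_wp <- n - length(pops)
  sig_w <- ss_wp / df_wp
  n0 <- (n - sum(table(pop)^2) / n) / df_ap
  sig_a <- (ss_ap / df_ap - sig_w) / n0
  list(ss = c(ss_ap, ss_wp), sigma = c(sig_a, sig_w),
       phi_st = sig_a / (sig_a + sig_w))
}

# 3-level moment equations (regions / populations / individuals)
brute_amova3 <- function(e2, pop, reg) {
  n <- length(pop)
  pops <- unique(pop); regs <- unique(reg)
  ssd <- function(idx) {
    acc <- 0
    if (length(idx) >= 2)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + e2[idx[a], idx[b]]
    acc / length(idx)
  }
  ss_tot <- ssd(1:n)
  ss_wp <- sum(sapply(pops, function(p) ssd(which(pop == p))))
  ss_wg <- sum(sapply(regs, function(r) ssd(which(reg == r))))
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp
  g <- length(regs); p_ <- length(pops)
  df <- c(g - 1, p_ - g, n - p_)
  sig_c <- ss_wp / df[3]
  np <- sapply(pops, function(p) sum(pop == p))
  nr <- sapply(regs, function(r) sum(reg == r))
  reg_of_pop <- sapply(pops, function(p) reg[pop == p][1])
  s_r <- sapply(regs, function(r) sum(np[reg_of_pop == r]^2) / nr[r])
  n1 <- (n - sum(s_r)) / df[2]
  n2 <- (sum(s_r) - sum(np^2) / n) / df[1]
  n3 <- (n - sum(nr^2) / n) / df[1]
  sig_b <- (ss_ap / df[2] - sig_c) / n1
  sig_a <- (ss_ag / df[1] - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(sigma = c(sig_a, sig_b, sig_c),
       phi = c(Phi_CT = sig_a / tot, Phi_SC = sig_b / (sig_b + sig_c),
               Phi_ST = (sig_a + sig_b) / tot))
}

# brute-force average pairwise difference count and per-site diversity
brute_pi <- function(seqs, len) {
  n <- length(seqs)
  ch <- strsplit(seqs, "")
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- ch[[i]]; b <- ch[[j]]
    ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
    tot <- tot + sum(a[ok] != b[ok])
  }
  k <- tot / choose(n, 2)
  c(pi = k / len, k = k)
}

# random small haplotype table whose reference row is its first haplotype
random_table <- function(seed, n_hap = 5, n_pos = 6, n_pop = 2, len = 40) {
  withr::with_seed(seed, {
    pos <- sort(sample(len, n_pos))
    repeat {
      states <- matrix(sample(c("A", "C", "G", "T"), n_hap * n_pos, TRUE),
                       n_hap, n_pos)
      distinct <- !anyDuplicated(apply(states, 1, paste, collapse = ""))
      variable <- all(apply(states, 2, function(s) length(unique(s)) >= 2))
      if (distinct && variable) break
    }
    counts <- matrix(rpois(n_hap * n_pop, 3) + 1L, n_hap, n_pop,
                     dimnames = list(paste0("Hap_", 1:n_hap),
                                     paste0("P", 1:n_pop)))
    haplotype_table(pos, states[1, ], states, counts)
  })
}

# write a small aligned FASTA + population map, return the two paths
write_fixture_fasta <- function(seqs, pops, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "aln.fa"); pm <- file.path(dir, "popmap.tsv")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fa)
  utils::write.table(data.frame(id = names(seqs), population = pops),
                     pm, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fa, popmap = pm)
}
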