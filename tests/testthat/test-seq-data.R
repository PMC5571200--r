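test_that("read_alignment parses, trims, and validates", {
  seqs <- setNames(replicate(15, paste(sample(c("A", "C", "G", "T"), 655,
                                              TRUE), collapse = "")),
                   paste0("s", 1:15))
  paths <- write_fixture_fasta(seqs, rep(c("P1", "P2", "P3"), each = 5))
  a <- read_alignment(paths["fasta"], paths["popmap"], trim_to = 604)
  expect_equal(a$length, 604)
  expect_equal(length(a$seqs), 15)

  # two identical records under distinct ids are two members
  paths2 <- write_fixture_fasta(c(x = "ACGT", y = "ACGT"), c("P1", "P1"))
  expect_equal(length(read_alignment(paths2["fasta"], paths2["popmap"])$seqs), 2)

  # empty FASTA
  empty <- withr::local_tempfile(fileext = ".fa"); file.create(empty)
  expect_error(read_alignment(empty, paths2["popmap"]), "no sequences")

  # ragged alignment names the offending id
  paths3 <- write_fixture_fasta(c(ok = "ACGTAC", short = "ACG"), c("P1", "P1"))
  expect_error(read_alignment(paths3["fasta"], paths3["popmap"]), "short")

  # unknown characters and unlabeled ids are rejected
  paths4 <- write_fixture_fasta(c(z = "ACXT"), "P1")
  expect_error(read_alignment(paths4["fasta"], paths4["popmap"]), "unknown char")
  paths5 <- write_fixture_fasta(c(u = "ACGT", v = "ACGT"), c("P1", "P1"))
  pm <- read.delim(paths5["popmap"]); pm <- pm[pm$id != "v", ]
  write.table(pm, paths5["popmap"], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignment(paths5["fasta"], paths5["popmap"]), "unlabeled.*v")
})

test_that("collapse and expand are mutually inverse on haplotype content", {
  # monomorphic alignment collapses to one haplotype, zero variable sites
  mono <- seq_alignment(setNames(rep(strrep("ACGT", 5), 10),
                                 paste0("m", 1:10)), rep("P1", 10))
  t0 <- collapse_haplotypes(mono)
  expect_equal(nrow(t0$states), 1)
  expect_length(t0$positions, 0)

  # collapse is idempotent through a round trip, counts preserved
  for (s in c(11, 22, 33)) {
    t <- random_table(s)
    a <- expand_table(t, total_length = 40)
    expect_equal(length(a$seqs), sum(t$counts))
    t2 <- collapse_haplotypes(a)
    # same variable positions and per-population counts, up to haplotype order
    expect_equal(t2$positions, t$positions)
    key <- function(x) apply(x$states, 1, paste, collapse = "")
    ord <- match(key(t), key(t2))
    expect_false(anyNA(ord))
    expect_equal(unname(t2$counts[ord, colnames(t$counts)]), unname(t$counts))
    # collapsing the re-expansion changes nothing further
    t3 <- collapse_haplotypes(expand_table(t2, 40))
    expect_equal(t3$states, t2$states)
    expect_equal(t3$counts, t2$counts)
  }

  # single haplotype, count 1
  t1 <- coi_haplotype_table()
  one <- t1; one$counts <- matrix(c(1L, rep(0L, 14)), ncol = 1,
                                  dimnames = list(rownames(t1$counts), "NW"))
  expect_equal(length(expand_table(one, 604)$seqs), 1)
})

test_that("frequency regeneration conserves totals by largest remainder", {
  # the published example: 80% of 291 gives 233 copies
  a <- regenerate_from_frequencies(
    data.frame(haplotype = c("H1", "H2"), frequency = c(0.8, 0.2)),
    c(H1 = "AAAA", H2 = "AAAT"), total_n = 291)
  expect_equal(unname(attr(a, "counts")["H1"]), 233)
  expect_equal(length(a$seqs), 291)

  # single haplotype at 100%
  b <- regenerate_from_frequencies(
    data.frame(haplotype = "H", frequency = 1), c(H = "ACGT"), 50)
  expect_equal(length(b$seqs), 50)

  # {0.5, 0.5} of 7: first-listed keeps the extra copy
  expect_message(
    cc <- regenerate_from_frequencies(
      data.frame(haplotype = c("A", "B"), frequency = c(0.5, 0.5)),
      c(A = "AAAA", B = "TTTT"), 7),
    "largest-remainder")
  expect_equal(unname(attr(cc, "counts")), c(4L, 3L))

  expect_error(regenerate_from_frequencies(
    data.frame(haplotype = "H", frequency = 0.5), c(H = "ACGT"), 10),
    "1%")
})

test_that("diagnostic sites require fixation inside and absence outside", {
  pos <- c(3L, 7L, 9L)
  states <- rbind(A1 = c("A", "C", "G"),
                  A2 = c("A", "T", "T"),
                  B1 = c("G", "C", "G"))
  counts <- cbind(P1 = c(5L, 2L, 0L), P2 = c(0L, 0L, 4L))
  t <- haplotype_table(pos, states[1, ], states, counts)
  d <- find_diagnostic_sites(t, focal = "P1")
  # site 3 separates P1 (all A) from P2 (G); sites 7 and 9 vary inside P1
  # and share states with P2
  expect_equal(d$position, 3L)
  expect_equal(d$state, "A")
  # symmetric call for the complement finds the same position, other state
  d2 <- find_diagnostic_sites(t, focal = "P2")
  expect_true(3L %in% d2$position)
  # diagnostic sites are always a subset of the variable positions
  expect_true(all(d$position %in% t$positions))

  # missing states are ignored when testing fixedness; an all-missing focal
  # column is an error
  states_n <- rbind(A1 = c("A", "N", "G"), A2 = c("A", "N", "T"),
                    B1 = c("G", "T", "G"))
  tn <- haplotype_table(pos, c("A", "C", "G"), states_n, counts)
  expect_error(find_diagnostic_sites(tn, focal = "P1"), "missing data.*7")
  expect_error(find_diagnostic_sites(t, focal = "nope"), "unknown")
})

test_that("haplotype reports round-trip and use dot notation", {
  t <- coi_haplotype_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_report(t, path)
  # the most common Southern haplotype differs from the reference at
  # exactly two scored positions
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  hap8 <- raw[raw$haplotype == "Hap_8", -(1:4)]
  expect_equal(sum(hap8 != "."), 2)
  ref <- raw[raw$haplotype == "reference", -(1:4)]
  expect_equal(sum(ref == "."), 0)
  # round trip preserves the table
  t2 <- read_haplotype_table(path)
  expect_equal(t2$positions, t$positions)
  expect_equal(t2$states, t$states)
  expect_equal(t2$counts[rownames(t$counts), colnames(t$counts)], t$counts)
  expect_equal(t2$ref_states, t$ref_states)
})
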