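#' Codominant multilocus genotype matrix
#'
#' Holds diploid codominant genotypes (e.g. microsatellite allele sizes) as
#' two integer allele matrices. A genotype is missing when either allele is
#' missing; missing individuals are excluded locus-wise from all estimators.
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele codes; `NA`
#'   (or 0 in file input) marks a missing allele. Dimnames give individual ids
#'   and locus names.
#' @param pop Character vector of population labels, one per individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, pop) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2))) stop("allele matrices differ in shape")
  if (length(pop) != nrow(a1)) stop("one population label per individual needed")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  if (is.null(rownames(a1))) rownames(a1) <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(colnames(a1))) colnames(a1) <- paste0("loc", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  structure(list(a1 = a1, a2 = a2, pop = as.character(pop)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$a1), "individuals x", ncol(x$a1), "loci;",
      length(unique(x$pop)), "population(s)\n")
  invisible(x)
}

#' Read a wide two-column-per-locus genotype table
#'
#' GenAlEx-style layout: columns `id`, `population`, then two columns per
#' locus holding integer allele codes; `0`, blank or `NA` mark a missing
#' allele.
#'
#' @param path CSV (default) or TSV path.
#' @param sep Field separator.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(d)))
    stop("genotype table needs 'id' and 'population' columns")
  al <- as.matrix(d[, setdiff(names(d), c("id", "population")), drop = FALSE])
  storage.mode(al) <- "integer"
  if (ncol(al) %% 2L != 0L) stop("expected two allele columns per locus")
  al[al == 0L] <- NA
  odd <- seq(1L, ncol(al), by = 2L)
  loci <- sub("(\\.|_)?[12ab]$", "", colnames(al)[odd])
  a1 <- al[, odd, drop = FALSE]; a2 <- al[, odd + 1L, drop = FALSE]
  dimnames(a1) <- dimnames(a2) <- list(d$id, loci)
  genotype_matrix(a1, a2, d$population)
}

#' Write a genotype matrix in the wide two-column layout
#'
#' @param g A [genotype_matrix].
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(g, path, sep = ",") {
  L <- ncol(g$a1)
  out <- data.frame(id = rownames(g$a1), population = g$pop)
  for (j in seq_len(L)) {
    out[[paste0(colnames(g$a1)[j], ".1")]] <- ifelse(is.na(g$a1[, j]), 0L, g$a1[, j])
    out[[paste0(colnames(g$a1)[j], ".2")]] <- ifelse(is.na(g$a2[, j]), 0L, g$a2[, j])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
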