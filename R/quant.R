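#' Total ion current normalization
#'
#' Each run (column) is divided by its total signal and rescaled by the
#' mean column sum so the matrix keeps its magnitude scale; after
#' normalization all column sums are equal.
#'
#' @param m non-negative numeric matrix, precursors x runs.
#' @return normalized matrix.
#' @export
tic_normalize <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  cs <- colSums(m)
  if (any(cs <= 0)) stop("zero total ion current in column(s): ",
                         paste(which(cs <= 0), collapse = ", "))
  sweep(m, 2L, cs, "/") * mean(cs)
}

#' Differential abundance between two groups
#'
#' Welch two-sample t-test on `log2(area + pseudocount)` per precursor,
#' with Benjamini-Hochberg control over all tested precursors. The
#' pseudocount is half the smallest nonzero value of the matrix. Precursors
#' constant within both groups get p = 1 by convention.
#'
#' @param m abundance matrix, precursors x runs (rownames identify
#'   precursors).
#' @param groups character vector of group labels, one per column.
#' @param group_a,group_b the two labels to compare; the log2 fold change
#'   is `mean(group_a) - mean(group_b)` on the log scale.
#' @param alpha BH-adjusted significance threshold.
#' @return data.frame: precursor, log2_fc, p, adj_p, significant.
#' @export
differential_abundance <- function(m, groups, group_a, group_b,
                                   alpha = 0.05) {
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per group")
  nz <- m[m > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else 1
  lm2 <- log2(m + pseudo)
  res <- t(apply(lm2, 1L, function(x) {
    a <- x[ia]; b <- x[ib]
    fc <- mean(a) - mean(b)
    if (var(a) == 0 && var(b) == 0)
      return(c(fc = fc, p = if (mean(a) == mean(b)) 1 else 0))
    c(fc = fc, p = t.test(a, b)$p.value)
  }))
  adj <- p.adjust(res[, "p"], method = "BH")
  data.frame(precursor = rownames(m), log2_fc = res[, "fc"],
             p = res[, "p"], adj_p = adj, significant = adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allele frequency from a genotype tally
#'
#' @param n_alleles_of_interest observed allele count.
#' @param n_individuals genotyped individuals (diploid).
#' @return percent, rounded to 0.1.
#' @examples
#' allele_frequency(4, 19)  # 10.5
#' allele_frequency(8, 9)   # 44.4
#' @export
allele_frequency <- function(n_alleles_of_interest, n_individuals) {
  stopifnot(n_individuals > 0,
            n_alleles_of_interest >= 0,
            n_alleles_of_interest <= 2 * n_individuals)
  round(100 * n_alleles_of_interest / (2 * n_individuals), 1)
}
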