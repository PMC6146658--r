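#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index comparing two labelings of the same
#' items; 1 means identical partitions, 0 is the chance expectation. Used in
#' parameter-recovery checks of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any type coercible to factor).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
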