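#' Pipeline configuration
#'
#' Collects the tunable thresholds of the analysis with their defaults:
#' grey-correlation resolution ratio rho = 0.5, co-expression edge threshold
#' 0.94, differential-expression probability cutoff 0.6 and |log2 fold change|
#' cutoff 1, Bonferroni-adjusted enrichment alpha 0.05, and 1500-bp promoters.
#'
#' @param gcc_rho resolution ratio for the grey correlation coefficient,
#'   in (0, 1].
#' @param gcc_threshold co-expression edge threshold on the GCC, in (0, 1].
#' @param deg_prob_threshold minimum differential-expression probability.
#' @param deg_log2fc_threshold minimum |log2 fold change| (inclusive).
#' @param fdr_alpha Bonferroni-adjusted significance level for enrichment.
#' @param promoter_length promoter length in bp upstream of the TSS.
#' @param crucial_go_terms character vector of stimulus-response GO BP term
#'   ids or name keywords used for crucial-DEG selection.
#' @param seed integer random seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(gcc_rho = 0.5,
                            gcc_threshold = 0.94,
                            deg_prob_threshold = 0.6,
                            deg_log2fc_threshold = 1.0,
                            fdr_alpha = 0.05,
                            promoter_length = 1500L,
                            crucial_go_terms = default_crucial_terms(),
                            seed = 1L) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x > 1)
      stop(nm, " must be a single value in (0, 1]")
  }
  chk01(gcc_rho, "gcc_rho")
  chk01(gcc_threshold, "gcc_threshold")
  chk01(deg_prob_threshold, "deg_prob_threshold")
  chk01(fdr_alpha, "fdr_alpha")
  if (!is.numeric(deg_log2fc_threshold) || deg_log2fc_threshold < 0)
    stop("deg_log2fc_threshold must be non-negative")
  if (!is.numeric(promoter_length) || promoter_length <= 0)
    stop("promoter_length must be positive")
  structure(list(
    gcc_rho = gcc_rho, gcc_threshold = gcc_threshold,
    deg_prob_threshold = deg_prob_threshold,
    deg_log2fc_threshold = deg_log2fc_threshold,
    fdr_alpha = fdr_alpha, promoter_length = as.integer(promoter_length),
    crucial_go_terms = crucial_go_terms, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Default crucial-term keyword list
#'
#' A reconstruction of a stimulus-response biological-process keyword list
#' used to retain "crucial" DEGs; it is configuration, not ground truth, and
#' should be replaced by a curated term list for real analyses.
#'
#' @return character vector of keywords matched against GO term names.
#' @export
default_crucial_terms <- function() {
  c("response to stimulus", "response to stress", "response to cold",
    "response to heat", "response to water deprivation", "response to salt",
    "response to abscisic acid", "response to osmotic stress",
    "abiotic stimulus", "hormone")
}
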