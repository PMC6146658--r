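# Relative expression, a simplified noise-distribution differential-expression
# probability, DEG filtering and set summaries, crucial-DEG selection, and the
# 2^-dCt qRT-PCR transform.

#' Relative expression (log2 fold change vs control)
#'
#' For each gene and treatment, log2((mean treatment FPKM + c) /
#' (mean control FPKM + c)) where c is a pseudocount that bounds the fold
#' change at zero counts.
#'
#' @param em an [expression_matrix()].
#' @param pseudocount positive pseudocount c (default 1 FPKM).
#' @return gene x treatment matrix of class `relative_expression` with
#'   attribute `pseudocount`.
#' @export
relative_expression <- function(em, pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"), pseudocount > 0)
  trts <- treatments(em)
  ctrl_cols <- em$samples$sample[em$samples$condition == em$control]
  ctrl_mean <- rowMeans(em$fpkm[, ctrl_cols, drop = FALSE])
  out <- vapply(trts, function(t) {
    cols <- em$samples$sample[em$samples$condition == t]
    if (length(cols) == 0) stop("treatment ", t, " has zero replicates")
    log2((rowMeans(em$fpkm[, cols, drop = FALSE]) + pseudocount) /
         (ctrl_mean + pseudocount))
  }, numeric(nrow(em$fpkm)))
  out <- matrix(out, nrow = nrow(em$fpkm),
                dimnames = list(rownames(em$fpkm), trts))
  structure(out, pseudocount = pseudocount, class = c("relative_expression", "matrix"))
}

#' Noise-distribution differential-expression probability
#'
#' A simplified analogue of a noise-based DE probability: for each gene the
#' signal statistics are M = |log2 ratio of condition means| and
#' D = |difference of condition means|; the noise distribution pools the same
#' statistics over every within-condition replicate pair across all genes and
#' conditions; the probability is the fraction of noise points strictly
#' dominated by the signal (M_noise < M and D_noise < D). This is a documented
#' simplification, not a re-implementation of the published method it stands
#' in for.
#'
#' @param em an [expression_matrix()].
#' @param treatment treatment condition to contrast against the control.
#' @param pseudocount pseudocount for log ratios.
#' @return named numeric vector of probabilities in \[0, 1\], one per gene.
#' @export
noise_probability <- function(em, treatment, pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  conds <- unique(em$samples$condition)
  reps_per <- table(em$samples$condition)
  if (all(reps_per < 2))
    stop("noise distribution undefined: no condition has >= 2 replicates")
  if (sum(em$samples$condition == em$control) < 2)
    stop("need >= 2 replicates in the control condition")
  t_cols <- em$samples$sample[em$samples$condition == treatment]
  c_cols <- em$samples$sample[em$samples$condition == em$control]
  if (length(t_cols) == 0) stop("unknown treatment: ", treatment)

  mt <- rowMeans(em$fpkm[, t_cols, drop = FALSE])
  mc <- rowMeans(em$fpkm[, c_cols, drop = FALSE])
  M <- abs(log2((mt + pseudocount) / (mc + pseudocount)))
  D <- abs(mt - mc)

  noise_M <- list(); noise_D <- list()
  for (cond in conds) {
    cols <- em$samples$sample[em$samples$condition == cond]
    if (length(cols) < 2) next
    prs <- utils::combn(cols, 2)
    for (j in seq_len(ncol(prs))) {
      x <- em$fpkm[, prs[1, j]]; y <- em$fpkm[, prs[2, j]]
      noise_M[[length(noise_M) + 1L]] <- abs(log2((x + pseudocount) / (y + pseudocount)))
      noise_D[[length(noise_D) + 1L]] <- abs(x - y)
    }
  }
  nM <- unlist(noise_M, use.names = FALSE)
  nD <- unlist(noise_D, use.names = FALSE)
  # strict double dominance, chunked so memory stays linear in the noise pool
  probs <- numeric(length(M))
  chunk <- max(1L, floor(5e6 / length(nM)))
  for (s in seq(1, length(M), by = chunk)) {
    e <- min(s + chunk - 1L, length(M))
    dom <- outer(M[s:e], nM, ">") & outer(D[s:e], nD, ">")
    probs[s:e] <- rowMeans(dom)
  }
  setNames(probs, rownames(em$fpkm))
}

#' Noise probabilities for every treatment
#'
#' @param em an [expression_matrix()].
#' @param pseudocount pseudocount for log ratios.
#' @return gene x treatment matrix of probabilities.
#' @export
noise_probability_matrix <- function(em, pseudocount = 1) {
  trts <- treatments(em)
  out <- vapply(trts, function(t) noise_probability(em, t, pseudocount),
                numeric(nrow(em$fpkm)))
  matrix(out, nrow = nrow(em$fpkm), dimnames = list(rownames(em$fpkm), trts))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG under a treatment iff probability >= `prob_threshold` and
#' |log2FC| >= `log2fc_threshold` (both boundaries inclusive by default; set
#' `inclusive_fc = FALSE` for a strict fold-change inequality). A log2FC of
#' exactly 0 is assigned no direction.
#'
#' @param rel relative-expression matrix from [relative_expression()].
#' @param probs gene x treatment probability matrix
#'   (e.g. [noise_probability_matrix()]), or one read from file.
#' @param prob_threshold probability cutoff (default 0.6, inclusive).
#' @param log2fc_threshold |log2FC| cutoff (default 1).
#' @param inclusive_fc treat the fold-change boundary as inclusive.
#' @return data.frame of calls: gene_id, treatment, probability, log2fc,
#'   direction, is_deg.
#' @export
call_degs <- function(rel, probs, prob_threshold = 0.6, log2fc_threshold = 1,
                      inclusive_fc = TRUE) {
  stopifnot(identical(rownames(rel), rownames(probs)),
            identical(colnames(rel), colnames(probs)))
  long <- expand.grid(gene_id = rownames(rel), treatment = colnames(rel),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$probability <- probs[cbind(long$gene_id, long$treatment)]
  long$log2fc <- rel[cbind(long$gene_id, long$treatment)]
  long$direction <- ifelse(long$log2fc > 0, "up",
                           ifelse(long$log2fc < 0, "down", NA_character_))
  fc_ok <- if (inclusive_fc) abs(long$log2fc) >= log2fc_threshold
           else abs(long$log2fc) > log2fc_threshold
  long$is_deg <- long$probability >= prob_threshold & fc_ok
  long
}

#' DEG counts over a probability-threshold sweep
#'
#' @param rel relative-expression matrix.
#' @param probs probability matrix.
#' @param prob_grid probability thresholds to sweep.
#' @param log2fc_threshold |log2FC| cutoff held fixed.
#' @return data.frame: threshold, treatment, n_up, n_down, n_deg.
#' @export
deg_threshold_sweep <- function(rel, probs,
                                prob_grid = seq(0.5, 0.95, by = 0.05),
                                log2fc_threshold = 1) {
  rows <- lapply(prob_grid, function(p) {
    calls <- call_degs(rel, probs, p, log2fc_threshold)
    agg <- by(calls, calls$treatment, function(d) {
      data.frame(threshold = p, treatment = d$treatment[1],
                 n_up = sum(d$is_deg & d$direction == "up", na.rm = TRUE),
                 n_down = sum(d$is_deg & d$direction == "down", na.rm = TRUE),
                 n_deg = sum(d$is_deg), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Venn-style membership summary of DEG calls
#'
#' Counts, over all treatments, every non-empty membership class (which
#' combination of treatments a gene is a DEG under). Genes that are DEGs
#' under no treatment are excluded.
#'
#' @param calls DEG-call data.frame from [call_degs()], optionally with a
#'   `family` column for per-family totals.
#' @return list: `classes` (data.frame members/count), `n_deg_genes`,
#'   `n_multi` (DEG under >= 2 treatments), and `per_family_unique` when
#'   family labels are present.
#' @export
venn_summary <- function(calls) {
  deg <- calls[calls$is_deg, , drop = FALSE]
  membership <- tapply(deg$treatment, deg$gene_id, function(t)
    paste(sort(unique(t)), collapse = "+"))
  classes <- as.data.frame(table(members = membership), stringsAsFactors = FALSE)
  names(classes) <- c("members", "count")
  per_family <- NULL
  if ("family" %in% names(calls) && nrow(deg) > 0) {
    fam <- tapply(deg$family, deg$gene_id, `[`, 1L)
    per_family <- table(fam)
  }
  n_treat_per_gene <- tapply(deg$treatment, deg$gene_id,
                             function(t) length(unique(t)))
  list(classes = classes,
       n_deg_genes = length(membership),
       n_multi = sum(n_treat_per_gene >= 2),
       per_family_unique = per_family)
}

#' Select crucial DEGs by stimulus-response annotation
#'
#' A DEG is crucial iff it carries at least one annotation matching the
#' configured crucial-term list (matched against GO term ids exactly, and
#' against term names as case-insensitive substrings). An empty term list is
#' an error: silent pass-through is forbidden.
#'
#' @param calls DEG-call data.frame from [call_degs()].
#' @param go_table annotation data.frame with columns `gene_id`, `term`, and
#'   optionally `name`.
#' @param crucial_terms character vector of term ids and/or name keywords.
#' @return `calls` with an added logical `is_crucial` column.
#' @export
select_crucial <- function(calls, go_table, crucial_terms) {
  if (length(crucial_terms) == 0)
    stop("crucial_terms is empty; refusing silent pass-through")
  hit <- go_table$term %in% crucial_terms
  if ("name" %in% names(go_table)) {
    pat <- paste(vapply(tolower(crucial_terms),
                        function(k) gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", k), ""),
                 collapse = "|")
    hit <- hit | grepl(pat, tolower(go_table$name))
  }
  crucial_genes <- unique(go_table$gene_id[hit])
  calls$is_crucial <- calls$is_deg & calls$gene_id %in% crucial_genes
  calls
}

#' Per-treatment and per-family crucial-DEG tallies
#'
#' @param calls call data.frame carrying `is_crucial` (and optionally
#'   `family`).
#' @return list: `per_treatment` (distinct crucial genes per treatment),
#'   `total` (distinct crucial genes overall), and `per_family_treatment`
#'   when family labels are present.
#' @export
crucial_summary <- function(calls) {
  cr <- calls[calls$is_crucial, , drop = FALSE]
  per_trt <- tapply(cr$gene_id, cr$treatment, function(g) length(unique(g)))
  per_trt <- per_trt[!is.na(per_trt)]
  out <- list(per_treatment = per_trt, total = length(unique(cr$gene_id)))
  if ("family" %in% names(cr) && nrow(cr) > 0) {
    out$per_family_treatment <- table(cr$family, cr$treatment)
    fam <- tapply(cr$family, cr$gene_id, `[`, 1L)
    out$per_family_total <- table(fam)
  }
  out
}

#' qRT-PCR relative expression (2^-dCt)
#'
#' @param delta_ct finite cycle-threshold difference(s).
#' @return 2^(-delta_ct).
#' @export
ddct <- function(delta_ct) {
  if (any(!is.finite(delta_ct))) stop("delta_ct must be finite")
  2^(-delta_ct)
}

#' Cluster relative-expression profiles
#'
#' Genes are clustered by Euclidean distance, treatments by 1 - Kendall's tau
#' correlation, both with average linkage. A constant treatment column has
#' undefined tau; its distance is set to 1 (with a message).
#'
#' @param rel relative-expression matrix (>= 2 genes, >= 2 treatments).
#' @return list: `genes` and `arrays` ([stats::hclust] objects), plus
#'   `gene_order` and `array_order` leaf orders.
#' @export
cluster_expression <- function(rel) {
  m <- unclass(rel)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 genes and >= 2 treatments")
  hg <- stats::hclust(stats::dist(m), method = "average")
  tau <- suppressWarnings(stats::cor(m, method = "kendall"))
  if (anyNA(tau)) {
    message("constant treatment column: undefined tau treated as distance 1")
    tau[is.na(tau)] <- 0
  }
  ha <- stats::hclust(stats::as.dist(1 - tau), method = "average")
  list(genes = hg, arrays = ha,
       gene_order = rownames(m)[hg$order], array_order = colnames(m)[ha$order])
}
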