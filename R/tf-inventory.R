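# Rule-based TF family/subfamily assignment from domain-hit tables.
#
# Signature domains: AP2 -> AP2/EREBP, bZIP_1/bZIP_2 -> bZIP, MYB -> MYB,
# NAM -> NAC, WRKY -> WRKY. WRKY calls additionally require a zinc-finger
# motif (C2H2 or C2HC); the accepted degenerate WRKY cores are WRRY, WSKY,
# WKRY, WVKY, WKKY and WKNY. B3 and zinc_finger are co-domains, not
# signatures.

.signature_map <- c(AP2 = "AP2/EREBP", bZIP_1 = "bZIP", bZIP_2 = "bZIP",
                    MYB = "MYB", NAM = "NAC", WRKY = "WRKY")

.wrky_cores <- c("WRKY", "WRRY", "WSKY", "WKRY", "WVKY", "WKKY", "WKNY")

.is_wrky_core <- function(variant) {
  v <- toupper(substr(as.character(variant), 1, 4))
  v[is.na(variant) | variant == ""] <- "WRKY"  # unannotated core treated canonical
  v %in% .wrky_cores
}

.zf_type <- function(hits) {
  zf <- hits[hits$domain_name == "zinc_finger", , drop = FALSE]
  types <- toupper(as.character(zf$variant))
  if (any(types == "C2H2")) "C2H2" else if (any(types == "C2HC")) "C2HC" else NA_character_
}

#' Classify one gene into a TF family from its domain hits
#'
#' A family is assigned when at least one qualifying hit of the family's
#' signature domain survives the E-value cutoff. WRKY genes must carry both a
#' WRKY domain (canonical or accepted degenerate core) and a zinc-finger
#' motif; a WRKY domain without the zinc finger is rejected. Hits of signature
#' domains from more than one family yield family "none" with reason
#' "ambiguous".
#'
#' @param hits data.frame of domain hits for one gene, with columns
#'   `gene_id`, `domain_name`, `start`, `end`, `e_value`, `variant`.
#' @param e_value_cutoff qualifying E-value cutoff (default 1e-5; hits with
#'   `e_value < cutoff` qualify).
#' @return one-row data.frame: gene_id, family, subfamily (NA), rejection_reason.
#' @export
classify_family <- function(hits, e_value_cutoff = 1e-5) {
  gene <- if (nrow(hits) > 0) as.character(hits$gene_id[1]) else NA_character_
  call <- function(family, reason = NA_character_)
    data.frame(gene_id = gene, family = family, subfamily = NA_character_,
               rejection_reason = reason, stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(call("none", "no qualifying domains"))
  if (length(unique(hits$gene_id)) > 1)
    stop("classify_family expects hits for a single gene")
  ok <- hits$e_value < e_value_cutoff
  hits <- hits[ok, , drop = FALSE]
  # degenerate-core filtering: a WRKY-named hit with a non-accepted core
  # variant is not a WRKY domain match
  drop <- hits$domain_name == "WRKY" & !.is_wrky_core(hits$variant)
  hits <- hits[!drop, , drop = FALSE]
  sig <- hits$domain_name[hits$domain_name %in% names(.signature_map)]
  fams <- unique(unname(.signature_map[sig]))
  if (length(fams) == 0) return(call("none", "no qualifying domains"))
  if (length(fams) > 1) return(call("none", "ambiguous"))
  if (fams == "WRKY" && is.na(.zf_type(hits)))
    return(call("none", "missing zinc finger"))
  call(fams)
}

#' Fill in the subfamily of a family call
#'
#' AP2/EREBP: two AP2 domains gives AP2; one AP2 plus a B3 domain gives RAV;
#' a single AP2 gives "EREBP-unresolved" (the DREB-vs-ERF split and lettered
#' subgroups require phylogeny and are consumed as annotation input). WRKY:
#' two WRKY domains + C2H2 gives I, one WRKY + C2H2 gives II, one WRKY + C2HC
#' gives III. MYB: 1/2/3/4 repeats give 1R/R2R3/3R/4R. bZIP and NAC
#' subfamilies are annotation pass-through.
#'
#' @param call one-row family call from [classify_family()].
#' @param hits the gene's domain hits (same table passed to
#'   [classify_family()]).
#' @param e_value_cutoff qualifying E-value cutoff.
#' @param annotation optional externally supplied subfamily label (used for
#'   bZIP/NAC and for resolving EREBP subgroups).
#' @return the call with `subfamily` filled.
#' @export
classify_subfamily <- function(call, hits, e_value_cutoff = 1e-5,
                               annotation = NA_character_) {
  if (call$family == "none") return(call)
  hits <- hits[hits$e_value < e_value_cutoff, , drop = FALSE]
  n_dom <- function(d) sum(hits$domain_name == d)
  sub <- switch(call$family,
    "AP2/EREBP" = {
      n <- n_dom("AP2")
      if (n >= 3) "unresolved"
      else if (n == 2) "AP2"
      else if (n == 1 && n_dom("B3") >= 1) "RAV"
      else if (n == 1) {
        if (!is.na(annotation) && nzchar(annotation)) annotation else "EREBP-unresolved"
      } else "unresolved"
    },
    "WRKY" = {
      n <- sum(hits$domain_name == "WRKY" & .is_wrky_core(hits$variant))
      zf <- .zf_type(hits)
      if (n > 2 || is.na(zf)) "unresolved"
      else if (n == 2 && zf == "C2H2") "I"
      else if (n == 1 && zf == "C2H2") "II"
      else if (n == 1 && zf == "C2HC") "III"
      else "unresolved"
    },
    "MYB" = {
      n <- n_dom("MYB")
      if (n == 1) "1R" else if (n == 2) "R2R3"
      else if (n == 3) "3R" else if (n == 4) "4R" else "unresolved"
    },
    # bZIP / NAC: annotation pass-through only
    if (!is.na(annotation) && nzchar(annotation)) annotation else NA_character_
  )
  if (identical(sub, "unresolved"))
    message("gene ", call$gene_id, ": inconsistent domain counts, subfamily unresolved")
  call$subfamily <- sub
  call
}

#' Classify all genes in a domain-hit table
#'
#' @param hit_table data.frame of domain hits for many genes.
#' @param e_value_cutoff qualifying E-value cutoff.
#' @param annotations optional data.frame (gene_id, subfamily) of
#'   phylogeny-derived subfamily annotations.
#' @return data.frame of family calls, one row per gene.
#' @export
classify_families <- function(hit_table, e_value_cutoff = 1e-5,
                              annotations = NULL) {
  genes <- unique(as.character(hit_table$gene_id))
  rows <- lapply(genes, function(g) {
    hits <- hit_table[hit_table$gene_id == g, , drop = FALSE]
    ann <- NA_character_
    if (!is.null(annotations)) {
      i <- match(g, annotations$gene_id)
      if (!is.na(i)) ann <- annotations$subfamily[i]
    }
    classify_subfamily(classify_family(hits, e_value_cutoff), hits,
                       e_value_cutoff, annotation = ann)
  })
  do.call(rbind, rows)
}

#' Per-chromosome gene counts for a family
#'
#' Unanchored genes (chromosome `NA`) are excluded from the matrix and
#' counted separately.
#'
#' @param records gene-record data.frame with columns `gene_id`, `family`,
#'   `chromosome`, `species`.
#' @param family family name to tally.
#' @param chromosomes optional character vector fixing the chromosome order;
#'   a record with a chromosome outside this set is an error.
#' @return list with `counts` (species x chromosome integer matrix) and
#'   `unanchored` (named integer vector per species).
#' @export
chromosome_count_matrix <- function(records, family, chromosomes = NULL) {
  rec <- records[records$family == family, , drop = FALSE]
  anchored <- rec[!is.na(rec$chromosome), , drop = FALSE]
  unanch <- table(rec$species[is.na(rec$chromosome)])
  if (nrow(anchored) == 0) {
    return(list(counts = matrix(integer(0), nrow = 0, ncol = 0),
                unanchored = setNames(as.integer(unanch), names(unanch))))
  }
  chroms <- if (is.null(chromosomes)) sort(unique(anchored$chromosome)) else chromosomes
  if (!all(anchored$chromosome %in% chroms))
    stop("unknown chromosome label: ",
         paste(setdiff(anchored$chromosome, chroms), collapse = ", "))
  tab <- table(factor(anchored$species),
               factor(anchored$chromosome, levels = chroms))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  list(counts = m, unanchored = setNames(as.integer(unanch), names(unanch)))
}

#' Chi-squared homogeneity test of two chromosome count vectors
#'
#' Tests whether two per-chromosome count vectors share a common distribution,
#' using the pooled-margin homogeneity model without continuity correction.
#' Chromosomes with zero pooled counts are dropped (with a message).
#'
#' @param countsA,countsB equal-length non-negative integer vectors.
#' @param alpha significance level for the decision flag.
#' @return list: statistic, df, p_value, different (p < alpha), dropped.
#' @export
chromosome_homogeneity_test <- function(countsA, countsB, alpha = 0.05) {
  if (length(countsA) != length(countsB)) stop("count vectors differ in length")
  if (any(countsA < 0) || any(countsB < 0)) stop("counts must be non-negative")
  pooled <- countsA + countsB
  if (all(pooled == 0)) stop("all categories have zero pooled counts")
  drop <- pooled == 0
  if (any(drop)) message("dropping ", sum(drop), " zero-pooled categories")
  a <- countsA[!drop]; b <- countsB[!drop]
  ht <- suppressWarnings(stats::chisq.test(rbind(a, b), correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       different = unname(ht$p.value) < alpha, dropped = sum(drop))
}

#' Cluster chromosome count vectors
#'
#' Agglomerative clustering of count vectors with distance 1 - Pearson
#' correlation and average linkage. A constant row has undefined correlation;
#' its distance to every other row is set to 1 (with a message). Rows are
#' label-sorted before clustering so leaf order is deterministic under ties.
#'
#' @param count_matrix numeric matrix with at least two named rows.
#' @return list with `hclust` (an [stats::hclust] object) and `order`
#'   (leaf labels in dendrogram order).
#' @export
cluster_count_vectors <- function(count_matrix) {
  if (nrow(count_matrix) < 2) stop("need at least two rows to cluster")
  m <- count_matrix[order(rownames(count_matrix)), , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(m)))
  if (anyNA(cc)) {
    message("constant row(s): undefined correlation treated as distance 1")
    cc[is.na(cc)] <- 0
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = rownames(m)[hc$order])
}
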