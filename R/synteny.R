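# Categorization of genes from cross-species homologous sets into
# novel / conserved / multi-copy / lost, and the summary statistics over
# families and sub-genomes.

#' Categorize genes from homologous sets
#'
#' Categories, defined against the focal species and its two direct
#' ancestors:
#' \itemize{
#'   \item novel: a focal gene whose set contains no ancestor member;
#'   \item conserved: a focal gene whose set has exactly one copy in the focal
#'     species and in each of both ancestors;
#'   \item multi_copy: all focal members of any set where some species
#'     (focal or ancestor) contributes two or more members — this takes
#'     precedence over novel (flagged);
#'   \item lost: an ancestor gene whose set contains no focal member
#'     (attributed to that ancestor's sub-genome).
#' }
#' Outgroup members (e.g. A. thaliana) are carried along but do not affect
#' the category logic. A focal gene fitting none of the definitions (single
#' copy with only one ancestor represented) is returned as `unclassified`.
#'
#' @param sets data.frame with columns `set_id`, `species`, `gene_id`.
#' @param focal_species focal species name (default "B. napus").
#' @param ancestor_species the two direct ancestors, in sub-genome order
#'   (A then C).
#' @param records optional gene-record data.frame supplying `family`,
#'   `subfamily` and `chromosome` (for sub-genome assignment) of focal genes.
#' @return data.frame of category calls: gene_id, species, category,
#'   sub_genome, family, subfamily, flagged.
#' @export
categorize_homolog_sets <- function(sets,
                                    focal_species = "B. napus",
                                    ancestor_species = c("B. rapa", "B. oleracea"),
                                    records = NULL) {
  stopifnot(all(c("set_id", "species", "gene_id") %in% names(sets)))
  if (anyDuplicated(sets$gene_id) > 0) {
    dup <- unique(sets$gene_id[duplicated(sets$gene_id)])
    stop("gene in two sets: ", paste(utils::head(dup, 3), collapse = ", "))
  }
  core <- sets[sets$species %in% c(focal_species, ancestor_species), , drop = FALSE]
  out <- vector("list", length(unique(core$set_id)))
  i <- 0L
  for (sid in unique(core$set_id)) {
    s <- core[core$set_id == sid, , drop = FALSE]
    copies <- table(factor(s$species, levels = c(focal_species, ancestor_species)))
    n_focal <- copies[[focal_species]]
    multi <- any(copies >= 2)
    rows <- NULL
    if (n_focal == 0) {
      anc <- s[s$species %in% ancestor_species, , drop = FALSE]
      rows <- data.frame(gene_id = anc$gene_id, species = anc$species,
                         category = "lost",
                         sub_genome = ifelse(anc$species == ancestor_species[1], "A", "C"),
                         flagged = FALSE, stringsAsFactors = FALSE)
    } else {
      foc <- s[s$species == focal_species, , drop = FALSE]
      no_anc <- sum(copies[ancestor_species]) == 0
      cat <- if (multi) "multi_copy"
             else if (no_anc) "novel"
             else if (all(copies == 1)) "conserved"
             else "unclassified"
      rows <- data.frame(gene_id = foc$gene_id, species = focal_species,
                         category = cat, sub_genome = NA_character_,
                         flagged = multi && no_anc, stringsAsFactors = FALSE)
    }
    i <- i + 1L
    out[[i]] <- rows
  }
  calls <- do.call(rbind, out)
  calls$family <- NA_character_
  calls$subfamily <- NA_character_
  if (!is.null(records)) {
    idx <- match(calls$gene_id, records$gene_id)
    calls$family <- records$family[idx]
    if ("subfamily" %in% names(records)) calls$subfamily <- records$subfamily[idx]
    if ("chromosome" %in% names(records)) {
      chr <- records$chromosome[idx]
      foc <- calls$species == focal_species
      calls$sub_genome[foc] <- sub_genome_from_chromosome(chr[foc])
    }
  }
  rownames(calls) <- NULL
  calls[, c("gene_id", "species", "category", "sub_genome",
            "family", "subfamily", "flagged")]
}

#' Sub-genome from a chromosome label
#'
#' `chrA*` maps to "A", `chrC*` to "C", anything else (including NA) to
#' "unplaced". Case-insensitive.
#'
#' @param chromosome character vector of chromosome labels.
#' @return character vector over \{"A", "C", "unplaced"\}.
#' @export
sub_genome_from_chromosome <- function(chromosome) {
  out <- rep("unplaced", length(chromosome))
  out[grepl("^chrA", chromosome, ignore.case = TRUE)] <- "A"
  out[grepl("^chrC", chromosome, ignore.case = TRUE)] <- "C"
  out
}

#' Summary statistics over category calls
#'
#' Tallies per-family counts per category and per-sub-genome lost counts, and
#' reports two fraction definitions per category: the unweighted mean over
#' families of (category count / family size), and the pooled fraction
#' (total category count / total size). Fractions are percentages.
#'
#' @param calls category-call data.frame from [categorize_homolog_sets()].
#' @param family_sizes named numeric vector of focal-species family sizes;
#'   if NULL, sizes are derived from the focal calls themselves.
#' @param focal_species focal species name.
#' @return list: `counts` (family x category), `lost_by_subgenome`,
#'   `lost_total`, `mean_fraction_pct` and `pooled_fraction_pct` per category.
#' @export
category_summary <- function(calls, family_sizes = NULL,
                             focal_species = "B. napus") {
  cats <- c("novel", "conserved", "multi_copy", "unclassified")
  foc <- calls[calls$species == focal_species, , drop = FALSE]
  fams <- if (!is.null(family_sizes)) names(family_sizes)
          else sort(unique(stats::na.omit(foc$family)))
  counts <- table(factor(foc$family, levels = fams),
                  factor(foc$category, levels = cats))
  counts <- matrix(as.integer(counts), nrow = length(fams),
                   dimnames = list(fams, cats))
  if (is.null(family_sizes)) family_sizes <- rowSums(counts)
  sizes <- as.numeric(family_sizes[fams])

  lost <- calls[calls$category == "lost", , drop = FALSE]
  lost_by_sg <- table(factor(lost$sub_genome, levels = c("A", "C")),
                      factor(lost$family, levels = fams))

  frac <- function(cat) {
    if (length(fams) == 0 || all(sizes == 0))
      return(c(mean = 0, pooled = 0))
    per <- 100 * counts[, cat] / sizes
    c(mean = round(mean(per), 1),
      pooled = round(100 * sum(counts[, cat]) / sum(sizes), 1))
  }
  fr <- vapply(cats, frac, c(mean = 0, pooled = 0))
  list(
    counts = counts,
    lost_by_subgenome = matrix(as.integer(lost_by_sg), nrow = 2,
                               dimnames = list(c("A", "C"), fams)),
    lost_total = c(A = sum(lost$sub_genome == "A", na.rm = TRUE),
                   C = sum(lost$sub_genome == "C", na.rm = TRUE),
                   total = nrow(lost)),
    mean_fraction_pct = fr["mean", ],
    pooled_fraction_pct = fr["pooled", ]
  )
}
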