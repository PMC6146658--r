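# IUPAC consensus scanning of fixed-length promoters for cis-regulatory
# elements, and distribution summaries per family / chromosome / subfamily.

.iupac_classes <- c(A = "A", C = "C", G = "G", T = "T",
                    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

.iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

.consensus_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!chars %in% names(.iupac_classes))
  if (length(bad) > 0)
    stop("invalid IUPAC code '", chars[bad[1]], "' at position ", bad[1],
         " of consensus ", consensus)
  # an N in the subject sequence only ever matches the consensus code N
  paste0(vapply(chars, function(ch) {
    cls <- .iupac_classes[[ch]]
    if (nchar(cls) == 1) cls else paste0("[", cls, "]")
  }, ""), collapse = "")
}

.revcomp_consensus <- function(consensus) {
  chars <- rev(strsplit(toupper(consensus), "")[[1]])
  paste0(.iupac_comp[chars], collapse = "")
}

#' Default cis-element consensus table
#'
#' PlantCARE-style consensus strings for ten commonly profiled stress and
#' hormone response elements. These consensi are editable configuration, not
#' ground truth: published element definitions vary between databases, and
#' users should supply their own table for real promoter sets.
#'
#' @return data.frame with columns `name`, `consensus`, `associated_response`.
#' @export
default_motif_table <- function() {
  data.frame(
    name = c("ABRE", "HSE", "LTR", "MBS", "TCA-element", "TGACG-motif",
             "TC-rich repeats", "P-box", "GARE-motif", "TGA-element"),
    consensus = c("TACGTG", "AGAAAATTCG", "CCGAAA", "CAACTG", "CCATCTTTTT",
                  "TGACG", "ATTTTCTTCA", "CCTTTTG", "TCTGTTG", "AACGAC"),
    associated_response = c("ABA responsiveness", "heat responsiveness",
                            "low-temperature responsiveness",
                            "drought inducibility (MYB binding)",
                            "salicylic acid responsiveness",
                            "MeJA responsiveness",
                            "defense and stress responsiveness",
                            "gibberellin responsiveness",
                            "gibberellin responsiveness",
                            "auxin responsiveness"),
    stringsAsFactors = FALSE
  )
}

#' Scan one promoter sequence for consensus motifs
#'
#' Reports every exact IUPAC-consensus occurrence; overlapping matches are
#' allowed. Reverse-strand hits are found by scanning the reverse-complemented
#' consensus on the forward sequence, so positions are always forward
#' coordinates of the match start. An `N` in the sequence matches only the
#' consensus code `N`.
#'
#' @param seq a nucleotide string over A/C/G/T/N (case-insensitive).
#' @param motifs motif table as from [default_motif_table()].
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param gene_id id recorded in the output.
#' @return data.frame of hits: gene_id, motif, position (1-based), strand.
#' @export
scan_promoter <- function(seq, motifs, both_strands = TRUE, gene_id = NA_character_) {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0)
    stop("invalid character '", substr(seq, bad, bad), "' at offset ", bad)
  empty <- data.frame(gene_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) == 0) return(empty)
  out <- list(empty)
  scan1 <- function(consensus, name, strand) {
    rx <- paste0("(?=", .consensus_regex(consensus), ")")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    pos <- as.integer(m[m > 0])
    if (length(pos) == 0) return(NULL)
    data.frame(gene_id = gene_id, motif = name, position = pos,
               strand = strand, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[i]
    out[[length(out) + 1L]] <- scan1(cons, motifs$name[i], "+")
    if (both_strands)
      out[[length(out) + 1L]] <- scan1(.revcomp_consensus(cons), motifs$name[i], "-")
  }
  res <- do.call(rbind, out)
  res[order(res$motif, res$position, res$strand), , drop = FALSE]
}

#' Scan a set of promoters
#'
#' @param seqs named character vector of promoter sequences.
#' @param motifs motif table.
#' @param both_strands scan both strands.
#' @return combined hit data.frame (see [scan_promoter()]).
#' @export
scan_promoters <- function(seqs, motifs, both_strands = TRUE) {
  hits <- lapply(names(seqs), function(g)
    scan_promoter(seqs[[g]], motifs, both_strands, gene_id = g))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Cis-element distribution summaries
#'
#' Per family, the proportion of genes carrying each motif at least once
#' (a gene counts once per motif regardless of hit multiplicity), plus count
#' matrices of motif-carrying genes by chromosome and by subfamily.
#'
#' @param hits hit data.frame from [scan_promoters()].
#' @param records gene-record data.frame (gene_id, family, subfamily,
#'   chromosome).
#' @return list with `proportions` (family x motif), `by_chromosome` and
#'   `by_subfamily` count matrices.
#' @export
element_distribution <- function(hits, records) {
  unknown <- setdiff(hits$gene_id, records$gene_id)
  if (length(unknown) > 0)
    stop("hit for unknown gene: ", paste(utils::head(unknown, 3), collapse = ", "))
  fams <- sort(unique(records$family))
  mots <- sort(unique(hits$motif))
  pres <- unique(hits[, c("gene_id", "motif")])
  idx <- match(pres$gene_id, records$gene_id)
  pres$family <- records$family[idx]
  pres$chromosome <- records$chromosome[idx]
  pres$subfamily <- records$subfamily[idx]

  count_by <- function(key) {
    keys <- sort(unique(stats::na.omit(key)))
    tab <- table(factor(key[!is.na(key)], levels = keys),
                 factor(pres$motif[!is.na(key)], levels = mots))
    matrix(as.integer(tab), nrow = length(keys),
           dimnames = list(keys, mots))
  }
  counts <- count_by(pres$family)
  sizes <- table(factor(records$family, levels = fams))
  props <- matrix(0, nrow = length(fams), ncol = length(mots),
                  dimnames = list(fams, mots))
  if (length(mots) > 0 && nrow(counts) > 0)
    props[rownames(counts), ] <- counts / as.numeric(sizes[rownames(counts)])
  list(proportions = props,
       by_chromosome = count_by(pres$chromosome),
       by_subfamily = count_by(pres$subfamily))
}
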