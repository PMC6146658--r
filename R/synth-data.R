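# Synthetic-data module: generates every input the pipeline consumes --
# gene inventory with rule-consistent domain hits, 1500-bp promoters with
# planted cis-elements, homologous sets in known category proportions, an
# FPKM matrix with planted co-expression clusters and DE effects, family-
# biased GO annotations, a homology map, and a sparse regulatory graph with
# planted triangle motifs -- together with machine-readable ground truth.

.default_families <- c("AP2/EREBP", "bZIP", "MYB", "NAC", "WRKY")
.family_codes <- c("AP2/EREBP" = "AP2", "bZIP" = "BZP", "MYB" = "MYB",
                   "NAC" = "NAC", "WRKY" = "WRK")

#' Synthetic-data configuration
#'
#' Defaults emulate the study design this generator stands in for: five TF
#' families, a 10-chromosome A sub-genome and 9-chromosome C sub-genome,
#' about 19 percent unanchored genes, five treatments (cold, heat, drought,
#' salt, ABA) with three replicates plus a three-replicate control, planted
#' co-expression clusters with a log2 effect size of 2, and log-scale
#' replicate noise.
#'
#' @param n_genes_per_family genes per family (>= 1).
#' @param families family names.
#' @param n_chromosomes_A,n_chromosomes_C chromosome counts per sub-genome.
#' @param unanchored_fraction fraction of genes on unanchored scaffolds.
#' @param treatments treatment names.
#' @param n_replicates replicates per condition.
#' @param n_clusters planted co-expression clusters (>= 1).
#' @param null_fraction fraction of genes with a flat (non-DE) profile.
#' @param de_effect_log2fc planted effect size in log2 units.
#' @param noise_sd replicate noise standard deviation on the log2 scale.
#' @param n_go_terms total number of GO BP terms in the synthetic ontology.
#' @param go_family_bias probability that a gene draws terms from its own
#'   family's term pool.
#' @param prop_novel,prop_conserved,prop_lost planted synteny-category
#'   proportions (per family; the remainder is multi-copy).
#' @param n_triangles planted triangle motifs in the regulatory graph.
#' @param seed random seed fixing all outputs bit-for-bit.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes_per_family = 40L,
                         families = .default_families,
                         n_chromosomes_A = 10L,
                         n_chromosomes_C = 9L,
                         unanchored_fraction = 0.19,
                         treatments = c("cold", "heat", "drought", "salt", "ABA"),
                         n_replicates = 3L,
                         n_clusters = 5L,
                         null_fraction = 0.2,
                         de_effect_log2fc = 2,
                         noise_sd = 0.25,
                         n_go_terms = 60L,
                         go_family_bias = 0.7,
                         prop_novel = 0.076,
                         prop_conserved = 0.094,
                         prop_lost = 0.04,
                         n_triangles = 6L,
                         seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x))
      stop("invalid config field ", nm, ": must be a count >= 1")
    as.integer(x)
  }
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)
      stop("invalid config field ", nm, ": must be a proportion in [0, 1]")
    x
  }
  cfg <- list(
    n_genes_per_family = chk_count(n_genes_per_family, "n_genes_per_family"),
    families = families,
    n_chromosomes_A = chk_count(n_chromosomes_A, "n_chromosomes_A"),
    n_chromosomes_C = chk_count(n_chromosomes_C, "n_chromosomes_C"),
    unanchored_fraction = chk_prop(unanchored_fraction, "unanchored_fraction"),
    treatments = treatments,
    n_replicates = chk_count(n_replicates, "n_replicates"),
    n_clusters = chk_count(n_clusters, "n_clusters"),
    null_fraction = chk_prop(null_fraction, "null_fraction"),
    de_effect_log2fc = de_effect_log2fc,
    noise_sd = noise_sd,
    n_go_terms = chk_count(n_go_terms, "n_go_terms"),
    go_family_bias = chk_prop(go_family_bias, "go_family_bias"),
    prop_novel = chk_prop(prop_novel, "prop_novel"),
    prop_conserved = chk_prop(prop_conserved, "prop_conserved"),
    prop_lost = chk_prop(prop_lost, "prop_lost"),
    n_triangles = chk_count(n_triangles, "n_triangles"),
    seed = as.integer(seed)
  )
  if (cfg$noise_sd < 0) stop("invalid config field noise_sd: must be >= 0")
  if (cfg$prop_novel + cfg$prop_conserved > 1)
    stop("invalid config fields prop_novel/prop_conserved: sum exceeds 1")
  structure(cfg, class = "synth_config")
}

.fam_code <- function(family) {
  code <- .family_codes[family]
  code[is.na(code)] <- toupper(substr(family[is.na(code)], 1, 3))
  code
}

#' Generate the gene inventory and its companion tables
#'
#' Produces gene records with family-consistent, rule-recoverable domain
#' hits (e.g. WRKY genes carry one or two WRKY domains plus a C2H2 or C2HC
#' zinc-finger annotation), 1500-bp promoters with cis-element consensus
#' occurrences planted at recorded forward-strand positions, and homologous
#' sets built directly in the configured category proportions.
#'
#' @param cfg a [synth_config()].
#' @return list: `records`, `hits`, `promoters`, `planted_motifs`,
#'   `homolog_sets`, `truth` (planted subfamilies, categories, motif table).
#' @export
generate_inventory <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, .generate_inventory_impl(cfg))
}

.generate_inventory_impl <- function(cfg) {
  fams <- cfg$families
  n <- cfg$n_genes_per_family
  chroms <- c(sprintf("chrA%02d", seq_len(cfg$n_chromosomes_A)),
              sprintf("chrC%02d", seq_len(cfg$n_chromosomes_C)))

  recs <- list(); hit_rows <- list()
  for (f in fams) {
    code <- .fam_code(f)
    ids <- sprintf("Bn%s%04d", code, seq_len(n))
    anch <- stats::runif(n) >= cfg$unanchored_fraction
    chr <- ifelse(anch, sample(chroms, n, replace = TRUE), NA_character_)
    sub <- .plant_subfamily(f, n)
    recs[[f]] <- data.frame(
      gene_id = ids, species = "B. napus", family = f, subfamily = sub,
      chromosome = chr, sub_genome = sub_genome_from_chromosome(chr),
      anchored = anch, stringsAsFactors = FALSE
    )
    hit_rows[[f]] <- .plant_domain_hits(ids, f, sub)
  }
  records <- do.call(rbind, recs); rownames(records) <- NULL
  hits <- do.call(rbind, hit_rows); rownames(hits) <- NULL

  motifs <- default_motif_table()
  prom <- .plant_promoters(records$gene_id, motifs)
  hsets <- .plant_homolog_sets(records, cfg)

  list(records = records, hits = hits,
       promoters = prom$seqs, planted_motifs = prom$planted,
       homolog_sets = hsets$sets,
       truth = list(subfamily = stats::setNames(records$subfamily, records$gene_id),
                    category = hsets$category,
                    lost_sub_genome = hsets$lost_sub_genome,
                    motif_table = motifs))
}

.plant_subfamily <- function(family, n) {
  switch(family,
    "AP2/EREBP" = sample(c("AP2", "RAV", "EREBP-unresolved"), n, TRUE,
                         prob = c(0.1, 0.1, 0.8)),
    "WRKY" = sample(c("I", "II", "III"), n, TRUE, prob = c(0.2, 0.6, 0.2)),
    "MYB" = sample(c("1R", "R2R3", "3R", "4R"), n, TRUE,
                   prob = c(0.35, 0.55, 0.07, 0.03)),
    rep(NA_character_, n)
  )
}

.plant_domain_hits <- function(ids, family, subfamily) {
  n <- length(ids)
  ev <- function(k) 10^stats::runif(k, -30, -8)
  row <- function(id, dom, start, len, variant = NA_character_)
    data.frame(gene_id = id, domain_name = dom, start = start,
               end = start + len - 1L, e_value = ev(1), variant = variant,
               stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(n)) {
    id <- ids[i]; sub <- subfamily[i]
    rows <- switch(family,
      "AP2/EREBP" = {
        n_ap2 <- if (identical(sub, "AP2")) 2L else 1L
        r <- lapply(seq_len(n_ap2), function(j) row(id, "AP2", 30L + 80L * j, 60L))
        if (identical(sub, "RAV")) r <- c(r, list(row(id, "B3", 260L, 90L)))
        r
      },
      "bZIP" = list(row(id, sample(c("bZIP_1", "bZIP_2"), 1), 40L, 55L)),
      "MYB" = {
        n_rep <- c("1R" = 1L, "R2R3" = 2L, "3R" = 3L, "4R" = 4L)[sub]
        lapply(seq_len(n_rep), function(j) row(id, "MYB", 10L + 55L * j, 48L))
      },
      "NAC" = list(row(id, "NAM", 15L, 130L)),
      "WRKY" = {
        n_wrky <- if (identical(sub, "I")) 2L else 1L
        zf <- if (identical(sub, "III")) "C2HC" else "C2H2"
        core <- if (stats::runif(1) < 0.1)
          sample(c("WRRY", "WSKY", "WKRY", "WVKY", "WKKY", "WKNY"), 1)
        else "WRKYGQK"
        r <- lapply(seq_len(n_wrky), function(j)
          row(id, "WRKY", 100L + 120L * j, 58L, variant = core))
        c(r, list(row(id, "zinc_finger", 400L, 24L, variant = zf)))
      },
      list(row(id, "MYB", 10L, 48L))
    )
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

.plant_promoters <- function(ids, motifs, length_bp = 1500L, max_iter = 60L) {
  n <- length(ids)
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), length_bp, TRUE), collapse = ""), "")
  names(seqs) <- ids
  planted <- list()
  occupied <- stats::setNames(vector("list", n), ids)  # planted intervals per gene
  for (i in seq_len(n)) {
    k <- sample(0:3, 1)
    if (k == 0) next
    picks <- sample(nrow(motifs), k)
    s <- seqs[[i]]
    for (p in picks) {
      cons <- motifs$consensus[p]
      len <- nchar(cons)
      # non-overlapping placement (12-bp padding) so plantings never clobber
      for (try in 1:50) {
        pos <- sample(length_bp - len + 1L, 1)
        clash <- any(vapply(occupied[[i]], function(iv)
          pos <= iv[2] + 12L && pos + len - 1L >= iv[1] - 12L, TRUE))
        if (!clash) break
        pos <- NA_integer_
      }
      if (is.na(pos)) next
      substr(s, pos, pos + len - 1L) <- cons  # forward strand
      occupied[[i]] <- c(occupied[[i]], list(c(pos, pos + len - 1L)))
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = ids[i], motif = motifs$name[p], position = pos,
        strand = "+", stringsAsFactors = FALSE)
    }
    seqs[[i]] <- s
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(gene_id = character(0), motif = character(0),
                             position = integer(0), strand = character(0))
  # sanitize: scramble chance occurrences of motifs not planted in a gene so
  # gene-level presence matches the planting table exactly; bases inside a
  # planted interval are never touched
  for (it in seq_len(max_iter)) {
    hits <- scan_promoters(seqs, motifs, both_strands = TRUE)
    key_p <- paste(planted$gene_id, planted$motif)
    spurious <- hits[!paste(hits$gene_id, hits$motif) %in% key_p, , drop = FALSE]
    if (nrow(spurious) == 0) break
    for (j in seq_len(nrow(spurious))) {
      g <- spurious$gene_id[j]
      len <- nchar(motifs$consensus[match(spurious$motif[j], motifs$name)])
      span <- spurious$position[j]:(spurious$position[j] + len - 1L)
      prot <- unlist(lapply(occupied[[g]], function(iv) iv[1]:iv[2]))
      span <- setdiff(span, prot)
      if (length(span) == 0) next
      s <- seqs[[g]]
      for (b in span) substr(s, b, b) <- sample(c("A", "C", "G", "T"), 1)
      seqs[[g]] <- s
    }
  }
  list(seqs = seqs, planted = planted)
}

.plant_homolog_sets <- function(records, cfg) {
  rows <- list(); category <- character(0); lost_sg <- character(0)
  set_no <- 0L
  add <- function(species, gene_id) {
    data.frame(set_id = sprintf("HS%05d", set_no), species = species,
               gene_id = gene_id, stringsAsFactors = FALSE)
  }
  for (f in cfg$families) {
    genes <- records$gene_id[records$family == f]
    n <- length(genes)
    k_nov <- round(cfg$prop_novel * n)
    k_con <- round(cfg$prop_conserved * n)
    genes <- sample(genes)  # random category placement
    nov <- genes[seq_len(k_nov)]
    con <- genes[k_nov + seq_len(k_con)]
    multi <- genes[-seq_len(k_nov + k_con)]
    code <- .fam_code(f)
    anc_i <- 0L
    anc_id <- function(prefix) {
      anc_i <<- anc_i + 1L
      sprintf("%s%s%04d", prefix, code, anc_i)
    }
    for (g in nov) {
      set_no <- set_no + 1L
      rows[[length(rows) + 1L]] <- add("B. napus", g)
      category[g] <- "novel"
    }
    for (g in con) {
      set_no <- set_no + 1L
      rows[[length(rows) + 1L]] <- rbind(
        add("B. napus", g),
        add("B. rapa", anc_id("Br")),
        add("B. oleracea", anc_id("Bo")))
      category[g] <- "conserved"
    }
    if (length(multi) > 0) {
      pair_of <- rep(seq_len(ceiling(length(multi) / 2)), each = 2)[seq_along(multi)]
      for (p in unique(pair_of)) {
        members <- multi[pair_of == p]
        set_no <- set_no + 1L
        grp <- do.call(rbind, lapply(members, function(g) add("B. napus", g)))
        grp <- rbind(grp, add("B. rapa", anc_id("Br")))
        if (length(members) == 1) # odd leftover: duplicated ancestor copy makes it multi
          grp <- rbind(grp, add("B. rapa", anc_id("Br")))
        rows[[length(rows) + 1L]] <- grp
        for (g in members) category[g] <- "multi_copy"
      }
    }
    k_lost <- round(cfg$prop_lost * n)
    for (j in seq_len(k_lost)) {
      set_no <- set_no + 1L
      if (j %% 2 == 1) {
        id <- anc_id("Br")
        rows[[length(rows) + 1L]] <- add("B. rapa", id)
        lost_sg[id] <- "A"
      } else {
        id <- anc_id("Bo")
        rows[[length(rows) + 1L]] <- add("B. oleracea", id)
        lost_sg[id] <- "C"
      }
    }
  }
  sets <- do.call(rbind, rows); rownames(sets) <- NULL
  list(sets = sets, category = category, lost_sub_genome = lost_sg)
}

#' Generate the expression matrix with planted structure
#'
#' FPKM values are log-normal around cluster-specific treatment means: gene g
#' in cluster j has log2 FPKM = mu_g + effect_j(t) + eps with replicate noise
#' eps ~ N(0, noise_sd). Cluster j's profile carries +de_effect_log2fc at
#' treatment j and -de_effect_log2fc at the next treatment (cyclically), so
#' cluster profiles are pairwise distinct; a configurable fraction of genes
#' has a flat profile (cluster 0, not DE anywhere).
#'
#' @param cfg a [synth_config()].
#' @param inventory output of [generate_inventory()].
#' @return list: `em` (an [expression_matrix()]), `truth` (per-gene cluster
#'   labels, planted log2FC matrix, per-gene-treatment DE flags).
#' @export
generate_expression <- function(cfg, inventory) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 1L, .generate_expression_impl(cfg, inventory))
}

.generate_expression_impl <- function(cfg, inventory) {
  genes <- inventory$records$gene_id
  ng <- length(genes)
  trts <- cfg$treatments
  nt <- length(trts)
  n_null <- round(cfg$null_fraction * ng)
  cluster <- c(rep(0L, n_null),
               sample(seq_len(cfg$n_clusters), ng - n_null, replace = TRUE))
  cluster <- sample(cluster)  # decouple cluster from family order
  names(cluster) <- genes

  profiles <- matrix(0, nrow = cfg$n_clusters + 1L, ncol = nt,
                     dimnames = list(as.character(0:cfg$n_clusters), trts))
  for (j in seq_len(cfg$n_clusters)) {
    up <- ((j - 1L) %% nt) + 1L
    dn <- (j %% nt) + 1L
    profiles[j + 1L, up] <- cfg$de_effect_log2fc
    profiles[j + 1L, dn] <- profiles[j + 1L, dn] - cfg$de_effect_log2fc
  }

  mu <- stats::rnorm(ng, mean = log2(100), sd = 1)
  conds <- c("control", trts)
  samples <- data.frame(
    sample = unlist(lapply(conds, function(cn)
      sprintf("%s_r%d", cn, seq_len(cfg$n_replicates)))),
    condition = rep(conds, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(conds)),
    stringsAsFactors = FALSE
  )
  fpkm <- matrix(0, nrow = ng, ncol = nrow(samples),
                 dimnames = list(genes, samples$sample))
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    eff <- if (cond == "control") rep(0, ng)
           else profiles[cbind(cluster + 1L, match(cond, trts))]
    eps <- if (cfg$noise_sd > 0) stats::rnorm(ng, 0, cfg$noise_sd) else 0
    fpkm[, s] <- 2^(mu + eff + eps)
  }
  planted_log2fc <- profiles[cluster + 1L, , drop = FALSE]
  rownames(planted_log2fc) <- genes
  em <- expression_matrix(fpkm, samples, control = "control")
  list(em = em,
       truth = list(cluster = cluster,
                    planted_log2fc = planted_log2fc,
                    is_de = abs(planted_log2fc) >= cfg$de_effect_log2fc))
}

#' Generate GO annotations, a regulatory graph and a homology map
#'
#' Genes of the same family draw terms from their family's term pool with
#' probability `go_family_bias` (so the process-gene projection is denser
#' within families). The regulatory graph over partner-species genes is
#' triangle-free by construction outside of `n_triangles` planted
#' same-family triangles: random edges run only between TF nodes and
#' non-TF neighbor nodes.
#'
#' @param cfg a [synth_config()].
#' @param inventory output of [generate_inventory()].
#' @return list: `annotations` (gene_id, term, name), `term_table`,
#'   `regulatory` (directed igraph), `homology_map` (node, partner),
#'   `truth` (planted triangle triples).
#' @export
generate_go_and_regulatory <- function(cfg, inventory) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 2L, .generate_go_reg_impl(cfg, inventory))
}

.generate_go_reg_impl <- function(cfg, inventory) {
  rec <- inventory$records
  fams <- cfg$families
  nf <- length(fams)
  n_terms <- cfg$n_go_terms
  term_ids <- sprintf("GO:SYN%04d", seq_len(n_terms))
  pool_of <- rep(seq_len(nf), length.out = n_terms)
  stress_names <- c("response to cold", "response to heat",
                    "response to water deprivation", "response to salt stress",
                    "response to abscisic acid stimulus")
  term_name <- sprintf("synthetic process %d", seq_len(n_terms))
  # the first term of each family pool is a stimulus-response term
  for (j in seq_len(nf)) {
    first <- which(pool_of == j)[1]
    term_name[first] <- stress_names[((j - 1) %% length(stress_names)) + 1]
  }
  term_table <- data.frame(term = term_ids, name = term_name,
                           namespace = "biological_process",
                           pool = fams[pool_of], stringsAsFactors = FALSE)

  ann <- list()
  for (i in seq_len(nrow(rec))) {
    fam_pool <- term_ids[pool_of == match(rec$family[i], fams)]
    k <- sample(1:5, 1)
    draws <- vapply(seq_len(k), function(z) {
      if (stats::runif(1) < cfg$go_family_bias) sample(fam_pool, 1)
      else sample(term_ids, 1)
    }, "")
    draws <- unique(draws)
    ann[[i]] <- data.frame(gene_id = rec$gene_id[i], term = draws,
                           name = term_table$name[match(draws, term_table$term)],
                           namespace = "biological_process",
                           stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann); rownames(annotations) <- NULL

  # homology map: a subset of focal genes gets a partner-species counterpart
  mapped <- rec$gene_id[stats::runif(nrow(rec)) < 0.6]
  at_tf <- sprintf("ATSYN%04d", seq_along(mapped))
  homology_map <- data.frame(node = at_tf, partner = mapped,
                             stringsAsFactors = FALSE)
  tf_family <- stats::setNames(rec$family[match(mapped, rec$gene_id)], at_tf)

  # planted triangles among same-family TF nodes (disjoint triples)
  tri_nodes <- character(0); tri_edges <- list(); triples <- list()
  avail <- split(at_tf, tf_family[at_tf])
  planted <- 0L
  for (f in names(avail)) {
    while (planted < cfg$n_triangles && length(avail[[f]]) >= 3) {
      v <- avail[[f]][1:3]
      avail[[f]] <- avail[[f]][-(1:3)]
      planted <- planted + 1L
      triples[[planted]] <- v
      tri_edges[[planted]] <- data.frame(
        from = c(v[1], v[2], v[3]), to = c(v[2], v[3], v[1]),
        stringsAsFactors = FALSE)
      tri_nodes <- c(tri_nodes, v)
    }
  }
  if (planted < cfg$n_triangles)
    warning("only ", planted, " of ", cfg$n_triangles,
            " triangles could be planted (too few mapped genes per family)")

  # bipartite random part: TF -> non-TF targets and regulators -> TF, with no
  # edges among non-TF nodes and none touching planted-triangle TFs, so the
  # skeleton has no triangles outside the planted ones
  n_other <- max(10L, 3L * length(at_tf))
  others <- sprintf("ATNBR%04d", seq_len(n_other))
  free_tf <- setdiff(at_tf, tri_nodes)
  if (length(free_tf) == 0) free_tf <- others  # degenerate: all TFs planted
  n_rand <- 2L * length(at_tf)
  rand_edges <- data.frame(
    from = character(n_rand), to = character(n_rand), stringsAsFactors = FALSE)
  for (e in seq_len(n_rand)) {
    tf <- sample(free_tf, 1); ot <- sample(others, 1)
    if (stats::runif(1) < 0.5) {
      rand_edges$from[e] <- tf; rand_edges$to[e] <- ot
    } else {
      rand_edges$from[e] <- ot; rand_edges$to[e] <- tf
    }
  }
  edges <- rbind(do.call(rbind, tri_edges), rand_edges)
  g <- graph_from_edges(edges, directed = TRUE, nodes = c(at_tf, others))
  g <- igraph::set_vertex_attr(g, "family",
         value = unname(tf_family[igraph::V(g)$name]))
  list(annotations = annotations, term_table = term_table,
       regulatory = g, homology_map = homology_map,
       truth = list(triangles = triples, n_triangles = planted))
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running all three generators under one configuration.
#'
#' @param cfg a [synth_config()].
#' @return list with `inventory`, `expression`, `go_reg` components.
#' @export
generate_all <- function(cfg) {
  inv <- generate_inventory(cfg)
  expr <- generate_expression(cfg, inv)
  gr <- generate_go_and_regulatory(cfg, inv)
  list(inventory = inv, expression = expr, go_reg = gr)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same formats the pipeline reads: TSV tables, FASTA promoters and
#' a JSON ground-truth file.
#'
#' @param synth output of [generate_all()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synth_outputs <- function(synth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv_table(synth$inventory$records, p("inventory.tsv"))
  write_tsv_table(synth$inventory$hits, p("domain_hits.tsv"))
  write_tsv_table(synth$inventory$homolog_sets, p("homolog_sets.tsv"))
  write_tsv_table(synth$inventory$planted_motifs, p("planted_motifs.tsv"))
  write_promoters(synth$inventory$promoters, p("promoters.fasta"))
  write_expression(synth$expression$em, p("fpkm.tsv"), p("samples.tsv"))
  write_tsv_table(synth$go_reg$annotations, p("go_annotations.tsv"))
  write_tsv_table(synth$go_reg$homology_map, p("homology_map.tsv"))
  write_edge_list(synth$go_reg$regulatory, p("regulatory_edges.tsv"))
  truth <- list(
    subfamily = as.list(synth$inventory$truth$subfamily),
    category = as.list(synth$inventory$truth$category),
    cluster = as.list(synth$expression$truth$cluster),
    n_triangles = synth$go_reg$truth$n_triangles
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE)
  invisible(outdir)
}
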