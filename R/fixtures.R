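#' Generate a random rooted ontology DAG
#'
#' Emulates the structure of HPO/GO: a single root, each subsequent term
#' attached by 1..`max_parents` "is_a" edges to previously generated
#' terms whose depth is below `max_depth`. Acyclic by construction
#' (parents always precede children); byte-identical output under a
#' fixed seed.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per non-root term.
#' @param max_depth Maximum term depth.
#' @param seed Integer seed.
#' @param prefix Accession prefix (e.g. `"HP"`, `"GO"`).
#' @param d_max_mode Passed to [ontology()].
#' @param path Optional OBO output path (written via [write_obo()]).
#' @return An `rd_ontology`.
#' @export
generate_dag <- function(n_terms, max_parents = 3L, max_depth = 8L, seed = 1L,
                         prefix = "HP", d_max_mode = "exact", path = NULL) {
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (max_parents < 1L || max_depth < 1L)
    stop("max_parents and max_depth must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  parents <- list()
  depth <- c(0L, rep(NA_integer_, n_terms - 1L))
  for (i in seq_len(n_terms)[-1L]) {
    pool <- which(depth[seq_len(i - 1L)] < max_depth)
    np <- sample.int(min(max_parents, length(pool)), 1L)
    # bias toward deep parents so generated DAGs are deep like HPO/GO,
    # not the log-depth graphs uniform attachment would give
    wt <- (depth[pool] + 1L)^2
    ps <- if (length(pool) == 1L) pool else sample(pool, np, prob = wt)
    parents[[ids[i]]] <- ids[ps]
    depth[i] <- min(depth[ps]) + 1L
  }
  dag <- ontology(ids, paste("term", seq_len(n_terms)), parents,
                  d_max_mode = d_max_mode)
  if (!is.null(path)) write_obo(dag, path)
  dag
}

# Undirected ball of terms within `radius` edges of `anchor`.
term_neighborhood <- function(dag, anchor, radius) {
  seen <- anchor
  frontier <- anchor
  for (r in seq_len(radius)) {
    nxt <- unique(unlist(c(dag$parents[frontier], dag$children[frontier]),
                         use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

# Greedily pick `k` anchors maximizing the minimum pairwise semantic
# distance, starting from the most distant pair.
pick_anchors <- function(dag, k, candidates = dag$ids) {
  D <- term_distance_matrix(dag, candidates, candidates)
  far <- which(D == max(D), arr.ind = TRUE)[1L, ]
  anchors <- candidates[far]
  while (length(anchors) < k) {
    mind <- apply(D[, anchors, drop = FALSE], 1L, min)
    anchors <- c(anchors, candidates[which.max(mind)])
  }
  anchors[seq_len(k)]
}

#' Generate a synthetic disease knowledge base with known ground truth
#'
#' Emulates the Orphanet annotation structure: diseases annotated with
#' weighted phenotype terms (frequency classes drawn from the standard
#' ladder), pathogenic genes annotated with per-aspect GO terms, and
#' prevalence classes. With `n_clusters > 1`, diseases are planted
#' around widely separated anchor terms (phenotype and gene annotations
#' drawn from the anchors' graph neighborhoods) so true cluster
#' memberships are known; the manifest records them.
#'
#' @param phenotype_dag Optional `rd_ontology` (default: generated,
#'   `dag_terms` terms).
#' @param go_dags Optional named list `cc`/`mf`/`bp` (default:
#'   generated).
#' @param n_diseases Number of diseases (default 60).
#' @param terms_per_disease Phenotype terms per disease (default 8).
#' @param genes_per_disease Pathogenic genes per disease (default 2).
#' @param n_genes Size of the gene pool (default 30).
#' @param go_terms_per_aspect GO terms per gene per aspect (default 3).
#' @param n_clusters Planted cluster count (1 = no planted structure).
#' @param anchor_radius Neighborhood radius around each anchor term.
#' @param dag_terms Terms in each generated DAG.
#' @param seed Integer seed (fully determines all artifacts).
#' @param dir Optional directory: writes the OBO ontologies, the
#'   phenotype/gene TSVs, an Orphanet-style XML, the gene-GO TSV, and a
#'   JSON manifest.
#' @return List with `kb` (an `rd_kb`), `manifest` (seed, parameters,
#'   per-disease assignments, true cluster memberships, file paths), and
#'   `files` (named paths, when `dir` was given).
#' @export
generate_knowledge_base <- function(phenotype_dag = NULL, go_dags = NULL,
                                    n_diseases = 60L, terms_per_disease = 8L,
                                    genes_per_disease = 2L, n_genes = 30L,
                                    go_terms_per_aspect = 3L, n_clusters = 1L,
                                    anchor_radius = 1L, dag_terms = 200L,
                                    seed = 1L, dir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  if (is.null(phenotype_dag))
    phenotype_dag <- generate_dag(dag_terms, seed = seed + 11L, prefix = "HP",
                                  max_depth = 10L)
  if (is.null(go_dags))
    go_dags <- list(cc = generate_dag(dag_terms %/% 2L, seed = seed + 21L, prefix = "GO"),
                    mf = generate_dag(dag_terms %/% 2L, seed = seed + 22L, prefix = "GO"),
                    bp = generate_dag(dag_terms %/% 2L, seed = seed + 23L, prefix = "GO"))
  set.seed(seed)

  ladder <- c("Obligate (100%)", "Very frequent (99-80%)", "Frequent (79-30%)",
              "Occasional (29-5%)", "Very rare (<4-1%)")
  ladder_prob <- c(0.1, 0.45, 0.35, 0.07, 0.03)
  prevalence_pool <- c("<1 / 1 000 000", "1-9 / 1 000 000", "1-9 / 100 000",
                       "1-5 / 10 000", "unknown")

  # per-cluster sampling pools (whole DAG when no planted structure)
  membership <- if (n_clusters > 1L)
    rep_len(seq_len(n_clusters), n_diseases) else rep(1L, n_diseases)
  phen_pools <- if (n_clusters > 1L) {
    deep <- phenotype_dag$ids[phenotype_dag$depth >= stats::quantile(phenotype_dag$depth, 0.5)]
    anchors <- pick_anchors(phenotype_dag, n_clusters, deep)
    lapply(anchors, function(a) {
      pool <- term_neighborhood(phenotype_dag, a, anchor_radius)
      r <- anchor_radius
      while (length(pool) < terms_per_disease + 2L) {
        r <- r + 1L
        pool <- term_neighborhood(phenotype_dag, a, r)
      }
      pool
    })
  } else list(phenotype_dag$ids)

  gene_symbols <- sprintf("GENE%03d", seq_len(n_genes))
  gene_cluster <- rep_len(seq_len(max(membership)), n_genes)
  go_pools <- lapply(c(cc = "cc", mf = "mf", bp = "bp"), function(a) {
    dagA <- go_dags[[a]]
    if (n_clusters > 1L) {
      anchors <- pick_anchors(dagA, n_clusters)
      lapply(anchors, function(x) {
        pool <- term_neighborhood(dagA, x, anchor_radius)
        r <- anchor_radius
        while (length(pool) < go_terms_per_aspect + 1L) {
          r <- r + 1L
          pool <- term_neighborhood(dagA, x, r)
        }
        pool
      })
    } else list(dagA$ids)
  })

  gene_annotations <- list()
  for (g in seq_len(n_genes)) {
    cl <- gene_cluster[g]
    gene_annotations[[gene_symbols[g]]] <- lapply(go_pools, function(pools) {
      pool <- pools[[min(cl, length(pools))]]
      sort(sample(pool, min(go_terms_per_aspect, length(pool))))
    })
  }

  disease_ids <- sprintf("ORPHA:%d", 100000L + seq_len(n_diseases))
  phen_rows <- list(); gene_rows <- list()
  prevalence <- stats::setNames(sample(prevalence_pool, n_diseases, replace = TRUE),
                                disease_ids)
  records <- list()
  gene_map <- list()
  for (i in seq_len(n_diseases)) {
    id <- disease_ids[i]
    pool <- phen_pools[[min(membership[i], length(phen_pools))]]
    terms <- sort(sample(pool, min(terms_per_disease, length(pool))))
    labels <- sample(ladder, length(terms), replace = TRUE, prob = ladder_prob)
    cluster_genes <- gene_symbols[gene_cluster == membership[i]]
    if (!length(cluster_genes)) cluster_genes <- gene_symbols
    genes <- sort(sample(cluster_genes,
                         min(genes_per_disease, length(cluster_genes))))
    records[[id]] <- list(disease_id = id, name = paste("disease", i),
                          terms = terms, freq_labels = labels,
                          xrefs = sprintf("OMIM:%06d", 600000L + i))
    gene_map[[id]] <- genes
    phen_rows[[i]] <- data.frame(disease_id = id, disease_name = paste("disease", i),
                                 hpo_id = terms, frequency_label = labels,
                                 xref = sprintf("OMIM:%06d", 600000L + i))
    gene_rows[[i]] <- data.frame(disease_id = id, gene_symbol = genes)
  }

  kb <- assemble_knowledge_base(records, gene_map, gene_annotations,
                                phenotype_dag, go_dags,
                                prevalence = prevalence)

  manifest <- list(seed = seed,
                   parameters = list(n_diseases = n_diseases,
                                     terms_per_disease = terms_per_disease,
                                     genes_per_disease = genes_per_disease,
                                     n_genes = n_genes,
                                     go_terms_per_aspect = go_terms_per_aspect,
                                     n_clusters = n_clusters,
                                     anchor_radius = anchor_radius),
                   membership = stats::setNames(membership, disease_ids),
                   diseases = lapply(records, function(r)
                     list(terms = r$terms, freq_labels = r$freq_labels)),
                   genes = gene_map,
                   census = as.list(kb$census))

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(phenotype_obo = file.path(dir, "phenotype.obo"),
               go_cc_obo = file.path(dir, "go_cc.obo"),
               go_mf_obo = file.path(dir, "go_mf.obo"),
               go_bp_obo = file.path(dir, "go_bp.obo"),
               phenotypes_tsv = file.path(dir, "disease_phenotypes.tsv"),
               phenotypes_xml = file.path(dir, "disease_phenotypes.xml"),
               genes_tsv = file.path(dir, "disease_genes.tsv"),
               genes_xml = file.path(dir, "disease_genes.xml"),
               gene_go_tsv = file.path(dir, "gene_go.tsv"),
               manifest = file.path(dir, "manifest.json"))
    write_obo(phenotype_dag, files[["phenotype_obo"]])
    write_obo(go_dags$cc, files[["go_cc_obo"]])
    write_obo(go_dags$mf, files[["go_mf_obo"]])
    write_obo(go_dags$bp, files[["go_bp_obo"]])
    phen_df <- do.call(rbind, phen_rows)
    utils::write.table(phen_df, files[["phenotypes_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_orphanet_phenotype_xml(records, files[["phenotypes_xml"]])
    utils::write.table(do.call(rbind, gene_rows), files[["genes_tsv"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_orphanet_gene_xml(gene_map, files[["genes_xml"]])
    go_df <- do.call(rbind, lapply(names(gene_annotations), function(s)
      do.call(rbind, lapply(c("cc", "mf", "bp"), function(a)
        if (length(gene_annotations[[s]][[a]]))
          data.frame(symbol = s, aspect = a, go_id = gene_annotations[[s]][[a]])))))
    utils::write.table(go_df, files[["gene_go_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$files <- as.list(files)
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         digits = NA)
  }

  list(kb = kb, manifest = manifest, files = files)
}

write_orphanet_phenotype_xml <- function(records, path) {
  doc <- xml2::xml_new_root("JDBOR")
  dl <- xml2::xml_add_child(doc, "DisorderList")
  for (r in records) {
    d <- xml2::xml_add_child(dl, "Disorder")
    xml2::xml_add_child(d, "OrphaCode", sub("^ORPHA:", "", r$disease_id))
    xml2::xml_add_child(d, "Name", r$name)
    if (length(r$xrefs)) {
      xl <- xml2::xml_add_child(d, "ExternalReferenceList")
      for (x in r$xrefs) {
        e <- xml2::xml_add_child(xl, "ExternalReference")
        xml2::xml_add_child(e, "Source", sub(":.*$", "", x))
        xml2::xml_add_child(e, "Reference", sub("^[^:]*:", "", x))
      }
    }
    al <- xml2::xml_add_child(d, "HPODisorderAssociationList")
    for (j in seq_along(r$terms)) {
      a <- xml2::xml_add_child(al, "HPODisorderAssociation")
      h <- xml2::xml_add_child(a, "HPO")
      xml2::xml_add_child(h, "HPOId", r$terms[j])
      xml2::xml_add_child(h, "HPOTerm", r$terms[j])
      f <- xml2::xml_add_child(a, "HPOFrequency")
      xml2::xml_add_child(f, "Name", r$freq_labels[j])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

write_orphanet_gene_xml <- function(gene_map, path) {
  doc <- xml2::xml_new_root("JDBOR")
  dl <- xml2::xml_add_child(doc, "DisorderList")
  for (id in names(gene_map)) {
    d <- xml2::xml_add_child(dl, "Disorder")
    xml2::xml_add_child(d, "OrphaCode", sub("^ORPHA:", "", id))
    xml2::xml_add_child(d, "Name", id)
    gl <- xml2::xml_add_child(d, "DisorderGeneAssociationList")
    for (g in gene_map[[id]]) {
      a <- xml2::xml_add_child(gl, "DisorderGeneAssociation")
      ge <- xml2::xml_add_child(a, "Gene")
      xml2::xml_add_child(ge, "Symbol", g)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Generate a synthetic case TSV
#'
#' Builds evaluation cases from a knowledge base: each case's query is
#' the target disease's characteristic phenotypes, optionally degraded
#' by [make_imprecise_query()]; targets are recorded by their OMIM-style
#' xref so the case file exercises the same resolution path as real
#' published cases.
#'
#' @param kb An `rd_kb`.
#' @param n_cases Number of cases.
#' @param terms_per_case Query size.
#' @param n_imprecise Imprecision level applied to each query.
#' @param seed Integer seed.
#' @param path Optional TSV output path.
#' @return Data frame as from [load_cases()] (invisibly also written to
#'   `path`).
#' @export
generate_cases <- function(kb, n_cases = 10L, terms_per_case = 4L,
                           n_imprecise = 0L, seed = 1L, path = NULL) {
  eligible <- Filter(function(id) length(kb$diseases[[id]]$terms) >= terms_per_case,
                     eligible_diseases(kb, "phenotype"))
  if (length(eligible) < n_cases)
    stop("only ", length(eligible), " diseases have >= ", terms_per_case,
         " phenotypes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  targets <- sort(sample(eligible, n_cases))
  rows <- lapply(seq_along(targets), function(i) {
    q <- make_characteristic_query(kb, targets[i], terms_per_case)
    q <- make_imprecise_query(kb$phenotype_dag, q, n_imprecise,
                              seed = seed + 31L * i)
    xref <- kb$diseases[[targets[i]]]$xrefs
    data.frame(case_id = sprintf("case%02d", i),
               target_xref = if (length(xref)) xref[1L] else targets[i],
               terms = paste(q, collapse = ","))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df$terms <- lapply(strsplit(df$terms, ","), trimws)
  df
}

#' Agreement between two label vectors under the best label matching
#'
#' Fraction of points whose labels agree after the cluster labels of
#' `b` are permuted to best match `a` (exhaustive search over
#' permutations; intended for small k).
#'
#' @param a,b Integer label vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(lb) > 8L) stop("label_agreement supports at most 8 clusters")
  perms <- all_perms(length(lb))
  best <- 0
  for (p in perms) {
    relab <- la[p[match(b, lb)]]
    best <- max(best, sum(!is.na(relab) & relab == a) / length(a))
  }
  best
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
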