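#' Default frequency-class weight table
#'
#' Numeric weights for the standard Orphanet/HPO phenotype frequency
#' classes, taken as the midpoints of the printed class bands:
#' Obligate (100%) = 1.0, Very frequent (99-80%) = 0.895,
#' Frequent (79-30%) = 0.545, Occasional (29-5%) = 0.17,
#' Very rare (<4-1%) = 0.02, Excluded (0%) = 0. Pass a modified copy to
#' [assemble_knowledge_base()] to probe score sensitivity.
#'
#' @return Named numeric vector.
#' @export
default_frequency_weights <- function() {
  c("Obligate (100%)"       = 1.0,
    "Very frequent (99-80%)" = 0.895,
    "Frequent (79-30%)"      = 0.545,
    "Occasional (29-5%)"     = 0.17,
    "Very rare (<4-1%)"      = 0.02,
    "Excluded (0%)"          = 0.0)
}

#' Map a phenotype frequency class to a numeric weight
#'
#' Accepts full class labels ("Frequent (79-30%)"), bare class names
#' ("Frequent", case-insensitive), or literal numeric fractions ("0.35"),
#' which pass through unchanged.
#'
#' @param label Character vector of frequency labels.
#' @param table Named numeric weight table (see
#'   [default_frequency_weights()]).
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
frequency_weight <- function(label, table = default_frequency_weights()) {
  label <- trimws(as.character(label))
  out <- rep(NA_real_, length(label))

  hit <- match(label, names(table))
  out[!is.na(hit)] <- table[hit[!is.na(hit)]]

  bare <- tolower(trimws(sub("\\s*\\(.*\\)\\s*$", "", names(table))))
  need <- is.na(out)
  hit2 <- match(tolower(sub("\\s*\\(.*\\)\\s*$", "", label[need])), bare)
  out[need][!is.na(hit2)] <- table[hit2[!is.na(hit2)]]

  need <- is.na(out)
  num <- suppressWarnings(as.numeric(label[need]))
  ok <- !is.na(num) & num >= 0 & num <= 1
  out[need][ok] <- num[ok]

  if (anyNA(out))
    stop("unknown frequency label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  out
}

#' Load disease-phenotype annotations
#'
#' Reads disease -> phenotype associations with frequency classes from
#' either the package's TSV dialect (columns `disease_id`, `disease_name`,
#' `hpo_id`, `frequency_label`, optional `xref`) or Orphanet-product-style
#' XML (`DisorderList/Disorder` with `HPODisorderAssociation` children).
#' Frequency classes are validated but carried as labels; numeric weights
#' are assigned later by [assemble_knowledge_base()].
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"orphanet_xml"`.
#' @param weights Weight table used only to validate labels.
#' @return Named list of disease records, each a list with `disease_id`,
#'   `name`, `terms`, `freq_labels`, `xrefs`. Diseases with zero valid
#'   phenotype rows are retained with empty `terms`.
#' @export
load_disease_phenotypes <- function(path, dialect = c("tsv", "orphanet_xml"),
                                    weights = default_frequency_weights()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path)
  rows <- if (dialect == "tsv") read_phenotype_tsv(path) else read_phenotype_xml(path)
  frequency_weight(rows$frequency_label, weights)   # validates labels
  recs <- list()
  for (i in seq_len(nrow(rows))) {
    id <- rows$disease_id[i]
    if (is.null(recs[[id]]))
      recs[[id]] <- list(disease_id = id, name = rows$disease_name[i],
                         terms = character(), freq_labels = character(),
                         xrefs = character())
    if (rows$hpo_id[i] %in% recs[[id]]$terms) {
      warning("duplicate phenotype ", rows$hpo_id[i], " for disease ", id,
              "; keeping first")
      next
    }
    if (nzchar(rows$hpo_id[i])) {
      recs[[id]]$terms <- c(recs[[id]]$terms, rows$hpo_id[i])
      recs[[id]]$freq_labels <- c(recs[[id]]$freq_labels, rows$frequency_label[i])
    }
    if (!is.null(rows$xref) && nzchar(rows$xref[i]))
      recs[[id]]$xrefs <- unique(c(recs[[id]]$xrefs,
                                   strsplit(rows$xref[i], ",", fixed = TRUE)[[1L]]))
  }
  recs
}

read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("disease_id", "disease_name", "hpo_id", "frequency_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype TSV ", path, " missing column(s): ", paste(miss, collapse = ", "))
  df
}

read_phenotype_xml <- function(path) {
  doc <- xml2::read_xml(path)
  disorders <- xml2::xml_find_all(doc, ".//Disorder")
  if (!length(disorders)) stop("no Disorder elements in ", path)
  out <- list()
  for (d in disorders) {
    code <- xml2::xml_text(xml2::xml_find_first(d, "./OrphaCode"))
    if (is.na(code) || !nzchar(code))
      stop("Disorder element without OrphaCode in ", path)
    id <- if (startsWith(code, "ORPHA:")) code else paste0("ORPHA:", code)
    nm <- xml2::xml_text(xml2::xml_find_first(d, "./Name"))
    xr <- vapply(xml2::xml_find_all(d, ".//ExternalReference"),
                 function(e) paste0(
                   xml2::xml_text(xml2::xml_find_first(e, "./Source")), ":",
                   xml2::xml_text(xml2::xml_find_first(e, "./Reference"))),
                 character(1))
    assoc <- xml2::xml_find_all(d, ".//HPODisorderAssociation")
    if (!length(assoc)) {
      out[[length(out) + 1L]] <- data.frame(
        disease_id = id, disease_name = nm, hpo_id = "",
        frequency_label = "Excluded (0%)",
        xref = paste(xr, collapse = ","), stringsAsFactors = FALSE)
      next
    }
    for (a in assoc) {
      hpo <- xml2::xml_text(xml2::xml_find_first(a, ".//HPOId"))
      freq <- xml2::xml_text(xml2::xml_find_first(a, ".//HPOFrequency/Name"))
      out[[length(out) + 1L]] <- data.frame(
        disease_id = id, disease_name = nm, hpo_id = hpo,
        frequency_label = freq, xref = paste(xr, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Load disease-gene annotations
#'
#' Reads disease -> pathogenic-gene associations from the TSV dialect
#' (columns `disease_id`, `gene_symbol`) or Orphanet-product-style XML
#' (`Disorder` with `DisorderGeneAssociation/Gene/Symbol` children).
#'
#' @inheritParams load_disease_phenotypes
#' @return Named list: disease id -> character vector of gene symbols.
#'   Diseases with only empty gene fields are omitted with a warning.
#' @export
load_disease_genes <- function(path, dialect = c("tsv", "orphanet_xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(c("disease_id", "gene_symbol"), names(df))
    if (length(miss))
      stop("gene TSV ", path, " missing column(s): ", paste(miss, collapse = ", "))
  } else {
    doc <- xml2::read_xml(path)
    disorders <- xml2::xml_find_all(doc, ".//Disorder")
    if (!length(disorders)) stop("no Disorder elements in ", path)
    df <- do.call(rbind, lapply(disorders, function(d) {
      code <- xml2::xml_text(xml2::xml_find_first(d, "./OrphaCode"))
      id <- if (startsWith(code, "ORPHA:")) code else paste0("ORPHA:", code)
      syms <- vapply(xml2::xml_find_all(d, ".//DisorderGeneAssociation/Gene/Symbol"),
                     xml2::xml_text, character(1))
      if (!length(syms)) syms <- ""
      data.frame(disease_id = id, gene_symbol = syms, stringsAsFactors = FALSE)
    }))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$disease_id[i]; g <- trimws(df$gene_symbol[i])
    if (nzchar(g)) out[[id]] <- unique(c(out[[id]], g))
  }
  empty <- setdiff(unique(df$disease_id), names(out))
  if (length(empty))
    warning(length(empty), " disease(s) with empty gene lists omitted from gene map")
  out
}

#' Load gene -> GO annotations
#'
#' Reads per-aspect GO term sets for genes from a TSV (columns `symbol`,
#' `aspect` in cc/mf/bp, `go_id`) or a GAF 2.x file (columns 3, 5, 9;
#' aspect codes F/P/C).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gaf"`.
#' @return Named list: gene symbol -> list with character vectors `cc`,
#'   `mf`, `bp`.
#' @export
load_gene_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(c("symbol", "aspect", "go_id"), names(df))
    if (length(miss))
      stop("gene annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  } else {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "!",
                             stringsAsFactors = FALSE)
    df <- data.frame(symbol = raw[[3L]], go_id = raw[[5L]],
                     aspect = c(F = "mf", P = "bp", C = "cc")[raw[[9L]]],
                     stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(df$aspect), c("cc", "mf", "bp"))
  if (length(bad)) stop("unknown GO aspect(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    s <- df$symbol[i]
    if (is.null(out[[s]])) out[[s]] <- list(cc = character(), mf = character(),
                                            bp = character())
    out[[s]][[df$aspect[i]]] <- unique(c(out[[s]][[df$aspect[i]]], df$go_id[i]))
  }
  out
}

#' Assemble a disease knowledge base
#'
#' Cross-validates phenotype and gene annotations against their
#' ontologies (resolving aliases, dropping unresolvable terms with a
#' logged count), assigns numeric frequency weights, flags diseases whose
#' phenotypes are all "Excluded" (weight 0; retained but excluded from
#' map construction by default), and reports the annotation census:
#' diseases with phenotypes, diseases with genes, and their overlap.
#'
#' @param phenotypes Output of [load_disease_phenotypes()].
#' @param genes Output of [load_disease_genes()] (may be `NULL`).
#' @param gene_annotations Output of [load_gene_annotations()] (may be
#'   `NULL`).
#' @param phenotype_dag `rd_ontology` for phenotype terms.
#' @param go_dags Named list of `rd_ontology` objects `cc`, `mf`, `bp`
#'   (may be `NULL` when no gene map is built).
#' @param weights Frequency-class weight table.
#' @param prevalence Optional named character vector of prevalence-class
#'   labels by disease id.
#' @return An object of class `rd_kb`.
#' @export
assemble_knowledge_base <- function(phenotypes, genes = NULL,
                                    gene_annotations = NULL,
                                    phenotype_dag, go_dags = NULL,
                                    weights = default_frequency_weights(),
                                    prevalence = NULL) {
  stopifnot(inherits(phenotype_dag, "rd_ontology"))
  dropped <- 0L
  diseases <- list()
  for (rec in phenotypes) {
    resolved <- resolve_terms(phenotype_dag, rec$terms, partial = TRUE)
    keep <- !is.na(resolved)
    dropped <- dropped + sum(!keep)
    terms <- resolved[keep]
    w <- frequency_weight(rec$freq_labels[keep], weights)
    dup <- duplicated(terms)
    terms <- terms[!dup]; w <- w[!dup]
    diseases[[rec$disease_id]] <- list(
      disease_id = rec$disease_id, name = rec$name,
      terms = unname(terms), weights = unname(w),
      freq_labels = rec$freq_labels[keep][!dup],
      genes = character(),
      prevalence_class = if (!is.null(prevalence) && rec$disease_id %in% names(prevalence))
        prevalence[[rec$disease_id]] else "unknown",
      xrefs = rec$xrefs,
      all_excluded = length(terms) > 0L && all(w == 0))
  }
  for (id in names(genes)) {
    if (is.null(diseases[[id]]))
      diseases[[id]] <- list(disease_id = id, name = id, terms = character(),
                             weights = numeric(), freq_labels = character(),
                             genes = character(),
                             prevalence_class = if (!is.null(prevalence) && id %in% names(prevalence))
                               prevalence[[id]] else "unknown",
                             xrefs = character(), all_excluded = FALSE)
    diseases[[id]]$genes <- genes[[id]]
  }
  if (!is.null(gene_annotations) && !is.null(go_dags)) {
    for (s in names(gene_annotations)) {
      for (aspect in c("cc", "mf", "bp")) {
        terms <- gene_annotations[[s]][[aspect]]
        if (!length(terms)) next
        resolved <- resolve_terms(go_dags[[aspect]], terms, partial = TRUE)
        dropped <- dropped + sum(is.na(resolved))
        gene_annotations[[s]][[aspect]] <- unique(resolved[!is.na(resolved)])
      }
    }
  }
  if (dropped > 0L)
    warning(dropped, " annotation term(s) did not resolve and were dropped")
  if (!length(diseases)) stop("empty knowledge base")

  has_phen <- vapply(diseases, function(d) length(d$terms) > 0L, TRUE)
  has_gene <- vapply(diseases, function(d) length(d$genes) > 0L, TRUE)
  census <- c(phenotype = sum(has_phen), gene = sum(has_gene),
              overlap = sum(has_phen & has_gene))

  structure(list(diseases = diseases, genes = gene_annotations,
                 phenotype_dag = phenotype_dag, go_dags = go_dags,
                 census = census, weights_table = weights,
                 dropped_terms = dropped),
            class = "rd_kb")
}

#' Disease ids eligible for a map of the given kind
#'
#' Phenotype maps require at least one resolvable phenotype with a
#' positive weight; gene maps require at least one annotated gene.
#'
#' @param kb An `rd_kb`.
#' @param kind `"phenotype"` or `"gene"`.
#' @return Sorted character vector of disease ids.
#' @export
eligible_diseases <- function(kb, kind = c("phenotype", "gene")) {
  kind <- match.arg(kind)
  keep <- vapply(kb$diseases, function(d) {
    if (kind == "phenotype") length(d$terms) > 0L && !isTRUE(d$all_excluded)
    else length(d$genes) > 0L &&
      (is.null(kb$genes) || length(intersect(d$genes, names(kb$genes))) > 0L)
  }, TRUE)
  sort(names(kb$diseases)[keep])
}

#' Report the knowledge-base annotation census
#'
#' Returns (and prints) the number of phenotype-annotated diseases,
#' gene-annotated diseases, and their overlap, side by side with a set
#' of reference counts for manual comparison. The default reference is
#' the census of the published Orphanet-2019 RDmap release
#' (3287 / 3789 / 1718); counts are database-version dependent, so the
#' comparison is reported, never asserted.
#'
#' @param kb An `rd_kb`.
#' @param reference Named numeric vector with entries `phenotype`,
#'   `gene`, `overlap`, or `NULL` to suppress the comparison.
#' @return Data frame with columns `count` and (if given) `reference`.
#' @export
kb_census <- function(kb, reference = rdmap_reference_census()) {
  out <- data.frame(count = as.integer(kb$census),
                    row.names = names(kb$census))
  if (!is.null(reference))
    out$reference <- as.integer(reference[rownames(out)])
  out
}

#' Census of the published Orphanet-2019 RDmap release
#'
#' Disease counts of the public RDmap built on the 2019 Orphanet
#' snapshot, for side-by-side reporting against a locally assembled
#' knowledge base.
#'
#' @return Named integer vector (`phenotype`, `gene`, `overlap`).
#' @export
rdmap_reference_census <- function() {
  c(phenotype = 3287L, gene = 3789L, overlap = 1718L)
}

#' @export
print.rd_kb <- function(x, ...) {
  cat("Rare-disease knowledge base\n")
  cat(sprintf("  diseases with phenotypes: %d\n", x$census[["phenotype"]]))
  cat(sprintf("  diseases with genes:      %d\n", x$census[["gene"]]))
  cat(sprintf("  overlap:                  %d\n", x$census[["overlap"]]))
  cat(sprintf("  phenotype DAG: %d terms (d_max %d, %s)\n",
              length(x$phenotype_dag$ids), x$phenotype_dag$d_max,
              x$phenotype_dag$d_max_mode))
  if (!is.null(x$genes)) cat(sprintf("  annotated genes: %d\n", length(x$genes)))
  if (x$dropped_terms > 0L)
    cat(sprintf("  dropped unresolvable terms: %d\n", x$dropped_terms))
  invisible(x)
}
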