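#' Characteristic phenotype query for a disease
#'
#' The `terms_per_query` highest-frequency-weight phenotype terms of a
#' disease; ties at the cut are broken by term id so the selection is
#' deterministic.
#'
#' @param kb An `rd_kb`.
#' @param disease_id Disease id.
#' @param terms_per_query Number of terms (default 4).
#' @return Character vector of term ids.
#' @export
make_characteristic_query <- function(kb, disease_id, terms_per_query = 4L) {
  d <- kb$diseases[[disease_id]]
  if (is.null(d)) stop("unknown disease id: ", disease_id)
  if (length(d$terms) < terms_per_query)
    stop("disease ", disease_id, " has fewer than ", terms_per_query,
         " phenotypes")
  ord <- order(-d$weights, d$terms)
  d$terms[ord][seq_len(terms_per_query)]
}

#' Replace query terms by imprecise stand-ins
#'
#' Simulates imprecise clinical description: a uniform random subset of
#' `n_imprecise` query terms is each replaced by a uniformly chosen
#' graph-adjacent term (parent or child) from
#' [neighbors_for_imprecision()]. Replacements never equal the original
#' term. A term with no neighbors is left in place and another candidate
#' is drawn; if too few terms have neighbors the result carries
#' attribute `incomplete = TRUE`.
#'
#' @param dag Phenotype `rd_ontology`.
#' @param query Character vector of term ids.
#' @param n_imprecise Number of terms to degrade (0..length(query)).
#' @param seed Integer seed (deterministic output).
#' @return Character vector the same length as `query`.
#' @export
make_imprecise_query <- function(dag, query, n_imprecise, seed = 1L) {
  if (n_imprecise < 0L || n_imprecise > length(query))
    stop("n_imprecise must be in [0, length(query)]")
  if (n_imprecise == 0L) return(query)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- query
  candidates <- sample(seq_along(query))
  replaced <- 0L
  for (i in candidates) {
    if (replaced == n_imprecise) break
    nb <- neighbors_for_imprecision(dag, query[i])
    if (!length(nb)) next
    out[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
    replaced <- replaced + 1L
  }
  if (replaced < n_imprecise) attr(out, "incomplete") <- TRUE
  out
}

#' In silico imprecise-phenotype benchmark
#'
#' For each sampled target disease, a characteristic query of its
#' highest-frequency phenotypes is built and degraded to each
#' imprecision level (the same degraded query is fed to every method, so
#' comparisons are paired); the target's tie-aware rank in each method's
#' search result is recorded and aggregated per level and method.
#'
#' @param kb An `rd_kb`.
#' @param n_diseases Number of target diseases to sample (uniformly,
#'   among diseases with at least `terms_per_query` phenotypes).
#' @param terms_per_query Query size (default 4).
#' @param levels Imprecision levels (default `0:terms_per_query`).
#' @param methods Search methods to compare.
#' @param seed Master seed.
#' @param weighted Use frequency weights in the semantic scores. Off by
#'   default: the benchmark isolates semantic versus lexical term
#'   matching, and multiplying a matched distance by the matched term's
#'   within-disease frequency lets rarely-annotated terms of unrelated
#'   diseases deflate their scores, a property of the weighted search
#'   score that is studied separately.
#' @return Object of class `rd_eval`: list with `per_query` (data frame:
#'   target, level, method, rank, score), `summary` (per level x method:
#'   `frac_rank1`, `frac_top10`, `mean_rank`), and `config`.
#' @export
run_insilico <- function(kb, n_diseases = 60L, terms_per_query = 4L,
                         levels = 0:4, methods = c("similarity",
                                                   "similarity_avg", "jaccard"),
                         seed = 1L, weighted = FALSE) {
  eligible <- Filter(function(id) length(kb$diseases[[id]]$terms) >= terms_per_query,
                     eligible_diseases(kb, "phenotype"))
  if (!length(eligible)) stop("no disease has enough phenotypes for the benchmark")
  if (max(levels) > terms_per_query)
    stop("imprecision level exceeds the query size")
  n_diseases <- min(n_diseases, length(eligible))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  targets <- sort(sample(eligible, n_diseases))

  rows <- vector("list", length(targets) * length(levels) * length(methods))
  r <- 0L
  for (ti in seq_along(targets)) {
    target <- targets[ti]
    base_query <- make_characteristic_query(kb, target, terms_per_query)
    for (lv in levels) {
      query <- make_imprecise_query(kb$phenotype_dag, base_query, lv,
                                    seed = seed + 7919L * ti + lv)
      for (m in methods) {
        hits <- search_diseases(kb, query, method = m, weighted = weighted,
                                max_hits = Inf)
        i <- match(target, hits$disease_id)
        r <- r + 1L
        rows[[r]] <- data.frame(target = target, level = lv, method = m,
                                rank = hits$rank[i], score = hits$score[i])
      }
    }
  }
  per_query <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(per_query$rank,
                                      by = list(level = per_query$level,
                                                method = per_query$method),
                                      FUN = f)
  summary <- agg(function(r) mean(r == 1L))
  names(summary)[3L] <- "frac_rank1"
  summary$frac_top10 <- agg(function(r) mean(r <= 10L))$x
  summary$mean_rank <- agg(mean)$x
  structure(list(per_query = per_query, summary = summary,
                 config = list(n_diseases = n_diseases,
                               terms_per_query = terms_per_query,
                               levels = levels, methods = methods,
                               seed = seed, weighted = weighted)),
            class = "rd_eval")
}

#' @export
print.rd_eval <- function(x, ...) {
  cat("In silico imprecise-phenotype benchmark\n")
  cat(sprintf("  %d targets, %d-term queries, seed %d\n",
              x$config$n_diseases, x$config$terms_per_query, x$config$seed))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Read a literature-case TSV
#'
#' Columns: `case_id`, `target_xref` (e.g. an OMIM accession, resolved
#' against knowledge-base xrefs at evaluation time), `terms`
#' (comma-separated phenotype ids), and optional `reported_rank` /
#' `reported_score` reference columns.
#'
#' @param path TSV path.
#' @return Data frame with list-column `terms`.
#' @export
load_cases <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("case_id", "target_xref", "terms"), names(df))
  if (length(miss)) stop("case TSV missing column(s): ", paste(miss, collapse = ", "))
  df$terms <- lapply(strsplit(df$terms, ","), trimws)
  df
}

#' The 20 published-case queries shipped with the package
#'
#' Twenty rare-disease case reports (OMIM-identified target diseases
#' with clinician-curated HPO query terms) used to benchmark the
#' phenotype search, together with the ranks and similarity scores the
#' published RDmap (Orphanet 2019 snapshot) reported for them.
#'
#' @return Data frame as from [load_cases()].
#' @export
literature_cases <- function() {
  load_cases(system.file("extdata", "literature_cases.tsv", package = "rdmap",
                         mustWork = TRUE))
}

#' Rank literature cases against a knowledge base
#'
#' For each case the target disease is resolved (directly by id or via
#' the knowledge base's external xrefs), the case's phenotype terms are
#' searched, and the target's tie-aware rank and score are recorded.
#' Cases whose target is absent from the knowledge base are reported as
#' unresolved and excluded from the summaries with a count. When the
#' case table carries `reported_rank` / `reported_score` columns they
#' are kept side-by-side in the per-case output for comparison.
#'
#' @param kb An `rd_kb`.
#' @param cases Data frame from [load_cases()] (default: the packaged
#'   20 published cases).
#' @param method Search method (default `"similarity"`).
#' @param weighted Use frequency weights.
#' @return Object of class `rd_case_eval`: list with `per_case` (case,
#'   target, rank, score, and any reported reference columns), `summary`
#'   (mean/median/max rank, mean and sd of target score), and
#'   `n_unresolved`.
#' @export
run_literature_cases <- function(kb, cases = literature_cases(),
                                 method = "similarity", weighted = TRUE) {
  if (!nrow(cases)) stop("empty case list")
  xref_index <- list()
  for (id in names(kb$diseases))
    for (x in kb$diseases[[id]]$xrefs) xref_index[[x]] <- c(xref_index[[x]], id)

  rows <- list()
  for (i in seq_len(nrow(cases))) {
    xref <- cases$target_xref[i]
    target <- if (xref %in% names(kb$diseases)) xref
              else if (!is.null(xref_index[[xref]])) xref_index[[xref]][1L]
              else NA_character_
    terms <- resolve_terms(kb$phenotype_dag, cases$terms[[i]], partial = TRUE)
    terms <- terms[!is.na(terms)]
    rank <- NA_integer_; score <- NA_real_
    if (!is.na(target) && length(terms)) {
      hits <- search_diseases(kb, terms, method = method, weighted = weighted,
                              max_hits = Inf)
      j <- match(target, hits$disease_id)
      if (!is.na(j)) { rank <- hits$rank[j]; score <- hits$score[j] }
    }
    row <- data.frame(case_id = cases$case_id[i], target_xref = xref,
                      target_id = target, rank = rank, score = score)
    if ("reported_rank" %in% names(cases)) row$reported_rank <- cases$reported_rank[i]
    if ("reported_score" %in% names(cases)) row$reported_score <- cases$reported_score[i]
    rows[[i]] <- row
  }
  per_case <- do.call(rbind, rows)
  resolved <- per_case[!is.na(per_case$rank), ]
  summary <- list(mean_rank = mean(resolved$rank),
                  median_rank = stats::median(resolved$rank),
                  max_rank = if (nrow(resolved)) max(resolved$rank) else NA,
                  mean_score = mean(resolved$score),
                  sd_score = stats::sd(resolved$score),
                  n_resolved = nrow(resolved))
  structure(list(per_case = per_case, summary = summary,
                 n_unresolved = sum(is.na(per_case$rank)),
                 method = method, weighted = weighted),
            class = "rd_case_eval")
}

#' @export
print.rd_case_eval <- function(x, ...) {
  cat(sprintf("Literature-case evaluation (%s method): %d case(s), %d unresolved\n",
              x$method, nrow(x$per_case), x$n_unresolved))
  with(x$summary, cat(sprintf(
    "  mean rank %.2f, median %.1f, max %d; target score %.3f +/- %.3f\n",
    mean_rank, median_rank, max_rank, mean_score, sd_score)))
  print(x$per_case, row.names = FALSE, digits = 4)
  invisible(x)
}
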