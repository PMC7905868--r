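#' One-way query-to-disease similarity score
#'
#' The default search score: each query term is matched to its nearest
#' term in the disease's annotation, and the mean of those matched
#' distances (each multiplied by the matched term's frequency weight;
#' query terms carry weight 1) is returned. Smaller = more similar; 0
#' when every query term appears in the disease's annotation. The
#' one-way direction makes the score robust to incomplete queries: extra
#' disease annotations are never penalized.
#'
#' @param dag Phenotype `rd_ontology`.
#' @param query_terms Non-empty character vector of term ids.
#' @param disease Disease record with non-empty `terms` and `weights`.
#' @param weighted Multiply by the matched term's frequency weight
#'   (default TRUE); with FALSE all disease weights are treated as 1.
#' @param D Optional precomputed normalized term-distance matrix
#'   (dimnames covering query and disease terms).
#' @return A number in `[0, 1]`.
#' @export
score_one_way <- function(dag, query_terms, disease, weighted = TRUE, D = NULL) {
  if (!length(query_terms)) stop("empty query")
  if (!length(disease$terms)) stop("disease without phenotypes: ", disease$disease_id)
  q <- resolve_terms(dag, query_terms)
  t <- resolve_terms(dag, disease$terms)
  Dqt <- if (is.null(D)) term_distance_matrix(dag, q, t) else D[q, t, drop = FALSE]
  w <- if (weighted) disease$weights else rep(1, length(t))
  one_way_weighted(Dqt, rep(1, length(q)), w)
}

#' Symmetric two-way similarity score ("Similarity-Avg")
#'
#' The weighted disease phenotype distance applied with the query
#' treated as a pseudo-disease with unit weights: both directions
#' (query -> disease and disease -> query) are averaged, so unmatched
#' disease annotations do penalize the score.
#'
#' @inheritParams score_one_way
#' @return A number in `[0, 1]`.
#' @export
score_similarity_avg <- function(dag, query_terms, disease, weighted = TRUE,
                                 D = NULL) {
  if (!length(query_terms)) stop("empty query")
  q <- resolve_terms(dag, unique(query_terms))
  pseudo <- list(disease_id = "<query>", terms = q, weights = rep(1, length(q)))
  dis <- disease
  if (!weighted) dis$weights <- rep(1, length(dis$terms))
  Dsub <- if (is.null(D)) NULL else D
  disease_phenotype_distance(dag, pseudo, dis, D = Dsub)
}

#' Rank knowledge-base diseases against a query phenotype set
#'
#' Scores every phenotype-annotated disease with the chosen method and
#' returns hits sorted by score (ascending; smaller = more similar) with
#' tie-aware ranks. Jaccard scores are converted to distances `1 - J`
#' for a uniform sort order; the raw similarity is kept in a `jaccard`
#' column. An optional score threshold (keep `score <= threshold`) and
#' prevalence-class filter mirror the map front end's slider and
#' prevalence switches.
#'
#' @param kb An `rd_kb`.
#' @param terms Character vector of query term ids (aliases allowed).
#' @param method `"similarity"` (one-way, default), `"similarity_avg"`,
#'   or `"jaccard"`.
#' @param threshold Optional maximum score in `[0, 1]`.
#' @param prevalence Optional character vector of prevalence classes to
#'   keep.
#' @param weighted Use frequency weights in the semantic scores.
#' @param max_hits Result cap (default 100); ties at the boundary are
#'   all included. `Inf` disables the cap.
#' @return Object of class `rd_hits`: data frame with columns
#'   `disease_id`, `name`, `score`, `rank` (tie-aware: 1 + number of
#'   strictly smaller scores), `prevalence_class`, and `jaccard` for the
#'   Jaccard method.
#' @export
search_diseases <- function(kb, terms, method = c("similarity",
                                                  "similarity_avg", "jaccard"),
                            threshold = NULL, prevalence = NULL,
                            weighted = TRUE, max_hits = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(kb, "rd_kb"))
  if (!length(terms)) stop("empty query")
  dag <- kb$phenotype_dag
  q <- resolve_terms(dag, unique(terms))   # errors list unknown ids

  ids <- eligible_diseases(kb, "phenotype")
  jac <- NULL
  if (method == "jaccard") {
    scores <- vapply(ids, function(id) {
      t <- resolve_terms(dag, kb$diseases[[id]]$terms)
      1 - jaccard_similarity(q, t)
    }, 0)
    jac <- 1 - scores
  } else {
    all_terms <- sort(unique(c(q, unlist(lapply(kb$diseases[ids], `[[`, "terms"),
                                         use.names = FALSE))))
    D <- term_distance_matrix(dag, all_terms, all_terms)
    scorer <- if (method == "similarity") score_one_way else score_similarity_avg
    scores <- vapply(ids, function(id)
      scorer(dag, q, kb$diseases[[id]], weighted = weighted, D = D), 0)
  }

  hits <- data.frame(disease_id = ids,
                     name = vapply(kb$diseases[ids], `[[`, "", "name"),
                     score = unname(scores),
                     prevalence_class = vapply(kb$diseases[ids], `[[`, "",
                                               "prevalence_class"),
                     row.names = NULL)
  if (!is.null(jac)) hits$jaccard <- unname(jac)
  hits <- hits[order(hits$score, hits$disease_id), ]
  hits$rank <- vapply(hits$score, function(s) 1L + sum(hits$score < s), 0L)

  if (!is.null(threshold)) hits <- hits[hits$score <= threshold, ]
  if (!is.null(prevalence)) hits <- hits[hits$prevalence_class %in% prevalence, ]
  if (is.finite(max_hits) && nrow(hits) > max_hits) {
    cut <- hits$score[max_hits]
    hits <- hits[hits$score <= cut, ]     # ties at the cap all included
  }
  rownames(hits) <- NULL
  class(hits) <- c("rd_hits", "data.frame")
  hits
}

#' Tie-aware rank of a target disease in a hit list
#'
#' The rank counts only strictly better (smaller) scores: a target tied
#' with others but with none better has rank 1.
#'
#' @param hits An `rd_hits` data frame.
#' @param target_disease_id Disease id to locate.
#' @return A positive integer, or `NA_integer_` ("not retrieved") when
#'   the target was filtered out of the hit list.
#' @export
rank_of_target <- function(hits, target_disease_id) {
  i <- match(target_disease_id, hits$disease_id)
  if (is.na(i)) return(NA_integer_)
  hits$rank[i]
}

#' @export
print.rd_hits <- function(x, n = 10L, ...) {
  cat(sprintf("Search hits: %d disease(s)\n", nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
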