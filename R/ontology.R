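#' Construct an ontology DAG
#'
#' Low-level constructor for a rooted directed acyclic graph of ontology
#' terms linked by "is_a" (child -> parent) edges, the structure shared by
#' the Human Phenotype Ontology and the three Gene Ontology aspects.
#' Validates referential integrity and acyclicity, computes term depths
#' (shortest edge count from any root) and caches the normalization
#' constant `d_max` used by [term_distance()].
#'
#' @param ids Character vector of canonical term accessions (unique).
#' @param names Character vector of term labels, parallel to `ids`.
#' @param parents Named list (by term id) of character vectors of parent
#'   term ids; terms with no parents are roots.
#' @param aliases Named character vector mapping alternative ids to
#'   canonical ids (may be empty).
#' @param d_max_mode How to compute the cached `d_max`: `"depth_bound"`
#'   (2 x maximum depth, an upper bound suitable for large ontologies) or
#'   `"exact"` (all-pairs maximum common-ancestor-path distance; quadratic,
#'   intended for small or test ontologies).
#' @return An object of class `rd_ontology`: a list with elements `ids`,
#'   `names`, `parents`, `children`, `aliases`, `roots`, `depth`,
#'   `d_max`, `d_max_mode`.
#' @seealso [load_obo()], [term_distance()], [compute_d_max()]
#' @export
ontology <- function(ids, names = ids, parents = list(), aliases = character(),
                     d_max_mode = c("depth_bound", "exact")) {
  d_max_mode <- match.arg(d_max_mode)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(names) != length(ids)) stop("`names` must parallel `ids`")
  parents <- parents[intersect(names(parents), ids)]
  full_parents <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) full_parents[[id]] <- unique(as.character(parents[[id]]))
  unknown <- setdiff(unlist(full_parents, use.names = FALSE), ids)
  if (length(unknown))
    stop("is_a reference to unknown term id(s): ", paste(unknown, collapse = ", "))
  if (length(aliases)) {
    bad <- setdiff(aliases, ids)
    if (length(bad)) stop("alias target(s) not in ontology: ", paste(bad, collapse = ", "))
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) children[[id]] <- character()
  for (id in ids) for (p in full_parents[[id]]) children[[p]] <- c(children[[p]], id)

  check_acyclic(ids, full_parents)

  roots <- ids[vapply(full_parents, length, 0L) == 0L]
  if (!length(roots)) stop("ontology has no root term")

  depth <- compute_depths(ids, children, roots)

  dag <- structure(
    list(ids = ids,
         names = stats::setNames(as.character(names), ids),
         parents = full_parents, children = children,
         aliases = aliases, roots = roots, depth = depth,
         d_max = NA_integer_, d_max_mode = d_max_mode,
         cache = new.env(parent = emptyenv())),
    class = "rd_ontology")
  dag$d_max <- compute_d_max(dag, d_max_mode)
  dag
}

# Kahn's algorithm over child -> parent edges; leftovers form cycles.
check_acyclic <- function(ids, parents) {
  n_out <- vapply(parents, length, 0L)          # edges to parents
  incoming <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) incoming[[p]] <- c(incoming[[p]], id)
  queue <- ids[n_out == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in incoming[[v]]) {
      n_out[[ch]] <- n_out[[ch]] - 1L
      if (n_out[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    member <- ids[n_out > 0L][1L]
    stop("cycle detected in is_a relations involving term ", member)
  }
  invisible(TRUE)
}

compute_depths <- function(ids, children, roots) {
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[roots] <- 0L
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) stop("term(s) unreachable from any root: ",
                         paste(ids[is.na(depth)], collapse = ", "))
  depth
}

#' Load an OBO-format ontology
#'
#' Parses an OBO flat file into an [ontology()] DAG. Honored tags within
#' `[Term]` stanzas: `id`, `name`, `alt_id`, `is_a`, `is_obsolete`. Only
#' "is_a" edges are used; other relationship types and stanza kinds are
#' ignored. Obsolete terms are skipped; `alt_id`s are recorded as aliases
#' resolving to the canonical id.
#'
#' @param path Path to a readable OBO file.
#' @inheritParams ontology
#' @return An `rd_ontology` object.
#' @export
load_obo <- function(path, d_max_mode = c("depth_bound", "exact")) {
  d_max_mode <- match.arg(d_max_mode)
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas found in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  other_stanzas <- grep("^\\[(?!Term\\])", lines, perl = TRUE)

  ids <- character(); labels <- character()
  parents <- list(); aliases <- character()
  for (s in seq_along(stanza_starts)) {
    from <- stanza_starts[s] + 1L
    to <- bounds[s + 1L] - 1L
    # stanza ends at the next stanza header of any kind
    cut <- other_stanzas[other_stanzas >= from & other_stanzas <= to]
    if (length(cut)) to <- min(cut) - 1L
    if (to < from) next
    block <- lines[from:to]
    tagval <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), block, value = TRUE)
      sub("\\s*!.*$", "", trimws(sub(paste0("^", tag, ":"), "", hits)))
    }
    if (length(grep("^is_obsolete:\\s*true", block))) next
    id <- tagval("id")
    if (length(id) != 1L) stop("OBO stanza without a single id near line ", from)
    ids <- c(ids, id)
    nm <- tagval("name")
    labels <- c(labels, if (length(nm)) nm[[1L]] else id)
    isa <- tagval("is_a")
    if (length(isa)) parents[[id]] <- isa
    alt <- tagval("alt_id")
    if (length(alt)) aliases[alt] <- id
  }
  ontology(ids, labels, parents, aliases, d_max_mode = d_max_mode)
}

#' Write an ontology to OBO format
#'
#' Inverse of [load_obo()] for the tag subset this package uses; used by
#' the synthetic-fixture generators and for round-trip testing.
#'
#' @param dag An `rd_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "rd_ontology"))
  out <- c("format-version: 1.2", "")
  for (id in dag$ids) {
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", dag$names[[id]]))
    alt <- names(dag$aliases)[dag$aliases == id]
    for (a in alt) out <- c(out, paste0("alt_id: ", a))
    for (p in dag$parents[[id]])
      out <- c(out, paste0("is_a: ", p, " ! ", dag$names[[p]]))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Resolve term ids against an ontology
#'
#' Maps each id to its canonical term id, following `alt_id` aliases.
#'
#' @param dag An `rd_ontology`.
#' @param ids Character vector of term ids (canonical or alias).
#' @param partial If `TRUE`, unresolvable ids become `NA` instead of an
#'   error.
#' @return Character vector of canonical ids.
#' @export
resolve_terms <- function(dag, ids, partial = FALSE) {
  ids <- as.character(ids)
  out <- ifelse(ids %in% dag$ids, ids, unname(dag$aliases[ids]))
  if (!partial && anyNA(out))
    stop("unknown term id(s): ", paste(ids[is.na(out)], collapse = ", "))
  out
}

# Shortest up-distance from `id` to each of its ancestors (self included,
# distance 0), by breadth-first search over parent edges.
ancestor_dists <- function(dag, id) {
  dist <- stats::setNames(0L, id)
  frontier <- id
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# n_terms x n_terms matrix A with A[i, a] = shortest up-distance from term i
# to ancestor a, Inf where a is not an ancestor of i. Cached on the DAG.
ancestor_matrix <- function(dag) {
  if (!is.null(dag$cache) && !is.null(dag$cache$A)) return(dag$cache$A)
  n <- length(dag$ids)
  A <- matrix(Inf, n, n, dimnames = list(dag$ids, dag$ids))
  for (id in dag$ids) {
    ad <- ancestor_dists(dag, id)
    A[id, names(ad)] <- ad
  }
  if (!is.null(dag$cache)) dag$cache$A <- A
  A
}

# Full unnormalized min-plus common-ancestor distance matrix over all
# terms (Inf where no common ancestor exists). Cached on the DAG; only
# materialized for desk-scale ontologies.
raw_distance_matrix <- function(dag) {
  if (!is.null(dag$cache) && !is.null(dag$cache$M)) return(dag$cache$M)
  A <- ancestor_matrix(dag)
  n <- nrow(A)
  M <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (a in seq_len(n)) {
    col <- A[, a]
    fin <- which(is.finite(col))
    if (!length(fin)) next
    M[fin, fin] <- pmin(M[fin, fin, drop = FALSE], outer(col[fin], col[fin], "+"))
  }
  diag(M) <- 0
  if (!is.null(dag$cache)) dag$cache$M <- M
  M
}

#' Normalized common-ancestor-path distance between two terms
#'
#' The distance between terms `t1` and `t2` is the minimum over their
#' common ancestors `a` of `dist(t1 -> a) + dist(t2 -> a)` (shortest
#' child-to-ancestor edge counts), normalized by the ontology's `d_max`.
#' It is symmetric, lies in `[0, 1]` when `d_max` was computed exactly,
#' and is 0 iff both ids resolve to the same term. Terms from different
#' connected components (no common ancestor) get distance 1.
#'
#' @param dag An `rd_ontology`.
#' @param t1,t2 Term ids (aliases allowed).
#' @return A single number in `[0, 1]`.
#' @export
term_distance <- function(dag, t1, t2) {
  t1 <- resolve_terms(dag, t1); t2 <- resolve_terms(dag, t2)
  if (t1 == t2) return(0)
  a1 <- ancestor_dists(dag, t1)
  a2 <- ancestor_dists(dag, t2)
  common <- intersect(names(a1), names(a2))
  if (!length(common)) return(1)
  raw <- min(a1[common] + a2[common])
  if (is.na(dag$d_max) || dag$d_max <= 0L) return(as.numeric(t1 != t2))
  min(raw / dag$d_max, 1)
}

#' Pairwise term-distance matrix
#'
#' Computes [term_distance()] for all pairs `ids1 x ids2` in one pass via
#' a min-plus product over the ancestor incidence structure; used
#' internally by the disease-distance and search code paths.
#'
#' @param dag An `rd_ontology`.
#' @param ids1,ids2 Term id vectors (default: all terms).
#' @param normalized Divide by `d_max` (default) or return raw edge counts.
#' @return Numeric matrix `length(ids1) x length(ids2)`.
#' @export
term_distance_matrix <- function(dag, ids1 = dag$ids, ids2 = ids1,
                                 normalized = TRUE) {
  ids1 <- resolve_terms(dag, ids1); ids2 <- resolve_terms(dag, ids2)
  if (length(dag$ids) <= 3000L) {
    M <- raw_distance_matrix(dag)[ids1, ids2, drop = FALSE]
  } else {
    A <- ancestor_matrix(dag)
    M <- matrix(Inf, length(ids1), length(ids2), dimnames = list(ids1, ids2))
    for (a in dag$ids) {
      c1 <- A[ids1, a]; c2 <- A[ids2, a]
      if (all(is.infinite(c1)) || all(is.infinite(c2))) next
      M <- pmin(M, outer(c1, c2, "+"))
    }
    M[outer(ids1, ids2, "==")] <- 0
  }
  if (normalized) {
    if (is.na(dag$d_max) || dag$d_max <= 0L) {
      M[] <- as.numeric(outer(ids1, ids2, "!="))
    } else {
      M <- M / dag$d_max
      M[is.infinite(M)] <- 1      # different connected components
      M <- pmin(M, 1)
      M[outer(ids1, ids2, "==")] <- 0
    }
  }
  M
}

#' Compute the distance normalization constant d_max
#'
#' `mode = "exact"` takes the maximum over all term pairs of the
#' unnormalized common-ancestor-path distance (quadratic; for small or
#' test ontologies). `mode = "depth_bound"` returns `2 x max(depth)`, an
#' upper bound on the exact value, suitable for ontologies with tens of
#' thousands of terms.
#'
#' @param dag An `rd_ontology` (non-empty).
#' @param mode `"exact"` or `"depth_bound"`.
#' @return A non-negative integer. A single-term ontology yields 0 (the
#'   normalized distance is then degenerate and guarded downstream).
#' @export
compute_d_max <- function(dag, mode = c("depth_bound", "exact")) {
  mode <- match.arg(mode)
  if (!length(dag$ids)) stop("empty ontology")
  if (length(dag$ids) == 1L) {
    warning("single-term ontology: d_max = 0, normalized distance undefined")
    return(0L)
  }
  if (mode == "depth_bound") return(2L * max(dag$depth))
  M <- raw_distance_matrix(dag)
  as.integer(max(M[is.finite(M)]))
}

#' Set the cached d_max of an ontology
#'
#' Recomputes and caches `d_max` under the requested mode; returns the
#' updated ontology. The mode in effect is recorded on the object and in
#' all serialized outputs.
#'
#' @inheritParams compute_d_max
#' @return The updated `rd_ontology`.
#' @export
set_d_max <- function(dag, mode = c("depth_bound", "exact")) {
  mode <- match.arg(mode)
  dag$d_max <- compute_d_max(dag, mode)
  dag$d_max_mode <- mode
  dag
}

#' Graph-adjacent terms used to simulate imprecise phenotypes
#'
#' Returns the union of a term's parents and children — the candidate
#' pool from which an "imprecise" stand-in for a clinical phenotype is
#' drawn in the in silico benchmark.
#'
#' @param dag An `rd_ontology`.
#' @param t A term id.
#' @return Character vector of term ids (excludes `t`; empty only for an
#'   isolated root with no children).
#' @export
neighbors_for_imprecision <- function(dag, t) {
  t <- resolve_terms(dag, t)
  setdiff(unique(c(dag$parents[[t]], dag$children[[t]])), t)
}

#' @export
print.rd_ontology <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d root(s), max depth %d\n",
              length(x$ids), length(x$roots), max(x$depth)))
  cat(sprintf("d_max = %d (%s mode), %d alias id(s)\n",
              x$d_max, x$d_max_mode, length(x$aliases)))
  invisible(x)
}
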