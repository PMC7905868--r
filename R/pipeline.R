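#' Build a validated pipeline configuration
#'
#' Collects the file paths, model parameters and master seed that drive
#' [run_pipeline()]. `config` may be a named list or the path of a YAML
#' file with the same keys; entries in `...` override it. A serialized
#' copy of the effective configuration is written next to every pipeline
#' output.
#'
#' @param config Named list or YAML file path. Recognized keys:
#'   `phenotype_obo`, `go_cc_obo`, `go_mf_obo`, `go_bp_obo`,
#'   `disease_phenotypes`, `disease_genes`, `gene_annotations`,
#'   `annotation_dialect` ("tsv"/"orphanet_xml"), `out_dir`,
#'   `d_max_mode`, `k_range`, `B`, `stability_threshold`, `restarts`,
#'   `seed`, `frequency_weights` (named list overriding
#'   [default_frequency_weights()]).
#' @param ... Individual overrides.
#' @return A validated list of class `rd_config`.
#' @export
rdmap_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(phenotype_obo = NULL, go_cc_obo = NULL, go_mf_obo = NULL,
                   go_bp_obo = NULL, disease_phenotypes = NULL,
                   disease_genes = NULL, gene_annotations = NULL,
                   annotation_dialect = "tsv", out_dir = ".",
                   d_max_mode = "depth_bound", k_range = 2:8, B = 20L,
                   stability_threshold = 0.8, restarts = 10L, seed = 1L,
                   frequency_weights = NULL)
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!cfg$annotation_dialect %in% c("tsv", "orphanet_xml"))
    stop("annotation_dialect must be 'tsv' or 'orphanet_xml'")
  if (!cfg$d_max_mode %in% c("depth_bound", "exact"))
    stop("d_max_mode must be 'depth_bound' or 'exact'")
  for (key in c("phenotype_obo", "go_cc_obo", "go_mf_obo", "go_bp_obo",
                "disease_phenotypes", "disease_genes", "gene_annotations"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config file for ", key, " does not exist: ", cfg[[key]])
  structure(cfg, class = "rd_config")
}

stage_deps <- list(load = character(),
                   phen_matrix = "load", gene_matrix = "load",
                   phen_map = "phen_matrix", gene_map = "gene_matrix",
                   overlap = c("phen_map", "gene_map"))

#' Run the offline map-construction pipeline
#'
#' Executes the requested stages of load -> distance matrices -> map
#' embeddings -> cluster overlap, writing all artifacts (distance-matrix
#' caches, map JSONs, overlap table, census report) under the config's
#' `out_dir` together with the effective configuration and input hashes
#' for provenance. Distance matrices found on disk are reused when their
#' recorded input hashes match the current inputs; stale caches are
#' recomputed with a warning.
#'
#' @param config An `rd_config` (see [rdmap_config()]).
#' @param stages Subset of `load`, `phen_matrix`, `gene_matrix`,
#'   `phen_map`, `gene_map`, `overlap`; prerequisite stages are pulled
#'   in automatically.
#' @return Named list of artifact paths (plus the in-memory `kb` and
#'   any fitted maps), invisibly.
#' @export
run_pipeline <- function(config, stages = c("load", "phen_matrix", "gene_matrix",
                                            "phen_map", "gene_map", "overlap")) {
  stopifnot(inherits(config, "rd_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  # close over dependencies
  need <- stages
  repeat {
    more <- setdiff(unique(unlist(stage_deps[need])), need)
    if (!length(more)) break
    need <- c(more, need)
  }
  order_all <- c("load", "phen_matrix", "gene_matrix", "phen_map", "gene_map",
                 "overlap")
  need <- order_all[order_all %in% need]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out <- list(config = file.path(config$out_dir, "config.json"))

  input_files <- unlist(Filter(Negate(is.null),
                               config[c("phenotype_obo", "go_cc_obo", "go_mf_obo",
                                        "go_bp_obo", "disease_phenotypes",
                                        "disease_genes", "gene_annotations")]))
  input_hash <- unname(tools::md5sum(input_files))

  kb <- NULL; maps <- list()
  for (stage in need) {
    if (stage == "load") {
      if (is.null(config$phenotype_obo) || is.null(config$disease_phenotypes))
        stop("stage 'load' requires phenotype_obo and disease_phenotypes")
      message("[load] reading ontologies and annotations")
      weights <- if (is.null(config$frequency_weights)) default_frequency_weights()
                 else unlist(config$frequency_weights)
      pd <- load_obo(config$phenotype_obo, d_max_mode = config$d_max_mode)
      gd <- NULL
      if (!is.null(config$go_cc_obo))
        gd <- list(cc = load_obo(config$go_cc_obo, d_max_mode = config$d_max_mode),
                   mf = load_obo(config$go_mf_obo, d_max_mode = config$d_max_mode),
                   bp = load_obo(config$go_bp_obo, d_max_mode = config$d_max_mode))
      phen <- load_disease_phenotypes(config$disease_phenotypes,
                                      config$annotation_dialect, weights)
      genes <- if (!is.null(config$disease_genes))
        load_disease_genes(config$disease_genes, config$annotation_dialect)
      ganno <- if (!is.null(config$gene_annotations))
        load_gene_annotations(config$gene_annotations)
      kb <- assemble_knowledge_base(phen, genes, ganno, pd, gd, weights = weights)
      census_path <- file.path(config$out_dir, "census.json")
      jsonlite::write_json(
        list(census = as.list(kb$census),
             reference = as.list(rdmap_reference_census()),
             note = "reference = published Orphanet-2019 RDmap release; version dependent, reported for manual comparison"),
        census_path, auto_unbox = TRUE, digits = NA)
      out$census <- census_path
      message(sprintf("[load] census: %d phenotype / %d gene / %d overlap (reference %d/%d/%d)",
                      kb$census[["phenotype"]], kb$census[["gene"]],
                      kb$census[["overlap"]], 3287L, 3789L, 1718L))
    } else if (stage %in% c("phen_matrix", "gene_matrix")) {
      kind <- if (stage == "phen_matrix") "phenotype" else "gene"
      prefix <- file.path(config$out_dir, paste0(kind, "_distances"))
      sidecar <- paste0(prefix, ".inputs.json")
      dm <- NULL
      if (file.exists(paste0(prefix, ".tsv")) && file.exists(sidecar)) {
        prev <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        cache_hash <- unname(tools::md5sum(paste0(prefix, c(".tsv", ".ids"))))
        if (!identical(unname(prev$md5), input_hash)) {
          warning("stale cache for ", prefix, "; recomputing")
        } else if (!identical(unname(prev$cache_md5), cache_hash)) {
          warning("corrupted cache file for ", prefix, "; recomputing")
        } else {
          message("[", stage, "] cache hit, reusing ", prefix)
          dm <- read_distance_matrix(prefix)
        }
      }
      if (is.null(dm)) {
        message("[", stage, "] computing ", kind, " distance matrix")
        dm <- build_distance_matrix(kb, kind)
        write_distance_matrix(dm, prefix)
        jsonlite::write_json(
          list(files = input_files, md5 = input_hash,
               cache_md5 = unname(tools::md5sum(paste0(prefix, c(".tsv", ".ids")))),
               seed = config$seed),
          sidecar, auto_unbox = TRUE, digits = NA)
      }
      maps[[paste0(kind, "_dm")]] <- dm
      out[[stage]] <- paste0(prefix, ".tsv")
    } else if (stage %in% c("phen_map", "gene_map")) {
      kind <- if (stage == "phen_map") "phenotype" else "gene"
      message("[", stage, "] embedding and clustering")
      m <- rdmap(kb, kind, k_range = config$k_range, B = config$B,
                 threshold = config$stability_threshold, seed = config$seed,
                 restarts = config$restarts,
                 distance_matrix = maps[[paste0(kind, "_dm")]])
      path <- file.path(config$out_dir, paste0(kind, "_map.json"))
      write_map_json(m, path)
      maps[[kind]] <- m
      out[[stage]] <- path
    } else if (stage == "overlap") {
      message("[overlap] cross-tabulating cluster membership")
      ov <- cluster_overlap(maps$phenotype, maps$gene)
      path <- file.path(config$out_dir, "cluster_overlap.tsv")
      utils::write.table(ov, path, sep = "\t", quote = FALSE, row.names = FALSE)
      out$overlap <- path
    }
  }
  invisible(c(out, list(kb = kb), maps))
}
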