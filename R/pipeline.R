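#' Assemble and validate a pipeline run configuration
#'
#' @param genome Path to the genome FASTA.
#' @param peaks Path to the accessible-region BED.
#' @param fragments Named character vector of fragment BED paths, one per
#'   condition.
#' @param motifs Path to a JASPAR PFM file.
#' @param outdir Output directory.
#' @param genes,motif_gene_map Optional paths (gene BED6; TSV with columns
#'   `gene_id`, `motif_id`) enabling the network stage.
#' @param source_motif Source motif id for the network stage.
#' @param seed Seed for all stochastic steps.
#' @param window,smooth_w,agg_window,flank,cut Stage parameters (see the
#'   stage functions).
#' @return A validated `run_config` list; round-trips losslessly through
#'   [jsonlite::write_json()] / [read_run_config()].
#' @export
run_config <- function(genome, peaks, fragments, motifs, outdir,
                       genes = NULL, motif_gene_map = NULL,
                       source_motif = NULL, seed = 1L,
                       window = 20L, smooth_w = 1L, agg_window = NULL,
                       flank = 60L, cut = 0.5) {
  if (is.null(names(fragments)) || any(!nzchar(names(fragments)))) {
    abort("fragments must be a named vector: condition = path")
  }
  cfg <- list(genome = genome, peaks = peaks,
              fragments = as.list(fragments), motifs = motifs,
              outdir = outdir, genes = genes,
              motif_gene_map = motif_gene_map, source_motif = source_motif,
              seed = as.integer(seed), window = as.integer(window),
              smooth_w = as.integer(smooth_w), agg_window = agg_window,
              flank = as.integer(flank), cut = cut)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  paths <- c(genome = cfg$genome, peaks = cfg$peaks, motifs = cfg$motifs,
             unlist(cfg$fragments), genes = cfg$genes,
             motif_gene_map = cfg$motif_gene_map)
  missing_f <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_f) > 0) {
    abort(sprintf("missing input file(s): %s",
                  paste(sprintf("%s (%s)", names(missing_f), missing_f),
                        collapse = ", ")))
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON path written by [jsonlite::write_json()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has no NULL scalar: absent optionals come back as empty lists
  x <- lapply(x, function(e) if (is.list(e) && length(e) == 0) NULL else e)
  do.call(run_config, c(
    x[setdiff(names(x), "fragments")],
    list(fragments = unlist(x$fragments))))
}

cond_file <- function(outdir, stem, cond, ext = "bedgraph") {
  file.path(outdir, sprintf("%s_%s.%s", stem, cond, ext))
}

#' Run the full footprinting pipeline
#'
#' Executes, in order, the requested stages: `correct` (bias estimation and
#' correction per condition), `score` (footprint scoring of corrected
#' tracks), `bindetect` (motif scanning, site scoring, normalization,
#' bound/unbound classification, per-site log2FC and the differential
#' volcano table), `aggregate` (per-motif aggregate profiles and FPD),
#' `cluster` (motif tree by binding-site overlap) and `network` (TF-TF
#' network, when gene inputs are configured). Stages communicate only
#' through their declared file artifacts in `outdir`, so later stages can
#' be re-run alone against existing outputs. A `manifest.json` records
#' package version, parameters and input/output checksums.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stages to run (default all
#'   applicable).
#' @return Path of the manifest file, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("correct", "score", "bindetect",
                                         "aggregate", "cluster", "network")) {
  validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  conds <- names(cfg$fragments)
  if (is.null(cfg$genes) || is.null(cfg$motif_gene_map) ||
      is.null(cfg$source_motif)) {
    stages <- setdiff(stages, "network")
  }
  done <- character()
  for (st in stages) {
    switch(st,
           correct = stage_correct(cfg, conds),
           score = stage_score(cfg, conds),
           bindetect = stage_bindetect(cfg, conds),
           aggregate = stage_aggregate(cfg, conds),
           cluster = stage_cluster(cfg),
           network = stage_network(cfg, conds),
           abort(sprintf("unknown stage: %s", st)))
    done <- c(done, st)
  }
  outputs <- list.files(cfg$outdir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest <- list(
    package = "footprintr",
    version = as.character(utils::packageVersion("footprintr")),
    stages = done,
    parameters = unclass(cfg),
    input_md5 = as.list(tools::md5sum(unlist(
      cfg[c("genome", "peaks", "motifs")], use.names = FALSE))),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  mpath <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

stage_correct <- function(cfg, conds) {
  genome <- read_fasta(cfg$genome)
  peaks <- merge_intervals(read_bed(cfg$peaks))
  write_bed(peaks, file.path(cfg$outdir, "regions.bed"))
  sizes <- nchar(genome)
  for (cc in conds) {
    frags <- read_bed(cfg$fragments[[cc]])
    ev <- fragments_to_cutsites(frags, chrom_sizes = sizes)
    bundle <- bias_correct(ev, genome, peaks, window = cfg$window,
                           smooth_w = cfg$smooth_w, seed = cfg$seed)
    for (kind in c("observed", "bias", "expected", "corrected")) {
      write_bedgraph(bundle[[kind]], cond_file(cfg$outdir, kind, cc))
    }
    write_bias_model(bundle$model,
                     cond_file(cfg$outdir, "bias_model", cc, "json"))
  }
}

stage_score <- function(cfg, conds) {
  regions <- read_bed(file.path(cfg$outdir, "regions.bed"))
  for (cc in conds) {
    corrected <- read_bedgraph(cond_file(cfg$outdir, "corrected", cc),
                               regions = regions, kind = "corrected")
    scores <- footprint_score(corrected)
    write_bedgraph(scores, cond_file(cfg$outdir, "scores", cc))
  }
}

stage_bindetect <- function(cfg, conds) {
  genome <- read_fasta(cfg$genome)
  regions <- read_bed(file.path(cfg$outdir, "regions.bed"))
  motifs <- motif_models(read_jaspar(cfg$motifs))
  sites <- scan_motifs(motifs, genome, regions)
  tracks <- lapply(stats::setNames(conds, conds), function(cc) {
    read_bedgraph(cond_file(cfg$outdir, "scores", cc), regions = regions,
                  kind = "footprint")
  })
  sites <- sites |>
    score_sites(tracks, agg_window = cfg$agg_window) |>
    normalize_scores(conds) |>
    classify_bound(conds)
  thresholds <- attr(sites, "thresholds")
  if (length(conds) >= 2) {
    sites <- site_log2fc(sites, conds[1], conds[2])
    volcano <- differential_binding(sites, conds[1], conds[2],
                                    seed = cfg$seed)
    readr::write_tsv(volcano, file.path(cfg$outdir, "volcano.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(sites, file.path(cfg$outdir, "sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(thresholds, file.path(cfg$outdir, "thresholds.tsv"),
                   progress = FALSE)
}

stage_aggregate <- function(cfg, conds) {
  regions <- read_bed(file.path(cfg$outdir, "regions.bed"))
  sites <- readr::read_tsv(file.path(cfg$outdir, "sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  rows <- list()
  for (cc in conds) {
    corrected <- read_bedgraph(cond_file(cfg$outdir, "corrected", cc),
                               regions = regions, kind = "corrected")
    for (mid in unique(sites$motif_id)) {
      msites <- sites[sites$motif_id == mid, ]
      prof <- tryCatch(aggregate_footprints(msites, corrected,
                                            flank = cfg$flank),
                       error = function(e) NULL)
      if (is.null(prof)) next
      rows[[length(rows) + 1L]] <- tibble(
        motif_id = mid, condition = cc, offset = prof$offset,
        value = prof$value, n_sites = attr(prof, "n_sites"),
        fpd = fpd(prof, relative = FALSE))
    }
  }
  readr::write_tsv(bind_rows(rows),
                   file.path(cfg$outdir, "aggregate_profiles.tsv"),
                   progress = FALSE)
}

stage_cluster <- function(cfg) {
  sites <- readr::read_tsv(file.path(cfg$outdir, "sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  bound_cols <- grep("^bound_", names(sites), value = TRUE)
  use <- if (length(bound_cols) > 0) {
    keep <- Reduce(`|`, lapply(bound_cols, function(b) sites[[b]]))
    if (any(keep)) sites[keep, ] else sites
  } else sites
  D <- overlap_distance_matrix(use)
  tree <- build_tree(D, cut = cfg$cut)
  writeLines(tree$newick, file.path(cfg$outdir, "tree.newick"))
  readr::write_tsv(tree$clusters, file.path(cfg$outdir, "clusters.tsv"),
                   progress = FALSE)
}

stage_network <- function(cfg, conds) {
  sites <- readr::read_tsv(file.path(cfg$outdir, "sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  if (is.null(sites$log2fc)) abort("network stage needs >= 2 conditions")
  genes <- read_genes(cfg$genes)
  map <- readr::read_tsv(cfg$motif_gene_map, show_col_types = FALSE,
                         progress = FALSE)
  annotated <- annotate_promoters(sites, genes)
  net <- create_network(annotated, map, cfg$source_motif,
                        require_bound = conds[2])
  write_network(net, file.path(cfg$outdir, "network_edges.tsv"),
                file.path(cfg$outdir, "network_nodes.json"))
}
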