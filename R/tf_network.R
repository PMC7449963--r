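#' Assign binding sites to gene promoter windows
#'
#' A site is assigned to every gene whose promoter window overlaps it by at
#' least 1 bp. The window is anchored at the TSS and strand-aware: for +
#' genes it spans `upstream` bp before to `downstream` bp after the TSS
#' (default -10000/+1000), mirrored for - genes. Multi-gene assignments are
#' kept; sites hitting no promoter are labelled intergenic.
#'
#' @param sites Binding-site tibble.
#' @param genes Gene tibble from [read_genes()] (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param upstream,downstream Window extents in bp relative to the TSS.
#' @return `sites` expanded to one row per (site, assigned gene), with added
#'   `gene_id` (NA for intergenic) and `annotation`
#'   (`"promoter"`/`"intergenic"`).
#' @export
annotate_promoters <- function(sites, genes, upstream = 10000L,
                               downstream = 1000L) {
  if (any(!genes$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  win_start <- ifelse(genes$strand == "+", genes$tss - upstream,
                      genes$tss - downstream)
  win_end <- ifelse(genes$strand == "+", genes$tss + downstream + 1L,
                    genes$tss + upstream + 1L)
  sites$.site_row <- seq_len(nrow(sites))
  pairs <- list()
  for (ch in unique(sites$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(gi) == 0 || length(si) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$start[si] + 1L, sites$end[si]),
      IRanges::IRanges(win_start[gi] + 1L, win_end[gi])
    )
    if (length(ov) == 0) next
    pairs[[length(pairs) + 1L]] <- tibble(
      .site_row = si[S4Vectors::queryHits(ov)],
      gene_id = genes$gene_id[gi[S4Vectors::subjectHits(ov)]]
    )
  }
  assigned <- if (length(pairs)) bind_rows(pairs) else
    tibble(.site_row = integer(), gene_id = character())
  out <- left_join(sites, assigned, by = ".site_row",
                   relationship = "many-to-many") |>
    mutate(annotation = ifelse(is.na(.data$gene_id), "intergenic", "promoter")) |>
    select(-".site_row")
  out
}

#' Build the directed TF-to-TF network from promoter binding
#'
#' Draws an edge A -> B when a binding site of motif A with strengthening
#' binding (`log2fc > 0`, and bound in the target condition when
#' `require_bound`) lies in the promoter window of a gene encoding motif B.
#' Node levels are breadth-first distances from `source_motif`; nodes
#' farther than `max_level` are pruned (default 2, giving three network
#' layers). Self-edges are recorded in the edge list but do not affect
#' levels.
#'
#' @param annotated Output of [annotate_promoters()] with `log2fc` (and a
#'   `bound_<condition>` column when `require_bound`).
#' @param motif_gene_map Tibble `gene_id`, `motif_id` linking genes to the
#'   motifs they encode.
#' @param source_motif Motif id at level 0.
#' @param max_level Maximum BFS level retained (default 2).
#' @param require_bound Condition name: only sites with
#'   `bound_<require_bound> == TRUE` support edges; `NULL` disables the
#'   bound filter.
#' @return A `tf_network` list: `nodes` (tibble `motif_id`, `level`),
#'   `edges` (tibble `source_tf`, `target_tf`, `n_sites`, `mean_log2fc`,
#'   `self`).
#' @export
create_network <- function(annotated, motif_gene_map, source_motif,
                           max_level = 2L, require_bound = NULL) {
  if (!source_motif %in% annotated$motif_id) {
    abort(sprintf("source motif %s absent from site set", source_motif))
  }
  if (is.null(annotated$log2fc)) abort("sites need a log2fc column; run site_log2fc() first")
  d <- annotated |>
    filter(.data$annotation == "promoter", .data$log2fc > 0)
  if (!is.null(require_bound)) {
    bcol <- paste0("bound_", require_bound)
    if (is.null(d[[bcol]])) abort(sprintf("column %s missing", bcol))
    d <- filter(d, .data[[bcol]])
  }
  edges_all <- d |>
    inner_join(motif_gene_map, by = "gene_id",
               relationship = "many-to-many") |>
    rename(source_tf = "motif_id.x", target_tf = "motif_id.y") |>
    group_by(.data$source_tf, .data$target_tf) |>
    summarise(n_sites = dplyr::n(), mean_log2fc = mean(.data$log2fc),
              .groups = "drop") |>
    mutate(self = .data$source_tf == .data$target_tf)
  nonself <- filter(edges_all, !.data$self)
  all_nodes <- unique(c(source_motif, edges_all$source_tf, edges_all$target_tf))
  if (nrow(nonself) > 0) {
    g <- igraph::graph_from_data_frame(
      nonself[c("source_tf", "target_tf")], directed = TRUE,
      vertices = all_nodes)
    dist <- igraph::distances(g, v = source_motif, mode = "out")[1, ]
    level <- dist[all_nodes]
  } else {
    level <- stats::setNames(c(0, rep(Inf, length(all_nodes) - 1L)), all_nodes)
    level[source_motif] <- 0
  }
  keep <- names(level)[is.finite(level) & level <= max_level]
  nodes <- tibble(motif_id = keep, level = as.integer(level[keep])) |>
    arrange(.data$level, .data$motif_id)
  edges <- filter(edges_all, .data$source_tf %in% keep, .data$target_tf %in% keep)
  structure(list(nodes = nodes, edges = edges), class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("TF network: %d nodes over %d levels, %d edges (%d self)\n",
              nrow(x$nodes), length(unique(x$nodes$level)), nrow(x$edges),
              sum(x$edges$self)))
  invisible(x)
}

#' Write a TF network as a TSV edge list plus JSON node table
#'
#' @param network A `tf_network`.
#' @param edges_path,nodes_path Output paths.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(network, edges_path, nodes_path) {
  readr::write_tsv(network$edges, edges_path, progress = FALSE)
  jsonlite::write_json(network$nodes, nodes_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(edges_path)
}
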