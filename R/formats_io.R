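#' Read a FASTA file into a named vector of uppercase sequences
#'
#' @param path Path to a FASTA file.
#' @param ambiguous How to treat characters outside A/C/G/T/N: `"to_n"`
#'   (default) maps them to N, `"error"` rejects the file.
#' @return Named character vector, one uppercase DNA string per record.
#' @export
read_fasta <- function(path, ambiguous = c("to_n", "error")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty FASTA file: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate sequence name in %s: %s",
                  path, nm[duplicated(nm)][1]))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "error") {
      abort(sprintf("sequence %s contains characters outside A/C/G/T/N", nm[which(bad)[1]]))
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  stats::setNames(seqs, nm)
}

#' Read a BED file of genomic intervals
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Strand is
#' taken from column 6 when present, otherwise ".".
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) abort(sprintf("BED line %d has fewer than 3 columns", which(nf < 3)[1]))
  getcol <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  start_chr <- getcol(2)
  end_chr <- getcol(3)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | start_chr != as.character(start) |
                 end_chr != as.character(end))
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: non-integer coordinates ('%s', '%s')",
                  bad[1], start_chr[bad[1]], end_chr[bad[1]]))
  }
  inv <- which(start >= end)
  if (length(inv) > 0) {
    abort(sprintf("BED line %d: start >= end (%d >= %d)", inv[1], start[inv[1]], end[inv[1]]))
  }
  strand <- getcol(6, NA_character_)
  strand[!strand %in% c("+", "-")] <- "."
  tibble(
    chrom = getcol(1),
    start = start,
    end = end,
    name = getcol(4),
    score = suppressWarnings(as.double(getcol(5))),
    strand = strand
  )
}

#' Write intervals to a BED file
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`; extra columns are appended after column 6).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) dplyr::coalesce(as.character(x$name), ".") else ".",
    score = if ("score" %in% names(x)) dplyr::coalesce(as.character(x$score), "0") else "0",
    strand = if ("strand" %in% names(x)) dplyr::coalesce(x$strand, ".") else "."
  )
  extra <- setdiff(names(x), c("chrom", "start", "end", "name", "score", "strand"))
  for (col in extra) out[[col]] <- x[[col]]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Convert aligned fragments to single-base Tn5 cut events
#'
#' Each sequenced fragment marks two Tn5 insertions. Because Tn5 inserts as a
#' dimer and duplicates 9 bp, fragment ends must be shifted towards the
#' fragment interior to land on the insertion centers: the start by
#' `+shift_plus` and the last base (`end - 1`) by `-shift_minus`
#' (defaults +4/-5, the standard ATAC-seq convention).
#'
#' @param fragments Interval tibble of fragments (0-based half-open).
#' @param shift_plus,shift_minus Integer end shifts.
#' @param chrom_sizes Optional named integer vector of chromosome lengths;
#'   events outside `[0, size)` are dropped (a message reports the count).
#' @return A tibble of cut events with columns `chrom`, `pos` (0-based base
#'   of insertion) and `strand` (`+` for start-derived, `-` for end-derived).
#' @export
fragments_to_cutsites <- function(fragments, shift_plus = 4L, shift_minus = 5L,
                                  chrom_sizes = NULL) {
  check_intervals(fragments, "fragments")
  ev <- tibble(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start + shift_plus, fragments$end - 1L - shift_minus),
    strand = rep(c("+", "-"), each = nrow(fragments))
  )
  keep <- ev$pos >= 0L
  if (!is.null(chrom_sizes)) {
    sz <- unname(chrom_sizes[ev$chrom])
    keep <- keep & !is.na(sz) & ev$pos < sz
  }
  dropped <- sum(!keep)
  if (dropped > 0) inform(sprintf("dropped %d cut events outside chromosome bounds", dropped))
  ev[keep, , drop = FALSE]
}

#' Pile cut events into per-base observed cutsite tracks
#'
#' @param events Cut-event tibble (`chrom`, `pos`).
#' @param regions Disjoint interval tibble; overlapping regions are an error
#'   (merge with [merge_intervals()] first). Events outside all regions are
#'   ignored.
#' @return A track tibble: one row per region with columns `chrom`, `start`,
#'   `end`, `kind` (= "observed") and a list-column `values` of per-base
#'   counts.
#' @export
pileup <- function(events, regions) {
  check_intervals(regions, "regions")
  if (intervals_overlap(regions)) {
    abort("regions overlap; merge them first with merge_intervals()")
  }
  values <- vector("list", nrow(regions))
  ev_by_chrom <- split(events$pos, events$chrom)
  for (i in seq_len(nrow(regions))) {
    w <- regions$end[i] - regions$start[i]
    p <- ev_by_chrom[[regions$chrom[i]]]
    v <- numeric(w)
    if (!is.null(p)) {
      p <- p[p >= regions$start[i] & p < regions$end[i]]
      if (length(p) > 0) {
        tab <- tabulate(p - regions$start[i] + 1L, nbins = w)
        v <- as.numeric(tab)
      }
    }
    values[[i]] <- v
  }
  tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
         kind = "observed", values = values)
}

#' Write signal tracks to a bedGraph file
#'
#' Runs of equal value are merged into single lines; output is sorted by
#' chromosome and start. Round-trips losslessly through [read_bedgraph()].
#'
#' @param tracks Track tibble (`chrom`, `start`, `end`, `values` list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (nrow(tracks) == 0) return(invisible(path))
  tracks <- tracks[order(tracks$chrom, tracks$start), , drop = FALSE]
  lines <- unlist(lapply(seq_len(nrow(tracks)), function(i) {
    v <- tracks$values[[i]]
    r <- rle(v)
    ends <- tracks$start[i] + cumsum(r$lengths)
    starts <- ends - r$lengths
    sprintf("%s\t%d\t%d\t%.15g", tracks$chrom[i], starts, ends, r$values)
  }))
  writeLines(lines, con)
  invisible(path)
}

#' Read a bedGraph file into per-region signal tracks
#'
#' @param path Path to a bedGraph file.
#' @param regions Optional interval tibble declaring the regions to
#'   reconstruct; by default contiguous covered blocks become regions.
#' @param kind Track kind label to attach.
#' @return Track tibble as produced by [pileup()].
#' @export
read_bedgraph <- function(path, regions = NULL, kind = "observed") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  kind = character(), values = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  d <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)),
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    value = as.double(vapply(fields, `[[`, character(1), 4))
  ) |> arrange(.data$chrom, .data$start)
  if (is.null(regions)) {
    regions <- d |>
      group_by(.data$chrom) |>
      mutate(grp = cumsum(.data$start != dplyr::lag(.data$end, default = -1L))) |>
      group_by(.data$chrom, .data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      select("chrom", "start", "end")
  }
  values <- vector("list", nrow(regions))
  d_by_chrom <- split(d, d$chrom)
  for (i in seq_len(nrow(regions))) {
    w <- regions$end[i] - regions$start[i]
    v <- numeric(w)
    dc <- d_by_chrom[[regions$chrom[i]]]
    if (!is.null(dc)) {
      dc <- dc[dc$end > regions$start[i] & dc$start < regions$end[i], , drop = FALSE]
      for (j in seq_len(nrow(dc))) {
        lo <- max(dc$start[j], regions$start[i]) - regions$start[i] + 1L
        hi <- min(dc$end[j], regions$end[i]) - regions$start[i]
        v[lo:hi] <- dc$value[j]
      }
    }
    values[[i]] <- v
  }
  tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
         kind = kind, values = values)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2016+ text format: a `>ID name` header followed by four
#' rows `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of counts.
#' Per-column sums may differ between columns; counts are kept as given.
#'
#' @param path Path to a JASPAR PFM file (one or more motifs).
#' @return A tibble with one row per motif: `motif_id`, `name`, `length` and
#'   a list-column `pfm` (4 x L count matrix, rows A/C/G/T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) abort(sprintf("JASPAR file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0) abort("no motif headers ('>') found")
  bounds <- c(hdr, length(lines) + 1L)
  out <- lapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[hdr[i]])
    parts <- strsplit(header, "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1]
    rows <- lapply(BASES, function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1) abort(sprintf("motif %s: missing or duplicated %s row", motif_id, b))
      stripped <- sub(paste0("^", b), "", ln)
      nums <- regmatches(stripped, gregexpr("-?[0-9.]+", stripped))[[1]]
      as.numeric(nums)
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      abort(sprintf("motif %s: rows of unequal length (%s)", motif_id,
                    paste(lens, collapse = ",")))
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- BASES
    if (any(pfm < 0)) abort(sprintf("motif %s: negative counts", motif_id))
    tibble(motif_id = motif_id, name = name, length = ncol(pfm), pfm = list(pfm))
  })
  bind_rows(out)
}

#' Write motifs to a JASPAR-format PFM file
#'
#' @param motifs Tibble with `motif_id`, `name` and list-column `pfm`
#'   (4 x L counts, rows A/C/G/T).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(motifs))) {
    writeLines(sprintf(">%s %s", motifs$motif_id[i], motifs$name[i]), con)
    pfm <- motifs$pfm[[i]]
    for (b in seq_along(BASES)) {
      writeLines(sprintf("%s  [ %s ]", BASES[b],
                         paste(formatC(pfm[b, ], width = 6), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a minimal gene table (BED-like) and derive TSS positions
#'
#' Accepts a 6-column BED of gene spans (`name` = gene id, strand required).
#' The transcription start site is `start` for + genes and `end - 1` for -
#' genes.
#'
#' @param path Path to a BED6 file of gene spans.
#' @return A tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path) {
  g <- read_bed(path)
  if (any(!g$strand %in% c("+", "-"))) {
    abort("gene table requires strand '+' or '-' in column 6")
  }
  tibble(
    gene_id = g$name,
    chrom = g$chrom,
    tss = ifelse(g$strand == "+", g$start, g$end - 1L),
    strand = g$strand
  )
}
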