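#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr pmap imap walk
NULL

BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(BASES, BASES, paste0)) # AA,CA,GA,TA,AC,... column-major

# integer-encode an uppercase DNA string: A=1 C=2 G=3 T=4, anything else NA
encode_seq <- function(s) {
  x <- utf8ToInt(s)
  out <- rep(NA_integer_, length(x))
  out[x == 65L] <- 1L # A
  out[x == 67L] <- 2L # C
  out[x == 71L] <- 3L # G
  out[x == 84L] <- 4L # T
  out
}

decode_seq <- function(v) {
  ch <- c("A", "C", "G", "T")[v]
  ch[is.na(ch)] <- "N"
  paste(ch, collapse = "")
}

revcomp_int <- function(v) rev(5L - v)

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ordered dinucleotide code in 1..16 from two base codes (column-major as DINUCS)
dinuc_code <- function(b1, b2) b1 + 4L * (b2 - 1L)

# Dinucleotide log-weight matrices over overlapping window offsets are only
# identified up to "gauge" moves: a base potential h(b) can be shifted from
# the second-base margin of offset r to the first-base margin of offset r+1
# (and per-row constants) without changing any window's total weight. This
# returns a projector onto the orthogonal complement of that subspace -- the
# canonical (minimum-norm) representative -- so that two matrices describing
# the same bias compare cell for cell.
dinuc_gauge_project <- function(lw) {
  K <- nrow(lw)
  cell <- function(r, d) (d - 1L) * K + r
  cols <- list()
  if (K >= 2) {
    for (r in seq_len(K - 1L)) {
      for (b in 1:4) {
        v <- numeric(K * 16L)
        for (b1 in 1:4) v[cell(r, dinuc_code(b1, b))] <- 1
        for (b2 in 1:4) v[cell(r + 1L, dinuc_code(b, b2))] <- -1
        cols[[length(cols) + 1L]] <- v
      }
    }
  }
  for (r in seq_len(K)) {
    v <- numeric(K * 16L)
    v[cell(r, 1:16)] <- 1
    cols[[length(cols) + 1L]] <- v
  }
  G <- do.call(cbind, cols)
  qrG <- qr(G)
  Q <- qr.Q(qrG)[, seq_len(qrG$rank), drop = FALSE]
  v <- as.vector(lw)
  out <- matrix(v - Q %*% crossprod(Q, v), K, 16L)
  dimnames(out) <- dimnames(lw)
  out
}

# run function with a temporary RNG state seeded by `seed`; restores global state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sliding mean with window w (centered, truncated at edges); w = 1 is identity
sliding_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_intervals <- function(x, what = "intervals") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s", what, paste(missing_cols, collapse = ", ")))
  }
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval at row %d (start=%s end=%s)",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# TRUE if any two intervals (per chromosome) overlap
intervals_overlap <- function(x) {
  any(vapply(split(x, x$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])
  }, logical(1)))
}

#' Merge overlapping or bookended intervals
#'
#' Collapses a table of genomic intervals into its union, the standard
#' preprocessing for accessible-region ("peak") sets before pileup and
#' scanning. Strand is ignored; merged intervals carry strand ".".
#'
#' @param x A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A tibble of disjoint intervals sorted by chromosome and start.
#' @export
merge_intervals <- function(x) {
  check_intervals(x)
  x |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(grp = cumsum(.data$start > cummax(dplyr::lag(.data$end, default = -1L)))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    transmute(.data$chrom, .data$start, .data$end,
              name = NA_character_, score = NA_real_, strand = ".") |>
    arrange(.data$chrom, .data$start)
}
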