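#' Configuration for the synthetic footprinting dataset
#'
#' Defines a toy genome with accessible peaks, implanted motif instances
#' with known bound/unbound labels per condition, a known Tn5 dinucleotide
#' bias, and footprint-shaped depletion at bound sites. The same config
#' (including `seed`) always produces byte-identical output.
#'
#' @param seed Integer seed driving every random choice.
#' @param genome_length Total genome size in bp, split evenly over
#'   `n_chroms` chromosomes (default 200 kb over 2).
#' @param n_chroms Number of chromosomes (default 2).
#' @param n_peaks Number of accessible regions (default 200).
#' @param peak_width_mean,peak_width_sd,peak_width_min Peak width
#'   distribution (rounded normal, clipped; defaults 400/50/200 bp).
#' @param motifs Tibble with `motif_id` and `consensus` columns (implanted
#'   verbatim), or `NULL` for a bias-only dataset. Default: two 10-bp TF
#'   consensi.
#' @param n_sites_per_motif Implanted instances per motif (default 150).
#' @param conditions Condition names (default `c("A", "B")`).
#' @param bound_fraction Fraction of each motif's sites bound, recycled over
#'   motifs x conditions (scalar, per-condition vector, or
#'   motif x condition matrix; default 0.3).
#' @param footprint_depth Fractional depletion of insertion probability
#'   inside bound sites, in `[0, 1]` (default 0.5: a bound TF halves the
#'   local cut rate, typical of mid-residence-time factors).
#' @param bias_strength Scale of the true Tn5 dinucleotide preference: each
#'   log-weight cell is drawn N(0, 0.15 * bias_strength), giving per-base
#'   bias weights spanning roughly e^-1.3..e^1.3 at strength 1 (default 1).
#' @param reads_per_peak Mean Tn5 insertions per peak per condition
#'   (default 200, about 1 cut event per bp in a 400-bp peak).
#' @param accessibility_cv Peaks get a Gamma-distributed accessibility
#'   multiplier with mean 1 and this coefficient of variation (default 0.7,
#'   matching the wide dynamic range of real peak heights). Bound sites are
#'   preferentially placed in more accessible peaks.
#' @param anti_tn5_motif Optional consensus whose dinucleotides the true
#'   bias disfavors (never bound): a false-footprint control.
#' @param anti_strength Log-weight penalty per disfavored dinucleotide cell
#'   (default 0.3).
#' @param n_anti_sites Implanted instances of the anti-Tn5 motif
#'   (default 100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_chroms = 2L,
                       n_peaks = 200L,
                       peak_width_mean = 400,
                       peak_width_sd = 50,
                       peak_width_min = 200L,
                       motifs = default_sim_motifs(),
                       n_sites_per_motif = 150L,
                       conditions = c("A", "B"),
                       bound_fraction = 0.3,
                       footprint_depth = 0.5,
                       bias_strength = 1,
                       reads_per_peak = 200,
                       accessibility_cv = 0.7,
                       anti_tn5_motif = NULL,
                       anti_strength = 0.3,
                       n_anti_sites = 100L) {
  if (footprint_depth < 0 || footprint_depth > 1) abort("footprint_depth must be in [0, 1]")
  if (any(bound_fraction < 0 | bound_fraction > 1)) abort("bound fractions must be in [0, 1]")
  if (bias_strength < 0) abort("bias_strength must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Default simulated TF motif set
#'
#' @return Tibble of two 10-bp consensus motifs.
#' @export
default_sim_motifs <- function() {
  tibble(motif_id = c("simA", "simB"),
         consensus = c("TGACTCAGCA", "CCGGAAGTGA"))
}

#' Soft position frequency matrices for consensus motifs
#'
#' Builds a JASPAR-style PFM tibble from consensus strings: the consensus
#' base gets `match_count` counts per column, the other bases
#' `other_count`, giving an informative but not degenerate motif for the
#' scanner.
#'
#' @param motifs Tibble with `motif_id` and `consensus` (e.g.
#'   [default_sim_motifs()], or the `motifs` element of a [sim_config()]).
#' @param match_count,other_count Per-column counts (defaults 85 / 5).
#' @return Tibble compatible with [motif_models()] and [write_jaspar()]:
#'   `motif_id`, `name`, `length`, `pfm`.
#' @export
consensus_pfms <- function(motifs, match_count = 85, other_count = 5) {
  pfms <- map(motifs$consensus, function(s) {
    v <- encode_seq(s)
    if (anyNA(v)) abort(sprintf("consensus %s contains non-ACGT characters", s))
    m <- matrix(other_count, 4, length(v), dimnames = list(BASES, NULL))
    m[cbind(v, seq_along(v))] <- match_count
    m
  })
  tibble(motif_id = motifs$motif_id, name = motifs$motif_id,
         length = nchar(motifs$consensus), pfm = pfms)
}

# expand bound_fraction spec to a motifs x conditions matrix
bound_fraction_matrix <- function(cfg, motif_ids) {
  bf <- cfg$bound_fraction
  n_m <- length(motif_ids)
  n_c <- length(cfg$conditions)
  if (is.matrix(bf)) {
    stopifnot(nrow(bf) == n_m, ncol(bf) == n_c)
    m <- bf
  } else if (length(bf) == n_c) {
    m <- matrix(bf, n_m, n_c, byrow = TRUE)
  } else {
    m <- matrix(rep_len(bf, n_m * n_c), n_m, n_c)
  }
  dimnames(m) <- list(motif_ids, cfg$conditions)
  m
}

# draw the true dinucleotide log-weight matrix ((k-1) x 16)
draw_true_bias <- function(cfg, window = 20L) {
  lw <- matrix(stats::rnorm((window - 1L) * 16L, 0, 0.15 * cfg$bias_strength),
               nrow = window - 1L, ncol = 16L, dimnames = list(NULL, DINUCS))
  if (!is.null(cfg$anti_tn5_motif)) {
    v <- encode_seq(cfg$anti_tn5_motif)
    dn <- unique(dinuc_code(v[-length(v)], v[-1L]))
    lw[, dn] <- lw[, dn] - cfg$anti_strength
  }
  # report the ground truth in the canonical gauge; gauge moves leave every
  # window's weight (and hence the simulated data) unchanged
  dinuc_gauge_project(lw)
}

# bias_model object from a true log-weight matrix (uniform background)
true_bias_model <- function(lw, window = 20L) {
  bg <- matrix(1 / 16, nrow = window - 1L, ncol = 16L,
               dimnames = list(NULL, DINUCS))
  w <- exp(lw) / 16
  dn <- w / rowSums(w)
  colnames(dn) <- DINUCS
  structure(list(window = as.integer(window), dinuc_probs = dn,
                 background_probs = bg, pseudocount = 0,
                 n_events = NA_integer_, log_weights = lw),
            class = "bias_model")
}

#' Generate a synthetic footprinting dataset with known ground truth
#'
#' Builds an i.i.d.-uniform genome, places disjoint accessible peaks,
#' implants motif consensus instances at known positions, draws a true Tn5
#' dinucleotide bias, assigns bound/unbound labels per condition
#' (preferentially bound in more accessible peaks), and samples Tn5
#' insertions per condition with per-base probability proportional to
#' accessibility x sequence-bias weight x (1 - footprint_depth at bound
#' sites). Each insertion at base p is emitted as a fragment `[p-4, p+6)`,
#' so the standard +4/-5 cutsite shifts place both derived cut events back
#' at p.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset` list: `genome` (named character vector), `peaks`
#'   (interval tibble with `accessibility`), `fragments` (named list of
#'   interval tibbles, one per condition), `truth` (site tibble with
#'   `bound_<condition>` columns), `true_bias` (a `bias_model` with the
#'   generating log-weights), `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chrom_len <- as.integer(cfg$genome_length / cfg$n_chroms)
    chroms <- paste0("chr", seq_len(cfg$n_chroms))

    genome_chars <- lapply(chroms, function(ch) {
      sample(BASES, chrom_len, replace = TRUE)
    })
    names(genome_chars) <- chroms

    # peaks: one per equal slot, random offset, non-overlapping by design
    per_chrom <- ceiling(cfg$n_peaks / cfg$n_chroms)
    slot <- chrom_len %/% per_chrom
    peaks <- bind_rows(lapply(seq_along(chroms), function(ci) {
      n_here <- min(per_chrom, cfg$n_peaks - (ci - 1L) * per_chrom)
      if (n_here <= 0) return(NULL)
      w <- pmin(pmax(round(stats::rnorm(n_here, cfg$peak_width_mean,
                                        cfg$peak_width_sd)),
                     cfg$peak_width_min), slot - 60L)
      off <- floor(stats::runif(n_here, 30, slot - w - 30))
      start <- (seq_len(n_here) - 1L) * slot + as.integer(off)
      tibble(chrom = chroms[ci], start = start, end = start + as.integer(w))
    }))
    peaks$name <- sprintf("peak%d", seq_len(nrow(peaks)))
    shape <- 1 / cfg$accessibility_cv^2
    peaks$accessibility <- stats::rgamma(nrow(peaks), shape = shape,
                                         rate = shape)
    peaks$strand <- "."
    peaks$score <- NA_real_

    # implant motif instances (exact consensus), one strand, non-overlapping
    motif_tbl <- cfg$motifs
    if (!is.null(cfg$anti_tn5_motif)) {
      motif_tbl <- bind_rows(motif_tbl,
                             tibble(motif_id = "antiTn5",
                                    consensus = cfg$anti_tn5_motif))
    }
    truth <- NULL
    occupied <- replicate(nrow(peaks), IRanges::IRanges(), simplify = FALSE)
    if (!is.null(motif_tbl) && nrow(motif_tbl) > 0) {
      site_rows <- list()
      for (m in seq_len(nrow(motif_tbl))) {
        mid <- motif_tbl$motif_id[m]
        cons <- motif_tbl$consensus[m]
        L <- nchar(cons)
        n_want <- if (mid == "antiTn5") cfg$n_anti_sites else cfg$n_sites_per_motif
        margin <- 70L # aggregate flank + slack inside the peak
        placed <- 0L
        attempts <- 0L
        while (placed < n_want && attempts < 50L * n_want) {
          attempts <- attempts + 1L
          pi <- sample.int(nrow(peaks), 1L)
          lo <- peaks$start[pi] + margin
          hi <- peaks$end[pi] - margin - L
          if (hi < lo) next
          s <- as.integer(floor(stats::runif(1, lo, hi + 1)))
          r <- IRanges::IRanges(s + 1L, s + L)
          if (IRanges::countOverlaps(r, occupied[[pi]]) > 0) next
          occupied[[pi]] <- c(occupied[[pi]], r)
          placed <- placed + 1L
          site_rows[[length(site_rows) + 1L]] <- tibble(
            motif_id = mid, chrom = peaks$chrom[pi], start = s, end = s + L,
            strand = "+", peak = pi)
        }
        if (placed < n_want) {
          warn(sprintf("motif %s: placed %d of %d sites", mid, placed, n_want))
        }
      }
      truth <- bind_rows(site_rows)
      # write consensi into the genome
      for (i in seq_len(nrow(truth))) {
        cons <- motif_tbl$consensus[match(truth$motif_id[i], motif_tbl$motif_id)]
        idx <- (truth$start[i] + 1L):truth$end[i]
        genome_chars[[truth$chrom[i]]][idx] <- strsplit(cons, "")[[1]]
      }
      # bound labels: exact per-motif counts, weighted towards accessible peaks
      bfm <- bound_fraction_matrix(cfg, motif_tbl$motif_id)
      for (cc in cfg$conditions) {
        col <- paste0("bound_", cc)
        truth[[col]] <- FALSE
        for (mid in motif_tbl$motif_id) {
          if (mid == "antiTn5") next
          sel <- which(truth$motif_id == mid)
          n_bound <- round(bfm[mid, cc] * length(sel))
          if (n_bound > 0) {
            wts <- peaks$accessibility[truth$peak[sel]]
            pick <- sample(sel, n_bound, prob = wts)
            truth[[col]][pick] <- TRUE
          }
        }
      }
    }

    genome <- vapply(genome_chars, paste, character(1), collapse = "")
    lw <- draw_true_bias(cfg)
    tb <- true_bias_model(lw)

    # per-base insertion intensity inside each peak, shared across conditions
    bias_tracks <- score_sequence_bias(tb, genome, peaks)

    fragments <- stats::setNames(vector("list", length(cfg$conditions)),
                                 cfg$conditions)
    for (cc in cfg$conditions) {
      frag_rows <- list()
      for (pi in seq_len(nrow(peaks))) {
        u <- bias_tracks$values[[pi]]
        if (!is.null(truth)) {
          here <- truth[truth$peak == pi, , drop = FALSE]
          if (nrow(here) > 0) {
            bcol <- paste0("bound_", cc)
            for (j in seq_len(nrow(here))) {
              if (isTRUE(here[[bcol]][j])) {
                idx <- (here$start[j] - peaks$start[pi] + 1L):
                  (here$end[j] - peaks$start[pi])
                u[idx] <- u[idx] * (1 - cfg$footprint_depth)
              }
            }
          }
        }
        n_ins <- stats::rpois(1, cfg$reads_per_peak * peaks$accessibility[pi])
        if (n_ins == 0 || sum(u) == 0) next
        pos_local <- sample.int(length(u), n_ins, replace = TRUE, prob = u)
        p <- peaks$start[pi] + pos_local - 1L
        frag_rows[[length(frag_rows) + 1L]] <- tibble(
          chrom = peaks$chrom[pi], start = p - 4L, end = p + 6L)
      }
      fr <- bind_rows(frag_rows)
      fragments[[cc]] <- fr[order(fr$chrom, fr$start), , drop = FALSE]
    }

    structure(list(genome = genome, peaks = peaks, fragments = fragments,
                   truth = truth, true_bias = tb, config = cfg),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic footprinting dataset: %d chroms (%s bp), %d peaks, %s truth sites, conditions: %s\n",
    length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
    nrow(x$peaks), if (is.null(x$truth)) "no" else nrow(x$truth),
    paste(names(x$fragments), collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `genome.fa`, `peaks.bed`, `fragments_<condition>.bed`, `truth.tsv`
#' and `true_bias.json` under `dir`.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(sim$genome), function(ch) {
    c(paste0(">", ch), sim$genome[[ch]])
  })), fa)
  write_bed(sim$peaks, file.path(dir, "peaks.bed"))
  for (cc in names(sim$fragments)) {
    write_bed(sim$fragments[[cc]],
              file.path(dir, sprintf("fragments_%s.bed", cc)))
  }
  if (!is.null(sim$truth)) {
    readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  write_bias_model(sim$true_bias, file.path(dir, "true_bias.json"))
  invisible(dir)
}

#' Serialize / restore a bias model as JSON
#'
#' @param model A `bias_model`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_bias_model()` returns the model.
#' @export
write_bias_model <- function(model, path) {
  jsonlite::write_json(
    list(window = model$window,
         dinuc_probs = model$dinuc_probs,
         background_probs = model$background_probs,
         pseudocount = model$pseudocount,
         n_events = model$n_events),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bias_model
#' @export
read_bias_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- as.matrix(x$dinuc_probs)
  bg <- as.matrix(x$background_probs)
  colnames(dn) <- colnames(bg) <- DINUCS
  structure(list(window = as.integer(x$window), dinuc_probs = dn,
                 background_probs = bg, pseudocount = x$pseudocount,
                 n_events = x$n_events),
            class = "bias_model")
}

#' Area under the ROC curve by explicit rank counting
#'
#' Mann-Whitney formulation: the average rank of the positive scores, with
#' ties sharing mid-ranks, converted to the probability that a random
#' positive outscores a random negative.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Logical (or 0/1) truth labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compare binding predictions with simulation truth
#'
#' Joins predicted sites to truth sites by exact interval and motif match,
#' then reports AUROC of the prediction score against the true bound label,
#' precision/recall of the predicted bound flag, and the absolute error of
#' the predicted bound fraction.
#'
#' @param predictions Site tibble with `motif_id`, `chrom`, `start`, `end`,
#'   a score column and a bound column.
#' @param truth Truth tibble from [simulate_dataset()].
#' @param condition Condition name; uses `bound_<condition>` in `truth`.
#' @param score_col,bound_col Column names in `predictions` (defaults
#'   `norm_<condition>` and `bound_<condition>`).
#' @return One-row tibble: `n_matched`, `auroc`, `precision`, `recall`,
#'   `bound_fraction_error`.
#' @export
truth_metrics <- function(predictions, truth, condition,
                          score_col = paste0("norm_", condition),
                          bound_col = paste0("bound_", condition)) {
  tcol <- paste0("bound_", condition)
  j <- inner_join(predictions, truth[c("motif_id", "chrom", "start", "end", tcol)],
                  by = c("motif_id", "chrom", "start", "end"),
                  suffix = c("", ".truth"))
  truth_lab <- j[[if (tcol %in% names(predictions)) paste0(tcol, ".truth") else tcol]]
  if (nrow(j) == 0) abort("no overlap between predictions and truth sites")
  pred_bound <- j[[bound_col]]
  tp <- sum(pred_bound & truth_lab)
  precision <- if (sum(pred_bound) == 0) NA_real_ else tp / sum(pred_bound)
  recall <- if (sum(truth_lab) == 0) NA_real_ else tp / sum(truth_lab)
  au <- if (sum(truth_lab) == 0 || sum(!truth_lab) == 0) NA_real_ else
    auroc(j[[score_col]], truth_lab)
  tibble(n_matched = nrow(j), auroc = au, precision = precision,
         recall = recall,
         bound_fraction_error = abs(mean(pred_bound) - mean(truth_lab)))
}
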