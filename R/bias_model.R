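#' Estimate Tn5 sequence bias as a dinucleotide weight matrix
#'
#' Tn5 prefers particular sequence contexts around its insertion point, which
#' imprints footprint-like structure on ATAC-seq signal that has nothing to do
#' with protein binding. The preference is modelled as a dinucleotide weight
#' matrix (DWM): for a window of `window` bases centered on the insertion
#' point, the probability of each ordered dinucleotide at each of the
#' `window - 1` offsets, estimated from all event-centered windows and
#' contrasted against the background dinucleotide composition of the supplied
#' regions.
#'
#' @param events Cut-event tibble (`chrom`, `pos`, optionally `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @param regions Interval tibble of accessible regions supplying the
#'   background composition; background windows are centered at every region
#'   position (subsampled to `bg_sample` when larger, seeded).
#' @param window Even window size in bp around the insertion point
#'   (default 20: 10 left, 10 right).
#' @param pseudocount Count added to every dinucleotide cell before row
#'   normalization (default 1).
#' @param stranded If `TRUE`, events on the minus strand are counted on the
#'   reverse-complement window. Default `FALSE`: with the standard +4/-5
#'   shifts both fragment-end events mark the same centered insertion, so all
#'   windows are read on the forward strand.
#' @param bg_sample Maximum number of background window positions (default
#'   100000).
#' @param seed Seed for background subsampling; same seed gives a
#'   bit-identical model.
#' @param refine If `TRUE` (default), the marginal dinucleotide estimate is
#'   refined by iterative proportional fitting. Window offsets overlap (the
#'   dinucleotides at offsets r and r+1 share a base), so raw marginal
#'   frequencies at one offset absorb part of the preference acting at its
#'   neighbors; the refinement fits the product-over-offsets model by
#'   maximum likelihood, matching the observed marginals over the
#'   background window population and thereby unmixing the overlap
#'   leakage.
#' @param max_iter,tol Refinement iteration cap and convergence tolerance
#'   on the largest log-weight update.
#' @return A `bias_model` object: `window`, `dinuc_probs` ((window-1) x 16,
#'   rows sum to 1), `background_probs` (same shape), `pseudocount`,
#'   `n_events`.
#' @export
estimate_bias <- function(events, genome, regions, window = 20L,
                          pseudocount = 1, stranded = FALSE,
                          bg_sample = 100000L, seed = NULL,
                          refine = TRUE, max_iter = 50L, tol = 1e-3) {
  if (window < 4L || window %% 2L != 0L) abort("window must be even and >= 4")
  check_intervals(regions, "regions")
  if (nrow(events) == 0) abort("no cut events supplied")
  if (nrow(events) < 1000) {
    warn(sprintf("only %d cut events; bias estimates will be noisy (>= 1000 recommended)",
                 nrow(events)))
  }
  half <- window %/% 2L
  codes <- lapply(genome, encode_seq)

  # dinucleotide codes of all full windows centered at pos: n x (window-1)
  window_dinucs <- function(chrom, pos, minus = NULL) {
    out <- list()
    for (ch in unique(chrom)) {
      cv <- codes[[ch]]
      if (is.null(cv)) abort(sprintf("chromosome %s not in genome", ch))
      sel <- chrom == ch
      p <- pos[sel]
      ok <- p - half >= 0L & p + half - 1L <= length(cv) - 1L
      p <- p[ok]
      if (length(p) == 0) next
      idx <- outer(p + 1L - half, 0:(window - 1L), `+`)
      b <- matrix(cv[idx], nrow = length(p))
      if (!is.null(minus)) {
        m <- minus[sel][ok]
        if (any(m)) b[m, ] <- 5L - b[m, window:1L, drop = FALSE]
      }
      d <- dinuc_code(b[, -window, drop = FALSE], b[, -1L, drop = FALSE])
      out[[length(out) + 1L]] <- d[stats::complete.cases(d), , drop = FALSE]
    }
    if (length(out) == 0) return(matrix(integer(0), 0, window - 1L))
    do.call(rbind, out)
  }
  count_dinucs <- function(D) {
    t(apply(D, 2, tabulate, nbins = 16L))
  }

  minus <- if (stranded && "strand" %in% names(events)) events$strand == "-" else NULL
  Dfg <- window_dinucs(events$chrom, events$pos, minus)
  if (nrow(Dfg) == 0) abort("no cut events with a full sequence window inside the genome")
  fg <- count_dinucs(Dfg)

  bg_pos <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    tibble(chrom = regions$chrom[i], pos = seq(regions$start[i], regions$end[i] - 1L))
  }))
  if (nrow(bg_pos) > bg_sample) {
    keep <- with_seed(seed, sample.int(nrow(bg_pos), bg_sample))
    bg_pos <- bg_pos[sort(keep), , drop = FALSE]
  }
  Dbg <- window_dinucs(bg_pos$chrom, bg_pos$pos)
  if (nrow(Dbg) == 0) abort("no background windows inside the genome")
  bg <- count_dinucs(Dbg)

  normalize <- function(m) {
    m <- m + pseudocount
    m / rowSums(m)
  }
  p_obs <- normalize(fg)
  bgp <- normalize(bg)
  lw <- log(p_obs / bgp)

  if (refine) {
    # coordinate-wise iterative proportional fitting: one offset at a time,
    # keeping the window weights updated incrementally
    K <- window - 1L
    lw <- matrix(0, K, 16L)
    w <- rep(1, nrow(Dbg))
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (r in seq_len(K)) {
        wbar <- mean(w)
        wc <- numeric(16)
        rs <- rowsum(w, Dbg[, r])
        wc[as.integer(rownames(rs))] <- rs[, 1]
        p_model <- (wc + pseudocount * wbar) /
          (sum(wc) + 16 * pseudocount * wbar)
        upd <- log(p_obs[r, ] / p_model)
        upd <- upd - mean(upd)
        delta <- max(delta, max(abs(upd)))
        lw[r, ] <- lw[r, ] + upd
        w <- w * exp(upd[Dbg[, r]])
        w <- w / mean(w)
      }
      if (delta < tol) break
    }
    lw <- dinuc_gauge_project(lw)
  }

  dn <- bgp * exp(lw)
  dn <- dn / rowSums(dn)
  colnames(dn) <- colnames(bgp) <- DINUCS
  structure(
    list(window = as.integer(window), dinuc_probs = dn, background_probs = bgp,
         pseudocount = pseudocount, n_events = nrow(events)),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("Tn5 dinucleotide bias model: window %d bp, %d offsets x 16 dinucleotides, fit on %d events\n",
              x$window, x$window - 1L, x$n_events))
  lr <- log(x$dinuc_probs / x$background_probs)
  cat(sprintf("max |log-ratio| vs background: %.3f\n", max(abs(lr))))
  invisible(x)
}

#' Tidy a Tn5 bias model into a long tibble
#'
#' @param x A `bias_model`.
#' @param ... Unused.
#' @return A tibble with one row per (offset, dinucleotide):
#'   `offset`, `dinuc`, `prob`, `background`, `log_ratio`.
#' @export
tidy.bias_model <- function(x, ...) {
  k <- x$window - 1L
  tibble(
    offset = rep(seq_len(k), times = 16L),
    dinuc = rep(DINUCS, each = k),
    prob = as.vector(x$dinuc_probs),
    background = as.vector(x$background_probs),
    log_ratio = as.vector(log(x$dinuc_probs / x$background_probs))
  )
}

#' @rdname tidy.bias_model
#' @export
glance.bias_model <- function(x, ...) {
  tibble(window = x$window, n_events = x$n_events,
         pseudocount = x$pseudocount,
         max_abs_log_ratio = max(abs(log(x$dinuc_probs / x$background_probs))))
}

#' Per-position Tn5 bias weights for regions
#'
#' The bias weight at a position is the product over window offsets of the
#' ratio of the model's dinucleotide probability to the background
#' probability, computed in log space. Windows containing N or running off
#' the chromosome get weight 1 (background).
#'
#' @param model A `bias_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param regions Interval tibble.
#' @return Track tibble with `kind = "bias"`, one row per region.
#' @export
score_sequence_bias <- function(model, genome, regions) {
  check_intervals(regions, "regions")
  k <- model$window
  half <- k %/% 2L
  lw <- log(model$dinuc_probs / model$background_probs) # (k-1) x 16
  codes <- lapply(genome, encode_seq)
  values <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cv <- codes[[regions$chrom[i]]]
    if (is.null(cv)) abort(sprintf("chromosome %s not in genome", regions$chrom[i]))
    W <- regions$end[i] - regions$start[i]
    # sequence segment covering all windows, padded with NA off-chromosome
    seg_from <- regions$start[i] - half       # 0-based
    seg_to <- regions$end[i] - 1L + half
    seg_idx <- seg_from:seg_to
    seg <- rep(NA_integer_, length(seg_idx))
    ok <- seg_idx >= 0L & seg_idx <= length(cv) - 1L
    seg[ok] <- cv[seg_idx[ok] + 1L]
    dc <- dinuc_code(seg[-length(seg)], seg[-1L])  # dinuc starting at each seg pos
    logw <- numeric(W)
    bad <- logical(W)
    for (r in seq_len(k - 1L)) {
      d <- dc[seq_len(W) + r - 1L]
      na <- is.na(d)
      bad <- bad | na
      d[na] <- 1L
      logw <- logw + lw[r, d]
    }
    logw[bad] <- 0
    values[[i]] <- unname(exp(logw))
  }
  tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
         kind = "bias", values = values)
}

track_align <- function(a, b, what) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom & a$start == b$start & a$end == b$end)) {
    abort(sprintf("%s: tracks must cover identical regions", what))
  }
}

#' Expected cutsite track under the sequence-bias model
#'
#' Redistributes each region's total observed cut count proportionally to the
#' per-position bias weight: the signal Tn5 alone would produce in that
#' region. Per region, the expected values sum exactly to the observed sum.
#'
#' @param observed Observed track tibble (from [pileup()]).
#' @param bias Bias-weight track tibble (from [score_sequence_bias()]),
#'   covering the same regions.
#' @return Track tibble with `kind = "expected"`.
#' @export
expected_track <- function(observed, bias) {
  track_align(observed, bias, "expected_track")
  exp_values <- map2(observed$values, bias$values, function(o, b) {
    tot <- sum(o)
    if (tot == 0) return(numeric(length(o)))
    sb <- sum(b)
    if (sb <= 0) return(rep(tot / length(o), length(o)))
    b / sb * tot
  })
  mutate(observed, kind = "expected", values = !!exp_values)
}

#' Bias-corrected cutsite track
#'
#' Subtracts the expected (bias-driven) signal from the observed signal,
#' optionally after smoothing both with a centered sliding mean. The
#' corrected track sums to ~0 per region and highlights protein-driven
#' depletion with sequence bias removed.
#'
#' @param observed,expected Track tibbles over identical regions.
#' @param smooth_w Sliding-mean window (default 1 = no smoothing).
#' @return Track tibble with `kind = "corrected"`.
#' @export
correct_track <- function(observed, expected, smooth_w = 1L) {
  track_align(observed, expected, "correct_track")
  corr_values <- map2(observed$values, expected$values, function(o, e) {
    sliding_mean(o, smooth_w) - sliding_mean(e, smooth_w)
  })
  mutate(observed, kind = "corrected", values = !!corr_values)
}

#' One-call Tn5 bias correction (the full observed/bias/expected/corrected bundle)
#'
#' Convenience wrapper chaining [pileup()], [estimate_bias()],
#' [score_sequence_bias()], [expected_track()] and [correct_track()].
#'
#' @inheritParams estimate_bias
#' @param smooth_w Passed to [correct_track()].
#' @param model Optional pre-fit `bias_model`; estimated from `events` when
#'   `NULL`.
#' @return A list with elements `observed`, `bias`, `expected`, `corrected`
#'   (track tibbles over the same regions) and `model`.
#' @export
bias_correct <- function(events, genome, regions, window = 20L,
                         pseudocount = 1, stranded = FALSE, smooth_w = 1L,
                         bg_sample = 100000L, seed = NULL, model = NULL) {
  regions <- merge_intervals(regions)
  observed <- pileup(events, regions)
  if (is.null(model)) {
    model <- estimate_bias(events, genome, regions, window = window,
                           pseudocount = pseudocount, stranded = stranded,
                           bg_sample = bg_sample, seed = seed)
  }
  bias <- score_sequence_bias(model, genome, regions)
  expected <- expected_track(observed, bias)
  corrected <- correct_track(observed, expected, smooth_w = smooth_w)
  list(observed = observed, bias = bias, expected = expected,
       corrected = corrected, model = model)
}
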