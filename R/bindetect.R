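#' Build scoring models from position frequency matrices
#'
#' Converts PFM counts to log-odds matrices
#' `log2(((count + pc) / (colsum + 4 pc)) / bg)` and derives a match-score
#' threshold at a given p-value under the background base composition. The
#' score distribution of a random background k-mer is computed exactly by
#' dynamic-programming convolution over columns on a discretized score grid;
#' the threshold is the smallest score whose upper-tail probability is at
#' most `pval`.
#'
#' @param motifs Tibble from [read_jaspar()] (`motif_id`, `name`, `pfm`).
#' @param bg Background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount Added per PFM cell before normalization (default 1).
#' @param pval Match p-value defining the threshold (default 1e-4).
#' @param granularity Score discretization step in bits for the DP
#'   (default 0.001).
#' @return Input tibble with added list-column `logodds` (4 x L), `bg`
#'   (length-4), and numeric `threshold`.
#' @export
motif_models <- function(motifs, bg = rep(0.25, 4), pseudocount = 1,
                         pval = 1e-4, granularity = 0.001) {
  bg <- bg / sum(bg)
  lo_list <- map(motifs$pfm, function(pfm) {
    if (ncol(pfm) < 4) warn("motif shorter than 4 bp; matches will be unspecific")
    probs <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
    log2(probs / bg)
  })
  thr <- map_dbl(lo_list, motif_score_threshold, bg = bg, pval = pval,
                 granularity = granularity)
  motifs |>
    mutate(logodds = lo_list, bg = list(bg), threshold = thr)
}

# exact upper-tail threshold of the discretized log-odds score under bg
motif_score_threshold <- function(logodds, bg, pval = 1e-4, granularity = 0.001) {
  sc <- round(logodds / granularity) # 4 x L integer scores
  lo_min <- sum(apply(sc, 2, min))
  lo_max <- sum(apply(sc, 2, max))
  width <- lo_max - lo_min + 1L
  dist <- numeric(width) # index s - running_min + 1
  dist[1L] <- 1
  run_min <- 0L
  run_max <- 0L
  for (j in seq_len(ncol(sc))) {
    new_min <- run_min + min(sc[, j])
    new_max <- run_max + max(sc[, j])
    nd <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      off <- run_min + sc[b, j] - new_min
      idx <- seq_len(run_max - run_min + 1L)
      nd[idx + off] <- nd[idx + off] + dist[idx] * bg[b]
    }
    dist <- nd
    run_min <- new_min
    run_max <- new_max
  }
  tail_p <- rev(cumsum(rev(dist)))
  hit <- which(tail_p <= pval)
  # rounding each column to the grid moves a k-mer's total score by at most
  # L*granularity/2, so lift the threshold by that margin: any real score
  # reaching it must round to a grid score in the <= pval tail
  margin <- ncol(sc) * granularity / 2
  if (length(hit) == 0) {
    # short/degenerate motifs: even the best k-mer is more frequent than
    # pval under the background; fall back to exact-best matches only
    return(run_max * granularity - margin)
  }
  (run_min + hit[1L] - 1L) * granularity + margin
}

# score every start position of coded sequence v with a 4 x L matrix
scan_scores <- function(v, mat) {
  L <- ncol(mat)
  n <- length(v) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    b <- v[j:(j + n - 1L)]
    sj <- unname(mat[, j])[b]
    sj[is.na(b)] <- -Inf
    s <- s + sj
  }
  s
}

#' Scan genomic regions for motif matches
#'
#' Both strands are scanned; a binding site is reported wherever the
#' log-odds score meets the motif's threshold. Overlapping matches of the
#' same motif on the same strand are resolved by keeping the higher score
#' (ties broken leftmost).
#'
#' @param motifs Tibble from [motif_models()].
#' @param genome Named character vector of chromosome sequences.
#' @param regions Disjoint interval tibble.
#' @return Binding-site tibble: `chrom`, `start`, `end`, `strand`,
#'   `motif_id`, `match_score`, sorted by motif, chromosome, start.
#' @export
scan_motifs <- function(motifs, genome, regions) {
  check_intervals(regions, "regions")
  codes <- lapply(genome, encode_seq)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    cv <- codes[[regions$chrom[i]]]
    if (is.null(cv)) abort(sprintf("chromosome %s not in genome", regions$chrom[i]))
    v <- cv[(regions$start[i] + 1L):regions$end[i]]
    for (m in seq_len(nrow(motifs))) {
      lo <- motifs$logodds[[m]]
      L <- ncol(lo)
      if (L > length(v)) next
      lo_rc <- lo[4:1, L:1, drop = FALSE] # reverse-complement motif
      for (str in c("+", "-")) {
        s <- scan_scores(v, if (str == "+") lo else lo_rc)
        hit <- which(s >= motifs$threshold[m])
        if (length(hit) == 0) next
        out[[length(out) + 1L]] <- tibble(
          chrom = regions$chrom[i],
          start = regions$start[i] + hit - 1L,
          end = regions$start[i] + hit - 1L + L,
          strand = str,
          motif_id = motifs$motif_id[m],
          match_score = s[hit]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), motif_id = character(),
                  match_score = double()))
  }
  sites <- bind_rows(out)
  sites |>
    group_by(.data$motif_id, .data$strand, .data$chrom) |>
    group_modify(~ resolve_overlaps(.x)) |>
    ungroup() |>
    arrange(.data$motif_id, .data$chrom, .data$start) |>
    select("chrom", "start", "end", "strand", "motif_id", "match_score")
}

# greedy same-strand overlap resolution: best score first, ties leftmost
resolve_overlaps <- function(d) {
  if (nrow(d) <= 1) return(d)
  d <- d[order(-d$match_score, d$start), , drop = FALSE]
  kept <- logical(nrow(d))
  taken <- IRanges::IRanges()
  for (i in seq_len(nrow(d))) {
    r <- IRanges::IRanges(d$start[i] + 1L, d$end[i])
    if (IRanges::countOverlaps(r, taken) == 0) {
      kept[i] <- TRUE
      taken <- c(taken, r)
    }
  }
  d[kept, , drop = FALSE]
}

# locate, for each site, the index of the track region containing it (NA if none)
site_region_index <- function(sites, tracks) {
  tr <- split(seq_len(nrow(tracks)), tracks$chrom)
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in names(tr)) {
    ti <- tr[[ch]]
    rng <- IRanges::IRanges(tracks$start[ti] + 1L, tracks$end[ti])
    sel <- which(sites$chrom == ch)
    if (length(sel) == 0) next
    srng <- IRanges::IRanges(sites$start[sel] + 1L, sites$end[sel])
    ov <- IRanges::findOverlaps(srng, rng, type = "within", select = "first")
    idx[sel] <- ti[ov]
  }
  idx
}

#' Assign per-condition footprint scores to binding sites
#'
#' Each site's score in a condition summarizes the footprint-score track
#' over the site interval extended by `agg_window` bp on each side
#' (default: half the motif length), clipped to the containing region. The
#' default summary is the mean over that window; `agg = "max"` takes the
#' window maximum instead (more sensitive to a sharp optimum, but on sparse
#' signal it chases noise peaks). Sites outside all scored regions get
#' score 0 and `in_region = FALSE`.
#'
#' @param sites Binding-site tibble from [scan_motifs()].
#' @param score_tracks Named list (one element per condition) of footprint
#'   track tibbles over identical regions.
#' @param agg_window Extension in bp; `NULL` means half the motif length.
#' @param agg Window summary: `"mean"` (default) or `"max"`.
#' @return `sites` with `in_region` and one `score_<condition>` column per
#'   condition.
#' @export
score_sites <- function(sites, score_tracks, agg_window = NULL,
                        agg = c("mean", "max")) {
  agg_fun <- match.fun(match.arg(agg))
  if (is.null(names(score_tracks)) || any(!nzchar(names(score_tracks)))) {
    abort("score_tracks must be a named list (one track set per condition)")
  }
  conds <- names(score_tracks)
  ref <- score_tracks[[1]]
  for (cc in conds[-1]) track_align(ref, score_tracks[[cc]], "score_sites")
  ridx <- site_region_index(sites, ref)
  sites$in_region <- !is.na(ridx)
  aw <- if (is.null(agg_window)) (sites$end - sites$start) %/% 2L else
    rep(as.integer(agg_window), nrow(sites))
  for (cc in conds) {
    tv <- score_tracks[[cc]]$values
    sc <- numeric(nrow(sites))
    ok <- which(sites$in_region)
    for (i in ok) {
      ri <- ridx[i]
      lo <- max(sites$start[i] - aw[i], ref$start[ri]) - ref$start[ri] + 1L
      hi <- min(sites$end[i] + aw[i], ref$end[ri]) - ref$start[ri]
      sc[i] <- agg_fun(tv[[ri]][lo:hi])
    }
    sites[[paste0("score_", cc)]] <- sc
  }
  sites
}

#' Quantile-normalize per-condition site scores
#'
#' Full quantile normalization of the per-condition score distributions over
#' the union of all motifs' sites: each condition's sorted scores are mapped
#' to the mean of the sorted scores across conditions (ties share the mean
#' of the values they span). This places all conditions on a common scale so
#' that global shifts in signal depth do not masquerade as TF activity
#' changes. With a single condition the scores are returned unchanged.
#'
#' @param sites Site tibble with `score_<condition>` columns.
#' @param conditions Character vector of condition names; default: all
#'   `score_*` columns.
#' @return `sites` with added `norm_<condition>` columns.
#' @export
normalize_scores <- function(sites, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- sub("^score_", "", grep("^score_", names(sites), value = TRUE))
  }
  if (length(conditions) == 0) abort("no score_<condition> columns found")
  m <- as.matrix(sites[paste0("score_", conditions)])
  if (length(conditions) == 1) {
    nm <- m
  } else {
    nm <- limma::normalizeQuantiles(m, ties = TRUE)
  }
  colnames(nm) <- paste0("norm_", conditions)
  bind_cols(sites, as_tibble(nm))
}

# robust two-component gaussian fit on a numeric vector; mclust first,
# two-means EM-free fallback for degenerate inputs
fit_two_gaussians <- function(x) {
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(fit) && all(is.finite(unlist(fit$parameters$mean)))) {
    mu <- as.numeric(fit$parameters$mean)
    sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sig) == 1) sig <- rep(sig, 2)
    w <- as.numeric(fit$parameters$pro)
    if (all(is.finite(c(mu, sig, w))) && all(sig > 0)) {
      return(list(mean = mu, sd = sig, weight = w, engine = "mclust"))
    }
  }
  km <- stats::kmeans(x, centers = matrix(range(x), ncol = 1), iter.max = 50)
  mu <- as.numeric(km$centers)
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
  sig <- vapply(1:2, function(k) {
    xs <- x[km$cluster == k]
    max(stats::sd(xs), 1e-4)
  }, numeric(1))
  sig[is.na(sig)] <- 1e-4
  list(mean = mu, sd = sig, weight = w, engine = "kmeans")
}

#' Fit the bound/unbound two-component model to one motif's scores
#'
#' Fits a two-component Gaussian mixture to `log(1 + score)` and places the
#' bound/unbound threshold at the smallest score whose posterior probability
#' of belonging to the higher-mean component reaches 0.5. Degenerate fits
#' (component means within 1e-3 or a component weight below 0.01) declare
#' all sites unbound (threshold `Inf`).
#'
#' @param scores Non-negative numeric vector of normalized footprint scores.
#' @param min_sites Below this many sites (default 50) no model is fit and
#'   all sites are unbound, with a warning.
#' @return A `bound_fit` object with elements `threshold` (original score
#'   scale), `bound` (logical vector), `params` (mixture parameters),
#'   `degenerate`, `n`.
#' @export
fit_bound_classifier <- function(scores, min_sites = 50L) {
  if (any(!is.finite(scores))) abort("non-finite footprint scores")
  n <- length(scores)
  make <- function(threshold, params, degenerate) {
    structure(list(threshold = threshold, bound = scores >= threshold,
                   params = params, degenerate = degenerate, n = n),
              class = "bound_fit")
  }
  if (n < min_sites) {
    warn(sprintf("%d sites < %d required for mixture fit; all unbound", n, min_sites))
    return(make(Inf, NULL, TRUE))
  }
  x <- log1p(scores)
  if (diff(range(x)) < 1e-12) return(make(Inf, NULL, TRUE))
  fit <- fit_two_gaussians(x)
  hi <- which.max(fit$mean)
  lo <- 3L - hi
  if (abs(fit$mean[hi] - fit$mean[lo]) < 1e-3 || min(fit$weight) < 0.01) {
    return(make(Inf, fit, TRUE))
  }
  grid <- seq(min(x), max(x), length.out = 1024L)
  post_hi <- fit$weight[hi] * stats::dnorm(grid, fit$mean[hi], fit$sd[hi])
  post_lo <- fit$weight[lo] * stats::dnorm(grid, fit$mean[lo], fit$sd[lo])
  post <- post_hi / (post_hi + post_lo)
  crossing <- which(post >= 0.5 & grid > fit$mean[lo])
  if (length(crossing) == 0) return(make(Inf, fit, TRUE))
  make(expm1(grid[crossing[1L]]), fit, FALSE)
}

#' @export
print.bound_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("bound/unbound fit on %d sites: degenerate; all unbound\n", x$n))
  } else {
    cat(sprintf("bound/unbound fit on %d sites: threshold %.4g, %d bound (%.1f%%)\n",
                x$n, x$threshold, sum(x$bound), 100 * mean(x$bound)))
  }
  invisible(x)
}

#' Tidy / summarize a bound/unbound mixture fit
#'
#' @param x A `bound_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per mixture component (`component`, `mean`,
#'   `sd`, `weight`, on the `log(1+score)` scale). `glance()`: one row with
#'   `n`, `threshold`, `bound_fraction`, `degenerate`.
#' @export
tidy.bound_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(component = integer(), mean = double(), sd = double(),
                  weight = double()))
  }
  ord <- order(x$params$mean)
  tibble(component = 1:2, mean = x$params$mean[ord], sd = x$params$sd[ord],
         weight = x$params$weight[ord])
}

#' @rdname tidy.bound_fit
#' @export
glance.bound_fit <- function(x, ...) {
  tibble(n = x$n, threshold = x$threshold,
         bound_fraction = mean(x$bound), degenerate = x$degenerate)
}

#' Classify sites bound/unbound per motif and condition
#'
#' Applies [fit_bound_classifier()] to each motif's normalized scores in
#' each condition.
#'
#' @param sites Site tibble with `norm_<condition>` columns.
#' @param conditions Conditions to classify (default: all `norm_*` columns).
#' @param min_sites Passed to [fit_bound_classifier()].
#' @return `sites` with added logical `bound_<condition>` columns; the
#'   per-motif thresholds are attached as attribute `"thresholds"` (tibble
#'   `motif_id`, `condition`, `threshold`, `degenerate`).
#' @export
classify_bound <- function(sites, conditions = NULL, min_sites = 50L) {
  if (is.null(conditions)) {
    conditions <- sub("^norm_", "", grep("^norm_", names(sites), value = TRUE))
  }
  thr <- list()
  for (cc in conditions) sites[[paste0("bound_", cc)]] <- FALSE
  for (mid in unique(sites$motif_id)) {
    sel <- sites$motif_id == mid
    for (cc in conditions) {
      f <- fit_bound_classifier(sites[[paste0("norm_", cc)]][sel], min_sites)
      sites[[paste0("bound_", cc)]][sel] <- f$bound
      thr[[length(thr) + 1L]] <- tibble(motif_id = mid, condition = cc,
                                        threshold = f$threshold,
                                        degenerate = f$degenerate)
    }
  }
  attr(sites, "thresholds") <- bind_rows(thr)
  sites
}

#' Per-site binding change between two conditions
#'
#' `log2((score_c2 + pc) / (score_c1 + pc))` on normalized scores, the
#' per-site fold change of footprint strength (positive = stronger binding
#' in `c2`).
#'
#' @param sites Site tibble with `norm_<c1>`, `norm_<c2>`.
#' @param c1,c2 Condition names (change is reported as c2 over c1).
#' @param pseudocount Stabilizer added to both scores (default 1).
#' @return `sites` with added `log2fc` column.
#' @export
site_log2fc <- function(sites, c1, c2, pseudocount = 1) {
  s1 <- sites[[paste0("norm_", c1)]]
  s2 <- sites[[paste0("norm_", c2)]]
  if (is.null(s1) || is.null(s2)) abort("normalized scores missing; run normalize_scores() first")
  mutate(sites, log2fc = log2((s2 + pseudocount) / (s1 + pseudocount)))
}

#' Differential TF binding between two conditions
#'
#' For each motif, the raw differential score is the difference of mean
#' normalized site scores (`c2` minus `c1`). To judge whether a motif's
#' shift is larger than expected for an arbitrary site set of its size, the
#' raw score is standardized against a background distribution built from
#' `n_background` random subsamples (of `bg_size` sites, default the motif's
#' own site count) drawn from the union of all motifs' sites; the
#' standardized score is a z-value and the p-value its two-sided normal
#' tail. One row per motif (the volcano table).
#'
#' @param sites Site tibble with `norm_<condition>` columns (all motifs).
#' @param c1,c2 Condition names.
#' @param n_background Number of background subsamples (default 100).
#' @param bg_size Subsample size; `NULL` (default) uses each motif's site
#'   count.
#' @param seed Seed making the background draws reproducible.
#' @return A tibble with `motif_id`, `n_sites`, `mean_<c1>`, `mean_<c2>`,
#'   `diff_raw`, `differential_score` (standardized), `p_value`,
#'   `neg_log10_p`.
#' @export
differential_binding <- function(sites, c1, c2, n_background = 100L,
                                 bg_size = NULL, seed = NULL) {
  s1 <- sites[[paste0("norm_", c1)]]
  s2 <- sites[[paste0("norm_", c2)]]
  if (is.null(s1) || is.null(s2)) abort("normalized scores missing; run normalize_scores() first")
  site_diff <- s2 - s1
  n_total <- length(site_diff)
  motifs <- sort(unique(sites$motif_id))
  with_seed(seed, {
    rows <- lapply(motifs, function(mid) {
      sel <- sites$motif_id == mid
      n_m <- sum(sel)
      raw <- mean(site_diff[sel])
      size <- if (is.null(bg_size)) n_m else min(bg_size, n_total)
      bg <- vapply(seq_len(n_background), function(b) {
        mean(site_diff[sample.int(n_total, size)])
      }, numeric(1))
      sd_bg <- stats::sd(bg)
      if (!is.finite(sd_bg) || sd_bg == 0) {
        warn(sprintf("motif %s: zero-variance background; p set to 1", mid))
        z <- 0
        p <- 1
      } else {
        z <- (raw - mean(bg)) / sd_bg
        p <- 2 * stats::pnorm(-abs(z))
      }
      out <- tibble(motif_id = mid, n_sites = n_m, m1 = mean(s1[sel]),
                    m2 = mean(s2[sel]), diff_raw = raw,
                    differential_score = z, p_value = p,
                    neg_log10_p = -log10(pmax(p, 1e-300)))
      names(out)[3:4] <- paste0("mean_", c(c1, c2))
      out
    })
    bind_rows(rows)
  })
}
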