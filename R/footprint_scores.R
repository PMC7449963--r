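#' Scoring parameters for footprint statistics
#'
#' @param fp_widths Candidate footprint window widths in bp
#'   (default `seq(8, 20, 2)`).
#' @param flank_width Flank window width in bp on each side of the candidate
#'   footprint (default 30). Must be at least half the largest width.
#' @param min_value Floor applied to the signal before scoring (default 0,
#'   so negative corrected values do not reward depletion twice).
#' @param combiner How depletion and accessibility are combined (see
#'   [footprint_score()]): `"depletion_scaled"` (default) or
#'   `"depletion_accessibility"`.
#' @return A `score_params` list.
#' @export
score_params <- function(fp_widths = seq(8L, 20L, 2L), flank_width = 30L,
                         min_value = 0,
                         combiner = c("depletion_scaled",
                                      "depletion_accessibility")) {
  if (any(fp_widths < 2)) abort("all footprint widths must be >= 2")
  if (flank_width < max(fp_widths) / 2) {
    abort("flank_width must be >= max(fp_widths)/2")
  }
  structure(list(fp_widths = as.integer(fp_widths),
                 flank_width = as.integer(flank_width),
                 min_value = min_value,
                 combiner = match.arg(combiner)),
            class = "score_params")
}

# per-position means of [p - floor(w/2), +w) center window and its two flanks;
# returns list(C, L, R, valid) for one width on one floored signal vector
window_means <- function(x, w, flank) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  p <- seq_len(n)
  c_lo <- p - w %/% 2L
  c_hi <- c_lo + w - 1L
  l_lo <- c_lo - flank
  r_hi <- c_hi + flank
  valid <- l_lo >= 1L & r_hi <= n
  sm <- function(lo, hi) (cs[pmin(pmax(hi, 1L), n) + 1L] - cs[pmin(pmax(lo - 1L, 0L), n) + 1L])
  C <- ifelse(valid, sm(c_lo, c_hi) / w, 0)
  L <- ifelse(valid, sm(l_lo, c_lo - 1L) / flank, 0)
  R <- ifelse(valid, sm(c_hi + 1L, r_hi) / flank, 0)
  list(C = C, L = L, R = R, valid = valid)
}

score_one_region <- function(x, params, method) {
  n <- length(x)
  need <- 2L * params$flank_width + max(params$fp_widths)
  if (n < need) {
    warn(sprintf("region of length %d shorter than %d required for scoring; all-zero scores",
                 n, need))
    return(numeric(n))
  }
  x <- pmax(x, params$min_value)
  if (method == "footprint") {
    additive <- identical(params$combiner, "depletion_accessibility")
    best <- rep(0, n)
    for (w in params$fp_widths) {
      m <- window_means(x, w, params$flank_width)
      flank_mean <- (m$L + m$R) / 2
      s <- pmax(0, flank_mean - m$C)
      if (additive) s <- s + pmax(0, flank_mean)
      s[!m$valid] <- 0
      best <- pmax(best, s)
    }
    best
  } else { # fos
    worst_fos <- 1e6
    best <- rep(worst_fos, n)
    any_valid <- rep(FALSE, n)
    for (w in params$fp_widths) {
      m <- window_means(x, w, params$flank_width)
      fos <- (m$C + 1) / (m$L + 1) + (m$C + 1) / (m$R + 1)
      fos[m$L <= -1 | m$R <= -1] <- worst_fos
      fos[!m$valid] <- worst_fos
      best <- pmin(best, fos)
      any_valid <- any_valid | m$valid
    }
    out <- -best
    out[!any_valid] <- 0
    out
  }
}

#' Combined depletion + accessibility footprint score
#'
#' For each position and candidate footprint width `w`, let `C` be the mean
#' (floored) signal over the centered window of width `w`, and `L`, `R` the
#' means over `flank_width` windows immediately left and right. The default
#' (`combiner = "depletion_scaled"`) score is the maximum over widths of the
#' depletion contrast `max(0, (L+R)/2 - C)` left on the absolute signal
#' scale. Because the flank level is the local accessibility, this one
#' number is depletion weighted by accessibility: the same fractional dip
#' scores higher where the region is more accessible, and unreadably sparse
#' regions score near 0. That is what distinguishes it from scale-free
#' pure-depletion statistics like FOS, which rank a deep dip in a barely
#' covered region as high as one backed by many cuts.
#' `combiner = "depletion_accessibility"` instead adds an explicit
#' accessibility term `max(0, (L+R)/2)` to the contrast; it is kept for
#' comparison but double-counts accessibility (the contrast already scales
#' with it) and adds the flank's sampling noise a second time. Positions
#' whose windows exceed the region bounds score 0.
#'
#' @param tracks Track tibble (normally `kind = "corrected"`).
#' @param params A [score_params()] object.
#' @return Track tibble with `kind = "footprint"`.
#' @export
footprint_score <- function(tracks, params = score_params()) {
  mutate(tracks, kind = "footprint",
         values = map(.data$values, score_one_region, params = params,
                      method = "footprint"))
}

#' Footprint occupancy score (FOS), sign-flipped
#'
#' The classical pure-depletion statistic:
#' `FOS = min over w of (C+1)/(L+1) + (C+1)/(R+1)`. Smaller FOS means a
#' deeper footprint, so the score is emitted as `-FOS` to share the
#' "larger = more bound" convention with [footprint_score()]. A flat signal
#' of any level scores exactly -2: FOS is blind to accessibility.
#'
#' @inheritParams footprint_score
#' @return Track tibble with `kind = "footprint"` holding `-FOS` values.
#' @export
fos_score <- function(tracks, params = score_params()) {
  mutate(tracks, kind = "footprint",
         values = map(.data$values, score_one_region, params = params,
                      method = "fos"))
}
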