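#' Floor track values
#'
#' Replaces every value below `min_value` with `min_value`. Corrected
#' tracks are mean-zero per region, so depth metrics that normalize by the
#' flank level (like [fpd()]) need the non-negative part of the signal,
#' exactly as the footprint scorer uses it.
#'
#' @param tracks Track tibble.
#' @param min_value Floor (default 0).
#' @return Track tibble with floored `values`.
#' @export
floor_track <- function(tracks, min_value = 0) {
  mutate(tracks, values = map(.data$values, pmax, min_value))
}

#' Aggregate footprint profile over a set of binding sites
#'
#' Averages the signal in windows of `flank` bp on each side of every site
#' (minus-strand site windows are reversed before averaging), the standard
#' motif-centered aggregate footprint plot. Sites whose window leaves the
#' containing scored region, or which fall outside all regions, are dropped.
#'
#' @param sites Binding-site tibble; all sites must share one motif length.
#' @param tracks Track tibble holding the signal to aggregate.
#' @param flank Flank width in bp on each side of the site (default 60).
#' @return An `aggregate_profile` tibble with columns `offset` (bp relative
#'   to the site start) and `value`, and attributes `n_sites`, `motif_len`,
#'   `flank`.
#' @export
aggregate_footprints <- function(sites, tracks, flank = 60L) {
  if (nrow(sites) == 0) abort("no sites to aggregate")
  lens <- unique(sites$end - sites$start)
  if (length(lens) != 1) abort("all sites must share one motif length")
  L <- lens
  width <- L + 2L * flank
  ridx <- site_region_index(sites, tracks)
  acc <- numeric(width)
  n_used <- 0L
  for (i in seq_len(nrow(sites))) {
    ri <- ridx[i]
    if (is.na(ri)) next
    lo <- sites$start[i] - flank
    hi <- sites$end[i] + flank
    if (lo < tracks$start[ri] || hi > tracks$end[ri]) next
    v <- tracks$values[[ri]][(lo - tracks$start[ri] + 1L):(hi - tracks$start[ri])]
    if (!is.null(sites$strand) && !is.na(sites$strand[i]) && sites$strand[i] == "-") {
      v <- rev(v)
    }
    acc <- acc + v
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("no usable sites (all windows exceed region bounds)")
  out <- tibble(offset = seq_len(width) - 1L - flank, value = acc / n_used)
  structure(out, n_sites = n_used, motif_len = L, flank = as.integer(flank),
            class = c("aggregate_profile", class(out)))
}

#' Footprint depth (FPD) of an aggregate profile
#'
#' The relative depletion at the motif: mean signal in two flank windows of
#' `flank_for_fpd` bp immediately outside the central motif window, minus
#' the mean over the motif window, divided by the flank mean (0 when the
#' flank mean is not positive). 1 means complete depletion, 0 no footprint,
#' negative values an anti-footprint (signal enriched at the motif, the
#' signature of sequence that attracts Tn5).
#'
#' @param profile An `aggregate_profile`, or a plain numeric vector (then
#'   `motif_len` is required).
#' @param motif_len Central window width; taken from the profile attribute
#'   when available.
#' @param flank_for_fpd Flank window width in bp (default 20).
#' @param relative If `TRUE` (default), divide the flank-minus-center
#'   difference by the flank mean (0 when the flank mean is not positive):
#'   a depth fraction comparable across TFs with different accessibility.
#'   Use `relative = FALSE` on bias-corrected signal, which is mean-zero
#'   per region so its flank level is not a meaningful denominator; the
#'   absolute difference is then in the same per-base cut units as the
#'   observed and expected tracks, making depths comparable across the
#'   three track kinds.
#' @return A single numeric FPD value.
#' @export
fpd <- function(profile, motif_len = NULL, flank_for_fpd = 20L,
                relative = TRUE) {
  v <- if (is.data.frame(profile)) profile$value else as.numeric(profile)
  if (is.null(motif_len)) motif_len <- attr(profile, "motif_len")
  if (is.null(motif_len)) abort("motif_len required")
  W <- length(v)
  if (W < motif_len + 2L * flank_for_fpd) {
    abort("profile too short for requested motif and flank windows")
  }
  c0 <- (W - motif_len) %/% 2L + 1L
  center <- v[c0:(c0 + motif_len - 1L)]
  left <- v[(c0 - flank_for_fpd):(c0 - 1L)]
  right <- v[(c0 + motif_len):(c0 + motif_len + flank_for_fpd - 1L)]
  fl <- mean(c(left, right))
  if (!relative) return(fl - mean(center))
  if (fl <= 0) return(0)
  (fl - mean(center)) / fl
}

#' Test whether a motif leaves a measurable aggregate footprint
#'
#' Compares the observed FPD of the site aggregate against a null
#' distribution of FPDs from aggregates built at the same number of
#' positions drawn uniformly at random within the scored regions (so the
#' null preserves accessible-sequence composition). The footprint is called
#' measurable when the observed FPD exceeds the null's 95th percentile.
#'
#' @param sites Binding-site tibble (one motif).
#' @param tracks Signal track tibble (normally corrected).
#' @param n_null Number of null aggregates (default 200, minimum 100).
#' @param seed Seed for the null draws; same seed, identical null.
#' @param flank,flank_for_fpd Passed to [aggregate_footprints()] / [fpd()].
#' @param relative Passed to [fpd()]; default `FALSE` because the test is
#'   normally run on bias-corrected (mean-zero) signal.
#' @return One-row tibble: `fpd_obs`, `null_q95`, `measurable`, `n_sites`,
#'   `n_null`.
#' @export
measurable_footprint_test <- function(sites, tracks, n_null = 200L,
                                      seed = NULL, flank = 60L,
                                      flank_for_fpd = 20L, relative = FALSE) {
  if (n_null < 100L) abort("n_null must be >= 100")
  lens <- unique(sites$end - sites$start)
  if (length(lens) != 1) abort("all sites must share one motif length")
  L <- lens
  prof <- aggregate_footprints(sites, tracks, flank = flank)
  fpd_obs <- fpd(prof, flank_for_fpd = flank_for_fpd, relative = relative)
  # candidate null positions: site starts whose full window fits in a region
  margin <- flank
  cand <- bind_rows(lapply(seq_len(nrow(tracks)), function(i) {
    lo <- tracks$start[i] + margin
    hi <- tracks$end[i] - margin - L
    if (hi < lo) return(NULL)
    tibble(chrom = tracks$chrom[i], start = seq(lo, hi))
  }))
  n_s <- attr(prof, "n_sites")
  if (nrow(cand) < n_s) abort("fewer candidate null positions than sites")
  null_fpd <- with_seed(seed, vapply(seq_len(n_null), function(b) {
    pick <- cand[sample.int(nrow(cand), n_s), , drop = FALSE]
    ns <- tibble(chrom = pick$chrom, start = pick$start, end = pick$start + L,
                 strand = "+")
    fpd(aggregate_footprints(ns, tracks, flank = flank),
        flank_for_fpd = flank_for_fpd, relative = relative)
  }, numeric(1)))
  q95 <- stats::quantile(null_fpd, 0.95, names = FALSE)
  tibble(fpd_obs = fpd_obs, null_q95 = q95, measurable = fpd_obs > q95,
         n_sites = n_s, n_null = as.integer(n_null))
}
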