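toy_motif <- function(consensus = "TAAT", id = "toy") {
  motif_models(consensus_pfms(tibble::tibble(motif_id = id,
                                             consensus = consensus)))
}

test_that("motif thresholds match the exact enumeration oracle", {
  set.seed(41)
  # an exact 1e-4 threshold exists only for motifs of length >= 7
  # (the single best k-mer already has probability 4^-L under uniform bg)
  for (L in c(7, 8, 9)) {
    pfm <- matrix(rpois(4 * L, 5) + 1, 4, L, dimnames = list(c("A","C","G","T"), NULL))
    pfm[cbind(sample(1:4, L, replace = TRUE), 1:L)] <- 60 # informative columns
    m <- motif_models(tibble::tibble(motif_id = "m", name = "m",
                                     length = L, pfm = list(pfm)))
    lo <- m$logodds[[1]]
    thr <- m$threshold
    p_at <- naive_tail_prob(lo, rep(0.25, 4), thr)
    expect_lte(p_at, 1e-4)
    # tight up to the discretization margin: one grid bucket lower (plus the
    # rounding slack of L * granularity) the exact tail already exceeds p
    p_below <- naive_tail_prob(lo, rep(0.25, 4), thr - (L + 1) * 0.001)
    expect_gt(p_below, 1e-4)
  }
})

test_that("unreachable p-values fall back to exact-best-match thresholds", {
  m <- toy_motif("TAAT")
  lo <- m$logodds[[1]]
  best <- sum(apply(lo, 2, max))
  expect_lte(m$threshold, best)
  expect_gt(m$threshold, best - 0.01)
  # only the consensus k-mer reaches it
  expect_equal(naive_tail_prob(lo, rep(0.25, 4), m$threshold), 0.25^4)
})

test_that("match rate on random sequence is calibrated to the threshold p-value", {
  genome <- random_genome(100000, seed = 43)
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L)
  set.seed(44)
  pfm <- matrix(rpois(4 * 8, 15) + 1, 4, 8, dimnames = list(c("A","C","G","T"), NULL))
  m <- motif_models(tibble::tibble(motif_id = "m", name = "m",
                                   length = 8L, pfm = list(pfm)))
  # count raw over-threshold positions per strand (before overlap resolution)
  v <- footprintr:::encode_seq(genome[[1]])
  lo <- m$logodds[[1]]
  n_pos <- length(v) - 7L
  hits_fwd <- sum(footprintr:::scan_scores(v, lo) >= m$threshold)
  sd3 <- 3 * sqrt(n_pos * 1e-4 * (1 - 1e-4))
  expect_lt(abs(hits_fwd - n_pos * 1e-4), sd3 + 1)
})

test_that("consensus matches are found on the correct strand and position", {
  m <- toy_motif("TAAT")
  genome <- c(chr1 = paste0(strrep("C", 30), "TAAT", strrep("C", 30)))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 64L)
  s <- scan_motifs(m, genome, regions)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 30L)
  expect_equal(s$end, 34L)
  expect_equal(s$strand, "+")

  genome2 <- c(chr1 = paste0(strrep("C", 30), "ATTA", strrep("C", 30)))
  s2 <- scan_motifs(m, genome2, regions)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$strand, "-")
  expect_equal(s2$start, 30L)

  # motif longer than region: region skipped without error
  tiny <- tibble::tibble(chrom = "chr1", start = 0L, end = 3L)
  expect_equal(nrow(scan_motifs(m, genome, tiny)), 0L)
})

test_that("overlapping same-strand matches keep the higher score, ties leftmost", {
  m <- toy_motif("AAAA")
  genome <- c(chr1 = paste0(strrep("C", 10), "AAAAAA", strrep("C", 10)))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 26L)
  s <- scan_motifs(m, genome, regions)
  s_plus <- s[s$strand == "+", ]
  expect_equal(nrow(s_plus), 1L)  # three overlapping perfect matches collapse
  expect_equal(s_plus$start, 10L) # tie broken to the leftmost
})

test_that("production scanner equals the brute-force positional scan", {
  set.seed(46)
  for (rep_i in 1:3) {
    genome <- random_genome(1500, seed = 46 + rep_i)
    regions <- tibble::tibble(chrom = "chr1", start = 10L, end = 1490L)
    L <- c(5, 6, 7)[rep_i]
    pfm <- matrix(rpois(4 * L, 10) + 1, 4, L,
                  dimnames = list(c("A","C","G","T"), NULL))
    m <- motif_models(tibble::tibble(motif_id = "m", name = "m", length = L,
                                     pfm = list(pfm)),
                      pval = 1e-3) # denser hits exercise overlap resolution
    got <- scan_motifs(m, genome, regions)
    got <- got[order(got$start, got$strand), ]
    seq_region <- substr(genome[[1]], 11, 1490)
    want <- naive_scan(m$logodds[[1]], m$threshold, seq_region, region_start = 10L)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$match_score, unname(want$match_score), tolerance = 1e-12)
  }
})

test_that("site scoring aggregates the requested window summary", {
  tr <- toy_tracks(list(c(0, 5, 0)), kind = "footprint")
  sites <- tibble::tibble(chrom = "chr1", start = 0L, end = 3L, strand = "+",
                          motif_id = "m", match_score = 1)
  s_max <- score_sites(sites, list(A = tr), agg_window = 0, agg = "max")
  expect_equal(s_max$score_A, 5)
  s_mean <- score_sites(sites, list(A = tr), agg_window = 0, agg = "mean")
  expect_equal(s_mean$score_A, 5 / 3)

  tr0 <- toy_tracks(list(rep(0, 10)), kind = "footprint")
  sites0 <- dplyr::mutate(sites, end = 4L)
  expect_equal(score_sites(sites0, list(A = tr0))$score_A, 0)

  # site outside every scored region is flagged and scored 0
  far <- dplyr::mutate(sites, start = 500L, end = 503L)
  sf <- score_sites(far, list(A = tr))
  expect_false(sf$in_region)
  expect_equal(sf$score_A, 0)
})

test_that("quantile normalization matches distributions across conditions", {
  set.seed(47)
  base <- rexp(400)
  sites <- tibble::tibble(motif_id = "m",
                          score_A = base,
                          score_B = sample(base)) # same multiset, reordered
  n1 <- normalize_scores(sites)
  expect_equal(sort(n1$norm_A), sort(n1$norm_B))

  sites2 <- tibble::tibble(motif_id = "m", score_A = base,
                           score_B = base + 3)
  n2 <- normalize_scores(sites2)
  expect_equal(sort(n2$norm_A), sort(n2$norm_B), tolerance = 1e-12)

  sites3 <- tibble::tibble(motif_id = "m", score_A = rexp(500),
                           score_B = rgamma(500, 2), score_C = runif(500))
  n3 <- normalize_scores(sites3)
  expect_equal(mean(n3$norm_A), mean(n3$norm_B), tolerance = 1e-9)
  expect_equal(mean(n3$norm_A), mean(n3$norm_C), tolerance = 1e-9)

  # single condition: identity
  n4 <- normalize_scores(tibble::tibble(motif_id = "m", score_A = base))
  expect_equal(n4$norm_A, base)
})

test_that("bound classification recovers mixture fractions and degenerates safely", {
  for (frac in c(0.1, 0.3, 0.5)) {
    set.seed(300 + round(100 * frac))
    n <- 2000
    nb <- round(frac * n)
    x <- pmax(c(rnorm(n - nb, 0.5, 0.3), rnorm(nb, 2.0, 0.5)), 0)
    f <- fit_bound_classifier(expm1(x))
    expect_lt(abs(mean(f$bound) - frac), 0.05)
  }

  # identical scores: declared degenerate, all unbound
  f1 <- fit_bound_classifier(rep(2, 200))
  expect_true(f1$degenerate)
  expect_equal(sum(f1$bound), 0L)

  # clearly separable two-point mixture
  f2 <- fit_bound_classifier(c(rep(0.1, 700), rep(5, 300)))
  expect_gt(f2$threshold, 0.1)
  expect_lt(f2$threshold, 5)
  expect_equal(sum(f2$bound), 300L)

  expect_warning(f3 <- fit_bound_classifier(runif(20)), "all unbound")
  expect_equal(sum(f3$bound), 0L)
  expect_error(fit_bound_classifier(c(1, NA, 3)), "non-finite")

  # tidiers
  expect_equal(nrow(tidy(f2)), 2L)
  expect_equal(glance(f2)$bound_fraction, 0.3)
})

test_that("classify_bound labels per motif and condition with thresholds attached", {
  set.seed(48)
  sites <- tibble::tibble(
    motif_id = rep(c("m1", "m2"), each = 300),
    norm_A = pmax(c(expm1(c(rnorm(210, 0.5, 0.3), rnorm(90, 2.2, 0.4))),
                    expm1(rnorm(300, 0.5, 0.3))), 0))
  out <- classify_bound(sites, "A")
  thr <- attr(out, "thresholds")
  expect_equal(nrow(thr), 2L)
  m1_frac <- mean(out$bound_A[out$motif_id == "m1"])
  expect_lt(abs(m1_frac - 0.3), 0.07)
})

test_that("per-site log2 fold change follows its pseudocount formula", {
  sites <- tibble::tibble(motif_id = "m", norm_A = c(2, 7, 0),
                          norm_B = c(8, 7, 0))
  out <- site_log2fc(sites, "A", "B")
  expect_equal(out$log2fc, c(log2(9 / 3), 0, 0))
  expect_equal(out$log2fc[1], 1.585, tolerance = 1e-3)
})

test_that("differential binding is null for identical conditions and finds shifts", {
  set.seed(49)
  sites <- tibble::tibble(motif_id = rep(sprintf("m%02d", 1:50), each = 80),
                          norm_A = rexp(4000))
  n_tot <- nrow(sites)
  sites$norm_B <- sites$norm_A
  v0 <- suppressWarnings(differential_binding(sites, "A", "B", seed = 7))
  expect_true(all(v0$diff_raw == 0))
  expect_true(all(v0$differential_score == 0))
  expect_true(all(v0$p_value >= 0.99))

  # shift one motif's sites strongly in B; a strong shift slightly
  # contaminates the pooled background, so specificity is judged across seeds
  frac_clean <- vapply(1:3, function(s) {
    set.seed(100 + s)
    sites2 <- tibble::tibble(motif_id = rep(sprintf("m%03d", 1:100), each = 50),
                             norm_A = rexp(5000))
    sites2$norm_B <- sites2$norm_A * exp(rnorm(5000, 0, 0.2))
    sdd <- sd(sites2$norm_B - sites2$norm_A)
    up <- sites2$motif_id == "m007"
    sites2$norm_B[up] <- sites2$norm_B[up] + 3 * sdd
    v <- differential_binding(sites2, "A", "B", seed = s)
    expect_equal(v$motif_id[which.max(abs(v$differential_score))], "m007")
    expect_lt(v$p_value[v$motif_id == "m007"], 0.01)
    # determinism: same seed, identical p-values
    v2 <- differential_binding(sites2, "A", "B", seed = s)
    expect_identical(v$p_value, v2$p_value)
    mean(v$p_value[v$motif_id != "m007"] > 0.05)
  }, numeric(1))
  expect_gte(mean(frac_clean), 0.9)
})

test_that("permuted condition labels keep the differential test calibrated", {
  frac_sig <- vapply(1:5, function(s) {
    set.seed(500 + s)
    sites <- tibble::tibble(motif_id = rep(sprintf("m%02d", 1:30), each = 60),
                            norm_A = rexp(1800))
    sites$norm_B <- sites$norm_A * exp(rnorm(1800, 0, 0.25))
    swap <- runif(1800) < 0.5
    tmp <- sites$norm_A[swap]
    sites$norm_A[swap] <- sites$norm_B[swap]
    sites$norm_B[swap] <- tmp
    v <- differential_binding(sites, "A", "B", seed = s)
    mean(v$p_value < 0.05)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.10)
})
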