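test_that("unbiased events give dinucleotide probabilities close to background", {
  genome <- random_genome(100000, seed = 2)
  regions <- tibble::tibble(chrom = "chr1", start = 100L, end = 99900L)
  set.seed(3)
  ev <- tibble::tibble(chrom = "chr1",
                       pos = sample(100:99899, 20000, replace = TRUE),
                       strand = "+")
  m <- estimate_bias(ev, genome, regions, seed = 5, refine = FALSE)
  expect_lt(max(abs(m$dinuc_probs - m$background_probs)), 0.02)
})

test_that("events centered on a fixed dinucleotide concentrate the center row", {
  # genome of TA repeated; all events on the T of a TA step
  genome <- c(chr1 = paste(rep("TA", 5000), collapse = ""))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  ev <- tibble::tibble(chrom = "chr1", pos = seq(100L, 9000L, 2L), strand = "+")
  m <- suppressWarnings(
    estimate_bias(ev, genome, regions, refine = FALSE, pseudocount = 1e-6))
  # offset r covers genomic bases (pos - half + r - 1, pos - half + r):
  # offset 11 starts at the insertion base itself, offset 10 ends on it
  expect_gt(m$dinuc_probs[11, "TA"], 0.99)
  expect_gt(m$dinuc_probs[10, "AT"], 0.99)
})

test_that("the estimator recovers a known dinucleotide bias (canonical gauge)", {
  sim <- fixture("bias_sim", function() {
    simulate_dataset(sim_config(seed = 5, motifs = NULL, reads_per_peak = 250,
                                footprint_depth = 0))
  })
  ev <- fragments_to_cutsites(sim$fragments$A, chrom_sizes = nchar(sim$genome))
  m <- estimate_bias(ev, sim$genome, merge_intervals(sim$peaks), seed = 3)
  r <- cor(as.vector(sim$true_bias$log_weights),
           as.vector(log(m$dinuc_probs / m$background_probs)))
  expect_gt(r, 0.9)
})

test_that("bias model estimation is deterministic given the seed", {
  sim <- fixture("bias_sim", function() {
    simulate_dataset(sim_config(seed = 5, motifs = NULL, reads_per_peak = 250,
                                footprint_depth = 0))
  })
  ev <- fragments_to_cutsites(sim$fragments$A, chrom_sizes = nchar(sim$genome))
  regions <- merge_intervals(sim$peaks)
  m1 <- estimate_bias(ev, sim$genome, regions, seed = 42, bg_sample = 20000L)
  m2 <- estimate_bias(ev, sim$genome, regions, seed = 42, bg_sample = 20000L)
  expect_identical(m1, m2)
})

test_that("an identity model scores weight exactly 1 everywhere", {
  genome <- random_genome(2000, seed = 7)
  regions <- tibble::tibble(chrom = "chr1", start = 50L, end = 500L)
  bg <- matrix(1 / 16, 19, 16, dimnames = list(NULL, footprintr:::DINUCS))
  model <- structure(list(window = 20L, dinuc_probs = bg,
                          background_probs = bg, pseudocount = 1,
                          n_events = 0L), class = "bias_model")
  tr <- score_sequence_bias(model, genome, regions)
  expect_equal(tr$values[[1]], rep(1, 450))
})

test_that("a single-offset 2:1 preference doubles the weight at matching sites", {
  genome <- c(chr1 = paste0(strrep("C", 30), "TA", strrep("C", 30)))
  regions <- tibble::tibble(chrom = "chr1", start = 20L, end = 44L)
  bg <- matrix(1 / 16, 19, 16, dimnames = list(NULL, footprintr:::DINUCS))
  dn <- bg
  dn[10, "TA"] <- 2 / 16 # favored 2:1 at the center offset only
  dn[10, ] <- dn[10, ] / sum(dn[10, ])
  model <- structure(list(window = 20L, dinuc_probs = dn,
                          background_probs = bg, pseudocount = 1,
                          n_events = 0L), class = "bias_model")
  tr <- score_sequence_bias(model, genome, regions)
  # offset 10 of a window centered at pos covers bases pos-1, pos:
  # the TA at genomic 30,31 is hit when the window center sits at pos 31
  v <- tr$values[[1]]
  # row renormalization: row sums to 17/16, so TA cell is 2/17, others 1/17
  expect_equal(v[31 - 20 + 1], (2 / 17) / (1 / 16), tolerance = 1e-12)
  expect_equal(v[5], (1 / 17) / (1 / 16), tolerance = 1e-12)
})

test_that("log-space scoring matches a direct product oracle", {
  genome <- random_genome(3000, seed = 13)
  regions <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L)
  set.seed(14)
  bg <- matrix(1 / 16, 19, 16, dimnames = list(NULL, footprintr:::DINUCS))
  dn <- matrix(rexp(19 * 16), 19, 16)
  dn <- dn / rowSums(dn)
  colnames(dn) <- footprintr:::DINUCS
  model <- structure(list(window = 20L, dinuc_probs = dn,
                          background_probs = bg, pseudocount = 1,
                          n_events = 0L), class = "bias_model")
  tr <- score_sequence_bias(model, genome, regions)
  v <- tr$values[[1]]
  bases <- strsplit(genome[[1]], "")[[1]]
  for (p in c(100, 150, 399)) { # 0-based positions
    w <- 1
    for (r in 1:19) {
      d1 <- bases[p - 10 + r - 1 + 1] # window offset r, 1-based genome index
      d2 <- bases[p - 10 + r + 1]
      dcode <- paste0(d1, d2)
      w <- w * dn[r, dcode] / bg[r, dcode]
    }
    expect_lt(abs(v[p - 100 + 1] - w) / w, 1e-10)
  }
})

test_that("expected tracks redistribute totals proportionally to bias", {
  obs <- toy_tracks(list(c(5, 3)), kind = "observed")
  bias <- toy_tracks(list(c(3, 1)), kind = "bias")
  e <- expected_track(obs, bias)
  expect_equal(e$values[[1]], c(6, 2))

  obs2 <- toy_tracks(list(rep(2, 10)), kind = "observed")
  bias2 <- toy_tracks(list(rep(0.7, 10)), kind = "bias")
  expect_equal(expected_track(obs2, bias2)$values[[1]], rep(2, 10))

  obs3 <- toy_tracks(list(rep(0, 6)), kind = "observed")
  bias3 <- toy_tracks(list(runif(6) + 0.1), kind = "bias")
  expect_equal(expected_track(obs3, bias3)$values[[1]], rep(0, 6))

  # conservation on random fixtures
  set.seed(21)
  obs4 <- toy_tracks(lapply(1:5, function(i) as.numeric(rpois(100, 2))),
                     kind = "observed")
  bias4 <- toy_tracks(lapply(1:5, function(i) rexp(100) + 0.01), kind = "bias")
  e4 <- expected_track(obs4, bias4)
  expect_equal(purrr::map_dbl(e4$values, sum), purrr::map_dbl(obs4$values, sum),
               tolerance = 1e-6)
})

test_that("corrected tracks are observed minus expected and sum to zero", {
  obs <- toy_tracks(list(c(4, 0)), kind = "observed")
  exp_t <- toy_tracks(list(c(2, 2)), kind = "expected")
  expect_equal(correct_track(obs, exp_t)$values[[1]], c(2, -2))

  same <- toy_tracks(list(runif(20)), kind = "observed")
  expect_equal(correct_track(same, dplyr::mutate(same, kind = "expected"))$values[[1]],
               rep(0, 20))

  set.seed(22)
  obs3 <- toy_tracks(lapply(1:4, function(i) as.numeric(rpois(150, 3))),
                     kind = "observed")
  bias3 <- toy_tracks(lapply(1:4, function(i) rexp(150) + 0.05), kind = "bias")
  corr <- correct_track(obs3, expected_track(obs3, bias3))
  for (v in corr$values) expect_lt(abs(sum(v)), 1e-6 * length(v))
})

test_that("full bundle satisfies conservation on simulated data", {
  run <- default_run()
  b <- run$bundles$A
  so <- purrr::map_dbl(b$observed$values, sum)
  se <- purrr::map_dbl(b$expected$values, sum)
  sc <- purrr::map_dbl(b$corrected$values, sum)
  expect_equal(se, so, tolerance = 1e-6)
  expect_true(all(abs(sc) <= 1e-6 * lengths(b$corrected$values)))
})

test_that("bias model tidiers expose the log-ratio cells", {
  run <- default_run()
  td <- tidy(run$bundles$A$model)
  expect_equal(nrow(td), 19 * 16)
  expect_true(all(c("offset", "dinuc", "log_ratio") %in% names(td)))
  gl <- glance(run$bundles$A$model)
  expect_equal(gl$window, 20L)
})
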