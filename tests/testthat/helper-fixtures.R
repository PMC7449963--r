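# shared fixtures, built lazily once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

random_consensus <- function(n, L, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), name)
}

# default simulation plus both conditions bias-corrected, shared by tests
default_run <- function() {
  fixture("default_run", function() {
    sim <- simulate_dataset(sim_config(seed = 1))
    sizes <- nchar(sim$genome)
    bundles <- lapply(sim$fragments, function(fr) {
      ev <- fragments_to_cutsites(fr, chrom_sizes = sizes)
      bias_correct(ev, sim$genome, sim$peaks, seed = 1)
    })
    list(sim = sim, bundles = bundles)
  })
}

# track tibble from an explicit list of value vectors on one chromosome
toy_tracks <- function(values, chrom = "chr1", gap = 50L, start0 = 0L,
                       kind = "corrected") {
  starts <- integer(length(values))
  s <- start0
  for (i in seq_along(values)) {
    starts[i] <- s
    s <- s + length(values[[i]]) + gap
  }
  tibble::tibble(chrom = chrom, start = starts,
                 end = starts + lengths(values), kind = kind,
                 values = values)
}

# ---- independent oracles (deliberately naive implementations) ----

# position-by-position motif scan over one region, both strands
naive_scan <- function(lo, threshold, seq_string, region_start = 0L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(seq_string, "")[[1]]
  L <- ncol(lo)
  hits <- list()
  for (strand in c("+", "-")) {
    for (p in seq_len(length(bases) - L + 1L)) {
      kmer <- bases[p:(p + L - 1L)]
      if (strand == "-") kmer <- rev(unname(comp[kmer]))
      if (anyNA(kmer)) next
      s <- 0
      ok <- TRUE
      for (j in seq_len(L)) {
        b <- match(kmer[j], c("A", "C", "G", "T"))
        if (is.na(b)) { ok <- FALSE; break }
        s <- s + lo[b, j]
      }
      if (ok && s >= threshold) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          start = region_start + p - 1L, end = region_start + p - 1L + L,
          strand = strand, match_score = s)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), match_score = double()))
  }
  d <- dplyr::bind_rows(hits)
  # same-strand greedy overlap resolution: best score first, ties leftmost
  out <- list()
  for (str in unique(d$strand)) {
    ds <- d[d$strand == str, ]
    ds <- ds[order(-ds$match_score, ds$start), ]
    kept <- ds[0, ]
    for (i in seq_len(nrow(ds))) {
      if (nrow(kept) == 0 ||
          all(ds$start[i] >= kept$end | ds$end[i] <= kept$start)) {
        kept <- rbind(kept, ds[i, ])
      }
    }
    out[[str]] <- kept
  }
  d <- dplyr::bind_rows(out)
  d[order(d$start, d$strand), ]
}

# exact motif-score tail probability by enumeration of all 4^L k-mers
naive_tail_prob <- function(lo, bg, threshold) {
  L <- ncol(lo)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(grid))
  pr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc[i] <- sum(lo[cbind(grid[i, ], 1:L)])
    pr[i] <- prod(bg[grid[i, ]])
  }
  sum(pr[sc >= threshold])
}

# direct windowed footprint scorer, O(n * w) per width
naive_footprint_score <- function(x, widths = seq(8, 20, 2), flank = 30,
                                  min_value = 0, additive = FALSE) {
  n <- length(x)
  if (n < 2 * flank + max(widths)) return(numeric(n))
  x <- pmax(x, min_value)
  out <- numeric(n)
  for (p in seq_len(n)) {
    best <- 0
    for (w in widths) {
      c_lo <- p - w %/% 2
      c_hi <- c_lo + w - 1
      l_lo <- c_lo - flank
      r_hi <- c_hi + flank
      if (l_lo < 1 || r_hi > n) next
      C <- mean(x[c_lo:c_hi])
      L <- mean(x[l_lo:(c_lo - 1)])
      R <- mean(x[(c_hi + 1):r_hi])
      s <- max(0, (L + R) / 2 - C)
      if (additive) s <- s + max(0, (L + R) / 2)
      best <- max(best, s)
    }
    out[p] <- best
  }
  out
}

naive_fos_score <- function(x, widths = seq(8, 20, 2), flank = 30,
                            min_value = 0) {
  n <- length(x)
  if (n < 2 * flank + max(widths)) return(numeric(n))
  x <- pmax(x, min_value)
  out <- numeric(n)
  for (p in seq_len(n)) {
    best <- 1e6
    any_valid <- FALSE
    for (w in widths) {
      c_lo <- p - w %/% 2
      c_hi <- c_lo + w - 1
      if (c_lo - flank < 1 || c_hi + flank > n) next
      any_valid <- TRUE
      C <- mean(x[c_lo:c_hi])
      L <- mean(x[(c_lo - flank):(c_lo - 1)])
      R <- mean(x[(c_hi + 1):(c_hi + flank)])
      fos <- if (L <= -1 || R <= -1) 1e6 else (C + 1) / (L + 1) + (C + 1) / (R + 1)
      best <- min(best, fos)
    }
    out[p] <- if (any_valid) -best else 0
  }
  out
}

# O(n^3) agglomerative clustering; returns merge heights in merge order
naive_linkage_heights <- function(D, method = "complete") {
  n <- nrow(D)
  active <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  dist_sets <- function(a, b) {
    vals <- D[unlist(a), unlist(b)]
    if (method == "complete") max(vals) else min(vals)
  }
  while (length(active) > 1) {
    best <- Inf
    bi <- bj <- 0
    for (i in seq_len(length(active) - 1)) {
      for (j in (i + 1):length(active)) {
        d <- dist_sets(active[[i]], active[[j]])
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active[[bj]] <- NULL
  }
  heights
}

# breadth-first shortest-path levels from a source over a directed edge list
naive_bfs_levels <- function(edges, source) {
  nodes <- unique(c(source, edges$from, edges$to))
  lev <- stats::setNames(rep(Inf, length(nodes)), nodes)
  lev[source] <- 0
  frontier <- source
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (f in frontier) {
      for (t in edges$to[edges$from == f]) {
        if (!is.finite(lev[t])) {
          lev[t] <- lev[f] + 1
          nxt <- c(nxt, t)
        }
      }
    }
    frontier <- unique(nxt)
  }
  lev
}
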