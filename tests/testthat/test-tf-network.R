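toy_genes <- function() {
  tibble::tibble(gene_id = c("gS", "gT1", "gT2", "gU1", "gU2", "gX"),
                 chrom = "chr1",
                 tss = c(50000L, 100000L, 150000L, 200000L, 250000L, 300000L),
                 strand = c("+", "+", "+", "+", "+", "-"))
}

site_row <- function(motif, pos, log2fc, bound = TRUE, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos) + 10L, strand = "+", motif_id = motif,
                 log2fc = log2fc, bound_B = bound)
}

test_that("promoter annotation is strand-aware with the -10000/+1000 window", {
  genes <- toy_genes()
  s1 <- site_row("m", 40500, 1)  # 9.5 kb upstream of + TSS at 50000
  a1 <- annotate_promoters(s1, genes)
  expect_equal(a1$gene_id, "gS")
  expect_equal(a1$annotation, "promoter")

  s2 <- site_row("m", 51500, 1)  # 1.5 kb downstream: outside +1000
  a2 <- annotate_promoters(s2, genes)
  expect_true(is.na(a2$gene_id))
  expect_equal(a2$annotation, "intergenic")

  # on a minus-strand gene, upstream extends to the right of the TSS
  s3 <- site_row("m", 301500, 1)
  a3 <- annotate_promoters(s3, genes)
  expect_equal(a3$gene_id, "gX")
  s4 <- site_row("m", 298500, 1)  # 1.5 kb left of - TSS: outside downstream
  expect_equal(annotate_promoters(s4, genes)$annotation, "intergenic")
})

test_that("annotation keeps multi-gene hits and is order-independent", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(10000L, 10500L), strand = "+")
  s <- site_row("m", 9800, 1)
  a <- annotate_promoters(s, genes)
  expect_setequal(a$gene_id, c("g1", "g2"))

  many <- dplyr::bind_rows(site_row("m1", 9800, 1), site_row("m2", 500000, 1))
  a1 <- annotate_promoters(many, genes)
  a2 <- annotate_promoters(many[2:1, ], genes)
  key <- function(d) dplyr::arrange(d, motif_id, start, gene_id)
  expect_equal(key(a1), key(a2))
  # idempotence: re-annotating the distinct underlying sites reproduces
  # the same assignment table
  a3 <- annotate_promoters(
    dplyr::distinct(dplyr::select(a1, -gene_id, -annotation)), genes)
  expect_equal(key(a3), key(a1))
})

test_that("the TF network follows positive-fold-change promoter binding with BFS levels", {
  genes <- toy_genes()
  map <- tibble::tibble(gene_id = c("gS", "gT1", "gT2", "gU1", "gU2"),
                        motif_id = c("S", "T1", "T2", "U1", "U2"))
  sites <- dplyr::bind_rows(
    site_row("S", 95000, 1.2),   # S -> T1
    site_row("S", 145000, 0.8),  # S -> T2
    site_row("T1", 195000, 0.5), # T1 -> U1
    site_row("T1", 245000, 0.3), # T1 -> U2
    site_row("S", 45000, 0.9))   # S -> S self-edge
  ann <- annotate_promoters(sites, genes)
  net <- create_network(ann, map, "S", require_bound = "B")
  lv <- stats::setNames(net$nodes$level, net$nodes$motif_id)
  expect_equal(lv[c("S", "T1", "T2", "U1", "U2")],
               c(S = 0L, T1 = 1L, T2 = 1L, U1 = 2L, U2 = 2L))
  expect_equal(nrow(net$edges), 5L)
  expect_equal(sum(net$edges$self), 1L)

  # negative fold change never makes an edge
  neg <- dplyr::bind_rows(sites, site_row("S", 195000, -0.5)) # S->U1 blocked
  net2 <- create_network(annotate_promoters(neg, genes), map, "S",
                         require_bound = "B")
  expect_false(any(net2$edges$source_tf == "S" & net2$edges$target_tf == "U1"))

  # unbound sites are excluded when require_bound is set
  unb <- dplyr::bind_rows(sites, site_row("T2", 195000, 2, bound = FALSE))
  net3 <- create_network(annotate_promoters(unb, genes), map, "S",
                         require_bound = "B")
  expect_false(any(net3$edges$source_tf == "T2"))
  net4 <- create_network(annotate_promoters(unb, genes), map, "S",
                         require_bound = NULL)
  expect_true(any(net4$edges$source_tf == "T2"))

  expect_error(create_network(ann, map, "missing"), "absent")
})

test_that("max_level prunes deep nodes and no positive sites leaves the source alone", {
  genes <- toy_genes()
  map <- tibble::tibble(gene_id = c("gS", "gT1", "gT2", "gU1"),
                        motif_id = c("S", "T1", "T2", "U1"))
  chain <- dplyr::bind_rows(
    site_row("S", 95000, 1),    # S -> T1 (level 1)
    site_row("T1", 145000, 1),  # T1 -> T2 (level 2)
    site_row("T2", 195000, 1))  # T2 -> U1 (level 3, pruned at max_level 2)
  net <- create_network(annotate_promoters(chain, genes), map, "S",
                        max_level = 2, require_bound = "B")
  expect_false("U1" %in% net$nodes$motif_id)
  expect_equal(max(net$nodes$level), 2L)

  none <- dplyr::mutate(chain, log2fc = -abs(log2fc))
  net0 <- create_network(annotate_promoters(none, genes), map, "S",
                         require_bound = "B")
  expect_equal(net0$nodes$motif_id, "S")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("network levels match a naive shortest-path oracle on random graphs", {
  set.seed(81)
  for (rep_i in 1:5) {
    n_tf <- 12
    tfs <- sprintf("F%02d", 1:n_tf)
    genes <- tibble::tibble(gene_id = paste0("g", tfs), chrom = "chr1",
                            tss = seq(50000L, by = 50000L, length.out = n_tf),
                            strand = "+")
    map <- tibble::tibble(gene_id = paste0("g", tfs), motif_id = tfs)
    pairs <- expand.grid(from = tfs, to = tfs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to & runif(nrow(pairs)) < 0.15, ]
    if (nrow(pairs) == 0) next
    sites <- dplyr::bind_rows(purrr::map2(pairs$from, pairs$to, function(f, t) {
      site_row(f, genes$tss[genes$gene_id == paste0("g", t)] - 5000, 1)
    }))
    ann <- annotate_promoters(sites, genes)
    net <- create_network(ann, map, "F01", max_level = 100,
                          require_bound = "B")
    oracle <- naive_bfs_levels(data.frame(from = pairs$from, to = pairs$to),
                               "F01")
    keep <- names(oracle)[is.finite(oracle)]
    lv <- stats::setNames(net$nodes$level, net$nodes$motif_id)
    expect_setequal(net$nodes$motif_id, keep)
    expect_equal(as.numeric(lv[keep]), as.numeric(oracle[keep]))
  }
})

test_that("networks serialize to an edge TSV and node JSON", {
  genes <- toy_genes()
  map <- tibble::tibble(gene_id = c("gS", "gT1"), motif_id = c("S", "T1"))
  sites <- site_row("S", 95000, 1.2)
  net <- create_network(annotate_promoters(sites, genes), map, "S",
                        require_bound = "B")
  ef <- withr::local_tempfile()
  nf <- withr::local_tempfile()
  write_network(net, ef, nf)
  back_e <- readr::read_tsv(ef, show_col_types = FALSE)
  expect_equal(back_e$source_tf, "S")
  back_n <- jsonlite::read_json(nf, simplifyVector = TRUE)
  expect_setequal(back_n$motif_id, c("S", "T1"))
})
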