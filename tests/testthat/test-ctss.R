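# CTSS tables, tpm normalisation, distance clustering, promoter widths,
# TSS profiles, TOPscore, read filter, PRTE score, window fractions.

mk_records <- function(pos, count, chrom = "chr1", strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             strand = rep_len(strand, length(pos)), count = count,
             stringsAsFactors = FALSE)
}

test_that("ctss_table validates records and tracks library size", {
  t <- ctss_table(mk_records(c(10, 20), c(2, 8)), sample_id = "s1")
  expect_identical(attr(t, "library_size"), 10)
  expect_error(ctss_table(mk_records(c(10, 10), c(1, 1))), "unique")
  expect_error(ctss_table(mk_records(10, -1)), "negative")
  expect_error(ctss_table(data.frame(chrom = "c", pos = 1, strand = ".",
                                     count = 1)), "strand")
})

test_that("normalize_tpm conserves a total of one million", {
  t <- normalize_tpm(ctss_table(mk_records(c(10, 20), c(2, 8))))
  expect_equal(t$tpm, c(200000, 800000))
  t1 <- normalize_tpm(ctss_table(mk_records(5, 7)))
  expect_equal(t1$tpm, 1e6)
  set.seed(1)
  tr <- normalize_tpm(ctss_table(mk_records(1:50, sample(1:1000, 50))))
  expect_equal(sum(tr$tpm), 1e6, tolerance = 1e-12)
  expect_error(normalize_tpm(ctss_table(mk_records(integer(0), integer(0)))),
               "empty")
})

test_that("cluster_ctss forms maximal distance-linked clusters", {
  tc <- cluster_ctss(mk_records(c(100, 105, 130), c(1, 1, 1)), maxdist = 20)
  expect_identical(nrow(tc$clusters), 2L)
  expect_identical(tc$members$cluster_id, c(1L, 1L, 2L))
  one <- cluster_ctss(mk_records(50, 3), maxdist = 20)
  expect_identical(nrow(one$clusters), 1L)
  expect_identical(one$clusters$dominant_pos, 50)
  # strand and chromosome separate clusters even at distance 0
  df <- rbind(mk_records(100, 1, strand = "+"), mk_records(100, 1, strand = "-"),
              mk_records(100, 1, chrom = "chr2"))
  expect_identical(nrow(cluster_ctss(df, 20)$clusters), 3L)
})

test_that("cluster_ctss equals the transitive-closure oracle and is order-invariant", {
  set.seed(13)
  for (rep in 1:25) {
    df <- data.frame(chrom = sample(c("c1", "c2"), 200, TRUE),
                     pos = sample(1:2000, 200),
                     strand = sample(c("+", "-"), 200, TRUE),
                     count = sample(1:50, 200, TRUE),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(df[c("chrom", "pos", "strand")]), ]
    md <- sample(c(5, 20, 50), 1)
    tc <- cluster_ctss(df, maxdist = md)
    m <- tc$members
    # same partition as the closure oracle (compare as label co-membership)
    lab_o <- oracle_cluster(m, md)
    expect_identical(as.integer(factor(m$cluster_id, levels = unique(m$cluster_id))),
                     as.integer(factor(lab_o, levels = unique(lab_o))))
    # input order must not matter
    tc2 <- cluster_ctss(df[sample(nrow(df)), ], maxdist = md)
    expect_identical(tc$members, tc2$members)
    expect_identical(tc$clusters, tc2$clusters)
  }
})

test_that("quantile_width matches cumulative enumeration and the 10-bp cut", {
  w <- quantile_width(100, 50)
  expect_identical(w$width, 1L)
  expect_identical(w$shape, "sharp")
  w10 <- quantile_width(1:10, rep(1, 10))
  expect_identical(w10$q_low_pos, 1L)
  expect_identical(w10$q_high_pos, 9L)
  expect_identical(w10$width, 9L)
  expect_identical(w10$shape, "sharp")
  w15 <- quantile_width(1:15, rep(1, 15))
  expect_gte(w15$width, 10)
  expect_identical(w15$shape, "broad")
  # minus strand accumulates in transcription direction (descending coords)
  wm <- quantile_width(1:10, c(rep(0, 9), 10), strand = "-")
  expect_identical(wm$width, 1L)
  expect_error(quantile_width(integer(0), integer(0)), "empty")
  set.seed(17)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    pos <- sort(sample(1:200, n))
    cnt <- sample(1:100, n, TRUE)
    st <- sample(c("+", "-"), 1)
    expect_identical(quantile_width(pos, cnt, st)$width,
                     as.integer(oracle_quantile_width(pos, cnt, st, 0.1, 0.9)))
  }
})

test_that("widening a tag distribution never decreases the quantile width", {
  set.seed(19)
  for (i in 1:50) {
    pos <- 1:21
    w <- exp(-(pos - 11)^2 / (2 * 2^2))
    wide <- exp(-(pos - 11)^2 / (2 * 6^2))
    cnt_n <- round(w / sum(w) * 1e4)
    cnt_w <- round(wide / sum(wide) * 1e4)
    expect_gte(quantile_width(pos, cnt_w)$width,
               quantile_width(pos, cnt_n)$width)
  }
})

# tiny hand-built genome for score tests
toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    #        1         11        21        31        41        51        61
    chrT = paste0("AAAAAAAAAA", "CTTTTGAAAA", "GAAAAAAAAA", "CCCCCTTCCA",
                  strrep("A", 40))
  ))
}

test_that("tss_sequence reads transcript-strand sequence from both strands", {
  g <- toy_genome()
  expect_identical(tss_sequence(g, "chrT", 11, "+", 5), "CTTTT")
  # minus strand: reverse complement of the upstream window
  expect_identical(tss_sequence(g, "chrT", 15, "-", 5), "AAAAG")
  expect_error(tss_sequence(g, "chrX", 1, "+", 5), "unknown chromosome")
  expect_error(tss_sequence(g, "chrT", 1e6, "+", 5), "outside")
})

test_that("topscore weights capped run lengths by tag fractions", {
  g <- toy_genome()
  # single TSS over CTTTTG: run length 5
  p1 <- gene_tss_profile(11, 100, "+", "chrT", g, gene_id = "A")
  expect_equal(topscore(p1)$topscore, 5)
  expect_true(topscore(p1)$is_top_gt2)
  # 50/50 split between run-5 TSS and purine-start TSS
  p2 <- gene_tss_profile(c(11, 21), c(50, 50), "+", "chrT", g)
  expect_equal(topscore(p2)$topscore, 2.5)
  # a 20-pyrimidine tract is capped at 16
  g2 <- Biostrings::DNAStringSet(c(chrP = paste0(strrep("T", 25), strrep("A", 10))))
  p3 <- gene_tss_profile(1, 10, "+", "chrP", g2)
  expect_equal(topscore(p3)$topscore, 16)
  # homogeneous profile equals min(L, cap) exactly; all-purine gives 0
  gp <- Biostrings::DNAStringSet(c(chrG = strrep("G", 30)))
  p4 <- gene_tss_profile(c(5, 10), c(3, 7), "+", "chrG", gp)
  expect_identical(topscore(p4)$topscore, 0)
  expect_error(gene_tss_profile(11, 0, "+", "chrT", g), "zero tags")
  # range bound
  expect_lte(topscore(p2)$topscore, 16)
  expect_gte(topscore(p2)$topscore, 0)
})

test_that("filter_min_avg_reads applies the strict >500 mean rule", {
  m <- rbind(kept = c(600, 600), edge = c(500, 500), under = c(10, 20),
             uneven = c(0, 1200))
  expect_identical(filter_min_avg_reads(m), c("kept", "uneven"))
  # brute-force agreement on a random table
  set.seed(23)
  m2 <- matrix(sample(0:1000, 300, TRUE), 100,
               dimnames = list(sprintf("g%d", 1:100), NULL))
  expect_identical(filter_min_avg_reads(m2),
                   rownames(m2)[sapply(1:100, function(i) mean(m2[i, ]) > 500)])
})

test_that("gene_prte_scores flags genes by the strict >10 CPM rule", {
  # hand-built genome: PRTE planted in gene A only, purine background
  seqA <- paste0(strrep("G", 10), "CCTTCTTCC", strrep("A", 61))
  seqB <- strrep("AG", 40)
  g <- Biostrings::DNAStringSet(c(chrH = paste0(seqA, seqB)))
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chrH",
                      strand = "+", start = c(1L, 81L), end = c(80L, 160L),
                      stringsAsFactors = FALSE)
  # 30 PRTE-containing tags in A; library padded to 2e6 via gene B
  tab <- ctss_table(data.frame(chrom = "chrH", pos = c(5L, 100L),
                               strand = "+", count = c(30L, 2e6 - 30L)))
  sc <- gene_prte_scores(tab, g, genes)
  expect_equal(sc$prte_score[sc$gene_id == "A"], 15)
  expect_true(sc$prte_flag[sc$gene_id == "A"])
  expect_false(sc$prte_flag[sc$gene_id == "B"])
  # score exactly 10 is not flagged (strict >)
  tab10 <- ctss_table(data.frame(chrom = "chrH", pos = c(5L, 100L),
                                 strand = "+", count = c(20L, 2e6 - 20L)))
  sc10 <- gene_prte_scores(tab10, g, genes)
  expect_equal(sc10$prte_score[sc10$gene_id == "A"], 10)
  expect_false(sc10$prte_flag[sc10$gene_id == "A"])
  # conservation: per-gene PRTE counts never exceed the library size
  expect_lte(sum(sc$prte_count), attr(tab, "library_size"))
  # CTSS outside any gene is skipped with a message
  tab_out <- ctss_table(data.frame(chrom = "chrH", pos = c(5L, 200L),
                                   strand = "+", count = c(30L, 10L)))
  expect_message(gene_prte_scores(tab_out, g, genes), "outside any gene")
})

test_that("window_read_fractions normalises within each gene's windows", {
  tab <- ctss_table(data.frame(chrom = "c", pos = c(5L, 15L, 25L),
                               strand = "+", count = c(30L, 10L, 60L)))
  win <- data.frame(chrom = "c", start = c(1L, 11L, 21L), end = c(10L, 20L, 30L),
                    strand = "+", gene_id = "g", window = 1:3,
                    stringsAsFactors = FALSE)
  fr <- window_read_fractions(tab, win)
  expect_equal(fr$fraction, c(0.3, 0.1, 0.6))
  # all tags in one window
  tab1 <- ctss_table(data.frame(chrom = "c", pos = 5L, strand = "+",
                                count = 100L))
  expect_equal(window_read_fractions(tab1, win)$fraction, c(1, 0, 0))
  # zero tags anywhere: fractions undefined
  tabz <- ctss_table(data.frame(chrom = "c", pos = 500L, strand = "+",
                                count = 5L))
  expect_true(all(is.na(window_read_fractions(tabz, win)$fraction)))
})
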