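test_that("island relation follows the 2kb/4kb cutoffs", {
  # island covering 1-based 10001..11000 (BED [10000, 11000))
  isl <- data.frame(start = 10000L, end = 11000L)
  got <- classify_island_relation(c(10500L, 12500L, 14500L, 16000L), isl)
  expect_identical(as.character(got$relation),
                   c("Island", "Shore", "Shelf", "OpenSea"))
  expect_equal(got$distance, c(0, 1500, 3500, 5000))
  # boundary distances: 2000 is still Shore, 4000 still Shelf
  b <- classify_island_relation(c(13000L, 15000L, 15001L), isl)
  expect_identical(as.character(b$relation), c("Shore", "Shelf", "OpenSea"))
  # no islands on the chromosome
  none <- classify_island_relation(5000L, isl[0, ])
  expect_identical(as.character(none$relation), "OpenSea")
  expect_identical(none$distance, Inf)
  expect_error(
    classify_island_relation(1L, data.frame(start = c(10, 5), end = c(20, 9))),
    "sorted")
  expect_error(
    classify_island_relation(1L, data.frame(start = c(5, 10), end = c(15, 20))),
    "overlapping")
})

test_that("island relation matches a brute-force nearest-edge scan", {
  set.seed(505)
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    starts <- sort(sample.int(50000L, k))
    ends <- starts + sample(200:1500, k, replace = TRUE)
    ok <- c(TRUE, starts[-1] > ends[-k])
    isl <- data.frame(start = starts, end = ends)[ok, , drop = FALSE]
    pos <- sample.int(55000L, 25)
    got <- classify_island_relation(pos, isl)
    for (i in seq_along(pos)) {
      oracle <- brute_island_relation(pos[i], isl)
      expect_identical(as.character(got$relation[i]), oracle$relation)
      expect_equal(got$distance[i], oracle$distance)
    }
  }
})

test_that("island detection scores windows by observed/expected CpG ratio", {
  # hand count: CGCGCGCGCG has 5 CG dinucleotides, 5 C, 5 G -> O/E = 2
  seq <- "CGCGCGCGCG"
  isl <- detect_islands(seq, min_len = 5L, oe_min = 0.6, window = 10L)
  expect_identical(nrow(isl), 1L)
  expect_equal(isl$oe, 2.0)
  expect_identical(c(isl$start, isl$end), c(0L, 10L))
  # all-A sequence: O/E = 0 everywhere, no islands
  expect_identical(nrow(detect_islands(strrep("A", 1000))), 0L)
  expect_identical(nrow(detect_islands("")), 0L)
})

test_that("reported islands survive a brute-force window rescan", {
  set.seed(606)
  for (rep in 1:10) {
    # CpG-rich patches in an AT-rich background
    chunks <- sample(c("AT", "TA", "CG", "GC", "CA", "TG"), 2500,
                     replace = TRUE, prob = c(0.3, 0.3, 0.12, 0.08, 0.1, 0.1))
    seq <- paste(chunks, collapse = "")
    isl <- detect_islands(seq)
    if (nrow(isl)) {
      expect_true(all(isl$end - isl$start > 200))
      for (i in seq_len(nrow(isl))) {
        # every island must contain at least one qualifying window...
        ws <- (isl$start[i] + 1):(isl$end[i] - 200 + 1)
        oes <- vapply(ws, function(s) brute_window_oe(seq, s), numeric(1))
        expect_true(any(oes > 0.6))
        # ...and its first window qualifies (runs start at a qualifying window)
        expect_gt(brute_window_oe(seq, isl$start[i] + 1), 0.6)
      }
    }
    # no qualifying window outside any island is adjacent-mergeable:
    # windows just beyond each island end must fail the threshold
    for (i in seq_len(nrow(isl))) {
      s_after <- isl$end[i] + 1
      if (s_after + 200 - 1 <= nchar(seq)) {
        expect_lte(brute_window_oe(seq, s_after), 0.6)
      }
    }
  }
})

test_that("the 15-state collapse maps every mnemonic to its category", {
  map <- chromhmm_collapse_map()
  expected <- c(TssA = "TSS", TssBiv = "TSS",
                TssAFlnk = "FlankingTSS", BivFlnk = "FlankingTSS",
                Tx = "Transcribed", TxFlnk = "Transcribed",
                TxWk = "Transcribed",
                Enh = "Enhancer", EnhG = "Enhancer", EnhBiv = "Enhancer",
                `ZNF/Rpts` = "Repressed", Het = "Repressed",
                ReprPC = "Repressed", ReprPCWk = "Repressed",
                Quies = "Repressed")
  expect_identical(length(map), 15L)
  for (state in names(expected)) {
    expect_identical(unname(map[state]), unname(expected[state]))
  }
  # surjective onto the five categories
  expect_setequal(unique(unname(map)),
                  c("TSS", "FlankingTSS", "Transcribed", "Enhancer",
                    "Repressed"))
})

test_that("chromatin-state lookup respects the BED half-open convention", {
  seg <- data.frame(start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L),
                    state = c("Quies", "Enh", "TssA"))
  got <- map_chromatin_state(c(1000L, 1001L, 2000L, 2001L, 3000L, 3001L), seg)
  expect_identical(got$state, c("Quies", "Enh", "Enh", "TssA", "TssA", NA))
  expect_identical(got$category,
                   c("Repressed", "Enhancer", "Enhancer", "TSS", "TSS",
                     "Unassigned"))
  expect_error(map_chromatin_state(1L, data.frame(
    start = c(0L, 500L), end = c(1000L, 1500L), state = c("Enh", "Tx"))),
    "overlap")
  expect_error(map_chromatin_state(1L, data.frame(
    start = 0L, end = 10L, state = "NotAState")), "mnemonic")
})

test_that("gene features follow the 450K taxonomy with precedence", {
  genes <- data.frame(gene = "G1", start = 10000L, end = 20000L,
                      strand = "+", utr5_end = 11000L, utr3_start = 19000L)
  got <- assign_gene_feature(
    c(9900L, 9000L, 10500L, 15000L, 19500L, 30000L), genes)
  expect_identical(as.character(got$feature),
                   c("TSS200", "TSS1500", "5'UTR", "Body", "3'UTR",
                     "Intergenic"))
  # minus strand: TSS at the gene end
  gm <- data.frame(gene = "G2", start = 10000L, end = 20000L,
                   strand = "-", utr5_end = 11000L, utr3_start = 19000L)
  gotm <- assign_gene_feature(c(20100L, 21000L, 19500L, 10500L), gm)
  expect_identical(as.character(gotm$feature),
                   c("TSS200", "TSS1500", "5'UTR", "3'UTR"))
  # overlapping genes: promoter wins over body
  two <- rbind(genes,
               data.frame(gene = "G3", start = 9500L, end = 9950L,
                          strand = "-", utr5_end = 9600L, utr3_start = 9900L))
  gp <- assign_gene_feature(9900L, two)
  expect_identical(as.character(gp$feature), "TSS200")
})

test_that("probe annotation proportions sum to one per track", {
  tiny <- make_tiny_paired(n_probes = 200L)
  ann <- annotate_probes(tiny$sim$manifest[, c("probe_id", "chrom", "pos")],
                         tiny$sim$islands, tiny$sim$chrom_states,
                         tiny$sim$genes)
  expect_identical(ann$probe_id, tiny$sim$manifest$probe_id)
  expect_equal(sum(prop.table(table(ann$feature))), 1)
  expect_equal(sum(prop.table(table(ann$island_relation))), 1)
  assigned <- ann$category != "Unassigned"
  expect_equal(sum(prop.table(table(ann$category[assigned]))), 1)
})
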