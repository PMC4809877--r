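# independent run-length oracle: mark expressed positions, cluster them by
# gap, then filter by length
oracle_candidates <- function(depth, params) {
  pos <- which(depth >= params$min_depth)  # 1-based
  if (length(pos) == 0) return(NULL)
  grp <- cumsum(c(0, diff(pos) - 1 > params$merge_gap))
  out <- do.call(rbind, lapply(split(pos, grp), function(p) {
    data.frame(start = min(p) - 1L, end = max(p))
  }))
  len <- out$end - out$start
  out <- out[len >= params$min_length & len <= params$max_length, ,
             drop = FALSE]
  if (nrow(out) == 0) return(NULL)
  out$mean_depth <- vapply(seq_len(nrow(out)), function(i)
    mean(depth[(out$start[i] + 1):out$end[i]]), numeric(1))
  rownames(out) <- NULL
  out[order(out$start), ]
}

test_that("candidate calling matches a brute-force run-length oracle", {
  params <- detection_params(min_depth = 5, min_length = 30,
                             max_length = 400, merge_gap = 10)
  ann <- genome_annotation(c(chr = 3000))
  for (seed in 1:10) {
    set.seed(seed)
    cov <- strand_coverage(ann)
    # scattered blocks of varying depth and width plus noise
    for (k in 1:8) {
      s <- sample(0:2800, 1)
      w <- sample(5:200, 1)
      cov <- paint(cov, "chr", sample(c("+", "-"), 1), s,
                   min(s + w, 3000), sample(2:12, 1))
    }
    got <- call_candidate_intervals(cov, params)
    for (st in c("+", "-")) {
      want <- oracle_candidates(cov$chr[[st]], params)
      have <- got[got$strand == st, c("start", "end", "mean_depth")]
      if (is.null(want)) {
        expect_equal(nrow(have), 0L)
      } else {
        expect_equal(as.data.frame(have), want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("gap merging switches exactly at merge_gap", {
  params <- detection_params(min_depth = 5, min_length = 10, merge_gap = 25)
  ann <- genome_annotation(c(chr = 1000))
  base <- strand_coverage(ann)
  base <- paint(base, "chr", "+", 100, 200, 10)

  merged <- paint(base, "chr", "+", 200 + 24, 300, 10)  # gap 24
  expect_equal(nrow(call_candidate_intervals(merged, params)), 1L)
  at_gap <- paint(base, "chr", "+", 200 + 25, 300, 10)  # gap 25 (== merges)
  expect_equal(nrow(call_candidate_intervals(at_gap, params)), 1L)
  split <- paint(base, "chr", "+", 200 + 26, 300, 10)   # gap 26
  expect_equal(nrow(call_candidate_intervals(split, params)), 2L)
})

test_that("a rectangular block yields one exact candidate; zero coverage none", {
  ann <- genome_annotation(c(chr = 1000))
  cov <- strand_coverage(ann)
  expect_equal(nrow(call_candidate_intervals(cov)), 0L)
  cov <- paint(cov, "chr", "-", 300, 500, 10)
  got <- call_candidate_intervals(cov)
  expect_equal(got$start, 300L)
  expect_equal(got$end, 500L)
  expect_equal(got$strand, "-")
  expect_equal(got$mean_depth, 10)
})

test_that("5'-UTR-like candidates are removed on the correct strand/side", {
  ann <- toy_annotation()  # G1 + [500,900); G2 - [1200,1600)
  params <- detection_params(utr_max_distance = 50, min_length = 30)
  cand <- tibble::tibble(
    replicon = "chr",
    strand = c("+", "+", "-", "-", "+", "+"),
    start = c(430L, 330L, 430L, 1620L, 1620L, 30L),
    end = c(480L, 440L, 480L, 1680L, 1680L, 90L),
    mean_depth = 10)
  kept <- remove_utr_like(cand, ann, params)
  # + candidate ending 20 nt before G1 start: removed
  expect_false(any(kept$strand == "+" & kept$end == 480))
  # + candidate ending 60 nt before G1 start: kept
  expect_true(any(kept$strand == "+" & kept$end == 440))
  # - candidate at the same coordinates (antisense to the G1 side): kept
  expect_true(any(kept$strand == "-" & kept$end == 480))
  # - candidate starting 20 nt after G2's genomic end (upstream of a minus
  # gene start): removed
  expect_false(any(kept$strand == "-" & kept$start == 1620))
  # + candidate there: kept
  expect_true(any(kept$strand == "+" & kept$start == 1620))
  # gene-desert candidate: kept
  expect_true(any(kept$start == 30))
  # abutting (distance 0) counts as UTR-like
  abut <- tibble::tibble(replicon = "chr", strand = "+", start = 450L,
                         end = 500L, mean_depth = 10)
  expect_equal(nrow(remove_utr_like(abut, ann, params)), 0L)
})

test_that("classification separates cis, trans, and read-through", {
  ann <- toy_annotation()
  params <- detection_params(min_length = 40, min_antisense_overlap = 0.5)
  cand <- tibble::tibble(
    replicon = "chr",
    strand = c("-", "+", "+", "-"),
    start = c(600L, 950L, 520L, 860L),
    end = c(800L, 1100L, 700L, 1060L),
    mean_depth = 10)
  calls <- classify_calls(cand, ann, params)
  # fully antisense within G1 -> cis
  cis <- calls[calls$start == 600, ]
  expect_equal(cis$mode, "cis")
  expect_equal(cis$antisense_locus, "G1")
  # intergenic -> trans
  expect_equal(calls$mode[calls$start == 950], "trans")
  # same-strand overlap of G1 body -> discarded
  expect_false(any(calls$start == 520))
  # antisense overlap 40/200 < 50% and same-strand free -> not called
  expect_false(any(calls$start == 860))
  expect_equal(calls$size, calls$end - calls$start)
})

test_that("maximal-overlap target wins, ties break lexicographically", {
  ann <- genome_annotation(
    c(chr = 2000),
    tibble::tibble(locus_tag = c("GB", "GA"), replicon = "chr",
                   start = c(100L, 400L), end = c(400L, 800L),
                   strand = "+", product = NA, category = NA))
  # candidate antisense over both genes: 60% in GB side vs 40% in GA
  cand <- tibble::tibble(replicon = "chr", strand = "-", start = 280L,
                         end = 480L, mean_depth = 8)
  calls <- classify_calls(cand, ann, detection_params(min_length = 40))
  expect_equal(calls$antisense_locus, "GB")
  # perfect tie: equal overlap of both genes -> smaller locus tag
  tie <- tibble::tibble(replicon = "chr", strand = "-", start = 300L,
                        end = 500L, mean_depth = 8)
  calls_tie <- classify_calls(tie, ann, detection_params(min_length = 40))
  expect_equal(calls_tie$antisense_locus, "GA")
})

test_that("read-through past a same-strand 3' end is trimmed, not discarded", {
  ann <- toy_annotation()  # G1 + [500,900)
  params <- detection_params(min_length = 50)
  cand <- tibble::tibble(replicon = "chr", strand = "+", start = 850L,
                         end = 1100L, mean_depth = 10)
  calls <- classify_calls(cand, ann, params)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 900L)   # trimmed to the gene 3' end
  expect_equal(calls$end, 1100L)
  expect_equal(calls$mode, "trans")
  # too short after trimming -> dropped
  short <- tibble::tibble(replicon = "chr", strand = "+", start = 700L,
                          end = 940L, mean_depth = 10)
  expect_equal(nrow(classify_calls(short, ann, params)), 0L)
})

test_that("detection commutes with reverse-complementing the genome", {
  ann <- toy_annotation()
  cov <- strand_coverage(ann)
  cov <- paint(cov, "chr", "-", 600, 800, 12)    # cis antisense to G1
  cov <- paint(cov, "chr", "+", 950, 1100, 9)    # trans
  calls <- detect_srnas(cov, ann)

  # reverse-complement every replicon: reflect coordinates, swap strands
  L <- ann$replicons
  ann_rc <- genome_annotation(
    L, transform(ann$genes,
                 start = as.integer(L[replicon] - end),
                 end = as.integer(L[replicon] - start),
                 strand = ifelse(strand == "+", "-", "+")))
  cov_rc <- strand_coverage(ann_rc)
  for (r in names(cov)) {
    cov_rc[[r]][["+"]] <- rev(cov[[r]][["-"]])
    cov_rc[[r]][["-"]] <- rev(cov[[r]][["+"]])
  }
  calls_rc <- detect_srnas(cov_rc, ann_rc)
  # map the mirrored calls back onto original coordinates
  back <- transform(calls_rc,
                    start = as.integer(L[replicon] - end),
                    end = as.integer(L[replicon] - start),
                    strand = ifelse(strand == "+", "-", "+"))
  back <- back[order(back$start), ]
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
  expect_equal(back$mode, calls$mode)
  expect_equal(back$strand, calls$strand)
  expect_equal(back$antisense_locus, calls$antisense_locus)

  # shift everything by a constant offset
  off <- 137L
  ann_sh <- genome_annotation(
    ann$replicons + off,
    transform(ann$genes, start = start + off, end = end + off))
  cov_sh <- strand_coverage(ann_sh)
  for (r in names(cov)) for (st in c("+", "-"))
    cov_sh[[r]][[st]][(off + 1):(off + length(cov[[r]][[st]]))] <-
      cov[[r]][[st]]
  calls_sh <- detect_srnas(cov_sh, ann_sh)
  expect_equal(calls_sh$start, calls$start + off)
  expect_equal(calls_sh$end, calls$end + off)
  expect_equal(calls_sh$mode, calls$mode)
})

test_that("planted sRNAs at twice the depth threshold are recovered", {
  for (seed in 1:3) {
    cfg <- small_config(700 + seed)
    g <- generate_genome(cfg)
    cm <- simulate_counts(g$truth, cfg)
    cov <- simulate_coverage(g$truth, g$annotation, cm, cfg)
    calls <- detect_srnas(cov, g$annotation)
    tr <- g$truth$srnas
    md <- vapply(seq_len(nrow(tr)), function(i)
      mean(cov[[tr$replicon[i]]][[tr$strand[i]]][(tr$start[i] + 1):tr$end[i]]),
      numeric(1))
    deep <- which(md >= 10)
    ok <- vapply(deep, function(i) {
      m <- calls$replicon == tr$replicon[i] & calls$strand == tr$strand[i]
      any(m & abs(calls$start - tr$start[i]) <= 25 &
            abs(calls$end - tr$end[i]) <= 25)
    }, logical(1))
    expect_true(all(ok))
    # pure background produces no calls
    cm0 <- cm; cm0$counts[] <- 0L
    cov0 <- simulate_coverage(g$truth, g$annotation, cm0, cfg)
    expect_equal(nrow(detect_srnas(cov0, g$annotation)), 0L)
  }
})
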