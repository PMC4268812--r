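test_that("anchoring recovers identity and reverse-complement matches", {
  set.seed(21)
  s <- rand_seq_chr(500)
  a <- find_anchors(c(r = s), c(q = s))
  a_plus <- a[a$strand == "+", ]
  expect_equal(nrow(a_plus), 1)
  expect_equal(a_plus$ref_start, 0L)
  expect_equal(a_plus$length, 500L)
  a <- find_anchors(c(r = s), c(q = oracle_revcomp(s)))
  a_minus <- a[a$strand == "-", ]
  expect_equal(nrow(a_minus), 1)
  expect_equal(a_minus$length, 500L)
  expect_equal(a_minus$qry_start, 0L)  # start on the rc'd query
})

test_that("anchors equal the exhaustive enumeration oracle", {
  set.seed(22)
  cfg <- aligner_config()
  for (rep in 1:100) {
    n <- sample(80:300, 1)
    ref <- rand_seq_chr(n)
    qry <- if (rep %% 2 == 0) mutated_copy(ref, sample(0:3, 1))
           else paste0(rand_seq_chr(30), substring(ref, 10, n - 10),
                       rand_seq_chr(20))
    got <- find_anchors(c(r = ref), c(q = qry), cfg)
    got_plus <- got[got$strand == "+", c("ref_start", "qry_start", "length")]
    want <- oracle_anchors(ref, qry, cfg$min_match)
    rownames(got_plus) <- rownames(want) <- NULL
    expect_equal(got_plus, want, label = sprintf("seed rep %d", rep))
    # minus strand against the rc'd query, same convention
    got_minus <- got[got$strand == "-", c("ref_start", "qry_start", "length")]
    want_minus <- oracle_anchors(ref, oracle_revcomp(qry), cfg$min_match)
    rownames(got_minus) <- rownames(want_minus) <- NULL
    expect_equal(got_minus, want_minus)
  }
})

test_that("anchors never cross N runs", {
  set.seed(23)
  left <- rand_seq_chr(60)
  right <- rand_seq_chr(60)
  ref <- paste0(left, strrep("N", 5), right)
  a <- find_anchors(c(r = ref), c(q = ref))
  a <- a[a$strand == "+", ]
  expect_equal(nrow(a), 2)
  expect_equal(sort(a$length), c(60L, 60L))
})

mk_anchor_df <- function(rs, qs, len) {
  data.frame(ref_seq = "r", ref_start = rs, qry_seq = "q", qry_start = qs,
             length = len, strand = "+", qry_start_fwd = qs,
             qry_end_fwd = qs + len, stringsAsFactors = FALSE)
}

test_that("clustering chains nearby anchors and applies the length floor", {
  cfg <- aligner_config()
  # two 40 bp anchors 50 bp apart on the same diagonal chain together
  a <- cluster_anchors(mk_anchor_df(c(0L, 90L), c(0L, 90L), c(40L, 40L)), cfg)
  expect_equal(length(unique(a$cluster)), 1L)
  # a lone 60 bp anchor dies (60 < 65); a lone 70 bp anchor survives
  expect_equal(nrow(cluster_anchors(mk_anchor_df(0L, 0L, 60L), cfg)), 0L)
  expect_equal(nrow(cluster_anchors(mk_anchor_df(0L, 0L, 70L), cfg)), 1L)
  # a distant anchor on a shifted diagonal starts its own cluster
  a <- cluster_anchors(mk_anchor_df(c(0L, 5000L), c(0L, 9000L), c(80L, 80L)),
                       cfg)
  expect_equal(length(unique(a$cluster)), 2L)
})

test_that("extension computes identity and classifies indel events", {
  set.seed(24)
  cfg <- aligner_config()
  s <- rand_seq_chr(400)
  # identical sequences: identity 1, no events
  al <- align_genomes(c(r = s), c(q = s), cfg)
  expect_equal(al$blocks$identity, 1)
  expect_equal(al$blocks$subs, 0)
  expect_equal(nrow(al$large_indels), 0)
  # one substitution in the middle
  q <- mutated_copy(s, 0)
  v <- strsplit(q, "", fixed = TRUE)[[1]]
  v[200] <- setdiff(c("A", "C", "G", "T"), v[200])[1]
  al <- align_genomes(c(r = s), c(q = paste(v, collapse = "")), cfg)
  expect_equal(nrow(al$blocks), 1)
  expect_equal(al$blocks$subs, 1)
  expect_equal(al$blocks$identity, (400 - 1) / 400)
  # 7 bp deletion in the query: one large indel event of size 7
  qdel <- paste0(substring(s, 1, 200), substring(s, 208, 400))
  al <- align_genomes(c(r = s), c(q = qdel), cfg)
  expect_equal(nrow(al$blocks), 1)
  expect_equal(al$large_indels$size, 7L)
  expect_equal(al$blocks$small_indels, 0)
  # 3 bp deletion counts as a small indel event instead
  qdel3 <- paste0(substring(s, 1, 200), substring(s, 204, 400))
  al <- align_genomes(c(r = s), c(q = qdel3), cfg)
  expect_equal(al$blocks$small_indels, 1)
  expect_equal(nrow(al$large_indels), 0)
})

mk_blocks <- function(rs, re, qs, qe, w, rseq = "r", qseq = "q") {
  data.frame(ref_seq = rseq, ref_start = rs, ref_end = re, qry_seq = qseq,
             qry_start = qs, qry_end = qe, strand = "+", identity = 1,
             cols = w, matches = w, subs = 0, small_indels = 0L,
             stringsAsFactors = FALSE)
}

test_that("one-to-one filtering keeps the heavier of conflicting blocks", {
  b <- rbind(mk_blocks(0L, 900L, 0L, 900L, 900),
             mk_blocks(2000L, 2400L, 0L, 400L, 400))
  kept <- filter_one_to_one(b)
  expect_equal(kept$matches, 900)
  disjoint <- rbind(mk_blocks(0L, 100L, 0L, 100L, 100),
                    mk_blocks(200L, 300L, 200L, 300L, 100))
  expect_equal(nrow(filter_one_to_one(disjoint)), 2)
})

test_that("one-to-one filtering equals the exponential-search oracle", {
  set.seed(25)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    rs <- sample.int(500L, n)
    qs <- sample.int(500L, n)
    len <- sample.int(150L, n)
    b <- mk_blocks(rs, rs + len, qs, qs + len, as.numeric(len),
                   rseq = sample(c("r1", "r2"), n, replace = TRUE),
                   qseq = sample(c("q1", "q2"), n, replace = TRUE))
    kept <- filter_one_to_one(b)
    expect_equal(sum(kept$matches), oracle_one_to_one_weight(b),
                 label = sprintf("rep %d", rep))
    # kept blocks never overlap on either axis
    for (ax in list(c("ref_seq", "ref_start", "ref_end"),
                    c("qry_seq", "qry_start", "qry_end"))) {
      d <- kept[order(kept[[ax[1]]], kept[[ax[2]]]), ]
      if (nrow(d) > 1) {
        same <- d[[ax[1]]][-1] == d[[ax[1]]][-nrow(d)]
        expect_true(all(d[[ax[2]]][-1][same] >= d[[ax[3]]][-nrow(d)][same]))
      }
    }
  }
})

test_that("difference summaries detect rearrangements", {
  set.seed(26)
  cfg <- aligner_config()
  s1 <- rand_seq_chr(1000); s2 <- rand_seq_chr(1000); s3 <- rand_seq_chr(1000)
  gp <- strrep("N", 100)  # scaffold gap: blocks cannot extend or chain across
  ref <- c(r = paste0(s1, s2, s3))
  # identical genomes
  d <- summarize_diff(filter_one_to_one(align_genomes(ref, ref, cfg)),
                      ref, ref, cfg)
  expect_equal(d$avg_identity, 1)
  expect_equal(d$unaligned_ref_frac, 0)
  expect_equal(d$unaligned_qry_frac, 0)
  expect_equal(d$inversions + d$relocations + d$translocations, 0)
  expect_equal(d$snps_small_indels, 0)
  # middle third reverse-complemented: inversion, no translocation
  refg <- c(r = paste0(s1, gp, s2, gp, s3))
  qinv <- c(q = paste0(s1, gp, oracle_revcomp(s2), gp, s3))
  d <- summarize_diff(filter_one_to_one(align_genomes(refg, qinv, cfg)),
                      refg, qinv, cfg)
  expect_gte(d$inversions, 1)
  expect_equal(d$translocations, 0)
  # segments exchanged between two scaffolds: translocation
  s4 <- rand_seq_chr(1000)
  ref2 <- c(r1 = paste0(s1, gp, s2), r2 = paste0(s3, gp, s4))
  q2 <- c(q1 = paste0(s1, gp, s3), q2 = paste0(s2, gp, s4))
  d <- summarize_diff(filter_one_to_one(align_genomes(ref2, q2, cfg)),
                      ref2, q2, cfg)
  expect_gte(d$translocations, 1)
  # segment moved within a scaffold: relocation
  qrel <- c(q = paste0(s1, gp, s3, gp, s2))
  d <- summarize_diff(filter_one_to_one(align_genomes(refg, qrel, cfg)),
                      refg, qrel, cfg)
  expect_gte(d$relocations, 1)
  expect_equal(d$translocations, 0)
  # empty block set: zero summary with unaligned fractions 1
  d0 <- summarize_diff(mk_blocks(0L, 1L, 0L, 1L, 1)[0, ], ref, qinv, cfg)
  expect_equal(d0$unaligned_ref_frac, 1)
  expect_equal(d0$avg_identity, 0)
})

test_that("unaligned regions complement the aligned intervals exactly", {
  set.seed(27)
  cfg <- aligner_config()
  s <- rand_seq_chr(2000)
  al <- align_genomes(c(r = s), c(q = s), cfg)
  expect_equal(iv_count(unaligned_regions(c(r = s), al, "ref")), 0L)
  # planted 5 kbp insertion in the target
  ins <- rand_seq_chr(5000)
  tail_seq <- rand_seq_chr(2000)
  tgt <- c(r = paste0(s, ins, tail_seq))
  oth <- c(q = paste0(s, tail_seq))
  al <- align_genomes(tgt, oth, cfg)
  ua <- unaligned_regions(tgt, al, "ref")
  expect_equal(iv_count(ua), 1L)
  expect_lt(abs(iv_total_bp(ua) - 5000), 100)  # small extension slack
  # per-base oracle on a toy pair
  blocks <- al$blocks
  v <- oracle_bitmap(data.frame(start = blocks$ref_start,
                                end = blocks$ref_end), nchar(tgt))
  want <- bitmap_to_intervals(!v)
  expect_equal(ua$start, want$start)
  expect_equal(ua$end, want$end)
})

test_that("raising the cluster floor never increases aligned bases", {
  set.seed(28)
  ref <- c(r = rand_seq_chr(3000))
  qry <- c(q = mutated_copy(ref[["r"]], 60))
  aligned_bp <- vapply(c(65, 200, 1000), function(mc) {
    al <- align_genomes(ref, qry, aligner_config(min_cluster = mc))
    if (nrow(al$blocks) == 0) return(0)
    iv_total_bp(normalize_intervals(data.frame(
      seqname = al$blocks$ref_seq, start = al$blocks$ref_start,
      end = al$blocks$ref_end)))
  }, 1.0)
  expect_true(all(diff(aligned_bp) <= 0))
})
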