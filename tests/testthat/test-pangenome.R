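lens <- c(chr1 = 10000L)

test_that("base classification follows the Venn set algebra", {
  # nothing unaligned: everything is core
  lab <- classify_bases(lens, interval_set(), interval_set(),
                        names = c("A", "B", "C"))
  expect_equal(iv_total_bp(lab$ABC), 10000)
  expect_equal(iv_total_bp(lab$A), 0)
  # a base unaligned to both others is specific
  u1 <- interval_set("chr1", 100L, 200L)
  u2 <- interval_set("chr1", c(150L, 500L), c(250L, 600L))
  lab <- classify_bases(lens, u1, u2, names = c("A", "B", "C"))
  expect_equal(as.data.frame(lab$A),
               as.data.frame(interval_set("chr1", 150L, 200L)))
  # unaligned to C only -> shared with B only
  expect_equal(iv_total_bp(lab$AB), 100 + 50)   # [500,600) and [200,250)
  expect_equal(iv_total_bp(lab$AC), 50)         # [100,150)
  expect_error(classify_bases(lens, interval_set("chr1", 0L, 20000L), u2),
               "beyond genome bounds")
})

test_that("the four sectors partition the genome for random inputs", {
  set.seed(51)
  for (rep in 1:20) {
    mk <- function() {
      s <- sample.int(9900L, 40) - 1L
      normalize_intervals(data.frame(seqname = "chr1", start = s,
                                     end = s + sample.int(100L, 40,
                                                          replace = TRUE)))
    }
    lab <- classify_bases(lens, mk(), mk(), names = c("A", "B", "C"))
    tot <- sum(vapply(lab, iv_total_bp, 1.0))
    expect_equal(tot, 10000)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(iv_total_bp(iv_intersect(lab[[i]], lab[[j]])), 0)
  }
})

mk_labeling <- function(specific, genome_len = 10000L,
                        names = c("A", "B", "C")) {
  u <- normalize_intervals(data.frame(seqname = "chr1",
                                      start = specific$start,
                                      end = specific$end))
  classify_bases(c(chr1 = genome_len), u, u, names = names)
}

test_that("specific-region calling applies length and coverage criteria", {
  crit <- specific_region_criteria()
  prof_const <- function(v, n = 10000L) list(chr1 = rep(as.integer(v), n))
  # 99 bp region fails the length floor even with perfect coverage
  lab <- mk_labeling(data.frame(start = 1000L, end = 1099L))
  got <- call_specific_regions(lab, prof_const(50),
                               list(prof_const(0), prof_const(0)), crit)
  expect_equal(iv_count(got), 0L)
  # 500 bp region with 150x self coverage is repetitive
  lab <- mk_labeling(data.frame(start = 1000L, end = 1500L))
  got <- call_specific_regions(lab, prof_const(150),
                               list(prof_const(0), prof_const(0)), crit)
  expect_equal(iv_count(got), 0L)
  # 500 bp region, self 50x, cross 2x and 0x, is accepted
  got <- call_specific_regions(lab, prof_const(50),
                               list(prof_const(2), prof_const(0)), crit)
  expect_equal(iv_count(got), 1L)
  expect_equal(attr(got, "self_cov"), 50)
  # cross coverage at the bound (10x) rejects: strictly below required
  got <- call_specific_regions(lab, prof_const(50),
                               list(prof_const(10), prof_const(0)), crit)
  expect_equal(iv_count(got), 0L)
  # self coverage bounds are inclusive
  for (v in c(10, 100)) {
    got <- call_specific_regions(lab, prof_const(v),
                                 list(prof_const(0), prof_const(0)), crit)
    expect_equal(iv_count(got), 1L, label = sprintf("self %dx", v))
  }
})

test_that("raising the cross-coverage cap never loses called regions", {
  set.seed(52)
  lab <- mk_labeling(data.frame(start = c(1000L, 3000L, 5000L),
                                end = c(1500L, 3600L, 5900L)))
  self <- list(chr1 = rep(50L, 10000))
  cross <- list(chr1 = sample(0:20, 10000, replace = TRUE))
  counts <- vapply(c(2, 10, 30), function(cap) {
    iv_count(call_specific_regions(
      lab, self, list(cross, cross),
      specific_region_criteria(cross_cov_max = cap)))
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("gene sector assignment follows the exonic majority rule", {
  # gene with 90% of exonic bases core, 10% specific -> core sector
  ann <- new_annotation_set(data.frame(
    seqname = "chr1", type = c("gene", "mRNA", "exon"),
    start = 1000L, end = 2000L, strand = "+", gene = "g1",
    transcript = c(NA, "t1", "t1"), stringsAsFactors = FALSE))
  lab <- mk_labeling(data.frame(start = 1900L, end = 2000L))  # 10% specific
  a <- assign_gene_sectors(ann, lab)
  expect_equal(a$sector, "ABC")
  # gene fully inside a specific segment -> specific
  lab2 <- mk_labeling(data.frame(start = 500L, end = 2500L))
  expect_equal(assign_gene_sectors(ann, lab2)$sector, "A")
  # exact tie resolves toward the more-shared sector
  lab3 <- mk_labeling(data.frame(start = 1500L, end = 2000L))  # 50/50
  expect_equal(assign_gene_sectors(ann, lab3)$sector, "ABC")
  # two transcripts double-count their shared exon
  ann2 <- new_annotation_set(data.frame(
    seqname = "chr1", type = c("gene", "mRNA", "exon", "mRNA", "exon"),
    start = c(1000L, 1000L, 1000L, 1000L, 1000L),
    end = c(2000L, 2000L, 2000L, 1400L, 1400L),
    strand = "+", gene = "g2",
    transcript = c(NA, "t1", "t1", "t2", "t2"), stringsAsFactors = FALSE))
  # specific [1000,1400) counts twice (800) vs core [1400,2000) once (600)
  lab4 <- mk_labeling(data.frame(start = 1000L, end = 1400L))
  expect_equal(assign_gene_sectors(ann2, lab4)$sector, "A")
})

test_that("venn summary uses reporting precedence and conserves totals", {
  fz <- fixture_zero()
  gn <- names(fz$sim$genomes)
  venn <- venn_summary(fz$labelings[gn], fz$sim$annotations[gn])
  l <- substr(gn, 1, 1)
  # all 7 sectors present, non-negative
  expect_equal(nrow(venn), 7L)
  expect_true(all(venn$bp >= 0))
  # sectors touching genome 1 sum to its length
  g1 <- sum(venn$bp[venn$sector %in% c(paste0(l[1], l[2], l[3]),
                                       paste0(l[1], l[2]),
                                       paste0(l[1], l[3]), l[1])])
  expect_equal(g1, nchar(fz$sim$genomes[[1]][["chr1"]]))
  # recovered sector totals match planted truth exactly (zero divergence)
  canon <- function(tag) paste(sort(strsplit(tag, "")[[1]]), collapse = "")
  for (g in gn) {
    tg <- truth_sectors(fz$sim$truth, g)
    for (tag in names(fz$labelings[[g]])) {
      want <- canon(tag)
      planted <- sum(tg$end[tg$sector == want] - tg$start[tg$sector == want])
      expect_equal(iv_total_bp(fz$labelings[[g]][[tag]]), planted,
                   label = paste(g, tag))
    }
  }
})

test_that("spacing statistics distinguish regular from random placement", {
  regular <- interval_set("chr1", seq(0L, 90000L, 10000L),
                          seq(100L, 90100L, 10000L))
  st <- spacing_stats(regular)
  expect_equal(st$mean_gap, 10000)
  expect_equal(st$sd_gap, 0)
  set.seed(53)
  pos <- sort(sample.int(2e6, 200))
  rand <- normalize_intervals(data.frame(seqname = "chr1", start = pos,
                                         end = pos + 50L))
  st <- spacing_stats(rand)
  expect_gt(st$cv, 0.8)
  expect_lt(st$cv, 1.2)
  expect_error(spacing_stats(interval_set("chr1", c(0L, 200L),
                                          c(100L, 300L))),
               "insufficient")
})

test_that("genic filtering keeps whole regions meeting the overlap floor", {
  ann <- new_annotation_set(data.frame(
    seqname = "chr1", type = c("gene", "mRNA", "exon"),
    start = 1000L, end = 2000L, strand = "+", gene = "g1",
    transcript = c(NA, "t1", "t1"), stringsAsFactors = FALSE))
  regions <- interval_set("chr1", c(850L, 3000L), c(1150L, 3500L))
  kept <- call_genic_specific_regions(regions, ann)
  expect_equal(iv_count(kept), 1L)
  expect_equal(kept$start, 850L)  # flanking bases retained
  expect_equal(kept$end, 1150L)
})
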