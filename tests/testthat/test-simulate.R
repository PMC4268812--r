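only_core_cfg <- function(seed = 41) {
  sim_config(seed = seed, core_length = 10000, n_core_segments = 1,
             sector_segment_lengths = list(), snp_rate = 0,
             small_indel_rate = 0, repeat_family_specs = list(),
             gene_density = 0, read_depth = 5)
}

test_that("a core-only config yields three identical genomes", {
  sim <- simulate_trio(only_core_cfg())
  g <- vapply(sim$genomes, function(x) x[["chr1"]], "")
  expect_equal(nchar(g[[1]]), 10000L)
  expect_true(all(g == g[[1]]))
  ts <- sim$truth$sectors
  expect_equal(nrow(ts), 3L)
  expect_true(all(ts$start == 0 & ts$end == 10000 & ts$sector == "ABC"))
})

test_that("a planted specific segment lengthens exactly one genome", {
  cfg <- sim_config(seed = 42, core_length = 10000, n_core_segments = 1,
                    sector_segment_lengths = list(A = 2000L), snp_rate = 0,
                    small_indel_rate = 0, repeat_family_specs = list(),
                    gene_density = 0)
  sim <- simulate_trio(cfg)
  lens <- vapply(sim$genomes, function(x) nchar(x[["chr1"]]), 1L)
  # genome A carries the 2 kbp segment plus one junction gap
  expect_equal(unname(lens["A"] - lens["B"]), 2000L + cfg$gap_len)
  expect_equal(unname(lens["B"]), unname(lens["C"]))
  tA <- truth_sectors(sim$truth, "A", origin = "segment")
  expect_equal(sum(tA$end[tA$sector == "A"] - tA$start[tA$sector == "A"]),
               2000)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- fixture_small_cfg(seed = 43)
  s1 <- simulate_trio(cfg)
  s2 <- simulate_trio(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  r1 <- simulate_reads(s1$genomes$A, cfg, seed = 5)
  r2 <- simulate_reads(s2$genomes$A, cfg, seed = 5)
  expect_identical(as.character(r1), as.character(r2))
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixture(s1, d1, reads = list(A = r1))
  p2 <- write_fixture(s2, d2, reads = list(A = r2))
  for (nm in setdiff(names(p1), "manifest"))
    expect_equal(tools::md5sum(p1[[nm]])[[1]], tools::md5sum(p2[[nm]])[[1]],
                 label = nm)
})

test_that("truth sector intervals tile each genome exactly", {
  sim <- simulate_trio(fixture_small_cfg(seed = 44))
  for (g in names(sim$genomes)) {
    d <- truth_sectors(sim$truth, g)
    expect_equal(d$start[1], 0L)
    expect_equal(d$end[nrow(d)], nchar(sim$genomes[[g]][["chr1"]]))
    expect_true(all(d$start[-1] == d$end[-nrow(d)]))  # no gaps, no overlap
    expect_equal(sum(d$end - d$start), nchar(sim$genomes[[g]][["chr1"]]))
  }
})

test_that("mutation rates change sequences but not sector labels", {
  cfg0 <- fixture_small_cfg(seed = 45)
  cfg1 <- fixture_small_cfg(seed = 45)
  cfg0$snp_rate <- 0; cfg0$small_indel_rate <- 0
  cfg1$snp_rate <- 0.01; cfg1$small_indel_rate <- 1e-3
  s0 <- simulate_trio(cfg0)
  s1 <- simulate_trio(cfg1)
  expect_false(identical(s0$genomes$A, s1$genomes$A))
  for (g in names(s0$genomes)) {
    t0 <- truth_sectors(s0$truth, g)
    t1 <- truth_sectors(s1$truth, g)
    expect_equal(t1$sector, t0$sector)
    expect_equal(t1$origin, t0$origin)
  }
})

test_that("error-free reads are exact substrings and hit the target depth", {
  cfg <- fixture_small_cfg(seed = 46)
  sim <- simulate_trio(cfg)
  reads <- simulate_reads(sim$genomes$A, cfg)
  glen <- nchar(sim$genomes$A[["chr1"]])
  expect_lt(abs(sum(Biostrings::width(reads)) - cfg$read_depth * glen) /
              (cfg$read_depth * glen), 0.01)
  g <- sim$genomes$A[["chr1"]]
  set.seed(1)
  for (r in as.character(reads[sample(length(reads), 30)])) {
    expect_true(grepl(r, g, fixed = TRUE) ||
                  grepl(oracle_revcomp(r), g, fixed = TRUE))
  }
  expect_error(simulate_reads(c(chr = "ACGTACGT"), cfg), "read length")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(snp_rate = 1.2), "snp_rate")
  expect_error(sim_config(sector_segment_lengths = list(A = -5L)), "positive")
  expect_error(
    sim_config(core_length = 1000, n_core_segments = 1,
               sector_segment_lengths = list(),
               repeat_family_specs = list(c(unit_length = 500,
                                            copy_number = 10))),
    "repeat content")
})

test_that("every planted gene lies inside exactly one sector segment", {
  sim <- simulate_trio(fixture_small_cfg(seed = 47))
  genes <- sim$truth$genes
  expect_gt(nrow(genes), 10)
  for (g in unique(genes$genome)) {
    gg <- genes[genes$genome == g, ]
    segs <- truth_sectors(sim$truth, g, origin = "segment")
    for (i in seq_len(nrow(gg))) {
      host <- segs[segs$start <= gg$start[i] & segs$end >= gg$end[i], ]
      expect_equal(nrow(host), 1L)
      expect_equal(host$sector, gg$sector[i])
    }
  }
  # annotation invariants: CDS within exon union per transcript
  ann <- sim$annotations$A
  cds <- annotation_intervals(ann, "CDS")
  exons <- annotation_intervals(ann, "exon")
  expect_equal(iv_total_bp(iv_subtract(cds, exons)), 0)
})

test_that("fixtures round-trip through the standard formats", {
  cfg <- only_core_cfg(seed = 48)
  sim <- simulate_trio(cfg)
  dir <- file.path(tempdir(), "fxrt")
  paths <- write_fixture(sim, dir)
  expect_equal(sum(grepl("_fasta$", names(paths))), 3L)
  expect_equal(sum(grepl("_gff3$", names(paths))), 3L)
  expect_equal(sum(grepl("_bed$", names(paths))), 3L)
  expect_true(file.exists(paths[["manifest"]]))
  # truth BED round trip
  bed <- read_bed(paths[["A_bed"]])
  tA <- truth_sectors(sim$truth, "A")
  expect_equal(bed$start, tA$start)
  expect_equal(bed$end, tA$end)
  expect_equal(bed$name, tA$sector)
  # FASTA round trip
  fa <- Biostrings::readDNAStringSet(paths[["A_fasta"]])
  expect_equal(as.character(fa[[1]]), sim$genomes$A[["chr1"]])
})
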