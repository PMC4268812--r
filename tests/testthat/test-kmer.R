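test_that("counting handles short reads, duplicates and strand symmetry", {
  set.seed(11)
  short <- rand_seq_chr(20)
  expect_equal(kmer_histogram(kmer_count(short, 21)),
               data.frame(multiplicity = numeric(0), n_kmers = numeric(0)))
  r <- rand_seq_chr(25)
  db <- kmer_count(c(r, r), 21)
  h <- kmer_histogram(db)
  expect_equal(h$multiplicity, 2)
  expect_equal(h$n_kmers, 5)
  # matches the enumeration oracle
  want <- oracle_kmer_counts(c(r, r), 21)
  expect_equal(sort(unname(kmer_lookup(db, names(want)))),
               sort(unname(as.numeric(want))))
  # a read and its reverse complement count as two copies of the read
  db_rc <- kmer_count(c(r, oracle_revcomp(r)), 21)
  expect_equal(kmer_histogram(db_rc), h)
  expect_error(kmer_count("ACGT", 4), "odd")
})

test_that("non-ACGT windows are skipped", {
  r <- paste0(rand_seq_chr(30), "N", rand_seq_chr(30))
  db <- kmer_count(r, 21)
  st <- .kmer_db_stats_cpp(db$ptr)
  expect_equal(st$total, 2 * (30 - 21 + 1))
})

test_that("histogram mass equals total counted windows", {
  set.seed(12)
  reads <- vapply(1:50, function(i) rand_seq_chr(60), "")
  db <- kmer_count(reads, 21)
  h <- kmer_histogram(db)
  expect_equal(sum(h$multiplicity * h$n_kmers), 50 * (60 - 21 + 1))
})

test_that("mode estimation ignores the error peak and reports no-signal", {
  h <- data.frame(multiplicity = c(1, 60, 120),
                  n_kmers = c(1e6, 5e5, 1e4))
  expect_equal(estimate_mode(h, 10), 60)
  expect_error(estimate_mode(data.frame(multiplicity = 5, n_kmers = 100), 10),
               "no signal")
  # ties break toward the smaller multiplicity
  h2 <- data.frame(multiplicity = c(40, 50), n_kmers = c(7, 7))
  expect_equal(estimate_mode(h2, 10), 40)
})

test_that("coverage profile equals brute-force window lookup", {
  set.seed(13)
  genome <- rand_seq_chr(200)
  starts <- sample.int(200 - 40, 60, replace = TRUE)
  reads <- substring(genome, starts, starts + 39)
  flip <- runif(60) < 0.5
  reads[flip] <- vapply(reads[flip], oracle_revcomp, "")
  db <- kmer_count(reads, 21)
  expect_equal(coverage_profile(genome, db), oracle_profile(genome, reads, 21))
  expect_equal(length(coverage_profile(genome, db)), 200 - 21 + 1)
  expect_equal(length(coverage_profile(rand_seq_chr(10), db)), 0)
})

test_that("a single substitution zeroes exactly k consecutive positions", {
  set.seed(14)
  cfg <- sim_config(seed = 14, read_depth = 50, read_length = 100)
  genome <- rand_seq_chr(2000)
  reads <- simulate_reads(c(chr = genome), cfg)
  db <- kmer_count(reads, 21)
  base <- coverage_profile(genome, db)
  expect_true(all(base > 0))
  v <- strsplit(genome, "", fixed = TRUE)[[1]]
  v[1000] <- setdiff(c("A", "C", "G", "T"), v[1000])[1]
  mut <- coverage_profile(paste(v, collapse = ""), db)
  zeros <- which(mut == 0)
  expect_equal(length(zeros), 21)
  expect_equal(zeros, (1000 - 21 + 1):1000)
})

test_that("profiles are invariant to reverse-complementing the reads", {
  set.seed(15)
  genome <- rand_seq_chr(300)
  starts <- sample.int(250, 40, replace = TRUE)
  reads <- substring(genome, starts, starts + 49)
  db1 <- kmer_count(reads, 21)
  db2 <- kmer_count(vapply(reads, oracle_revcomp, ""), 21)
  expect_equal(kmer_histogram(db1), kmer_histogram(db2))
  expect_equal(coverage_profile(genome, db1), coverage_profile(genome, db2))
})

test_that("mean region coverage follows the arithmetic definition", {
  expect_equal(mean_region_coverage(rep(7L, 10), 2, 8), 7)
  expect_equal(mean_region_coverage(c(0L, 0L, 100L, 100L), 0, 4), 50)
  expect_error(mean_region_coverage(1:10, 5, 5), "empty")
  set.seed(16)
  for (rep in 1:20) {
    p <- sample.int(50L, 30, replace = TRUE)
    s <- sample.int(25, 1); e <- s + sample.int(5, 1)
    expect_equal(mean_region_coverage(p, s, e), mean(p[(s + 1):e]))
  }
})

test_that("repeat classification uses a strict 100x boundary", {
  th <- kmer_thresholds()
  expect_equal(classify_repetitive(12210, th), "repetitive")
  expect_equal(classify_repetitive(50, th), "unique")
  expect_equal(classify_repetitive(100, th), "unique")
  expect_equal(classify_repetitive(100.001, th), "repetitive")
})

test_that("presence calling masks repetitive spikes", {
  th <- kmer_thresholds()
  expect_equal(call_presence(rep(100L, 500), th), "present")
  spiky <- rep(0L, 500)
  spiky[c(100:105, 300:305)] <- 5000L
  expect_equal(call_presence(spiky, th), "absent")
  half <- c(rep(50L, 250), rep(0L, 250))
  expect_equal(call_presence(half, th), "ambiguous")
  expect_equal(call_presence(rep(5000L, 100), th), "ambiguous")
  expect_error(call_presence(integer(0), th), "shorter than k")
})

test_that("database dump/load round trips and is deterministic", {
  set.seed(17)
  reads <- vapply(1:20, function(i) rand_seq_chr(50), "")
  db <- kmer_count(reads, 21)
  p1 <- tempfile(); p2 <- tempfile()
  kmer_db_dump(db, p1)
  kmer_db_dump(kmer_count(reads, 21), p2)
  expect_equal(tools::md5sum(p1)[[1]], tools::md5sum(p2)[[1]])
  back <- kmer_db_load(p1)
  expect_equal(kmer_histogram(back), kmer_histogram(db))
  g <- rand_seq_chr(100)
  expect_equal(coverage_profile(g, back), coverage_profile(g, db))
})

test_that("mode recovery tracks the analytic k-mer coverage expectation", {
  # expected k-mer coverage = depth * (1 - (k-1)/L) * (1 - e)^k
  depth <- 50; L <- 100; e <- 0.001; k <- 21
  expected <- depth * (1 - (k - 1) / L) * (1 - e)^k
  modes <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 600 + s, read_depth = depth, read_length = L,
                      read_error_rate = e)
    g <- c(chr = {set.seed(900 + s); rand_seq_chr(50000)})
    reads <- simulate_reads(g, cfg, seed = 600 + s)
    estimate_mode(kmer_histogram(kmer_count(reads, k)))
  }, 1.0)
  expect_true(all(abs(modes - expected) / expected <= 0.2))
})

test_that("bedgraph export collapses runs of equal coverage", {
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(list(chr = c(3L, 3L, 0L, 7L)), path)
  lines <- readLines(path)
  expect_equal(lines[-1], c("chr\t0\t2\t3", "chr\t2\t3\t0", "chr\t3\t4\t7"))
})
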