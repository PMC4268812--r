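#' Count canonical k-mers in a read set
#'
#' Every length-k window of every read is unified with its reverse
#' complement (the lexicographically smaller of the two encodings is kept)
#' and counted; windows containing non-ACGT characters are skipped. The
#' default k = 21 is long enough that a random 21-mer is not expected to
#' occur by chance in a genome of a few hundred Mbp, yet short enough to be
#' robust to sequencing errors.
#'
#' @param reads a `DNAStringSet`, character vector of read sequences, or
#'   path(s) to FASTA/FASTQ files (gzip allowed).
#' @param k odd k-mer length between 1 and 31 (default 21). Oddness makes
#'   the canonical form unique (no reverse-complement palindromes).
#' @return A `kmer_db` object (external hash table plus `k`).
#' @export
kmer_count <- function(reads, k = 21) {
  if (k %% 2 == 0) stop("k must be odd so canonical k-mers are unique")
  if (k < 1 || k > 31) stop("k must be in [1, 31]")
  reads <- as_read_characters(reads)
  db <- .kmer_count_cpp(reads, as.integer(k))
  structure(list(ptr = db, k = as.integer(k)), class = "kmer_db")
}

as_read_characters <- function(reads) {
  if (is.character(reads) && length(reads) > 0 &&
      all(file.exists(reads))) {
    seqs <- unlist(lapply(reads, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p)) "fastq" else "fasta"
      as.character(Biostrings::readDNAStringSet(p, format = fmt))
    }))
    return(unname(seqs))
  }
  if (inherits(reads, "DNAStringSet")) return(unname(as.character(reads)))
  as.character(reads)
}

#' Database size summary
#'
#' @param db a `kmer_db`.
#' @return List with `n_distinct` (distinct canonical k-mers) and `total`
#'   (total counted windows).
#' @export
kmer_db_stats <- function(db) {
  stopifnot(inherits(db, "kmer_db"))
  .kmer_db_stats_cpp(db$ptr)
}

#' @export
print.kmer_db <- function(x, ...) {
  st <- .kmer_db_stats_cpp(x$ptr)
  cat(sprintf("kmer_db: k=%d, %s distinct canonical k-mers, %s total\n",
              x$k, format(st$n_distinct, big.mark = ","),
              format(st$total, big.mark = ",")))
  invisible(x)
}

#' K-mer frequency histogram
#'
#' Tabulates, for each multiplicity m, the number of distinct canonical
#' k-mers observed exactly m times in the read sample.
#'
#' @param db a `kmer_db`.
#' @return Data frame with columns `multiplicity` and `n_kmers`, sorted by
#'   multiplicity.
#' @export
kmer_histogram <- function(db) {
  stopifnot(inherits(db, "kmer_db"))
  .kmer_histogram_cpp(db$ptr)
}

#' Estimate single-copy k-mer coverage from a histogram
#'
#' Returns the mode of the k-mer frequency histogram after excluding
#' erroneous low-multiplicity k-mers (counts below `error_cutoff`). The mode
#' of the distribution corresponds to the average k-mer coverage of
#' single-copy, non-repetitive sequence. Ties break toward the smaller
#' multiplicity.
#'
#' @param hist histogram data frame from [kmer_histogram()].
#' @param error_cutoff minimum multiplicity considered (default 10).
#' @return The modal multiplicity (integer).
#' @export
estimate_mode <- function(hist, error_cutoff = 10) {
  h <- hist[hist$multiplicity >= error_cutoff, , drop = FALSE]
  if (nrow(h) == 0)
    stop("no signal: histogram is empty at or above the error cutoff")
  h$multiplicity[which.max(h$n_kmers)]
}

#' K-mer coverage profile along a sequence
#'
#' For each start position i of a sequence, reports the read-sample count of
#' the canonical k-mer spanning [i, i + k). Positions whose window contains
#' an N (or any non-ACGT character) get value 0; the final k - 1 positions
#' of the sequence carry no value, so the profile has length
#' `nchar(sequence) - k + 1` (empty for sequences shorter than k).
#'
#' @param sequence a single character string or `DNAString`/`DNAStringSet`
#'   of length one.
#' @param db a `kmer_db` built from the read sample.
#' @return Integer vector of per-position counts.
#' @export
coverage_profile <- function(sequence, db) {
  stopifnot(inherits(db, "kmer_db"))
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1)
    sequence <- as.character(sequence[[1]])
  }
  sequence <- as.character(sequence)
  .coverage_profile_cpp(db$ptr, sequence, db$k)
}

#' Mean k-mer coverage over an interval
#'
#' Arithmetic mean of profile values whose k-mer start positions fall in
#' [start, end), zeros included. Start positions beyond the profile span
#' (the trailing k - 1 bases of the sequence) are excluded.
#'
#' @param profile integer vector from [coverage_profile()].
#' @param start,end 0-based half-open interval of start positions.
#' @return Mean coverage (double); 0 when no profile position falls in the
#'   interval.
#' @export
mean_region_coverage <- function(profile, start, end) {
  if (end <= start) stop("empty interval")
  lo <- max(0L, as.integer(start)) + 1L
  hi <- min(length(profile), as.integer(end))
  if (hi < lo) return(0)
  mean(profile[lo:hi])
}

#' Default k-mer thresholds
#'
#' Operating points for repeat classification and locus presence calling:
#' k-mers seen fewer than `error_cutoff` times are treated as sequencing
#' errors when estimating coverage modes; regions whose mean k-mer coverage
#' exceeds `repeat_threshold` are classified repetitive; presence calling
#' requires per-position coverage of at least `presence_self_min` in the
#' carrying genome and genome-specific region calling caps the cross-genome
#' mean below `presence_cross_max`.
#'
#' @param error_cutoff minimum multiplicity for mode estimation.
#' @param repeat_threshold fold coverage above which sequence is repetitive.
#' @param presence_self_min,presence_cross_max per-genome coverage bounds.
#' @return A list of thresholds.
#' @export
kmer_thresholds <- function(error_cutoff = 10, repeat_threshold = 100,
                            presence_self_min = 10, presence_cross_max = 10) {
  stopifnot(error_cutoff >= 1, repeat_threshold > presence_self_min)
  list(error_cutoff = error_cutoff, repeat_threshold = repeat_threshold,
       presence_self_min = presence_self_min,
       presence_cross_max = presence_cross_max)
}

#' Classify a region as unique or repetitive by mean k-mer coverage
#'
#' @param mean_cov mean k-mer coverage of the region.
#' @param thresholds from [kmer_thresholds()].
#' @return `"repetitive"` if strictly above the repeat threshold, else
#'   `"unique"`.
#' @export
classify_repetitive <- function(mean_cov, thresholds = kmer_thresholds()) {
  stopifnot(all(mean_cov >= 0))
  ifelse(mean_cov > thresholds$repeat_threshold, "repetitive", "unique")
}

#' Call presence/absence of a locus from its k-mer coverage profile
#'
#' Positions whose coverage exceeds the repeat threshold are masked (they
#' reflect high-copy repeats shared across genomes, not the locus itself).
#' Among the remaining positions, the locus is `present` when at least
#' `frac_present` of them are covered at `presence_self_min` or more,
#' `absent` when at most `frac_absent` are, and `ambiguous` otherwise
#' (including when every position is masked).
#'
#' @param profile integer coverage profile over the locus.
#' @param thresholds from [kmer_thresholds()].
#' @param frac_present,frac_absent calling fractions (defaults 0.8 / 0.2).
#' @return `"present"`, `"absent"` or `"ambiguous"`.
#' @export
call_presence <- function(profile, thresholds = kmer_thresholds(),
                          frac_present = 0.8, frac_absent = 0.2) {
  if (length(profile) < 1)
    stop("locus shorter than k: empty coverage profile")
  keep <- profile <= thresholds$repeat_threshold
  if (!any(keep)) return("ambiguous")
  frac <- mean(profile[keep] >= thresholds$presence_self_min)
  if (frac >= frac_present) "present"
  else if (frac <= frac_absent) "absent"
  else "ambiguous"
}

#' Dump and reload a k-mer database as TSV
#'
#' The dump is a two-column TSV (canonical k-mer string, count) sorted by
#' the packed k-mer encoding, with a `#k=<k>` header line; byte-identical
#' for identical databases.
#'
#' @param db a `kmer_db`.
#' @param path output (input) file path.
#' @return `kmer_db_dump`: `path` invisibly. `kmer_db_load`: a `kmer_db`.
#' @export
kmer_db_dump <- function(db, path) {
  df <- .kmer_db_dump_cpp(db$ptr, db$k)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d", db$k), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname kmer_db_dump
#' @export
kmer_db_load <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^#k=\\d+$", header)) stop("not a kmer_db dump: ", path)
  k <- as.integer(sub("^#k=", "", header))
  df <- utils::read.table(path, sep = "\t", skip = 1,
                          col.names = c("kmer", "count"),
                          colClasses = c("character", "numeric"))
  ptr <- .kmer_db_build_cpp(df$kmer, df$count, k)
  structure(list(ptr = ptr, k = k), class = "kmer_db")
}

#' Look up canonical counts for explicit k-mers (mainly for testing)
#'
#' @param db a `kmer_db`.
#' @param kmers character vector of length-k strings.
#' @return Numeric vector of counts (0 for unseen or non-ACGT k-mers).
#' @export
kmer_lookup <- function(db, kmers) {
  .kmer_lookup_cpp(db$ptr, kmers, db$k)
}

#' Export coverage profiles as BedGraph
#'
#' Adjacent positions with equal coverage are collapsed into one 0-based
#' half-open record.
#'
#' @param profiles named list of profiles (one per sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (nm in names(profiles)) {
    v <- profiles[[nm]]
    if (length(v) == 0) next
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    writeLines(sprintf("%s\t%d\t%d\t%d", nm, s, e, r$values), con)
  }
  invisible(path)
}
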