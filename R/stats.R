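#' N50 of a set of lengths
#'
#' The length at which the cumulative sum of descending-sorted lengths
#' first reaches half the total: at least half the total length lies in
#' pieces at least this long.
#'
#' @param lengths numeric vector of piece lengths.
#' @return The N50 length (0 for an empty set).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# contigs: scaffold pieces between runs of >= min_gap_run Ns
split_contigs <- function(seq, min_gap_run = 1) {
  pat <- sprintf("N{%d,}", min_gap_run)
  pieces <- strsplit(gsub(pat, "\n", seq), "\n", fixed = TRUE)[[1]]
  pieces[nchar(pieces) > 0]
}

#' Assembly summary statistics
#'
#' Span, non-N bases, scaffold and contig counts and N50s, and genome
#' coverage percentages against an assumed genome size. Contigs are
#' obtained by splitting scaffolds at runs of at least `min_gap_run` Ns;
#' contig count and N50 are reported over contigs longer than
#' `min_contig` bp. Coverage percentages are span (or bases) over the
#' assumed size, to one decimal, half-up.
#'
#' @param assembly a sequence set.
#' @param assumed_size assumed total genome size, bp (the reference rice
#'   genome convention is 389 Mbp).
#' @param min_gap_run minimum N run that splits a contig.
#' @param min_contig minimum contig length reported.
#' @return A list of statistics.
#' @export
assembly_stats <- function(assembly, assumed_size = 389e6, min_gap_run = 1,
                           min_contig = 1000) {
  if (assumed_size <= 0) stop("assumed genome size must be positive")
  assembly <- as_sequence_set(assembly)
  if (length(assembly) == 0) stop("empty assembly")
  span <- sum(as.numeric(nchar(assembly)))
  nN <- sum(vapply(assembly, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))), 1L))
  bases <- span - nN
  contigs <- unlist(lapply(assembly, split_contigs,
                           min_gap_run = min_gap_run))
  clen <- nchar(contigs)
  big <- clen[clen > min_contig]
  list(
    total_span = span,
    total_bases = bases,
    n_scaffolds = length(assembly),
    scaffold_n50 = n50(nchar(assembly)),
    max_scaffold = max(nchar(assembly)),
    n_contigs = length(big),
    contig_n50 = n50(big),
    max_contig = if (length(big)) max(big) else 0,
    coverage_span_pct = round_half_up(100 * span / assumed_size, 1),
    coverage_bases_pct = round_half_up(100 * bases / assumed_size, 1)
  )
}

#' Genome coverage percentage from totals
#'
#' @param total_bp assembled span or bases, bp.
#' @param assumed_size assumed genome size, bp.
#' @return Percentage to one decimal, half-up rounding.
#' @export
coverage_pct <- function(total_bp, assumed_size = 389e6) {
  if (assumed_size <= 0) stop("assumed genome size must be positive")
  round_half_up(100 * total_bp / assumed_size, 1)
}

#' Region-table summary (total bp, count, floor mean, sd, max)
#'
#' The mean region size is the integer floor of total/count, matching the
#' reporting convention of the package's specific-region tables; the
#' standard deviation is the population standard deviation of the region
#' lengths, rounded to an integer.
#'
#' @param set an `interval_set` (or a vector of region lengths via
#'   `lengths`).
#' @param profiles optional named list of coverage profiles; when given,
#'   the position-weighted mean k-mer coverage over all regions is
#'   reported.
#' @return List: `total_bp`, `regions`, `mean_size`, `sd_size`, `max_size`,
#'   and `mean_kmer_cov` (NA without profiles). All zero for an empty set.
#' @export
region_summary <- function(set, profiles = NULL) {
  set <- as_interval_set(set)
  if (nrow(set) == 0)
    return(list(total_bp = 0, regions = 0, mean_size = 0, sd_size = 0,
                max_size = 0, mean_kmer_cov = NA_real_))
  lens <- as.numeric(set$end - set$start)
  total <- sum(lens)
  n <- length(lens)
  cov <- NA_real_
  if (!is.null(profiles)) {
    vals <- unlist(lapply(seq_len(n), function(i) {
      p <- profiles[[set$seqname[i]]]
      lo <- set$start[i] + 1L
      hi <- min(length(p), set$end[i])
      if (hi < lo) numeric(0) else p[lo:hi]
    }))
    cov <- if (length(vals)) mean(vals) else NA_real_
  }
  list(total_bp = total, regions = n, mean_size = floor(total / n),
       sd_size = round(sqrt(mean((lens - mean(lens))^2))),
       max_size = max(lens), mean_kmer_cov = cov)
}

#' Floor-mean region size from printed totals
#'
#' @param total_bp total region bp.
#' @param count region count.
#' @return `floor(total_bp / count)`.
#' @export
floor_mean_size <- function(total_bp, count) {
  if (count <= 0) stop("count must be positive")
  floor(total_bp / count)
}
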