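#' @useDynLib pantrio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Construct a normalized genomic interval set
#'
#' An `interval_set` is a data frame of 0-based half-open intervals
#' (`seqname`, `start`, `end`), kept sorted with overlapping or touching
#' intervals merged. This is the base-set ("BED-like") representation used
#' throughout the package: two records covering the same bases are the same
#' set. Interval arithmetic is delegated to IRanges.
#'
#' @param seqname character vector of sequence names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @return An `interval_set` data frame with columns `seqname`, `start`, `end`.
#' @examples
#' interval_set("chr1", c(5L, 8L), c(10L, 12L))  # merges to [5,12)
#' @export
interval_set <- function(seqname = character(), start = integer(),
                         end = integer()) {
  if (length(seqname) == 1) seqname <- rep(seqname, length(start))
  if (length(start) != length(end) || length(seqname) != length(start))
    stop("seqname, start, end must have equal length")
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("negative interval start")
  if (any(start >= end)) stop("interval with start >= end")
  normalize_intervals(data.frame(seqname = as.character(seqname),
                                 start = start, end = end,
                                 stringsAsFactors = FALSE))
}

new_interval_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

empty_interval_set <- function() {
  new_interval_set(data.frame(seqname = character(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE))
}

#' Normalize raw intervals
#'
#' Sorts and coalesces overlapping or touching intervals per sequence.
#'
#' @param df data frame with columns `seqname`, `start`, `end` (0-based
#'   half-open).
#' @return An `interval_set`.
#' @export
normalize_intervals <- function(df) {
  stopifnot(all(c("seqname", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(empty_interval_set())
  if (any(df$start >= df$end)) stop("interval with start >= end")
  parts <- lapply(split(df, df$seqname), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(seqname = d$seqname[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$seqname, out$start), , drop = FALSE]
  new_interval_set(out)
}

as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) x else normalize_intervals(x)
}

iv_to_iranges <- function(set) {
  lapply(split(set, set$seqname),
         function(d) IRanges::IRanges(d$start + 1L, d$end))
}

iranges_to_iv <- function(lst) {
  keep <- vapply(lst, length, 1L) > 0L
  lst <- lst[keep]
  if (length(lst) == 0) return(empty_interval_set())
  out <- do.call(rbind, lapply(names(lst), function(nm) {
    r <- lst[[nm]]
    data.frame(seqname = nm, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$seqname, out$start), , drop = FALSE]
  new_interval_set(out)
}

iv_binop <- function(a, b, fun) {
  a <- as_interval_set(a)
  b <- as_interval_set(b)
  ra <- iv_to_iranges(a)
  rb <- iv_to_iranges(b)
  seqs <- union(names(ra), names(rb))
  res <- lapply(seqs, function(s) {
    fun(if (is.null(ra[[s]])) IRanges::IRanges() else ra[[s]],
        if (is.null(rb[[s]])) IRanges::IRanges() else rb[[s]])
  })
  names(res) <- seqs
  iranges_to_iv(res)
}

#' Interval set arithmetic
#'
#' Exact base-set union, intersection and difference of two interval sets.
#'
#' @param a,b `interval_set` objects (or coercible data frames).
#' @return An `interval_set`.
#' @export
iv_union <- function(a, b) iv_binop(a, b, IRanges::union)

#' @rdname iv_union
#' @export
iv_intersect <- function(a, b) iv_binop(a, b, IRanges::intersect)

#' @rdname iv_union
#' @export
iv_subtract <- function(a, b) iv_binop(a, b, IRanges::setdiff)

#' Complement of an interval set within sequence bounds
#'
#' @param set an `interval_set`.
#' @param seqlens named vector of sequence lengths (bp).
#' @return The `interval_set` of bases not covered by `set`.
#' @export
iv_complement <- function(set, seqlens) {
  full <- interval_set(names(seqlens), rep(0L, length(seqlens)),
                       as.integer(seqlens))
  iv_subtract(full, set)
}

#' Interval set summaries
#'
#' Total covered bases, number of intervals, and maximum interval length.
#'
#' @param set an `interval_set`.
#' @return An integer scalar (returned as double for large totals).
#' @export
iv_total_bp <- function(set) {
  set <- as_interval_set(set)
  if (nrow(set) == 0) return(0)
  sum(as.numeric(set$end - set$start))
}

#' @rdname iv_total_bp
#' @export
iv_count <- function(set) nrow(as_interval_set(set))

#' @rdname iv_total_bp
#' @export
iv_max_len <- function(set) {
  set <- as_interval_set(set)
  if (nrow(set) == 0) return(0)
  max(set$end - set$start)
}

#' Intersect an interval set with annotation categories
#'
#' Splits annotated gene structure into mutually exclusive base categories
#' with precedence CDS > 5' UTR > 3' UTR > non-coding exon > remaining mRNA,
#' then reports how many bases of `set` fall in each category.
#'
#' @param set an `interval_set`.
#' @param annotation an `annotation_set` (see [read_gff3()]).
#' @param exclusive if `FALSE`, report raw (overlapping) per-category
#'   intersections instead of the disjointified ones.
#' @return Named numeric vector of base counts for categories `cds`, `utr5`,
#'   `utr3`, `noncoding_exon`, `mrna_other`.
#' @export
annotate_overlap <- function(set, annotation, exclusive = TRUE) {
  set <- as_interval_set(set)
  cats <- list(
    cds = annotation_intervals(annotation, "CDS"),
    utr5 = annotation_intervals(annotation, "five_prime_UTR"),
    utr3 = annotation_intervals(annotation, "three_prime_UTR"),
    exon = annotation_intervals(annotation, "exon"),
    mrna = annotation_intervals(annotation, "mRNA")
  )
  # non-coding exon = exon minus CDS/UTRs; mRNA-other = mRNA minus exons
  if (exclusive) {
    seen <- cats$cds
    out <- c(cds = iv_total_bp(iv_intersect(set, cats$cds)))
    for (nm in c("utr5", "utr3")) {
      part <- iv_subtract(cats[[nm]], seen)
      out[nm] <- iv_total_bp(iv_intersect(set, part))
      seen <- iv_union(seen, cats[[nm]])
    }
    nce <- iv_subtract(cats$exon, seen)
    out["noncoding_exon"] <- iv_total_bp(iv_intersect(set, nce))
    seen <- iv_union(seen, cats$exon)
    out["mrna_other"] <- iv_total_bp(iv_intersect(set, iv_subtract(cats$mrna, seen)))
  } else {
    out <- c(cds = iv_total_bp(iv_intersect(set, cats$cds)),
             utr5 = iv_total_bp(iv_intersect(set, cats$utr5)),
             utr3 = iv_total_bp(iv_intersect(set, cats$utr3)),
             noncoding_exon = iv_total_bp(iv_intersect(set, cats$exon)),
             mrna_other = iv_total_bp(iv_intersect(set, cats$mrna)))
  }
  out
}

#' Keep intervals overlapping annotated genes by a minimum amount
#'
#' Retains (whole) intervals whose overlap with the union of annotated gene
#' spans is at least `min_bp`.
#'
#' @param set an `interval_set`.
#' @param annotation an `annotation_set`, or an `interval_set` of gene spans.
#' @param min_bp minimum overlap in bases (default 100).
#' @return The filtered `interval_set`.
#' @export
min_overlap_filter <- function(set, annotation, min_bp = 100) {
  set <- as_interval_set(set)
  genes <- if (inherits(annotation, "interval_set")) annotation
           else gene_spans(annotation)
  if (nrow(set) == 0 || nrow(genes) == 0) return(empty_interval_set())
  ov <- numeric(nrow(set))
  for (s in unique(set$seqname)) {
    qi <- which(set$seqname == s)
    g <- genes[genes$seqname == s, , drop = FALSE]
    if (nrow(g) == 0) next
    rq <- IRanges::IRanges(set$start[qi] + 1L, set$end[qi])
    rg <- IRanges::IRanges(g$start + 1L, g$end)
    hits <- IRanges::findOverlaps(rq, rg)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      rq[S4Vectors::queryHits(hits)], rg[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[qi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  new_interval_set(set[ov >= min_bp, , drop = FALSE])
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open; these functions read the first three columns
#' (plus the name column when present) and write BED3/BED6.
#'
#' @param path file path.
#' @return `read_bed`: a data frame with `seqname`, `start`, `end` and, when
#'   present, `name`; coordinates 0-based half-open.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("seqname", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[, seq_len(min(ncol(df), 4)), drop = FALSE]
}

#' @rdname read_bed
#' @param df data frame with `seqname`, `start`, `end`, optionally `name`.
#' @export
write_bed <- function(df, path) {
  out <- df[, c("seqname", "start", "end")]
  if (!is.null(df$name)) {
    out$name <- df$name
    out$score <- 0L
    out$strand <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
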