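# Independent brute-force oracles. These deliberately share no code with the
# package internals: string enumeration instead of packed hashing, per-base
# bitmaps instead of IRanges, exhaustive subset search instead of
# branch-and-bound.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# all length-k windows of a string, NA for windows containing non-ACGT
oracle_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1), k:n)
  w[grepl("[^ACGT]", w)] <- NA
  w
}

# canonical k-mer count table from reads, by enumeration
oracle_kmer_counts <- function(reads, k) {
  w <- unlist(lapply(reads, oracle_windows, k = k))
  w <- w[!is.na(w)]
  if (length(w) == 0) return(table(character(0)))
  table(vapply(w, oracle_canonical, ""))
}

# per-position profile of seq against a read set, by window lookup
oracle_profile <- function(seq, reads, k) {
  counts <- oracle_kmer_counts(reads, k)
  w <- oracle_windows(seq, k)
  vapply(w, function(x) {
    if (is.na(x)) return(0L)
    cx <- oracle_canonical(x)
    if (cx %in% names(counts)) as.integer(counts[[cx]]) else 0L
  }, 1L, USE.NAMES = FALSE)
}

# exhaustive maximal exact matches >= min_match, unique in ref (forward
# strand substring occurs exactly once in ref). 0-based starts.
oracle_anchors <- function(ref, qry, min_match, unique_ref = TRUE) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(qry, "", fixed = TRUE)[[1]]
  rn <- length(rc); qn <- length(qc)
  valid_r <- rc %in% c("A", "C", "G", "T")
  valid_q <- qc %in% c("A", "C", "G", "T")
  M <- outer(seq_len(rn), seq_len(qn),
             function(i, j) rc[i] == qc[j] & valid_r[i] & valid_q[j])
  L <- matrix(0L, rn + 1, qn + 1)
  for (i in rn:1)
    L[i, 1:qn] <- ifelse(M[i, ], L[i + 1, 2:(qn + 1)] + 1L, 0L)
  out <- list()
  for (i in seq_len(rn)) for (j in seq_len(qn)) {
    if (!M[i, j]) next
    if (i > 1 && j > 1 && M[i - 1, j - 1]) next  # not leftmost
    len <- L[i, j]
    if (len < min_match) next
    if (unique_ref) {
      s <- substring(ref, i, i + len - 1)
      occ <- sum(substring(ref, 1:(rn - len + 1),
                           len:rn) == s)
      if (occ > 1) next
    }
    out[[length(out) + 1]] <- data.frame(ref_start = i - 1L,
                                         qry_start = j - 1L, length = len)
  }
  if (length(out) == 0)
    return(data.frame(ref_start = integer(), qry_start = integer(),
                      length = integer()))
  d <- do.call(rbind, out)
  d[order(d$ref_start, d$qry_start), , drop = FALSE]
}

# per-base bitmap interval algebra on one sequence
oracle_bitmap <- function(df, n) {
  v <- logical(n)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

bitmap_to_intervals <- function(v) {
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- c(0L, e[-length(e)])
  data.frame(start = s[r$values], end = e[r$values])
}

# exhaustive maximum-weight mutually consistent subset of blocks
oracle_one_to_one_weight <- function(blocks) {
  n <- nrow(blocks)
  stopifnot(n <= 14)
  conflicts <- function(i, j) {
    (blocks$ref_seq[i] == blocks$ref_seq[j] &&
       blocks$ref_start[i] < blocks$ref_end[j] &&
       blocks$ref_start[j] < blocks$ref_end[i]) ||
      (blocks$qry_seq[i] == blocks$qry_seq[j] &&
         blocks$qry_start[i] < blocks$qry_end[j] &&
         blocks$qry_start[j] < blocks$qry_end[i])
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (a in seq_along(sel)) {
        for (b in seq_len(a - 1)) {
          if (conflicts(sel[a], sel[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(blocks$matches[sel]))
  }
  best
}

rand_seq_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random query derived from ref by sparse substitution, guaranteeing
# shared anchors
mutated_copy <- function(ref, n_snps) {
  v <- strsplit(ref, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(v), n_snps)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
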