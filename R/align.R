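#' Aligner configuration
#'
#' Parameters of the anchor-based whole-genome aligner. Defaults mirror the
#' sensitive settings commonly used for cross-variety plant genome
#' comparisons: anchors of at least 30 bp, clusters retained from 65 bp of
#' summed anchor length, a diagonal-drift band factor of 5, and a 90 bp
#' cluster gap bound.
#'
#' @param min_match minimum anchor (maximal exact match) length, bp.
#' @param min_cluster minimum summed anchor length per cluster, bp.
#' @param diag_band band factor: anchors chain when their diagonal drift is
#'   at most `diag_band` times the gap between them.
#' @param max_gap maximum gap between chained anchors, bp.
#' @param small_indel_cutoff indel events of at most this size count with
#'   substitutions as "SNPs and small indels"; larger events are reported
#'   individually.
#' @param relocation_gap distance beyond which in-order adjacent blocks on
#'   the same reference sequence count as relocated, bp.
#' @param min_ext_ident minimum local identity while extending block ends.
#' @param max_dp_gap safety bound on gap sizes closed by dynamic
#'   programming; a larger gap splits the block instead.
#' @param unique_ref require anchors to be unique in the reference (their
#'   matched reference substring occurs exactly once on the reference
#'   forward strand); set `FALSE` for maximal-match mode.
#' @return A list of aligner settings.
#' @export
aligner_config <- function(min_match = 30, min_cluster = 65, diag_band = 5,
                           max_gap = 90, small_indel_cutoff = 5,
                           relocation_gap = 10000, min_ext_ident = 0.65,
                           max_dp_gap = 2000, unique_ref = TRUE) {
  stopifnot(min_match > 0, min_cluster > 0, diag_band > 0, max_gap > 0,
            small_indel_cutoff > 0, relocation_gap > small_indel_cutoff)
  list(min_match = min_match, min_cluster = min_cluster,
       diag_band = diag_band, max_gap = max_gap,
       small_indel_cutoff = small_indel_cutoff,
       relocation_gap = relocation_gap, min_ext_ident = min_ext_ident,
       max_dp_gap = max_dp_gap, unique_ref = unique_ref)
}

as_sequence_set <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)) || any(names(x) == ""))
    stop("a sequence set must be a named character vector or DNAStringSet")
  x
}

seq_lengths <- function(x) {
  x <- as_sequence_set(x)
  vapply(x, nchar, 1L)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find maximal exact match anchors between two sequence sets
#'
#' Reports, for every (reference sequence, query sequence, strand) triple,
#' all maximal exact matches of length at least `min_match` that are unique
#' in the reference. Matches cannot be extended on either side and never
#' span non-ACGT characters. For minus-strand anchors, `qry_start` is given
#' on the reverse-complemented query; `qry_start_fwd`/`qry_end_fwd` give the
#' forward-strand interval.
#'
#' @param ref,qry sequence sets (named character vectors or
#'   `DNAStringSet`s).
#' @param config from [aligner_config()].
#' @return Data frame with columns `ref_seq`, `ref_start`, `qry_seq`,
#'   `qry_start`, `length`, `strand`, `qry_start_fwd`, `qry_end_fwd`
#'   (0-based half-open).
#' @export
find_anchors <- function(ref, qry, config = aligner_config()) {
  ref <- as_sequence_set(ref)
  qry <- as_sequence_set(qry)
  out <- list()
  for (rn in names(ref)) {
    for (qn in names(qry)) {
      qfwd <- qry[[qn]]
      qlen <- nchar(qfwd)
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") qfwd else revcomp(qfwd)
        a <- .find_anchors_cpp(ref[[rn]], qs, config$min_match,
                               config$unique_ref)
        if (nrow(a) == 0) next
        fwd_start <- if (strand == "+") a$qry_start
                     else qlen - (a$qry_start + a$length)
        out[[length(out) + 1]] <- data.frame(
          ref_seq = rn, ref_start = a$ref_start,
          qry_seq = qn, qry_start = a$qry_start, length = a$length,
          strand = strand, qry_start_fwd = fwd_start,
          qry_end_fwd = fwd_start + a$length, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(ref_seq = character(), ref_start = integer(),
                      qry_seq = character(), qry_start = integer(),
                      length = integer(), strand = character(),
                      qry_start_fwd = integer(), qry_end_fwd = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Chain anchors of one (ref_seq, qry_seq, strand) triple into clusters.
# Returns the anchors (possibly trimmed to remove small overlaps) with a
# cluster id column; clusters under min_cluster summed anchor length are
# dropped.
chain_one_triple <- function(a, config) {
  a <- a[order(a$ref_start, a$qry_start), , drop = FALSE]
  n <- nrow(a)
  cluster <- integer(n)
  # active clusters: list of (tail_re, tail_qe, id)
  act_re <- integer(0); act_qe <- integer(0); act_id <- integer(0)
  next_id <- 1L
  rs <- a$ref_start; qs <- a$qry_start; len <- a$length
  for (i in seq_len(n)) {
    keep <- act_re >= rs[i] - config$max_gap
    act_re <- act_re[keep]; act_qe <- act_qe[keep]; act_id <- act_id[keep]
    assigned <- FALSE
    for (j in rev(seq_along(act_id))) {
      rgap <- rs[i] - act_re[j]
      qgap <- qs[i] - act_qe[j]
      t <- max(0L, -rgap, -qgap)
      if (t >= len[i]) next
      rg <- rgap + t; qg <- qgap + t
      g <- max(rg, qg)
      if (g <= config$max_gap && abs(rg - qg) <= config$diag_band * max(g, 1)) {
        rs[i] <- rs[i] + t; qs[i] <- qs[i] + t; len[i] <- len[i] - t
        cluster[i] <- act_id[j]
        act_re[j] <- rs[i] + len[i]; act_qe[j] <- qs[i] + len[i]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      cluster[i] <- next_id
      act_re <- c(act_re, rs[i] + len[i])
      act_qe <- c(act_qe, qs[i] + len[i])
      act_id <- c(act_id, next_id)
      next_id <- next_id + 1L
    }
  }
  a$ref_start <- rs; a$qry_start <- qs; a$length <- len
  a$cluster <- cluster
  tot <- tapply(a$length, a$cluster, sum)
  good <- as.integer(names(tot)[tot >= config$min_cluster])
  a <- a[a$cluster %in% good, , drop = FALSE]
  a[order(a$cluster, a$ref_start), , drop = FALSE]
}

#' Cluster anchors into chains
#'
#' Anchors (from one reference/query sequence pair and strand) are chained
#' greedily in reference order when the gap to a cluster tail is at most
#' `max_gap` on both axes and the diagonal drift is at most
#' `diag_band * gap`; small anchor overlaps are resolved by trimming the
#' later anchor. Clusters whose summed anchor length is below `min_cluster`
#' are discarded.
#'
#' @param anchors data frame from [find_anchors()].
#' @param config from [aligner_config()].
#' @return The anchors with a `cluster` column, sorted by cluster and
#'   reference start.
#' @export
cluster_anchors <- function(anchors, config = aligner_config()) {
  if (nrow(anchors) == 0) {
    anchors$cluster <- integer(0)
    return(anchors)
  }
  key <- paste(anchors$ref_seq, anchors$qry_seq, anchors$strand)
  parts <- lapply(split(anchors, key), chain_one_triple, config = config)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Extend anchor clusters into alignment blocks
#'
#' Gaps between chained anchors are closed by global alignment with unit
#' mismatch/indel costs; block ends are extended while local identity stays
#' above `min_ext_ident`. Substitutions, small indel events (size at most
#' `small_indel_cutoff`) and large indel events are recorded per block. A
#' gap exceeding `max_dp_gap`, or an anchor inconsistent with its
#' predecessor, splits the block at that gap.
#'
#' @param clustered anchors with a `cluster` column from
#'   [cluster_anchors()].
#' @param ref,qry the sequence sets the anchors were computed from.
#' @param config from [aligner_config()].
#' @return A list with `blocks` (data frame: coordinates 0-based half-open,
#'   query interval on the forward strand, `identity`, `cols`, `matches`,
#'   `subs`, `small_indels`) and `large_indels` (data frame `block`, `size`;
#'   `block` indexes rows of `blocks`).
#' @export
extend_clusters <- function(clustered, ref, qry, config = aligner_config()) {
  ref <- as_sequence_set(ref)
  qry <- as_sequence_set(qry)
  blocks <- list()
  larges <- list()
  nblocks <- 0L
  key <- paste(clustered$ref_seq, clustered$qry_seq, clustered$strand)
  for (k in unique(key)) {
    a <- clustered[key == k, , drop = FALSE]
    rn <- a$ref_seq[1]; qn <- a$qry_seq[1]; strand <- a$strand[1]
    qfwd <- qry[[qn]]
    qlen <- nchar(qfwd)
    qseq <- if (strand == "+") qfwd else revcomp(qfwd)
    res <- .extend_clusters_cpp(ref[[rn]], qseq,
                                as.integer(a$ref_start),
                                as.integer(a$qry_start),
                                as.integer(a$length),
                                as.integer(a$cluster),
                                as.integer(config$small_indel_cutoff),
                                as.integer(config$max_dp_gap),
                                config$min_ext_ident)
    b <- res$blocks
    li <- res$large_indels
    fwd_start <- if (strand == "+") b$qry_start else qlen - b$qry_end
    fwd_end <- if (strand == "+") b$qry_end else qlen - b$qry_start
    blocks[[length(blocks) + 1]] <- data.frame(
      ref_seq = rn, ref_start = b$ref_start, ref_end = b$ref_end,
      qry_seq = qn, qry_start = fwd_start, qry_end = fwd_end,
      strand = strand, identity = b$matches / b$cols, cols = b$cols,
      matches = b$matches, subs = b$subs, small_indels = b$small_indels,
      stringsAsFactors = FALSE)
    if (nrow(li) > 0) {
      li$block <- li$block + 1L + nblocks
      larges[[length(larges) + 1]] <- li
    }
    nblocks <- nblocks + nrow(b)
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(ref_seq = character(), ref_start = integer(),
               ref_end = integer(), qry_seq = character(),
               qry_start = integer(), qry_end = integer(),
               strand = character(), identity = numeric(), cols = numeric(),
               matches = numeric(), subs = numeric(),
               small_indels = integer(), stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  larges <- if (length(larges)) do.call(rbind, larges) else
    data.frame(block = integer(), size = integer())
  rownames(larges) <- NULL
  list(blocks = blocks, large_indels = larges)
}

#' Align two genomes
#'
#' Runs anchor finding, clustering and extension for every sequence pair
#' and strand, producing the full (repeat-inclusive) alignment block set.
#'
#' @param ref,qry sequence sets.
#' @param config from [aligner_config()].
#' @return As [extend_clusters()].
#' @export
align_genomes <- function(ref, qry, config = aligner_config()) {
  anchors <- find_anchors(ref, qry, config)
  clustered <- cluster_anchors(anchors, config)
  if (nrow(clustered) == 0)
    return(extend_clusters(clustered, ref, qry, config))
  extend_clusters(clustered, ref, qry, config)
}

# exact maximum-weight independent set by branch and bound; conflict is a
# logical adjacency matrix, weights positive
mwis_exact <- function(conflict, w) {
  n <- length(w)
  ord <- order(w, decreasing = TRUE)
  conflict <- conflict[ord, ord, drop = FALSE]
  w <- w[ord]
  suffix <- rev(cumsum(rev(w)))
  best <- list(weight = -1, sel = logical(n))
  sel <- logical(n)
  recurse <- function(i, cur, alive) {
    if (cur + sum(w[alive & seq_len(n) >= i]) <= best$weight) return()
    if (i > n) {
      if (cur > best$weight) best <<- list(weight = cur, sel = sel)
      return()
    }
    if (!alive[i]) { recurse(i + 1, cur, alive); return() }
    # take i
    sel[i] <<- TRUE
    alive2 <- alive & !conflict[i, ]
    alive2[i] <- FALSE
    recurse(i + 1, cur + w[i], alive2)
    sel[i] <<- FALSE
    # skip i
    alive[i] <- FALSE
    recurse(i + 1, cur, alive)
  }
  recurse(1, 0, rep(TRUE, n))
  keep <- logical(n)
  keep[ord] <- best$sel
  keep
}

#' Filter alignment blocks to a one-to-one set
#'
#' Selects a maximum-weight subset of blocks that is mutually consistent:
#' no two kept blocks overlap in reference coordinates or in query
#' coordinates. Block weight is alignment length times identity (the number
#' of matched columns), so long, accurate alignments win over repetitive
#' alternatives. Conflict components of up to 20 blocks are solved exactly;
#' larger components fall back to a greedy sweep by weight.
#'
#' @param blocks data frame of blocks, or the list from [align_genomes()]
#'   (in which case the large-indel table is subset and re-indexed too).
#' @return The retained rows of `blocks` (or the filtered list).
#' @export
filter_one_to_one <- function(blocks) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    keep <- filter_one_to_one_idx(blocks$blocks)
    li <- blocks$large_indels
    li <- li[li$block %in% keep, , drop = FALSE]
    li$block <- match(li$block, keep)
    return(list(blocks = blocks$blocks[keep, , drop = FALSE],
                large_indels = li))
  }
  blocks[filter_one_to_one_idx(blocks), , drop = FALSE]
}

filter_one_to_one_idx <- function(blocks) {
  n <- nrow(blocks)
  if (n <= 1) return(seq_len(n))
  conflict <- matrix(FALSE, n, n)
  edge_overlaps <- function(seqs, starts, ends) {
    for (s in unique(seqs)) {
      idx <- which(seqs == s)
      if (length(idx) < 2) next
      r <- IRanges::IRanges(starts[idx] + 1L, ends[idx])
      h <- IRanges::findOverlaps(r, r)
      qi <- idx[S4Vectors::queryHits(h)]
      si <- idx[S4Vectors::subjectHits(h)]
      keep <- qi != si
      conflict[cbind(qi[keep], si[keep])] <<- TRUE
    }
  }
  edge_overlaps(blocks$ref_seq, blocks$ref_start, blocks$ref_end)
  edge_overlaps(blocks$qry_seq, blocks$qry_start, blocks$qry_end)
  w <- blocks$matches
  # connected components
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(conflict[i, ])
      if (length(nb)) {
        m <- min(comp[i], comp[nb])
        if (any(c(comp[i], comp[nb]) != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- logical(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    if (length(idx) <= 20) {
      keep[idx] <- mwis_exact(conflict[idx, idx, drop = FALSE], w[idx])
    } else {
      ord <- idx[order(w[idx], decreasing = TRUE)]
      taken <- integer(0)
      for (i in ord) {
        if (!any(conflict[i, taken])) taken <- c(taken, i)
      }
      keep[taken] <- TRUE
    }
  }
  which(keep)
}

#' Summarize the differences implied by one-to-one alignments
#'
#' Walks blocks in query order, classifying adjacent pairs: a strand change
#' is an inversion; a change of reference sequence is a translocation;
#' blocks on the same reference that are out of order, or in order but
#' separated by more than `relocation_gap`, are relocations. Substitutions
#' plus indel events of at most `small_indel_cutoff` bases form the "SNPs
#' and small indels" count; larger indel events are counted individually.
#'
#' @param aligned list from [align_genomes()] (after filtering its `blocks`
#'   with [filter_one_to_one()]), or a blocks data frame.
#' @param large_indels the large-indel event table matching `aligned` rows
#'   (needed only when `aligned` is a bare data frame).
#' @param ref,qry the aligned sequence sets (for unaligned fractions).
#' @param config from [aligner_config()].
#' @return A list: `unaligned_ref_frac`, `unaligned_qry_frac`,
#'   `avg_identity`, `snps_small_indels`, `indels_gt_cutoff`, `inversions`,
#'   `relocations`, `translocations`.
#' @export
summarize_diff <- function(aligned, ref, qry, config = aligner_config(),
                           large_indels = NULL) {
  if (is.list(aligned) && !is.data.frame(aligned)) {
    blocks <- aligned$blocks
    large_indels <- aligned$large_indels
  } else {
    blocks <- aligned
    if (is.null(large_indels))
      large_indels <- data.frame(block = integer(), size = integer())
  }
  rlen <- seq_lengths(ref)
  qlen <- seq_lengths(qry)
  if (nrow(blocks) == 0) {
    return(list(unaligned_ref_frac = 1, unaligned_qry_frac = 1,
                avg_identity = 0, snps_small_indels = 0,
                indels_gt_cutoff = 0, inversions = 0, relocations = 0,
                translocations = 0))
  }
  ref_cov <- iv_total_bp(normalize_intervals(data.frame(
    seqname = blocks$ref_seq, start = blocks$ref_start,
    end = blocks$ref_end)))
  qry_cov <- iv_total_bp(normalize_intervals(data.frame(
    seqname = blocks$qry_seq, start = blocks$qry_start,
    end = blocks$qry_end)))
  inv <- reloc <- transl <- 0L
  b <- blocks[order(blocks$qry_seq, blocks$qry_start), , drop = FALSE]
  if (nrow(b) > 1) {
    for (i in seq_len(nrow(b) - 1)) {
      x <- b[i, ]; y <- b[i + 1, ]
      if (x$qry_seq != y$qry_seq) next
      if (x$strand != y$strand) { inv <- inv + 1L; next }
      if (x$ref_seq != y$ref_seq) { transl <- transl + 1L; next }
      gap <- if (x$strand == "+") y$ref_start - x$ref_end
             else x$ref_start - y$ref_end
      if (gap < 0 || gap > config$relocation_gap) reloc <- reloc + 1L
    }
  }
  list(
    unaligned_ref_frac = 1 - ref_cov / sum(as.numeric(rlen)),
    unaligned_qry_frac = 1 - qry_cov / sum(as.numeric(qlen)),
    avg_identity = sum(blocks$matches) / sum(blocks$cols),
    snps_small_indels = sum(blocks$subs) + sum(blocks$small_indels),
    indels_gt_cutoff = nrow(large_indels),
    inversions = inv, relocations = reloc, translocations = transl
  )
}

#' Regions of a genome not covered by any alignment
#'
#' Complement, per sequence of the chosen side, of the union of aligned
#' intervals. Pass the pre-filter (repeat-inclusive) block set to obtain
#' candidate novel sequence rather than copy-number differences.
#'
#' @param target the sequence set whose unaligned regions are wanted.
#' @param blocks alignment blocks (data frame, or list from
#'   [align_genomes()]).
#' @param side which side of the alignment `target` is: `"ref"` or `"qry"`.
#' @return An `interval_set` on `target`.
#' @export
unaligned_regions <- function(target, blocks, side = c("ref", "qry")) {
  side <- match.arg(side)
  if (is.list(blocks) && !is.data.frame(blocks)) blocks <- blocks$blocks
  lens <- seq_lengths(target)
  if (nrow(blocks) == 0) return(iv_complement(empty_interval_set(), lens))
  cols <- if (side == "ref") c("ref_seq", "ref_start", "ref_end")
          else c("qry_seq", "qry_start", "qry_end")
  cov <- normalize_intervals(stats::setNames(
    blocks[, cols], c("seqname", "start", "end")))
  iv_complement(cov, lens)
}

#' Export alignment blocks as TSV
#'
#' @param aligned list from [align_genomes()] or a blocks data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(aligned, path) {
  blocks <- if (is.data.frame(aligned)) aligned else aligned$blocks
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
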