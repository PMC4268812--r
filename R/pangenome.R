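#' Classify every base of a genome into Venn sectors
#'
#' Given the regions of a focal genome unaligned to each of the two other
#' genomes, derives the four sectors touching the focal genome by set
#' algebra: specific = unaligned to both; shared with one other = unaligned
#' to the second only; core = aligned to both. The four interval sets
#' partition the genome exactly.
#'
#' @param genome the focal sequence set (for sequence lengths), or a named
#'   vector of sequence lengths.
#' @param unaligned1,unaligned2 `interval_set`s of focal-genome regions with
#'   no alignment to other genome 1 / 2 (repeat-inclusive alignments).
#' @param names character vector `c(focal, other1, other2)` used to label
#'   sectors (single letters taken from the first character of each name).
#' @return A `sector_labeling`: list of `interval_set`s named by sector
#'   (e.g. `A`, `AB`, `AC`, `ABC` for focal A), plus attributes `focal` and
#'   `letters`.
#' @export
classify_bases <- function(genome, unaligned1, unaligned2,
                           names = c("A", "B", "C")) {
  lens <- if (is.numeric(genome)) genome else seq_lengths(genome)
  bounds_ok <- function(u) {
    all(u$end <= lens[u$seqname]) && all(u$seqname %in% names(lens))
  }
  if (!bounds_ok(unaligned1) || !bounds_ok(unaligned2))
    stop("unaligned intervals extend beyond genome bounds")
  l <- substr(names, 1, 1)
  specific <- iv_intersect(unaligned1, unaligned2)
  core <- iv_complement(iv_union(unaligned1, unaligned2), lens)
  with1 <- iv_subtract(unaligned2, unaligned1)  # aligned to 1, not to 2
  with2 <- iv_subtract(unaligned1, unaligned2)
  out <- stats::setNames(
    list(specific, with1, with2, core),
    c(l[1], paste0(l[1], l[2]), paste0(l[1], l[3]),
      paste0(l[1], l[2], l[3])))
  attr(out, "focal") <- names[1]
  attr(out, "letters") <- l
  attr(out, "seqlens") <- lens
  class(out) <- "sector_labeling"
  out
}

# canonical 7-sector names for a letter triple, in reporting order
venn_sector_names <- function(l) {
  c(paste0(l[1], l[2], l[3]), paste0(l[1], l[2]), paste0(l[1], l[3]),
    paste0(l[2], l[3]), l[1], l[2], l[3])
}

# sort the letters of a sector tag into canonical order
canon_sector <- function(tag, l) {
  vapply(strsplit(tag, ""), function(ch)
    paste(l[sort(match(ch, l))], collapse = ""), character(1))
}

#' Seven-sector Venn summary of a trio
#'
#' Combines the three per-genome labelings into the seven sectors of the
#' three-way Venn diagram, reporting for each sector the total bp, the
#' exonic bp, and the gene count. Shared sectors are measurable in several
#' genomes; the reported value comes from the first genome (in the order
#' given) that touches the sector, and per-genome values are kept in the
#' `per_genome` attribute.
#'
#' @param labelings list of three `sector_labeling`s, in reporting
#'   precedence order.
#' @param annotations list of three `annotation_set`s (same order).
#' @param assignments list of three gene-sector assignment data frames from
#'   [assign_gene_sectors()]; may be `NULL` to skip gene counts.
#' @return Data frame with columns `sector`, `bp`, `exonic_bp`, `genes`.
#' @export
venn_summary <- function(labelings, annotations, assignments = NULL) {
  l <- attr(labelings[[1]], "letters")
  sectors <- venn_sector_names(l)
  out <- data.frame(sector = sectors, bp = NA_real_, exonic_bp = NA_real_,
                    genes = NA_real_, stringsAsFactors = FALSE)
  for (gi in seq_along(labelings)) {
    lab <- labelings[[gi]]
    exons <- annotation_intervals(annotations[[gi]], "exon")
    for (tag in names(lab)) {
      sector <- canon_sector(tag, attr(labelings[[1]], "letters"))
      row <- match(sector, out$sector)
      if (!is.na(out$bp[row])) next  # earlier genome takes precedence
      out$bp[row] <- iv_total_bp(lab[[tag]])
      out$exonic_bp[row] <- iv_total_bp(iv_intersect(lab[[tag]], exons))
      if (!is.null(assignments)) {
        a <- assignments[[gi]]
        out$genes[row] <- sum(canon_sector(a$sector, l) == sector)
      }
    }
  }
  out
}

#' Specific-region calling criteria
#'
#' A genome-specific region must be at least `min_length` bp, have mean
#' k-mer coverage from the genome's own reads within `self_cov_range`
#' (below: likely assembly error; above: repetitive), and mean coverage
#' below `cross_cov_max` from each of the other two genomes' reads.
#'
#' @param min_length minimum region length, bp.
#' @param self_cov_range inclusive `[low, high]` self-coverage bounds.
#' @param cross_cov_max exclusive upper bound on cross-genome coverage.
#' @return A criteria list.
#' @export
specific_region_criteria <- function(min_length = 100,
                                     self_cov_range = c(10, 100),
                                     cross_cov_max = 10) {
  stopifnot(min_length > 0, self_cov_range[1] <= self_cov_range[2])
  list(min_length = min_length, self_cov_range = self_cov_range,
       cross_cov_max = cross_cov_max)
}

region_means <- function(set, profiles) {
  vapply(seq_len(nrow(set)), function(i) {
    p <- profiles[[set$seqname[i]]]
    if (is.null(p)) stop("missing coverage profile for sequence ",
                         set$seqname[i])
    mean_region_coverage(p, set$start[i], set$end[i])
  }, 1.0)
}

#' Call genome-specific non-repetitive regions
#'
#' Takes the maximal runs of the focal genome's specific sector and keeps
#' those satisfying the length and k-mer coverage criteria: long enough,
#' single-copy by the genome's own reads, and absent from the other two
#' genomes' reads. Coverage is evaluated per region as a whole, over k-mer
#' start positions.
#'
#' @param labeling a `sector_labeling` of the focal genome.
#' @param self_profiles named list (by sequence) of coverage profiles from
#'   the focal genome's reads.
#' @param cross_profiles list of two such profile lists, from the other two
#'   genomes' reads.
#' @param criteria from [specific_region_criteria()].
#' @return An `interval_set` of called regions, with attributes
#'   `self_cov` (per-region mean self coverage).
#' @export
call_specific_regions <- function(labeling, self_profiles, cross_profiles,
                                  criteria = specific_region_criteria()) {
  specific <- labeling[[attr(labeling, "letters")[1]]]
  if (nrow(specific) == 0) return(empty_interval_set())
  keep <- (specific$end - specific$start) >= criteria$min_length
  set <- new_interval_set(specific[keep, , drop = FALSE])
  if (nrow(set) == 0) return(empty_interval_set())
  self_cov <- region_means(set, self_profiles)
  ok <- self_cov >= criteria$self_cov_range[1] &
        self_cov <= criteria$self_cov_range[2]
  for (cp in cross_profiles) {
    cross <- region_means(set, cp)
    ok <- ok & cross < criteria$cross_cov_max
  }
  out <- new_interval_set(set[ok, , drop = FALSE])
  attr(out, "self_cov") <- self_cov[ok]
  out
}

#' Restrict specific regions to those intersecting annotated genes
#'
#' Keeps whole regions whose overlap with annotated gene spans is at least
#' `min_overlap` bp; retained regions may extend past the gene into
#' flanking promoter or regulatory sequence.
#'
#' @param regions output of [call_specific_regions()].
#' @param annotation an `annotation_set`.
#' @param min_overlap minimum gene overlap, bp (default 100).
#' @return An `interval_set`.
#' @export
call_genic_specific_regions <- function(regions, annotation,
                                        min_overlap = 100) {
  min_overlap_filter(regions, annotation, min_bp = min_overlap)
}

#' Assign genes to Venn sectors by majority of exonic bases
#'
#' For each gene, exonic bases falling in each sector are summed across all
#' transcripts (exons shared by several transcripts count once per
#' transcript), and the gene is assigned to the sector with the most bases.
#' Ties resolve toward the more-shared sector (core, then pairwise in
#' reporting order, then specific), which is conservative against
#' overcalling novelty.
#'
#' @param annotation an `annotation_set` of the focal genome.
#' @param labeling the focal genome's `sector_labeling`.
#' @return Data frame with one row per gene: `gene`, `sector`, and the
#'   supporting exonic bp per sector.
#' @export
assign_gene_sectors <- function(annotation, labeling) {
  exons <- gene_exons(annotation)
  if (nrow(exons) == 0)
    return(data.frame(gene = character(), sector = character(),
                      stringsAsFactors = FALSE))
  tags <- names(labeling)
  # precedence: core > pairwise (in labeling order) > specific
  pref <- c(tags[4], tags[2], tags[3], tags[1])
  support <- matrix(0, nrow = length(unique(exons$gene)), ncol = 4,
                    dimnames = list(unique(exons$gene), pref))
  for (tag in tags) {
    sect <- labeling[[tag]]
    if (nrow(sect) == 0) next
    for (s in unique(exons$seqname)) {
      ei <- which(exons$seqname == s)
      g <- sect[sect$seqname == s, , drop = FALSE]
      if (nrow(g) == 0) next
      re <- IRanges::IRanges(exons$start[ei] + 1L, exons$end[ei])
      rg <- IRanges::IRanges(g$start + 1L, g$end)
      hits <- IRanges::findOverlaps(re, rg)
      if (length(hits) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        re[S4Vectors::queryHits(hits)], rg[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, exons$gene[ei[S4Vectors::queryHits(hits)]], sum)
      support[names(agg), tag] <- support[names(agg), tag] + as.numeric(agg)
    }
  }
  tot <- rowSums(support)
  if (any(tot == 0))
    stop("gene(s) with zero exonic bases: ",
         paste(utils::head(rownames(support)[tot == 0]), collapse = ", "))
  sector <- pref[apply(support, 1, which.max)]  # which.max: first (most
                                                # shared) wins ties
  data.frame(gene = rownames(support), sector = sector,
             support[, c(4, 2, 3, 1), drop = FALSE], stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Spacing statistics of localized regions
#'
#' Gaps between consecutive region midpoints per sequence; under uniform
#' random placement the gaps are approximately exponential, so the
#' coefficient of variation (sd/mean) is near 1.
#'
#' @param regions an `interval_set` (at least 3 regions).
#' @return List: `mean_gap`, `sd_gap`, `cv` (sd/mean), `n_gaps`.
#' @export
spacing_stats <- function(regions) {
  regions <- as_interval_set(regions)
  if (nrow(regions) < 3) stop("insufficient regions: need at least 3")
  gaps <- unlist(lapply(split(regions, regions$seqname), function(d) {
    mid <- sort((d$start + d$end) / 2)
    if (length(mid) < 2) return(numeric(0))
    diff(mid)
  }))
  if (length(gaps) < 2) stop("insufficient regions: need at least 3 on a sequence")
  m <- mean(gaps)
  s <- stats::sd(gaps)
  list(mean_gap = m, sd_gap = s, cv = s / m, n_gaps = length(gaps))
}
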