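#' Configuration for the synthetic genome-trio simulator
#'
#' Describes a trio of diverged genomes (call them A, B and C) sharing a
#' common core, with pairwise-shared and genome-specific segments, one
#' high-copy tandem repeat family per genome, SNP/small-indel divergence
#' between lineages, annotated gene models, and shotgun reads. The defaults
#' are the package's standard validation conditions: a 1 Mbp core in 20
#' segments, ten genome-specific segments of 0.5-5 kbp per genome, five
#' 2 kbp segments per pairwise sector, one 50-copy repeat family per genome,
#' and 60-fold error-free 100 bp reads.
#'
#' @param seed integer seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @param core_length total length of the fully shared core, bp, split into
#'   `n_core_segments` segments.
#' @param n_core_segments number of core segments.
#' @param sector_segment_lengths named list mapping Venn sectors (`ABC`,
#'   `AB`, `AC`, `BC`, `A`, `B`, `C`) to vectors of segment lengths (bp);
#'   `ABC` entries add to the core.
#' @param snp_rate substitutions per bp applied independently to each
#'   genome's copy of a shared segment (so pairwise divergence is about
#'   twice this rate).
#' @param small_indel_rate indel events per bp, sizes 1 to `indel_max`.
#' @param indel_max maximum small-indel size, bp (default 5, the boundary
#'   between "small" and reportable large indels).
#' @param repeat_family_specs list of `c(unit_length, copy_number)` pairs;
#'   each spec plants, in every genome, one genome-private tandem array of
#'   `copy_number` exact copies of a random unit.
#' @param gene_density genes per 10 kbp of non-repeat segment.
#' @param read_depth fold coverage of simulated reads.
#' @param read_length read length, bp.
#' @param read_error_rate substitution errors per read base.
#' @param gap_len length of the N run separating consecutive segments in a
#'   scaffold; must exceed the aligner's `max_gap` so alignments cannot
#'   bridge planted junctions.
#' @param genome_names names of the three genomes.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       core_length = 1e6,
                       n_core_segments = 20,
                       sector_segment_lengths = list(
                         ABC = integer(0),
                         AB = rep(2000L, 5), AC = rep(2000L, 5),
                         BC = rep(2000L, 5),
                         A = as.integer(round(seq(500, 5000, length.out = 10))),
                         B = as.integer(round(seq(500, 5000, length.out = 10))),
                         C = as.integer(round(seq(500, 5000, length.out = 10)))),
                       snp_rate = 0.005,
                       small_indel_rate = 2e-4,
                       indel_max = 5,
                       repeat_family_specs = list(c(unit_length = 400,
                                                    copy_number = 50)),
                       gene_density = 2,
                       read_depth = 60,
                       read_length = 100,
                       read_error_rate = 0,
                       gap_len = 100,
                       genome_names = c("A", "B", "C")) {
  stopifnot(core_length > 0, n_core_segments >= 1,
            snp_rate >= 0, snp_rate < 1,
            small_indel_rate >= 0, small_indel_rate < 1,
            read_error_rate >= 0, read_error_rate < 1,
            read_depth > 0, read_length > 0, gap_len >= 0,
            length(genome_names) == 3, !anyDuplicated(genome_names),
            !anyDuplicated(substr(genome_names, 1, 1)))
  sectors <- c("ABC", "AB", "AC", "BC", "A", "B", "C")
  ssl <- stats::setNames(vector("list", 7), sectors)
  for (s in sectors) {
    v <- sector_segment_lengths[[s]]
    ssl[[s]] <- if (is.null(v)) integer(0) else as.integer(v)
    if (any(ssl[[s]] <= 0)) stop("sector segment lengths must be positive")
  }
  rep_total <- sum(vapply(repeat_family_specs,
                          function(x) x[["unit_length"]] * x[["copy_number"]],
                          1))
  planted <- core_length + sum(unlist(ssl))
  if (rep_total > planted)
    stop("total repeat content exceeds genome length")
  cfg <- list(seed = as.integer(seed), core_length = core_length,
              n_core_segments = n_core_segments,
              sector_segment_lengths = ssl, snp_rate = snp_rate,
              small_indel_rate = small_indel_rate, indel_max = indel_max,
              repeat_family_specs = repeat_family_specs,
              gene_density = gene_density, read_depth = read_depth,
              read_length = read_length, read_error_rate = read_error_rate,
              gap_len = as.integer(gap_len), genome_names = genome_names)
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply SNPs and small indels to one segment copy; returns the mutated
# sequence, the offsets needed to project ancestral coordinates into the
# mutated copy, and the variant records.
mutate_segment <- function(seq, snp_rate, indel_rate, indel_max) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  variants <- list()
  if (snp_rate > 0) {
    pos <- which(stats::runif(n) < snp_rate)
    if (length(pos)) {
      for (p in pos) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        chars[p] <- alt
      }
      variants[[length(variants) + 1]] <-
        data.frame(pos = pos - 1L, type = "snp", size = 1L)
    }
  }
  events <- NULL
  if (indel_rate > 0) {
    pos <- which(stats::runif(n) < indel_rate)
    # keep indels away from segment ends so segment length truth stays clean
    pos <- pos[pos > indel_max & pos < n - indel_max]
    if (length(pos)) {
      ins <- stats::runif(length(pos)) < 0.5
      size <- sample.int(indel_max, length(pos), replace = TRUE)
      events <- data.frame(pos = pos, ins = ins, size = size)
      variants[[length(variants) + 1]] <-
        data.frame(pos = pos - 1L, type = ifelse(ins, "ins", "del"),
                   size = size)
      for (i in order(-events$pos)) {
        p <- events$pos[i]; s <- events$size[i]
        if (events$ins[i]) {
          chars <- append(chars, sample(c("A", "C", "G", "T"), s,
                                        replace = TRUE), after = p)
        } else {
          s <- min(s, length(chars) - p)
          chars <- chars[-((p + 1):(p + s))]
        }
      }
    }
  }
  list(seq = paste(chars, collapse = ""),
       events = events,
       variants = if (length(variants)) do.call(rbind, variants) else NULL)
}

# Project ancestral 0-based positions through a segment's indel events.
project_positions <- function(pos, events) {
  if (is.null(events) || nrow(events) == 0) return(pos)
  ev <- events[order(events$pos), , drop = FALSE]
  delta <- ifelse(ev$ins, ev$size, -ev$size)
  shift <- cumsum(delta)
  idx <- findInterval(pos, ev$pos + 1e-9)  # events strictly before pos
  pos + ifelse(idx == 0, 0, shift[pmax(idx, 1)]) * (idx > 0)
}

# Distribute "special" items (genome-specific segments and repeat arrays)
# into distinct gaps of the shuffled ordinary segment order so no two are
# adjacent.
interleave_order <- function(n_ordinary, n_special) {
  if (n_special > n_ordinary + 1)
    stop("too many genome-specific segments to keep them non-adjacent")
  o <- sample.int(n_ordinary)
  s <- sample.int(n_special)
  gaps <- sort(sample.int(n_ordinary + 1, n_special))
  out <- list()
  oi <- 1L
  for (g in seq_len(n_ordinary + 1)) {
    k <- match(g, gaps)
    if (!is.na(k)) out[[length(out) + 1]] <- -s[k]  # negative = special
    if (g <= n_ordinary) {
      out[[length(out) + 1]] <- o[oi]
      oi <- oi + 1L
    }
  }
  unlist(out)
}

place_genes_on_segment <- function(len, density) {
  n_genes <- floor(len * density / 1e4)
  if (n_genes < 1 || len < 800) return(NULL)
  slot <- len / n_genes
  out <- list()
  for (i in seq_len(n_genes)) {
    lo <- round((i - 1) * slot) + 50
    hi <- round(i * slot) - 50
    if (hi - lo < 700) next
    glen <- sample(600:min(3000, hi - lo), 1)
    gstart <- lo + sample.int(hi - lo - glen + 1, 1) - 1L
    n_ex <- if (glen >= 900) sample(2:4, 1) else 1L
    # exon/intron layout: equal slices, introns of 100 bp carved between
    bounds <- round(seq(0, glen, length.out = n_ex + 1))
    exons <- data.frame(start = bounds[-(n_ex + 1)], end = bounds[-1])
    if (n_ex > 1) {
      exons$start[-1] <- exons$start[-1] + 50
      exons$end[-n_ex] <- exons$end[-n_ex] - 50
    }
    strand <- sample(c("+", "-"), 1)
    out[[length(out) + 1]] <- list(start = gstart, end = gstart + glen,
                                   strand = strand, exons = exons)
  }
  out
}

#' Simulate a genome trio with known ground truth
#'
#' Builds three genomes as concatenations of sector segments in randomized
#' order (one scaffold per genome, segments separated by `gap_len` Ns so
#' planted junctions can never be bridged by exact matches). Shared segments
#' differ between genomes only through the configured SNP/indel process;
#' repeat families are planted as genome-private exact tandem arrays; gene
#' models are placed wholly inside segments and carried consistently by
#' every genome sharing the segment. Truth records the post-mutation
#' coordinates of every sector segment, N gap, repeat array, variant and
#' gene. N gaps are labelled with the genome's own specific sector (truth
#' column `origin` distinguishes `segment`, `gap` and `repeat` intervals),
#' because bases that align to nothing are observationally genome-specific.
#'
#' @param config a [sim_config()].
#' @return A list with `genomes` (list of named character vectors, one
#'   scaffold `chr1` per genome), `annotations` (list of `annotation_set`s),
#'   and `truth` (list: `sectors`, `repeats`, `variants`, `genes`).
#' @export
simulate_trio <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gnames <- config$genome_names
  sector_of <- function(tag) {
    # map internal tags (built on A/B/C placeholders) to genome-name sectors
    chartr("ABC", paste(substr(gnames, 1, 1), collapse = ""), tag)
  }

  # --- ancestral segment catalog ---------------------------------------
  segs <- list()
  add_seg <- function(sector, len, is_repeat = FALSE, seq = NULL) {
    id <- length(segs) + 1L
    segs[[id]] <<- list(id = id, sector = sector, length = as.integer(len),
                        is_repeat = is_repeat,
                        seq = if (is.null(seq)) rand_dna(len) else seq,
                        genes = NULL)
    id
  }
  core_each <- diff(round(seq(0, config$core_length,
                              length.out = config$n_core_segments + 1)))
  for (len in core_each) add_seg("ABC", len)
  for (s in c("ABC", "AB", "AC", "BC", "A", "B", "C"))
    for (len in config$sector_segment_lengths[[s]]) add_seg(s, len)
  for (g in c("A", "B", "C")) {
    for (spec in config$repeat_family_specs) {
      unit <- rand_dna(spec[["unit_length"]])
      add_seg(g, spec[["unit_length"]] * spec[["copy_number"]],
              is_repeat = TRUE,
              seq = strrep(unit, spec[["copy_number"]]))
    }
  }

  # --- gene placement on the ancestral catalog -------------------------
  for (i in seq_along(segs)) {
    if (segs[[i]]$is_repeat) next
    segs[[i]]$genes <- place_genes_on_segment(segs[[i]]$length,
                                              config$gene_density)
  }

  in_genome <- function(sector, g) grepl(g, sector, fixed = TRUE)

  genomes <- list()
  annotations <- list()
  truth_sectors <- list()
  truth_repeats <- list()
  truth_variants <- list()
  truth_genes <- list()

  for (gi in seq_along(gnames)) {
    g <- c("A", "B", "C")[gi]
    gname <- gnames[gi]
    present <- Filter(function(s) in_genome(s$sector, g), segs)

    # order first, from a per-genome sub-seed, so layout is independent of
    # how many draws the mutation process consumes (raising mutation rates
    # must not reshuffle segments)
    set.seed(config$seed + 7919L * gi)
    special <- which(vapply(present, function(s) s$sector == g, TRUE))
    ordinary <- setdiff(seq_along(present), special)
    ord_code <- interleave_order(length(ordinary), length(special))
    order_idx <- ifelse(ord_code > 0, ordinary[pmax(ord_code, 1)],
                        special[pmax(-ord_code, 1)])

    # mutate each present non-repeat segment copy independently
    set.seed(config$seed + 7919L * gi + 1L)
    inst <- lapply(present, function(s) {
      if (s$is_repeat || (config$snp_rate == 0 && config$small_indel_rate == 0))
        return(list(seg = s, seq = s$seq, events = NULL, variants = NULL))
      m <- mutate_segment(s$seq, config$snp_rate, config$small_indel_rate,
                          config$indel_max)
      list(seg = s, seq = m$seq, events = m$events, variants = m$variants)
    })

    pos <- 0L
    pieces <- character(0)
    sect <- list(); reps <- list(); vars <- list(); genes_tr <- list()
    ann <- list()
    gene_counter <- 0L
    for (j in seq_along(order_idx)) {
      x <- inst[[order_idx[j]]]
      len <- nchar(x$seq)
      pieces <- c(pieces, x$seq)
      sect[[length(sect) + 1]] <- data.frame(
        genome = gname, seqname = "chr1", start = pos, end = pos + len,
        sector = sector_of(x$seg$sector),
        origin = if (x$seg$is_repeat) "repeat" else "segment",
        stringsAsFactors = FALSE)
      if (x$seg$is_repeat)
        reps[[length(reps) + 1]] <- data.frame(
          genome = gname, seqname = "chr1", start = pos, end = pos + len,
          stringsAsFactors = FALSE)
      if (!is.null(x$variants)) {
        v <- x$variants
        v$pos <- pos + project_positions(v$pos, x$events)
        v$genome <- gname
        vars[[length(vars) + 1]] <- v
      }
      for (gene in x$seg$genes) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("%s_g%04d", gname, gene_counter)
        gs <- pos + project_positions(gene$start, x$events)
        ge <- pos + project_positions(gene$end, x$events)
        ex <- data.frame(
          start = pos + project_positions(gene$exons$start, x$events),
          end = pos + project_positions(gene$exons$end, x$events))
        tid <- paste0(gid, ".1")
        rows <- data.frame(
          seqname = "chr1",
          type = c("gene", "mRNA", rep("exon", nrow(ex))),
          start = c(gs, gs, ex$start), end = c(ge, ge, ex$end),
          strand = gene$strand, gene = gid,
          transcript = c(NA, tid, rep(tid, nrow(ex))),
          stringsAsFactors = FALSE)
        # CDS: exon bases minus 60 bp UTRs at each gene end
        utr5 <- 60L; utr3 <- 60L
        cds <- ex
        cds$start[1] <- min(cds$start[1] + utr5, cds$end[1])
        ncds <- nrow(cds)
        cds$end[ncds] <- max(cds$end[ncds] - utr3, cds$start[ncds])
        cds <- cds[cds$end > cds$start, , drop = FALSE]
        if (nrow(cds))
          rows <- rbind(rows, data.frame(
            seqname = "chr1", type = "CDS", start = cds$start,
            end = cds$end, strand = gene$strand, gene = gid,
            transcript = tid, stringsAsFactors = FALSE))
        ann[[length(ann) + 1]] <- rows
        genes_tr[[length(genes_tr) + 1]] <- data.frame(
          genome = gname, gene = gid, seqname = "chr1", start = gs, end = ge,
          sector = sector_of(x$seg$sector), stringsAsFactors = FALSE)
      }
      pos <- pos + len
      if (j < length(order_idx) && config$gap_len > 0) {
        pieces <- c(pieces, strrep("N", config$gap_len))
        sect[[length(sect) + 1]] <- data.frame(
          genome = gname, seqname = "chr1", start = pos,
          end = pos + config$gap_len, sector = sector_of(g),
          origin = "gap", stringsAsFactors = FALSE)
        pos <- pos + config$gap_len
      }
    }
    genomes[[gname]] <- c(chr1 = paste(pieces, collapse = ""))
    annotations[[gname]] <- new_annotation_set(
      if (length(ann)) do.call(rbind, ann) else
        data.frame(seqname = character(), type = character(),
                   start = integer(), end = integer(), strand = character(),
                   gene = character(), transcript = character(),
                   stringsAsFactors = FALSE))
    truth_sectors[[gname]] <- do.call(rbind, sect)
    truth_repeats[[gname]] <- if (length(reps)) do.call(rbind, reps) else NULL
    truth_variants[[gname]] <- if (length(vars)) do.call(rbind, vars) else NULL
    truth_genes[[gname]] <- if (length(genes_tr)) do.call(rbind, genes_tr)
                            else NULL
  }

  truth <- list(
    sectors = do.call(rbind, truth_sectors),
    repeats = do.call(rbind, truth_repeats),
    variants = do.call(rbind, truth_variants),
    genes = do.call(rbind, truth_genes)
  )
  rownames(truth$sectors) <- NULL
  list(genomes = genomes, annotations = annotations, truth = truth,
       config = config)
}

#' Truth accessors
#'
#' `truth_sectors` returns one genome's sector intervals (optionally only
#' those of a given origin); `truth_specific_regions` returns the planted
#' genome-specific non-repeat segments, the ground truth for
#' [call_specific_regions()].
#'
#' @param truth the `truth` element of [simulate_trio()] output.
#' @param genome genome name.
#' @param origin optional filter: `"segment"`, `"gap"`, `"repeat"`.
#' @return A data frame of intervals (with `sector` labels), or an
#'   `interval_set`.
#' @export
truth_sectors <- function(truth, genome, origin = NULL) {
  d <- truth$sectors[truth$sectors$genome == genome, , drop = FALSE]
  if (!is.null(origin)) d <- d[d$origin %in% origin, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname truth_sectors
#' @export
truth_specific_regions <- function(truth, genome) {
  d <- truth_sectors(truth, genome, origin = "segment")
  d <- d[d$sector == substr(genome, 1, 1), , drop = FALSE]
  if (nrow(d) == 0) return(empty_interval_set())
  normalize_intervals(d[, c("seqname", "start", "end")])
}

#' Simulate shotgun reads from a genome
#'
#' Single-end reads drawn uniformly over the genome with uniform strand,
#' with independent per-base substitution errors at `read_error_rate`. The
#' read count is `round(depth * genome_length / read_length)`, so total read
#' bases are within rounding of `depth * genome_length`.
#'
#' @param genome a sequence set (named character vector or `DNAStringSet`).
#' @param config a [sim_config()] (uses `read_depth`, `read_length`,
#'   `read_error_rate`).
#' @param seed seed for this read set (default: the config seed).
#' @return A `DNAStringSet` of reads.
#' @export
simulate_reads <- function(genome, config = sim_config(),
                           seed = config$seed) {
  genome <- as_sequence_set(genome)
  rl <- config$read_length
  lens <- seq_lengths(genome)
  if (config$read_depth <= 0) stop("read depth must be positive")
  if (rl > min(lens)) stop("read length exceeds shortest scaffold")
  set.seed(seed)
  total <- sum(as.numeric(lens))
  n <- round(config$read_depth * total / rl)
  scaf <- sample(seq_along(lens), n, replace = TRUE, prob = lens)
  out <- character(n)
  for (si in seq_along(lens)) {
    idx <- which(scaf == si)
    if (!length(idx)) next
    starts <- sample.int(lens[si] - rl + 1L, length(idx), replace = TRUE)
    out[idx] <- substring(genome[[si]], starts, starts + rl - 1L)
  }
  reads <- Biostrings::DNAStringSet(out)
  minus <- which(stats::runif(n) < 0.5)
  if (length(minus))
    reads[minus] <- Biostrings::reverseComplement(reads[minus])
  if (config$read_error_rate > 0) {
    nerr <- stats::rbinom(n, rl, config$read_error_rate)
    hit <- which(nerr > 0)
    if (length(hit)) {
      ch <- as.character(reads[hit])
      for (j in seq_along(hit)) {
        v <- strsplit(ch[j], "", fixed = TRUE)[[1]]
        p <- sample.int(rl, nerr[hit[j]])
        for (q in p) {
          if (v[q] %in% c("A", "C", "G", "T"))
            v[q] <- sample(setdiff(c("A", "C", "G", "T"), v[q]), 1)
        }
        ch[j] <- paste(v, collapse = "")
      }
      reads[hit] <- Biostrings::DNAStringSet(ch)
    }
  }
  names(reads) <- sprintf("read%07d", seq_len(n))
  reads
}

#' Write a simulated trio (and optional reads) to disk
#'
#' Writes per-genome FASTA (80-column wrap), GFF3 annotations, BED6 truth
#' sectors (name field = sector label), optional FASTQ reads (Phred+33,
#' constant quality "I"), and a JSON manifest recording the configuration
#' and seed.
#'
#' @param sim output of [simulate_trio()].
#' @param dir output directory (created if needed).
#' @param reads optional named list of `DNAStringSet` read sets per genome.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_fixture <- function(sim, dir, reads = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (g in names(sim$genomes)) {
    fa <- file.path(dir, paste0(g, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genomes[[g]]), fa, width = 80)
    paths[paste0(g, "_fasta")] <- fa
    gff <- file.path(dir, paste0(g, ".gff3"))
    write_gff3(sim$annotations[[g]], gff)
    paths[paste0(g, "_gff3")] <- gff
    bed <- file.path(dir, paste0(g, ".sectors.bed"))
    d <- truth_sectors(sim$truth, g)
    write_bed(data.frame(seqname = d$seqname, start = d$start, end = d$end,
                         name = d$sector), bed)
    paths[paste0(g, "_bed")] <- bed
    if (!is.null(reads[[g]])) {
      fq <- file.path(dir, paste0(g, ".reads.fastq"))
      r <- reads[[g]]
      Biostrings::writeXStringSet(
        r, fq, format = "fastq",
        qualities = Biostrings::BStringSet(
          rep(strrep("I", unique(Biostrings::width(r))[1]), length(r))))
      paths[paste0(g, "_fastq")] <- fq
    }
  }
  manifest <- file.path(dir, "manifest.json")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, files = as.list(paths)),
                       manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- manifest
  invisible(paths)
}
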