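md5_of <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(unname(tools::md5sum(x)))
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

# stage cache: recompute when the dependency hash changes or the
# intermediate was deleted
stage <- function(dir, name, dep_hash, compute, log = TRUE) {
  rds <- file.path(dir, paste0(name, ".rds"))
  meta <- file.path(dir, paste0(name, ".hash"))
  if (file.exists(rds) && file.exists(meta) &&
      identical(readLines(meta, warn = FALSE)[1], dep_hash)) {
    if (log) message("[pantrio] ", name, ": cached")
    return(readRDS(rds))
  }
  if (log) message("[pantrio] ", name, ": computing")
  t0 <- Sys.time()
  val <- tryCatch(compute(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  saveRDS(val, rds)
  writeLines(dep_hash, meta)
  if (log) message(sprintf("[pantrio] %s: done in %.1fs", name,
                           as.numeric(Sys.time() - t0, units = "secs")))
  val
}

load_genome <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    as.character(Biostrings::readDNAStringSet(x))
  else as_sequence_set(x)
}

load_annotation <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) read_gff3(x)
  else x
}

#' Run the full trio pan-genome pipeline
#'
#' Orchestrates the analysis end to end for three genomes: pairwise
#' whole-genome alignment, one-to-one filtering and difference summaries,
#' unaligned-region extraction, per-base Venn classification, canonical
#' k-mer counting and coverage profiling of each genome against all three
#' read sets, genome-specific non-repetitive region calling, genic
#' filtering, gene sector assignment, and table-shaped reports. Stages are
#' cached as RDS intermediates under `out_dir` keyed by input checksums, so
#' re-running with identical inputs reuses them and deleting an
#' intermediate regenerates only that stage and its dependents.
#'
#' @param genomes named list of three sequence sets (or FASTA paths); the
#'   name order sets the reporting precedence.
#' @param annotations named list of three `annotation_set`s (or GFF3
#'   paths).
#' @param reads named list of three read sets (`DNAStringSet`s, character
#'   vectors, or FASTA/FASTQ paths).
#' @param out_dir output directory.
#' @param k k-mer length (default 21).
#' @param aligner from [aligner_config()].
#' @param criteria from [specific_region_criteria()].
#' @param thresholds from [kmer_thresholds()].
#' @param assumed_size assumed genome size for coverage percentages.
#' @param quiet suppress stage log messages.
#' @return Invisibly, a list with all computed objects (`stats`, `aligned`,
#'   `diffs`, `labelings`, `profiles`, `specific`, `genic`, `assignments`,
#'   `venn`, `tables`).
#' @export
run_pipeline <- function(genomes, annotations, reads, out_dir, k = 21,
                         aligner = aligner_config(),
                         criteria = specific_region_criteria(),
                         thresholds = kmer_thresholds(),
                         assumed_size = 389e6, quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- !quiet
  gnames <- names(genomes)
  stopifnot(length(genomes) == 3, !is.null(gnames),
            identical(sort(names(annotations)), sort(gnames)),
            identical(sort(names(reads)), sort(gnames)))
  G <- lapply(genomes, load_genome)
  A <- lapply(annotations[gnames], load_annotation)
  in_hash <- vapply(c(G, reads[gnames]), md5_of, "")
  cfg_hash <- md5_of(list(k, aligner, criteria, thresholds))

  # k-mer databases (cached as count tables, rebuilt into hash maps)
  dbs <- list()
  for (g in gnames) {
    tab <- stage(out_dir, paste0("kmers_", g),
                 paste(md5_of(reads[[g]]), k), function() {
      db <- kmer_count(as_read_characters(reads[[g]]), k)
      .kmer_db_dump_cpp(db$ptr, db$k)
    }, log)
    ptr <- .kmer_db_build_cpp(tab$kmer, tab$count, as.integer(k))
    dbs[[g]] <- structure(list(ptr = ptr, k = as.integer(k)),
                          class = "kmer_db")
  }

  # coverage profiles: each genome against each read set
  profiles <- list()
  for (g in gnames) {
    for (r in gnames) {
      nm <- paste0(g, "_by_", r)
      profiles[[nm]] <- stage(out_dir, paste0("profile_", nm),
                              paste(in_hash[g], in_hash[r], k), function() {
        lapply(G[[g]], coverage_profile, db = dbs[[r]])
      }, log)
    }
  }

  # pairwise alignments (one per unordered pair; both sides used)
  pairs <- utils::combn(gnames, 2, simplify = FALSE)
  aligned <- list()
  diffs <- list()
  for (p in pairs) {
    nm <- paste0(p[1], "_vs_", p[2])
    aligned[[nm]] <- stage(out_dir, paste0("align_", nm),
                           paste(in_hash[p[1]], in_hash[p[2]], cfg_hash),
                           function() {
      align_genomes(G[[p[1]]], G[[p[2]]], aligner)
    }, log)
    one <- filter_one_to_one(aligned[[nm]])
    diffs[[nm]] <- summarize_diff(one, G[[p[1]]], G[[p[2]]], aligner)
  }

  # unaligned regions per genome vs each other genome (repeat-inclusive)
  unal <- list()
  for (g in gnames) {
    others <- setdiff(gnames, g)
    for (o in others) {
      nm <- paste0(g, "_vs_", o)
      pnm <- if (!is.null(aligned[[paste0(g, "_vs_", o)]]))
        list(paste0(g, "_vs_", o), "ref") else list(paste0(o, "_vs_", g), "qry")
      unal[[nm]] <- unaligned_regions(G[[g]], aligned[[pnm[[1]]]],
                                      side = pnm[[2]])
    }
  }

  # Venn classification
  labelings <- list()
  for (g in gnames) {
    others <- setdiff(gnames, g)
    labelings[[g]] <- classify_bases(
      G[[g]], unal[[paste0(g, "_vs_", others[1])]],
      unal[[paste0(g, "_vs_", others[2])]], names = c(g, others))
  }

  # specific regions + genic subsets + gene assignment
  specific <- list(); genic <- list(); assignments <- list()
  for (g in gnames) {
    others <- setdiff(gnames, g)
    specific[[g]] <- call_specific_regions(
      labelings[[g]], profiles[[paste0(g, "_by_", g)]],
      list(profiles[[paste0(g, "_by_", others[1])]],
           profiles[[paste0(g, "_by_", others[2])]]), criteria)
    genic[[g]] <- call_genic_specific_regions(specific[[g]], A[[g]])
    assignments[[g]] <- assign_gene_sectors(A[[g]], labelings[[g]])
  }

  venn <- venn_summary(labelings[gnames], A[gnames], assignments[gnames])

  # reports ------------------------------------------------------------
  stats <- lapply(G, assembly_stats, assumed_size = assumed_size)
  tables <- list()
  tables$assembly_stats <- data.frame(
    genome = gnames,
    do.call(rbind, lapply(stats[gnames], as.data.frame)),
    row.names = NULL)
  tables$diff_summary <- data.frame(
    pair = names(diffs),
    do.call(rbind, lapply(diffs, as.data.frame)), row.names = NULL)
  mk_region_table <- function(sets, with_cov = FALSE) {
    data.frame(genome = gnames, do.call(rbind, lapply(gnames, function(g) {
      s <- region_summary(sets[[g]],
                          profiles = if (with_cov)
                            profiles[[paste0(g, "_by_", g)]])
      as.data.frame(s)
    })), row.names = NULL)
  }
  # regions of the first (reference-precedence) genome unaligned to each
  # other genome, with k-mer coverage from that other genome's reads
  refg <- gnames[1]
  unal_vs_ref <- stats::setNames(lapply(gnames, function(g) {
    if (g == refg) empty_interval_set()
    else unal[[paste0(refg, "_vs_", g)]]
  }), gnames)
  tables$unaligned_regions <- data.frame(
    genome = gnames, do.call(rbind, lapply(gnames, function(g)
      as.data.frame(region_summary(
        unal_vs_ref[[g]],
        profiles = profiles[[paste0(refg, "_by_", g)]])))),
    row.names = NULL)
  tables$unaligned_annotation <- data.frame(
    genome = gnames, do.call(rbind, lapply(gnames, function(g)
      as.data.frame(as.list(annotate_overlap(unal_vs_ref[[g]], A[[refg]]))))),
    row.names = NULL)
  tables$specific_regions <- mk_region_table(specific, with_cov = TRUE)
  tables$genic_specific <- mk_region_table(genic, with_cov = TRUE)
  tables$venn <- venn

  for (nm in names(tables))
    utils::write.table(tables[[nm]],
                       file.path(out_dir, paste0("table_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in gnames) {
    lab <- labelings[[g]]
    bed <- do.call(rbind, lapply(names(lab), function(tag) {
      d <- lab[[tag]]
      if (nrow(d) == 0) return(NULL)
      data.frame(seqname = d$seqname, start = d$start, end = d$end,
                 name = tag)
    }))
    bed <- bed[order(bed$seqname, bed$start), ]
    write_bed(bed, file.path(out_dir, paste0("sectors_", g, ".bed")))
    write_bed(as.data.frame(specific[[g]]),
              file.path(out_dir, paste0("specific_", g, ".bed")))
    utils::write.table(assignments[[g]],
                       file.path(out_dir, paste0("gene_sectors_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "pantrio",
    version = as.character(utils::packageVersion("pantrio")),
    genomes = gnames,
    input_md5 = as.list(in_hash),
    config = list(k = k, aligner = aligner, criteria = criteria,
                  thresholds = thresholds, assumed_size = assumed_size))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(stats = stats, aligned = aligned, diffs = diffs,
                 unaligned = unal, labelings = labelings,
                 profiles = profiles, specific = specific, genic = genic,
                 assignments = assignments, venn = venn, tables = tables))
}
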