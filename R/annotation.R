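#' Read a GFF3 gene annotation
#'
#' Parses gene/mRNA/exon/CDS/UTR features into a flat `annotation_set` data
#' frame with internal 0-based half-open coordinates. Feature parentage is
#' resolved so every exon/CDS/UTR row carries its transcript and gene id.
#' Parsing is delegated to rtracklayer.
#'
#' @param path path to a GFF3 file.
#' @return An `annotation_set`: data frame with columns `seqname`, `type`,
#'   `start`, `end` (0-based half-open), `strand`, `gene`, `transcript`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  keep <- df$type %in% c("gene", "mRNA", "exon", "CDS",
                         "five_prime_UTR", "three_prime_UTR")
  df <- df[keep, , drop = FALSE]
  mrna_gene <- df$parent[df$type == "mRNA"]
  names(mrna_gene) <- df$id[df$type == "mRNA"]
  is_sub <- !(df$type %in% c("gene", "mRNA"))
  df$transcript <- ifelse(df$type == "mRNA", df$id,
                          ifelse(is_sub, df$parent, NA_character_))
  df$gene <- ifelse(df$type == "gene", df$id,
                    ifelse(df$type == "mRNA", df$parent,
                           unname(mrna_gene[df$transcript])))
  new_annotation_set(df[, c("seqname", "type", "start", "end", "strand",
                            "gene", "transcript")])
}

new_annotation_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Write an annotation set as GFF3
#'
#' Emits gene/mRNA/exon/CDS/UTR records with ID/Parent attributes,
#' converting internal 0-based half-open coordinates to GFF3's 1-based
#' inclusive convention.
#'
#' @param ann an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  attr_col <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    t <- ann$type[i]
    if (t == "gene") {
      attr_col[i] <- sprintf("ID=%s", ann$gene[i])
    } else if (t == "mRNA") {
      attr_col[i] <- sprintf("ID=%s;Parent=%s", ann$transcript[i], ann$gene[i])
    } else {
      attr_col[i] <- sprintf("ID=%s:%s:%d;Parent=%s", ann$transcript[i],
                             tolower(t), i, ann$transcript[i])
    }
  }
  lines <- sprintf("%s\tpantrio\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   ann$seqname, ann$type, ann$start + 1L, ann$end,
                   ann$strand, ifelse(ann$type == "CDS", "0", "."), attr_col)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract feature intervals from an annotation set
#'
#' @param ann an `annotation_set`.
#' @param type feature type (`"gene"`, `"mRNA"`, `"exon"`, `"CDS"`,
#'   `"five_prime_UTR"`, `"three_prime_UTR"`).
#' @return An `interval_set` of the (merged) bases covered by that feature
#'   type.
#' @export
annotation_intervals <- function(ann, type) {
  d <- ann[ann$type == type, , drop = FALSE]
  if (nrow(d) == 0) return(empty_interval_set())
  normalize_intervals(d[, c("seqname", "start", "end")])
}

#' @rdname annotation_intervals
#' @export
gene_spans <- function(ann) annotation_intervals(ann, "gene")

#' Per-gene exon records (all transcripts, not unioned)
#'
#' @param ann an `annotation_set`.
#' @return Data frame of exon rows with `gene` and `transcript` ids kept;
#'   shared exons appearing in several transcripts appear once per
#'   transcript.
#' @export
gene_exons <- function(ann) {
  ann[ann$type == "exon", , drop = FALSE]
}
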