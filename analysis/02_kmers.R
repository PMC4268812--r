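# Stage 2: canonical 21-mer counting and coverage profiling.
#
# Counts canonical 21-mers in each genome's reads, estimates the
# single-copy coverage mode from the frequency histogram (excluding
# erroneous k-mers below 10 copies), and profiles every genome against all
# three read sets. With 60x reads of 100 bp the expected single-copy k-mer
# coverage is 60 * (1 - 20/100) = 48x.

source("analysis/00_config.R")

sim <- readRDS(file.path(SCRATCH, "sim.rds"))
reads <- readRDS(file.path(SCRATCH, "reads.rds"))
gn <- names(sim$genomes)

modes <- data.frame(genome = gn, distinct_kmers = NA_real_,
                    total_kmers = NA_real_, mode_fold = NA_real_)
profiles <- list()
for (g in gn) {
  db <- kmer_count(reads[[g]], 21)
  st <- kmer_db_stats(db)
  h <- kmer_histogram(db)
  modes[modes$genome == g, -1] <-
    c(st$n_distinct, st$total, estimate_mode(h))
  utils::write.table(h, file.path(RESULTS, paste0("kmer_hist_", g, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tgt in gn) {
    profiles[[paste0(tgt, "_by_", g)]] <-
      lapply(sim$genomes[[tgt]], coverage_profile, db = db)
  }
  cat(sprintf("%s: %s distinct canonical 21-mers, mode %dx\n", g,
              format(st$n_distinct, big.mark = ","),
              modes$mode_fold[modes$genome == g]))
}
saveRDS(profiles, file.path(SCRATCH, "profiles.rds"))
utils::write.table(modes, file.path(RESULTS, "kmer_modes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# coverage track of genome A by its own and by another genome's reads
write_bedgraph(profiles[[paste0(gn[1], "_by_", gn[1])]],
               file.path(RESULTS, paste0("coverage_", gn[1], "_self.bedgraph")))
write_bedgraph(profiles[[paste0(gn[1], "_by_", gn[2])]],
               file.path(RESULTS, paste0("coverage_", gn[1], "_cross.bedgraph")))
cat("profiles and BedGraph tracks written\n")
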