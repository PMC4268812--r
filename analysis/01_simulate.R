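# Stage 1: simulate the genome trio and its read sets.
#
# Builds three ~1.07 Mbp genomes sharing a 1 Mbp core, with ten
# genome-specific segments (0.5-5 kbp), five segments per pairwise-shared
# sector, and one genome-private 50-copy tandem repeat array each, then
# draws 60x error-free 100 bp shotgun reads per genome. Ground truth
# (sector intervals, repeats, variants, genes) is written as BED/GFF3.

source("analysis/00_config.R")

cfg <- trio_config()
sim <- simulate_trio(cfg)
gn <- names(sim$genomes)
reads <- lapply(setNames(gn, gn), function(g)
  simulate_reads(sim$genomes[[g]], cfg, seed = SEED + match(g, gn)))

paths <- write_fixture(sim, file.path(RESULTS, "trio"), reads = NULL)
saveRDS(sim, file.path(SCRATCH, "sim.rds"))
saveRDS(reads, file.path(SCRATCH, "reads.rds"))

for (g in gn) {
  glen <- nchar(sim$genomes[[g]][["chr1"]])
  tg <- truth_sectors(sim$truth, g, origin = "segment")
  spec <- sum(tg$end[tg$sector == substr(g, 1, 1)] -
                tg$start[tg$sector == substr(g, 1, 1)])
  cat(sprintf(
    "%s: %s bp, %d reads (%.0fx), planted specific (non-repeat) %d bp\n",
    g, format(glen, big.mark = ","), length(reads[[g]]),
    sum(Biostrings::width(reads[[g]])) / glen, spec))
}
cat("fixture written under", file.path(RESULTS, "trio"), "\n")
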