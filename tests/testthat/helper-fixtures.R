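# Shared simulation fixtures, built once per test run. The "validation
# scale" trio (1 Mbp core, ten 0.5-5 kbp specific segments and one 50-copy
# repeat array per genome, 60x error-free reads) is the package's standard
# recovery benchmark; the zero-divergence variant checks exact truth
# recovery and needs no reads.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# zero-divergence trio + pairwise alignments + per-genome labelings
fixture_zero <- function() memo("zero", function() {
  cfg <- sim_config(seed = 402, snp_rate = 0, small_indel_rate = 0)
  sim <- simulate_trio(cfg)
  gn <- names(sim$genomes)
  aligned <- list()
  for (p in combn(gn, 2, simplify = FALSE)) {
    aligned[[paste0(p[1], "_vs_", p[2])]] <-
      align_genomes(sim$genomes[[p[1]]], sim$genomes[[p[2]]])
  }
  unal <- list()
  for (g in gn) for (o in setdiff(gn, g)) {
    nm <- paste0(g, "_vs_", o)
    unal[[nm]] <- if (!is.null(aligned[[nm]]))
      unaligned_regions(sim$genomes[[g]], aligned[[nm]], "ref")
    else unaligned_regions(sim$genomes[[g]],
                           aligned[[paste0(o, "_vs_", g)]], "qry")
  }
  labelings <- lapply(setNames(gn, gn), function(g) {
    o <- setdiff(gn, g)
    classify_bases(sim$genomes[[g]], unal[[paste0(g, "_vs_", o[1])]],
                   unal[[paste0(g, "_vs_", o[2])]], names = c(g, o))
  })
  list(cfg = cfg, sim = sim, aligned = aligned, unal = unal,
       labelings = labelings)
})

# divergent trio (snp 0.005) with reads, run through the full pipeline
fixture_div <- function() memo("div", function() {
  cfg <- sim_config(seed = 402)
  sim <- simulate_trio(cfg)
  gn <- names(sim$genomes)
  reads <- lapply(setNames(gn, gn), function(g)
    simulate_reads(sim$genomes[[g]], cfg, seed = cfg$seed + match(g, gn)))
  out_dir <- file.path(tempdir(), "pantrio-fixture-div")
  res <- run_pipeline(sim$genomes, sim$annotations, reads, out_dir,
                      quiet = TRUE)
  list(cfg = cfg, sim = sim, reads = reads, out_dir = out_dir, res = res)
})

# small, fast trio for pipeline plumbing tests
fixture_small_cfg <- function(seed = 31) {
  sim_config(
    seed = seed, core_length = 6e4, n_core_segments = 6,
    sector_segment_lengths = list(
      AB = rep(1500L, 2), AC = rep(1500L, 2), BC = rep(1500L, 2),
      A = c(800L, 2500L, 5000L), B = c(800L, 2500L, 5000L),
      C = c(800L, 2500L, 5000L)),
    repeat_family_specs = list(c(unit_length = 300, copy_number = 30)),
    read_depth = 40)
}
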