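test_that("simulated genomes respect composition and density settings", {
  cfg <- sim_config(genome_length = 10000L, gc_fraction = 0.5,
                    gene_density = 0, repeat_density = 0, seed = 2)
  sim <- simulate_genome(cfg)
  s <- unclass(sim$genome)[["chr1"]]
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.45)  # binomial concentration at n = 10k
  expect_lt(gc, 0.55)
  expect_equal(nrow(sim$features), 0L) # gene_density 0 -> no features
  # same seed -> byte-identical files
  cfg2 <- sim_config(genome_length = 8000L, gene_density = 0.3,
                     repeat_density = 0.1, motif = "GCGCATTA",
                     motif_spacing = 500L, seed = 5)
  a <- simulate_genome(cfg2); b <- simulate_genome(cfg2)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(as.data.frame(a$features), as.data.frame(b$features))
  # motif instances are written into the sequence at recorded positions
  mt <- a$features[a$features$feature_type == "motif"]
  expect_gt(nrow(mt), 0)
  for (i in seq_len(nrow(mt)))
    expect_equal(substr(unclass(a$genome)[["chr1"]], mt$start[i] + 1,
                        mt$end[i]), "GCGCATTA")
})

test_that("methylome emission matches configured rates and coverage law", {
  cfg <- sim_config(genome_length = 150000L, gene_density = 0,
                    repeat_density = 0,
                    context_base_rates = c(CG = 0.3, CHG = 0.15, CHH = 0.05),
                    coverage_lambda = 15, seed = 5)
  sim <- simulate_genome(cfg)
  me <- simulate_methylome(sim$genome, sim$features, cfg)
  tr <- me$truth
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- tr[tr$context == ctx]
    rate <- cfg$context_base_rates[[ctx]]
    se <- sqrt(rate * (1 - rate) / nrow(sel))
    expect_lt(abs(mean(sel$state) - rate), 3 * se)
  }
  # unknown-call fraction tracks the Poisson CDF P(X <= 10)
  punk <- ppois(10, 15)
  se <- sqrt(punk * (1 - punk) / nrow(me$calls))
  expect_lt(abs(mean(me$calls$status == "unknown") - punk), 4 * se)
})

test_that("strong motif effects concentrate methylation near motifs", {
  cfg <- sim_config(genome_length = 60000L, gc_fraction = 0.5,
                    gene_density = 0, repeat_density = 0,
                    motif = "GCGCATTA", motif_spacing = 500L,
                    context_base_rates = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                    motif_effect = stats::qlogis(0.95) - stats::qlogis(0.05),
                    coverage_lambda = 30, seed = 6)
  sim <- simulate_genome(cfg)
  me <- simulate_methylome(sim$genome, sim$features, cfg)
  near <- me$truth[me$truth$near_motif == TRUE]
  far <- me$truth[me$truth$near_motif == FALSE]
  se <- sqrt(0.95 * 0.05 / nrow(near))
  expect_lt(abs(mean(near$state) - 0.95), 4 * se)
  expect_lt(mean(far$state), 0.07)
})

test_that("the latent field controls neighbor correlation", {
  base <- list(genome_length = 60000L, gene_density = 0, repeat_density = 0,
               context_base_rates = c(CG = 0.5, CHG = 0.5, CHH = 0.5),
               coverage_lambda = 30, seed = 7)
  cfg0 <- do.call(sim_config, c(base, list(rho = 0, spatial_scale = 0)))
  cfg1 <- do.call(sim_config, c(base, list(rho = 0.99, spatial_scale = 3)))
  sim <- simulate_genome(cfg0)
  s0 <- simulate_methylome(sim$genome, sim$features, cfg0)$truth$state
  s1 <- simulate_methylome(sim$genome, sim$features, cfg1)$truth$state
  ac <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(ac(s0)), 0.05) # independence without the field
  expect_gt(ac(s1), 0.5)       # strong spatial autocorrelation with it
})

test_that("the emitted report re-reads to exactly the internal call set", {
  fx <- make_fixture("neighbor_driven", seed = 9)
  d <- withr::local_tempdir()
  paths <- write_fixture(fx, d)
  g <- read_fasta(paths["fasta"])
  back <- read_cytosine_report(paths["report"], g)
  cols <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads",
            "level", "status")
  expect_equal(as.list(as.data.frame(fx$calls))[cols],
               as.list(as.data.frame(back))[cols])
})

test_that("divergent pair plants disjoint motifs", {
  pair <- make_fixture("divergent_pair", seed = 11)
  ma <- pair$species_a$config$motif
  mb <- pair$species_b$config$motif
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_false(ma == mb)
  expect_false(ma == rc(mb)) # neither motif is the other's reverse complement
  # planted instances are recorded only for the species' own motif
  mta <- pair$species_a$features[pair$species_a$features$feature_type == "motif"]
  expect_true(all(vapply(seq_len(nrow(mta)), function(i)
    substr(unclass(pair$species_a$genome)[["chr1"]], mta$start[i] + 1,
           mta$end[i]) == ma, logical(1))))
})

test_that("unknown profile raises", {
  expect_error(make_fixture("nonexistent"), "arg")
})
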