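test_that("one-hot encoding follows the A,C,G,T column order", {
  g <- genome(c(chr1 = "AACGTA"))
  centers <- data.table::data.table(chrom = "chr1", pos = 3L, strand = "+")
  enc <- encode_windows(g, centers, W_s = 4)
  m <- matrix(enc$X[1, ], 4, 4) # W_s x 4, channel-major columns
  expect_equal(m, rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                        c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(enc$keys, "ACGT")
})

test_that("N bases give all-zero one-hot rows", {
  g <- genome(c(chr1 = "ANCGTA"))
  enc <- encode_windows(g, data.table::data.table(chrom = "chr1", pos = 3L,
                                                  strand = "+"), 4)
  m <- matrix(enc$X[1, ], 4, 4)
  expect_equal(m[1, ], c(0, 0, 0, 0)) # the N row
  expect_equal(sum(m), 3)
})

test_that("minus-strand windows equal the plus-strand encoding of the reverse complement", {
  g <- genome(c(chr1 = "AATTACGGTT"))
  # center C at pos 6 on - strand (G on +); its window [4,8) read 5'->3' on -
  encm <- encode_windows(g, data.table::data.table(chrom = "chr1", pos = 6L,
                                                   strand = "-"), 4)
  # reverse complement of the [4,8) slice ACGG is CCGT
  expect_equal(encm$keys, "CCGT")
  gp <- genome(c(chrP = "AAAACCGTAA"))
  encp <- encode_windows(gp, data.table::data.table(chrom = "chrP", pos = 6L,
                                                    strand = "+"), 4)
  expect_equal(encm$X, encp$X)
})

test_that("decoding the one-hot matrix recovers the genome slice", {
  withr::with_seed(11, {
    for (trial in 1:4) {
      g <- genome(stats::setNames(random_seq(120, trial + 50), "c"))
      codes_all <- strsplit(unclass(g)[["c"]], "")[[1]]
      pos <- sample(20:100, 6)
      enc <- encode_windows(g, data.table::data.table(chrom = "c", pos = pos,
                                                      strand = "+"), 20)
      for (i in seq_along(pos)) {
        slice <- paste(codes_all[(pos[i] - 10 + 1):(pos[i] + 10)],
                       collapse = "")
        expect_equal(enc$keys[i], slice)
        m <- matrix(enc$X[i, ], 20, 4)
        decoded <- c("A", "C", "G", "T")[apply(m, 1, which.max)]
        expect_equal(paste(decoded, collapse = ""), slice)
      }
    }
  })
})

test_that("annotation channels are strand-swapped and reversed on minus windows", {
  g <- genome(c(chr1 = strrep("A", 6), chr2 = strrep("G", 6)))
  feats <- data.table::data.table(chrom = "chr1", start = 2L, end = 4L,
                                  strand = "+", feature_type = "gene")
  tr <- build_tracks(feats, g)
  tr$chr2 <- tr$chr1 # same track content for the minus-strand chromosome
  # plus-strand center: channel 5 (own-strand gene) = gene_fwd positions
  encp <- encode_windows(g, data.table::data.table(chrom = "chr1", pos = 3L,
                                                   strand = "+"), 4, tr)
  mp <- matrix(encp$X[1, ], 4, 7)
  expect_equal(mp[, 5], c(0, 1, 1, 0)) # window [1,5): gene bits at 2,3
  expect_equal(mp[, 6], c(0, 0, 0, 0))
  # minus-strand center on chr2 (all G): same window, channels swap + reverse
  encm <- encode_windows(g, data.table::data.table(chrom = "chr2", pos = 3L,
                                                   strand = "-"), 4, tr)
  mm <- matrix(encm$X[1, ], 4, 7)
  expect_equal(mm[, 6], rev(c(0, 1, 1, 0)))
  expect_equal(mm[, 5], c(0, 0, 0, 0))
})

test_that("out-of-bounds windows are rejected, not padded", {
  g <- genome(c(chr1 = "ACGTACGTAC"))
  enc <- encode_windows(g, data.table::data.table(
    chrom = "chr1", pos = c(1L, 5L, 9L), strand = "+"), 8)
  expect_equal(enc$keep, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(enc$X), 1L)
})

test_that("neighbor vectors order covered neighbors by coordinate", {
  g <- genome(c(chr1 = strrep("C", 200)))
  pos <- c(50L, 90L, 100L, 105L, 130L)
  lev <- c(0.1, 0.9, 0.5, 0.2, 0.8)
  calls <- make_calls(g, rep("chr1", 5), pos, rep("+", 5),
                      meth = round(lev * 20), total = rep(20L, 5))
  nb <- build_neighbor_vectors(calls,
                               data.table::data.table(chrom = "chr1",
                                                      pos = 100L), W_p = 4)
  expect_true(nb$keep)
  expect_equal(nb$V[1, ], c(0.1, 0.9, 0.2, 0.8))
})

test_that("neighbor vectors reject centers without enough covered cytosines and exclude unknowns", {
  g <- genome(c(chr1 = strrep("C", 200)))
  # only one covered cytosine upstream of 100 (the other has coverage <= 10)
  calls <- make_calls(g, rep("chr1", 5), c(50L, 90L, 100L, 105L, 130L),
                      rep("+", 5), meth = c(5L, 5L, 5L, 5L, 5L),
                      total = c(10L, 20L, 20L, 20L, 20L))
  nb <- build_neighbor_vectors(calls,
                               data.table::data.table(chrom = "chr1",
                                                      pos = 100L), W_p = 4)
  expect_false(nb$keep)
  # default W_p is 20: 10 per side
  expect_equal(build_neighbor_vectors(calls,
    data.table::data.table(chrom = "chr1", pos = 100L))$W_p, 20L)
})

test_that("neighbor vectors never include unknown-status cytosines", {
  cfg <- sim_config(genome_length = 20000L, gene_density = 0,
                    coverage_lambda = 12, seed = 19)
  sim <- simulate_genome(cfg)
  me <- simulate_methylome(sim$genome, sim$features, cfg)
  covered_levels <- sort(unique(me$calls$level[me$calls$total_reads > 10]))
  centers <- me$calls[me$calls$status != "unknown"][1:50]
  nb <- build_neighbor_vectors(me$calls, centers, W_p = 6)
  expect_true(all(nb$V %in% covered_levels))
})

test_that("balanced sampling is exact, shrinks to availability, and reproducible", {
  cfg <- sim_config(genome_length = 30000L, gene_density = 0,
                    context_base_rates = c(CG = 0.5, CHG = 0.5, CHH = 0.5),
                    coverage_lambda = 20, seed = 23)
  sim <- simulate_genome(cfg)
  me <- simulate_methylome(sim$genome, sim$features, cfg)
  s <- sample_balanced(me$calls, "CG", 100, seed = 1)
  expect_equal(sum(s$label), 50)
  expect_equal(nrow(s), 100)
  expect_equal(unique(s$context), "CG") # single-context draws stay pure
  sall <- sample_balanced(me$calls, "ALL", 90, seed = 1)
  tab <- table(sall$context, sall$status)
  expect_true(all(tab == 15))
  # reproducibility
  expect_equal(sample_balanced(me$calls, "CG", 100, seed = 7),
               sample_balanced(me$calls, "CG", 100, seed = 7))
  # shrink-to-availability: request more than the scarce cell can serve
  scarce <- me$calls[me$calls$context == "CHH"]
  n_meth <- sum(scarce$status == "methylated")
  s2 <- sample_balanced(me$calls, "CHH", 2L * (n_meth + 10L), seed = 2)
  expect_equal(nrow(s2), 2L * n_meth)
  expect_equal(mean(s2$label), 0.5)
  # empty required cell raises
  nometh <- me$calls[me$calls$status != "methylated"]
  expect_error(sample_balanced(nometh, "CG", 10, seed = 1), "no available")
  expect_error(sample_balanced(me$calls, "ALL", 100, seed = 1),
               "divisible by 6")
})

test_that("80/10/10 split is stratified, deduplicated and deterministic", {
  ds <- toy_sequence_dataset(n = 1000, W_s = 20, seed = 5)
  sp <- split_80_10_10(ds, seed = 9)
  expect_equal(length(sp$train$y), 800)
  expect_equal(length(sp$validation$y), 100)
  expect_equal(length(sp$test$y), 100)
  expect_equal(mean(sp$train$y), 0.5)
  expect_equal(mean(sp$test$y), 0.5)
  # no key occurs in more than one partition
  expect_length(intersect(sp$train$keys, sp$test$keys), 0)
  expect_length(intersect(sp$train$keys, sp$validation$keys), 0)
  # duplicated sequences are removed before partitioning
  ds2 <- ds_subset(ds, c(1, 1:99))
  sp2 <- split_80_10_10(ds2, seed = 9)
  expect_equal(length(sp2$train$y) + length(sp2$validation$y) +
                 length(sp2$test$y), 99L)
  # determinism
  sp3 <- split_80_10_10(ds, seed = 9)
  expect_identical(sp$train$keys, sp3$train$keys)
  expect_error(split_80_10_10(ds_subset(ds, 1:5), seed = 1), "at least 10")
})

test_that("built datasets have exactly balanced labels", {
  fx <- make_fixture("annotation_driven", seed = 3)
  tr <- build_tracks(fx$features, fx$genome)
  for (ctx in c("CG", "ALL")) {
    n <- if (ctx == "ALL") 600L else 600L
    ds <- build_sequence_dataset(fx$genome, fx$calls, ctx, n, 50, tr,
                                 seed = 4)
    expect_equal(mean(ds$y), 0.5)
    expect_equal(ncol(ds$X), 50L * 7L)
  }
  nds <- build_neighbor_dataset(fx$calls, "CG", 400, 20, seed = 4)
  expect_equal(mean(nds$y), 0.5)
  expect_equal(ncol(nds$X), 20L)
  cds <- build_combined_dataset(fx$genome, fx$calls, "CG", 400, 50, tr, 20,
                                seed = 4)
  expect_equal(mean(cds$y), 0.5)
  expect_equal(ncol(cds$X2), 20L)
})
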