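# Synthetic genomes, annotations and methylomes with known structure, so that
# every other module is testable without real BS-Seq data. Fully reproducible
# under a seed.

#' Simulation configuration
#'
#' Defaults emulate a small plant-like chromosome: GC fraction 0.36, genes
#' covering about a third of the sequence, repeats about 15%, mean read depth
#' 15 with binomial read emission at level 0.9 for truly methylated and 0.1
#' for truly unmethylated cytosines (so the >=0.5 call recovers the true state
#' with high probability at that depth). Context base rates default to
#' plant-scale values (CG highest, CHH lowest). Each cytosine's methylation
#' probability is
#' `plogis(qlogis(base[context]) + gene_effect*in_gene + repeat_effect*in_repeat
#'  + motif_effect*near_motif + spatial_scale*z)`,
#' with z an AR(1) latent field over consecutive cytosines (autocorrelation
#' `rho`); with `motif_deterministic = TRUE` the state is instead exactly
#' `near_motif` (a noiseless rule with Bayes accuracy 1).
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param gc_fraction GC content of the i.i.d. background sequence.
#' @param gene_density,repeat_density Target fraction of the genome covered.
#' @param gene_length,repeat_length Length ranges (uniform) in bp.
#' @param motif Planted motif string, or `NULL` for none.
#' @param motif_spacing Minimum gap between planted motif instances; actual
#'   gaps are `motif_spacing + U(0, motif_spacing)`.
#' @param motif_effect_window Half-width in bp of the motif's effect zone.
#' @param context_base_rates Named P(methylated | context) for CG/CHG/CHH.
#' @param gene_effect,repeat_effect,motif_effect Logit shifts.
#' @param motif_deterministic If TRUE, state = near_motif exactly.
#' @param state_rule `"bernoulli"` draws the state from Bernoulli(p);
#'   `"latent_sign"` sets the state deterministically to 1 when the total
#'   logit is positive (used by the neighbor-driven fixture, where the label
#'   must be determined by, not merely correlated with, the latent field).
#' @param rho,spatial_scale AR(1) autocorrelation of the latent field over
#'   consecutive cytosines and its logit-scale weight.
#' @param coverage_lambda Mean (Poisson) read depth.
#' @param level_methylated,level_unmethylated True read-level methylation
#'   probabilities given the binary state.
#' @param seed Integer root seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, n_chroms = 1L,
                       gc_fraction = 0.36,
                       gene_density = 0.35, gene_length = c(1000L, 4000L),
                       repeat_density = 0.15, repeat_length = c(300L, 2000L),
                       motif = NULL, motif_spacing = 650L,
                       motif_effect_window = 50L,
                       context_base_rates = c(CG = 0.3, CHG = 0.15,
                                              CHH = 0.05),
                       gene_effect = 0, repeat_effect = 0, motif_effect = 0,
                       motif_deterministic = FALSE,
                       state_rule = c("bernoulli", "latent_sign"),
                       rho = 0, spatial_scale = 0,
                       coverage_lambda = 15, level_methylated = 0.9,
                       level_unmethylated = 0.1, seed = 1L) {
  stopifnot(genome_length > 0, n_chroms > 0,
            gc_fraction >= 0, gc_fraction <= 1,
            all(context_base_rates > 0), all(context_base_rates < 1),
            rho >= 0, rho < 1, coverage_lambda > 0,
            level_methylated >= 0, level_methylated <= 1,
            level_unmethylated >= 0, level_unmethylated <= 1)
  state_rule <- match.arg(state_rule)
  structure(as.list(environment()), class = "sim_config")
}

# place non-overlapping intervals to a target covered fraction
.place_intervals <- function(L, density, len_range, rng_ok = TRUE) {
  if (density <= 0) return(matrix(integer(), 0, 2))
  mean_len <- mean(len_range)
  mean_gap <- max(1, mean_len * (1 - density) / density)
  out <- list()
  cur <- ceiling(stats::rexp(1, 1 / mean_gap))
  while (TRUE) {
    len <- round(stats::runif(1, len_range[1], len_range[2]))
    if (cur + len > L) break
    out[[length(out) + 1L]] <- c(cur, cur + len)
    cur <- cur + len + ceiling(stats::rexp(1, 1 / mean_gap))
  }
  if (length(out) == 0L) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

#' Simulate a genome with gene, repeat and planted-motif annotation
#'
#' Bases are i.i.d. at the configured GC fraction; genes are non-overlapping
#' stranded intervals, repeats are placed independently (and may overlap
#' genes), and planted motif instances overwrite the background sequence at
#' recorded positions.
#'
#' @param config A [sim_config()].
#' @return List: `genome` ([genome()]), `features` (data.table of gene/repeat
#'   /motif intervals as in [read_gff3()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    gfrac <- config$gc_fraction
    probs <- c(A = (1 - gfrac) / 2, C = gfrac / 2, G = gfrac / 2,
               T = (1 - gfrac) / 2)
    seqs <- character(config$n_chroms)
    feats <- list()
    for (k in seq_len(config$n_chroms)) {
      L <- config$genome_length
      chrom <- paste0("chr", k)
      base_vec <- sample(names(probs), L, replace = TRUE, prob = probs)
      genes <- .place_intervals(L, config$gene_density, config$gene_length)
      if (nrow(genes))
        feats[[length(feats) + 1L]] <- data.table::data.table(
          chrom = chrom, start = genes[, 1], end = genes[, 2],
          strand = sample(c("+", "-"), nrow(genes), replace = TRUE),
          feature_type = "gene")
      reps <- .place_intervals(L, config$repeat_density, config$repeat_length)
      if (nrow(reps))
        feats[[length(feats) + 1L]] <- data.table::data.table(
          chrom = chrom, start = reps[, 1], end = reps[, 2], strand = ".",
          feature_type = "repeat")
      if (!is.null(config$motif)) {
        mlen <- nchar(config$motif)
        mbases <- strsplit(config$motif, "")[[1]]
        pos <- list()
        cur <- config$motif_spacing +
          round(stats::runif(1, 0, config$motif_spacing))
        while (cur + mlen <= L - config$motif_spacing) {
          pos[[length(pos) + 1L]] <- cur
          base_vec[(cur + 1L):(cur + mlen)] <- mbases
          cur <- cur + mlen + config$motif_spacing +
            round(stats::runif(1, 0, config$motif_spacing))
        }
        if (length(pos))
          feats[[length(feats) + 1L]] <- data.table::data.table(
            chrom = chrom, start = unlist(pos),
            end = unlist(pos) + mlen, strand = "+", feature_type = "motif")
      }
      seqs[k] <- paste(base_vec, collapse = "")
      names(seqs)[k] <- chrom
    }
    list(genome = genome(seqs),
         features = if (length(feats)) data.table::rbindlist(feats)
         else data.table::data.table(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     feature_type = character()))
  })
}

# membership of positions (0-based) in a set of [start,end) intervals,
# optionally dilated by `pad` on both sides
.in_intervals <- function(pos, ivs, pad = 0L) {
  if (nrow(ivs) == 0L) return(logical(length(pos)))
  ivs <- ivs[order(ivs$start)]
  # merge (intervals may touch after padding)
  st <- ivs$start - pad; en <- ivs$end + pad
  keep <- which(c(TRUE, st[-1] > cummax(en[-length(en)])))
  if (length(keep) < length(st)) {
    grp <- factor(findInterval(seq_along(st), keep),
                  levels = seq_along(keep))
    st <- as.numeric(tapply(st, grp, min))
    en <- as.numeric(tapply(en, grp, max))
  }
  i <- findInterval(pos, st)
  i > 0 & pos < en[pmax(i, 1)]
}

#' Simulate a methylome over a genome
#'
#' Enumerates every cytosine with defined context on both strands, draws its
#' true state from the logistic model described in [sim_config()], emits
#' Poisson read depth and binomial methylated-read counts, and returns both
#' the resulting call set and the ground truth.
#'
#' @param genome A [genome()] object.
#' @param features Feature table (gene/repeat/motif rows) as produced by
#'   [simulate_genome()].
#' @param config The [sim_config()] (its `seed` is offset internally so the
#'   genome and methylome draws are independent).
#' @return List: `calls` (a `methylation_calls` object) and `truth`
#'   (data.table with p_true, state, in_gene, in_repeat, near_motif).
#' @export
simulate_methylome <- function(genome, features, config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (ch in names(genome)) {
    codes <- chrom_codes(genome, ch)
    plus <- which(codes == 2L) - 1L
    minus <- which(codes == 3L) - 1L
    dt <- data.table::data.table(
      chrom = ch, pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))))
    dt <- dt[order(dt$pos)]
    dt$context <- assign_context(genome, ch, dt$pos, dt$strand)
    dt <- dt[!is.na(dt$context)]
    gch <- features[features$chrom == ch & features$feature_type == "gene"]
    rch <- features[features$chrom == ch & features$feature_type == "repeat"]
    mch <- features[features$chrom == ch & features$feature_type == "motif"]
    dt$in_gene <- .in_intervals(dt$pos, gch)
    dt$in_repeat <- .in_intervals(dt$pos, rch)
    dt$near_motif <- .in_intervals(dt$pos, mch,
                                   pad = config$motif_effect_window)
    rows[[length(rows) + 1L]] <- dt
  }
  truth <- data.table::rbindlist(rows)
  withr::with_seed(config$seed + 1L, {
    logit <- stats::qlogis(config$context_base_rates[truth$context]) +
      config$gene_effect * truth$in_gene +
      config$repeat_effect * truth$in_repeat +
      config$motif_effect * truth$near_motif
    if (config$spatial_scale > 0 && config$rho > 0) {
      z <- numeric(nrow(truth))
      start <- 1L
      for (ch in unique(truth$chrom)) {
        idx <- which(truth$chrom == ch)
        e <- stats::rnorm(length(idx))
        zc <- numeric(length(idx))
        zc[1] <- e[1]
        if (length(idx) > 1L)
          for (t in 2:length(idx))
            zc[t] <- config$rho * zc[t - 1] + sqrt(1 - config$rho^2) * e[t]
        z[idx] <- zc
      }
      logit <- logit + config$spatial_scale * z
    }
    truth$p_true <- stats::plogis(logit)
    if (isTRUE(config$motif_deterministic)) {
      truth$state <- as.integer(truth$near_motif)
      truth$p_true <- as.numeric(truth$state)
    } else if (identical(config$state_rule, "latent_sign")) {
      truth$state <- as.integer(logit > 0)
      truth$p_true <- as.numeric(truth$state)
    } else {
      truth$state <- stats::rbinom(nrow(truth), 1L, truth$p_true)
    }
    total <- stats::rpois(nrow(truth), config$coverage_lambda)
    lev <- ifelse(truth$state == 1L, config$level_methylated,
                  config$level_unmethylated)
    meth <- stats::rbinom(nrow(truth), total, lev)
  })
  calls <- new_call_set(data.table::data.table(
    chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
    context = truth$context, meth_reads = meth, total_reads = total),
    genome)
  list(calls = calls, truth = truth)
}

#' Canned fixture bundles
#'
#' Profiles with known, controllable signal used by the test suite:
#' \describe{
#'   \item{motif_driven}{No gene/repeat effects; the state is exactly
#'     "within 50 bp of a planted 8-mer" (deterministic rule, Bayes accuracy
#'     1), emitted at depth 30 with levels 0.95/0.05 so calls recover the
#'     state with high probability.}
#'   \item{annotation_driven}{P(methylated) is 0.9 inside genes and 0.1
#'     outside; no motif, no spatial field. Sequence alone carries no signal;
#'     annotation channels carry nearly all of it.}
#'   \item{neighbor_driven}{An i.i.d. sequence with a strongly autocorrelated
#'     latent field (rho 0.995); the state is the sign of the field
#'     (deterministic given the field), so neighboring methylation levels
#'     determine the center's label while the sequence carries none of it.}
#'   \item{divergent_pair}{Two motif_driven "species" with different planted
#'     8-mers (neither the reverse complement of the other), for cross-species
#'     grids.}
#' }
#'
#' @param profile One of the profile names above.
#' @param seed Integer root seed.
#' @return For `divergent_pair`, a named list of two bundles; otherwise one
#'   bundle: list(genome, features, calls, truth, config, profile).
#' @export
make_fixture <- function(profile = c("motif_driven", "annotation_driven",
                                     "neighbor_driven", "divergent_pair"),
                         seed = 1L) {
  profile <- match.arg(profile)
  one <- function(cfg, prof) {
    sim <- simulate_genome(cfg)
    me <- simulate_methylome(sim$genome, sim$features, cfg)
    list(genome = sim$genome, features = sim$features, calls = me$calls,
         truth = me$truth, config = cfg, profile = prof)
  }
  if (profile == "motif_driven") {
    one(sim_config(genome_length = 400000L, gc_fraction = 0.5,
                   gene_density = 0, repeat_density = 0,
                   motif = "GCGCATTA", motif_spacing = 650L,
                   motif_effect_window = 50L, motif_deterministic = TRUE,
                   coverage_lambda = 30, level_methylated = 0.95,
                   level_unmethylated = 0.05, seed = seed),
        profile)
  } else if (profile == "annotation_driven") {
    one(sim_config(genome_length = 200000L, gc_fraction = 0.4,
                   gene_density = 0.4, repeat_density = 0,
                   context_base_rates = c(CG = 0.1, CHG = 0.1, CHH = 0.1),
                   gene_effect = stats::qlogis(0.9) - stats::qlogis(0.1),
                   coverage_lambda = 30, seed = seed),
        profile)
  } else if (profile == "neighbor_driven") {
    one(sim_config(genome_length = 150000L, gc_fraction = 0.4,
                   gene_density = 0, repeat_density = 0,
                   context_base_rates = c(CG = 0.5, CHG = 0.5, CHH = 0.5),
                   state_rule = "latent_sign",
                   rho = 0.995, spatial_scale = 3,
                   coverage_lambda = 30, seed = seed),
        profile)
  } else {
    list(
      species_a = one(sim_config(genome_length = 200000L, gc_fraction = 0.5,
                                 gene_density = 0, repeat_density = 0,
                                 motif = "GCGCATTA", motif_spacing = 650L,
                                 motif_effect_window = 50L,
                                 motif_deterministic = TRUE,
                                 coverage_lambda = 30,
                                 level_methylated = 0.95,
                                 level_unmethylated = 0.05, seed = seed),
                      "divergent_pair"),
      species_b = one(sim_config(genome_length = 200000L, gc_fraction = 0.5,
                                 gene_density = 0, repeat_density = 0,
                                 motif = "TACGGTCA", motif_spacing = 650L,
                                 motif_effect_window = 50L,
                                 motif_deterministic = TRUE,
                                 coverage_lambda = 30,
                                 level_methylated = 0.95,
                                 level_unmethylated = 0.05,
                                 seed = seed + 1000L),
                      "divergent_pair"))
  }
}

#' Write a fixture bundle to disk
#'
#' Emits FASTA (genome), GFF3 (genes and motifs), BED (repeats), a
#' Bismark-style cytosine report, a ground-truth TSV and the configuration as
#' JSON. Byte-identical across runs for a fixed seed.
#'
#' @param fixture A bundle from [make_fixture()] (not the divergent pair).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "features.gff3"),
             bed = file.path(dir, "repeats.bed"),
             report = file.path(dir, "cytosine_report.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_fasta(fixture$genome, paths["fasta"])
  gf <- fixture$features[fixture$features$feature_type != "repeat"]
  lines <- c("##gff-version 3",
             if (nrow(gf)) sprintf("%s\tmethpred_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s%d",
                                   gf$chrom, gf$feature_type, gf$start + 1L,
                                   gf$end, gf$strand, gf$feature_type,
                                   seq_len(nrow(gf))))
  writeLines(lines, paths["gff3"])
  rf <- fixture$features[fixture$features$feature_type == "repeat"]
  writeLines(if (nrow(rf)) sprintf("%s\t%d\t%d\trepeat%d\t0\t.", rf$chrom,
                                   rf$start, rf$end, seq_len(nrow(rf)))
             else character(0), paths["bed"])
  write_cytosine_report(fixture$calls, paths["report"])
  data.table::fwrite(fixture$truth, paths["truth"], sep = "\t")
  cfg <- fixture$config
  cfg$context_base_rates <- as.list(cfg$context_base_rates)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
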