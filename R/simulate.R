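## Synthetic data with known ground truth: a random genome with planted
## piRNA cluster loci (each expressing a fixed set of discrete piRNA
## species with 1U/10A-style positional bias), planted miRNA hairpins,
## tRNAs, simple repeats and TE copies, and per-sample read sets for the
## roles the pipeline expects.  Oxidation is emulated by removing
## contaminant and degradation reads (unmethylated 3' ends) from the
## oxidized library while piRNA-species reads survive.

#' Simulation configuration
#'
#' Defaults emulate the statistical structure the pipeline assumes:
#' read lengths peaked at 28 nt within 25-32, germline libraries with a
#' 0.77 U bias at position 1 and 0.491 A at position 10, somatic
#' libraries biased toward G at position 1 and U at position 10, ~1% of
#' reads from miRNA/tRNA/degradation contaminants, and clusters spaced
#' well beyond the 1 kb merge distance so ground truth is unambiguous.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_scaffolds,scaffold_length Genome shape.
#' @param n_clusters Planted cluster loci.
#' @param cluster_length Min/max cluster locus length (bp).
#' @param cluster_spacing Minimum gap between planted loci (bp), must
#'   exceed the merge distance used downstream.
#' @param n_species Discrete piRNA species per cluster and pool.
#' @param species_sdlog,cluster_sdlog Log-normal abundance spread of
#'   species within clusters and of clusters within a library.
#' @param n_testis_only Clusters expressed in germline only; the rest are
#'   shared with soma.
#' @param somatic_level Somatic expression level of shared clusters,
#'   relative to testis.
#' @param n_up,n_down Shared clusters with a planted tumor fold change.
#' @param fold_change Planted tumor/control fold change (default 4.5).
#' @param replicate_sdlog Between-replicate log-normal noise on cluster
#'   abundances (pooled samples, hence small).
#' @param te_fraction Fraction of clusters carrying a TE copy.
#' @param n_tes,te_length TE library size and copy length range.
#' @param te_divergence Per-site mutation rate of planted TE copies.
#' @param n_mirnas,mirna_length,n_trnas,trna_length Contaminant source
#'   sequences planted in the genome.
#' @param n_simple_repeats Simple-repeat runs planted (masked regions).
#' @param depth Reads per library.
#' @param germline_bias,somatic_bias Named vectors of base probabilities
#'   at positions 1 and 10 (see defaults).
#' @param contaminant_fracs Read fractions drawn from miRNA windows, tRNA
#'   windows and random genome fragments.
#' @param oxidation_survival Fraction of contaminant/degradation reads
#'   surviving oxidation (piRNA species survive fully).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 3L,
                       scaffold_length = 200000L,
                       n_clusters = 20L,
                       cluster_length = c(800L, 2500L),
                       cluster_spacing = 5000L,
                       n_species = 40L,
                       species_sdlog = 1,
                       cluster_sdlog = 0.8,
                       n_testis_only = 6L,
                       somatic_level = 0.8,
                       n_up = 5L,
                       n_down = 5L,
                       fold_change = 4.5,
                       replicate_sdlog = 0.1,
                       te_fraction = 0.4,
                       n_tes = 12L,
                       te_length = c(300L, 600L),
                       te_divergence = 0.03,
                       n_mirnas = 20L,
                       mirna_length = 70L,
                       n_trnas = 10L,
                       trna_length = 75L,
                       n_simple_repeats = 15L,
                       depth = 1e5,
                       germline_bias = list(
                         p1 = c(A = 0.0767, C = 0.0767, G = 0.0766,
                                T = 0.77),
                         p10 = c(A = 0.491, C = 0.131, G = 0.18,
                                 T = 0.198)),
                       somatic_bias = list(
                         p1 = c(A = 0.167, C = 0.167, G = 0.5, T = 0.166),
                         p10 = c(A = 0.2, C = 0.2, G = 0.2, T = 0.4)),
                       contaminant_fracs = c(mirna = 0.001,
                                             trna = 0.0008,
                                             degradation = 0.0015),
                       oxidation_survival = 0.01) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_testis_only + cfg$n_up + cfg$n_down <= cfg$n_clusters,
            all(unlist(cfg$germline_bias) >= 0),
            all(unlist(cfg$somatic_bias) >= 0),
            cfg$oxidation_survival >= 0, cfg$oxidation_survival <= 1,
            sum(cfg$contaminant_fracs) < 1)
  structure(cfg, class = "sim_config")
}

## length distribution of simulated reads: mode at 28 nt
read_length_probs <- c(`25` = 0.05, `26` = 0.08, `27` = 0.15, `28` = 0.30,
                       `29` = 0.18, `30` = 0.12, `31` = 0.08, `32` = 0.04)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

## pick piRNA species (start, length, strand) inside one cluster locus so
## that read positions 1 and 10 follow the requested base probabilities;
## reads stay exact genome substrings because the bias lives in the
## choice of start position, not in edits to the read.
place_species <- function(chars, lo, hi, n_species, bias, sdlog) {
  out <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    len <- as.integer(sample(names(read_length_probs), 1L,
                             prob = read_length_probs))
    starts <- lo:(hi - len + 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      b1 <- chars[starts]
      b10 <- chars[starts + 9L]
    } else {
      b1 <- comp_base(chars[starts + len - 1L])
      b10 <- comp_base(chars[starts + len - 10L])
    }
    t1 <- sample(names(bias$p1), 1L, prob = bias$p1)
    t10 <- sample(names(bias$p10), 1L, prob = bias$p10)
    cand <- starts[b1 == t1 & b10 == t10]
    if (!length(cand)) cand <- starts[b1 == t1]
    if (!length(cand)) cand <- starts
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    out[[i]] <- data.frame(start = s, length = len, strand = strand,
                           weight = stats::rlnorm(1L, sdlog = sdlog))
  }
  do.call(rbind, out)
}

#' Simulate a genome with planted piRNA clusters and contaminant sources
#'
#' Deterministic given `config$seed`.  Cluster loci are placed with gaps
#' of at least `cluster_spacing`; a `te_fraction` subset carries a
#' (slightly diverged) TE copy from a generated classed TE library.
#' miRNA hairpins, tRNAs and simple-repeat runs are planted between
#' clusters and reported as contaminant references / repeat mask.
#'
#' @param config `sim_config` object.
#' @return list with `genome` (DNAStringSet) and `truth`: cluster
#'   GRanges (label, fold change, TE placement), species table, miRNA /
#'   tRNA / TE libraries, repeat mask and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  scaff_names <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
  chrs <- lapply(seq_len(cfg$n_scaffolds),
                 function(i) random_dna(cfg$scaffold_length))
  names(chrs) <- scaff_names

  ## TE library
  te_classes <- sample(c("DNA", "LINE", "SINE", "LTR", "unknown"),
                       cfg$n_tes, replace = TRUE,
                       prob = c(0.3, 0.25, 0.1, 0.2, 0.15))
  te_lib <- data.frame(
    te_id = sprintf("TE%02d", seq_len(cfg$n_tes)),
    class = te_classes,
    sequence = vapply(seq_len(cfg$n_tes), function(i)
      random_dna(sample(cfg$te_length[1L]:cfg$te_length[2L], 1L)), ""),
    stringsAsFactors = FALSE)

  ## cluster loci, round-robin across scaffolds, sequential with spacing
  per_scaffold <- split(seq_len(cfg$n_clusters),
                        rep(seq_len(cfg$n_scaffolds),
                            length.out = cfg$n_clusters))
  loci <- list()
  n_te_clusters <- round(cfg$te_fraction * cfg$n_clusters)
  if (n_te_clusters > cfg$n_tes)
    stop("need n_tes >= te_fraction * n_clusters: each TE-bearing ",
         "cluster carries a distinct TE family so that multi-mapping ",
         "cannot blur the ground-truth cluster assignment of reads")
  te_bearing <- sample(seq_len(cfg$n_clusters), n_te_clusters)
  te_assign <- sample(te_lib$te_id, n_te_clusters, replace = FALSE)
  names(te_assign) <- te_bearing
  for (sci in seq_along(per_scaffold)) {
    pos <- 2000L
    for (ci in per_scaffold[[sci]]) {
      len <- sample(cfg$cluster_length[1L]:cfg$cluster_length[2L], 1L)
      start <- pos + cfg$cluster_spacing +
        sample.int(2000L, 1L)  # jitter
      end <- start + len - 1L
      if (end > cfg$scaffold_length - 2000L)
        stop("clusters do not fit scaffold ", sci,
             "; increase scaffold_length or reduce n_clusters")
      loci[[ci]] <- data.frame(cluster = ci, scaffold = scaff_names[sci],
                               start = start, end = end)
      ## plant TE copy inside the locus
      if (as.character(ci) %in% names(te_assign)) {
        te <- te_lib[te_lib$te_id == te_assign[[as.character(ci)]], ]
        copy <- mutate_seq(te$sequence, cfg$te_divergence)
        if (nchar(copy) > len) copy <- substr(copy, 1L, len)
        off <- start + sample.int(max(1L, len - nchar(copy)), 1L) - 1L
        substr(chrs[[scaff_names[sci]]], off, off + nchar(copy) - 1L) <- copy
      }
      pos <- end
    }
  }
  loci <- do.call(rbind, loci)

  ## labels and planted fold changes
  labels <- rep("shared", cfg$n_clusters)
  labels[sample(seq_len(cfg$n_clusters), cfg$n_testis_only)] <- "testis_only"
  shared_idx <- which(labels == "shared")
  fc <- rep(1, cfg$n_clusters)
  de_pick <- sample(shared_idx, cfg$n_up + cfg$n_down)
  fc[de_pick[seq_len(cfg$n_up)]] <- cfg$fold_change
  fc[de_pick[cfg$n_up + seq_len(cfg$n_down)]] <- 1 / cfg$fold_change

  ## contaminant sources and simple repeats planted between clusters
  plant_between <- function(n, make_seq) {
    planted <- list()
    for (i in seq_len(n)) {
      sc <- sample(scaff_names, 1L)
      seq <- make_seq()
      repeat {
        start <- sample.int(cfg$scaffold_length - nchar(seq) - 100L, 1L)
        iv <- c(start, start + nchar(seq) - 1L)
        ov <- loci$scaffold == sc & loci$start - 200L <= iv[2L] &
          loci$end + 200L >= iv[1L]
        if (!any(ov)) break
      }
      substr(chrs[[sc]], start, start + nchar(seq) - 1L) <- seq
      planted[[i]] <- data.frame(scaffold = sc, start = start,
                                 end = start + nchar(seq) - 1L,
                                 sequence = seq)
    }
    do.call(rbind, planted)
  }
  mirnas <- plant_between(cfg$n_mirnas,
                          function() random_dna(cfg$mirna_length))
  trnas <- plant_between(cfg$n_trnas,
                         function() random_dna(cfg$trna_length))
  reps <- plant_between(cfg$n_simple_repeats, function() {
    unit <- sample(c("TA", "CA", "AAG", "AT"), 1L)
    strrep(unit, ceiling(80 / nchar(unit)))
  })
  mask <- GenomicRanges::GRanges(
    seqnames = reps$scaffold,
    ranges = IRanges::IRanges(start = reps$start, end = reps$end),
    strand = "+")
  S4Vectors::mcols(mask)$repeat_name <- sprintf("SR%02d", seq_len(nrow(reps)))
  S4Vectors::mcols(mask)$repeat_class <- "Simple_repeat"

  ## piRNA species per cluster: a germline pool for every cluster and a
  ## somatic pool for shared clusters
  cluster_weight <- stats::rlnorm(cfg$n_clusters, sdlog = cfg$cluster_sdlog)
  species <- list()
  char_cache <- lapply(chrs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  for (ci in seq_len(cfg$n_clusters)) {
    row <- loci[loci$cluster == ci, ]
    chars <- char_cache[[row$scaffold]]
    pools <- if (labels[ci] == "shared") c("germline", "somatic")
             else "germline"
    for (pool in pools) {
      bias <- if (pool == "germline") cfg$germline_bias else cfg$somatic_bias
      sp <- place_species(chars, row$start, row$end, cfg$n_species, bias,
                          cfg$species_sdlog)
      sp$cluster <- ci
      sp$pool <- pool
      sp$scaffold <- row$scaffold
      species[[length(species) + 1L]] <- sp
    }
  }
  species <- do.call(rbind, species)
  species$sequence <- vapply(seq_len(nrow(species)), function(i) {
    s <- substring(chrs[[species$scaffold[i]]], species$start[i],
                   species$start[i] + species$length[i] - 1L)
    if (species$strand[i] == "-") revcomp(s) else s
  }, "")

  ## ground-truth cluster intervals: span of the planted species
  spans <- do.call(rbind, lapply(seq_len(cfg$n_clusters), function(ci) {
    sp <- species[species$cluster == ci, ]
    data.frame(cluster = ci, scaffold = sp$scaffold[1L],
               start = min(sp$start),
               end = max(sp$start + sp$length - 1L))
  }))
  clusters <- GenomicRanges::GRanges(
    seqnames = spans$scaffold,
    ranges = IRanges::IRanges(start = spans$start, end = spans$end),
    strand = "*")
  S4Vectors::mcols(clusters)$cluster <- spans$cluster
  S4Vectors::mcols(clusters)$label <- labels
  S4Vectors::mcols(clusters)$fold_change <- fc
  S4Vectors::mcols(clusters)$weight <- cluster_weight
  S4Vectors::mcols(clusters)$te_id <- NA_character_
  S4Vectors::mcols(clusters)$te_id[te_bearing] <- unname(te_assign)

  list(genome = Biostrings::DNAStringSet(unlist(chrs)),
       truth = list(clusters = clusters, species = species,
                    mirna = stats::setNames(mirnas$sequence,
                                            sprintf("mir-%d",
                                                    seq_len(nrow(mirnas)))),
                    trna = stats::setNames(trnas$sequence,
                                           sprintf("trna-%d",
                                                   seq_len(nrow(trnas)))),
                    te_library = te_lib, mask = mask, config = cfg))
}

## role-specific cluster abundance weights (NA rows excluded from pool)
role_cluster_weights <- function(truth, role, cfg) {
  cl <- truth$clusters
  w <- S4Vectors::mcols(cl)$weight
  lab <- S4Vectors::mcols(cl)$label
  fc <- S4Vectors::mcols(cl)$fold_change
  switch(role,
         oxidized_testis = ,
         testis = ,
         ovary = list(pool = "germline", w = w),
         somatic_control = list(
           pool = "somatic",
           w = ifelse(lab == "shared", cfg$somatic_level * w, 0)),
         tumor = list(
           pool = "somatic",
           w = ifelse(lab == "shared", cfg$somatic_level * w * fc, 0)),
         stop("unknown role: ", role))
}

#' Simulate one small-RNA library
#'
#' Reads are drawn from the planted piRNA species of the role's pool
#' (germline pools for testis/ovary/oxidized libraries, somatic pools —
#' shared clusters only — for somatic and tumor libraries, the latter
#' with the planted fold changes applied) plus miRNA-window, tRNA-window
#' and random-genome degradation contaminants.  In the oxidized library
#' contaminants are subsampled to `oxidation_survival` while species
#' reads survive.  Deterministic given `seed`.
#'
#' @param sim Output of [simulate_genome()].
#' @param role Sample role.
#' @param sample_id Sample identifier.
#' @param seed Per-sample seed.
#' @param depth Library depth (default from the config).
#' @return list with `reads` (collapsed data.frame) and
#'   `expected_counts` (per-cluster expected piRNA read counts).
#' @export
simulate_sample <- function(sim, role, sample_id, seed,
                            depth = sim$truth$config$depth) {
  cfg <- sim$truth$config
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  truth <- sim$truth
  rw <- role_cluster_weights(truth, role, cfg)

  contam <- cfg$contaminant_fracs
  if (role == "oxidized_testis") contam <- contam * cfg$oxidation_survival
  n_cat <- stats::rmultinom(1L, depth,
                            c(pirna = 1 - sum(contam), contam))[, 1L]

  ## piRNA reads: joint species draw (cluster weight x species weight,
  ## with replicate-level noise on cluster abundances)
  sp <- truth$species[truth$species$pool == rw$pool, ]
  cw <- rw$w * stats::rlnorm(length(rw$w), sdlog = cfg$replicate_sdlog)
  joint <- cw[sp$cluster] * sp$weight
  counts <- stats::rmultinom(1L, n_cat[["pirna"]], joint)[, 1L]
  reads_sp <- data.frame(sequence = sp$sequence[counts > 0],
                         count = counts[counts > 0])
  expected <- n_cat[["pirna"]] * tapply(joint / sum(joint), sp$cluster, sum)
  exp_counts <- stats::setNames(numeric(length(truth$clusters)),
                                seq_along(truth$clusters))
  exp_counts[names(expected)] <- expected

  window_reads <- function(sources, n) {
    if (n == 0L) return(character())
    vapply(seq_len(n), function(i) {
      src <- sources[[sample.int(length(sources), 1L)]]
      len <- as.integer(sample(names(read_length_probs), 1L,
                               prob = read_length_probs))
      len <- min(len, nchar(src))
      start <- sample.int(nchar(src) - len + 1L, 1L)
      s <- substr(src, start, start + len - 1L)
      if (stats::runif(1L) < 0.5) revcomp(s) else s
    }, "")
  }
  chr <- as.character(sim$genome)
  degradation_reads <- function(n) {
    if (n == 0L) return(character())
    vapply(seq_len(n), function(i) {
      sc <- sample(names(chr), 1L)
      len <- as.integer(sample(names(read_length_probs), 1L,
                               prob = read_length_probs))
      start <- sample.int(nchar(chr[[sc]]) - len + 1L, 1L)
      s <- substr(chr[[sc]], start, start + len - 1L)
      if (stats::runif(1L) < 0.5) revcomp(s) else s
    }, "")
  }
  contam_seqs <- c(window_reads(truth$mirna, n_cat[["mirna"]]),
                   window_reads(truth$trna, n_cat[["trna"]]),
                   degradation_reads(n_cat[["degradation"]]))

  reads <- collapse_reads(c(reads_sp$sequence, contam_seqs),
                          counts = c(reads_sp$count,
                                     rep(1L, length(contam_seqs))),
                          sample_id = sample_id)
  list(reads = reads, expected_counts = exp_counts)
}

#' Simulate a full experiment
#'
#' Genome plus six libraries: one oxidized testis, one untreated testis,
#' two somatic controls (`HP`-like) and two tumors (`IM`-like).
#' Per-sample seeds are derived from the master seed.
#'
#' @param config `sim_config` object.
#' @return list with `genome`, `truth`, `sample_sheet`, `reads` (one
#'   collapsed data.frame covering all samples) and `expected_counts`
#'   (clusters x samples matrix of expected piRNA read counts).
#' @export
simulate_experiment <- function(config) {
  sim <- simulate_genome(config)
  sheet <- data.frame(
    sample_id = c("ox_testis", "testis", "hp1", "hp2", "im1", "im2"),
    role = c("oxidized_testis", "testis", "somatic_control",
             "somatic_control", "tumor", "tumor"),
    group = c("reference", "reference", "HP", "HP", "IM", "IM"),
    stringsAsFactors = FALSE)
  reads <- list()
  expected <- matrix(0, nrow = length(sim$truth$clusters),
                     ncol = nrow(sheet),
                     dimnames = list(NULL, sheet$sample_id))
  for (i in seq_len(nrow(sheet))) {
    smp <- simulate_sample(sim, sheet$role[i], sheet$sample_id[i],
                           seed = config$seed + 7919L * i)
    reads[[i]] <- smp$reads
    expected[, i] <- smp$expected_counts
  }
  list(genome = sim$genome, truth = sim$truth, sample_sheet = sheet,
       reads = do.call(rbind, reads), expected_counts = expected)
}
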