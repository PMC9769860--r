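#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a multi-region gut-microbiome survey with an
#' optional longitudinal arm: regions contain locations, locations contain
#' participants, and each participant is sampled once (`months = 0`) or
#' monthly for `months` months. Taxon abundances follow a compositional
#' log-normal model: softmax of (taxon base log-mean + region offset +
#' location offset + individual offset + cumulative monthly random-walk
#' drift + per-sample noise), scaled to percent. Effects are additive on
#' the log scale and individually switch-off-able, so planted effect-size
#' orderings are directly testable. Core taxa are guaranteed to stay at or
#' above `core_floor` percent in every sample; the remaining taxa are
#' transient, flickering in and out of detection.
#'
#' Defaults mirror a phase-II-style design: 4 regions x 3 locations x 5
#' participants cross-sectionally, 150 genera of which 30 are core, with
#' the individual effect dominating the regional one and a minority of
#' Prevotella-dominant (ET_P) participants.
#'
#' @param n_regions,locations_per_region,participants_per_location design
#'   grid sizes.
#' @param n_taxa,n_core_taxa genus counts (core taxa are planted present in
#'   every sample).
#' @param months 0 for a cross-sectional cohort, otherwise the number of
#'   monthly time points per participant.
#' @param region_effect_sd,location_effect_sd,individual_effect_sd,noise_sd
#'   log-scale standard deviations of the additive effects.
#' @param drift_sd per-month log-scale random-walk step SD (temporal drift).
#' @param enterotype_fraction proportion of participants planted as
#'   Prevotella-dominant (ET_P); the boost rides on the individual effect,
#'   so it vanishes when `individual_effect_sd = 0`.
#' @param presence_prob target probability that a transient taxon is
#'   detected in a given sample.
#' @param core_floor detection floor (percent) that every core taxon is
#'   guaranteed to meet in every sample.
#' @param yogurt_effect log-scale boost of the Bifidobacterium-like taxon in
#'   yogurt-consuming participants.
#' @param seed integer; the single source of randomness.
#' @export
cohort_config <- function(n_regions = 4L, locations_per_region = 3L,
                          participants_per_location = 5L,
                          n_taxa = 150L, n_core_taxa = 30L, months = 0L,
                          region_effect_sd = 0.3, location_effect_sd = 0.15,
                          individual_effect_sd = 1.0, noise_sd = 0.3,
                          drift_sd = 0.15, enterotype_fraction = 0.15,
                          presence_prob = 0.6, core_floor = 0.01,
                          yogurt_effect = 0.5, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              locations_per_region = as.integer(locations_per_region),
              participants_per_location = as.integer(participants_per_location),
              n_taxa = as.integer(n_taxa), n_core_taxa = as.integer(n_core_taxa),
              months = as.integer(months),
              region_effect_sd = region_effect_sd,
              location_effect_sd = location_effect_sd,
              individual_effect_sd = individual_effect_sd,
              noise_sd = noise_sd, drift_sd = drift_sd,
              enterotype_fraction = enterotype_fraction,
              presence_prob = presence_prob, core_floor = core_floor,
              yogurt_effect = yogurt_effect, seed = as.integer(seed))
  sds <- c("region_effect_sd", "location_effect_sd", "individual_effect_sd",
           "noise_sd", "drift_sd")
  if (any(unlist(cfg[sds]) < 0)) stop("effect SDs must be >= 0")
  if (cfg$n_core_taxa > cfg$n_taxa) stop("n_core_taxa must be <= n_taxa")
  if (cfg$n_core_taxa < 2) stop("need at least the two marker genera as core taxa")
  if (cfg$enterotype_fraction < 0 || cfg$enterotype_fraction > 1)
    stop("enterotype_fraction must lie in [0, 1]")
  if (cfg$months > 0 && cfg$participants_per_location == 0)
    stop("months > 0 requires participants_per_location > 0")
  structure(cfg, class = "cohort_config")
}

#' Simulate a gut-microbiome cohort
#'
#' Generates the abundance table and metadata described by a
#' [cohort_config()]. The first three taxa are named Bacteroides,
#' Prevotella and Bifidobacterium and are always core; Bacteroides gets the
#' highest base log-mean so the cohort is Bacteroides-dominated, ET_P
#' participants get a Prevotella boost through their individual effect, and
#' yogurt-consuming participants get a Bifidobacterium boost. Transient
#' (non-core) taxa are present in a sample only when their latent
#' log-abundance clears a taxon-specific threshold calibrated to
#' `presence_prob`, so switching all randomness off makes every sample
#' identical. Any transient taxon that would satisfy the core rule by
#' chance is knocked out of one sample, keeping the planted core set
#' exactly recoverable. Output is a pure function of `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `abundance` (an [abundance_table()]), `metadata` (a
#'   `sample_metadata` data.frame) and `truth` (planted core taxa,
#'   per-participant enterotype, and the config).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)

  nt <- cfg$n_taxa
  ncore <- cfg$n_core_taxa
  taxa <- c("Bacteroides", "Prevotella", "Bifidobacterium",
            if (ncore > 3) sprintf("CoreGenus%02d", seq_len(ncore - 3)),
            if (nt > ncore) sprintf("Genus%03d", seq_len(nt - ncore)))[seq_len(nt)]
  core_idx <- seq_len(ncore)

  base <- numeric(nt)
  base[1] <- 3.5                       # Bacteroides dominates
  base[2] <- 1.5                       # Prevotella: core but subdominant in ET_B
  base[3] <- 1.0                       # Bifidobacterium
  if (ncore > 3) base[4:ncore] <- stats::rnorm(ncore - 3, 1.2, 0.8)
  if (nt > ncore) base[(ncore + 1):nt] <- stats::rnorm(nt - ncore, -1.0, 1.0)

  # design grid
  regions <- sprintf("R%d", seq_len(cfg$n_regions))
  grid <- expand.grid(p = seq_len(cfg$participants_per_location),
                      loc = seq_len(cfg$locations_per_region),
                      reg = seq_len(cfg$n_regions))
  participants <- data.frame(
    participant_id = sprintf("R%dL%dP%02d", grid$reg, grid$loc, grid$p),
    region = regions[grid$reg],
    location = sprintf("R%dL%d", grid$reg, grid$loc),
    stringsAsFactors = FALSE)
  np <- nrow(participants)
  if (np == 0) stop("empty design grid")

  # participant-level attributes
  participants$sex <- sample(c("F", "M"), np, replace = TRUE)
  participants$age <- round(stats::runif(np, 22, 65))
  participants$bmi <- round(stats::rnorm(np, 23, 2.5), 1)
  participants$yogurt <- sample(c(TRUE, FALSE), np, replace = TRUE)
  participants$alcohol <- sample(c(TRUE, FALSE), np, replace = TRUE)
  participants$smoking <- sample(c(TRUE, FALSE), np, replace = TRUE, prob = c(0.25, 0.75))
  participants$exercise <- sample(c(TRUE, FALSE), np, replace = TRUE)
  participants$enterotype <- ifelse(stats::runif(np) < cfg$enterotype_fraction,
                                    "ET_P", "ET_B")

  # taxon-level random effects
  reg_off <- matrix(stats::rnorm(cfg$n_regions * nt, 0, cfg$region_effect_sd),
                    cfg$n_regions, nt)
  loc_ids <- unique(participants$location)
  loc_off <- matrix(stats::rnorm(length(loc_ids) * nt, 0, cfg$location_effect_sd),
                    length(loc_ids), nt, dimnames = list(loc_ids, NULL))
  ind_off <- matrix(stats::rnorm(np * nt, 0, cfg$individual_effect_sd), np, nt)
  # enterotype rides on the individual effect: off when that effect is off
  etp <- participants$enterotype == "ET_P"
  ind_off[etp, 2] <- ind_off[etp, 2] + 4.0 * cfg$individual_effect_sd
  ind_off[participants$yogurt, 3] <- ind_off[participants$yogurt, 3] +
    cfg$yogurt_effect * cfg$individual_effect_sd

  months <- if (cfg$months > 0) seq_len(cfg$months) else NA_integer_
  n_per <- max(cfg$months, 1L)
  n_samples <- np * n_per

  meta <- participants[rep(seq_len(np), each = n_per), , drop = FALSE]
  meta$month_index <- rep(months, times = np)
  meta$sample_id <- if (cfg$months > 0)
    sprintf("%sM%02d", meta$participant_id, meta$month_index) else meta$participant_id
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "participant_id", "region", "location",
                   "month_index", "sex", "age", "bmi", "yogurt", "alcohol",
                   "smoking", "exercise", "enterotype")]

  # latent log-abundance per sample x taxon
  pidx <- rep(seq_len(np), each = n_per)
  lat <- matrix(base, n_samples, nt, byrow = TRUE) +
    reg_off[match(meta$region, regions), , drop = FALSE] +
    loc_off[meta$location, , drop = FALSE] +
    ind_off[pidx, , drop = FALSE]
  if (cfg$months > 0 && cfg$drift_sd > 0) {
    for (p in seq_len(np)) {
      steps <- matrix(stats::rnorm(cfg$months * nt, 0, cfg$drift_sd), cfg$months, nt)
      lat[pidx == p, ] <- lat[pidx == p, ] + apply(steps, 2, cumsum)
    }
  }
  lat <- lat + matrix(stats::rnorm(n_samples * nt, 0, cfg$noise_sd), n_samples, nt)

  # transient taxa: detected only when the latent clears a calibrated cutoff
  sd_tot <- sqrt(cfg$region_effect_sd^2 + cfg$location_effect_sd^2 +
                 cfg$individual_effect_sd^2 + cfg$noise_sd^2 +
                 cfg$drift_sd^2 * max(cfg$months, 0) / 2)
  w <- exp(lat)
  if (nt > ncore) {
    cutoff <- base - stats::qnorm(cfg$presence_prob) * sd_tot
    tr <- (ncore + 1):nt
    mask <- lat[, tr, drop = FALSE] >= matrix(cutoff[tr], n_samples, length(tr), byrow = TRUE)
    w[, tr] <- w[, tr, drop = FALSE] * mask
  }

  vals <- 100 * w / rowSums(w)
  dimnames(vals) <- list(meta$sample_id, taxa)

  # guarantee the planted core floor, renormalizing after each lift
  for (it in 1:5) {
    low <- vals[, core_idx, drop = FALSE] < cfg$core_floor
    if (!any(low)) break
    vals[, core_idx][low] <- cfg$core_floor * 1.5
    vals <- 100 * vals / rowSums(vals)
  }

  # a transient taxon satisfying the core rule by chance loses one sample;
  # in the fully deterministic regime (all SDs zero) presence is constant by
  # design and the knockout is skipped so identical samples stay identical
  if (nt > ncore && n_samples > 1 && sd_tot > 0) {
    for (t in (ncore + 1):nt) {
      if (all(vals[, t] >= cfg$core_floor)) {
        vals[sample.int(n_samples, 1), t] <- 0
      }
    }
    vals <- 100 * vals / rowSums(vals)
  }

  list(abundance = abundance_table(vals, rank = "genus", sum_tolerance = 1e-6),
       metadata = validate_metadata(meta),
       truth = list(core_taxa = taxa[core_idx],
                    enterotype = stats::setNames(participants$enterotype,
                                                 participants$participant_id),
                    config = cfg))
}

#' Plant per-sample gene truth for the screening simulator
#'
#' Assigns each gene a persistence label and realizes per-sample presence
#' accordingly: `cohort_stable` genes are present in every sample of every
#' participant, `individual_stable` genes in every sample of a random
#' subset of participants, `transient` genes in a scattered subset of
#' samples (never all samples of any multi-sample participant), and
#' `absent` genes nowhere. Present entries get a planted merged-coverage
#' fraction and identity; absent entries get coverage 0.
#'
#' @param meta `sample_metadata` (participant structure drives the labels).
#' @param catalog a [gene_catalog()].
#' @param p_cohort,p_individual,p_transient label probabilities (remainder
#'   is absent).
#' @param coverage_range,identity_range uniform ranges for planted coverage
#'   fraction and identity percent of present entries.
#' @param seed integer seed.
#' @return a `gene_truth` data.frame: sample_id, gene_id, coverage,
#'   identity, label; with a per-gene `labels` attribute.
#' @export
simulate_gene_truth <- function(meta, catalog, p_cohort = 0.07,
                                p_individual = 0.3, p_transient = 0.4,
                                coverage_range = c(0.93, 1),
                                identity_range = c(85, 99.5), seed = 1L) {
  set.seed(seed)
  samples <- meta$sample_id
  parts <- split(samples, meta$participant_id)
  genes <- catalog$gene_id
  lab <- sample(c("cohort_stable", "individual_stable", "transient", "absent"),
                length(genes), replace = TRUE,
                prob = c(p_cohort, p_individual, p_transient,
                         max(0, 1 - p_cohort - p_individual - p_transient)))
  pres <- matrix(FALSE, length(samples), length(genes),
                 dimnames = list(samples, genes))
  for (g in seq_along(genes)) {
    if (lab[g] == "cohort_stable") {
      pres[, g] <- TRUE
    } else if (lab[g] == "individual_stable") {
      # stable in some but never all participants (that would be cohort_stable)
      n_who <- min(max(1, stats::rbinom(1, length(parts), 0.3)),
                   max(1, length(parts) - 1))
      who <- sample(names(parts), n_who)
      pres[unlist(parts[who]), g] <- TRUE
    } else if (lab[g] == "transient") {
      n_on <- max(1, stats::rbinom(1, length(samples), 0.25))
      pres[sample(samples, n_on), g] <- TRUE
      # never all samples of a multi-sample participant: that would be stable
      for (p in parts) {
        if (length(p) > 1 && all(pres[p, g])) pres[sample(p, 1), g] <- FALSE
      }
      if (!any(pres[, g])) pres[sample(samples, 1), g] <- TRUE
    }
  }
  idx <- which(pres, arr.ind = TRUE)
  truth <- data.frame(
    sample_id = rep(samples, times = length(genes)),
    gene_id = rep(genes, each = length(samples)),
    coverage = 0, identity = NA_real_,
    label = rep(lab, each = length(samples)),
    stringsAsFactors = FALSE)
  on <- as.vector(pres)
  truth$coverage[on] <- stats::runif(sum(on), coverage_range[1], coverage_range[2])
  truth$identity[on] <- stats::runif(sum(on), identity_range[1], identity_range[2])
  attr(truth, "gene_labels") <- stats::setNames(lab, genes)
  class(truth) <- c("gene_truth", class(truth))
  truth
}

#' Emit alignment hits realizing planted gene coverage
#'
#' For each (sample, gene) row of `truth` with planted coverage `c`, emits
#' reads tiling the first `round(c * length)` bases of the gene: full
#' `read_len` reads laid end to end, with a final overlapping (or, for
#' short targets, clipped) read so the merged interval length equals the
#' target exactly. Hit identities are drawn around the planted identity.
#' Rows with coverage 0 emit nothing.
#'
#' @param truth a `gene_truth` data.frame from [simulate_gene_truth()] (or
#'   built by hand with the same columns).
#' @param catalog a [gene_catalog()].
#' @param read_len read length in bp (default 150).
#' @param identity_sd SD of per-hit identity around the planted value.
#' @param seed integer seed.
#' @return data.frame of hits with a `sample_id` column plus the
#'   [alignment_hits()] columns.
#' @export
simulate_gene_hits <- function(truth, catalog, read_len = 150L,
                               identity_sd = 0.5, seed = 1L) {
  set.seed(seed)
  glen <- stats::setNames(catalog$length_bp, catalog$gene_id)
  if (any(!truth$gene_id %in% names(glen)))
    stop("truth references genes absent from catalog")
  if (any(read_len > glen[unique(truth$gene_id[truth$coverage > 0])]))
    stop("read_len exceeds the length of a targeted gene")
  rows <- which(truth$coverage > 0)
  out <- vector("list", length(rows))
  for (r in seq_along(rows)) {
    i <- rows[r]
    L <- glen[[truth$gene_id[i]]]
    B <- max(1L, min(L, as.integer(round(truth$coverage[i] * L))))
    if (B >= read_len) {
      starts <- seq.int(1L, B - read_len + 1L, by = read_len)
      if (max(starts) + read_len - 1L < B) starts <- c(starts, B - read_len + 1L)
      ends <- pmin(starts + read_len - 1L, B)
    } else {
      starts <- 1L; ends <- B
    }
    ident <- pmin(100, pmax(0, stats::rnorm(length(starts), truth$identity[i],
                                            identity_sd)))
    out[[r]] <- data.frame(
      sample_id = truth$sample_id[i],
      read_id = sprintf("%s|%s|r%d", truth$sample_id[i], truth$gene_id[i],
                        seq_along(starts)),
      gene_id = truth$gene_id[i], identity_pct = ident,
      ref_start = starts, ref_end = ends, stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), read_id = character(0),
               gene_id = character(0), identity_pct = numeric(0),
               ref_start = integer(0), ref_end = integer(0))
  rownames(hits) <- NULL
  hits
}

#' Simulate a small resistance/virulence gene catalog
#'
#' Gene ids are built from common resistance-family prefixes so that the
#' packaged prefix class map assigns them drug classes; sequences are
#' random and returned only when `with_sequences = TRUE`.
#'
#' @param n_genes number of genes.
#' @param length_range gene length range in bp.
#' @param seed integer seed.
#' @param with_sequences also return a named character vector of sequences.
#' @export
simulate_gene_catalog <- function(n_genes = 30L, length_range = c(500L, 2500L),
                                  seed = 1L, with_sequences = FALSE) {
  set.seed(seed)
  prefixes <- c("bla", "tet", "erm", "aph", "aac", "qnr", "sul", "van",
                "cat", "dfr", "mcr", "fos")
  ids <- sprintf("%sSYN-%d_1_SYN%04d",
                 sample(prefixes, n_genes, replace = TRUE),
                 seq_len(n_genes), seq_len(n_genes))
  len <- sample(seq(length_range[1], length_range[2]), n_genes, replace = TRUE)
  cat <- gene_catalog(ids, len, assign_drug_class(ids, read_class_map()))
  if (!with_sequences) return(cat)
  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  list(catalog = cat, sequences = stats::setNames(seqs, ids))
}

#' Simulate two k-mer sets with controlled containment
#'
#' Builds two sets of `universe_size` distinct canonical k-mers whose exact
#' containment `|A n B| / min(|A|, |B|)` equals `containment` to within
#' `1 / universe_size` — the oracle against which sketch-based genetic
#' similarity is validated.
#'
#' @param universe_size number of k-mers per set.
#' @param containment target containment in `[0, 1]`.
#' @param seed integer seed.
#' @param k k-mer length (default 31).
#' @return list with character sets `a` and `b` and the realized
#'   `containment`.
#' @export
simulate_sequence_sets <- function(universe_size = 1e5, containment = 0.5,
                                   seed = 1L, k = 31L) {
  if (containment < 0 || containment > 1)
    stop("containment must lie in [0, 1]")
  n <- as.integer(universe_size)
  if (n < 1) stop("universe_size must be >= 1")
  shared <- as.integer(round(containment * n))
  set.seed(seed)
  u <- cpp_random_kmer_universe(2L * n - shared, as.integer(k))
  a <- u[seq_len(n)]
  b <- u[seq.int(n - shared + 1L, 2L * n - shared)]
  list(a = a, b = b, containment = shared / n)
}

#' Write the synthetic cohort to the pipeline's on-disk formats
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (abundance matrix TSV with taxa as
#'   rows, metadata TSV).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab_path <- file.path(dir, "abundance.tsv")
  mat <- t(unclass(sim$abundance))
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, ab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance = ab_path, metadata = meta_path))
}
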