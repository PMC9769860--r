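#' Assemble a pipeline run configuration
#'
#' Collects every tunable the pipeline uses: the screening and community
#' thresholds (each defaulting to its conventional value), the sketch
#' parameters of the genetic-similarity statistic, permutation and seed
#' settings, and either paths to real inputs or a [cohort_config()] for a
#' fully synthetic run. The configuration round-trips through JSON (and
#' YAML when the yaml package is available).
#'
#' @param core_floor core/detection floor, percent (default 0.01).
#' @param drm_retention DRM retention threshold, percent, strict > (0.1).
#' @param min_identity alignment identity threshold, percent, strict > (80).
#' @param min_coverage merged-coverage threshold, percent, strict > (90).
#' @param bin_fraction bin-taxonomy majority fraction, strict > (0.5).
#' @param vf_fraction virulence-factor stability fraction, strict > (0.6).
#' @param k,sketch_size,reps genetic-similarity sketch parameters
#'   (31, 10000, 10).
#' @param n_perm PERMANOVA permutations (default 199 for pipeline runs).
#' @param seed master seed; every stage derives from it.
#' @param cohort a [cohort_config()] used when `simulate = TRUE`; defaults
#'   to a 4-region longitudinal design (2 participants per region followed
#'   for 12 months).
#' @param simulate generate all inputs synthetically (default TRUE).
#' @param abundance_path,metadata_path,alignments_path,catalog_path optional
#'   real input files used when `simulate = FALSE`.
#' @param out_dir optional directory for TSV/JSON outputs and the manifest.
#' @export
run_config <- function(core_floor = 0.01, drm_retention = 0.1,
                       min_identity = 80, min_coverage = 90,
                       bin_fraction = 0.5, vf_fraction = 0.6,
                       k = 31L, sketch_size = 10000L, reps = 10L,
                       n_perm = 199L, seed = 1L, cohort = NULL,
                       simulate = TRUE, abundance_path = NULL,
                       metadata_path = NULL, alignments_path = NULL,
                       catalog_path = NULL, out_dir = NULL) {
  stopifnot(core_floor >= 0, drm_retention >= 0,
            min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            bin_fraction > 0, bin_fraction < 1,
            vf_fraction > 0, vf_fraction < 1,
            k >= 1, sketch_size >= 1, reps >= 1, n_perm >= 1)
  if (is.null(cohort))
    cohort <- cohort_config(n_regions = 4L, locations_per_region = 1L,
                            participants_per_location = 2L, months = 12L,
                            seed = as.integer(seed))
  structure(list(core_floor = core_floor, drm_retention = drm_retention,
                 min_identity = min_identity, min_coverage = min_coverage,
                 bin_fraction = bin_fraction, vf_fraction = vf_fraction,
                 k = as.integer(k), sketch_size = as.integer(sketch_size),
                 reps = as.integer(reps), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), cohort = cohort,
                 simulate = isTRUE(simulate),
                 abundance_path = abundance_path,
                 metadata_path = metadata_path,
                 alignments_path = alignments_path,
                 catalog_path = catalog_path, out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' @param config a [run_config()].
#' @param path destination (`.json`, or `.yaml`/`.yml` when the yaml
#'   package is installed).
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::write_yaml(unclass_config(config), path)
  } else {
    jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_config, x$cohort)
  x$cohort <- NULL
  do.call(run_config, c(x, list(cohort = cohort)))
}

run_stage <- function(name, expr, warn_collector = NULL) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      if (!is.null(warn_collector))
        warn_collector(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full cohort analysis pipeline
#'
#' Executes simulate (optional) -> community profile -> gene screen ->
#' genetic similarity -> cohort statistics, and returns a result bundle
#' together with a manifest recording the package version, every threshold
#' and seed used, and per-stage timings — enough to reproduce the run.
#' With `config$out_dir` set, result tables and the manifest are written
#' as TSV/JSON. Any stage error aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return list: abundance, metadata, diversity, core, enterotype, screen
#'   (results, presence, rollup), gs, distance, pcoa, contrasts, permanova,
#'   stability, manifest.
#' @export
run_cohort_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  warnings_log <- character(0)
  stage <- function(name, expr)
    run_stage(name, expr, function(msg)
      warnings_log <<- c(warnings_log, msg))

  if (config$simulate) {
    sim <- stage("simulate", simulate_cohort(config$cohort))
    ab <- sim$abundance; meta <- sim$metadata
    catalog <- simulate_gene_catalog(n_genes = 30L, seed = config$seed + 1L)
    truth <- simulate_gene_truth(meta, catalog, seed = config$seed + 2L)
    hits <- simulate_gene_hits(truth, catalog, seed = config$seed + 3L)
  } else {
    for (p in c("abundance_path", "metadata_path")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]]))
        stop(sprintf("pipeline stage 'input' failed: missing %s (%s)",
                     p, if (is.null(config[[p]])) "unset" else config[[p]]),
             call. = FALSE)
    }
    ab <- stage("input", read_abundance(config$abundance_path, "matrix"))
    meta <- stage("input", read_metadata(config$metadata_path))
    catalog <- truth <- hits <- NULL
    if (!is.null(config$alignments_path)) {
      if (!file.exists(config$alignments_path))
        stop("pipeline stage 'screen' failed: missing alignment file: ",
             config$alignments_path, call. = FALSE)
      catalog <- stage("screen", read_gene_catalog(config$catalog_path,
                                                   read_class_map()))
      hits <- stage("screen", read_alignments(config$alignments_path,
                                              "tabular", catalog))
      hits$sample_id <- "sample"
    }
  }
  tick("inputs")

  div <- stage("profile", diversity_indices(ab, config$core_floor))
  core <- stage("profile", core_taxa(ab, config$core_floor))
  et <- stage("profile", enterotype(ab))
  tick("profile")

  screen <- NULL
  if (!is.null(hits)) {
    res <- stage("screen", screen_cohort(hits, catalog,
                                         sample_ids = meta$sample_id,
                                         min_identity = config$min_identity,
                                         min_coverage = config$min_coverage))
    screen <- list(results = res,
                   presence = presence_matrix(res),
                   rollup = rollup_classes(res, catalog = catalog))
  }
  tick("screen")

  gs <- stage("gs", {
    sets <- simulate_sequence_sets(2e4, containment = 0.25,
                                   seed = config$seed + 4L, k = config$k)
    a <- build_sketch_set(sets$a, "demo_a", config$sketch_size, config$reps,
                          seed = config$seed)
    b <- build_sketch_set(sets$b, "demo_b", config$sketch_size, config$reps,
                          seed = config$seed)
    genetic_similarity(a, b)
  })
  tick("gs")

  d <- stage("cohort", bray_curtis(ab))
  ord <- stage("cohort", pcoa(d))
  contrasts <- list(region = stage("cohort", group_contrast(d, meta, "region")))
  if ("participant_id" %in% names(meta) &&
      any(duplicated(meta$participant_id)))
    contrasts$participant <- stage("cohort",
                                   group_contrast(d, meta, "participant_id"))
  months <- meta$month_index[!is.na(meta$month_index)]
  if (length(months) && diff(range(months)) > 6)   # long pairs need delta > 6
    contrasts$interval <- stage("cohort", interval_contrast(d, meta))
  sweep_factors <- intersect(c("participant_id", "region", "location",
                               "yogurt", "alcohol", "smoking", "exercise",
                               "sex"), names(meta))
  sweep <- stage("cohort", factor_sweep(d, meta, sweep_factors,
                                        n_perm = config$n_perm,
                                        seed = config$seed))
  stability <- NULL
  if (!is.null(screen) && !is.null(meta$month_index) &&
      any(!is.na(meta$month_index)))
    stability <- stage("cohort", stability_classify(screen$presence, meta,
                                                    config$vf_fraction))
  tick("cohort")

  manifest <- list(
    package = "gutcohort",
    version = as.character(utils::packageVersion("gutcohort")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    thresholds = config[c("core_floor", "drm_retention", "min_identity",
                          "min_coverage", "bin_fraction", "vf_fraction")],
    gs_parameters = config[c("k", "sketch_size", "reps")],
    n_perm = config$n_perm,
    simulate = config$simulate,
    cohort = if (config$simulate) unclass(config$cohort),
    warnings = warnings_log,
    timings_sec = as.list(timings))

  bundle <- list(abundance = ab, metadata = meta, diversity = div,
                 core = core, enterotype = et, screen = screen, gs = gs,
                 distance = d, pcoa = ord, contrasts = contrasts,
                 permanova = sweep, stability = stability,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(div, file.path(config$out_dir, "diversity.tsv"))
    write_table(core, file.path(config$out_dir, "core_taxa.tsv"))
    write_table(sweep, file.path(config$out_dir, "permanova.tsv"))
    if (!is.null(screen)) {
      write_table(screen$results, file.path(config$out_dir, "gene_screen.tsv"))
      m <- screen$presence
      write_table(data.frame(gene_id = rownames(m), m + 0, check.names = FALSE),
                  file.path(config$out_dir, "presence_matrix.tsv"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}
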