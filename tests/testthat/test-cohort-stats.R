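mk_table <- function(m, rank = "genus") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%d", seq_len(ncol(m)))
  abundance_table(m, rank = rank)
}

meta_for <- function(ids, ...) {
  df <- data.frame(sample_id = ids, ..., stringsAsFactors = FALSE)
  if (!"region" %in% names(df)) df$region <- "R1"
  validate_metadata(df)
}

test_that("Bray-Curtis matches the hand formula and its metric properties", {
  m <- rbind(a = c(6, 2, 2), b = c(2, 2, 6), c = c(6, 2, 2), d = c(0, 0, 10))
  colnames(m) <- c("x", "y", "z")
  d <- bray_curtis(abundance_table(m * 10, sum_tolerance = 1))
  expect_equal(d["a", "b"], (4 + 0 + 4) / 20)
  expect_equal(d["a", "c"], 0)                      # identical profiles
  expect_equal(d["a", "b"], oracle_bc(m["a", ], m["b", ]))
  # disjoint supports give 1
  m2 <- rbind(a = c(5, 5, 0, 0), b = c(0, 0, 5, 5))
  colnames(m2) <- letters[1:4]
  expect_equal(bray_curtis(abundance_table(m2, sum_tolerance = 100))["a", "b"], 1)
  # symmetry / range / zero diagonal enforced by the container
  expect_true(all(unclass(d) >= 0 & unclass(d) <= 1))
  expect_equal(unclass(d), t(unclass(d)))
  # all-zero sample is an error
  m3 <- rbind(a = c(1, 1), b = c(0, 0))
  colnames(m3) <- c("x", "y")
  expect_error(bray_curtis(abundance_table(m3, sum_tolerance = 100)), "all-zero")
})

test_that("PCoA reproduces simple geometries", {
  # three collinear points at 0, 1, 3: axis 1 recovers the line
  dm <- distance_matrix(as.matrix(dist(c(0, 1, 3))) / 10 * 10,
                        check_unit = FALSE)
  rownames(dm) <- colnames(dm) <- c("a", "b", "c")
  p <- pcoa(distance_matrix(unclass(dm) / 3), n_axes = 1)
  coords <- p$coordinates[, 1]
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(c(0, 1, 3) / 3)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # equilateral triangle: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  p2 <- pcoa(distance_matrix(eq), n_axes = 2)
  eigs <- p2$eigenvalues[p2$eigenvalues > 1e-8]
  expect_length(eigs, 2)
  expect_equal(eigs[1], eigs[2])
  # duplicate samples land on identical coordinates
  m <- rbind(a = c(5, 5), b = c(5, 5), c = c(9, 1))
  colnames(m) <- c("x", "y")
  p3 <- pcoa(bray_curtis(abundance_table(m * 10, sum_tolerance = 1)), 1)
  expect_equal(p3$coordinates["a", ], p3$coordinates["b", ])
  expect_warning(pcoa(bray_curtis(abundance_table(m * 10, sum_tolerance = 1)),
                      n_axes = 3), "truncated")
})

test_that("Wilcoxon p values match the enumeration oracle", {
  # worked 2+2 case: one-sided exact 1/6, two-sided 1/3
  r <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_equal(oracle_wilcoxon_p(c(1, 2), c(3, 4)), 1 / 3)
  # identical multisets: p = 1
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-6)
  expect_equal(wilcoxon_test(c(5, 5), c(5, 5))$p_value, 1)
  # exact vs oracle and exact vs approximate on random 6+6 draws
  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(6), 3); y <- round(rnorm(6, 0.5), 3)
    pe <- wilcoxon_test(x, y, exact = TRUE)$p_value
    expect_equal(pe, oracle_wilcoxon_p(x, y), tolerance = 1e-9)
    pa <- wilcoxon_test(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(wilcoxon_test(numeric(0), 1), "non-empty")
})

test_that("group contrasts partition pairs correctly", {
  ids <- c("a1", "a2", "b1", "b2")
  meta <- meta_for(ids, region = c("A", "A", "B", "B"))
  dm <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(dm) <- 0
  dm["a1", "a2"] <- dm["a2", "a1"] <- 0.1
  dm["b1", "b2"] <- dm["b2", "b1"] <- 0.2
  d <- distance_matrix(dm)
  gc <- group_contrast(d, meta, "region")
  expect_length(gc$within, 2)                        # 2 within pairs
  expect_length(gc$between, 4)                       # 4 between pairs
  expect_equal(sort(gc$within), c(0.1, 0.2))
  expect_equal(gc$mean_between, 0.5)
  # single level errors; level with < 2 samples warns
  expect_error(group_contrast(d, meta_for(ids, region = "A"), "region"),
               "< 2 levels")
  meta3 <- meta_for(ids, region = c("A", "A", "A", "B"))
  expect_warning(group_contrast(d, meta3, "region"), "< 2 samples")
  # per-level scheme returns one row per level
  pl <- group_contrast(d, meta, "region", scheme = "per_level")
  expect_equal(sort(pl$level), c("A", "B"))
})

test_that("PERMANOVA agrees with vegan and with the exhaustive oracle", {
  set.seed(41)
  m <- rbind(matrix(rnorm(30, 0), 3), matrix(rnorm(30, 1.5), 3))
  rownames(m) <- sprintf("S%d", 1:6)
  colnames(m) <- sprintf("T%d", 1:10)
  m <- abs(m)
  meta <- meta_for(rownames(m), region = rep(c("A", "B"), each = 3))
  d <- bray_curtis(mk_table(m))
  res <- permanova(d, meta, "region", n_perm = 999, seed = 1)
  # vegan cross-check of R2 and F
  av <- vegan::adonis2(stats::as.dist(unclass(d)) ~ region, data = meta,
                       permutations = 99)
  expect_equal(res$r_squared, av$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_f, av$F[1], tolerance = 1e-10)
  # n = 6 triggers exhaustive enumeration; oracle agrees exactly
  expect_true(res$exhaustive)
  orc <- oracle_permanova(unclass(d), meta$region)
  expect_equal(res$pseudo_f, orc$f, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
})

test_that("PERMANOVA R2 tends to 1 for maximally separated identical groups", {
  ids <- sprintf("S%d", 1:6)
  dm <- matrix(1, 6, 6, dimnames = list(ids, ids))
  dm[1:3, 1:3] <- 0
  dm[4:6, 4:6] <- 0
  d <- distance_matrix(dm)
  meta <- meta_for(ids, grp = rep(c("A", "B"), each = 3))
  res <- permanova(d, meta, "grp", n_perm = 99, seed = 1)
  expect_equal(res$r_squared, 1)
})

test_that("PERMANOVA is invariant to level relabeling and reproducible by seed", {
  sim <- simulate_cohort(cohort_config(n_regions = 2, locations_per_region = 1,
                                       participants_per_location = 5,
                                       n_taxa = 40, n_core_taxa = 8, seed = 2))
  d <- bray_curtis(sim$abundance)
  meta <- sim$metadata
  r1 <- permanova(d, meta, "region", n_perm = 199, seed = 7)
  meta2 <- meta
  meta2$region <- chartr("R", "Z", meta2$region)
  r2 <- permanova(d, meta2, "region", n_perm = 199, seed = 7)
  expect_equal(r1$r_squared, r2$r_squared)
  expect_equal(r1$p_value, r2$p_value)
  # reordering samples leaves R2 unchanged
  ord <- sample(nrow(unclass(d)))
  d3 <- distance_matrix(unclass(d)[ord, ord])
  expect_equal(permanova(d3, meta, "region", n_perm = 9, seed = 1)$r_squared,
               r1$r_squared)
  expect_error(permanova(d, meta_for(meta$sample_id, g = "one"), "g"),
               "single level")
})

test_that("factor sweep ranks factors by R2 and handles degenerate ones", {
  sim <- simulate_cohort(cohort_config(n_regions = 2, locations_per_region = 1,
                                       participants_per_location = 3,
                                       months = 4, n_taxa = 50,
                                       n_core_taxa = 10, seed = 3))
  d <- bray_curtis(sim$abundance)
  meta <- sim$metadata
  meta$constant <- "all_same"
  meta$region_copy <- meta$region
  expect_warning(fs <- factor_sweep(d, meta, c("participant_id", "region",
                                               "region_copy", "constant"),
                                    n_perm = 49, seed = 1), "constant")
  expect_equal(fs$r_squared, sort(fs$r_squared, decreasing = TRUE))
  expect_equal(fs$r_squared[fs$factor == "region"],
               fs$r_squared[fs$factor == "region_copy"])
  expect_gt(fs$r_squared[fs$factor == "participant_id"],
            fs$r_squared[fs$factor == "region"][1])
})

test_that("interval classification follows the consecutive/6-month rules", {
  expect_equal(interval_classify(3, 4), "short")
  expect_equal(interval_classify(1, 8), "long")      # delta 7 > 6
  expect_equal(interval_classify(2, 6), "other")
  expect_equal(interval_classify(1, 7), "other")     # delta 6 is not long
  expect_equal(interval_classify(c(1, 1), c(2, 12)), c("short", "long"))
  expect_error(interval_classify(NA, 3), "missing")
})

test_that("stability labels realize the strict rules at their boundaries", {
  samples <- c(sprintf("P1M%d", 1:5), sprintf("P2M%d", 1:5), "P3M1")
  meta <- meta_for(samples, region = "R1",
                   participant_id = rep(c("P1", "P2", "P3"), c(5, 5, 1)),
                   month_index = c(1:5, 1:5, 1))
  pres <- rbind(
    everywhere = rep(TRUE, 11),
    p1_only    = c(rep(TRUE, 5), rep(FALSE, 6)),
    three_of_5 = c(rep(TRUE, 3), rep(FALSE, 8)),
    four_of_5  = c(rep(TRUE, 4), rep(FALSE, 7)),
    nowhere    = rep(FALSE, 11))
  colnames(pres) <- samples
  expect_warning(st <- stability_classify(pres, meta, vf_fraction = 0.6),
                 "single sample")
  lab <- st$participant_labels
  expect_equal(dim(lab), c(5L, 2L))                   # P3 excluded
  expect_true(st$cohort_stable["everywhere"])
  expect_equal(unname(lab["p1_only", ]), c("individual_stable", "transient"))
  expect_false(st$cohort_stable["p1_only"])
  expect_true(st$time_stable["p1_only"])
  # VF rule: 3/5 = 0.6 is NOT > 0.6; 4/5 is
  expect_false(st$vf_stable["three_of_5", "P1"])
  expect_true(st$vf_stable["four_of_5", "P1"])
  expect_equal(unname(lab["nowhere", ]), c("transient", "transient"))
  expect_equal(st$summary$n_time_stable, 2)
  expect_error(suppressWarnings(stability_classify(pres[, "P3M1", drop = FALSE],
                                                   meta)), ">= 2")
})
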