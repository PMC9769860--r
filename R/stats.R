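#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`, computed with
#' vegan. Values lie in `[0, 1]` for non-negative abundances; identical
#' profiles give 0 and disjoint supports give 1. A sample with all-zero
#' abundances has no defined dissimilarity and raises an error.
#'
#' @param table an [abundance_table()] (or plain samples x taxa matrix)
#'   with at least 2 samples.
#' @return a [distance_matrix()].
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(m < 0)) stop("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("sample(s) with all-zero abundances: ",
         paste(rownames(m)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  distance_matrix(d)
}

#' Principal-coordinate analysis (classical multidimensional scaling)
#'
#' Double-centers `-d^2 / 2` and eigendecomposes it (via
#' [stats::cmdscale()]). Negative eigenvalues — possible because
#' Bray-Curtis is not Euclidean-embeddable — are dropped and their summed
#' magnitude is reported as a fraction of the total.
#'
#' @param d a [distance_matrix()].
#' @param n_axes number of coordinate axes requested.
#' @return list with `coordinates` (samples x axes), `eig_fraction`
#'   (variance fraction per returned axis, relative to the positive
#'   eigenvalue total), `negative_fraction`, and `eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  dm <- unclass(d)
  n <- nrow(dm)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(n_axes, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-8]
  rank <- length(pos)
  if (n_axes > rank)
    warning(sprintf("requested %d axes but only %d positive eigenvalues; truncated",
                    n_axes, rank))
  k <- min(n_axes, rank, ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("PCo%d", seq_len(k))
  list(coordinates = coords,
       eig_fraction = pos[seq_len(k)] / sum(pos),
       negative_fraction = sum(abs(eig[eig < 0])) / sum(abs(eig)),
       eigenvalues = eig)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided by default. With no ties and small samples the p value comes
#' from exact enumeration of rank assignments; otherwise the normal
#' approximation with tie and continuity correction is used
#' ([stats::wilcox.test()] semantics). Two identical multisets give p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) enumerates when `length(x) + length(y) <= 12` and
#'   there are no ties.
#' @param alternative passed through (default `"two.sided"`).
#' @return list with `statistic` (rank-sum U) and `p_value`.
#' @export
wilcoxon_test <- function(x, y, exact = NULL, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = alternative))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Within- versus between-group distance contrast
#'
#' Partitions the strict upper triangle of a distance matrix by a metadata
#' factor and compares the two distance lists with the Wilcoxon rank-sum
#' test, as is conventional for spatial/temporal dissimilarity contrasts.
#' The pairs share samples, so they are not independent; the test is the
#' field's descriptive convention, not a corrected inference (see the
#' methods vignette).
#'
#' @param d a [distance_matrix()].
#' @param meta `sample_metadata` covering the samples of `d`.
#' @param factor metadata column name with >= 2 levels among the samples.
#' @param scheme `"within_vs_between"` pools all within-level pairs against
#'   all between-level pairs; `"per_level"` tests each level's within
#'   pairs against the pooled between pairs.
#' @return for `"within_vs_between"`, a list with `within`, `between`,
#'   `statistic`, `p_value` and the group means; for `"per_level"`, a
#'   data.frame of per-level tests.
#' @export
group_contrast <- function(d, meta, factor,
                           scheme = c("within_vs_between", "per_level")) {
  scheme <- match.arg(scheme)
  dm <- unclass(d)
  lev <- meta[[factor]][match(rownames(dm), meta$sample_id)]
  if (anyNA(lev)) {
    keep <- !is.na(lev)
    dm <- dm[keep, keep, drop = FALSE]
    lev <- lev[keep]
  }
  if (length(unique(lev)) < 2) stop("factor '", factor, "' has < 2 levels")
  small <- names(which(table(lev) < 2))
  if (length(small))
    warning("level(s) with < 2 samples contribute no within pairs: ",
            paste(small, collapse = ", "))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  same <- lev[idx[, 1]] == lev[idx[, 2]]
  within <- dm[idx][same]
  between <- dm[idx][!same]
  if (scheme == "within_vs_between") {
    if (!length(within) || !length(between))
      stop("degenerate partition: need both within and between pairs")
    wt <- wilcoxon_test(within, between)
    return(list(label_within = "within", label_between = "between",
                within = within, between = between,
                mean_within = mean(within), mean_between = mean(between),
                statistic = wt$statistic, p_value = wt$p_value))
  }
  out <- lapply(unique(lev), function(l) {
    w <- dm[idx][same & lev[idx[, 1]] == l]
    if (!length(w) || !length(between))
      return(data.frame(level = l, n_within = length(w), mean_within = NA,
                        statistic = NA, p_value = NA))
    wt <- wilcoxon_test(w, between)
    data.frame(level = l, n_within = length(w), mean_within = mean(w),
               statistic = wt$statistic, p_value = wt$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "mean_between") <- mean(between)
  res
}

# all permutations of seq_len(n), as a list; used for exhaustive PERMANOVA
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- append(s + (s >= i), i, after = 0L)[c(seq_len(n))]
    }
  }
  out
}

permanova_ss <- function(d2, lev) {
  n <- nrow(d2)
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / n
  ss_within <- 0
  for (l in unique(lev)) {
    g <- which(lev == l)
    if (length(g) > 1) {
      sub <- d2[g, g, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(g)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Distance-based multivariate analysis of variance:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` is the analogous sum
#' within each factor level divided by the level size, and
#' `R^2 = SS_between / SS_total`. The pseudo-F statistic uses
#' `(a - 1, n - a)` degrees of freedom and significance comes from label
#' permutation with `p = (1 + b) / (1 + n_perm)`. When the samples admit
#' no more than `n_perm` distinct orderings (n <= 7 at the default 999)
#' the full permutation set is enumerated instead and p is exact.
#'
#' @param d a [distance_matrix()].
#' @param meta `sample_metadata`; samples with a missing factor value are
#'   dropped.
#' @param factor metadata column with >= 2 levels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed for the permutations.
#' @param strata optional metadata column restricting permutations to
#'   within-stratum shuffles (for nested designs).
#' @return list: factor, pseudo_f, r_squared, p_value, n_permutations,
#'   exhaustive, n, seed.
#' @export
permanova <- function(d, meta, factor, n_perm = 999L, seed = 1L,
                      strata = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  dm <- unclass(d)
  lev <- meta[[factor]][match(rownames(dm), meta$sample_id)]
  keep <- !is.na(lev)
  dm <- dm[keep, keep, drop = FALSE]
  lev <- as.character(lev[keep])
  n <- nrow(dm)
  a <- length(unique(lev))
  if (a < 2) stop("factor '", factor, "' has a single level")
  str_lev <- if (is.null(strata)) NULL else
    as.character(meta[[strata]][match(rownames(dm), meta$sample_id)])
  d2 <- dm^2
  ss <- permanova_ss(d2, lev)
  fstat <- function(s) (s[["between"]] / (a - 1)) / (s[["within"]] / (n - a))
  f_obs <- fstat(ss)

  exhaustive <- is.null(str_lev) && n <= 7 && factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) fstat(permanova_ss(d2, lev[p])),
                     numeric(1))
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    shuffle <- function() {
      if (is.null(str_lev)) return(sample.int(n))
      p <- seq_len(n)
      for (s in unique(str_lev)) {
        i <- which(str_lev == s)
        p[i] <- i[sample.int(length(i))]
      }
      p
    }
    b <- 0L
    for (k in seq_len(n_perm)) {
      if (fstat(permanova_ss(d2, lev[shuffle()])) >= f_obs - 1e-12) b <- b + 1L
    }
    p_val <- (1 + b) / (1 + n_perm)
    n_used <- n_perm
  }
  list(factor = factor, pseudo_f = f_obs,
       r_squared = ss[["between"]] / ss[["total"]],
       p_value = p_val, n_permutations = n_used,
       exhaustive = exhaustive, n = n, seed = seed)
}

#' Marginal PERMANOVA over a set of metadata factors
#'
#' Runs one single-factor [permanova()] per listed factor (samples with a
#' missing value dropped per factor) and returns the results sorted by
#' decreasing R-squared — the usual factor-attribution summary. Factors
#' with fewer than 2 levels among the available samples are skipped with a
#' warning.
#'
#' @inheritParams permanova
#' @param factors character vector of metadata column names.
#' @return data.frame: factor, r_squared, pseudo_f, p_value, n.
#' @export
factor_sweep <- function(d, meta, factors, n_perm = 999L, seed = 1L) {
  out <- lapply(factors, function(f) {
    lev <- meta[[f]][match(rownames(unclass(d)), meta$sample_id)]
    if (length(unique(lev[!is.na(lev)])) < 2) {
      warning("factor '", f, "' has < 2 levels; skipped")
      return(NULL)
    }
    r <- permanova(d, meta, f, n_perm = n_perm, seed = seed)
    data.frame(factor = f, r_squared = r$r_squared, pseudo_f = r$pseudo_f,
               p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable factors")
  res <- res[order(-res$r_squared), ]
  rownames(res) <- NULL
  res
}

#' Classify a sampling-interval pair as short, long or other
#'
#' Consecutive months (|delta| = 1) are "short"; intervals longer than 6
#' months are "long"; everything else is "other".
#'
#' @param month_i,month_j integer month indices (vectorized).
#' @export
interval_classify <- function(month_i, month_j) {
  if (anyNA(month_i) || anyNA(month_j)) stop("missing month index")
  delta <- abs(month_i - month_j)
  ifelse(delta == 1, "short", ifelse(delta > 6, "long", "other"))
}

#' Short- versus long-interval dissimilarity contrast
#'
#' Collects within-participant distance pairs, classifies each pair's
#' sampling interval with [interval_classify()], and tests short against
#' long with the Wilcoxon rank-sum test.
#'
#' @param d a [distance_matrix()] over longitudinal samples.
#' @param meta `sample_metadata` with participant_id and month_index.
#' @return list: short, long (distance vectors), mean_short, mean_long,
#'   statistic, p_value.
#' @export
interval_contrast <- function(d, meta) {
  dm <- unclass(d)
  i <- match(rownames(dm), meta$sample_id)
  part <- meta$participant_id[i]
  month <- meta$month_index[i]
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  same <- part[idx[, 1]] == part[idx[, 2]]
  cls <- interval_classify(month[idx[same, 1]], month[idx[same, 2]])
  dists <- dm[idx][same]
  short <- dists[cls == "short"]; long <- dists[cls == "long"]
  if (!length(short) || !length(long))
    stop("need both short- and long-interval within-participant pairs")
  wt <- wilcoxon_test(short, long)
  list(short = short, long = long, mean_short = mean(short),
       mean_long = mean(long), statistic = wt$statistic, p_value = wt$p_value)
}

#' Temporal stability classification of presence/absence features
#'
#' For a feature x sample presence matrix over a longitudinal cohort: a
#' feature is `individual_stable` for a participant when present in every
#' one of that participant's samples, otherwise `transient`; it is
#' `cohort_stable` when present in every sample of every participant; it
#' is "time-stable" when stable in at least one participant. Virulence
#' factors are conventionally summarised with a softer rule — present in
#' strictly more than `vf_fraction` of a participant's samples — reported
#' in `vf_stable`. Participants with a single sample are excluded with a
#' warning.
#'
#' @param presence logical matrix, features x samples.
#' @param meta `sample_metadata` mapping samples to participants.
#' @param vf_fraction the strict fraction threshold (default 0.6).
#' @return list: `participant_labels` (feature x participant character
#'   matrix), `cohort_stable`, `time_stable`, `vf_stable` (feature x
#'   participant logical), and a `summary` data.frame of counts.
#' @export
stability_classify <- function(presence, meta, vf_fraction = 0.6) {
  samples <- colnames(presence)
  part <- meta$participant_id[match(samples, meta$sample_id)]
  if (anyNA(part)) stop("presence matrix contains samples absent from metadata")
  by_p <- split(samples, part)
  single <- names(by_p)[lengths(by_p) < 2]
  if (length(single)) {
    warning("participant(s) with a single sample excluded: ",
            paste(single, collapse = ", "))
    by_p <- by_p[lengths(by_p) >= 2]
  }
  if (!length(by_p)) stop("no participant with >= 2 samples")
  feats <- rownames(presence)
  lab <- matrix("transient", length(feats), length(by_p),
                dimnames = list(feats, names(by_p)))
  vf <- matrix(FALSE, length(feats), length(by_p),
               dimnames = list(feats, names(by_p)))
  for (p in names(by_p)) {
    sub <- presence[, by_p[[p]], drop = FALSE]
    frac <- rowMeans(sub)
    lab[frac == 1, p] <- "individual_stable"
    vf[, p] <- frac > vf_fraction
  }
  cohort_stable <- apply(lab == "individual_stable", 1, all)
  time_stable <- apply(lab == "individual_stable", 1, any)
  list(participant_labels = lab, cohort_stable = cohort_stable,
       time_stable = time_stable, vf_stable = vf,
       summary = data.frame(
         n_features = length(feats),
         n_cohort_stable = sum(cohort_stable),
         n_individual_stable = sum(time_stable & !cohort_stable),
         n_time_stable = sum(time_stable),
         n_transient = sum(!time_stable)))
}
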