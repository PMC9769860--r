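#' Per-sample diversity indices
#'
#' Richness S counts taxa at or above the detection floor; Shannon H (in
#' nats by default) is computed on abundances renormalized over the
#' detected taxa; Pielou evenness J = H / log(S) and is undefined (NA) for
#' S <= 1. A sample with no detected taxa gets S = 0, H = 0, J = NA.
#'
#' @param table an [abundance_table()].
#' @param detection_floor minimum percent abundance for a taxon to count as
#'   detected; defaults to the core floor, 0.01.
#' @param base logarithm base for H (default `exp(1)`, i.e. nats).
#' @return data.frame with columns sample_id, richness, shannon, pielou.
#' @export
diversity_indices <- function(table, detection_floor = 0.01, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  m[m < detection_floor] <- 0
  s <- rowSums(m > 0)
  h <- vegan::diversity(m, index = "shannon", base = base)
  h[s == 0] <- 0
  j <- ifelse(s > 1, h / log(s, base = base), NA_real_)
  data.frame(sample_id = rownames(m), richness = as.integer(s),
             shannon = as.numeric(h), pielou = as.numeric(j),
             stringsAsFactors = FALSE)
}

#' Core taxa of a cohort
#'
#' A taxon is core when it reaches the floor (default 0.01 percent) in
#' every sample. Also reports prevalence at the floor, the cross-sample
#' mean with a normal-theory 95 percent confidence interval, and the
#' coefficient of variation computed over positive samples only (where the
#' taxon is at or above the floor), the scale on which abundance
#' volatility is usually quoted.
#'
#' @param table an [abundance_table()] with >= 2 samples.
#' @param floor core/detection floor in percent.
#' @param conf confidence level for the mean interval.
#' @return data.frame per taxon: prevalence, mean_pct, ci_lower, ci_upper,
#'   cv, is_core; sorted by decreasing mean.
#' @export
core_taxa <- function(table, floor = 0.01, conf = 0.95) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  if (nrow(m) < 2) stop("core_taxa needs at least 2 samples")
  if (ncol(m) == 0) stop("empty abundance table")
  detected <- m >= floor
  prev <- colMeans(detected)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  half <- stats::qt(1 - (1 - conf) / 2, df = nrow(m) - 1) * sdv / sqrt(nrow(m))
  cv <- vapply(seq_len(ncol(m)), function(t) {
    x <- m[detected[, t], t]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  }, numeric(1))
  out <- data.frame(taxon = colnames(m), prevalence = prev, mean_pct = mu,
                    ci_lower = mu - half, ci_upper = mu + half, cv = cv,
                    is_core = prev == 1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$mean_pct), ]
}

#' Screen a cohort for disease-related microorganisms (DRMs)
#'
#' Applies the cohort retention rule: a listed species is retained only
#' when its abundance is strictly greater than `retention` percent in at
#' least one sample. Per-sample positivity defaults to the same threshold;
#' set `positivity = 0` to count any nonzero detection instead (both
#' readings are in circulation, so this is configurable).
#'
#' @param table an [abundance_table()] at species rank.
#' @param drm_list character vector of species names, or a data.frame with
#'   a `species` column (see [read_drm_list()]).
#' @param retention retention threshold in percent (default 0.1, strict >).
#' @param positivity per-sample positivity threshold; `NULL` (default)
#'   reuses `retention`.
#' @return list with `summary` (per species: retained, n_positive,
#'   prevalence_pct) and `positivity` (retained species x sample logical
#'   matrix).
#' @export
drm_screen <- function(table, drm_list, retention = 0.1, positivity = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.data.frame(drm_list)) drm_list <- drm_list$species
  drm_list <- unique(as.character(drm_list))
  if (!length(drm_list)) stop("empty DRM list")
  if (is.null(positivity)) positivity <- retention
  m <- unclass(table)
  n <- nrow(m)
  vals <- matrix(0, n, length(drm_list), dimnames = list(rownames(m), drm_list))
  present <- intersect(drm_list, colnames(m))
  vals[, present] <- m[, present]
  retained <- apply(vals, 2, function(x) any(x > retention))
  pos <- vals > positivity
  summary <- data.frame(species = drm_list, retained = retained,
                        n_positive = colSums(pos),
                        prevalence_pct = 100 * colMeans(pos),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary,
       positivity = t(pos[, retained, drop = FALSE]))
}

#' Enterotype assignment by dominant marker genus
#'
#' Labels each sample ET_P when the Prevotella-type marker exceeds the
#' Bacteroides-type marker, otherwise ET_B (ties included: the documented
#' tie-break favours ET_B, the majority state). The marker pair is
#' configurable. Samples where both markers are absent from the table get
#' NA with a warning.
#'
#' @param table an [abundance_table()] at genus rank.
#' @param markers length-2 named character vector mapping labels to marker
#'   genera; default `c(ET_B = "Bacteroides", ET_P = "Prevotella")`.
#' @return named character vector of per-sample labels.
#' @export
enterotype <- function(table, markers = c(ET_B = "Bacteroides",
                                          ET_P = "Prevotella")) {
  stopifnot(inherits(table, "abundance_table"), length(markers) == 2)
  m <- unclass(table)
  get <- function(g) if (g %in% colnames(m)) m[, g] else rep(NA_real_, nrow(m))
  b <- get(markers[[1]]); p <- get(markers[[2]])
  if (all(is.na(b)) && all(is.na(p))) {
    warning("both marker genera absent from the table; labels are NA")
    return(stats::setNames(rep(NA_character_, nrow(m)), rownames(m)))
  }
  b[is.na(b)] <- 0; p[is.na(p)] <- 0
  stats::setNames(ifelse(p > b, names(markers)[2], names(markers)[1]),
                  rownames(m))
}
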