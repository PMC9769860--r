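#' Filter alignment hits by identity
#'
#' Strictly-greater filter (a hit at exactly the threshold is removed),
#' preserving input order.
#'
#' @param hits data.frame of hits (see [alignment_hits()]).
#' @param min_identity percent threshold, default 80.
#' @export
filter_identity <- function(hits, min_identity = 80) {
  hits[hits$identity_pct > min_identity, , drop = FALSE]
}

#' Merge alignment intervals on one gene
#'
#' Computes the union of 1-based inclusive intervals; overlapping or
#' touching intervals (end + 1 = start) merge, since per-base coverage is
#' the underlying quantity. Returns the merged disjoint intervals and the
#' total covered length in bp.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param gene_length optional; intervals past it raise an error naming the
#'   offender.
#' @return list with `intervals` (data.frame start/end) and `total_bp`.
#' @export
merge_intervals <- function(start, end, gene_length = NULL) {
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (!length(start)) return(list(intervals = data.frame(start = integer(0),
                                                         end = integer(0)),
                                  total_bp = 0L))
  if (any(start < 1L) || any(end < start)) stop("need 1 <= start <= end")
  if (!is.null(gene_length) && any(end > gene_length)) {
    bad <- which(end > gene_length)[1]
    stop(sprintf("interval %d [%d, %d] exceeds gene length %d",
                 bad, start[bad], end[bad], gene_length))
  }
  r <- IRanges::reduce(IRanges::IRanges(start = as.integer(start),
                                        end = as.integer(end)),
                       min.gapwidth = 1L)
  list(intervals = data.frame(start = IRanges::start(r), end = IRanges::end(r)),
       total_bp = sum(IRanges::width(r)))
}

#' Presence call from merged coverage
#'
#' `coverage_pct = 100 * merged_total / gene_length`; the gene is called
#' present only when coverage is strictly greater than `min_coverage`
#' (default 90), so 90 of 100 bases is an absent call.
#'
#' @param merged_total merged covered bases.
#' @param gene_length gene length in bp, > 0.
#' @param min_coverage percent threshold, strict >.
#' @return list with `coverage_pct` and `present`.
#' @export
call_presence <- function(merged_total, gene_length, min_coverage = 90) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(merged_total < 0 | merged_total > gene_length))
    stop("merged_total must lie in [0, gene_length]")
  cov <- 100 * merged_total / gene_length
  list(coverage_pct = cov, present = cov > min_coverage)
}

#' Screen one sample's hits against a gene catalog
#'
#' The screening pipeline: identity filter (> `min_identity`), per-gene
#' interval merge, then the strict merged-coverage presence call
#' (> `min_coverage`). Genes with no surviving hits get kept_hits 0,
#' coverage 0, absent.
#'
#' @param hits data.frame of hits for one sample.
#' @param catalog a [gene_catalog()]; every catalog gene is reported.
#' @param min_identity,min_coverage thresholds (defaults 80 and 90, both
#'   strict).
#' @return data.frame per gene: kept_hits, merged_bp, coverage_pct, present.
#' @export
screen_sample <- function(hits, catalog, min_identity = 80, min_coverage = 90) {
  kept <- filter_identity(hits, min_identity)
  unknown <- setdiff(unique(kept$gene_id), catalog$gene_id)
  if (length(unknown))
    stop("hits to gene(s) absent from catalog: ", paste(unknown, collapse = ", "))
  by_gene <- split(seq_len(nrow(kept)), factor(kept$gene_id,
                                               levels = catalog$gene_id))
  res <- lapply(seq_len(nrow(catalog)), function(g) {
    i <- by_gene[[g]]
    m <- merge_intervals(kept$ref_start[i], kept$ref_end[i],
                         gene_length = catalog$length_bp[g])
    c(kept = length(i), bp = m$total_bp)
  })
  kept_n <- vapply(res, `[[`, numeric(1), "kept")
  bp <- vapply(res, `[[`, numeric(1), "bp")
  call <- call_presence(bp, catalog$length_bp, min_coverage)
  data.frame(gene_id = catalog$gene_id, kept_hits = as.integer(kept_n),
             merged_bp = as.integer(bp), coverage_pct = call$coverage_pct,
             present = call$present & kept_n > 0, stringsAsFactors = FALSE)
}

#' Screen every sample of a cohort
#'
#' @param hits data.frame of hits with a `sample_id` column (e.g. from
#'   [simulate_gene_hits()]).
#' @param catalog a [gene_catalog()].
#' @param sample_ids samples to report; defaults to those seen in `hits`.
#' @inheritParams screen_sample
#' @return data.frame with sample_id plus the [screen_sample()] columns.
#' @export
screen_cohort <- function(hits, catalog, sample_ids = NULL,
                          min_identity = 80, min_coverage = 90) {
  if (is.null(sample_ids)) sample_ids <- unique(hits$sample_id)
  out <- lapply(sample_ids, function(s) {
    r <- screen_sample(hits[hits$sample_id == s, , drop = FALSE], catalog,
                       min_identity, min_coverage)
    cbind(sample_id = s, r, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-by-sample presence matrix from screening results
#'
#' @param results output of [screen_cohort()].
#' @return logical matrix, genes x samples.
#' @export
presence_matrix <- function(results) {
  genes <- unique(results$gene_id)
  samples <- unique(results$sample_id)
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(results$gene_id, results$sample_id)] <- results$present
  m
}

#' Roll present genes up into drug classes
#'
#' Counts present genes per (sample, class) using the catalog's class
#' labels or an explicit class map. Present genes mapping to no class are
#' counted under `"unassigned"` with a warning.
#'
#' @param results output of [screen_cohort()].
#' @param class_map named character vector gene_id -> class, or `NULL` to
#'   use `catalog$class_label`.
#' @param catalog a [gene_catalog()]; used when `class_map` is `NULL`.
#' @return data.frame sample_id, class, n_present.
#' @export
rollup_classes <- function(results, class_map = NULL, catalog = NULL) {
  if (is.null(class_map)) {
    if (is.null(catalog)) stop("provide class_map or catalog")
    class_map <- stats::setNames(catalog$class_label, catalog$gene_id)
  }
  pres <- results[results$present, , drop = FALSE]
  cls <- class_map[pres$gene_id]
  if (anyNA(cls)) {
    warning("present gene(s) missing from class map counted as 'unassigned': ",
            paste(unique(pres$gene_id[is.na(cls)]), collapse = ", "))
    cls[is.na(cls)] <- "unassigned"
  }
  if (!nrow(pres))
    return(data.frame(sample_id = character(0), class = character(0),
                      n_present = integer(0)))
  tab <- as.data.frame(table(sample_id = pres$sample_id, class = cls),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n_present"
  tab[tab$n_present > 0, ]
}

#' Majority-rule taxonomy for metagenome bins
#'
#' A bin inherits a phylum label only when one phylum is carried by
#' strictly more than `min_fraction` of its contigs; unclassified contigs
#' count in the denominator. Otherwise the bin is `"ambiguous"`.
#'
#' @param bins data.frame with columns bin_id, contig_id, phylum (NA for
#'   unclassified contigs).
#' @param min_fraction majority threshold (default 0.5, strict >).
#' @return data.frame bin_id, label, support (winning fraction).
#' @export
bin_taxonomy <- function(bins, min_fraction = 0.5) {
  stopifnot(all(c("bin_id", "contig_id", "phylum") %in% names(bins)))
  if (!nrow(bins)) stop("empty bin table")
  dup <- stats::aggregate(contig_id ~ bin_id, bins,
                          function(x) anyDuplicated(x) > 0)
  if (any(dup$contig_id))
    stop("duplicate contig ids within bin(s): ",
         paste(dup$bin_id[dup$contig_id], collapse = ", "))
  out <- lapply(split(bins, bins$bin_id), function(b) {
    n <- nrow(b)
    counts <- table(b$phylum[!is.na(b$phylum)])
    if (!length(counts))
      return(data.frame(bin_id = b$bin_id[1], label = "ambiguous", support = 0))
    frac <- max(counts) / n
    lab <- if (frac > min_fraction) names(counts)[which.max(counts)] else "ambiguous"
    data.frame(bin_id = b$bin_id[1], label = lab, support = frac,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
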