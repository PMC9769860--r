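#' Construct a sample-by-taxon relative-abundance table
#'
#' The central container for community analyses: a numeric matrix with one
#' row per sample and one column per taxon, holding relative abundances in
#' percent (0-100). Each taxon carries a rank tag (`"genus"`, `"species"` or
#' `"virus-genus"`). Per-sample sums may fall below 100 because unclassified
#' read mass is allowed; [renormalize()] rescales detected taxa to sum to
#' exactly 100.
#'
#' @param values numeric matrix, samples x taxa, in percent. Row names are
#'   sample ids, column names taxon ids.
#' @param rank character scalar or vector of per-taxon rank tags.
#' @param sum_tolerance allowed excess over 100 per sample row.
#' @return an `abundance_table`: the matrix with a `taxon_rank` attribute.
#' @export
abundance_table <- function(values, rank = "genus", sum_tolerance = 1e-6) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("abundance_table needs sample ids as row names and taxon ids as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in abundance table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids at the same rank")
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  if (ncol(values) > 0 && any(rowSums(values) > 100 + sum_tolerance))
    stop("per-sample abundance sums exceed 100%")
  rank <- rep_len(as.character(rank), ncol(values))
  structure(values, taxon_rank = rank, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x), ncol(x),
              paste(unique(attr(x, "taxon_rank")), collapse = "/")))
  if (nrow(x) && ncol(x)) {
    sub <- unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE]
    print(round(sub, 3))
  }
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  rank <- attr(x, "taxon_rank")
  m <- unclass(x)[i, j, ..., drop = FALSE]
  if (!missing(j)) rank <- rank[if (is.character(j)) match(j, colnames(x)) else j]
  else rank <- rank[seq_len(ncol(m))]
  structure(m, taxon_rank = rank, class = class(x))
}

#' Taxon rank tags of an abundance table
#' @param x an `abundance_table`.
#' @export
taxon_rank <- function(x) attr(x, "taxon_rank")

#' Rescale each sample to sum to exactly 100 percent
#'
#' Removes the unclassified mass by renormalizing over the detected taxa.
#' Samples whose row sum is zero are left at zero with a warning.
#'
#' @param x an `abundance_table`.
#' @export
renormalize <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  s <- rowSums(x)
  zero <- s <= 0
  if (any(zero)) {
    warning(sprintf("%d sample(s) have zero total abundance; left unscaled", sum(zero)))
    s[zero] <- 1
  }
  out <- unclass(x) * (100 / s)
  structure(out, taxon_rank = attr(x, "taxon_rank"), class = class(x))
}

#' Validate a cohort metadata table
#'
#' Metadata is a plain `data.frame` with one row per sample. Required
#' columns: `sample_id` (unique) and `region`. `location` must nest within
#' region (each location maps to exactly one region). `month_index`, when
#' present, is a non-negative integer for longitudinal samples and `NA` for
#' cross-sectional ones; a longitudinal participant must have it on every
#' sample. Extra columns (sex, yogurt, alcohol, smoking, exercise, age,
#' bmi, ...) are carried through untouched.
#'
#' @param meta data.frame of per-sample design factors.
#' @return the validated data.frame, invisibly classed `sample_metadata`.
#' @export
validate_metadata <- function(meta) {
  if (!is.data.frame(meta)) stop("metadata must be a data.frame")
  req <- c("sample_id", "region")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if ("location" %in% names(meta)) {
    if (any(!is.na(meta$location) & is.na(meta$region)))
      stop("location present without region")
    map <- unique(meta[!is.na(meta$location), c("location", "region")])
    bad <- map$location[duplicated(map$location)]
    if (length(bad))
      stop("location(s) mapped to more than one region: ", paste(bad, collapse = ", "))
  }
  if (all(c("month_index", "participant_id") %in% names(meta))) {
    by_p <- split(meta$month_index, meta$participant_id)
    bad <- names(by_p)[vapply(by_p, function(m) any(!is.na(m)) && any(is.na(m)), logical(1))]
    if (length(bad))
      stop("longitudinal participant(s) with missing month_index on some samples: ",
           paste(bad, collapse = ", "))
  }
  class(meta) <- unique(c("sample_metadata", class(meta)))
  invisible(meta)
}

#' Construct a gene catalog
#'
#' @param gene_id unique gene identifiers (e.g. ResFinder/VFDB-style header
#'   tokens such as `"blaOXA-85_1_JANA01000064"`).
#' @param length_bp gene lengths in bp, all > 0.
#' @param class_label drug class or virulence-factor category per gene;
#'   `"unassigned"` where unknown.
#' @export
gene_catalog <- function(gene_id, length_bp, class_label = "unassigned") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in catalog")
  length_bp <- as.integer(length_bp)
  if (any(is.na(length_bp)) || any(length_bp <= 0)) stop("length_bp must be > 0")
  data.frame(gene_id = gene_id, length_bp = length_bp,
             class_label = rep_len(as.character(class_label), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Construct a table of read-to-gene alignment hits
#'
#' Coordinates are 1-based inclusive on the gene reference throughout the
#' package (the BLAST-tabular convention; SAM positions are converted on
#' read-in).
#'
#' @param read_id,gene_id,identity_pct,ref_start,ref_end parallel vectors.
#' @param catalog optional gene catalog used to range-check coordinates.
#' @export
alignment_hits <- function(read_id, gene_id, identity_pct, ref_start, ref_end,
                           catalog = NULL) {
  h <- data.frame(read_id = as.character(read_id),
                  gene_id = as.character(gene_id),
                  identity_pct = as.numeric(identity_pct),
                  ref_start = as.integer(ref_start),
                  ref_end = as.integer(ref_end),
                  stringsAsFactors = FALSE)
  if (any(h$identity_pct < 0 | h$identity_pct > 100, na.rm = TRUE))
    stop("identity_pct must lie in [0, 100]")
  if (any(h$ref_start < 1L) || any(h$ref_end < h$ref_start))
    stop("need 1 <= ref_start <= ref_end")
  if (!is.null(catalog)) {
    idx <- match(h$gene_id, catalog$gene_id)
    if (anyNA(idx))
      stop("gene_id absent from catalog: ",
           paste(unique(h$gene_id[is.na(idx)]), collapse = ", "))
    over <- which(h$ref_end > catalog$length_bp[idx])
    if (length(over))
      stop(sprintf("hit %s on %s extends past gene end (%d > %d)",
                   h$read_id[over[1]], h$gene_id[over[1]],
                   h$ref_end[over[1]], catalog$length_bp[idx][over[1]]))
  }
  h
}

#' Construct a pairwise distance matrix
#'
#' @param values square symmetric numeric matrix with zero diagonal; row and
#'   column names are sample ids.
#' @param check_unit require all entries in `[0, 1]` (true for Bray-Curtis).
#' @export
distance_matrix <- function(values, check_unit = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(rownames(values))) stop("distance matrix needs sample ids as dimnames")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (check_unit && (any(values < -1e-12) || any(values > 1 + 1e-12)))
    stop("distances outside [0, 1]")
  colnames(values) <- rownames(values)
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples\n", nrow(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], 3))
  invisible(x)
}

# strict upper-triangle pair distances as a flat vector with pair indices
dist_pairs <- function(d) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(i = rownames(d)[idx[, 1]], j = colnames(d)[idx[, 2]],
             dist = d[idx], stringsAsFactors = FALSE)
}
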