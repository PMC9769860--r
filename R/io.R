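#' Read a taxonomic abundance table
#'
#' Two dialects are supported. `"kraken_report"` is the standard six-column
#' Kraken-2 report (percent, clade reads, direct reads, rank code, taxid,
#' indented name) and yields a one-sample table restricted to the requested
#' rank. `"matrix"` is a plain TSV with taxa as rows (first column = taxon
#' name) and samples as columns, all assumed to be at `rank`.
#'
#' @param path input file.
#' @param dialect `"kraken_report"` or `"matrix"`.
#' @param rank taxonomic rank to keep: `"genus"` (default), `"species"` or
#'   `"virus-genus"` (rank code G for both genus flavours, S for species).
#' @param sample_id sample name for the kraken dialect; defaults to the file
#'   base name.
#' @param use_clade_percent for kraken reports, use the clade-level percent
#'   column (default). Set `FALSE` to recompute percent from the
#'   direct-read-count column instead.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, dialect = c("matrix", "kraken_report"),
                           rank = "genus", sample_id = NULL,
                           use_clade_percent = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "matrix") {
    lines <- readLines(path)
    if (!length(lines)) stop("empty abundance matrix file: ", path)
    hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    samples <- trimws(hdr[-1])
    cells <- strsplit(lines[-1], "\t", fixed = TRUE)
    nc <- lengths(cells)
    if (any(nc != length(hdr)))
      stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                   which(nc != length(hdr))[1] + 1L, path, length(hdr),
                   nc[which(nc != length(hdr))[1]]))
    taxa <- trimws(vapply(cells, `[[`, "", 1L))
    if (anyDuplicated(taxa))
      stop("duplicate taxon at rank ", rank, ": ",
           paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    vals <- vapply(cells, function(r) suppressWarnings(as.numeric(r[-1])),
                   numeric(length(samples)))
    vals <- matrix(vals, nrow = length(samples),
                   dimnames = list(samples, taxa))
    if (anyNA(vals)) {
      bad <- which(apply(is.na(t(vals)), 1, any))[1]
      stop(sprintf("malformed row at line %d of %s: non-numeric abundance", bad + 1L, path))
    }
    return(abundance_table(vals, rank = rank))
  }

  # kraken_report
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(cells) >= 6L
  if (any(!ok))
    stop(sprintf("malformed row at line %d of %s: expected 6 tab-separated fields",
                 which(!ok)[1], path))
  rank_code <- vapply(cells, `[[`, "", 4L)
  want <- switch(rank, genus = "G", `virus-genus` = "G", species = "S",
                 stop("unsupported rank: ", rank))
  keep <- rank_code == want
  if (!any(keep)) {
    warning("no rows at rank ", rank, " in ", path)
    vals <- matrix(numeric(0), nrow = 1, ncol = 0,
                   dimnames = list(sample_id, character(0)))
    return(abundance_table(vals, rank = rank))
  }
  name <- trimws(vapply(cells[keep], `[[`, "", 6L))
  if (anyDuplicated(name))
    stop("duplicate taxon at rank ", rank, ": ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (use_clade_percent) {
    pct <- suppressWarnings(as.numeric(vapply(cells[keep], `[[`, "", 1L)))
  } else {
    direct <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 3L)))
    if (anyNA(direct))
      stop(sprintf("malformed row at line %d of %s: non-numeric read count",
                   which(is.na(direct))[1], path))
    tot <- sum(direct)
    pct <- if (tot > 0) 100 * direct[keep] / tot else direct[keep]
  }
  if (anyNA(pct))
    stop(sprintf("malformed row at line %d of %s: non-numeric percent",
                 which(keep)[which(is.na(pct))[1]], path))
  vals <- matrix(pct, nrow = 1, dimnames = list(sample_id, name))
  abundance_table(vals, rank = rank, sum_tolerance = 0.5)
}

#' Read read-to-gene alignments
#'
#' `"tabular"` reads 12-column BLAST-style output (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore);
#' reference coordinates with `sstart > send` are flipped so that
#' `ref_start <= ref_end`. `"sam"` reads SAM via Rsamtools; identity is
#' computed as `100 * (aligned - mismatches) / aligned`, where `aligned`
#' counts M/=/X columns and mismatches come from the NM tag after
#' subtracting inserted and deleted bases (or from the MD tag when NM is
#' absent). Unmapped records are always skipped; secondary and
#' supplementary alignments are kept by default since gene coverage may
#' legitimately come from multi-mapped reads.
#'
#' @param path alignment file.
#' @param format `"tabular"` or `"sam"`.
#' @param catalog a [gene_catalog()]; hits to genes absent from it raise an
#'   error.
#' @param include_secondary keep secondary/supplementary SAM records.
#' @param on_missing_nm `"error"` (default) or `"skip"` for SAM records
#'   lacking both NM and MD tags.
#' @return a data.frame of hits as from [alignment_hits()].
#' @export
read_alignments <- function(path, format = c("tabular", "sam"), catalog,
                            include_secondary = TRUE,
                            on_missing_nm = c("error", "skip")) {
  format <- match.arg(format)
  on_missing_nm <- match.arg(on_missing_nm)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tabular") {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 10) stop("tabular alignments need >= 10 columns (BLAST outfmt 6)")
    names(tab)[1:10] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                          "gapopen", "qstart", "qend", "sstart", "send")
    return(alignment_hits(tab$qseqid, tab$sseqid, tab$pident,
                          pmin(tab$sstart, tab$send),
                          pmax(tab$sstart, tab$send), catalog = catalog))
  }
  sam_to_hits(path, catalog, include_secondary, on_missing_nm)
}

sam_to_hits <- function(path, catalog, include_secondary, on_missing_nm) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("NM", "MD"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- r$flag
  keep <- bitwAnd(flag, 4L) == 0L
  if (!include_secondary)
    keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  if (!any(keep))
    return(alignment_hits(character(0), character(0), numeric(0), integer(0),
                          integer(0), catalog = catalog))
  cigar <- r$cigar[keep]
  ops <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- ops[, "M"] + ops[, "="] + ops[, "X"]
  indel_bases <- ops[, "I"] + ops[, "D"]
  n_keep <- sum(keep)
  nm <- if (is.null(r$tag$NM)) rep(NA_integer_, n_keep) else r$tag$NM[keep]
  md <- if (is.null(r$tag$MD)) rep(NA_character_, n_keep) else r$tag$MD[keep]
  mism <- nm - indel_bases
  no_nm <- is.na(mism)
  if (any(no_nm)) {
    mism[no_nm] <- vapply(md[no_nm], md_mismatches, numeric(1))
    still <- is.na(mism)
    if (any(still)) {
      if (on_missing_nm == "error")
        stop("SAM record(s) lacking both NM and MD tags: ",
             paste(utils::head(r$qname[keep][still], 3), collapse = ", "))
      warning(sum(still), " SAM record(s) lacking NM and MD skipped")
    }
  } else still <- rep(FALSE, length(mism))
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  ok <- !still
  alignment_hits(r$qname[keep][ok], as.character(r$rname[keep][ok]),
                 100 * (aligned[ok] - pmax(mism[ok], 0)) / aligned[ok],
                 r$pos[keep][ok], r$pos[keep][ok] + ref_width[ok] - 1L,
                 catalog = catalog)
}

# mismatch count from an MD tag: single letters outside ^-deletion runs
md_mismatches <- function(md) {
  if (is.na(md)) return(NA_real_)
  toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]|[0-9]+", md))[[1]]
  sum(grepl("^[A-Z]$", toks))
}

#' Read sample metadata
#'
#' A TSV with header; `sample_id` and `region` are required, everything else
#' (participant_id, location, month_index, sex, yogurt, alcohol, smoking,
#' exercise, age, bmi and any extra study-specific columns) is optional and
#' preserved. Values `""` and `"NA"` become missing.
#'
#' @param path TSV file.
#' @return a validated `sample_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("month_index" %in% names(meta)) meta$month_index <- as.integer(meta$month_index)
  validate_metadata(meta)
}

#' Write a result table to TSV or JSON
#'
#' TSV output round-trips through [utils::read.delim()]; JSON output is an
#' array of row objects.
#'
#' @param x data.frame (or matrix) to write.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.matrix(x)) x <- as.data.frame(x)
  if (format == "tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a gene catalog from FASTA
#'
#' Gene ids are the first whitespace-delimited token of each header
#' (compatible with ResFinder- and VFDB-style deflines); lengths come from
#' the sequences. Class labels are attached from `class_map` when given,
#' otherwise via [assign_drug_class()] prefix matching, otherwise
#' `"unassigned"`.
#'
#' @param path FASTA file of gene sequences.
#' @param class_map optional data.frame with columns `gene_id`/`prefix` and
#'   `class` (see [read_class_map()]).
#' @export
read_gene_catalog <- function(path, class_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  cls <- if (is.null(class_map)) "unassigned" else assign_drug_class(ids, class_map)
  gene_catalog(ids, Biostrings::width(seqs), cls)
}

#' Read a gene-to-drug-class map
#'
#' A TSV with columns `prefix` (or `gene_id` for exact matches) and `class`.
#' The packaged default, `drug_class_map_synthetic.tsv`, keys classes on
#' common resistance-gene family prefixes (bla -> beta-lactam, tet ->
#' tetracycline, ...) and is a synthetic, user-replaceable curation.
#'
#' @param path TSV file; defaults to the packaged synthetic map.
#' @export
read_class_map <- function(path = system.file("extdata",
                                              "drug_class_map_synthetic.tsv",
                                              package = "gutcohort")) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("prefix", "class") %in% names(map)))
    stop("class map needs columns 'prefix' and 'class'")
  map
}

#' Assign drug classes to gene ids by longest-prefix match
#'
#' @param gene_ids character vector of gene identifiers.
#' @param class_map data.frame with `prefix` and `class` columns.
#' @param unassigned label used when no prefix matches.
#' @export
assign_drug_class <- function(gene_ids, class_map, unassigned = "unassigned") {
  ord <- order(nchar(class_map$prefix), decreasing = TRUE)
  pref <- tolower(class_map$prefix[ord])
  cls <- class_map$class[ord]
  low <- tolower(gene_ids)
  out <- rep(unassigned, length(gene_ids))
  for (k in seq_along(pref)) {
    hit <- out == unassigned & startsWith(low, pref[k])
    out[hit] <- cls[k]
  }
  out
}

#' Read a disease-related-microorganism (DRM) species list
#'
#' A TSV with columns `species` and optionally `risk_group`. The packaged
#' default, `drm_list_synthetic.tsv`, is a small synthetic stand-in for a
#' curated national pathogen list and should be replaced with the user's
#' own curation for real screening.
#'
#' @param path TSV file; defaults to the packaged synthetic list.
#' @export
read_drm_list <- function(path = system.file("extdata", "drm_list_synthetic.tsv",
                                             package = "gutcohort")) {
  drm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(drm)) stop("DRM list needs a 'species' column")
  drm
}
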