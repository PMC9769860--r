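#' Canonical k-mers of a set of DNA sequences
#'
#' Every window of length `k` contributes the lexicographic minimum of
#' itself and its reverse complement; windows containing non-ACGT
#' characters are skipped, so an `N` splits a sequence into independent
#' runs. The result is a deduplicated character vector. Sequences shorter
#' than `k` contribute nothing (not an error).
#'
#' @param sequences character vector of DNA strings, or a
#'   `Biostrings::DNAStringSet`.
#' @param k k-mer length, default 31.
#' @export
canonical_kmers <- function(sequences, k = 31L) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  cpp_canonical_kmers(as.character(sequences), as.integer(k))
}

#' Build a repeated bottom-k sketch set for one sample
#'
#' "Taking `sketch_size` k-mers at random" is implemented MinHash-style:
#' repetition `r` keeps the `sketch_size` k-mers with the smallest values
#' under a seeded hash salted by `r`. This makes the draw a pure function
#' of the k-mer set and `(seed, r)`, so two samples with identical k-mer
#' content get identical sketches in every repetition and score a genetic
#' similarity of exactly 1 — the behaviour required for GS to act as a
#' similarity scale. When the sample has fewer than `sketch_size` distinct
#' k-mers the whole set is the sketch.
#'
#' @param kmers character vector of canonical k-mers (from
#'   [canonical_kmers()]), non-empty.
#' @param sample_id label carried into results.
#' @param sketch_size target k-mers per repetition (default 10,000).
#' @param reps number of repetitions (default 10).
#' @param seed integer hash seed; both members of a comparison must share it.
#' @param k k-mer length recorded on the sketch.
#' @return a `sketch_set` with elements `sample_id`, `k`, `sketch_size`,
#'   `reps`, `seed` and `sketches` (a list of `reps` character vectors).
#' @export
build_sketch_set <- function(kmers, sample_id = "sample", sketch_size = 10000L,
                             reps = 10L, seed = 1L, k = NULL) {
  if (!length(kmers)) stop("empty k-mer set")
  if (sketch_size <= 0 || reps <= 0) stop("sketch_size and reps must be positive")
  kmers <- unique(as.character(kmers))
  if (is.null(k)) k <- nchar(kmers[[1]])
  sketches <- lapply(seq_len(reps), function(r) {
    if (length(kmers) <= sketch_size) return(kmers)
    h <- cpp_hash_kmers(kmers, as.double(seed), as.integer(r))
    kmers[order(h)[seq_len(sketch_size)]]
  })
  structure(list(sample_id = sample_id, k = as.integer(k),
                 sketch_size = as.integer(sketch_size), reps = as.integer(reps),
                 seed = as.integer(seed), sketches = sketches),
            class = "sketch_set")
}

#' @export
print.sketch_set <- function(x, ...) {
  cat(sprintf("sketch_set '%s': %d reps x <=%d canonical %d-mers (seed %d)\n",
              x$sample_id, x$reps, x$sketch_size, x$k, x$seed))
  invisible(x)
}

#' Sketch a FASTA/FASTQ file directly
#'
#' Convenience wrapper: reads sequences, extracts canonical k-mers and
#' builds the sketch set. Note that what to sketch is the caller's choice;
#' in the source protocol the genetic-similarity statistic was computed on
#' reads left after host/taxon filtering, a step outside this package.
#'
#' @inheritParams build_sketch_set
#' @param path sequence file (FASTA or FASTQ).
#' @param k k-mer length, default 31.
#' @export
sketch_file <- function(path, sample_id = basename(path), k = 31L,
                        sketch_size = 10000L, reps = 10L, seed = 1L) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  build_sketch_set(canonical_kmers(seqs, k), sample_id = sample_id, k = k,
                   sketch_size = sketch_size, reps = reps, seed = seed)
}

#' Genetic similarity (GS) between two sketched samples
#'
#' For each repetition `i`, `N_i` is the number of shared k-mers between the
#' two samples' sketches; the statistic is
#' `GS = (N_1 + ... + N_reps) / N_sum`. When both samples saturate every
#' sketch, `N_sum = reps * sketch_size` (100,000 at the defaults);
#' otherwise `N_sum = sum_i min(|a_i|, |b_i|)`, which keeps GS in `[0, 1]`
#' and `GS(a, a) = 1` for small samples.
#'
#' @param a,b `sketch_set`s built with identical `(k, sketch_size, reps,
#'   seed)`.
#' @return a `gs_result` list: `sample_a`, `sample_b`, `shared_counts`
#'   (N_1..N_reps), `n_sum`, `gs`.
#' @export
genetic_similarity <- function(a, b) {
  stopifnot(inherits(a, "sketch_set"), inherits(b, "sketch_set"))
  for (f in c("k", "sketch_size", "reps", "seed"))
    if (!identical(a[[f]], b[[f]]))
      stop("sketch parameter mismatch between samples: ", f)
  ni <- mapply(function(x, y) length(intersect(x, y)), a$sketches, b$sketches)
  n_sum <- sum(pmin(lengths(a$sketches), lengths(b$sketches)))
  structure(list(sample_a = a$sample_id, sample_b = b$sample_id,
                 shared_counts = as.integer(ni), n_sum = as.integer(n_sum),
                 gs = sum(ni) / n_sum),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("GS(%s, %s) = %.4f  (N = %s; Nsum = %d)\n", x$sample_a,
              x$sample_b, x$gs, paste(x$shared_counts, collapse = ","), x$n_sum))
  invisible(x)
}

#' Pairwise genetic-similarity matrix over a list of sketch sets
#'
#' @param sketches named list of `sketch_set`s sharing parameters.
#' @return symmetric matrix of GS values with unit diagonal.
#' @export
gs_matrix <- function(sketches) {
  n <- length(sketches)
  ids <- vapply(sketches, `[[`, "", "sample_id")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- genetic_similarity(sketches[[i]], sketches[[j]])$gs
  m
}
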