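# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, per-base bookkeeping
# and hand-written formulas only.

# canonical k-mers by direct window enumeration
oracle_canonical_kmers <- function(seqs, k) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- character(0)
  for (s in toupper(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      r <- rc(w)
      out <- c(out, if (r < w) r else w)
    }
  }
  unique(out)
}

# merged interval length by per-base boolean array
oracle_covered_bp <- function(start, end, gene_length) {
  covered <- logical(gene_length)
  for (i in seq_along(start)) covered[start[i]:end[i]] <- TRUE
  sum(covered)
}

# two-sided rank-sum p by full enumeration of group assignments (no ties)
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  sums <- apply(utils::combn(n, length(x)), 2, function(i) sum(r[i]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# PERMANOVA sums of squares, pseudo-F and exhaustive permutation p,
# written independently: per-pair accumulation over combn indices
oracle_permanova <- function(dm, lev) {
  n <- nrow(dm)
  f_of <- function(lab) {
    pairs <- utils::combn(n, 2)
    sst <- sum(dm[t(pairs)]^2) / n
    ssw <- 0
    for (l in unique(lab)) {
      g <- which(lab == l)
      if (length(g) < 2) next
      gp <- utils::combn(g, 2)
      ssw <- ssw + sum(dm[t(gp)]^2) / length(g)
    }
    a <- length(unique(lab))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(lev)
  perms <- gtools_permutations(n)
  f_all <- vapply(perms, function(p) f_of(lev[p]), numeric(1))
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12))
}

# all permutations of 1..n (recursive, independent of the package's version)
gtools_permutations <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (i in seq_len(n)) {
    for (p in gtools_permutations(n - 1L)) {
      q <- p
      q[q >= i] <- q[q >= i] + 1L
      res[[length(res) + 1L]] <- c(i, q)
    }
  }
  res
}

# hand-rolled Bray-Curtis for two abundance vectors
oracle_bc <- function(x, y) sum(abs(x - y)) / sum(x + y)

# write a tiny SAM file with given records; returns the path
write_sam <- function(records, genes, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genes), genes))
  writeLines(c(hdr, records), path)
  path
}
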