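# Independent oracles and fixture builders. These deliberately do NOT call
# into the package's own machinery for the quantities they check.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T")
)

# regex oracle for a degenerate consensus
iupac_regex <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(l)
    paste0("[", paste(IUPAC_ORACLE[[l]], collapse = ""), "]"), ""),
    collapse = "")
}

# sample one realisation of a degenerate consensus
sample_consensus <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(l) {
    s <- IUPAC_ORACLE[[l]]
    s[sample.int(length(s), 1)]
  }, ""), collapse = "")
}

random_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

plant_in <- function(s, sub, pos = NULL) {
  if (is.null(pos)) pos <- sample.int(nchar(s) - nchar(sub) + 1, 1)
  substr(s, pos, pos + nchar(sub) - 1) <- sub
  s
}

# peak-sequence corpus with a site of the given architecture planted at
# the given per-sequence rate
planted_corpus <- function(n, len = 200, architecture = "full_site",
                           rate = 0.8, gc = 0.41) {
  cons <- re_consensus(architecture)
  vapply(seq_len(n), function(i) {
    s <- random_dna(len, gc)
    if (runif(1) < rate) s <- plant_in(s, sample_consensus(cons))
    s
  }, "")
}

# literal per-base membership oracle over small instances:
# returns, for every base of [1, glen], the sorted set of dataset ids
# covering it (as a key string; "" where uncovered)
per_base_membership <- function(peak_sets, glen) {
  mem <- matrix(FALSE, glen, length(peak_sets))
  for (j in seq_along(peak_sets)) {
    gr <- peak_sets[[j]]
    for (i in seq_along(gr)) {
      s <- max(1, GenomicRanges::start(gr)[i])
      e <- min(glen, GenomicRanges::end(gr)[i])
      if (s <= e) mem[s:e, j] <- TRUE
    }
  }
  ids <- names(peak_sets)
  apply(mem, 1, function(row)
    paste(sort(ids[row]), collapse = ","))
}

# expand a segmentation into the same per-base key representation
segments_to_per_base <- function(segs, glen) {
  out <- rep("", glen)
  for (i in seq_along(segs)) {
    s <- GenomicRanges::start(segs)[i]
    e <- GenomicRanges::end(segs)[i]
    out[s:e] <- S4Vectors::mcols(segs)$member_ids[i]
  }
  out
}

random_peak_sets <- function(n_datasets = 3, max_peaks = 8, glen = 2000,
                             chrom = "c1") {
  sets <- lapply(seq_len(n_datasets), function(d) {
    k <- sample.int(max_peaks, 1)
    st <- sample.int(glen - 60, k)
    w <- sample(10:50, k, replace = TRUE)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(st, width = pmin(w, glen - st)))
  })
  names(sets) <- paste0("ds", seq_len(n_datasets))
  sets
}

# best-alignment mean per-column total-variation distance between two
# probability matrices (either strand, full overlap of the shorter)
tv_align <- function(P, Q, min_overlap_frac = 0.8) {
  rc <- function(M) M[rev(seq_len(nrow(M))), c(4, 3, 2, 1), drop = FALSE]
  best <- Inf
  for (Qo in list(Q, rc(Q))) {
    long <- if (nrow(P) >= nrow(Qo)) P else Qo
    short <- if (nrow(P) >= nrow(Qo)) Qo else P
    for (off in 0:(nrow(long) - nrow(short))) {
      A <- long[off + seq_len(nrow(short)), , drop = FALSE]
      best <- min(best, mean(rowSums(abs(A - short)) / 2))
    }
  }
  best
}

make_gr <- function(starts, ends, chrom = "c1", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), ...)
}

# tiny de_table builder
det <- function(id, genes, lfc, p, platform = "rnaseq") {
  de_table(id, platform, genes, lfc, p)
}
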