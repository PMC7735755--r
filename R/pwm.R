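#' @name pwm
#' @title Position weight matrices for p53-family response elements
#'
#' @description
#' A `pwmotif` is the package's motif container: an L x 4 probability matrix
#' (columns A, C, G, T), an order-0 background model, the derived log-odds
#' matrix in bits, and a detection threshold calibrated against the
#' background score distribution. The canonical p53-family grammar is built
#' from the decameric half-site consensus RRRCWWGYYY (R = A/G, W = A/T,
#' Y = C/T): a full response element is two adjacent half-sites, variants
#' insert a 1-bp spacer, truncate to a three-quarter site (a full decamer
#' plus a half decamer) or to a single half-site. The p63-flavoured full
#' site relaxes the central WW of each half-site to NN while keeping the
#' invariant C and G core anchors (positions 4/7 and 14/17).
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Probability matrix from an IUPAC consensus string
#'
#' Each consensus letter becomes one matrix row with probability spread
#' uniformly over the letter's allowed bases (R gives A and G 0.5 each).
#'
#' @param consensus IUPAC string.
#' @return L x 4 probability matrix with columns A, C, G, T.
#' @export
consensus_to_probs <- function(consensus) {
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_SETS))
  if (length(bad)) stop("non-IUPAC letter in consensus: ", paste(bad, collapse = ","))
  probs <- t(vapply(letters_, function(l) {
    p <- numeric(4)
    names(p) <- DNA_BASES
    p[IUPAC_SETS[[l]]] <- 1 / length(IUPAC_SETS[[l]])
    p
  }, numeric(4)))
  rownames(probs) <- NULL
  probs
}

#' Response-element consensus strings
#'
#' @param architecture one of `"full_site"`, `"full_site_p63"`,
#'   `"full_site_spacer1"`, `"three_quarter"`, `"half_site"`.
#' @return IUPAC consensus string.
#' @export
re_consensus <- function(architecture = c("full_site", "full_site_p63",
                                          "full_site_spacer1",
                                          "three_quarter", "half_site")) {
  architecture <- match.arg(architecture)
  half <- "RRRCWWGYYY"
  half63 <- "RRRCNNGYYY"
  switch(architecture,
    full_site = paste0(half, half),
    full_site_p63 = paste0(half63, half63),
    full_site_spacer1 = paste0(half, "N", half),
    three_quarter = paste0(half, "RRRCW"),
    half_site = half
  )
}

#' Construct a motif object
#'
#' Builds the log-odds matrix (bits) from the probability matrix after
#' pseudocount regularisation, and sets the detection threshold from the
#' exact background score distribution (dynamic-programming convolution of
#' the per-column score distributions, binned at `bin` bits) such that the
#' expected hit rate on background sequence is at most `fp_per_window` per
#' scanned window, with an additional specificity floor at
#' `frac_max * max achievable score`.
#'
#' @param probs L x 4 probability matrix (columns A,C,G,T); rows must sum
#'   to 1.
#' @param background length-4 background base frequencies.
#' @param pseudocount per-base pseudocount mixed into `probs` before taking
#'   log-odds.
#' @param name motif identifier.
#' @param fp_per_window background false-hit bound per scanned window.
#' @param frac_max specificity floor as a fraction of the maximum
#'   achievable score.
#' @param bin score-distribution bin width in bits.
#' @param tier discovery tier label (integer) or `NA`.
#' @return object of class `pwmotif`.
#' @export
pwmotif <- function(probs, background = rep(0.25, 4), pseudocount = 0.01,
                    name = "motif", fp_per_window = 1e-3, frac_max = 0.85,
                    bin = 0.1, tier = NA_integer_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 1) stop("zero-length motif")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive frequencies")
  background <- background / sum(background)
  colnames(probs) <- DNA_BASES
  padj <- sweep(probs + pseudocount, 1, 1 + 4 * pseudocount, "/")
  lo <- log2(sweep(padj, 2, background, "/"))
  m <- structure(
    list(probs = probs, background = background, pseudocount = pseudocount,
         log_odds = lo, name = name, tier = tier,
         fp_per_window = fp_per_window, frac_max = frac_max, bin = bin),
    class = "pwmotif")
  m$detection_threshold <- pwm_threshold(lo, background, fp_per_window,
                                         frac_max, bin, site_probs = probs)
  m$family_like <- is_family_like(m)
  m$architecture <- label_architecture(m)
  m
}

#' @export
print.pwmotif <- function(x, ...) {
  cat(sprintf("pwmotif '%s': %d bp, IC %.1f bits, threshold %.2f bits, %s%s\n",
              x$name, nrow(x$probs), pwm_ic(x), x$detection_threshold,
              x$architecture,
              if (isTRUE(x$family_like)) " (p53-family-like)" else ""))
  invisible(x)
}

#' Canonical response-element motif
#'
#' @inheritParams re_consensus
#' @param background,pseudocount,... passed to [pwmotif()].
#' @return a `pwmotif` built from the grammar consensus.
#' @export
make_re_pwm <- function(architecture = "full_site",
                        background = rep(0.25, 4), pseudocount = 0.01, ...) {
  pwmotif(consensus_to_probs(re_consensus(architecture)),
          background = background, pseudocount = pseudocount,
          name = architecture, ...)
}

#' Total information content of a motif in bits
#'
#' @param motif a `pwmotif` or a bare probability matrix.
#' @param background background frequencies (taken from the motif if given
#'   one).
#' @return total IC relative to the background, summed over columns.
#' @export
pwm_ic <- function(motif, background = NULL) {
  if (inherits(motif, "pwmotif")) {
    probs <- motif$probs
    if (is.null(background)) background <- motif$background
  } else {
    probs <- motif
    if (is.null(background)) background <- rep(0.25, 4)
  }
  ratio <- sweep(probs, 2, background, "/")
  sum(ifelse(probs > 0, probs * log2(ratio), 0))
}

#' Maximum achievable log-odds score
#' @param motif a `pwmotif`.
#' @return sum of per-column maxima, in bits.
#' @export
pwm_max_score <- function(motif) sum(apply(motif$log_odds, 1, max))

#' Consensus string of a motif (per-column argmax base)
#' @param motif a `pwmotif` or probability matrix.
#' @return character string.
#' @export
pwm_consensus <- function(motif) {
  probs <- if (inherits(motif, "pwmotif")) motif$probs else motif
  paste(DNA_BASES[max.col(probs, ties.method = "first")], collapse = "")
}

#' Reverse complement of a probability matrix
#' @param probs L x 4 probability matrix.
#' @return L x 4 matrix of the reverse-complement motif.
#' @export
revcomp_probs <- function(probs) {
  out <- probs[rev(seq_len(nrow(probs))), c(4, 3, 2, 1), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Exact distribution of the total binned score when column j's base is
# drawn from weights[j, ] (background: one shared weight vector).
score_distribution <- function(lo, weights, bin = 0.1) {
  binned <- round(lo / bin)
  if (is.null(dim(weights)))
    weights <- matrix(weights, nrow(lo), 4, byrow = TRUE)
  dist <- 1
  off <- 0L
  for (j in seq_len(nrow(binned))) {
    v <- as.integer(binned[j, ])
    lo_i <- min(v)
    nd <- numeric(length(dist) + max(v) - lo_i)
    for (b in 1:4) {
      sh <- v[b] - lo_i
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * weights[j, b]
    }
    dist <- nd
    off <- off + lo_i
  }
  list(scores = (off + seq_along(dist) - 1) * bin, probs = dist)
}

# Detection threshold: the background false-hit bound (score with tail
# probability <= fp_per_window under the background distribution) is a
# hard floor; above it sits a specificity floor at frac_max times the
# expected score of a site drawn from the motif itself (computed with the
# raw probabilities, so structurally forbidden bases contribute nothing).
# Referencing the expected rather than the maximal site score keeps
# genuine-but-degenerate response elements detectable.
pwm_threshold <- function(lo, background, fp_per_window = 1e-3,
                          frac_max = 0.85, bin = 0.1, site_probs = NULL) {
  bgd <- score_distribution(lo, background, bin)
  tailp <- rev(cumsum(rev(bgd$probs)))
  ok <- which(tailp <= fp_per_window)
  maxs <- max(bgd$scores)
  dp_thr <- if (length(ok)) bgd$scores[ok[1]] else maxs
  ref <- if (is.null(site_probs)) maxs else sum(site_probs * lo)
  min(max(dp_thr, frac_max * ref), maxs)
}

## ---- integer-sequence plumbing used by the scanners -----------------------

seq_to_int <- function(s) {
  lut <- integer(256)
  lut[] <- NA_integer_
  lut[utf8ToInt("ACGTN") ] <- c(1L, 2L, 3L, 4L, 0L)
  lut[utf8ToInt("acgtn")] <- c(1L, 2L, 3L, 4L, 0L)
  v <- lut[utf8ToInt(s)]
  if (anyNA(v)) stop("sequence contains a non-ACGTN character")
  v
}

revcomp_int <- function(v) {
  r <- rev(v)
  ifelse(r == 0L, 0L, 5L - r)
}

# All windows of length L over a list of integer sequences, forward and
# (optionally) reverse strand. Offsets are 1-based forward-strand starts.
build_windows <- function(int_seqs, L, both_strands = TRUE) {
  Ws <- list(); seq_id <- list(); offs <- list(); strands <- list()
  k <- 0L
  for (i in seq_along(int_seqs)) {
    v <- int_seqs[[i]]
    n <- length(v) - L + 1L
    if (n < 1L) next
    idx <- outer(seq_len(n), 0:(L - 1L), "+")
    k <- k + 1L
    Ws[[k]] <- matrix(v[idx], nrow = n)
    seq_id[[k]] <- rep.int(i, n)
    offs[[k]] <- seq_len(n)
    strands[[k]] <- rep.int("+", n)
    if (both_strands) {
      rv <- revcomp_int(v)
      k <- k + 1L
      Ws[[k]] <- matrix(rv[idx], nrow = n)
      seq_id[[k]] <- rep.int(i, n)
      # window j on the reverse strand covers forward positions
      # (len - j - L + 2) .. (len - j + 1)
      offs[[k]] <- length(v) - seq_len(n) - L + 2L
      strands[[k]] <- rep.int("-", n)
    }
  }
  if (k == 0L)
    return(list(W = matrix(integer(0), 0, L), seq_id = integer(0),
                offset = integer(0), strand = character(0)))
  list(W = do.call(rbind, Ws), seq_id = unlist(seq_id),
       offset = unlist(offs), strand = unlist(strands))
}

# Best window per sequence for one motif; returns a data.frame aligned with
# seqs (one row per sequence, score -Inf when no scorable window exists).
scan_best_windows <- function(int_seqs, motif) {
  L <- nrow(motif$probs)
  win <- build_windows(int_seqs, L)
  n <- length(int_seqs)
  out <- data.frame(seq = seq_len(n), offset = NA_integer_,
                    strand = NA_character_, score = -Inf)
  if (nrow(win$W) == 0) return(out)
  sc <- cpp_score_windows(win$W, motif$log_odds)
  o <- order(win$seq_id, -sc)
  keep <- o[!duplicated(win$seq_id[o])]
  out$offset[win$seq_id[keep]] <- win$offset[keep]
  out$strand[win$seq_id[keep]] <- win$strand[keep]
  out$score[win$seq_id[keep]] <- sc[keep]
  out
}
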