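#' @name motif_discovery
#' @title De novo PWM discovery with iterative masking
#'
#' @description
#' A self-contained motif discovery engine over peak sequences. For every
#' candidate motif width, the most enriched words (counted with a
#' width-scaled mismatch allowance against an order-0 background) seed a
#' ZOOPS ("zero or one occurrence per sequence") EM refinement in which
#' every sequence contributes its best-scoring site on either strand, or
#' background. The refined motif with the largest total log-likelihood
#' gain across widths wins. The iterative wrapper mimics the masking
#' strategy used to dissect p53-family response elements: discover the
#' primary motif, remove every peak that contains it, and repeat on the
#' remainder until the best motif no longer looks p53-family-like.
NULL

#' Extract peak sequences from a genome
#'
#' @param regions `GRanges` of peaks/regions.
#' @param genome named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @param width 0 keeps each peak's native extent; a positive value
#'   re-centres every peak to a fixed width.
#' @param max_n_frac windows with more than this fraction of N bases are
#'   excluded.
#' @return named uppercase character vector (names are
#'   `chrom:start-end` region ids); peaks exceeding chromosome bounds are
#'   clipped with a warning.
#' @export
extract_peak_sequences <- function(regions, genome, width = 0,
                                   max_n_frac = 0.1) {
  if (!length(regions)) return(setNames(character(0), character(0)))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ","))
  s <- start(regions); e <- end(regions)
  if (width > 0) {
    mid <- floor((s + e) / 2)
    s <- mid - floor(width / 2)
    e <- s + width - 1
  }
  lens <- nchar(genome)[chrom]
  clipped <- s < 1 | e > lens
  if (any(clipped))
    warning(sum(clipped), " region(s) clipped at chromosome bounds")
  s <- pmax(s, 1)
  e <- pmin(e, lens)
  seqs <- toupper(substring(genome[chrom], s, e))
  names(seqs) <- paste0(chrom, ":", s - 1, "-", e)
  nfrac <- vapply(strsplit(seqs, ""), function(x) mean(x == "N"), 0)
  seqs[nfrac <= max_n_frac & nchar(seqs) > 0]
}

order0_background <- function(int_seqs) {
  cnt <- tabulate(unlist(int_seqs), nbins = 4)
  if (sum(cnt) == 0) return(rep(0.25, 4))
  (cnt + 1) / sum(cnt + 1)
}

# P(word of this composition matches the seed with <= maxmis mismatches)
# under the order-0 background: Poisson-binomial tail by convolution.
seed_bg_match_prob <- function(seed, background, maxmis) {
  p_match <- background[seed]
  dist <- 1
  for (p in p_match) dist <- c(dist * p, 0) + c(0, dist * (1 - p))
  sum(dist[seq_len(maxmis + 1)])
}

seed_to_pwm_probs <- function(seed, match_p = 0.7) {
  L <- length(seed)
  probs <- matrix((1 - match_p) / 3, L, 4)
  probs[cbind(seq_len(L), seed)] <- match_p
  colnames(probs) <- DNA_BASES
  probs
}

# One ZOOPS-EM refinement from a seed probability matrix. Hard (best-site)
# responsibilities; the objective (total assigned log-odds, bits) is kept
# non-decreasing by reverting the final step if it ever drops.
zoops_em <- function(win, n_seqs, probs0, background, pseudocount = 0.01,
                     max_iter = 30, tol = 1e-3) {
  probs <- probs0
  best <- list(probs = probs0, objective = -Inf)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    padj <- sweep(probs + pseudocount, 1, 1 + 4 * pseudocount, "/")
    lo <- log2(sweep(padj, 2, background, "/"))
    sc <- cpp_score_windows(win$W, lo)
    o <- order(win$seq_id, -sc)
    bst <- o[!duplicated(win$seq_id[o])]
    bst <- bst[is.finite(sc[bst]) & sc[bst] > 0]
    obj <- sum(sc[bst])
    if (obj < best$objective - 1e-9) break  # revert: keep previous best
    improved <- obj > best$objective + tol
    best <- list(probs = probs, objective = obj, n_assigned = length(bst))
    trace <- c(trace, obj)
    if (!improved && it > 1) { converged <- TRUE; break }
    if (!length(bst)) break
    cnt <- t(cpp_column_counts(win$W, bst))  # L x 4
    probs <- sweep(cnt + 2 * rep(background, each = nrow(cnt)), 1,
                   rowSums(cnt) + 2, "/")
    colnames(probs) <- DNA_BASES
  }
  best$trace <- trace
  best$converged <- converged
  best
}

trim_low_ic_flanks <- function(probs, background, trim_ic = 0.25,
                               min_len = 4) {
  ic_col <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    sum(ifelse(p > 0, p * log2(p / background), 0))
  }, 0)
  from <- 1; to <- nrow(probs)
  while (from < to - min_len + 2 && ic_col[from] < trim_ic) from <- from + 1
  while (to > from + min_len - 2 && ic_col[to] < trim_ic) to <- to - 1
  probs[from:to, , drop = FALSE]
}

#' De novo discovery of the most enriched motif
#'
#' @param sequences character vector of peak sequences (at least 20; the
#'   engine refuses underpowered inputs).
#' @param lengths candidate motif widths (default 10, 15, 20, 25 bp,
#'   spanning half-site to extended full-site response elements).
#' @param n_seeds number of top enriched seed words refined per width.
#' @param background order-0 base frequencies; estimated from the input
#'   sequences when `NULL`.
#' @param seed RNG seed for candidate sampling (deterministic given it).
#' @param max_iter EM iteration cap; non-convergence returns the best
#'   iterate with `attr(,"em_converged") = FALSE`.
#' @param n_candidates candidate words scored for enrichment per width.
#' @param max_count_windows subsample cap for mismatch counting.
#' @param trim_ic flanking columns below this IC (bits) are trimmed from
#'   the refined motif.
#' @param fp_per_window,frac_max detection-threshold parameters (see
#'   [pwmotif()]).
#' @param name motif name.
#' @return a `pwmotif` with attributes `objective`, `objective_trace`,
#'   `n_assigned`, `em_converged`.
#' @export
discover_motif <- function(sequences, lengths = c(10, 15, 20, 25),
                           n_seeds = 10, background = NULL, seed = NULL,
                           max_iter = 30, n_candidates = 60,
                           max_count_windows = 30000, trim_ic = 0.25,
                           fp_per_window = 1e-3, frac_max = 0.85,
                           name = "denovo") {
  if (length(sequences) < 20)
    stop("underpowered: need at least 20 sequences for de novo discovery")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  int_seqs <- lapply(sequences, seq_to_int)
  if (is.null(background)) background <- order0_background(int_seqs)
  best <- NULL
  for (L in lengths) {
    win <- build_windows(int_seqs, L)
    ok <- rowSums(win$W == 0L) == 0
    if (sum(ok) < 50) next
    win_ok <- list(W = win$W[ok, , drop = FALSE], seq_id = win$seq_id[ok])
    keys <- apply(win_ok$W, 1, paste, collapse = "")
    cand <- select_seed_candidates(win_ok, keys, n_candidates)
    if (!nrow(cand$W)) next
    maxmis <- ceiling(L / 5)
    # deterministic, strand-invariant subsample for mismatch counting:
    # stride over the lexicographically ordered window multiset
    sub <- if (nrow(win_ok$W) > max_count_windows) {
      ord <- order(keys)
      take <- ord[unique(round(seq(1, length(ord),
                                   length.out = max_count_windows)))]
      win_ok$W[take, , drop = FALSE]
    } else win_ok$W
    enr <- vapply(seq_len(nrow(cand$W)), function(i) {
      sd <- cand$W[i, ]
      k <- cpp_mismatch_count(sub, sd, maxmis)
      p0 <- seed_bg_match_prob(sd, background, maxmis)
      -pbinom(k - 1, nrow(sub), min(p0, 1), lower.tail = FALSE, log.p = TRUE)
    }, 0)
    top <- order(enr, decreasing = TRUE)[seq_len(min(n_seeds, length(enr)))]
    fits <- lapply(top, function(i)
      zoops_em(win_ok, length(int_seqs), seed_to_pwm_probs(cand$W[i, ]),
               background, max_iter = 8))
    objs <- vapply(fits, function(f) f$objective, 0)
    fit <- zoops_em(win_ok, length(int_seqs), fits[[which.max(objs)]]$probs,
                    background, max_iter = max_iter)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("no scorable windows: sequences too short or too many Ns")
  probs <- trim_low_ic_flanks(best$probs, background, trim_ic)
  m <- pwmotif(probs, background = background, name = name,
               fp_per_window = fp_per_window, frac_max = frac_max)
  attr(m, "objective") <- best$objective
  attr(m, "objective_trace") <- best$trace
  attr(m, "n_assigned") <- best$n_assigned
  attr(m, "em_converged") <- isTRUE(best$converged)
  if (!isTRUE(best$converged))
    warning("EM did not converge within max_iter; returning best iterate")
  m
}

# Candidate seeds: the most frequent exact words plus a random draw of
# distinct words (degenerate response elements rarely repeat exactly, so
# frequency alone would miss them). Selection is deterministic given the
# RNG state and strand-canonical: the window multiset contains both
# strands, and ties are broken lexicographically, so reverse-complementing
# the input corpus yields the same candidate set.
select_seed_candidates <- function(win_ok, keys, n_candidates) {
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  n_top <- min(ceiling(n_candidates / 3), length(tab))
  pick <- names(tab)[ord[seq_len(n_top)]]
  rest <- sort(setdiff(names(tab), pick))
  if (length(rest))
    pick <- c(pick, sample(rest, min(n_candidates - n_top, length(rest))))
  idx <- match(pick, keys)
  list(W = win_ok$W[idx, , drop = FALSE])
}

#' Iterative discovery with masking of explained peaks
#'
#' Runs [discover_motif()], and while the discovered motif is
#' p53-family-like (see [is_family_like()]), records it with the next tier
#' label, removes every sequence containing a match at the motif's
#' detection threshold, and repeats on the remainder.
#'
#' @param sequences character vector of peak sequences.
#' @param max_iters tier cap.
#' @param min_sequences stop when fewer sequences remain.
#' @param seed RNG seed; tier `t` uses `seed + t - 1`.
#' @param verbose log per-tier removal counts via `message()`.
#' @param ... passed to [discover_motif()].
#' @return list of family-like `pwmotif`s in tier order, with a
#'   `removal_log` attribute (data.frame: tier, n_in, n_removed) and a
#'   `final_motif` attribute holding the first non-family motif (or NULL).
#' @export
iterative_discovery <- function(sequences, max_iters = 6,
                                min_sequences = 20, seed = 1,
                                verbose = FALSE, ...) {
  tiers <- list()
  log <- data.frame(tier = integer(0), n_in = integer(0),
                    n_removed = integer(0))
  final <- NULL
  remaining <- sequences
  for (t in seq_len(max_iters)) {
    if (length(remaining) < min_sequences) break
    m <- discover_motif(remaining, seed = seed + t - 1,
                        name = paste0("tier", t), ...)
    if (!isTRUE(m$family_like)) { final <- m; break }
    hits <- scan_best_windows(lapply(remaining, seq_to_int), m)
    drop <- hits$score >= m$detection_threshold
    if (!any(drop)) {
      warning("family-like motif matched no sequence; stopping")
      final <- m
      break
    }
    m$tier <- t
    tiers[[t]] <- m
    log <- rbind(log, data.frame(tier = t, n_in = length(remaining),
                                 n_removed = sum(drop)))
    if (verbose)
      message("tier ", t, ": removed ", sum(drop), " of ",
              length(remaining), " sequences (", m$architecture, ")")
    remaining <- remaining[!drop]
  }
  attr(tiers, "removal_log") <- log
  attr(tiers, "final_motif") <- final
  tiers
}
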