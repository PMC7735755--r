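#' @name motif_classification
#' @title Hierarchical response-element architecture assignment
#'
#' @description
#' Bound regions are assigned to the first motif, in a fixed priority
#' order, whose best log-odds match reaches the motif's detection
#' threshold; each region is counted exactly once. Motifs are labelled by
#' the structural arrangement of their CWWG-like cores: two cores 10 bp
#' apart form a full response element, 11 bp apart a 1-bp-spacer element,
#' a single core with a flanking partial core a three-quarter site, a
#' lone core a half-site.
NULL

#' Best motif match in one sequence
#'
#' Scans both strands and returns the best-scoring window if it reaches
#' the motif's detection threshold.
#'
#' @param sequence character string (A,C,G,T,N).
#' @param motif a `pwmotif`.
#' @return list with `offset` (0-based), `strand`, `score` (bits), or
#'   `NULL` when no window reaches the threshold.
#' @export
scan_motif <- function(sequence, motif) {
  res <- scan_best_windows(list(seq_to_int(sequence)), motif)
  if (!is.finite(res$score[1]) || res$score[1] < motif$detection_threshold)
    return(NULL)
  list(offset = res$offset[1] - 1L, strand = res$strand[1],
       score = res$score[1])
}

#' Is a motif p53-family-like?
#'
#' Operational reading of "p53/p63-like": some alignment of the decameric
#' half-site consensus RRRCWWGYYY inside the motif (either strand) places
#' the invariant C and G core anchors (half-site positions 4 and 7) on
#' motif columns carrying at least probability 0.5 for C and G
#' respectively, and the motif's total information content reaches
#' `ic_floor` bits.
#'
#' @param motif a `pwmotif`.
#' @param ic_floor minimal total IC in bits (default 8).
#' @return logical.
#' @export
is_family_like <- function(motif, ic_floor = 8) {
  probs <- motif$probs
  L <- nrow(probs)
  if (L < 10) return(FALSE)
  if (pwm_ic(motif) < ic_floor) return(FALSE)
  has_core_anchor <- function(p) {
    any(vapply(0:(nrow(p) - 10), function(o)
      p[o + 4, "C"] >= 0.5 && p[o + 7, "G"] >= 0.5, TRUE))
  }
  has_core_anchor(probs) || has_core_anchor(revcomp_probs(probs))
}

find_cores <- function(probs) {
  L <- nrow(probs)
  if (L < 4) return(integer(0))
  which(vapply(seq_len(L - 3), function(i)
    probs[i, "C"] >= 0.5 && probs[i + 3, "G"] >= 0.5, TRUE))
}

#' Architecture label of a motif
#'
#' Structural analysis of the probability matrix: CWWG-like cores are
#' positions where the C edge and the G edge three bases downstream each
#' carry probability at least 0.5. Two cores starting 10 bp apart label
#' the motif a full site; 11 bp apart a full site with a 1-bp spacer; a
#' single core with partial-core evidence (a C one half-site downstream
#' or a G one half-site upstream of where the partner core would sit) a
#' three-quarter site; a lone core a half-site; no core, `other`.
#' Both orientations are considered.
#'
#' @param motif a `pwmotif`.
#' @return one of `"full_site"`, `"full_site_spacer1"`,
#'   `"three_quarter"`, `"half_site"`, `"other"`.
#' @export
label_architecture <- function(motif) {
  classify <- function(probs) {
    cores <- find_cores(probs)
    if (!length(cores)) return("other")
    if (length(cores) >= 2) {
      gaps <- as.vector(outer(cores, cores, "-"))
      if (any(gaps == 10)) return("full_site")
      if (any(gaps == 11)) return("full_site_spacer1")
    }
    L <- nrow(probs)
    partial <- any(vapply(cores, function(c_) {
      (c_ + 10 <= L && probs[c_ + 10, "C"] >= 0.5) ||
        (c_ - 7 >= 1 && probs[c_ - 7, "G"] >= 0.5)
    }, TRUE))
    if (partial) "three_quarter" else "half_site"
  }
  labs <- c(classify(motif$probs), classify(revcomp_probs(motif$probs)))
  priority <- c("full_site", "full_site_spacer1", "three_quarter",
                "half_site", "other")
  priority[min(match(labs, priority))]
}

#' Hierarchically assign regions to an ordered motif list
#'
#' Each region is assigned to the FIRST motif in priority order that
#' yields a match at its detection threshold; regions matching none are
#' labelled `"none"`. Assignment is exclusive: a region is counted once.
#'
#' @param region_seqs named character vector of region sequences (the
#'   priority convention is: primary shared motif first, then the primary
#'   factor-unique motif, then remaining tiers in discovery order).
#' @param ordered_motifs list of `pwmotif`s in priority order.
#' @return data.frame: `region_id`, `assigned_motif`, `tier_rank`
#'   (priority index, NA for none), `architecture`, `best_score`.
#' @export
hierarchical_assign <- function(region_seqs, ordered_motifs) {
  n <- length(region_seqs)
  ids <- names(region_seqs)
  if (is.null(ids)) ids <- paste0("region", seq_len(n))
  out <- data.frame(region_id = ids,
                    assigned_motif = rep("none", n),
                    tier_rank = rep(NA_integer_, n),
                    architecture = rep("none", n),
                    best_score = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  int_seqs <- lapply(region_seqs, seq_to_int)
  open <- seq_len(n)
  for (k in seq_along(ordered_motifs)) {
    if (!length(open)) break
    m <- ordered_motifs[[k]]
    res <- scan_best_windows(int_seqs[open], m)
    hit <- which(is.finite(res$score) & res$score >= m$detection_threshold)
    if (length(hit)) {
      rows <- open[hit]
      out$assigned_motif[rows] <- m$name
      out$tier_rank[rows] <- k
      out$architecture[rows] <- m$architecture
      out$best_score[rows] <- res$score[hit]
      open <- open[-hit]
    }
  }
  out
}

#' Architecture composition of assigned regions
#'
#' @param calls output of [hierarchical_assign()].
#' @return list of class `composition_summary`: `counts` (named integer,
#'   including `"none"`), `fractions` (sum to 1 including the unexplained
#'   class), `fractions_excl_none`, and `total`.
#' @export
composition <- function(calls) {
  lev <- c("full_site", "full_site_spacer1", "three_quarter", "half_site",
           "other", "none")
  counts <- table(factor(calls$architecture, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  total <- sum(counts)
  fr <- if (total) counts / total else setNames(numeric(length(lev)), lev)
  nn <- sum(counts[setdiff(lev, "none")])
  fr_ex <- if (nn) counts[setdiff(lev, "none")] / nn else
    setNames(numeric(length(lev) - 1), setdiff(lev, "none"))
  structure(list(counts = counts, fractions = fr,
                 fractions_excl_none = fr_ex, total = total),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("architecture composition over", x$total, "regions:\n")
  for (a in names(x$counts))
    cat(sprintf("  %-18s %6d  (%.1f%%)\n", a, x$counts[[a]],
                100 * x$fractions[[a]]))
  invisible(x)
}
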