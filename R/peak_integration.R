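#' @name peak_integration
#' @title Multi-dataset peak consensus and dataset-support counting
#'
#' @description
#' Peak sets from many ChIP-seq datasets are intersected on a common
#' genomic axis: every peak boundary becomes a breakpoint, each resulting
#' segment is annotated with the exact set of datasets covering it, and
#' dataset support (the number of distinct datasets) is the confidence
#' axis along which binding sites are ranked. Three class sets are built
#' from the p63 and p53 segmentations: sites shared by both factors
#' (support at least `min_shared` in each), and sites unique to one factor
#' (support at least `min_unique` in that factor and not a single dataset
#' of the other).
NULL

rlelist_to_granges <- function(cov, lower) {
  irl <- IRanges::slice(cov, lower = lower, rangesOnly = TRUE)
  GenomicRanges::GRanges(rep(names(irl), lengths(irl)),
                         unlist(irl, use.names = FALSE))
}

#' Consolidate replicate peak files into one dataset peak list
#'
#' With two or more replicates, the emitted peaks are the maximal genomic
#' regions covered by the peaks of at least two replicates. A single
#' replicate passes through unchanged.
#'
#' @param replicate_peaks list of `GRanges`, one per replicate.
#' @return `GRanges` of consolidated peaks.
#' @export
consolidate_replicates <- function(replicate_peaks) {
  if (!length(replicate_peaks)) stop("no replicate peak files given")
  if (length(replicate_peaks) == 1)
    return(GenomicRanges::reduce(GenomicRanges::granges(replicate_peaks[[1]])))
  segs <- support_segments(replicate_peaks)
  GenomicRanges::reduce(segs[mcols(segs)$support >= 2])
}

#' Sweep-line support segmentation across datasets
#'
#' @param per_dataset_peaks named list of `GRanges`, one consolidated peak
#'   list per dataset.
#' @return `GRanges` of non-overlapping segments with metadata `support`
#'   (number of distinct covering datasets) and `member_ids`
#'   (comma-separated dataset names); adjacent segments with identical
#'   member sets are merged.
#' @export
support_segments <- function(per_dataset_peaks) {
  if (!length(per_dataset_peaks))
    return(GenomicRanges::GRanges(support = integer(0)))
  ids <- names(per_dataset_peaks)
  if (is.null(ids)) ids <- paste0("ds", seq_along(per_dataset_peaks))
  red <- lapply(per_dataset_peaks, function(gr)
    GenomicRanges::reduce(GenomicRanges::granges(gr)))
  all <- unlist(GenomicRanges::GRangesList(red), use.names = FALSE)
  if (!length(all)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$support <- integer(0)
    mcols(gr)$member_ids <- character(0)
    return(gr)
  }
  owner <- rep(ids, lengths(red))
  segs <- GenomicRanges::disjoin(all)
  hits <- GenomicRanges::findOverlaps(segs, all)
  members <- tapply(owner[subjectHits(hits)], factor(queryHits(hits),
                    levels = seq_along(segs)),
                    function(x) paste(sort(unique(x)), collapse = ","))
  members <- as.character(members)
  # disjoin() output is sorted; members computed in that order
  mcols(segs)$member_ids <- members
  mcols(segs)$support <- lengths(strsplit(members, ","))
  merge_adjacent_segments(segs, key = members)
}

# Merge book-ended segments with an identical key, keeping mcols of runs.
merge_adjacent_segments <- function(segs, key) {
  if (!length(segs)) return(segs)
  chrom <- as.character(GenomicRanges::seqnames(segs))
  newrun <- c(TRUE, !(chrom[-1] == chrom[-length(segs)] &
                      start(segs)[-1] == end(segs)[-length(segs)] + 1 &
                      key[-1] == key[-length(segs)]))
  run <- cumsum(newrun)
  first <- which(newrun)
  out <- GenomicRanges::GRanges(chrom[first],
    IRanges::IRanges(start = tapply(start(segs), run, min),
                     end = tapply(end(segs), run, max)))
  mcols(out) <- mcols(segs)[first, , drop = FALSE]
  out
}

#' Dataset-support histogram of disjoint regions
#'
#' Counts disjoint regions per support level after merging book-ended
#' segments that share the same support count.
#'
#' @param segments output of [support_segments()].
#' @return named integer vector: support level to number of regions; sums
#'   to the total region count.
#' @export
support_histogram <- function(segments) {
  if (!length(segments)) return(setNames(integer(0), character(0)))
  merged <- merge_adjacent_segments(segments,
                                    key = as.character(mcols(segments)$support))
  tab <- table(mcols(merged)$support)
  setNames(as.integer(tab), names(tab))
}

#' Maximal merged binding-site regions with their peak support
#'
#' A binding site, for thresholding purposes, is a maximal merged region
#' of the segmentation; its support is the maximum segment support inside
#' it.
#'
#' @param segments output of [support_segments()].
#' @return `GRanges` with metadata `support`.
#' @export
merged_regions <- function(segments) {
  red <- GenomicRanges::reduce(GenomicRanges::granges(segments))
  if (!length(red)) {
    mcols(red)$support <- integer(0)
    return(red)
  }
  hits <- GenomicRanges::findOverlaps(red, segments)
  sup <- tapply(mcols(segments)$support[subjectHits(hits)],
                factor(queryHits(hits), levels = seq_along(red)), max)
  mcols(red)$support <- as.integer(sup)
  red
}

#' Build the shared and factor-unique peak class sets
#'
#' Classifies every maximal merged region of the combined (p63 + p53)
#' coverage. A region is `shared` when its maximal p63 and p53 segment
#' supports both reach `min_shared`; `p53_unique` when p53 support reaches
#' `min_unique` and not a single p63 dataset overlaps the region (by at
#' least 1 bp); `p63_unique` symmetric. Regions with 1 to
#' `min_shared - 1` datasets of the opposite factor belong to no class
#' set.
#'
#' @param p63_segments,p53_segments per-factor [support_segments()]
#'   output.
#' @param min_shared,min_unique dataset-support thresholds (default 5,
#'   matching the compiled 20-dataset p63 / 28-dataset p53 corpus).
#' @return list of class `peak_class_sets` with elements `shared`,
#'   `p53_unique`, `p63_unique` (each a `GRanges` with `support_p63`,
#'   `support_p53`), `regions` (all combined regions with their class) and
#'   `thresholds`.
#' @export
build_class_sets <- function(p63_segments, p53_segments,
                             min_shared = 5, min_unique = 5) {
  comb <- GenomicRanges::reduce(c(GenomicRanges::granges(p63_segments),
                                  GenomicRanges::granges(p53_segments)))
  max_sup <- function(regions, segs) {
    if (!length(regions)) return(integer(0))
    sup <- integer(length(regions))
    if (length(segs)) {
      hits <- GenomicRanges::findOverlaps(regions, segs)
      got <- tapply(mcols(segs)$support[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(regions)), max)
      sup <- as.integer(got)
      sup[is.na(sup)] <- 0L
    }
    sup
  }
  s63 <- max_sup(comb, p63_segments)
  s53 <- max_sup(comb, p53_segments)
  mcols(comb)$support_p63 <- s63
  mcols(comb)$support_p53 <- s53
  cls <- rep("none", length(comb))
  cls[s63 >= min_shared & s53 >= min_shared] <- "shared"
  cls[s53 >= min_unique & s63 == 0L] <- "p53_unique"
  cls[s63 >= min_unique & s53 == 0L] <- "p63_unique"
  mcols(comb)$class <- cls
  structure(list(shared = comb[cls == "shared"],
                 p53_unique = comb[cls == "p53_unique"],
                 p63_unique = comb[cls == "p63_unique"],
                 regions = comb,
                 thresholds = c(min_shared = min_shared,
                                min_unique = min_unique)),
            class = "peak_class_sets")
}
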