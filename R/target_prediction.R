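#' @name target_prediction
#' @title Multi-evidence direct-target calling
#'
#' @description
#' A gene is called a high-probability direct target when its absolute
#' Expression Score reaches `min_abs_score` (default 8, half the
#' 16-dataset corpus) and it is linked to a binding site supported by at
#' least `min_support` datasets (default 10, half the p63 corpus), either
#' through a TSS within `window` bp (default 5 kb, inclusive) or through
#' an elite enhancer:gene association overlapping the site. Calls carry
#' both evidence flags and can additionally be flagged for
#' direction-matched membership in an SCC-regulated gene set.
NULL

#' High-support binding sites
#'
#' @param segments [support_segments()] output (or any `GRanges` with a
#'   `support` metadata column; merged regions keep the maximal segment
#'   support).
#' @param min_support dataset-support floor (default 10).
#' @return `GRanges` of merged regions with `support >= min_support`.
#' @export
high_support_sites <- function(segments, min_support = 10) {
  reg <- merged_regions(segments)
  reg[mcols(reg)$support >= min_support]
}

#' Genes with a site near their TSS
#'
#' A gene is flagged when any site has at least 1 bp within
#' `[tss - window, tss + window]`; the distance is measured from the
#' nearest site boundary to the TSS point, the window boundary is
#' inclusive, and any TSS of a multi-TSS gene qualifies.
#'
#' @param sites `GRanges` (typically [high_support_sites()]).
#' @param tss_table data.frame from [read_tss()] (`pos` is 0-based).
#' @param window proximity window in bp (default 5000).
#' @return named logical vector over the genes of `tss_table`.
#' @export
proximal_genes <- function(sites, tss_table, window = 5000) {
  genes <- unique(tss_table$gene_id)
  out <- setNames(rep(FALSE, length(genes)), genes)
  if (!length(sites) || !nrow(tss_table)) return(out)
  pts <- GenomicRanges::GRanges(tss_table$chrom,
    IRanges::IRanges(tss_table$pos + 1, tss_table$pos + 1))
  hits <- GenomicRanges::findOverlaps(pts, sites + window)
  out[unique(tss_table$gene_id[queryHits(hits)])] <- TRUE
  out
}

#' Genes linked to a site through an enhancer association
#'
#' @param sites `GRanges` of high-support sites.
#' @param links `GRanges` from [read_enhancer_links()] (`gene_id`,
#'   `elite`).
#' @param require_elite only elite ("double-elite") links count
#'   (default TRUE).
#' @return named logical vector over the genes appearing in `links`.
#' @export
enhancer_genes <- function(sites, links, require_elite = TRUE) {
  genes <- unique(mcols(links)$gene_id)
  out <- setNames(rep(FALSE, length(genes)), genes)
  if (!length(sites) || !length(links)) return(out)
  use <- if (require_elite) links[mcols(links)$elite] else links
  if (!length(use)) return(out)
  hit <- IRanges::overlapsAny(use, sites)
  out[unique(mcols(use)$gene_id[hit])] <- TRUE
  out
}

#' Call high-probability direct targets
#'
#' @param score_table data.frame with `gene_id` and `score` (typically
#'   from [expression_score()]).
#' @param proximal_map,enhancer_map named logical vectors (see
#'   [proximal_genes()], [enhancer_genes()]); genes absent from a map
#'   count as FALSE.
#' @param min_abs_score absolute Expression Score floor (default 8).
#' @return data.frame of calls: `gene_id`, `score`, `proximal`,
#'   `enhancer_linked`, `direction` (up/down from the score sign),
#'   `scc_flag` (FALSE until [flag_gene_set()]); every emitted call has
#'   at least one evidence flag.
#' @export
call_targets <- function(score_table, proximal_map, enhancer_map,
                         min_abs_score = 8) {
  prox <- unname(proximal_map[score_table$gene_id])
  prox[is.na(prox)] <- FALSE
  enh <- unname(enhancer_map[score_table$gene_id])
  enh[is.na(enh)] <- FALSE
  keep <- abs(score_table$score) >= min_abs_score & (prox | enh) &
    score_table$score != 0
  out <- data.frame(gene_id = score_table$gene_id[keep],
                    score = score_table$score[keep],
                    proximal = prox[keep], enhancer_linked = enh[keep],
                    direction = ifelse(score_table$score[keep] > 0, "up",
                                       "down"),
                    scc_flag = FALSE, stringsAsFactors = FALSE)
  o <- order(-out$score, out$gene_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$proximal | out$enhancer_linked))
  out
}

#' Flag calls overlapping a direction-annotated gene set
#'
#' The flag is set only when the set's direction for the gene matches the
#' call's direction (a gene up-regulated by p63 is flagged only if the
#' set lists it as up).
#'
#' @param calls output of [call_targets()].
#' @param gene_set data.frame from [read_gene_set()] (`gene_id`,
#'   `direction`).
#' @return `calls` with an updated logical `scc_flag`.
#' @export
flag_gene_set <- function(calls, gene_set) {
  key <- paste(gene_set$gene_id, gene_set$direction)
  calls$scc_flag <- paste(calls$gene_id, calls$direction) %in% key
  calls
}

#' Read a published-style target table
#'
#' Reads the packaged high-probability target table (gene symbol,
#' Expression Score, proximal-binding flag, enhancer-binding flag,
#' SCC-overlap flag) shipped in `inst/extdata/table1_p63_targets.tsv`.
#'
#' @param path TSV with header `gene_id`, `score`, `proximal`,
#'   `enhancer`, `scc` (yes/no flags).
#' @return data.frame with logical flag columns.
#' @export
read_target_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "score", "proximal", "enhancer", "scc")
  if (length(setdiff(need, names(tab))))
    stop("target table needs columns: ", paste(need, collapse = ", "))
  tab$proximal <- tab$proximal == "yes"
  tab$enhancer <- tab$enhancer == "yes"
  tab$scc <- tab$scc == "yes"
  tab
}
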