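#' @name expression_meta
#' @title Vote-count meta-analysis of differential-expression datasets
#'
#' @description
#' The Expression Score of a gene is the number of datasets that call it
#' significantly up-regulated minus the number that call it significantly
#' down-regulated, computed over the datasets that cover the gene. Genes
#' must be covered by at least `min_datasets` datasets including at least
#' `min_rnaseq` RNA-seq datasets to be scored. All tables are assumed
#' sign-oriented so that positive log2 fold-change means "higher when p63
#' is active" (see the `sign_flip` argument of [read_de_table()]).
NULL

#' Per-gene significance call in one dataset
#'
#' A gene is called `up` when its adjusted p-value is at or below `alpha`
#' and its log2 fold-change exceeds `min_abs_log2fc`; `down` symmetric;
#' `ns` otherwise. The p-value boundary is inclusive.
#'
#' @param table a `de_table`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_abs_log2fc minimal absolute log2 fold-change (default 0:
#'   only the p-value gates the call).
#' @return data.frame with `gene_id` and `call` in `up`/`down`/`ns`.
#' @export
call_significance <- function(table, alpha = 0.05, min_abs_log2fc = 0) {
  stopifnot(inherits(table, "de_table"), alpha > 0, alpha < 1,
            min_abs_log2fc >= 0)
  d <- table$data
  call <- rep("ns", nrow(d))
  call[d$adj_p <= alpha & d$log2fc > min_abs_log2fc] <- "up"
  call[d$adj_p <= alpha & d$log2fc < -min_abs_log2fc] <- "down"
  data.frame(gene_id = d$gene_id, call = call, stringsAsFactors = FALSE)
}

#' Expression Score over a dataset corpus
#'
#' @param tables list of `de_table` objects (typically the 16 datasets of
#'   the compiled corpus).
#' @param alpha,min_abs_log2fc passed to [call_significance()].
#' @param min_datasets minimal number of covering datasets (default 3).
#' @param min_rnaseq minimal number of covering RNA-seq datasets
#'   (default 1). "Covering" means the gene appears in the dataset's table
#'   at all, significant or not.
#' @param median_over `"covered"` (default) computes the median log2
#'   fold-change over all covering datasets; `"significant"` over the
#'   significant ones only.
#' @return data.frame of scored genes: `gene_id`, `score`, `n_up`,
#'   `n_down`, `n_covered`, `n_covered_rnaseq`, `median_log2fc`, `group`
#'   (initially equal to `score`, see [merge_sparse_groups()]) and unique
#'   `rank` (see [ranked_list()]).
#' @export
expression_score <- function(tables, alpha = 0.05, min_abs_log2fc = 0,
                             min_datasets = 3, min_rnaseq = 1,
                             median_over = c("covered", "significant")) {
  median_over <- match.arg(median_over)
  if (!length(tables)) stop("need at least one DE table")
  platforms <- vapply(tables, function(t) t$platform, "")
  if (min_rnaseq > sum(platforms == "rnaseq")) {
    warning("fewer RNA-seq datasets than min_rnaseq; no gene can be scored")
    return(empty_score_table())
  }
  long <- do.call(rbind, lapply(tables, function(t) {
    calls <- call_significance(t, alpha, min_abs_log2fc)
    data.frame(gene_id = t$data$gene_id, log2fc = t$data$log2fc,
               call = calls$call, rnaseq = t$platform == "rnaseq",
               stringsAsFactors = FALSE)
  }))
  g <- factor(long$gene_id)
  n_up <- as.integer(tapply(long$call == "up", g, sum))
  n_down <- as.integer(tapply(long$call == "down", g, sum))
  n_cov <- as.integer(tapply(rep(1L, nrow(long)), g, sum))
  n_rna <- as.integer(tapply(long$rnaseq, g, sum))
  med <- if (median_over == "covered") {
    as.numeric(tapply(long$log2fc, g, median))
  } else {
    sig_med <- tapply(seq_len(nrow(long)), g, function(i) {
      i <- i[long$call[i] != "ns"]
      if (length(i)) median(long$log2fc[i]) else NA_real_
    })
    as.numeric(sig_med)
  }
  rec <- data.frame(gene_id = levels(g), score = n_up - n_down,
                    n_up = n_up, n_down = n_down, n_covered = n_cov,
                    n_covered_rnaseq = n_rna, median_log2fc = med,
                    stringsAsFactors = FALSE)
  rec <- rec[rec$n_covered >= min_datasets & rec$n_covered_rnaseq >= min_rnaseq, ]
  if (!nrow(rec)) {
    warning("no gene passes the coverage rule")
    return(empty_score_table())
  }
  rec$group <- rec$score
  rownames(rec) <- NULL
  ranked_list(rec)
}

empty_score_table <- function() {
  data.frame(gene_id = character(0), score = integer(0), n_up = integer(0),
             n_down = integer(0), n_covered = integer(0),
             n_covered_rnaseq = integer(0), median_log2fc = numeric(0),
             group = integer(0), rank = integer(0))
}

#' Merge sparsely populated extreme score groups
#'
#' Score groups are the integer score values. An extreme (outermost
#' positive or negative) group with fewer than `min_group_size` members is
#' merged one step toward zero; merging repeats until both terminal groups
#' satisfy the floor (or reach zero). The reported `group` label changes,
#' the raw `score` is preserved.
#'
#' @param records score table from [expression_score()].
#' @param min_group_size group-size floor (default 3).
#' @return the table with an updated `group` column.
#' @export
merge_sparse_groups <- function(records, min_group_size = 3) {
  if (!nrow(records)) return(records)
  grp <- records$group
  for (side in c(1, -1)) {
    repeat {
      vals <- sort(unique(grp[sign(grp) == side]) * side, decreasing = TRUE)
      if (!length(vals)) break
      ext <- vals[1] * side
      if (sum(grp == ext) >= min_group_size || ext == 0) break
      step <- ext - side
      grp[grp == ext] <- step
    }
  }
  records$group <- grp
  records
}

#' Uniquely ranked gene list
#'
#' Orders genes descending by score, ties broken descending by median
#' log2 fold-change, remaining ties broken lexicographically by gene id,
#' and assigns unique ranks 1..N. Suitable as a pre-ranked input for gene
#' set enrichment tools.
#'
#' @param records score table.
#' @return the table, ordered, with a `rank` column.
#' @export
ranked_list <- function(records) {
  if (!nrow(records)) {
    records$rank <- integer(0)
    return(records)
  }
  o <- order(-records$score, -records$median_log2fc, records$gene_id)
  records <- records[o, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Write the score table and ranked list
#' @param records score table.
#' @param dir output directory.
#' @return paths of the two written TSV files, invisibly.
#' @export
write_score_table <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "expression_score.tsv")
  p2 <- file.path(dir, "ranked_list.tsv")
  write.table(records, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(records[, c("gene_id", "rank", "score", "median_log2fc")],
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
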