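#' @name pipeline
#' @title End-to-end orchestration of the analysis stages
#'
#' @description
#' [run_all()] chains the five analysis stages — expression scoring, peak
#' integration, iterative motif discovery, architecture classification,
#' target calling — over an input directory laid out as written by
#' [simulate_inputs()] (the same layout accommodates real data: DE tables
#' plus manifest, per-dataset peak BEDs plus manifest, genome FASTA, TSS
#' table, enhancer links, gene set). A JSON run manifest records the
#' parameters, input checksums and per-stage counts so a run can be
#' audited and reproduced.
NULL

to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' Default pipeline parameters
#'
#' Every threshold of the published analysis chain is a named key with
#' its published default: significance `alpha` 0.05, coverage floors 3
#' datasets / 1 RNA-seq, class-set supports 5/5, high-support floor 10,
#' TSS window 5000 bp, absolute score floor 8, motif widths
#' 10/15/20/25 bp.
#'
#' @param ... overrides.
#' @return named list.
#' @export
run_params <- function(...) {
  p <- list(alpha = 0.05, min_abs_log2fc = 0, min_datasets = 3,
            min_rnaseq = 1, min_shared = 5, min_unique = 5,
            min_support = 10, window = 5000, min_abs_score = 8,
            lengths = c(10, 15, 20, 25), motif_set = "shared",
            max_tiers = 4, seed = 7, require_elite = TRUE,
            min_group_size = 3)
  modifyList(p, list(...))
}

read_peak_manifest_sets <- function(input_dir) {
  man <- read.delim(file.path(input_dir, "peak_manifest.tsv"),
                    stringsAsFactors = FALSE)
  out <- list()
  for (fac in unique(man$factor)) {
    sub <- man[man$factor == fac, ]
    if ("replicate_group" %in% names(sub) &&
        anyDuplicated(sub$replicate_group)) {
      grs <- lapply(split(sub$path, sub$replicate_group), function(paths)
        consolidate_replicates(lapply(paths, read_bed)))
      names(grs) <- unique(sub$replicate_group)
    } else {
      grs <- lapply(sub$path, read_bed)
      names(grs) <- sub$dataset_id
    }
    out[[fac]] <- grs
  }
  out
}

#' Run the full pipeline
#'
#' @param input_dir directory with the input bundle (see
#'   [simulate_inputs()] for the layout).
#' @param out_dir output directory (created).
#' @param params list from [run_params()].
#' @param verbose log per-stage counts.
#' @return invisibly, a list with the main stage results (`scores`,
#'   `class_sets`, `motifs`, `calls`, `composition`, `targets`) and the
#'   manifest.
#' @export
run_all <- function(input_dir, out_dir, params = run_params(),
                    verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message(...)
  manifest <- list(params = params, inputs = list(), counts = list())

  # stage 1: expression scoring -------------------------------------------
  expr_man_path <- file.path(input_dir, "expression_manifest.tsv")
  if (!file.exists(expr_man_path))
    stop("score stage: missing expression manifest: ", expr_man_path)
  expr_man <- read.delim(expr_man_path, stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(expr_man)), function(i)
    read_de_table(expr_man$path[i], expr_man$dataset_id[i],
                  expr_man$platform[i],
                  sign_flip = isTRUE(expr_man$sign_flip[i])))
  scores <- expression_score(tables, alpha = params$alpha,
                             min_abs_log2fc = params$min_abs_log2fc,
                             min_datasets = params$min_datasets,
                             min_rnaseq = params$min_rnaseq)
  scores <- merge_sparse_groups(scores, params$min_group_size)
  write_score_table(scores, out_dir)
  manifest$counts$scored_genes <- nrow(scores)
  note("score: ", nrow(scores), " genes scored")

  # stage 2: peak integration ---------------------------------------------
  peak_sets <- read_peak_manifest_sets(input_dir)
  if (!all(c("p63", "p53") %in% names(peak_sets)))
    stop("peaks stage: manifest must provide factors p63 and p53")
  seg63 <- support_segments(peak_sets$p63)
  seg53 <- support_segments(peak_sets$p53)
  class_sets <- build_class_sets(seg63, seg53, params$min_shared,
                                 params$min_unique)
  for (nm in c("shared", "p53_unique", "p63_unique")) {
    gr <- class_sets[[nm]]
    mcols(gr)$bed_name <- paste0(nm, "_", seq_along(gr))
    mcols(gr)$bed_score <- pmin(mcols(gr)$support_p63,
                                mcols(gr)$support_p53)
    if (nm == "p53_unique") mcols(gr)$bed_score <- mcols(gr)$support_p53
    if (nm == "p63_unique") mcols(gr)$bed_score <- mcols(gr)$support_p63
    write_bed(gr, file.path(out_dir, paste0(nm, ".bed")))
  }
  for (fac in c("p63", "p53")) {
    segs <- if (fac == "p63") seg63 else seg53
    mcols(segs)$bed_name <- mcols(segs)$member_ids
    mcols(segs)$bed_score <- mcols(segs)$support
    write_bed(segs, file.path(out_dir, paste0(fac, "_segments.bed")))
    hist <- support_histogram(segs)
    write.table(data.frame(support = names(hist), n_regions = hist,
                           row.names = NULL),
                file.path(out_dir, paste0(fac, "_support_histogram.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$counts$regions <- length(class_sets$regions)
  manifest$counts$shared <- length(class_sets$shared)
  manifest$counts$p63_unique <- length(class_sets$p63_unique)
  manifest$counts$p53_unique <- length(class_sets$p53_unique)
  note("peaks: ", length(class_sets$shared), " shared / ",
       length(class_sets$p63_unique), " p63-unique / ",
       length(class_sets$p53_unique), " p53-unique regions")

  # stage 3: iterative motif discovery ------------------------------------
  genome_path <- file.path(input_dir, "genome.fa")
  if (!file.exists(genome_path))
    stop("motif stage: missing genome FASTA: ", genome_path)
  genome <- read_fasta(genome_path)
  set_gr <- class_sets[[params$motif_set]]
  seqs <- extract_peak_sequences(set_gr, genome)
  motifs <- iterative_discovery(seqs, max_iters = params$max_tiers,
                                seed = params$seed,
                                lengths = params$lengths,
                                verbose = verbose)
  for (m in motifs)
    write_motif(m, file.path(out_dir, paste0(m$name, ".meme")))
  rl <- attr(motifs, "removal_log")
  write.table(rl, file.path(out_dir, "motif_removal_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$motif_tiers <- length(motifs)
  note("motifs: ", length(motifs), " family-like tier(s) on the ",
       params$motif_set, " set")

  # stage 4: architecture classification ----------------------------------
  calls <- hierarchical_assign(seqs, motifs)
  comp <- composition(calls)
  write.table(calls, file.path(out_dir, "architecture_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(architecture = names(comp$counts),
                         n = comp$counts, fraction = comp$fractions,
                         row.names = NULL),
              file.path(out_dir, "architecture_composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$classified <- comp$total

  # stage 5: target prediction --------------------------------------------
  tss <- read_tss(file.path(input_dir, "tss.tsv"))
  links <- read_enhancer_links(file.path(input_dir, "enhancer_links.tsv"))
  sites <- high_support_sites(seg63, params$min_support)
  prox <- proximal_genes(sites, tss, params$window)
  enh <- enhancer_genes(sites, links, params$require_elite)
  targets <- call_targets(scores, prox, enh, params$min_abs_score)
  scc_path <- file.path(input_dir, "scc_set.tsv")
  if (file.exists(scc_path))
    targets <- flag_gene_set(targets, read_gene_set(scc_path))
  write.table(format_target_table(targets),
              file.path(out_dir, "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$targets <- nrow(targets)
  manifest$counts$targets_up <- sum(targets$direction == "up")
  manifest$counts$targets_down <- sum(targets$direction == "down")
  note("targets: ", nrow(targets), " direct-target calls (",
       manifest$counts$targets_up, " up, ",
       manifest$counts$targets_down, " down)")

  # manifest ---------------------------------------------------------------
  input_files <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  input_files <- input_files[!grepl("ground_truth", input_files)]
  sums <- tools::md5sum(input_files)
  manifest$inputs <- as.list(setNames(unname(sums),
                                      basename(names(sums))))
  json <- to_json(manifest)
  tmp <- file.path(out_dir, ".run_manifest.tmp")
  writeLines(json, tmp)
  file.rename(tmp, file.path(out_dir, "run_manifest.json"))
  invisible(list(scores = scores, class_sets = class_sets, motifs = motifs,
                 calls = calls, composition = comp, targets = targets,
                 manifest = manifest))
}

#' Format target calls like the published target table
#' @param targets output of [call_targets()]/[flag_gene_set()].
#' @return data.frame with yes/no flag columns.
#' @export
format_target_table <- function(targets) {
  data.frame(gene_id = targets$gene_id, score = targets$score,
             proximal = ifelse(targets$proximal, "yes", "no"),
             enhancer = ifelse(targets$enhancer_linked, "yes", "no"),
             scc = ifelse(targets$scc_flag, "yes", "no"),
             stringsAsFactors = FALSE)
}
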