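#' @name synthetic_data
#' @title Synthetic input bundles with known ground truth
#'
#' @description
#' Generates the complete input surface of the pipeline — differential
#' expression tables across a dataset corpus, per-dataset peak sets with
#' planted response elements of known architecture and dataset support,
#' TSS and enhancer:gene tables wired to planted target genes — under a
#' single seeded configuration, so every downstream stage can be tested
#' against ground truth without any external download. Defaults emulate
#' the compiled study corpus: 16 expression datasets, 20 p63 and 28 p53
#' ChIP-seq datasets, five response-element architectures over an
#' order-0 background genome.
NULL

SITE_ARCHITECTURES <- c("full_site", "full_site_p63", "full_site_spacer1",
                        "three_quarter", "half_site")

#' Simulation configuration
#'
#' @param seed integer master seed; every generated byte is a function of
#'   it.
#' @param n_genes number of simulated genes.
#' @param n_datasets_expr expression datasets (default 16, the compiled
#'   corpus size); the first `n_rnaseq` are RNA-seq, the rest microarray.
#' @param n_rnaseq RNA-seq datasets among them.
#' @param frac_true_up,frac_true_down fractions of genes truly up-/
#'   down-regulated.
#' @param detect_prob per-dataset probability that a truly regulated,
#'   covered gene is called significant.
#' @param fp_rate probability that an unregulated covered gene is called
#'   significant (random sign).
#' @param alpha significance level used when emitting adjusted p-values.
#' @param cover_prob per-dataset coverage probability of a normal gene.
#' @param frac_sparse fraction of genes with sparse coverage
#'   (`sparse_cover_prob`), planted so that the >= 3-dataset coverage rule
#'   has something to exclude.
#' @param sparse_cover_prob coverage probability of sparse genes.
#' @param lfc_mean,lfc_sd log2 fold-change magnitude of significant calls.
#' @param null_lfc_sd log2 fold-change spread of non-significant calls.
#' @param n_datasets_p63,n_datasets_p53 ChIP-seq dataset counts
#'   (defaults 20 and 28).
#' @param genome_len background genome length in bp.
#' @param background_gc genome GC content (order-0 background).
#' @param chrom_name simulated chromosome name.
#' @param n_sites named integer vector of planted site counts per
#'   architecture (names among `r toString(SITE_ARCHITECTURES)`).
#' @param site_support_decay geometric decay of the dataset-support
#'   distribution (P(support = k) proportional to `decay^k`), emulating
#'   the observed long-tailed support histograms.
#' @param site_support_dist optional explicit support distribution
#'   (probabilities over support 1..K, truncated/renormalised per
#'   factor); overrides the decay.
#' @param peak_width,peak_jitter emitted peak width and uniform jitter of
#'   the peak centre around the planted site (bp).
#' @param frac_factor_both,frac_factor_p63,frac_factor_p53 factor profile
#'   probabilities of a planted site (bound by both factors or unique to
#'   one).
#' @param frac_wired_proximal,frac_wired_enhancer,frac_wired_both
#'   fractions of truly regulated genes wired to a high-support p63 site
#'   through TSS proximity only, an elite enhancer link only, or both.
#' @param n_distractor_links decoy links of each decoy type.
#' @param min_support dataset-support floor defining a "high-support"
#'   site for wiring (default 10, half of the p63 corpus).
#' @param tss_window TSS proximity window in bp (default 5000).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 2000, n_datasets_expr = 16,
                       n_rnaseq = 8, frac_true_up = 0.08,
                       frac_true_down = 0.05, detect_prob = 0.9,
                       fp_rate = 0.02, alpha = 0.05, cover_prob = 1,
                       frac_sparse = 0.02, sparse_cover_prob = 0.125,
                       lfc_mean = 1.5, lfc_sd = 0.5, null_lfc_sd = 0.25,
                       n_datasets_p63 = 20, n_datasets_p53 = 28,
                       genome_len = 1e6, background_gc = 0.41,
                       chrom_name = "chrS",
                       n_sites = c(full_site = 40, full_site_p63 = 20,
                                   full_site_spacer1 = 15,
                                   three_quarter = 20, half_site = 25),
                       site_support_decay = 0.85,
                       site_support_dist = NULL,
                       peak_width = 200, peak_jitter = 25,
                       frac_factor_both = 0.5, frac_factor_p63 = 0.3,
                       frac_factor_p53 = 0.2,
                       frac_wired_proximal = 0.4,
                       frac_wired_enhancer = 0.3,
                       frac_wired_both = 0.15,
                       n_distractor_links = 30,
                       min_support = 10, tss_window = 5000) {
  cfg <- as.list(environment())
  probs <- c(frac_true_up, frac_true_down, detect_prob, fp_rate, alpha,
             cover_prob, frac_sparse, sparse_cover_prob, background_gc,
             frac_factor_both, frac_factor_p63, frac_factor_p53,
             frac_wired_proximal, frac_wired_enhancer, frac_wired_both)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (frac_true_up + frac_true_down > 1) stop("true fractions exceed 1")
  if (frac_wired_proximal + frac_wired_enhancer + frac_wired_both > 1)
    stop("wiring fractions exceed 1")
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_rnaseq > n_datasets_expr) stop("n_rnaseq exceeds n_datasets_expr")
  if (any(!names(n_sites) %in% SITE_ARCHITECTURES))
    stop("unknown architecture in n_sites")
  if (genome_len < 1000) stop("genome_len too small")
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Simulate the differential-expression corpus
#'
#' Truly up-regulated genes are called significant-up in
#' Binomial(K, detect_prob) of the datasets covering them (symmetric for
#' down); unregulated genes are called significant with probability
#' `fp_rate` and a random sign. A small planted fraction of genes has
#' sparse coverage so the coverage rule of [expression_score()] is
#' exercised.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (list of `de_table`) and `truth`
#'   (data.frame: `gene_id`, `class` in up/down/null, `sparse`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(n))
    n_up <- round(config$frac_true_up * n)
    n_down <- round(config$frac_true_down * n)
    class <- rep("null", n)
    class[seq_len(n_up)] <- "up"
    if (n_down) class[n_up + seq_len(n_down)] <- "down"
    class <- sample(class)
    sparse <- runif(n) < config$frac_sparse
    truth <- data.frame(gene_id = genes, class = class, sparse = sparse,
                        stringsAsFactors = FALSE)
    tables <- lapply(seq_len(config$n_datasets_expr), function(d) {
      cover_p <- ifelse(sparse, config$sparse_cover_prob, config$cover_prob)
      cov <- runif(n) < cover_p
      idx <- which(cov)
      m <- length(idx)
      cls <- class[idx]
      sig <- runif(m) < ifelse(cls == "null", config$fp_rate,
                               config$detect_prob)
      dir <- ifelse(cls == "up", 1, ifelse(cls == "down", -1,
                    sample(c(-1, 1), m, replace = TRUE)))
      lfc <- ifelse(sig,
                    dir * abs(rnorm(m, config$lfc_mean, config$lfc_sd)),
                    rnorm(m, 0, config$null_lfc_sd) +
                      ifelse(cls == "null", 0, dir * 0.2))
      adj_p <- ifelse(sig, runif(m) * config$alpha,
                      config$alpha + runif(m) * (1 - config$alpha))
      de_table(dataset_id = sprintf("expr%02d", d),
               platform = if (d <= config$n_rnaseq) "rnaseq" else "microarray",
               gene_id = genes[idx], log2fc = lfc, adj_p = adj_p)
    })
    list(tables = tables, truth = truth)
  })
}

sample_from_consensus <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(l) {
    s <- IUPAC_SETS[[l]]
    s[sample.int(length(s), 1)]
  }, ""), collapse = "")
}

draw_support <- function(n_sites, n_datasets, config) {
  p <- if (is.null(config$site_support_dist)) {
    config$site_support_decay ^ seq_len(n_datasets)
  } else {
    if (length(config$site_support_dist) < n_datasets)
      stop("site_support_dist shorter than the dataset count")
    config$site_support_dist[seq_len(n_datasets)]
  }
  sample.int(n_datasets, n_sites, replace = TRUE, prob = p / sum(p))
}

#' Plant response-element sites into a background genome
#'
#' Sites of the five architectures are sampled from their degenerate
#' consensus grammars (uniform over each IUPAC set), written into an
#' order-0 background genome at non-overlapping positions, and emitted
#' into `k` per-dataset peak files per bound factor, where `k` is drawn
#' from the site-support distribution; each emitted peak of width
#' `peak_width` jitters by up to `peak_jitter` bp around the site.
#'
#' @param config a [sim_config()].
#' @param genome optional named character vector to plant into; generated
#'   from `background_gc` when `NULL`.
#' @return list with `genome` (named character), `sites` (`GRanges` with
#'   `site_id`, `architecture`, `factor`, `support_p63`, `support_p53`,
#'   `seq`) and `peaks` (list `p63`/`p53` of per-dataset `GRanges`).
#' @export
plant_sites <- function(config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 202L, {
    gc <- config$background_gc
    if (is.null(genome)) {
      bases <- sample(DNA_BASES, config$genome_len, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      genome <- setNames(paste(bases, collapse = ""), config$chrom_name)
    }
    chrom <- names(genome)[1]
    glen <- nchar(genome[[1]])
    n_sites <- config$n_sites[config$n_sites > 0]
    n_total <- sum(n_sites)
    empty_peaks <- function(k, prefix) setNames(
      replicate(k, GenomicRanges::GRanges(), simplify = FALSE),
      sprintf("%s_ds%02d", prefix, seq_len(k)))
    peaks <- list(p63 = empty_peaks(config$n_datasets_p63, "p63"),
                  p53 = empty_peaks(config$n_datasets_p53, "p53"))
    if (n_total == 0) {
      sites <- GenomicRanges::GRanges()
      mcols(sites) <- S4Vectors::DataFrame(site_id = character(0),
        architecture = character(0), factor = character(0),
        support_p63 = integer(0), support_p53 = integer(0),
        seq = character(0))
      return(list(genome = genome, sites = sites, peaks = peaks))
    }
    margin <- config$peak_width / 2 + config$peak_jitter + 30
    slot <- config$peak_width + 2 * config$peak_jitter + 60
    grid <- seq(ceiling(margin) + 1, glen - ceiling(margin) - 30, by = slot)
    if (length(grid) < n_total)
      stop("infeasible packing: genome too short for ", n_total, " sites")
    centers <- sort(sample(grid, n_total))
    arch <- rep(names(n_sites), n_sites)[sample.int(n_total)]
    factor_of <- vapply(arch, function(a) {
      if (a == "full_site_p63")
        sample(c("p63", "both"), 1)
      else sample(c("both", "p63", "p53"), 1,
                  prob = c(config$frac_factor_both, config$frac_factor_p63,
                           config$frac_factor_p53))
    }, "")
    seqs <- vapply(arch, function(a) sample_from_consensus(re_consensus(a)), "")
    site_start <- centers - floor(nchar(seqs) / 2)
    site_end <- site_start + nchar(seqs) - 1
    gseq <- genome[[1]]
    for (i in seq_len(n_total))
      substr(gseq, site_start[i], site_end[i]) <- seqs[i]
    genome[[1]] <- gseq
    sup63 <- integer(n_total); sup53 <- integer(n_total)
    add_peaks <- function(fac, n_ds, sup) {
      starts <- replicate(n_ds, integer(0), simplify = FALSE)
      for (i in which(sup > 0)) {
        ds <- sample.int(n_ds, sup[i])
        ctr <- centers[i] +
          round(runif(sup[i], -config$peak_jitter, config$peak_jitter))
        st <- ctr - floor(config$peak_width / 2)
        for (j in seq_along(ds))
          starts[[ds[j]]] <- c(starts[[ds[j]]], st[j])
      }
      for (d in seq_len(n_ds))
        if (length(starts[[d]]))
          peaks[[fac]][[d]] <<- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(sort(starts[[d]]), width = config$peak_width))
    }
    has63 <- factor_of %in% c("both", "p63")
    has53 <- factor_of %in% c("both", "p53")
    sup63[has63] <- draw_support(sum(has63), config$n_datasets_p63, config)
    sup53[has53] <- draw_support(sum(has53), config$n_datasets_p53, config)
    add_peaks("p63", config$n_datasets_p63, sup63)
    add_peaks("p53", config$n_datasets_p53, sup53)
    sites <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(site_start, site_end))
    mcols(sites) <- S4Vectors::DataFrame(
      site_id = sprintf("site%04d", seq_len(n_total)),
      architecture = arch, factor = factor_of,
      support_p63 = sup63, support_p53 = sup53, seq = seqs)
    list(genome = genome, sites = sites, peaks = peaks)
  })
}

#' Wire planted target genes to sites via TSS proximity or enhancers
#'
#' A configurable fraction of truly regulated genes receives a TSS within
#' the proximity window of a high-support p63 site; another fraction is
#' connected to such a site only through an elite enhancer link (its TSS
#' is kept clear of all high-support sites); a third gets both routes.
#' Decoy links (non-elite links from high-support sites, elite links from
#' low-support sites) and far-placed TSSs for all remaining genes are
#' added.
#'
#' @param config a [sim_config()].
#' @param expr_truth `truth` from [simulate_expression()].
#' @param sites `sites` from [plant_sites()].
#' @return list with `tss` (data.frame: gene_id, chrom, pos 0-based,
#'   strand), `links` (data.frame: chrom, start, end BED-style, gene_id,
#'   elite yes/no) and `targets` (ground truth: gene_id, route, direction).
#' @export
wire_targets <- function(config, expr_truth, sites) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 303L, {
    chrom <- config$chrom_name
    glen <- config$genome_len
    w <- config$tss_window
    high <- sites[mcols(sites)$support_p63 >= config$min_support]
    low <- sites[mcols(sites)$support_p63 > 0 &
                 mcols(sites)$support_p63 < config$min_support]
    true_genes <- expr_truth$gene_id[expr_truth$class != "null"]
    n_true <- length(true_genes)
    n_p <- round(config$frac_wired_proximal * n_true)
    n_e <- round(config$frac_wired_enhancer * n_true)
    n_b <- round(config$frac_wired_both * n_true)
    if (n_p + n_e + n_b > 0 && !length(high))
      stop("no high-support p63 site available for wiring")
    wired <- sample(true_genes, n_p + n_e + n_b)
    route <- rep(c("proximal", "enhancer", "both"), c(n_p, n_e, n_b))
    excl <- GenomicRanges::reduce(high + (w + 1000))
    far_pos <- function(k) {
      out <- integer(0)
      tries <- 0
      while (length(out) < k && tries < 200) {
        cand <- sample.int(glen - 2000, k - length(out)) + 1000
        gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cand, cand))
        ok <- !IRanges::overlapsAny(gr, excl)
        out <- c(out, cand[ok])
        tries <- tries + 1
      }
      if (length(out) < k) stop("could not place far TSSs; genome too busy")
      out[seq_len(k)]
    }
    tss_pos <- setNames(integer(0), character(0))
    links <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), gene_id = character(0),
                        elite = character(0), stringsAsFactors = FALSE)
    add_link <- function(site, gene, elite) {
      links[nrow(links) + 1, ] <<- list(chrom, max(0, start(site) - 401),
                                        end(site) + 400, gene,
                                        if (elite) "yes" else "no")
    }
    pick_site <- function() high[sample.int(length(high), 1)]
    for (i in seq_along(wired)) {
      g <- wired[i]
      s <- pick_site()
      if (route[i] %in% c("proximal", "both")) {
        ctr <- floor((start(s) + end(s)) / 2)
        tss_pos[g] <- ctr + sample(-4000:4000, 1)
        if (route[i] == "both") add_link(s, g, TRUE)
      } else {
        tss_pos[g] <- far_pos(1)
        add_link(s, g, TRUE)
      }
    }
    rest <- setdiff(expr_truth$gene_id, wired)
    tss_pos[rest] <- far_pos(length(rest))
    # decoys: non-elite links from high-support sites, elite links from
    # low-support sites, both to unwired genes
    nd <- config$n_distractor_links
    if (nd > 0 && length(rest)) {
      if (length(high))
        for (g in sample(rest, min(nd, length(rest))))
          add_link(pick_site(), g, FALSE)
      if (length(low))
        for (g in sample(rest, min(nd, length(rest))))
          add_link(low[sample.int(length(low), 1)], g, TRUE)
    }
    tss <- data.frame(gene_id = names(tss_pos), chrom = chrom,
                      pos = pmax(as.integer(tss_pos) - 1L, 0L),
                      strand = "+", stringsAsFactors = FALSE)
    tss <- tss[order(tss$gene_id), ]
    rownames(tss) <- NULL
    dir_of <- setNames(expr_truth$class, expr_truth$gene_id)
    targets <- data.frame(gene_id = wired, route = route,
                          direction = unname(dir_of[wired]),
                          stringsAsFactors = FALSE)
    list(tss = tss, links = links, targets = targets)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits everything [run_all()] consumes: DE tables plus manifest, genome
#' FASTA, per-dataset peak BEDs plus manifest, TSS table, enhancer:gene
#' links, a direction-annotated SCC-style gene set, and the ground truth
#' with a JSON manifest recording the configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, a list with the generated objects and `dir`.
#' @export
simulate_inputs <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(config)
  planted <- plant_sites(config)
  wiring <- wire_targets(config, expr$truth, planted$sites)
  dedir <- file.path(dir, "de_tables")
  dir.create(dedir, showWarnings = FALSE)
  demanifest <- data.frame(dataset_id = character(0), platform = character(0),
                           path = character(0), sign_flip = logical(0))
  for (t in expr$tables) {
    p <- file.path(dedir, paste0(t$dataset_id, ".tsv"))
    write.table(t$data, p, sep = "\t", quote = FALSE, row.names = FALSE)
    demanifest[nrow(demanifest) + 1, ] <-
      list(t$dataset_id, t$platform, p, FALSE)
  }
  write.table(demanifest, file.path(dir, "expression_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(planted$genome, file.path(dir, "genome.fa"))
  pkdir <- file.path(dir, "peaks")
  dir.create(pkdir, showWarnings = FALSE)
  pkmanifest <- data.frame(dataset_id = character(0), factor = character(0),
                           path = character(0))
  for (fac in names(planted$peaks)) {
    for (ds in names(planted$peaks[[fac]])) {
      p <- file.path(pkdir, paste0(ds, ".bed"))
      write_bed(planted$peaks[[fac]][[ds]], p)
      pkmanifest[nrow(pkmanifest) + 1, ] <- list(ds, fac, p)
    }
  }
  write.table(pkmanifest, file.path(dir, "peak_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(wiring$tss, file.path(dir, "tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(wiring$links, file.path(dir, "enhancer_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scc <- with_seed(config$seed + 404L, {
    n_in <- ceiling(nrow(wiring$targets) / 2)
    take <- if (nrow(wiring$targets))
      wiring$targets[sample.int(nrow(wiring$targets), n_in), ] else
      wiring$targets
    data.frame(gene_id = take$gene_id,
               direction = ifelse(take$direction == "up", "up", "down"),
               stringsAsFactors = FALSE)
  })
  write.table(scc, file.path(dir, "scc_set.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gtdir <- file.path(dir, "ground_truth")
  dir.create(gtdir, showWarnings = FALSE)
  write.table(expr$truth, file.path(gtdir, "expression_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(planted$sites), file.path(gtdir, "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(wiring$targets, file.path(gtdir, "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(config), created = "simulate_inputs")
  manifest$config$n_sites <- as.list(config$n_sites)
  writeLines(to_json(manifest), file.path(dir, "manifest.json"))
  invisible(list(dir = dir, expr = expr, planted = planted, wiring = wiring,
                 scc = scc))
}
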