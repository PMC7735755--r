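fixture_path <- function() {
  system.file("extdata", "table1_p63_targets.tsv", package = "p63grn")
}

test_that("high-support site selection thresholds merged regions monotonically", {
  sets <- c(lapply(setNames(1:12, paste0("a", 1:12)), function(i)
              make_gr(1001, 1200)),
            lapply(setNames(1:9, paste0("b", 1:9)), function(i)
              make_gr(5001, 5200)))
  segs <- support_segments(sets)
  hs10 <- high_support_sites(segs, 10)
  expect_equal(GenomicRanges::start(hs10), 1001)
  expect_equal(length(high_support_sites(segs, 9)), 2)
  hs11 <- high_support_sites(segs, 11)
  expect_true(all(IRanges::overlapsAny(hs11, hs10)))
})

test_that("TSS proximity is boundary-inclusive at exactly the window", {
  sites <- make_gr(1001, 1200)
  S4Vectors::mcols(sites)$support <- 12L
  tss <- data.frame(gene_id = c("at5000", "at5001", "inside"),
                    chrom = "c1", pos = c(6199, 6200, 1100), strand = "+")
  prox <- proximal_genes(sites, tss, window = 5000)
  expect_true(prox[["at5000"]])   # nearest boundary exactly 5000 bp away
  expect_false(prox[["at5001"]])  # 5001 bp away
  expect_true(prox[["inside"]])
  # any TSS of a multi-TSS gene qualifies
  tss2 <- data.frame(gene_id = "multi", chrom = "c1",
                     pos = c(90000, 1500), strand = "+")
  expect_true(proximal_genes(sites, tss2)[["multi"]])
})

test_that("enhancer linkage requires overlap and (by default) elite status", {
  sites <- make_gr(1001, 1200)
  links <- make_gr(c(1100, 1100, 9000), c(1600, 1600, 9400))
  S4Vectors::mcols(links)$gene_id <- c("g_elite", "g_plain", "g_far")
  S4Vectors::mcols(links)$elite <- c(TRUE, FALSE, TRUE)
  enh <- enhancer_genes(sites, links)
  expect_true(enh[["g_elite"]])
  expect_false(enh[["g_plain"]])
  expect_false(enh[["g_far"]])
  enh2 <- enhancer_genes(sites, links, require_elite = FALSE)
  expect_true(enh2[["g_plain"]])
})

test_that("target calls demand both the score floor and an evidence route", {
  scores <- data.frame(gene_id = c("IL1B", "DUSP6", "LOW", "NOEV"),
                       score = c(11, 14, 7, 12))
  prox <- c(IL1B = FALSE, DUSP6 = TRUE, LOW = TRUE, NOEV = FALSE)
  enh <- c(IL1B = TRUE, DUSP6 = TRUE, LOW = TRUE, NOEV = FALSE)
  calls <- call_targets(scores, prox, enh, min_abs_score = 8)
  expect_setequal(calls$gene_id, c("IL1B", "DUSP6"))
  il1b <- calls[calls$gene_id == "IL1B", ]
  expect_false(il1b$proximal)
  expect_true(il1b$enhancer_linked)
  expect_equal(il1b$direction, "up")
  expect_true(all(calls$proximal | calls$enhancer_linked))
})

test_that("raising thresholds never adds a target", {
  withr::local_seed(31)
  genes <- sprintf("g%03d", 1:100)
  scores <- data.frame(gene_id = genes,
                       score = sample(-15:15, 100, replace = TRUE))
  prox <- setNames(runif(100) < 0.4, genes)
  enh <- setNames(runif(100) < 0.4, genes)
  prev <- call_targets(scores, prox, enh, min_abs_score = 6)$gene_id
  for (thr in 7:12) {
    cur <- call_targets(scores, prox, enh, min_abs_score = thr)$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("gene-set flags require a direction match", {
  calls <- data.frame(gene_id = c("up_in_set", "up_in_down_set", "absent"),
                      score = c(9, 9, 9), proximal = TRUE,
                      enhancer_linked = FALSE,
                      direction = "up", scc_flag = FALSE)
  gs <- data.frame(gene_id = c("up_in_set", "up_in_down_set"),
                   direction = c("up", "down"))
  flagged <- flag_gene_set(calls, gs)
  expect_equal(flagged$scc_flag, c(TRUE, FALSE, FALSE))
  empty <- flag_gene_set(calls, gs[0, ])
  expect_false(any(empty$scc_flag))
})

test_that("the packaged target-table fixture loads with sane invariants", {
  tab <- read_target_table(fixture_path())
  expect_equal(nrow(tab), 180)
  expect_true(all(abs(tab$score) >= 8))
  expect_true(all(tab$proximal | tab$enhancer))
})

test_that("synthetic wiring is recovered end to end by the target caller", {
  cfg <- sim_config(seed = 14, n_genes = 600, genome_len = 8e5)
  expr <- simulate_expression(cfg)
  pl <- plant_sites(cfg)
  w <- wire_targets(cfg, expr$truth, pl$sites)
  scores <- expression_score(expr$tables)
  seg63 <- support_segments(pl$peaks$p63)
  sites <- high_support_sites(seg63, cfg$min_support)
  links <- GenomicRanges::GRanges(w$links$chrom,
    IRanges::IRanges(w$links$start + 1, w$links$end))
  S4Vectors::mcols(links)$gene_id <- w$links$gene_id
  S4Vectors::mcols(links)$elite <- w$links$elite == "yes"
  calls <- call_targets(scores, proximal_genes(sites, w$tss, cfg$tss_window),
                        enhancer_genes(sites, links), 8)
  gt <- w$targets$gene_id
  tp <- sum(calls$gene_id %in% gt)
  expect_gte(tp / nrow(calls), 0.9)   # precision
  expect_gte(tp / length(gt), 0.9)    # recall
  # evidence routes agree with the planted ones for enhancer-only genes
  eo <- w$targets$gene_id[w$targets$route == "enhancer"]
  eo_calls <- calls[calls$gene_id %in% eo, ]
  expect_true(all(!eo_calls$proximal))
  expect_true(all(eo_calls$enhancer_linked))
})
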