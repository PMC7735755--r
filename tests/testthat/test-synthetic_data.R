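test_that("configuration validation catches impossible settings", {
  expect_error(sim_config(detect_prob = 1.2), "probabilities")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_true_up = 0.7, frac_true_down = 0.5), "exceed")
  expect_error(sim_config(n_sites = c(banana = 5)), "architecture")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 31, n_genes = 120, genome_len = 1e5,
                    n_sites = c(full_site = 10, half_site = 5))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  pa <- plant_sites(cfg)
  pb <- plant_sites(cfg)
  expect_identical(pa$genome, pb$genome)
  expect_identical(as.data.frame(pa$sites), as.data.frame(pb$sites))
  wa <- wire_targets(cfg, a$truth, pa$sites)
  wb <- wire_targets(cfg, b$truth, pb$sites)
  expect_identical(wa, wb)
  cfg2 <- sim_config(seed = 32, n_genes = 120, genome_len = 1e5,
                     n_sites = c(full_site = 10, half_site = 5))
  expect_false(identical(plant_sites(cfg2)$genome, pa$genome))
})

test_that("planted sites obey their consensus grammar (regex oracle)", {
  cfg <- sim_config(seed = 8, n_genes = 50, genome_len = 3e5,
                    n_sites = c(full_site = 15, full_site_p63 = 10,
                                full_site_spacer1 = 10, three_quarter = 10,
                                half_site = 10))
  pl <- plant_sites(cfg)
  st <- as.data.frame(pl$sites)
  arch2cons <- c(full_site = "full_site", full_site_p63 = "full_site_p63",
                 full_site_spacer1 = "full_site_spacer1",
                 three_quarter = "three_quarter", half_site = "half_site")
  for (i in seq_len(nrow(st))) {
    rx <- iupac_regex(re_consensus(arch2cons[[st$architecture[i]]]))
    expect_match(st$seq[i], paste0("^", rx, "$"))
    # and the planted sequence is really in the genome at the site interval
    expect_equal(substr(pl$genome[[1]], st$start[i], st$end[i]), st$seq[i])
  }
})

test_that("per-site dataset support equals a brute-force recount of the peak files", {
  cfg <- sim_config(seed = 12, n_genes = 50, genome_len = 2e5,
                    n_sites = c(full_site = 12, half_site = 8))
  pl <- plant_sites(cfg)
  for (fac in c("p63", "p53")) {
    sup_col <- paste0("support_", fac)
    for (i in seq_along(pl$sites)) {
      site <- pl$sites[i]
      n_overlapping <- sum(vapply(pl$peaks[[fac]], function(gr)
        any(IRanges::overlapsAny(site, gr)), TRUE))
      expect_equal(n_overlapping, S4Vectors::mcols(pl$sites)[[sup_col]][i])
    }
  }
})

test_that("zero planted sites yield a background-only bundle", {
  cfg <- sim_config(seed = 3, n_genes = 20, genome_len = 5e4,
                    n_sites = c(full_site = 0))
  pl <- plant_sites(cfg)
  expect_equal(length(pl$sites), 0)
  expect_true(all(vapply(pl$peaks$p63, length, 1L) == 0))
  expect_true(all(vapply(pl$peaks$p53, length, 1L) == 0))
  expect_equal(nchar(pl$genome[[1]]), 5e4)
})

test_that("planted support histogram follows the requested distribution", {
  # explicit uniform support distribution over 1..20, 600 sites
  cfg <- sim_config(seed = 77, n_genes = 50, genome_len = 3e6,
                    n_sites = c(half_site = 600),
                    site_support_dist = rep(1 / 28, 28),
                    frac_factor_both = 0, frac_factor_p63 = 1,
                    frac_factor_p53 = 0)
  pl <- plant_sites(cfg)
  sup <- S4Vectors::mcols(pl$sites)$support_p63
  obs <- tabulate(sup, nbins = cfg$n_datasets_p63)
  chi <- suppressWarnings(
    chisq.test(obs, p = rep(1 / cfg$n_datasets_p63, cfg$n_datasets_p63)))
  expect_gt(chi$p.value, 0.01)
})

test_that("wired genes respect their planted evidence route", {
  cfg <- sim_config(seed = 21, n_genes = 400, genome_len = 1e6)
  expr <- simulate_expression(cfg)
  pl <- plant_sites(cfg)
  w <- wire_targets(cfg, expr$truth, pl$sites)
  high <- pl$sites[S4Vectors::mcols(pl$sites)$support_p63 >= cfg$min_support]
  # brute-force distance from every TSS to the nearest high-support site
  dist_to_high <- function(gene) {
    pos <- w$tss$pos[w$tss$gene_id == gene] + 1
    min(abs(c(GenomicRanges::start(high) - pos,
              GenomicRanges::end(high) - pos,
              if (any(GenomicRanges::start(high) <= pos &
                      GenomicRanges::end(high) >= pos)) 0)))
  }
  prox_genes <- w$targets$gene_id[w$targets$route == "proximal"]
  for (g in head(prox_genes, 15)) expect_lte(dist_to_high(g), 5000)
  enh_genes <- w$targets$gene_id[w$targets$route == "enhancer"]
  for (g in head(enh_genes, 15)) expect_gt(dist_to_high(g), 5000)
  # enhancer-wired genes carry an elite link
  elite_genes <- w$links$gene_id[w$links$elite == "yes"]
  expect_true(all(enh_genes %in% elite_genes))
})

test_that("zero wiring fractions produce zero planted targets", {
  cfg <- sim_config(seed = 4, n_genes = 100, genome_len = 5e5,
                    frac_wired_proximal = 0, frac_wired_enhancer = 0,
                    frac_wired_both = 0)
  expr <- simulate_expression(cfg)
  pl <- plant_sites(cfg)
  w <- wire_targets(cfg, expr$truth, pl$sites)
  expect_equal(nrow(w$targets), 0)
})

test_that("simulate_inputs writes a complete, reloadable bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, n_genes = 60, genome_len = 2e5,
                    n_sites = c(full_site = 8, half_site = 4),
                    frac_wired_proximal = 0, frac_wired_enhancer = 0,
                    frac_wired_both = 0)
  simulate_inputs(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression_manifest.tsv", "genome.fa", "peak_manifest.tsv",
      "tss.tsv", "enhancer_links.tsv", "scc_set.tsv", "manifest.json")))))
  man <- read.delim(file.path(dir, "expression_manifest.tsv"))
  expect_equal(nrow(man), cfg$n_datasets_expr)
  t1 <- read_de_table(man$path[1], man$dataset_id[1], man$platform[1])
  expect_gt(nrow(t1$data), 0)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(nchar(genome[[1]]), cfg$genome_len)
})
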