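test_that("peak sequences are extracted, clipped and N-filtered", {
  genome <- c(chr1 = paste(rep("ACGT", 25), collapse = ""))
  gr <- make_gr(11, 30, chrom = "chr1")
  seqs <- extract_peak_sequences(gr, genome)
  expect_equal(unname(nchar(seqs)), 20)
  expect_equal(unname(seqs), unname(substr(genome, 11, 30)))

  expect_warning(
    clipped <- extract_peak_sequences(make_gr(91, 120, chrom = "chr1"), genome),
    "clipped")
  expect_equal(unname(nchar(clipped)), 10)

  genome_n <- c(chr1 = paste0(strrep("N", 50), strrep("A", 50)))
  kept <- extract_peak_sequences(make_gr(c(1, 61), c(40, 100), chrom = "chr1"),
                                 genome_n)
  expect_equal(length(kept), 1)  # the 100%-N window is excluded

  expect_error(extract_peak_sequences(make_gr(1, 10, chrom = "chrX"), genome),
               "absent")
})

test_that("a planted exact word is recovered as the motif consensus", {
  withr::local_seed(501)
  word <- "TGACGTCATCGATTGGCTAA"
  seqs <- vapply(1:200, function(i) plant_in(random_dna(120), word), "")
  m <- discover_motif(seqs, seed = 3)
  cons <- pwm_consensus(m)
  rc <- pwm_consensus(revcomp_probs(m$probs))
  expect_true(grepl(cons, word, fixed = TRUE) ||
              grepl(rc, word, fixed = TRUE) ||
              grepl(word, cons, fixed = TRUE) || grepl(word, rc, fixed = TRUE))
  expect_gte(attr(m, "n_assigned"), 150)
})

test_that("background-only input yields a weak, non-family motif", {
  withr::local_seed(502)
  seqs <- vapply(1:150, function(i) random_dna(200), "")
  m <- discover_motif(seqs, seed = 9)
  expect_false(is_family_like(m))
  # independently computed information content stays low: best-site
  # selection over ~380 windows per sequence caps the apparent IC of a
  # background "motif" near log2(windows) ~ 7.5-8 bits, far below the
  # 12-24 bits of genuine response elements; the family predicate (core
  # anchors + IC floor) is what stops the iterative loop
  ic <- sum(m$probs * log2(pmax(m$probs, 1e-12) /
                            rep(m$background, each = nrow(m$probs))))
  expect_lt(ic, 10)
})

test_that("the EM objective is non-decreasing and underpowered input errors", {
  withr::local_seed(503)
  seqs <- planted_corpus(80, 150, "full_site", rate = 0.9)
  m <- discover_motif(seqs, seed = 2)
  trace <- attr(m, "objective_trace")
  expect_true(all(diff(trace) >= -1e-9))
  expect_error(discover_motif(seqs[1:10]), "underpowered")
})

test_that("discovery is strand-symmetric up to the reverse complement", {
  withr::local_seed(504)
  seqs <- planted_corpus(200, 150, "full_site_p63", rate = 0.9)
  rc_seqs <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  m1 <- discover_motif(seqs, seed = 6)
  m2 <- discover_motif(rc_seqs, seed = 6)
  # the motif found on reverse-complemented input matches the original
  # after reverse complement; compare best-aligned columns by L2
  rc_probs <- revcomp_probs(m2$probs)
  l2 <- function(A, B) mean(sqrt(rowSums((A - B)^2)))
  long <- if (nrow(m1$probs) >= nrow(rc_probs)) m1$probs else rc_probs
  short <- if (nrow(m1$probs) >= nrow(rc_probs)) rc_probs else m1$probs
  best <- min(vapply(0:(nrow(long) - nrow(short)), function(off) {
    A <- long[off + seq_len(nrow(short)), , drop = FALSE]
    min(l2(A, short), l2(A, revcomp_probs(short)))
  }, 0))
  expect_lt(best, 0.05)
})

test_that("detection thresholds bound the background false-hit rate", {
  withr::local_seed(505)
  m <- make_re_pwm("full_site", background = rep(0.25, 4))
  # 1e5 random background windows, scored directly
  n <- 1e5
  W <- matrix(sample.int(4, n * 20, replace = TRUE), n, 20)
  sc <- p63grn:::cpp_score_windows(W, m$log_odds)
  expect_lte(mean(sc >= m$detection_threshold), 1e-3)
  # and the threshold never exceeds the maximum achievable score
  expect_lte(m$detection_threshold, pwm_max_score(m))
})

test_that("the family predicate accepts response elements and rejects others", {
  expect_true(is_family_like(make_re_pwm("full_site")))
  expect_true(is_family_like(make_re_pwm("half_site")))
  expect_false(is_family_like(pwmotif(consensus_to_probs("NNTGACTCANN"))))
  expect_false(is_family_like(pwmotif(matrix(0.25, 20, 4))))
  # low-IC motifs fail the floor even with core anchors
  soft <- consensus_to_probs("NNNCNNGNNN")
  expect_false(is_family_like(pwmotif(soft)))
})

test_that("iterative discovery peels architectures in tiers and always progresses", {
  withr::local_seed(506)
  seqs <- c(planted_corpus(110, 200, "full_site", rate = 1),
            planted_corpus(60, 200, "half_site", rate = 1),
            vapply(1:30, function(i) random_dna(200), ""))
  tiers <- iterative_discovery(seqs, seed = 4)
  expect_gte(length(tiers), 2)
  archs <- vapply(tiers, function(m) m$architecture, "")
  expect_equal(archs[1], "full_site")
  expect_true("half_site" %in% archs)
  log <- attr(tiers, "removal_log")
  expect_true(all(log$n_removed >= 1))     # strict progress
  expect_true(all(diff(log$n_in) < 0))
  # tier labels carry the discovery order
  expect_equal(vapply(tiers, function(m) m$tier, 1L), seq_along(tiers))
})

test_that("a background-only corpus yields zero family tiers", {
  withr::local_seed(507)
  seqs <- vapply(1:120, function(i) random_dna(200), "")
  tiers <- iterative_discovery(seqs, seed = 11)
  expect_equal(length(tiers), 0)
})
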