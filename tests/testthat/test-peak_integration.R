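test_that("replicate consolidation keeps regions covered by two or more replicates", {
  pk <- make_gr(101, 200)
  reps <- list(pk, pk, make_gr(501, 600))
  out <- consolidate_replicates(reps)
  expect_equal(GenomicRanges::start(out), 101)
  expect_equal(GenomicRanges::end(out), 200)

  # partially overlapping replicates: per-base oracle says [151,200]
  out2 <- consolidate_replicates(list(make_gr(101, 200), make_gr(151, 250)))
  expect_equal(GenomicRanges::start(out2), 151)
  expect_equal(GenomicRanges::end(out2), 200)

  # single replicate passes through; zero is an error
  expect_equal(length(consolidate_replicates(list(pk))), 1)
  expect_error(consolidate_replicates(list()), "no replicate")
})

test_that("support segmentation annotates exact member sets", {
  three <- list(a = make_gr(1, 100), b = make_gr(1, 100), c = make_gr(1, 100))
  segs <- support_segments(three)
  expect_equal(length(segs), 1)
  expect_equal(S4Vectors::mcols(segs)$support, 3)
  expect_equal(S4Vectors::mcols(segs)$member_ids, "a,b,c")

  two <- list(A = make_gr(1, 100), B = make_gr(51, 150))
  segs2 <- support_segments(two)
  expect_equal(GenomicRanges::start(segs2), c(1, 51, 101))
  expect_equal(GenomicRanges::end(segs2), c(50, 100, 150))
  expect_equal(S4Vectors::mcols(segs2)$support, c(1, 2, 1))
  expect_equal(S4Vectors::mcols(segs2)$member_ids, c("A", "A,B", "B"))

  expect_equal(length(support_segments(list())), 0)
  expect_equal(length(support_segments(list(a = GenomicRanges::GRanges()))), 0)
})

test_that("sweep-line segmentation equals literal per-base membership counting", {
  withr::local_seed(1234)
  glen <- 2000
  for (i in 1:40) {
    sets <- random_peak_sets(n_datasets = sample(2:5, 1),
                             max_peaks = sample(3:20, 1), glen = glen)
    segs <- support_segments(sets)
    expect_identical(segments_to_per_base(segs, glen),
                     per_base_membership(sets, glen))
  }
})

test_that("covered basepairs are conserved by segmentation", {
  withr::local_seed(55)
  for (i in 1:10) {
    sets <- random_peak_sets(4, 10)
    segs <- support_segments(sets)
    input_union <- GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(
      lapply(sets, GenomicRanges::granges))))
    expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(segs))),
                 sum(GenomicRanges::width(input_union)))
  }
})

test_that("the support histogram counts disjoint regions per support level", {
  segs <- support_segments(list(a = make_gr(1, 100), b = make_gr(1, 100),
                                c = make_gr(1, 100), d = make_gr(301, 400),
                                e = make_gr(301, 400)))
  h <- support_histogram(segs)
  expect_equal(h[["3"]], 1)
  expect_equal(h[["2"]], 1)
  expect_equal(sum(h), 2)
  # book-ended segments with equal support merge into one region:
  # members differ ([1,50] = {a}, [51,100] = {b}) but support is 1 throughout
  segs2 <- support_segments(list(a = make_gr(1, 50), b = make_gr(51, 100)))
  expect_equal(length(segs2), 2)
  expect_equal(support_histogram(segs2), c("1" = 1L))
  expect_equal(length(support_histogram(GenomicRanges::GRanges())), 0)
})

test_that("class sets implement the shared/unique/exclusion-zone rules", {
  mk <- function(n_a, n_b, start, end, prefix) {
    sets <- c(replicate(n_a, make_gr(start, end), simplify = FALSE))
    names(sets) <- paste0(prefix, seq_len(n_a))
    sets
  }
  # region 1: 6x p63 and 6x p53 -> shared
  # region 2: 7x p53, 0 p63 -> p53_unique
  # region 3: 7x p53, 1x p63 -> exclusion zone (no class)
  p63_sets <- c(mk(6, 0, 1000, 1200, "x"), list(solo = make_gr(5001, 5200)))
  p53_sets <- c(mk(7, 0, 1000, 1200, "y"),
                lapply(setNames(1:7, paste0("z", 1:7)), function(i)
                  c(make_gr(3001, 3200), make_gr(5001, 5200))))
  cs <- build_class_sets(support_segments(p63_sets),
                         support_segments(p53_sets))
  expect_equal(GenomicRanges::start(cs$shared), 1000)
  expect_equal(GenomicRanges::start(cs$p53_unique), 3001)
  expect_equal(length(cs$p63_unique), 0)
  none <- cs$regions[S4Vectors::mcols(cs$regions)$class == "none"]
  expect_equal(GenomicRanges::start(none), 5001)
  # the three sets are pairwise disjoint by construction
  expect_equal(length(GenomicRanges::intersect(cs$shared, cs$p53_unique)), 0)
})

test_that("raising min_shared never grows the shared set", {
  withr::local_seed(808)
  for (i in 1:5) {
    p63_sets <- random_peak_sets(6, 12)
    p53_sets <- random_peak_sets(6, 12)
    s63 <- support_segments(p63_sets)
    s53 <- support_segments(p53_sets)
    prev <- NULL
    for (ms in 1:5) {
      cur <- build_class_sets(s63, s53, min_shared = ms)$shared
      if (!is.null(prev))
        expect_true(all(IRanges::overlapsAny(cur, prev, type = "equal")))
      prev <- cur
    }
  }
})
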