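random_small_track <- function(n_max = 50) {
  n <- sample(5:n_max, 1)
  chrom <- sort(sample(as.character(1:3), n, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(2e7, sum(chrom == ch)))))
  make_track(round(runif(n, 0, 1), 2), chrom, pos)   # rounding forces ties
}

test_that("rank_scores ranks extremes first with positional tie-breaks", {
  tr <- make_track(c(0.9, 0.7, 0.5), rep("1", 3), c(100L, 200L, 300L))
  expect_equal(rank_scores(tr), c(1L, 2L, 3L))
  expect_equal(rank_scores(tr, direction = "asc"), c(3L, 2L, 1L))

  tied <- make_track(c(0.5, 0.8, 0.5), c("2", "1", "1"),
                     c(100L, 50L, 900L))
  # equal values: earlier genome position (chrom 1 before 2) ranks better
  expect_equal(rank_scores(tied), c(3L, 1L, 2L))

  withna <- make_track(c(0.2, NaN, 0.6), rep("1", 3), c(1L, 2L, 3L))
  expect_equal(rank_scores(withna), c(2L, NA_integer_, 1L))
  expect_error(rank_scores(make_track(c(NaN, NaN), c("1", "1"), c(1L, 2L))),
               "no finite")
})

test_that("rank_scores equals the count-of-better-elements definition", {
  set.seed(301)
  for (rep in 1:20) {
    tr <- random_small_track()
    ranks <- rank_scores(tr)
    cr <- as.numeric(tr$chrom)
    for (i in seq_len(nrow(tr))) {
      better <- sum(tr$value > tr$value[i]) +
        sum(tr$value == tr$value[i] &
              (cr < cr[i] | (cr == cr[i] & tr$pos_bp < tr$pos_bp[i])))
      expect_identical(ranks[i], as.integer(better + 1))
    }
  }
})

test_that("an isolated top SNP yields a zero-length point region", {
  tr <- make_track(c(1.0, 0.1, 0.05), rep("1", 3),
                   c(5e6, 20e6, 30e6))
  regs <- call_regions(tr, region_params(n_top = 1,
                                         secondary_fraction = 0.99,
                                         window_bp = 1.5e6))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start_bp, 5e6)
  expect_equal(regs$end_bp, 5e6)
  expect_equal(regs$peak_marker_id, "m1")
})

test_that("clustered seeds merge transitively into one region", {
  pos <- seq(1e6, by = 1e6, length.out = 10)
  tr <- make_track(seq(1, 0.1, length.out = 10), rep("1", 10), pos)
  regs <- call_regions(tr, region_params(n_top = 10, secondary_fraction = 1,
                                         window_bp = 1.5e6))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start_bp, 1e6)
  expect_equal(regs$end_bp, 10e6)
  expect_equal(regs$n_members, 10)
})

test_that("the 10-marker toy equals exhaustive rule application", {
  tr <- make_track(c(9, 1, 2, 8, 3, 4, 10, 5, 6, 7), rep("1", 10),
                   seq(1e6, 10e6, by = 1e6))
  got <- call_regions(tr, region_params(n_top = 2, secondary_fraction = 0.5,
                                        window_bp = 3e6))
  want <- call_regions_oracle(tr, 2, 0.5, 3e6)
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start_bp, want$start_bp)
  expect_equal(got$end_bp, want$end_bp)
  expect_equal(got$peak_marker_id, want$peak_marker_id)
})

test_that("call_regions equals the brute-force oracle on random small tracks", {
  set.seed(302)
  for (rep in 1:200) {
    tr <- random_small_track()
    n_top <- sample(1:5, 1)
    frac <- runif(1, 0.05, 0.6)
    win <- sample.int(5e6, 1)
    got <- call_regions(tr, region_params(n_top, frac, win))
    want <- call_regions_oracle(tr, n_top, frac, win)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start_bp, want$start_bp)
    expect_equal(got$end_bp, want$end_bp)
    expect_equal(got$peak_marker_id, want$peak_marker_id)
  }
})

test_that("regions are non-overlapping, contain their peaks, and members are T1 or T2", {
  set.seed(303)
  for (rep in 1:20) {
    tr <- random_small_track()
    params <- region_params(n_top = 5, secondary_fraction = 0.3,
                            window_bp = 3e6)
    regs <- call_regions(tr, params)
    ranks <- rank_scores(tr)
    n_t2 <- ceiling(params$secondary_fraction * sum(!is.na(ranks)))
    for (i in seq_len(nrow(regs))) {
      expect_gte(regs$peak_pos_bp[i], regs$start_bp[i])
      expect_lte(regs$peak_pos_bp[i], regs$end_bp[i])
      mem_ranks <- ranks[match(regs$members[[i]], tr$marker_id)]
      expect_true(all(mem_ranks <= n_t2 | mem_ranks <= params$n_top))
      expect_true(any(mem_ranks <= params$n_top))
    }
    same <- split(regs, regs$chrom)
    for (s in same) if (nrow(s) > 1) {
      s <- s[order(s$start_bp), ]
      expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
    }
  }
})

test_that("widening the window never shrinks regions nor adds regions", {
  set.seed(304)
  for (rep in 1:10) {
    tr <- random_small_track()
    small <- call_regions(tr, region_params(3, 0.3, 1e6))
    big <- call_regions(tr, region_params(3, 0.3, 4e6))
    expect_lte(nrow(big), nrow(small))
    expect_gte(sum(big$end_bp - big$start_bp),
               sum(small$end_bp - small$start_bp))
  }
})

test_that("fewer ranked markers than seeds falls back to all with a warning", {
  tr <- make_track(c(0.4, 0.2), c("1", "1"), c(1e6, 2e6))
  expect_warning(regs <- call_regions(tr, region_params(n_top = 50)),
                 "using all")
  expect_equal(nrow(regs), 1)
})

test_that("region-set intersection keeps dual-support components only", {
  a <- data.frame(chrom = "1", start_bp = 10e6, end_bp = 12e6,
                  peak_pos_bp = 11e6, peak_value = 0.8,
                  stringsAsFactors = FALSE)
  b <- data.frame(chrom = "1", start_bp = 11.5e6, end_bp = 13e6,
                  peak_pos_bp = 12.5e6, peak_value = 1e-9,
                  stringsAsFactors = FALSE)
  v <- intersect_region_sets(a, b)
  expect_equal(nrow(v), 1)
  expect_equal(v$start_bp, 10e6)
  expect_equal(v$end_bp, 13e6)
  expect_equal(v$plink_peak_pos, 11e6)
  expect_equal(v$emmax_peak_pos, 12.5e6)

  # identical sets intersect to themselves with coincident peaks
  same <- intersect_region_sets(a, a)
  expect_equal(same$plink_peak_pos, same$emmax_peak_pos)

  disjoint <- data.frame(chrom = "2", start_bp = 1e6, end_bp = 2e6,
                         peak_pos_bp = 1.5e6, peak_value = 1e-5,
                         stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_region_sets(a, disjoint)), 0)

  # point regions count as intersectable points
  pt <- data.frame(chrom = "1", start_bp = 11e6, end_bp = 11e6,
                   peak_pos_bp = 11e6, peak_value = 1e-7,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_region_sets(a, pt)), 1)
})

test_that("intersection is symmetric up to peak labeling", {
  set.seed(305)
  mk_regs <- function() {
    n <- sample(2:5, 1)
    start <- sort(sample.int(3e7, n))
    data.frame(chrom = sample(c("1", "2"), n, replace = TRUE),
               start_bp = start, end_bp = start + sample.int(3e6, n),
               peak_pos_bp = start, peak_value = runif(n),
               stringsAsFactors = FALSE)
  }
  for (rep in 1:10) {
    a <- mk_regs(); b <- mk_regs()
    ab <- intersect_region_sets(a, b)
    ba <- intersect_region_sets(b, a)
    expect_equal(ab[c("chrom", "start_bp", "end_bp")],
                 ba[c("chrom", "start_bp", "end_bp")])
  }
})

test_that("recovery scoring matches the overlap definition", {
  truth <- data.frame(chrom = c("1", "2"), start_bp = c(1e6, 5e6),
                      end_bp = c(2e6, 6e6), stringsAsFactors = FALSE)
  exact <- cbind(vgr = 1:2, truth)
  expect_equal(recovery_score(exact, truth),
               list(sensitivity = 1.0, false_positive_count = 0L))
  none <- exact[0, ]
  expect_equal(recovery_score(none, truth)$sensitivity, 0)
  off <- data.frame(vgr = 1, chrom = "1", start_bp = 3e6, end_bp = 4e6)
  expect_equal(recovery_score(off, truth)$false_positive_count, 1L)
  expect_equal(recovery_score(off, truth, slack_bp = 1e6)$sensitivity, 0.5)
})
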