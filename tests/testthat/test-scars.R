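ann1 <- genome_annotation("chr1", 100e6, 45e6, 55e6)
ann2 <- genome_annotation("chr2", 80e6, 35e6, 45e6)

prof1 <- function(...) segment_profile("s", seg_df("chr1", ...))
prof2 <- function(...) segment_profile("s", seg_df("chr2", ...))

test_that("major copy state is the longest nonzero state, ties broken deterministically", {
  # length tally: (1,1) covers 60 Mb vs (2,1) 40 Mb
  expect_equal(unname(major_copy_state(
    prof1(c(0, 60e6), c(60e6, 100e6), c(1, 2), 1), "chr1")), c(1, 1))
  expect_equal(unname(major_copy_state(
    prof1(0, 100e6, 2, 1), "chr1")), c(2, 1))
  # exact 50/50 tie: lower total copy number wins
  expect_equal(unname(major_copy_state(
    prof1(c(0, 50e6), c(50e6, 100e6), c(1, 2), 1), "chr1")), c(1, 1))
  # total loss everywhere: no major state
  expect_null(major_copy_state(prof1(0, 100e6, 0, 0), "chr1"))
  expect_error(major_copy_state(prof1(0, 100e6, 1, 1), "chrZ", ann1),
               "unknown chromosome")
})

test_that("major copy state ties agree with the clause-by-clause oracle", {
  for (seed in 1:50) {
    case <- random_case(seed)
    prof <- merge_adjacent_equal(case$profile)
    for (chrom in unique(prof$segments$chrom)) {
      got <- major_copy_state(prof, chrom)
      want <- oracle_major_state(
        prof$segments[prof$segments$chrom == chrom, ])
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("NtAI counts telomeric imbalances deviating from the major state", {
  # q-telomeric AI deviating from (1,1)
  r <- count_ntai(prof1(c(0, 60e6), c(60e6, 100e6), c(1, 2), 1), ann1)
  expect_equal(r$count, 1L)
  expect_equal(r$events$chrom, "chr1")
  expect_equal(r$events$region_start, 60e6)
  expect_equal(r$events$breakpoints, "6e+07")

  # whole-chromosome AI spans the centromere: never counted
  expect_equal(count_ntai(prof1(0, 100e6, 2, 1), ann1)$count, 0L)

  # triploid-background correction: both telomeric segments equal the
  # (2,1) major state, so the interstitial event does not inflate NtAI
  tri <- prof1(c(0, 40e6, 60e6), c(40e6, 60e6, 100e6),
               c(2, 2, 2), c(1, 2, 1))
  expect_equal(count_ntai(merge_adjacent_equal(tri), ann1)$count, 0L)

  # fully balanced genome
  expect_equal(count_ntai(prof1(0, 100e6, 1, 1), ann1)$count, 0L)
})

test_that("NtAI honours the optional minimum event size", {
  p <- prof1(c(0, 60e6), c(60e6, 100e6), c(1, 2), 1)  # 40 Mb event
  expect_equal(count_ntai(p, ann1, scar_config(min_tai = 39e6))$count, 1L)
  expect_equal(count_ntai(p, ann1, scar_config(min_tai = 41e6))$count, 0L)
})

test_that("LST smoothing removes sub-3 Mb segments and joins equal flanks", {
  p <- prof1(c(55e6, 79.5e6, 81.5e6), c(79.5e6, 81.5e6, 100e6),
             c(1, 3, 1), 1)
  arms <- smooth_for_lst(p, ann1)
  q <- arms$chr1_q
  expect_equal(nrow(q), 1L)
  expect_equal(unname(q[1, 1:2]), c(55e6, 100e6))

  # nothing below 3 Mb: unchanged
  p2 <- prof1(c(55e6, 80e6), c(80e6, 100e6), c(1, 2), 1)
  expect_equal(nrow(smooth_for_lst(p2, ann1)$chr1_q), 2L)

  # single segment arm: unchanged
  p3 <- prof1(55e6, 100e6, 1, 1)
  expect_equal(nrow(smooth_for_lst(p3, ann1)$chr1_q), 1L)
})

test_that("LST counts breaks between >= 10 Mb flanks", {
  r <- count_lst(prof1(c(55e6, 80e6), c(80e6, 100e6), c(1, 2), 1), ann1)
  expect_equal(r$count, 1L)
  expect_equal(r$events$breakpoints, "8e+07")

  # 8 Mb middle segment (>= 3 Mb so not smoothed away) blocks both sides
  r2 <- count_lst(prof1(c(55e6, 70e6, 78e6), c(70e6, 78e6, 100e6),
                        c(1, 2, 1), 1), ann1)
  expect_equal(r2$count, 0L)

  expect_equal(count_lst(prof1(0, 100e6, 1, 1), ann1)$count, 0L)
})

test_that("LST gap rule: boundaries across >= 3 Mb of missing coverage are not counted", {
  # 2 Mb gap between different-state flanks: counted
  near <- prof1(c(55e6, 82e6), c(80e6, 100e6), c(1, 2), 1)
  expect_equal(count_lst(near, ann1)$count, 1L)
  # 3 Mb gap: not counted
  far <- prof1(c(55e6, 83e6), c(80e6, 100e6), c(1, 2), 1)
  expect_equal(count_lst(far, ann1)$count, 0L)
})

test_that("HRD-LOH counts >15 Mb LOH regions shorter than the chromosome", {
  expect_equal(count_hrd_loh(prof2(c(0, 20e6), c(20e6, 80e6),
                                   c(2, 1), c(0, 1)), ann2)$count, 1L)
  # whole-chromosome LOH is excluded
  expect_equal(count_hrd_loh(prof2(0, 80e6, 1, 0), ann2)$count, 0L)
  # 12 Mb is too short
  expect_equal(count_hrd_loh(prof2(c(0, 12e6), c(12e6, 80e6),
                                   c(1, 1), c(0, 1)), ann2)$count, 0L)
  # run merged across an internal copy-state change: 20 Mb total
  r <- count_hrd_loh(prof2(c(0, 10e6, 20e6), c(10e6, 20e6, 80e6),
                           c(2, 1, 1), c(0, 0, 1)), ann2)
  expect_equal(r$count, 1L)
  expect_equal(r$events$region_end, 20e6)
})

test_that("homozygous deletions break an LOH run without extending it", {
  # (1,0) 10 Mb + (0,0) 10 Mb + (1,0) 10 Mb: two sub-threshold runs, not
  # one 30 Mb region
  p <- prof2(c(0, 10e6, 20e6, 30e6), c(10e6, 20e6, 30e6, 80e6),
             c(1, 0, 1, 1), c(0, 0, 0, 1))
  expect_equal(count_hrd_loh(p, ann2)$count, 0L)
  # but each side long enough on its own is counted separately
  p2 <- segment_profile("s", seg_df("chr2",
    c(0, 16e6, 18e6, 50e6), c(16e6, 18e6, 34e6, 80e6),
    c(1, 0, 1, 1), c(0, 0, 0, 1)))
  expect_equal(count_hrd_loh(p2, ann2)$count, 2L)
})

test_that("score_sample composes the three counters", {
  ann <- genome_annotation(paste0("chr", 1:3),
                           c(100e6, 100e6, 100e6),
                           c(45e6, 45e6, 45e6), c(55e6, 55e6, 55e6))
  segs <- rbind(
    # chr1: q-telomeric AI deviating from the (1,1) major state -> 1 NtAI
    seg_df("chr1", c(0, 60e6), c(60e6, 100e6), c(1, 2), 1),
    # chr2: balanced q-arm state change with >= 10 Mb flanks -> 1 LST only
    seg_df("chr2", c(0, 55e6, 80e6), c(45e6, 80e6, 100e6),
           c(1, 1, 2), c(1, 1, 2)),
    # chr3: interstitial 20 Mb LOH isolated by 3 Mb coverage gaps -> 1 LOH
    seg_df("chr3", c(0, 8e6, 31e6), c(5e6, 28e6, 45e6),
           c(1, 1, 1), c(1, 0, 1)))
  r <- score_sample(segment_profile("s", segs, annotation = ann), ann)
  expect_equal(r$scores$ntai, 1L)
  expect_equal(r$scores$lst, 1L)
  expect_equal(r$scores$hrd_loh, 1L)
  expect_equal(nrow(r$events), 3L)

  balanced <- segment_profile("s0", seg_df("chr1", 0, 100e6, 1, 1))
  r0 <- score_sample(balanced, ann)
  expect_equal(unlist(r0$scores[, c("ntai", "lst", "hrd_loh")],
                      use.names = FALSE), c(0L, 0L, 0L))
})

test_that("scores are invariant to equal-state splitting and chromosome order", {
  for (seed in 1:25) {
    case <- random_case(seed)
    base <- score_sample(case$profile, case$annotation)$scores
    refined <- refine_profile(case$profile, seed + 1000)
    expect_equal(score_sample(refined, case$annotation)$scores, base)
    shuffled <- case$profile
    set.seed(seed)
    shuffled$segments <- shuffled$segments[sample(nrow(shuffled$segments)), ]
    shuffled <- segment_profile(shuffled$sample_id, shuffled$segments,
                                shuffled$ploidy, shuffled$acf)
    expect_equal(score_sample(shuffled, case$annotation)$scores, base)
  }
})

test_that("excluding chr17 can only lower the HRD-LOH count", {
  cfg17 <- scar_config(exclude_chroms = "chr17")
  ann <- hg_autosomes()
  for (seed in 1:10) {
    sim <- simulate_profile(sim_config(seed = seed, k_loh = 5))
    full <- count_hrd_loh(merge_adjacent_equal(sim$profile), ann)$count
    excl <- count_hrd_loh(merge_adjacent_equal(sim$profile), ann,
                          cfg17)$count
    expect_lte(excl, full)
  }
})

test_that("sex chromosomes are excluded from scoring by default", {
  ann <- genome_annotation(c("chr1", "chrX"), c(100e6, 155e6),
                           c(45e6, 58e6), c(55e6, 62e6))
  segs <- rbind(seg_df("chr1", 0, 100e6, 1, 1),
                seg_df("chrX", c(0, 30e6), c(30e6, 155e6), c(2, 1), c(0, 1)))
  p <- segment_profile("s", segs, annotation = ann)
  r <- score_sample(p, ann)
  expect_equal(unlist(r$scores[, c("ntai", "lst", "hrd_loh")],
                      use.names = FALSE), c(0L, 0L, 0L))
  rX <- score_sample(p, ann, scar_config(include_sex = TRUE))
  expect_gt(rX$scores$hrd_loh, 0L)
})
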