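reg <- function(...) {
  m <- rbind(...)
  data.frame(chrom = "c1", start = m[, 1], end = m[, 2],
             eg4_signal = 1, stratum = "S1")
}

test_that("pG4 containment filter honours half-open boundaries", {
  r <- reg(c(100, 200))
  inside <- data.frame(chrom = "c1", start = 150, end = 180, strand = "+")
  expect_equal(nrow(filter_regions_with_pg4(r, inside)), 1L)
  adjacent <- data.frame(chrom = "c1", start = 200, end = 230, strand = "+")
  expect_equal(nrow(filter_regions_with_pg4(r, adjacent)), 0L)
  onebp <- data.frame(chrom = "c1", start = 199, end = 230, strand = "+")
  expect_equal(nrow(filter_regions_with_pg4(r, onebp)), 1L)
  expect_equal(nrow(filter_regions_with_pg4(r[0, ], inside)), 0L)
})

test_that("stability is the strand-matched window maximum", {
  pg4 <- data.frame(chrom = "c1", start = 990, end = 1010, strand = "+")
  # midpoint 1000, window [925, 1075)
  mm <- data.frame(
    chrom = "c1",
    start = c(930, 960, 1000, 1040, 2000),
    end = c(940, 970, 1010, 1050, 2010),
    value = c(3.0, 27.5, 11.2, 99, 80),
    strand = c("+", "+", "+", "-", "+"))
  expect_equal(stability_of_pg4(pg4, mm), 27.5)
  # only opposite-strand coverage -> missing
  mm_minus <- transform(mm, strand = "-")
  expect_true(is.na(stability_of_pg4(pg4, mm_minus)))
  single <- data.frame(chrom = "c1", start = 995, end = 1005, value = 25.0,
                       strand = "+")
  expect_equal(stability_of_pg4(pg4, single), 25.0)
  bad <- transform(single, value = 150)
  expect_error(stability_of_pg4(pg4, bad), "\\[0, 100\\]")
})

test_that("phyloP window mean is strand-agnostic and per-base weighted", {
  pg4 <- data.frame(chrom = "c1", start = 990, end = 1010, strand = "+")
  # window [975, 1025); two fully contained single-base scores
  track <- data.frame(chrom = "c1", start = c(980, 1010), end = c(981, 1011),
                      value = c(1.0, 3.0))
  expect_equal(phylop_of_pg4(pg4, track), 2.0)
  expect_true(is.na(phylop_of_pg4(pg4, track[0, ])))
  # partial overlap weights by covered width: 5 bases of 4, 10 bases of 8
  track2 <- data.frame(chrom = "c1", start = c(970, 1015), end = c(980, 1035),
                       value = c(4, 8))
  expect_equal(phylop_of_pg4(pg4, track2), (5 * 4 + 10 * 8) / 15)
})

test_that("region value comes from the midpoint-nearest valued pG4", {
  r <- reg(c(1000, 1200))           # midpoint 1100
  pg4s <- data.frame(chrom = "c1", start = c(1100, 1130), end = c(1124, 1150),
                     strand = c("+", "+"))   # midpoints 1112, 1140
  expect_equal(assign_region_value(r, pg4s, c(5, 9)), 5)
  expect_equal(assign_region_value(r, pg4s, c(NA, 9)), 9)   # nearest valued
  expect_true(is.na(assign_region_value(r, pg4s, c(NA, NA))))
  # equidistant midpoints 1090 and 1110: lower start wins
  tie <- data.frame(chrom = "c1", start = c(1080, 1100), end = c(1100, 1120),
                    strand = c("-", "+"))
  expect_equal(assign_region_value(r, tie, c(1, 2)), 1)
  # single overlapping pG4
  expect_equal(assign_region_value(r, pg4s[1, ], 7), 7)
  # genome-wide mode reaches non-overlapping pG4s
  far <- data.frame(chrom = "c1", start = 5000, end = 5020, strand = "+")
  expect_true(is.na(assign_region_value(r, far, 3)))
  expect_equal(assign_region_value(r, far, 3, mode = "genomewide"), 3)
})

test_that("chromatin state is the midpoint's segment, half-open", {
  seg <- data.frame(chrom = "c1", start = c(100, 200), end = c(200, 300),
                    state = c("TssA", "Quies"))
  expect_equal(chrom_state_of_region(reg(c(100, 200)), seg), "TssA")  # mid 150
  expect_equal(chrom_state_of_region(reg(c(150, 250)), seg), "Quies") # mid 200
  expect_true(is.na(chrom_state_of_region(reg(c(500, 600)), seg)))
  overlapping <- rbind(seg, data.frame(chrom = "c1", start = 150, end = 250,
                                       state = "Tx"))
  expect_error(chrom_state_of_region(reg(c(100, 200)), overlapping),
               "overlapping")
})

test_that("ATAC intensity is mean coverage over mean depth", {
  r <- reg(c(1000, 1100))   # length 100
  frag <- data.frame(chrom = "c1", start = 1000, end = 1050)
  expect_equal(atac_intensity(r, frag, mean_depth = 1), 0.5)
  expect_equal(atac_intensity(r, frag, mean_depth = 2), 0.25)  # scaling law
  expect_equal(atac_intensity(r, frag[0, ], mean_depth = 1), 0)
  expect_error(atac_intensity(r, frag, mean_depth = 0), "> 0")
  # overlapping fragments stack
  expect_equal(atac_intensity(r, rbind(frag, frag), mean_depth = 1), 1)
})

test_that("TF occupancy and both recruitment modes", {
  r <- reg(c(1000, 1200))
  peaks <- data.frame(chrom = "c1",
                      start = c(1010, 1100, 1150, 5000),
                      end = c(1060, 1160, 1190, 5100),
                      tf = c("SP1", "SP1", "YY1", "CTCF"))
  m <- tf_metrics(r, peaks)
  expect_equal(m$occupancy[1, c("SP1", "YY1", "CTCF")], c(SP1 = 2L, YY1 = 1L,
                                                          CTCF = 0L))
  expect_equal(m$recruitment, 3L)
  expect_equal(tf_metrics(r, peaks, recruitment = "distinct")$recruitment, 2L)
  none <- tf_metrics(r, peaks[0, ])
  expect_equal(none$recruitment, 0L)
  expect_equal(ncol(none$occupancy), 0L)
})

test_that("fixtures are deterministic and satisfy their invariants", {
  cfg <- fixture_config(n_regions = 5, n_decoys = 2)
  fx1 <- make_genome_fixture(123, cfg)
  fx2 <- make_genome_fixture(123, cfg)
  expect_identical(fx1[setdiff(names(fx1), "config")],
                   fx2[setdiff(names(fx2), "config")])
  for (trk in list(fx1$regions, fx1$pg4s, fx1$mm_track, fx1$phylop_track,
                   fx1$segmentation, fx1$atac_fragments, fx1$tf_peaks)) {
    expect_true(all(trk$start >= 0))
    expect_true(all(trk$start < trk$end))
    expect_true(all(trk$end <= fx1$chrom_sizes[trk$chrom]))
  }
  expect_true(all(fx1$mm_track$value >= 0 & fx1$mm_track$value <= 100))
  # every non-decoy region contains a pG4; decoys contain none
  kept <- filter_regions_with_pg4(fx1$regions, fx1$pg4s)
  expect_equal(nrow(kept), 5L * 3L)
})

test_that("zero TF peaks give zero recruitment downstream", {
  cfg <- fixture_config(n_regions = 3, n_decoys = 0, peaks_per_tf = 0)
  fx <- make_genome_fixture(5, cfg)
  rt <- build_region_table(fx)
  expect_true(all(rt$tf_recruitment == 0L))
})

test_that("mapping agrees exactly with the per-base oracles", {
  set.seed(606)
  for (i in 1:25) {
    fx <- make_genome_fixture(sample.int(1e6, 1), rand_test_config())
    rt <- build_region_table(fx)
    oc <- oracle_region_table(fx)
    expect_equal(rt$region_id, oc$region_id)
    expect_equal(rt$stability, oc$stability)
    expect_equal(rt$phylop, oc$phylop)
    expect_equal(rt$chrom_state, oc$chrom_state)
    expect_equal(rt$atac, oc$atac)
    expect_equal(rt$tf_recruitment, oc$recruitment)
  }
})

test_that("translation invariance: shifting all coordinates changes nothing", {
  fx <- make_genome_fixture(2025, rand_test_config())
  rt1 <- build_region_table(fx)
  shift <- 500L
  fx2 <- fx
  fx2$chrom_sizes <- fx$chrom_sizes + shift
  for (nm in c("regions", "pg4s", "mm_track", "phylop_track", "segmentation",
               "atac_fragments", "tf_peaks")) {
    fx2[[nm]]$start <- fx[[nm]]$start + shift
    fx2[[nm]]$end <- fx[[nm]]$end + shift
  }
  rt2 <- build_region_table(fx2, mean_depth = sum(
    fx$atac_fragments$end - fx$atac_fragments$start) / sum(fx$chrom_sizes))
  rt1 <- build_region_table(fx, mean_depth = sum(
    fx$atac_fragments$end - fx$atac_fragments$start) / sum(fx$chrom_sizes))
  cols <- c("stability", "phylop", "chrom_state", "atac", "tf_recruitment")
  expect_equal(rt1[cols], rt2[cols])
})

test_that("strand flip of pG4s and MM% track leaves stability unchanged", {
  fx <- make_genome_fixture(31, rand_test_config())
  st1 <- stability_of_pg4(fx$pg4s, fx$mm_track)
  flip <- function(s) ifelse(s == "+", "-", "+")
  pg4f <- transform(fx$pg4s, strand = flip(strand))
  mmf <- transform(fx$mm_track, strand = flip(strand))
  expect_equal(stability_of_pg4(pg4f, mmf), st1)
})

test_that("build_region_table composes and propagates missingness", {
  fx <- make_genome_fixture(8, fixture_config(n_regions = 6, n_decoys = 3))
  rt <- build_region_table(fx)
  expect_equal(nrow(rt), 18L)          # decoys dropped by the filter
  expect_true(all(c("stability", "eg4_signal", "atac", "phylop",
                    "chrom_state", "tf_recruitment", "stratum")
                  %in% names(rt)))
  empty <- build_region_table(fx$regions[0, ], fx$pg4s, fx$mm_track,
                              fx$phylop_track, fx$segmentation,
                              fx$atac_fragments, fx$tf_peaks,
                              chrom_sizes = fx$chrom_sizes)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("stability", "chrom_state", "atac") %in% names(empty)))
})
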