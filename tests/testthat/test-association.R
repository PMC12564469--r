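test_that("Spearman matrix: diagonal, perfect inverse, oracle agreement", {
  set.seed(9)
  t <- data.frame(stability = runif(50), eg4_signal = runif(50),
                  atac = runif(50), stratum = "S1")
  t$phylop <- -t$stability                     # perfect monotone inverse
  cm <- spearman_matrix(t, c("stability", "eg4_signal", "atac", "phylop"))
  expect_equal(diag(cm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$rho["stability", "phylop"], -1)
  expect_true(isSymmetric(cm$rho))
  # rank-then-Pearson definitional oracle (mid-ranks)
  r_oracle <- cor(rank(t$stability), rank(t$eg4_signal))
  expect_equal(cm$rho["stability", "eg4_signal"], r_oracle, tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(10)
  t <- data.frame(a = rexp(40), b = rnorm(40))
  c1 <- spearman_matrix(t, c("a", "b"))$rho["a", "b"]
  t2 <- data.frame(a = log(t$a), b = exp(t$b / 2))
  c2 <- spearman_matrix(t2, c("a", "b"))$rho["a", "b"]
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("constant columns yield NA with a warning; NAs use complete pairs", {
  t <- data.frame(a = c(1, 1, 1, 1, 1), b = c(1, 2, 3, 4, 5),
                  c = c(5, 4, NA, 2, 1))
  # the constant column warns once per affected pair (a-b and a-c)
  expect_warning(
    expect_warning(cm <- spearman_matrix(t, c("a", "b", "c")), "constant"),
    "constant")
  expect_true(is.na(cm$rho["a", "b"]))
  expect_equal(cm$n["b", "c"], 4)
  expect_equal(cm$rho["b", "c"], -1)
})

test_that("state distributions: grouping, ordering, normalization", {
  t <- data.frame(chrom_state = c("TssA", "TssA", "Quies"),
                  stability = c(10, 30, 50),
                  tf_recruitment = c(2, 8, 4))
  sd_ <- state_distributions(t, "stability")
  expect_equal(sd_$state, chromhmm18_states())
  expect_equal(sd_$median[sd_$state == "TssA"], 20)
  expect_equal(sd_$n[sd_$state == "TssFlnk"], 0L)
  # recruitment normalized by its maximum
  sd2 <- state_distributions(t, "tf_recruitment")
  expect_equal(sd2$median[sd2$state == "Quies"], 0.5)
  # sort-based group-median oracle on random tables
  set.seed(11)
  t2 <- data.frame(chrom_state = sample(chromhmm18_states(), 300, TRUE),
                   stability = runif(300, 0, 100))
  sd3 <- state_distributions(t2, "stability")
  for (st in unique(t2$chrom_state)) {
    v <- sort(t2$stability[t2$chrom_state == st])
    expect_equal(sd3$median[sd3$state == st],
                 stats::median(v))
  }
  # a metric constant across states: all medians equal it
  t3 <- transform(t2, stability = 5)
  expect_true(all(state_distributions(t3, "stability")$median[
    table(factor(t3$chrom_state, chromhmm18_states())) > 0] == 5))
})

test_that("TSS-proximal assignment: closed window, strand-aware distance", {
  regions <- data.frame(chrom = "c1",
                        start = c(1000, 1000, 990),
                        end = c(1400, 1300, 1390),   # midpoints 1200/1150/1190
                        region_id = c("r1", "r2", "r3"),
                        stability = c(30, 10, NA),
                        stratum = "S1")
  tss <- data.frame(chrom = "c1", pos = 1000, gene_id = "g1", strand = "+")
  a <- tss_proximal_assignments(regions, tss, window_bp = 200)
  expect_setequal(a$region_id, c("r1", "r2", "r3"))
  expect_equal(a$distance[a$region_id == "r1"], 200L)   # exactly at +200
  a2 <- tss_proximal_assignments(regions, tss, window_bp = 199)
  expect_false("r1" %in% a2$region_id)                  # 200 > 199: excluded
  expect_equal(a$stability_class[a$region_id == "r1"], "High")
  expect_equal(a$stability_class[a$region_id == "r2"], "Low")
  expect_true(is.na(a$stability_class[a$region_id == "r3"]))
  # minus-strand gene: downstream is decreasing coordinates
  tss_m <- data.frame(chrom = "c1", pos = 1300, gene_id = "g2", strand = "-")
  am <- tss_proximal_assignments(regions, tss_m)
  expect_equal(am$distance[am$region_id == "r1"], 100L)
  expect_equal(am$distance[am$region_id == "r2"], 150L)
})

test_that("assignment count grows with the window and matches brute force", {
  fx <- make_genome_fixture(17, rand_test_config())
  rt <- build_region_table(fx)
  counts <- vapply(c(0, 100, 200, 400, 800), function(w)
    nrow(tss_proximal_assignments(rt, fx$tss, window_bp = w)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # all-pairs oracle at the default window
  a <- tss_proximal_assignments(rt, fx$tss)
  mid <- (rt$start + rt$end) %/% 2L
  expected <- 0L
  for (t in seq_len(nrow(fx$tss)))
    expected <- expected + sum(rt$chrom == fx$tss$chrom[t] &
                                 abs(mid - fx$tss$pos[t]) <= 200)
  expect_equal(nrow(a), expected)
})

test_that("gene-level class: nearest wins, any-high mode", {
  a <- data.frame(gene_id = c("g", "g"), region_id = c("r1", "r2"),
                  distance = c(-50L, 120L),
                  stability_class = c("Low", "High"))
  expect_equal(gene_stability_classes(a)$stability_class, "Low")
  expect_equal(gene_stability_classes(a, "any-high")$stability_class, "High")
})
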