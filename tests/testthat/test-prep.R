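mk_table <- function(n_per = 10, strata = c("S1", "S2")) {
  set.seed(42)
  n <- n_per * length(strata)
  data.frame(
    stability = runif(n, 0, 60),
    eg4_signal = rexp(n, 1 / 50),
    atac = runif(n, 0, 4),
    phylop = rnorm(n, 1, 1.5),
    tf_recruitment = rpois(n, 3),
    chrom_state = sample(chromhmm18_states(), n, TRUE),
    stratum = rep(strata, each = n_per))
}

test_that("stability uses the fixed cutoff, boundary inclusive", {
  t <- mk_table()
  t$stability[1:3] <- c(25.0, 24.9, 25.1)
  d <- discretize(t)
  expect_equal(as.character(d$Stability[1:3]), c("High", "Low", "High"))
  # configurable cutoff
  d2 <- discretize(t, stability_cutoff = 50)
  expect_equal(as.character(d2$Stability[1]), "Low")
})

test_that("median split: strict-greater rule, per stratum, tie options", {
  t <- data.frame(stability = 30, eg4_signal = c(1:5, 11:15),
                  atac = 1, phylop = 0, tf_recruitment = 0,
                  chrom_state = "TssA",
                  stratum = rep(c("S1", "S2"), each = 5))
  d <- discretize(t, metrics = "eg4_signal")
  expect_equal(as.character(d$eG4s),
               rep(c("Low", "Low", "Low", "High", "High"), 2))
  # constant metric: nothing exceeds the median -> all Low
  t2 <- transform(t, eg4_signal = 7)
  expect_true(all(discretize(t2, metrics = "eg4_signal")$eG4s == "Low"))
  # ties-High option flips values equal to the median
  d3 <- discretize(t, metrics = "eg4_signal", median_ties = "high")
  expect_equal(sum(d3$eG4s == "High"), 6L)
})

test_that("High fraction never exceeds one half under the strict rule", {
  t <- mk_table(50)
  d <- discretize(t)
  for (st in unique(d$stratum))
    for (v in c("eG4s", "ATACSig", "phyloP", "TFs")) {
      frac <- mean(d[[v]][d$stratum == st] == "High")
      expect_lte(frac, 0.5)
    }
})

test_that("incomplete rows are dropped with a message; tiny strata error", {
  t <- mk_table()
  t$stability[4] <- NA
  t$phylop[7] <- NA
  expect_message(d <- discretize(t), "dropped 2")
  expect_equal(nrow(d), nrow(t) - 2L)
  t2 <- mk_table()
  t2$stability[t2$stratum == "S2"][-1] <- NA
  expect_error(suppressMessages(discretize(t2)), "fewer than 2")
})

test_that("discretize output is idempotent under re-binarization", {
  d <- discretize(mk_table(30))
  expect_true(all(vapply(d[setdiff(names(d), "stratum")], is.factor,
                         logical(1))))
  expect_true(!anyNA(d))
})

test_that("equal-allocation sampling: exact counts, errors, empty case", {
  t <- mk_table(20, c("A", "B", "C"))
  d <- discretize(t)
  s <- stratified_sample(d, sampling_config("equal", 7, seed = 1))
  expect_equal(as.vector(table(s$stratum)), c(7L, 7L, 7L))
  expect_equal(nrow(stratified_sample(d, sampling_config("equal", 0))), 0L)
  expect_error(stratified_sample(d, sampling_config("equal", 21)),
               "stratum 'A'")
  # with replacement may exceed the stratum size
  s2 <- stratified_sample(d, sampling_config("equal", 25, seed = 2,
                                             replace = TRUE))
  expect_equal(nrow(s2), 75L)
})

test_that("proportional allocation rounds half to even", {
  t <- data.frame(x = seq_len(7639), stratum = "K562")
  s <- stratified_sample(t, sampling_config("proportional", 10, seed = 3))
  expect_equal(nrow(s), 764L)    # round(763.9)
  t2 <- data.frame(x = seq_len(25), stratum = "S")
  expect_equal(nrow(stratified_sample(t2, sampling_config("proportional", 10,
                                                          seed = 1))),
               2L)               # round(2.5) -> 2, half-even
})

test_that("sampling is seeded-reproducible and exchangeable", {
  d <- discretize(mk_table(200))
  s1 <- stratified_sample(d, sampling_config("equal", 80, seed = 9))
  s2 <- stratified_sample(d, sampling_config("equal", 80, seed = 9))
  expect_identical(s1, s2)
  # marginal of a column matches the stratum frequency within
  # hypergeometric error (3 sd) across a fixed seed set
  for (sd_ in 1:5) {
    s <- stratified_sample(d, sampling_config("equal", 100, seed = sd_))
    for (st in unique(d$stratum)) {
      pop <- d$eG4s[d$stratum == st] == "High"
      smp <- s$eG4s[s$stratum == st] == "High"
      Npop <- length(pop); n <- length(smp); K <- sum(pop)
      mu <- n * K / Npop
      sig <- sqrt(n * (K / Npop) * (1 - K / Npop) * (Npop - n) / (Npop - 1))
      expect_lt(abs(sum(smp) - mu), 3 * sig + 1e-9)
    }
  }
})
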