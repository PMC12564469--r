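p3 <- function(directed = NULL, undirected = NULL)
  pdag(c("A", "B", "C"), directed, undirected)

test_that("average model: inclusion threshold and boundary N", {
  cands <- c(replicate(5, p3(undirected = rbind(c("A", "B"))),
                       simplify = FALSE),
             replicate(5, p3(), simplify = FALSE))
  expect_equal(n_edges(average_model(cands, 5)), 1L)   # in 5 of 10 at N=5
  expect_equal(n_edges(average_model(cands, 6)), 0L)
  # N = 1 union, N = len intersection
  c2 <- list(p3(undirected = rbind(c("A", "B"))),
             p3(undirected = rbind(c("B", "C"))))
  expect_equal(n_edges(average_model(c2, 1)), 2L)
  expect_equal(n_edges(average_model(c2, 2)), 0L)
})

test_that("average model orientation is a plurality vote", {
  cands <- list(p3(directed = rbind(c("A", "B"))),
                p3(directed = rbind(c("A", "B"))),
                p3(directed = rbind(c("B", "A"))))
  m <- average_model(cands, 1)
  expect_equal(directed_edges(m), cbind(from = "A", to = "B"))
  # 1 vs 1 directed tie -> undirected
  tie <- average_model(cands[c(1, 3)], 1)
  expect_equal(nrow(undirected_edges(tie)), 1L)
})

test_that("accuracy/coverage equal the set-ratio formulas", {
  cons <- p3(undirected = rbind(c("A", "B"), c("B", "C")))
  cand1 <- p3(undirected = rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  ac <- accuracy_coverage(list(cand1), cons)
  expect_equal(unname(ac["accuracy"]), 2 / 3)
  expect_equal(unname(ac["coverage"]), 1)
  cand2 <- p3(undirected = rbind(c("A", "B")))
  ac2 <- accuracy_coverage(list(cand1, cand2), cons)
  expect_equal(unname(ac2["accuracy"]), (2 / 3 + 1) / 2)
  expect_equal(unname(ac2["coverage"]), (1 + 1 / 2) / 2)
  expect_equal(unname(accuracy_coverage(list(cons), cons)), c(1, 1))
  # empty candidate / empty consensus conventions
  expect_equal(unname(accuracy_coverage(list(p3()), cons)), c(1, 0))
  expect_equal(unname(accuracy_coverage(list(cand1), p3())), c(0, 1))
})

test_that("directed matching distinguishes orientation status", {
  cons <- p3(directed = rbind(c("A", "B")))
  cand <- p3(undirected = rbind(c("A", "B")))
  expect_equal(unname(accuracy_coverage(list(cand), cons)), c(1, 1))
  expect_equal(unname(accuracy_coverage(list(cand), cons, directed = TRUE)),
               c(0, 0))
})

test_that("robustness AUC: closed forms and fine-grid oracle", {
  expect_equal(robustness_auc(data.frame(accuracy = c(0, 1),
                                         coverage = c(1, 1))), 1)
  expect_equal(robustness_auc(data.frame(accuracy = c(0, 1),
                                         coverage = c(0, 1))), 0.5)
  expect_error(robustness_auc(data.frame(accuracy = c(0.4, 0.4),
                                         coverage = c(0, 1))), "degenerate")
  set.seed(33)
  for (i in 1:20) {
    pts <- data.frame(accuracy = sort(runif(sample(3:8, 1))),
                      coverage = runif(sample(3:8, 1) * 0 + 1))
    pts <- data.frame(accuracy = sort(runif(6)), coverage = runif(6))
    expect_equal(robustness_auc(pts), oracle_auc(pts), tolerance = 1e-7)
  }
})

test_that("common network intersects skeletons and counts directions", {
  m1 <- p3(directed = rbind(c("A", "B")), undirected = rbind(c("B", "C")))
  m2 <- p3(directed = rbind(c("A", "B"), c("C", "B")))
  cn <- common_network(list(m1, m2))
  expect_equal(nrow(cn$edges), 2L)
  ab <- cn$edges[cn$edges$from == "A", ]
  expect_equal(ab$freq_forward, 1)
  bc <- cn$edges[cn$edges$from == "B", ]
  expect_equal(bc$freq_forward, 0.25)    # one undirected (0.5), one C->B (0)
  # identical models: that model, frequencies at the extremes
  cn2 <- common_network(list(m2, m2))
  expect_equal(sort(cn2$edges$freq_forward), c(0, 1))
  # an edge absent from one model is excluded
  cn3 <- common_network(list(m1, p3(directed = rbind(c("A", "B")))))
  expect_equal(nrow(cn3$edges), 1L)
})

test_that("direction frequencies follow the 30/20 worked example", {
  models <- c(replicate(30, p3(directed = rbind(c("A", "B"))),
                        simplify = FALSE),
              replicate(20, p3(directed = rbind(c("B", "A"))),
                        simplify = FALSE))
  cn <- common_network(models)
  expect_equal(cn$edges$freq_forward, 0.6)
  r <- resolve_directions(cn)
  expect_equal(directed_edges(r), cbind(from = "A", to = "B"))
})

test_that("direction resolution: ties undirected, protected nodes sinkless", {
  cn <- structure(list(
    nodes = c("Stability", "X", "Y"),
    edges = data.frame(from = c("Stability", "X"), to = c("X", "Y"),
                       freq_forward = c(0.2, 0.5), n_models = 10L)),
    class = "g4_consensus")
  r <- resolve_directions(cn)
  expect_equal(directed_edges(r), cbind(from = "X", to = "Stability"))
  expect_equal(nrow(undirected_edges(r)), 1L)     # the 0.5 tie
  r2 <- resolve_directions(cn, protected = "Stability")
  expect_equal(nrow(directed_edges(r2)), 0L)      # X->Stability suppressed
})

test_that("degenerate trial loop: one trial, one set, N = 1", {
  spec <- g4_ground_truth()
  tab <- simulate_observations(spec, 400, seed = 5)
  tr <- run_trials(tab, sampling_config("equal", 300), n_sample_sets = 1,
                   n_trials = 1, N_grid = 1,
                   ci_config = ci_test_config(B = 150), master_seed = 7)
  expect_identical(pdag_adjacency(tr$average_models[["1"]][[1]]),
                   pdag_adjacency(tr$candidates[[1]][[1]]))
  expect_equal(tr$record$acc_mean, 1)
  expect_equal(tr$record$cov_mean, 1)
})

test_that("run_trials is bit-identical under a fixed master seed", {
  spec <- g4_ground_truth()
  tab <- simulate_observations(spec, 500, seed = 88)
  t1 <- run_trials(tab, sampling_config("equal", 300), n_sample_sets = 2,
                   n_trials = 2, N_grid = c(1, 2),
                   ci_config = ci_test_config(B = 100), master_seed = 33)
  t2 <- run_trials(tab, sampling_config("equal", 300), n_sample_sets = 2,
                   n_trials = 2, N_grid = c(1, 2),
                   ci_config = ci_test_config(B = 100), master_seed = 33)
  expect_identical(t1$record, t2$record)
  expect_identical(lapply(t1$candidates[[1]], pdag_adjacency),
                   lapply(t2$candidates[[1]], pdag_adjacency))
})

test_that("select_N picks the point nearest (1, 1)", {
  rec <- data.frame(N = c(3, 5, 7),
                    acc_mean = c(0.6, 0.9, 1.0),
                    cov_mean = c(1.0, 0.95, 0.5))
  expect_equal(select_N(rec), 5)
})
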