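test_that("fit_background is the pseudocount-smoothed mean control count", {
  counts <- rbind(P0 = c(rep(0, 7), 5), P7 = c(rep(7, 7), 5), PX = c(3, rep(0, 6), 5))
  m <- count_matrix(counts,
                    preys = data.frame(gene = rownames(counts),
                                       accession = paste0("A", 1:3), length = 100),
                    runs = data.frame(run_id = c(paste0("C", 1:7), "B1"),
                                      bait = c(rep("CONTROL", 7), "B"),
                                      replicate_index = c(1:7, 1)))
  expect_equal(fit_background(m, "P0", 0.1), 0.1 / 7)
  expect_equal(fit_background(m, "P7", 0), 7)
  # single control run, one count of 3
  m1 <- count_matrix(cbind(C1 = 3, B1 = 5),
                     preys = data.frame(gene = "PX", accession = "A", length = 100),
                     runs = data.frame(run_id = c("C1", "B1"),
                                       bait = c("CONTROL", "B"), replicate_index = c(1, 1)))
  expect_equal(fit_background(m1, "PX", 0.1), 3.1)
})

test_that("score_replicate is the Poisson-mixture posterior", {
  # equal rates: likelihood ratio 1, posterior equals the prior
  expect_equal(score_replicate(5, 2, 2, pi_true = 0.1), 0.1)
  expect_equal(score_replicate(5, 2, 2, pi_true = 0.3), 0.3)
  # zero count under a high specific rate is almost surely background
  expect_lt(score_replicate(0, 0.1, 20, 0.1), 0.01)
  # large count under a high specific rate is almost surely specific
  expect_gt(score_replicate(50, 0.5, 40, 0.1), 0.999)
  expect_error(score_replicate(Inf, 1, 2, 0.1), "non-finite")
})

test_that("score_replicate matches a first-principles Bayes computation to 1e-12", {
  grid <- expand.grid(lf = c(0.0142857, 0.5, 3.1), lt = c(1.5, 15, 40),
                      pi = c(0.1, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (k in 0:100) {
      expect_equal(score_replicate(k, g$lf, g$lt, g$pi),
                   oracle_iprob(k, g$lf, g$lt, g$pi),
                   tolerance = 1e-12)
    }
  }
})

test_that("iprob is non-decreasing in the count when lambda_true > lambda_false", {
  for (lf in c(0.1, 1, 5)) {
    ip <- vapply(0:100, score_replicate, numeric(1),
                 lambda_false = lf, lambda_true = lf + 8, pi_true = 0.1)
    expect_true(all(diff(ip) >= 0))
  }
})

test_that("final score averages the two highest replicate probabilities", {
  expect_equal(combine_iprobs(c(0.99, 0.95, 0.20)), 0.97)
  expect_equal(combine_iprobs(0.80), 0.80)
  expect_equal(combine_iprobs(c(0.5, 0.5)), 0.5)
})

test_that("score_bait scores only preys observed with the bait and is per-bait", {
  set.seed(7)
  genes <- c("SPEC", "CTRLONLY", "FLAT")
  counts <- rbind(
    SPEC = c(rpois(7, 0.2), 14, 16, 15, rpois(2, 0.2)),
    CTRLONLY = c(rpois(7, 2) + 1, 0, 0, 0, 0, 0),
    FLAT = c(rpois(7, 3), rpois(3, 3), rpois(2, 3)) + 1
  )
  runs <- data.frame(run_id = c(paste0("C", 1:7), paste0("B1_", 1:3), paste0("B2_", 1:2)),
                     bait = c(rep("CONTROL", 7), rep("B1", 3), rep("B2", 2)),
                     replicate_index = c(1:7, 1:3, 1:2))
  m <- count_matrix(counts,
                    preys = data.frame(gene = genes, accession = genes, length = 100),
                    runs = runs)
  res <- score_bait(m, "B1")
  expect_setdiff <- setdiff(res$prey, c("SPEC", "FLAT"))
  expect_length(expect_setdiff, 0)
  expect_false("CTRLONLY" %in% res$prey)
  expect_gt(res$score[res$prey == "SPEC"], 0.99)
  # a prey with the same count distribution in bait and controls scores ~pi_true
  expect_lt(abs(res$score[res$prey == "FLAT"] - 0.1), 0.12)
  # dropping the other bait's runs leaves B1 scores identical
  keep <- runs$bait != "B2"
  m1 <- count_matrix(counts[, keep],
                     preys = data.frame(gene = genes, accession = genes, length = 100),
                     runs = runs[keep, ])
  res1 <- score_bait(m1, "B1")
  expect_equal(res1$score, res$score)
  expect_equal(res1[paste0("iprob_", 1:3)], res[paste0("iprob_", 1:3)])
})

test_that("apply_thresholds honours >=, strict >, per-bait policies and manual includes", {
  res <- data.frame(bait = c("B1", "B1", "B2", "B3", "B3"),
                    prey = c("P1", "P2", "P3", "P4", "MEF2C"),
                    score = c(0.75, 0.74, 0.95, 0.90, 0.30))
  policy <- threshold_policy(
    default = 0.75,
    baits = list(B2 = list(threshold = 0.95, strict = TRUE),
                 B3 = list(threshold = 0.90, strict = FALSE)),
    manual_include = data.frame(bait = "B3", prey = "MEF2C"))
  out <- apply_thresholds(res, policy, filter = FALSE)
  expect_true(out$passes[out$prey == "P1"])    # 0.75 >= 0.75
  expect_false(out$passes[out$prey == "P2"])
  expect_false(out$passes[out$prey == "P3"])   # 0.95 not > 0.95
  expect_true(out$passes[out$prey == "P4"])    # 0.90 >= 0.90
  expect_true(out$passes[out$prey == "MEF2C"]) # manual rescue
  expect_true(out$manual[out$prey == "MEF2C"])
  expect_identical(sort(apply_thresholds(res, policy)$prey),
                   c("MEF2C", "P1", "P4"))
})

test_that("scorer recovers planted specific preys on the default synthetic design", {
  cfg <- sim_config(seed = 2024)
  sim <- simulate_counts(cfg)
  m <- zero_bait_self_counts(clean_preys(sim$matrix))
  res <- score_bait(m, "BAIT1")
  filt <- apply_thresholds(res, threshold_policy(0.75))
  spec <- sim$truth$prey[sim$truth$class == "specific" &
                           grepl("BAIT1", sim$truth$baits)]
  bg <- sim$truth$prey[sim$truth$class == "background"]
  expect_gte(mean(spec %in% filt$prey), 0.90)
  expect_lte(sum(filt$prey %in% bg) / length(bg), 0.05)
})
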