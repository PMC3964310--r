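test_that("peptide light fraction handles limits and the odds correction", {
  expect_equal(peptide_light_fraction(100, 100, 1), 0.5)
  expect_equal(peptide_light_fraction(100, 0, 1), 1)
  expect_equal(peptide_light_fraction(0, 100, 1), 0)
  # input mixed light-rich 2:1: equal channels correct to odds 1/2 -> 1/3
  expect_equal(peptide_light_fraction(100, 100, 2), 1 / 3)
  expect_error(peptide_light_fraction(0, 0), "zero")
})

test_that("input normalizer is the median of per-protein median odds", {
  # perfectly mixed input
  ip <- rbind(pep("A", c(10, 20), c(10, 20)), pep("B", c(5, 8, 9), c(5, 8, 9)))
  expect_equal(input_normalizer(ip), 1)
  # uniform 1.2:1 input
  ip2 <- rbind(pep("A", c(12, 24), c(10, 20)), pep("B", c(6, 12), c(5, 10)))
  expect_equal(input_normalizer(ip2), 1.2)
  # per-protein odds {0.8, 1.0, 1.5} -> median 1.0
  ip3 <- rbind(pep("A", c(8, 8), c(10, 10)),
               pep("B", c(7, 7), c(7, 7)),
               pep("C", c(15, 15), c(10, 10)))
  expect_equal(input_normalizer(ip3), 1)
  # no quantifiable protein (single peptides) disables normalization
  expect_warning(n <- input_normalizer(pep("A", 10, 10)), "quantifiable")
  expect_equal(n, 1)
  expect_warning(n2 <- input_normalizer(NULL), "disabled")
  expect_equal(n2, 1)
})

test_that("protein ratios are medians over >=2 peptides; singletons are dropped", {
  pairs <- rbind(
    pep("EXCH", c(10, 30, 50), c(10, 30, 50)),   # fractions 0.5 each
    pep("STABLE", c(40, 80), c(0, 0)),           # light-only -> 1.0
    pep("SINGLE", 100, 50)                       # one peptide -> excluded
  )
  exp <- idirt_experiment("HDAC1", pairs, input_pairs = NULL)
  suppressWarnings(st <- protein_stability(exp, normalizer = 1))
  expect_setequal(st$prey, c("EXCH", "STABLE"))
  expect_equal(st$ratio[st$prey == "EXCH"], 0.5)
  expect_equal(st$ratio[st$prey == "STABLE"], 1.0)
  expect_identical(attr(st, "dropped"), "SINGLE")
  expect_true(all(st$n_peptides >= 2))
})

test_that("ratios stay in [0,1]; ratio is 1 iff every peptide lacks heavy signal", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    L <- runif(n, 0, 100)
    H <- runif(n, 0, 100) * rbinom(n, 1, 0.7)
    L[L == 0 & H == 0] <- 1
    exp <- idirt_experiment("B", pep("P", L, H))
    suppressWarnings(st <- protein_stability(exp, normalizer = runif(1, 0.5, 2)))
    expect_gte(st$ratio, 0)
    expect_lte(st$ratio, 1)
    if (all(H == 0)) expect_equal(st$ratio, 1)
    # the median can only reach 1 when at least half the peptides are light-only
    if (sum(H > 0) > n / 2) expect_lt(st$ratio, 1)
  }
})

test_that("fully exchanging preys converge to 0.50 and stable preys resist leakage", {
  cfg <- sim_config(seed = 101, peptides_per_prey = 100,
                    exchange_fractions = 1, n_contaminants = 0)
  sim <- simulate_counts(cfg)
  pp <- simulate_peptides(cfg, sim$truth, "BAIT1")
  st <- protein_stability(pp$experiment)
  # the equilibrium signature: the cohort of exchanging preys centres on 0.50
  expect_lte(abs(median(st$ratio) - 0.5), 0.02)
  expect_lte(abs(st$ratio[1] - 0.5), 0.02)
  # non-exchanging prey with zero heavy noise is exactly 1.0
  stable <- idirt_experiment("B", pep("S", c(50, 60, 70), c(0, 0, 0)))
  suppressWarnings(expect_equal(protein_stability(stable, 1)$ratio, 1.0))
  # 5% heavy leakage keeps the ratio at or above 0.95
  leak <- idirt_experiment("B", pep("S", c(100, 100, 100), c(5, 5, 5)))
  suppressWarnings(expect_gte(protein_stability(leak, 1)$ratio, 0.95))
})

test_that("global light rescaling cancels when the input is co-rescaled", {
  cfg <- sim_config(seed = 9, n_baits = 1, n_specific_per_bait = 10,
                    shared_complex_size = 0, n_background_preys = 20)
  sim <- simulate_counts(cfg)
  pp <- simulate_peptides(cfg, sim$truth, "BAIT1")
  e1 <- pp$experiment
  st1 <- protein_stability(e1)
  e2 <- e1
  e2$pairs$light_intensity <- e2$pairs$light_intensity * 2
  e2$input_pairs$light_intensity <- e2$input_pairs$light_intensity * 2
  st2 <- protein_stability(e2)
  expect_equal(st2$ratio, st1$ratio, tolerance = 1e-9)
})

test_that("peptide tables round-trip through the TSV reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- rbind(cbind(pep("P1", c(10, 20), c(10, 10)), sample = "ip"),
               cbind(pep("IN1", c(5, 5), c(5, 5)), sample = "input"))
  names(tab)[1] <- "prey_gene"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  exp <- read_peptide_table(path, "hdac3")
  expect_equal(exp$bait, "HDAC3")
  expect_equal(nrow(exp$pairs), 2)
  expect_equal(nrow(exp$input_pairs), 2)
  st <- protein_stability(exp)
  expect_equal(st$normalizer[1], 1)
})

test_that("ambiguous and empty peptides are dropped with warnings", {
  pairs <- rbind(pep("P1", c(10, 20), c(10, 10), seq = c("AAA", "BBB")),
                 pep("P2", 30, 10, seq = "AAA"))  # AAA maps to P1 and P2
  expect_warning(exp <- idirt_experiment("B", pairs), "shared")
  expect_false("AAA" %in% exp$pairs$peptide_seq)
  expect_warning(idirt_experiment("B", pep("P", c(0, 1), c(0, 1))), "zero")
})
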