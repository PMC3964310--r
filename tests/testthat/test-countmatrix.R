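test_that("long dialect round-trips cell-identically and defaults missing cells to 0", {
  m <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  m2 <- read_count_matrix(path, "long")
  expect_identical(m2$counts[rownames(m$counts), colnames(m$counts)], m$counts)
  expect_identical(sort(m2$runs$bait), sort(m$runs$bait))

  write_tiny_long(path, drop_cell = TRUE)
  m3 <- read_count_matrix(path, "long")
  expect_equal(m3$counts["PREYA", "B1"], 0)
  expect_equal(m3$counts["PREYA", "B2"], m$counts["PREYA", "B2"])
})

test_that("duplicate (prey, run) cells and malformed headers are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_long(path, dup_cell = TRUE)
  expect_error(read_count_matrix(path, "long"), "duplicated")

  writeLines("prey_gene\tcount\nA\t3", path)
  expect_error(read_count_matrix(path, "long"), "header|columns")

  writeLines(c("prey_gene\tprey_accession\tprey_length\trun_id\tbait\tcount",
               "A\tACC1\t100\tR1\tB\t-3"), path)
  expect_error(read_count_matrix(path, "long"), "non-negative")
})

test_that("wide dialect parses '#run' metadata and sparse cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#run C1 CONTROL 1",
    "#run B1 BAITX 1",
    "prey_gene\tprey_accession\tprey_length\tC1\tB1",
    "PREYA\tACC1\t400\t2\t30",
    "PREYB\tACC2\t250\t0\t11"
  ), path)
  m <- read_count_matrix(path, "wide")
  expect_equal(dim(m$counts), c(2L, 2L))
  expect_equal(m$counts["PREYA", "B1"], 30)
  expect_equal(m$runs$bait[m$runs$run_id == "C1"], "CONTROL")
})

test_that("clean_preys removes exactly the blocklisted preys, case-insensitively", {
  m <- tiny_matrix()
  expect_identical(clean_preys(m, character())$counts, m$counts)
  m2 <- clean_preys(m, c("krt1", "preya"))
  expect_false("PREYA" %in% rownames(m2$counts))
  expect_identical(m2$counts["PREYB", ], m$counts["PREYB", ])
  m3 <- clean_preys(m, m$preys$gene)
  expect_equal(nrow(m3$counts), 0L)
})

test_that("zero_bait_self_counts zeroes only the bait's own gene in its own runs", {
  m <- tiny_matrix()
  z <- zero_bait_self_counts(m)
  expect_equal(unname(z$counts["BAITX", c("B1", "B2")]), c(0, 0))
  expect_equal(z$counts["BAITX", c("C1", "C2")], m$counts["BAITX", c("C1", "C2")])
  expect_identical(z$counts["PREYA", ], m$counts["PREYA", ])
  # bait gene absent from the matrix: no-op
  m2 <- clean_preys(m, "BAITX")
  expect_identical(zero_bait_self_counts(m2)$counts, m2$counts)
  # map missing a bait is a configuration error
  expect_error(zero_bait_self_counts(m, c(OTHER = "X")), "missing")
})

test_that("clean_preys and zero_bait_self_counts commute", {
  m <- tiny_matrix()
  a <- zero_bait_self_counts(clean_preys(m, "PREYB"))
  b <- clean_preys(zero_bait_self_counts(m), "PREYB")
  expect_identical(a$counts, b$counts)
})

test_that("normalize_counts matches the hand-computed scale factor", {
  # control totals {900, 1100}, bait totals {2000, 2000} -> factor 0.5
  counts <- rbind(P1 = c(900, 1100, 1960, 1970), P2 = c(0, 0, 40, 30))
  m <- count_matrix(counts,
                    preys = data.frame(gene = c("P1", "P2"),
                                       accession = c("A1", "A2"), length = c(100, 100)),
                    runs = data.frame(run_id = c("C1", "C2", "B1", "B2"),
                                      bait = c("CONTROL", "CONTROL", "B", "B"),
                                      replicate_index = c(1, 2, 1, 2)))
  nm <- normalize_counts(m, "B")
  expect_equal(unname(nm$scale_factors[c("B1", "B2")]), c(0.5, 0.5))
  expect_equal(unname(nm$scale_factors[c("C1", "C2")]), c(1, 1))
  expect_equal(nm$counts["P2", "B1"], 20)
})

test_that("normalization equalizes mean totals, preserves in-run rank order, factor 1 when balanced", {
  set.seed(42)
  for (i in 1:5) {
    counts <- matrix(rpois(8 * 6, lambda = sample(1:30, 1)), 8, 6,
                     dimnames = list(paste0("P", 1:8), paste0("R", 1:6)))
    m <- count_matrix(counts,
                      preys = data.frame(gene = paste0("P", 1:8),
                                         accession = paste0("A", 1:8), length = 100),
                      runs = data.frame(run_id = paste0("R", 1:6),
                                        bait = rep(c("CONTROL", "B"), each = 3),
                                        replicate_index = rep(1:3, 2)))
    nm <- normalize_counts(m, "B")
    tot <- colSums(nm$counts)
    expect_equal(mean(tot[1:3]), mean(tot[4:6]), tolerance = 1e-9)
    for (r in colnames(counts)) {
      expect_identical(order(nm$counts[, r]), order(m$counts[, r]))
    }
  }
  # single control 500 vs single bait 500 -> factor exactly 1
  counts <- cbind(C1 = c(200, 300), B1 = c(400, 100))
  m <- count_matrix(counts,
                    preys = data.frame(gene = c("P1", "P2"),
                                       accession = c("A1", "A2"), length = 100),
                    runs = data.frame(run_id = c("C1", "B1"),
                                      bait = c("CONTROL", "B"), replicate_index = c(1, 1)))
  expect_equal(unname(normalize_counts(m, "B")$scale_factors["B1"]), 1)
})

test_that("degenerate normalization inputs error", {
  m <- tiny_matrix()
  expect_error(normalize_counts(m, "NOSUCH"), "no runs")
  counts <- cbind(C1 = c(1, 1), B1 = c(0, 0))
  m0 <- count_matrix(counts,
                     preys = data.frame(gene = c("P1", "P2"),
                                        accession = c("A1", "A2"), length = 100),
                     runs = data.frame(run_id = c("C1", "B1"),
                                       bait = c("CONTROL", "B"), replicate_index = c(1, 1)))
  expect_error(normalize_counts(m0, "B"), "degenerate")
})

test_that("preys without a valid length are rejected with a warning", {
  counts <- rbind(P1 = c(1, 2), P2 = c(3, 4))
  expect_warning(
    m <- count_matrix(counts,
                      preys = data.frame(gene = c("P1", "P2"),
                                         accession = c("A1", "A2"),
                                         length = c(NA, 200)),
                      runs = data.frame(run_id = c("C1", "B1"),
                                        bait = c("CONTROL", "B"),
                                        replicate_index = c(1, 1))),
    "length")
  expect_identical(rownames(m$counts), "P2")
})
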