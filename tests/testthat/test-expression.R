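# Peak matching, clustering, quantification and series statistics.

test_that("peaks match all list entries within tolerance, none outside", {
  gl <- full_glycan_list()
  m <- match_peaks(data.frame(mz = 1362.50, area = 10), gl, 0.2)
  expect_identical(unique(m$composition_id), "200000000000000C")
  expect_equal(nrow(match_peaks(data.frame(mz = 1000, area = 1), gl, 0.2)), 0)
  # isobaric pair: oligomannose M9 vs fucosylated GlcA LacDiNAc
  m2 <- match_peaks(data.frame(mz = 2010.73, area = 1), gl, 0.2)
  expect_setequal(m2$composition_text,
                  c("(Hex)6 + (Man)3(GlcNAc)2",
                    "(HexNAc)3 (Fuc)1 (GlcA)1 + (Man)3(GlcNAc)2"))
  expect_true(all(abs(m2$delta_mz) <= 0.2))
  expect_error(match_peaks(data.frame(mz = 1, area = 1), gl[0, ], 0.2),
               "empty")
})

test_that("matching equals the brute-force all-pairs oracle on random instances", {
  gl <- tiny_glycan_list()
  set.seed(101)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    tol <- stats::runif(1, 0.05, 0.5)
    peaks <- data.frame(
      mz = stats::runif(n, 1300, 2500) +
        sample(c(0, gl$theoretical_mz), n, TRUE) * 0,
      area = stats::runif(n, 1, 100))
    # seed some peaks near true masses so matches actually occur
    hit <- sample(seq_len(n), min(n, 3))
    peaks$mz[hit] <- sample(gl$theoretical_mz, length(hit), TRUE) +
      stats::runif(length(hit), -2 * tol, 2 * tol)
    got <- match_peaks(peaks, gl, tol)
    want <- oracle_match(peaks, gl, tol)
    expect_identical(got[order(got$peak, got$entry), c("peak", "entry")],
                     want[order(want$peak, want$entry), ],
                     ignore_attr = TRUE)
  }
})

test_that("candidate sets grow monotonically with tolerance", {
  gl <- full_glycan_list()
  set.seed(5)
  peaks <- data.frame(mz = stats::runif(30, 1300, 3400), area = 1)
  tols <- c(0.05, 0.1, 0.2, 0.5)
  prev <- NULL
  for (t in tols) {
    m <- match_peaks(peaks, gl, t)
    key <- paste(m$peak, m$entry)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("replicate peaks cluster by single linkage with dense mass-ordered IDs", {
  pk <- data.frame(experiment = c("e1", "e2", "e3"),
                   mz = c(1362.48, 1362.52, 1362.50))
  ids <- cluster_across_experiments(pk, 0.2)
  expect_identical(ids, c(1L, 1L, 1L))
  pk2 <- data.frame(experiment = c("e1", "e1"), mz = c(1362.5, 1735.7))
  expect_identical(cluster_across_experiments(pk2, 0.2), c(1L, 2L))
  # numbering follows ascending mean m/z regardless of input order
  pk3 <- data.frame(experiment = c("e1", "e2", "e1", "e2"),
                    mz = c(2000.1, 2000.1, 1500.2, 1500.2))
  expect_identical(cluster_across_experiments(pk3, 0.2), c(2L, 2L, 1L, 1L))
})

test_that("clustering equals the connected-components oracle on small instances", {
  set.seed(202)
  done <- 0
  while (done < 15) {
    n_exp <- sample(2:4, 1)
    n <- sample(3:10, 1)
    tol <- 0.2
    pk <- data.frame(
      experiment = sample(paste0("e", seq_len(n_exp)), n, TRUE),
      mz = stats::runif(n, 1000, 1003))
    comp <- oracle_components(pk$mz, tol)
    # the equivalence domain: no experiment twice in one component
    if (any(vapply(split(pk$experiment, comp), anyDuplicated, 1L) > 0))
      next
    done <- done + 1
    ids <- cluster_across_experiments(pk, tol)
    # identical partitions up to relabeling: the joint labeling has exactly
    # as many distinct values as either labeling alone
    expect_equal(length(unique(ids)), length(unique(comp)))
    expect_equal(length(unique(paste(ids, comp))), length(unique(ids)))
  }
})

test_that("every matched peak lands in exactly one cluster even under conflicts", {
  # chain that forces an in-cluster experiment conflict
  pk <- data.frame(experiment = c("e1", "e2", "e1"),
                   mz = c(1000.00, 1000.15, 1000.30))
  ids <- cluster_across_experiments(pk, 0.2)
  expect_length(ids, 3)
  expect_true(all(ids >= 1))
  # conflicting e1 peaks are separated
  expect_false(ids[1] == ids[3])
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    pk <- data.frame(experiment = sample(paste0("e", 1:3), n, TRUE),
                     mz = stats::runif(n, 1000, 1002))
    ids <- cluster_across_experiments(pk, 0.2)
    expect_length(ids, n)                     # conservation
    for (g in split(seq_len(n), ids))
      expect_false(anyDuplicated(pk$experiment[g]) > 0)
  }
})

test_that("internal-standard ratio quantification is exact and scale-free", {
  expect_equal(quantify(1000, 500, 20), 40)
  expect_equal(quantify(0, 500, 20), 0)
  expect_equal(quantify(2000, 1000, 20), quantify(1000, 500, 20))
  expect_error(quantify(1, 0, 20))
})

test_that("series aggregation uses the n-1 standard deviation and percent CV", {
  amt <- rbind(c(2, 4), c(3, 3))
  st <- aggregate_series(amt, c("s1", "s1"))
  expect_equal(unname(st$mean[, 1]), c(3, 3))
  expect_equal(unname(st$sd[1, 1]), 1.4142, tolerance = 1e-4)
  expect_equal(unname(st$cv[1, 1]), 47.14, tolerance = 1e-3)
  expect_equal(unname(st$sd[2, 1]), 0)
  expect_equal(unname(st$cv[2, 1]), 0)
  st3 <- aggregate_series(matrix(c(10, 20, 30), 1), rep("a", 3))
  expect_equal(unname(st3$mean[1, 1]), 20)
  expect_equal(unname(st3$sd[1, 1]), 10)
  expect_equal(unname(st3$cv[1, 1]), 50)
  # singleton series: sd and cv not available
  st1 <- aggregate_series(matrix(c(5, 7), 1), c("a", "b"))
  expect_true(is.na(st1$sd[1, "a"]) && is.na(st1$cv[1, "b"]))
})

test_that("Welch test handles identical, separated and degenerate series", {
  expect_equal(test_between_series(c(1, 2, 3), c(1, 2, 3)), 1)
  p <- test_between_series(c(0, 0, 0, 0), c(10, 10.1, 9.9, 10.2))
  # oracle: Welch statistic with t distribution
  a <- c(0, 0, 0, 0); b <- c(10, 10.1, 9.9, 10.2)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 4 + var(b) / 4)
  df <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(p, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-12)
  expect_lt(p, 0.001)
  expect_equal(test_between_series(c(1, 2), c(3, 4)),
               test_between_series(c(3, 4), c(1, 2)))
  expect_equal(test_between_series(c(5, 5, 5), c(5, 5)), 1)
  expect_equal(test_between_series(c(5, 5, 5), c(6, 6)), 0)
})

test_that("zero_cut removes only all-zero rows and is idempotent", {
  tab <- data.frame(spectral_id = 1:3, amt.e1 = c(0, 1, 0),
                    amt.e2 = c(0, 0, NA))
  z <- zero_cut(tab)
  expect_identical(z$spectral_id, 2L)
  expect_identical(zero_cut(z), z)
})
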