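# Calibration fits, R-squared filter, linked glycans, URLs, reporting.

test_that("least squares recovers perfect and noisy lines", {
  f <- fit_calibration(c(2, 4, 6, 8, 10), c(2, 4, 6, 8, 10))
  expect_equal(f$a, 1); expect_equal(f$b, 0); expect_equal(f$r_squared, 1)
  set.seed(31)
  x <- rep(c(2, 4, 6, 8, 10), each = 4)
  y <- 3.2 * x + 1.5 + stats::rnorm(length(x), 0, 0.8)
  f2 <- fit_calibration(x, y)
  # closed-form normal-equation oracle
  sxx <- sum((x - mean(x))^2)
  a_hat <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b_hat <- mean(y) - a_hat * mean(x)
  r2_hat <- 1 - sum((y - a_hat * x - b_hat)^2) / sum((y - mean(y))^2)
  expect_equal(f2$a, a_hat, tolerance = 1e-9)
  expect_equal(f2$b, b_hat, tolerance = 1e-9)
  expect_equal(f2$r_squared, r2_hat, tolerance = 1e-9)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "distinct volumes")
})

test_that("constant response across volumes gives slope 0 and R-squared 1", {
  f <- fit_calibration(c(2, 4, 6, 8), c(5, 5, 5, 5))
  expect_equal(f$a, 0)
  expect_equal(f$r_squared, 1)  # zero residuals on a perfect constant
})

test_that("the R-squared filter is inclusive at the threshold", {
  fits <- data.frame(id = 1:3, r_squared = c(0.80, 0.79, 0.95))
  kept <- rcut_filter(fits, 0.8)
  expect_identical(kept$id, c(1L, 3L))
  expect_identical(rcut_filter(fits, 0)$id, fits$id)
})

test_that("linked glycans are exactly the one-residue neighbors", {
  target <- composition_id(parse_composition(
    "(HexNAc)2 (6NeuAc)1 + (Man)3(GlcNAc)2"))
  det <- data.frame(
    composition_id = c(
      composition_id(parse_composition("(HexNAc)2 + (Man)3(GlcNAc)2")),
      composition_id(parse_composition(
        "(Hex)1 (HexNAc)2 (6NeuAc)1 + (Man)3(GlcNAc)2")),
      composition_id(parse_composition(
        "(Hex)1 (HexNAc)3 (6NeuAc)1 + (Man)3(GlcNAc)2")),  # two residues away
      target),
    spectral_id = c(51L, 69L, 70L, 100L),
    stringsAsFactors = FALSE)
  ln <- linked_glycans(target, det[det$composition_id != target, ])
  expect_setequal(ln$spectral_id, c(51L, 69L))
  # symmetry of the relation
  for (i in seq_len(nrow(det)))
    for (j in seq_len(nrow(det))) {
      a_to_b <- nrow(linked_glycans(det$composition_id[i], det[j, ])) == 1
      b_to_a <- nrow(linked_glycans(det$composition_id[j], det[i, ])) == 1
      expect_identical(a_to_b, b_to_a)
    }
})

test_that("composition URLs fold in the core, sum SALSA variants, skip zeros", {
  u <- glyconnect_url(composition(c(Hex = 2, HexNAc = 1, "3-8NeuAc" = 1)))
  expect_identical(
    u, "https://glyconnect.expasy.org/browser/compositions?f=Hex:5HexNAc:3NeuAc:1")
  expect_identical(
    glyconnect_url(composition(c(HexNAc = 2, Fuc = 1))),
    "https://glyconnect.expasy.org/browser/compositions?f=Hex:3HexNAc:4dHex:1")
  expect_identical(
    glyconnect_url(composition(c(Hex = 2, HexNAc = 2, "6NeuAc" = 1,
                                 GlcA = 1))),
    "https://glyconnect.expasy.org/browser/compositions?f=Hex:5HexNAc:4NeuAc:1HexA:1")
  # SALSA variants with the same totals produce identical URLs
  v1 <- glyconnect_url(composition(c(Hex = 2, HexNAc = 2, "3-8NeuAc" = 2)))
  v2 <- glyconnect_url(composition(c(Hex = 2, HexNAc = 2, "3-8NeuAc" = 1,
                                     "6NeuAc" = 1)))
  v3 <- glyconnect_url(composition(c(Hex = 2, HexNAc = 2, "6NeuAc" = 2)))
  expect_identical(v1, v2); expect_identical(v2, v3)
  # no zero-count segment ever appears
  expect_false(grepl(":0", glyconnect_url(composition(c(Hex = 1)))))
  expect_error(glyconnect_url(composition(c(Hex = 1), has_core = FALSE)),
               "core")
})

test_that("summary rows render aggregates, amounts, links and URLs", {
  tab <- data.frame(
    spectral_id = c(1L, 2L),
    observed_mz = c(1362.481, 1524.533),
    composition_id = c("200000000000000C", "300000000000000C"),
    composition_text = c("(Hex)2 + (Man)3(GlcNAc)2",
                         "(Hex)3 + (Man)3(GlcNAc)2"),
    amt.e1 = c(1, 2), amt.e2 = c(2, 4), stringsAsFactors = FALSE)
  st <- aggregate_series(as.matrix(tab[, c("amt.e1", "amt.e2")]),
                         c("a", "a"))
  p <- withr::local_tempfile(fileext = ".csv")
  rows <- write_summary(tab, st, p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 2)
  # the two oligomannose signals are mutual one-residue neighbors
  expect_match(back$linked_glycans[1], "\\(Hex\\)3.*\\[2\\]")
  expect_match(back$linked_glycans[2], "\\(Hex\\)2.*\\[1\\]")
  expect_equal(back$mean.a, c(1.5, 3))
  expect_equal(back$amt.e2, c(2, 4))
  expect_match(back$glyconnect_url[1], "f=Hex:5HexNAc:2$")
})

test_that("calibration chart pages count one panel per fit and echo the fit", {
  mk_fit <- function(slope) fit_calibration(c(2, 4, 6, 8),
                                            slope * c(2, 4, 6, 8))
  fits <- data.frame(spectral_id = 1:3, observed_mz = c(1362.5, 1500, 1600),
                     composition_text = "(Hex)2 + (Man)3(GlcNAc)2",
                     composition_id = "200000000000000C",
                     r_squared = c(1, 1, 1))
  fits$fit <- list(mk_fit(1), mk_fit(2), mk_fit(3))
  p <- withr::local_tempfile(fileext = ".html")
  render_calibration_html(fits, p)
  html <- paste(readLines(p), collapse = "\n")
  expect_equal(lengths(regmatches(html, gregexpr("class=\"panel\"", html))),
               3)
  expect_match(html, "y = 2\\.000 x")
  expect_match(html, "R&#178; = 1\\.000")
  expect_match(html, "200000000000000C")
  # empty filter result still yields valid HTML with a notice
  render_calibration_html(fits[0, ], p)
  expect_match(paste(readLines(p), collapse = ""), "No glycans passed")
})
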