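# Composition enumeration, SALSA expansion and list IO.

test_that("the default list contains the newly admitted glycan classes", {
  gl <- full_glycan_list()
  must_have <- c(
    # LacDiNAc series (HexNAc exceeding Hex)
    "(HexNAc)2 (6NeuAc)1 + (Man)3(GlcNAc)2",
    "(HexNAc)2 (3-8NeuAc)1 + (Man)3(GlcNAc)2",
    "(Hex)1 (HexNAc)3 (6NeuAc)2 + (Man)3(GlcNAc)2",
    "(Hex)2 (HexNAc)4 (6NeuAc)3 + (Man)3(GlcNAc)2",
    # mannose-rich hybrids elongated to sialic acid or GlcA
    "(Hex)5 (HexNAc)1 (6NeuAc)1 + (Man)3(GlcNAc)2",
    "(Hex)5 (HexNAc)1 (Fuc)1 (GlcA)1 + (Man)3(GlcNAc)2",
    # oligomannose bounds
    "(Hex)2 + (Man)3(GlcNAc)2",
    "(Hex)6 + (Man)3(GlcNAc)2")
  expect_true(all(must_have %in% gl$composition_text))
  expect_false("(Hex)7 + (Man)3(GlcNAc)2" %in% gl$composition_text)
})

test_that("every published serum composition is generated", {
  gl <- full_glycan_list()
  ref <- serum_reference_rows()
  ids <- vapply(ref$composition_text, function(t)
    composition_id(parse_composition(t)), "")
  missing <- ref$composition_text[!(ids %in% gl$composition_id)]
  expect_length(missing, 0)
})

test_that("acid-competition constraints hold for every entry", {
  gl <- full_glycan_list()
  digit <- function(i) as.integer(substr(gl$composition_id, i, i))
  acids <- digit(6) + digit(7) + digit(8) + digit(9) + digit(14)
  expect_true(all(acids <= 4))
  expect_true(all(digit(14) <= 1))
  expect_true(all(digit(1) <= 6 & digit(2) <= 5 & digit(3) <= 3))
  # every entry carries the N-glycan core
  expect_true(all(grepl("C$", gl$composition_id)))
})

test_that("salsa_expand obeys the (a+1)(g+1) law against exhaustive splits", {
  base <- composition(c(Hex = 2, HexNAc = 2))
  for (a in 0:4) for (g in 0:(4 - a)) {
    variants <- salsa_expand(base, a, g)
    # oracle: enumerate every ordered (2,3/2,8 vs 2,6) split explicitly
    n_oracle <- nrow(expand.grid(ac38 = 0:a, gc38 = 0:g))
    expect_length(variants, n_oracle)
    expect_equal(length(variants), (a + 1) * (g + 1))
    ids <- vapply(variants, composition_id, "")
    expect_false(anyDuplicated(ids) > 0)
    for (v in variants) {
      s <- v$counts[6] + v$counts[7]  # 3-8NeuAc + 6NeuAc slots
      expect_equal(s, a)
      expect_equal(v$counts[8] + v$counts[9], g)
    }
    # masses form a lattice spaced 28.0313 Da
    mz <- sort(unique(round(vapply(variants, composition_mass, 0), 4)))
    if (length(mz) > 1)
      expect_equal(diff(mz), rep(28.0313, length(mz) - 1), tolerance = 1e-3)
  }
  expect_length(salsa_expand(base, 0, 3), 4)  # triantennary tri-NeuGc
  expect_length(salsa_expand(base, 0, 0), 1)
  expect_error(salsa_expand(composition(c("6NeuAc" = 1)), 1, 0),
               "already carries")
})

test_that("disialo-biantennary SALSA family matches the printed ladder", {
  fam <- salsa_expand(composition(c(Hex = 2, HexNAc = 2)), 2, 0)
  mz <- sort(vapply(fam, composition_mass, 0))
  expect_equal(round(mz[1], 1), 2376.9)  # di-(2,3/2,8)
  expect_equal(round(mz[2], 1), 2404.9)  # mixed
  expect_equal(mz[3] - mz[2], 28.0313, tolerance = 1e-4)
  expect_equal(mz[2] - mz[1], 28.0313, tolerance = 1e-4)
})

test_that("filtering is order-preserving, exact for NeuGc, identity when idle", {
  gl <- full_glycan_list()
  n_gc <- sum(as.integer(substr(gl$composition_id, 8, 8)) +
                as.integer(substr(gl$composition_id, 9, 9)) > 0)
  flt <- filter_glycan_list(gl, exclude_neugc = TRUE)
  expect_equal(nrow(flt), nrow(gl) - n_gc)
  expect_true(all(flt$composition_id %in% gl$composition_id))
  expect_identical(filter_glycan_list(gl), gl)
  set.seed(3)
  for (i in 1:5) {
    rng <- sort(stats::runif(2, 1300, 3400))
    sub <- filter_glycan_list(gl, mass_range = rng)
    expect_true(all(sub$theoretical_mz >= rng[1] &
                      sub$theoretical_mz <= rng[2]))
    expect_identical(sub$composition_id,
                     gl$composition_id[gl$theoretical_mz >= rng[1] &
                                         gl$theoretical_mz <= rng[2]])
  }
})

test_that("list CSV round-trips, accepts hand-added rows, rejects duplicates", {
  gl <- tiny_glycan_list()
  p <- withr::local_tempfile(fileext = ".csv")
  write_glycan_list(gl, p)
  gl2 <- read_glycan_list(p)
  expect_identical(gl2$composition_id, gl$composition_id)
  expect_identical(gl2$class, gl$class)
  expect_equal(gl2$theoretical_mz, gl$theoretical_mz, tolerance = 1e-6)
  # a user-edited row parses and matches like generated ones
  extra <- parse_composition("(Hex)2 (HexNAc)2 + (Man)3(GlcNAc)2")
  cat(sprintf("manual,%s,%s,%0.6f\n", composition_id(extra),
              format_composition(extra), composition_mass(extra)),
      file = p, append = TRUE)
  gl3 <- read_glycan_list(p)
  expect_equal(nrow(gl3), nrow(gl) + 1)
  m <- match_peaks(data.frame(mz = composition_mass(extra), area = 1),
                   gl3, 0.2)
  expect_true(composition_id(extra) %in% m$composition_id)
  # duplicated IDs are rejected with the offending line
  cat(sprintf("manual,%s,%s,%0.6f\n", composition_id(extra),
              format_composition(extra), composition_mass(extra)),
      file = p, append = TRUE)
  expect_error(read_glycan_list(p), "duplicate composition_id")
})

test_that("generation is deterministic: identical rules give identical CSV bytes", {
  gl1 <- enumerate_compositions(rules = default_class_rules()[1:2, ])
  gl2 <- enumerate_compositions(rules = default_class_rules()[1:2, ])
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_glycan_list(gl1, p1); write_glycan_list(gl2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
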