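test_that("dinucleotide counting overlaps and skips N-containing pairs", {
  c1 <- dinucleotide_counts(genome_tbl("g", "AAAA"))
  expect_equal(c1$count[c1$dinucleotide == "AA"], 3L)
  expect_equal(sum(c1$count), 3L)

  c2 <- dinucleotide_counts(genome_tbl("g", "ACGT"))
  expect_equal(c2$count[c2$dinucleotide %in% c("AC", "CG", "GT")],
               rep(1L, 3))
  expect_equal(sum(c2$count), 3L)

  c3 <- dinucleotide_counts(genome_tbl("g", "ANAT"))
  expect_equal(c3$count[c3$dinucleotide == "AT"], 1L)
  expect_equal(sum(c3$count), 1L)

  expect_error(dinucleotide_counts(genome_tbl("g", "A")),
               class = "phagemech_too_short")
})

test_that("frequency uses the genome length L as denominator", {
  f <- dinucleotide_frequency(genome_tbl("g", "AAAA"))
  expect_equal(f$frequency[f$dinucleotide == "AA"], 0.75)
  expect_equal(attr(f, "denominator_convention"), "genome_length")
  # with an N-free sequence the 16 frequencies sum to (L-1)/L exactly
  g <- random_genome(997, seed = 8)
  fr <- dinucleotide_frequency(g)
  expect_equal(sum(fr$frequency), 996 / 997)
  expect_equal(sum(fr$site_probability), 1)
})

test_that("differential matrix is a full 16 x 16 cross-difference", {
  f <- dinucleotide_frequency(genome_tbl(c("a", "b"),
                                         c(random_genome(400, 1)$sequence,
                                           random_genome(400, 2)$sequence)))
  d <- differential_frequency_matrix(f, "a", "b")
  expect_equal(nrow(d), 256L)
  m <- diff_matrix_wide(d)
  fa <- f$frequency[f$genome_id == "a"]
  fb <- f$frequency[f$genome_id == "b"]
  # spot-check the defining formula and the algebraic total
  expect_equal(m["AA", "TT"], fa[1] - fb[16])
  expect_equal(sum(d$difference), 16 * (sum(fa) - sum(fb)))
  # orientation flip negates every entry
  d2 <- differential_frequency_matrix(f, "a", "b",
                                      orientation = "col_minus_row")
  expect_equal(d2$difference, -d$difference)
})

test_that("self-difference matrix is antisymmetric with a zero diagonal", {
  f <- dinucleotide_frequency(random_genome(300, 5, id = "a"))
  d <- diff_matrix_wide(differential_frequency_matrix(f, "a", "a"))
  expect_equal(diag(d), rep(0, 16), ignore_attr = TRUE)
  expect_equal(d, -t(d))
})

test_that("a hand-built frequency vector gives constant rows", {
  fa <- tibble::tibble(genome_id = "a", dinucleotide = dinucleotides(),
                       frequency = c(0.5, rep(0, 15)))
  fb <- tibble::tibble(genome_id = "b", dinucleotide = dinucleotides(),
                       frequency = rep(1 / 16, 16))
  d <- diff_matrix_wide(
    differential_frequency_matrix(rbind(fa, fb), "a", "b"))
  expect_equal(unname(d["AA", ]), rep(0.4375, 16))
})

test_that("indicator tracks mark exactly the matching sites", {
  expect_equal(indicator_track(genome_tbl("g", "AAAA"), "AA")$indicator,
               c(1L, 1L, 1L))
  expect_equal(indicator_track(genome_tbl("g", "ACAC"), "CA")$indicator,
               c(0L, 1L, 0L))
  g <- random_genome(300, seed = 6)
  counts <- dinucleotide_counts(g)
  for (d in c("AA", "CG", "TA")) {
    expect_equal(sum(indicator_track(g, d)$indicator),
                 counts$count[counts$dinucleotide == d])
  }
  expect_error(indicator_track(genome_tbl("g", "ACGT"), "XY"),
               class = "phagemech_bad_dinucleotide")
})

test_that("pddf of a homogeneous genome is identically 1", {
  p <- pddf(genome_tbl("g", strrep("A", 200)), "AA", max_lag = 20)
  expect_equal(p$ratio, rep(1, 20))
  expect_equal(unique(p$site_probability), 1)
})

test_that("pddf at lag 1 is zero for hetero-dinucleotides", {
  g <- random_genome(20000, seed = 13)
  p <- pddf(g, c("AC", "TG", "CA"), max_lag = 5)
  expect_equal(p$ratio[p$lag == 1], rep(0, 3))
})

test_that("planted period-10 dinucleotides peak only at multiples of 10", {
  g <- plant_periodic_motif(genome_tbl("bg", strrep("C", 2000)), "AA",
                            period = 10, offset = 1)
  p <- pddf(g, "AA", max_lag = 40)
  mult <- p$lag %% 10 == 0
  expect_true(all(p$ratio[mult] > 1))
  expect_equal(p$ratio[!mult], rep(0, sum(!mult)))
})

test_that("pddf observed counts match the naive double-loop oracle", {
  for (seed in 1:3) {
    g <- random_genome(withr::with_seed(seed, sample(100:300, 1)), seed + 20)
    M <- g$length - 1L
    p <- pddf(g, max_lag = 15)
    for (d in c("AA", "AT", "CG", "GT", "TT")) {
      for (s in c(1L, 2L, 7L, 15L)) {
        got <- p$observed[p$dinucleotide == d & p$lag == s]
        expect_equal(got, naive_cooccurrence(g$sequence, d, s) / (M - s))
      }
    }
  }
})

test_that("pddf is deterministic and undefined for absent dinucleotides", {
  g <- genome_tbl("g", strrep("AC", 150))
  expect_identical(pddf(g, "AA", max_lag = 10),
                   pddf(g, "AA", max_lag = 10))
  p <- pddf(g, "GG", max_lag = 10)
  expect_true(all(is.na(p$ratio)))
  expect_error(pddf(genome_tbl("g", "ACGTACGT"), "AA", max_lag = 10),
               class = "phagemech_bad_lag")
})

test_that("periodicity scan recovers a planted period 10", {
  g <- plant_periodic_motif(genome_tbl("bg", strrep("C", 5000)), "AA",
                            period = 10, offset = 1)
  scan <- periodicity_scan(pddf(g, "AA"))
  expect_equal(scan$dominant_period, 10L)
  expect_true(scan$periodic)
})

test_that("a constant ratio series has no dominant period", {
  p <- pddf(genome_tbl("g", strrep("A", 300)), "AA")
  scan <- periodicity_scan(p)
  expect_true(is.na(scan$dominant_period))
  expect_equal(scan$prominence, 1)
  expect_false(scan$periodic)
})

test_that("periodicity scan refuses undefined ratios", {
  p <- pddf(genome_tbl("g", strrep("AC", 150)), "GG", max_lag = 10)
  expect_error(periodicity_scan(p, lag_range = c(2, 10)),
               class = "phagemech_undefined_ratio")
})
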