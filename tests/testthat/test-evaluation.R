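test_that("signed percentage deviation matches published spot checks", {
  expect_equal(signed_pct_deviation(10, 10), 0)
  expect_equal(round(signed_pct_deviation(40.8, 65)), -37)   # Martini, hTau40
  expect_equal(round(signed_pct_deviation(44.6, 37.9)), 18)  # bead, Proth. a
  expect_error(signed_pct_deviation(10, 0), "rg_exp")
})

test_that("chi-square vanishes for perfect predictions and matches a direct sum", {
  p <- write_tiny_table(rg_exp = c(10, 20, 30), rg_scaling = c(10, 20, 30))
  expect_equal(model_chi2(load_benchmark(p), "scaling"), 0)

  # independent brute-force re-summation over the canonical fixture
  tab <- load_benchmark()
  E <- experimental_rg(tab)
  for (m in benchmark_models()) {
    S <- model_rg(tab, m)
    acc <- 0
    for (i in seq_along(E)) acc <- acc + (E[i] - S[i])^2 / E[i]
    expect_equal(model_chi2(tab, m), acc, tolerance = 1e-12)
  }
})

test_that("chi-square is invariant under record reordering", {
  tab <- load_benchmark()
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  for (m in benchmark_models())
    expect_equal(model_chi2(shuffled, m), model_chi2(tab, m))
})

test_that("leave-one-out complements the full sum exactly", {
  tab <- load_benchmark()
  for (m in benchmark_models()) {
    terms <- chi2_terms(tab, m)
    full <- model_chi2(tab, m)
    for (p in tab$name) {
      loo <- chi2_leave_one_out(tab, m, p)
      expect_equal(loo + terms[[p]], full, tolerance = 1e-12)
      expect_lte(loo, full + 1e-12)
    }
  }
  expect_error(chi2_leave_one_out(tab, "scaling", "nonexistent"), "unknown")
  # removing a zero-contribution system leaves the total unchanged
  p <- write_tiny_table(rg_exp = c(10, 20, 30), rg_scaling = c(10, 25, 30))
  t2 <- load_benchmark(p)
  expect_equal(chi2_leave_one_out(t2, "scaling", "a"),
               model_chi2(t2, "scaling"))
})

test_that("missing cells are reported by protein name", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = c("a", "b"), n_residues = c(5, 6),
                       rg_exp = c(10, 20), rg_scaling = c(11, NA)),
            p, row.names = FALSE)
  expect_error(model_chi2(load_benchmark(p), "scaling"), "b")
})

test_that("trendlines report signed correlation of exact lines as +/-1", {
  x <- c(1, 2, 3, 4, 5)
  up <- bias_trend(2 + 3 * x, x)
  expect_equal(up$pearson_r, 1)
  expect_equal(up$r_squared_signed, 1)
  down <- bias_trend(10 - 2 * x, x)
  expect_equal(down$pearson_r, -1)
  expect_equal(down$r_squared_signed, -1)
  expect_error(bias_trend(c(1, 2, 3), c(4, 4, 4)), "constant")
  expect_error(bias_trend(c(1, 2), c(1, 2)), "at least 3")
})

test_that("published trendline statistics are reproduced by signed r", {
  # the benchmark's figure captions label signed correlation coefficients
  # as R^2; all four simulated-vs-experimental values and all four
  # error-vs-length values match r, sign included
  tab <- load_benchmark()
  E <- experimental_rg(tab)
  expected_sim <- c(scaling = 0.96, sop_idp = 0.95, bead_necklace = 0.95,
                    martini = 0.86)
  expected_len <- c(scaling = 0.67, sop_idp = 0.19, bead_necklace = 0.19,
                    martini = -0.25)
  for (m in benchmark_models()) {
    r_sim <- bias_trend(model_rg(tab, m), E)$pearson_r
    expect_equal(round(r_sim, 2), expected_sim[[m]], info = m)
    err <- signed_pct_deviation(model_rg(tab, m), E)
    r_len <- bias_trend(err, tab$n_residues)$pearson_r
    expect_equal(round(r_len, 2), expected_len[[m]], info = m)
  }
})

test_that("scorecard assembles all models, properties and rankings", {
  tab <- load_benchmark()
  set.seed(9)
  descriptors <- data.frame(
    name = tab$name,
    fcr = runif(24, 0, 0.6), ncpr = runif(24, 0, 0.3),
    kd_hydrophobicity = runif(24, -2, 0), proline_fraction = runif(24, 0, 0.2),
    disorder_score = runif(24, 0.4, 1))
  sc <- scorecard(tab, descriptors)
  expect_length(sc$chi2, 4L)
  expect_equal(nrow(sc$trends), 4L * 7L)
  expect_equal(sort(unique(sc$trends$property)),
               sort(c("rg_exp", "n_residues", "fcr", "ncpr",
                      "kd_hydrophobicity", "proline_fraction",
                      "disorder_score")))
  # published ranking: SOP-IDP <= bead-necklace < scaling law < Martini
  expect_lte(sc$chi2[["sop_idp"]], sc$chi2[["bead_necklace"]])
  expect_lt(sc$chi2[["bead_necklace"]], sc$chi2[["scaling"]])
  expect_lt(sc$chi2[["scaling"]], sc$chi2[["martini"]])
})

test_that("scorecard reports are byte-identical across repeated runs", {
  tab <- load_benchmark()
  sc <- scorecard(tab)
  d1 <- tempfile(); d2 <- tempfile()
  write_scorecard(sc, d1)
  write_scorecard(scorecard(tab), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
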