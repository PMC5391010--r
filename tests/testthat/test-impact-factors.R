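test_that("named cases reproduce the printed impact-factor rows", {
  pub <- published_table1()
  for (cs in pub$case) {
    f <- factors_for_case(cs)
    printed <- as.numeric(pub[pub$case == cs, -1])
    # tolerance of one unit in the last printed place: the source table
    # mixes rounding and truncation in its 3-4 digit cells
    expect_true(all(abs(unclass(f) - printed) <= 1e-3 + 1e-12),
                info = paste("case", cs))
  }
})

test_that("severity interpolation is the A + s (D - A) line", {
  a <- unclass(factors_for_case("A"))
  d <- unclass(factors_for_case("D"))
  expect_equal(unclass(factors_for_case(0)), a)
  expect_equal(unclass(factors_for_case(1)), d)
  expect_equal(unclass(factors_for_case(1 / 3)), a + (d - a) / 3)
  # spot checks against printed interpolants
  expect_equal(factors_for_case(1 / 3)[["f_SRleak"]], 1 + (1 / 3) * 4,
               tolerance = 1e-12)
  expect_equal(factors_for_case(2 / 3)[["f_Cabk"]], 1 + (2 / 3) * 0.530,
               tolerance = 1e-12)
  # continuity and componentwise monotonicity in s
  s_grid <- seq(0, 1, length.out = 21)
  mat <- sapply(s_grid, function(s) unclass(factors_for_case(s)))
  for (k in seq_len(nrow(mat))) {
    expect_true(all(diff(mat[k, ]) >= -1e-12) || all(diff(mat[k, ]) <= 1e-12),
                info = rownames(mat)[k])
  }
})

test_that("factor construction validates and coerces inputs", {
  expect_error(impact_factors(f_NaL = -1), "finite and >= 0")
  expect_error(factors_for_case("E"), "A, B, C, D")
  expect_warning(factors_for_case(1.5), "outside")
  v <- stats::setNames(rep(1, 11), names(impact_factors()))
  expect_s3_class(as_impact_factors(v), "impact_factors")
  expect_error(as_impact_factors(c(a = 1)), "cannot interpret")
  tab <- impact_factor_table()
  expect_identical(tab$case, c("A", "B", "C", "D"))
  expect_equal(tab$f_EC50SR[4], 0.89)
})
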