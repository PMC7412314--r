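test_that("exponential transform: exact and Taylor forms, symmetry, bounds", {
  tp_exact <- transform_params(360)
  tp_taylor <- transform_params(360, mode = "taylor")
  expect_equal(tp_exact$q, 43L)                 # floor(0.120 * 360)
  expect_equal(tp_exact$half_q, 21L)

  expect_equal(exponential_transform(0, tp_exact)$values, 0)
  expect_equal(exponential_transform(1, tp_exact)$values, exp(-1))
  expect_equal(exponential_transform(0.1, tp_taylor)$values, 0.09)
  expect_equal(exponential_transform(-0.1, tp_taylor)$values, 0.09)

  d <- seq(-3, 3, by = 0.01)
  e <- exponential_transform(d, tp_exact)$values
  expect_equal(e, rev(e))                       # even in d
  expect_true(all(e >= 0 & e <= exp(-1) + 1e-15))
  expect_equal(which.max(e), which(d == -1)[1]) # maximised at |d| = 1
  # monotone increasing on [0, 1]
  on01 <- exponential_transform(seq(0, 1, by = 0.01), tp_exact)$values
  expect_true(all(diff(on01) > 0))

  # Taylor clamp: negative lobe beyond |d| = 1 clipped at zero
  et <- exponential_transform(d, tp_taylor)$values
  expect_true(all(et >= 0))
  tp_raw <- transform_params(360, mode = "taylor", clamp_negative = FALSE)
  expect_lt(min(exponential_transform(d, tp_raw)$values), 0)
})

test_that("Taylor form agrees with the exact transform to third order", {
  tp_exact <- transform_params(360)
  tp_taylor <- transform_params(360, mode = "taylor")
  d <- seq(0.001, 0.3, by = 0.001)
  gap <- abs(exponential_transform(d, tp_exact)$values -
             exponential_transform(d, tp_taylor)$values)
  # remainder of exp(-x) after two terms is x^2/2 e^{-xi}, so C ~ 0.5
  expect_lt(max(gap / d^3), 0.6)
})

test_that("exponential transform compresses amplitude gaps", {
  # for 0 < u < v < 0.5 the transformed gap is smaller than the raw gap
  set.seed(42)
  tp <- transform_params(360, mode = "taylor")
  for (i in 1:200) {
    uv <- sort(runif(2, 1e-6, 0.5 - 1e-6))
    tu <- exponential_transform(uv[1], tp)$values
    tv <- exponential_transform(uv[2], tp)$values
    expect_lt(tv - tu, uv[2] - uv[1])
  }
})

test_that("accumulation matches the brute-force window sum", {
  tp <- transform_params(360)

  ones <- accumulate(rep(1, 200), tp)$values
  expect_true(all(ones[22:179] == 43))          # interior: full window

  imp <- numeric(201)
  imp[101] <- 1
  plateau <- accumulate(imp, tp)$values
  expect_equal(which(plateau == 1), 80:122)     # length-43 plateau

  set.seed(7)
  e <- runif(500)
  expect_equal(accumulate(e, tp)$values, oracle_box_sum(e, tp$half_q))

  d <- rnorm(400)
  expect_equal(abs_accumulate(d, tp)$values, oracle_box_sum(abs(d), tp$half_q))
  expect_equal(square_accumulate(d, tp)$values, oracle_box_sum(d^2, tp$half_q))
})

test_that("comparison transforms: tiny hand cases and homogeneity", {
  tp1 <- transform_params(10)                   # q = 1 -> half_q = 0 is too
  tp1$q <- 3L; tp1$half_q <- 1L                 # small; force half_q = 1
  expect_equal(abs_accumulate(c(1, -1, 1), tp1)$values[2], 3)
  expect_equal(square_accumulate(c(2, 0, 0), tp1)$values[1:2], c(4, 4))
  expect_equal(abs_accumulate(numeric(10), tp1)$values, numeric(10))

  tp <- transform_params(360)
  d <- rnorm(300)
  expect_equal(square_accumulate(3 * d, tp)$values,
               9 * square_accumulate(d, tp)$values)
})

test_that("accumulate is linear and translation-equivariant", {
  tp <- transform_params(360)
  set.seed(11)
  a <- runif(300)
  b <- runif(300)
  expect_equal(accumulate(2 * a + 3 * b, tp)$values,
               2 * accumulate(a, tp)$values + 3 * accumulate(b, tp)$values)
  # shifting the input shifts the interior of the output
  sh <- 50L
  sa <- accumulate(c(numeric(sh), a), tp)$values
  expect_equal(sa[(sh + 30):(sh + 270)], accumulate(a, tp)$values[30:270])
})
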