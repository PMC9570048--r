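sig_of <- function(y, label = "A") {
  cell_signal(paste0("c", seq_along(y)), label, y, "tested")
}

two_pop_signals <- function(x_ref, y_ref, x_con, y_con) {
  n <- length(x_ref) + length(x_con)
  labels <- c(rep("ref", length(x_ref)), rep("con", length(x_con)))
  ids <- paste0("c", seq_len(n))
  list(sig = cell_signal(ids, labels, c(y_ref, y_con), "tested"),
       cc = cell_signal(ids, labels, c(x_ref, x_con), "cell_cycle"))
}

test_that("single-population regression matches hand least squares", {
  # perfect line
  s <- two_pop_signals(c(0, 1, 2), c(0, 1, 2), numeric(0), numeric(0))
  fit <- fit_group_regression(s$sig, s$cc, "ref")
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  # constant y: slope 0, nothing explained
  s2 <- two_pop_signals(c(0, 1, 2), c(5, 5, 5), numeric(0), numeric(0))
  fit2 <- fit_group_regression(s2$sig, s2$cc, "ref")
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$r_squared, 0)
  # (0,0),(1,1),(2,1): slope 1/2, intercept 1/6, r2 3/4
  s3 <- two_pop_signals(c(0, 1, 2), c(0, 1, 1), numeric(0), numeric(0))
  fit3 <- fit_group_regression(s3$sig, s3$cc, "ref")
  expect_equal(fit3$slope, 0.5)
  expect_equal(fit3$intercept, 1 / 6)
  expect_equal(fit3$r_squared, 0.75)
  # constant covariate is an error
  s4 <- two_pop_signals(c(1, 1, 1), c(0, 1, 2), numeric(0), numeric(0))
  expect_error(fit_group_regression(s4$sig, s4$cc, "ref"), "constant")
})

test_that("intercept contrast recovers exact parallel lines", {
  s <- two_pop_signals(c(0, 1, 2), c(0, 1, 2),
                       c(0, 1, 2), c(1, 2, 3))
  ct <- intercept_contrast(s$sig, s$cc, "con", "ref")
  expect_equal(ct$slope, 1)
  expect_equal(ct$delta, 1)
  expect_equal(ct$se, 0)
  # programmed 0.5 offset, zero residuals
  s2 <- two_pop_signals(c(0, 1, 2), c(0, 1, 2),
                        c(0, 1, 2), c(0.5, 1.5, 2.5))
  ct2 <- intercept_contrast(s2$sig, s2$cc, "con", "ref")
  expect_equal(ct2$slope, 1)
  expect_equal(ct2$delta, 0.5)
})

test_that("contrast of a population against itself is exactly zero", {
  set.seed(5)
  x <- rnorm(10); y <- 2 + x + rnorm(10, 0, 0.2)
  s <- two_pop_signals(x, y, numeric(0), numeric(0))
  ct <- intercept_contrast(s$sig, s$cc, "ref", "ref")
  expect_equal(ct$delta, 0)
  expect_gt(ct$p_value, 0.99)
})

test_that("contrast equals the normal-equations oracle on random data", {
  set.seed(17)
  for (rep in 1:25) {
    nr <- sample(3:10, 1); nc <- sample(3:10, 1)
    x_ref <- rnorm(nr); y_ref <- rnorm(nr)
    x_con <- rnorm(nc); y_con <- rnorm(nc)
    s <- two_pop_signals(x_ref, y_ref, x_con, y_con)
    ct <- intercept_contrast(s$sig, s$cc, "con", "ref")
    oracle <- ancova_oracle(x_ref, y_ref, x_con, y_con)
    expect_equal(ct$delta, oracle$delta, tolerance = 1e-10)
    expect_equal(ct$se, oracle$se, tolerance = 1e-10)
    expect_equal(ct$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(ct$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("contrast is antisymmetric and shifts by an added constant", {
  set.seed(23)
  x_ref <- rnorm(8); y_ref <- rnorm(8)
  x_con <- rnorm(9); y_con <- rnorm(9)
  s <- two_pop_signals(x_ref, y_ref, x_con, y_con)
  ct <- intercept_contrast(s$sig, s$cc, "con", "ref")
  swapped <- intercept_contrast(s$sig, s$cc, "ref", "con")
  expect_equal(swapped$delta, -ct$delta)
  expect_equal(swapped$se, ct$se)
  shift <- two_pop_signals(x_ref, y_ref, x_con, y_con + 1.7)
  ct_shift <- intercept_contrast(shift$sig, shift$cc, "con", "ref")
  expect_equal(ct_shift$delta, ct$delta + 1.7)
})

test_that("contrast guards its preconditions", {
  s <- two_pop_signals(c(0, 1, 2), c(0, 1, 2), c(0, 1), c(0, 1))
  expect_error(intercept_contrast(s$sig, s$cc, "con", "ref"), ">= 3")
  s2 <- two_pop_signals(c(1, 1, 1), c(0, 1, 2), c(1, 1, 1), c(0, 1, 2))
  expect_error(intercept_contrast(s2$sig, s2$cc, "con", "ref"),
               "constant")
  s3 <- two_pop_signals(rnorm(4), rnorm(4), rnorm(4), rnorm(4))
  expect_error(intercept_contrast(s3$sig, s3$cc, "con", "ref",
                                  alpha = 1.2), "alpha")
})

test_that("adequacy check separates linear from curved data", {
  # exactly linear: the line is the whole story
  s <- two_pop_signals(0:5, 2 + 3 * (0:5), numeric(0), numeric(0))
  rep1 <- adequacy_check(s$sig, s$cc, "ref")
  expect_equal(rep1$linear_fraction, 1, tolerance = 1e-8)
  # pure symmetric parabola: line explains nothing of what the
  # quadratic explains
  x <- -2:2
  s2 <- two_pop_signals(x, x^2, numeric(0), numeric(0))
  rep2 <- adequacy_check(s2$sig, s2$cc, "ref")
  expect_equal(rep2$r_squared_linear, 0, tolerance = 1e-12)
  expect_equal(rep2$linear_fraction, 0, tolerance = 1e-12)
  expect_lt(rep2$p_quadratic, 0.01)
  # constant y: degenerate guard
  s3 <- two_pop_signals(0:4, rep(2, 5), numeric(0), numeric(0))
  rep3 <- adequacy_check(s3$sig, s3$cc, "ref")
  expect_true(rep3$degenerate)
  expect_equal(rep3$linear_fraction, 0)
})

test_that("on noisy linear data the line captures almost everything", {
  set.seed(31)
  x <- rnorm(200)
  y <- 1 + 0.8 * x + rnorm(200, 0, 0.1)
  s <- two_pop_signals(x, y, numeric(0), numeric(0))
  rep <- adequacy_check(s$sig, s$cc, "ref")
  expect_gt(rep$linear_fraction, 0.99)
  expect_gt(rep$p_quadratic, 0.001)
})
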