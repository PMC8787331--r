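test_that("clock tables load with intercept separated and bad tables error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(synthetic_clock_table("hannum"), path)
  ck <- load_clock_table(path, name = "hannum")
  expect_s3_class(ck, "clock_definition")
  expect_length(ck$coefficients, 71)
  expect_false("(Intercept)" %in% names(ck$coefficients))

  # intercept-only table
  readr::write_csv(
    data.frame(probe_id = "(Intercept)", coefficient = 1), path)
  expect_error(load_clock_table(path), class = "dnamtraj_format_error")
  # duplicate probe
  readr::write_csv(
    data.frame(probe_id = c("(Intercept)", "cg1", "cg1"),
               coefficient = c(1, 2, 3)), path)
  expect_error(load_clock_table(path), class = "dnamtraj_format_error")
  # no intercept row
  readr::write_csv(
    data.frame(probe_id = c("cg1", "cg2"), coefficient = c(1, 2)), path)
  expect_error(load_clock_table(path), class = "dnamtraj_format_error")
})

test_that("probe intersection across tissues matches a set oracle", {
  ck <- clock_definition("toy", 0, c(cg1 = 1, cg2 = 2, cg3 = 3))
  mk <- function(probes) {
    m <- matrix(0.5, length(probes), 2,
                dimnames = list(probes, c("s1", "s2")))
    m
  }
  both <- intersect_probes(ck, mk(c("cg1", "cg2", "cg3")),
                           mk(c("cg1", "cg2", "cg3")))
  expect_setequal(both$probes, c("cg1", "cg2", "cg3"))
  expect_equal(both$report$n_missing, 0)

  one_short <- intersect_probes(ck, mk(c("cg1", "cg2", "cg3")),
                                mk(c("cg1", "cg3")))
  expect_setequal(one_short$probes, c("cg1", "cg3"))
  expect_equal(one_short$report$n_retained, 2)
  expect_equal(one_short$report$n_missing, 1)

  set.seed(11)
  for (i in 1:20) {
    clock_probes <- sample(sprintf("cg%03d", 1:60), 25)
    t1 <- sample(sprintf("cg%03d", 1:60), 40)
    t2 <- sample(sprintf("cg%03d", 1:60), 40)
    ck2 <- clock_definition("r", 0, stats::setNames(runif(25), clock_probes))
    got <- intersect_probes(ck2, mk(t1), mk(t2))$probes
    expect_setequal(got, intersect(intersect(clock_probes, t1), t2))
  }
})

test_that("linear predictor equals the explicit dot product", {
  ck <- clock_definition("one", 0.5, c(cgA = 2))
  b <- matrix(0.25, 1, 1, dimnames = list("cgA", "s1"))
  expect_equal(unname(linear_predictor(ck, b)), 1.0)

  # zero coefficients: score is the intercept for every sample
  ck0 <- clock_definition("zero", 3.5, c(cgA = 0, cgB = 0))
  b2 <- matrix(runif(6), 3, 2, dimnames = list(c("cgA", "cgB", "cgC"),
                                               c("s1", "s2")))
  expect_equal(unname(linear_predictor(ck0, b2)), c(3.5, 3.5))

  set.seed(4)
  probes <- sprintf("cg%03d", 1:50)
  coefs <- stats::setNames(rnorm(50), probes)
  ckr <- clock_definition("r50", rnorm(1), coefs)
  br <- matrix(runif(50 * 7), 50, 7,
               dimnames = list(probes, paste0("s", 1:7)))
  oracle <- apply(br, 2, function(col) ckr$intercept + sum(coefs * col))
  expect_equal(linear_predictor(ckr, br), oracle, tolerance = 1e-12)

  expect_error(linear_predictor(ckr, br, probe_set = character(0)))
  bad <- br; bad[1, 1] <- 1.5
  expect_error(linear_predictor(ckr, bad),
               class = "dnamtraj_validation_error")
})

test_that("Horvath transform is the exact piecewise inverse and monotone", {
  expect_equal(horvath_inverse(0), 20)
  expect_equal(horvath_inverse(1), 41)
  ages <- c(0, 5, 20, 60, 100)
  expect_equal(horvath_inverse(horvath_forward(ages)), ages,
               tolerance = 1e-12)
  x <- seq(-3, 4, by = 0.01)
  expect_true(all(diff(horvath_inverse(x)) > 0))
  expect_error(horvath_inverse(NaN))
})

test_that("per-sample standardization makes scores shift-invariant", {
  set.seed(8)
  probes <- sprintf("cg%02d", 1:20)
  ck <- clock_definition("z", 1, stats::setNames(rnorm(20), probes),
                         standardize_per_sample = TRUE)
  b <- matrix(runif(20 * 3, 0.2, 0.6), 20, 3,
              dimnames = list(probes, paste0("s", 1:3)))
  shifted <- pmin(pmax(b + 0.2, 0), 1)
  expect_equal(linear_predictor(ck, b), linear_predictor(ck, shifted),
               tolerance = 1e-10)
})

test_that("missing-probe policies behave as contracted", {
  ck <- clock_definition("two", 1, c(cgA = 2, cgB = 4))
  b <- matrix(0.5, 1, 2, dimnames = list("cgA", c("s1", "s2")))
  out <- compute_dnam_age(ck, b, probe_policy = "drop_missing")
  expect_equal(out$n_probes_used, c(1L, 1L))
  expect_equal(out$n_probes_missing, c(1L, 1L))
  expect_equal(out$dnam_age, c(2, 2))  # 1 + 2 * 0.5
  expect_equal(out$n_probes_used + out$n_probes_missing,
               rep(length(ck$coefficients), 2))
  expect_error(compute_dnam_age(ck, b, probe_policy = "strict"),
               class = "dnamtraj_missing_probe_error")

  # identity vs horvath_inverse with the same coefficients compose exactly
  ckh <- clock_definition("h", 1, c(cgA = 2, cgB = 4),
                          transform = "horvath_inverse")
  b2 <- matrix(runif(4, 0, 0.2), 2, 2,
               dimnames = list(c("cgA", "cgB"), c("s1", "s2")))
  ident <- compute_dnam_age(ck, b2)$dnam_age
  horv <- compute_dnam_age(ckh, b2)$dnam_age
  expect_equal(horv, horvath_inverse(ident))
})

test_that("DNAm age equals a naive per-sample loop on random clocks", {
  set.seed(12)
  probes <- sprintf("cg%03d", 1:30)
  ck <- clock_definition("r", rnorm(1), stats::setNames(rnorm(30), probes))
  b <- matrix(runif(30 * 5), 30, 5, dimnames = list(probes, paste0("s", 1:5)))
  out <- compute_dnam_age(ck, b)
  naive <- vapply(colnames(b), function(s) {
    ck$intercept + sum(ck$coefficients[probes] * b[probes, s])
  }, numeric(1))
  expect_equal(out$dnam_age, unname(naive), tolerance = 1e-10)
})
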