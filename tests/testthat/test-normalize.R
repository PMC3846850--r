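test_that("flooring replaces sub-floor values only", {
  v <- matrix(c(0.05, 5, 0, 0.1), 2, 2,
              dimnames = list(c("f1", "f2"), c("S1", "S2")))
  out <- floor_baseline(expr_mat(v), floor = 0.1)
  expect_equal(unname(em_matrix(out)), matrix(c(0.1, 5, 0.1, 0.1), 2, 2))
  expect_equal(stage(out), "floored")
  expect_error(floor_baseline(expr_mat(v), floor = -1), class = "ersvm_config_error")

  zeros <- expr_mat(matrix(0, 3, 1, dimnames = list(paste0("f", 1:3), "S1")))
  expect_true(all(em_matrix(floor_baseline(zeros)) == 0.1))
})

test_that("per-array scaling makes every column median exactly 1", {
  v <- matrix(c(1, 2, 3, 7, 7, 7), 3, 2,
              dimnames = list(paste0("f", 1:3), c("S1", "S2")))
  out <- normalize_per_array(floor_baseline(expr_mat(v)))
  x <- em_matrix(out)
  expect_equal(unname(x[, "S1"]), c(0.5, 1, 1.5))
  expect_equal(unname(x[, "S2"]), c(1, 1, 1))

  withr::with_seed(5, v99 <- matrix(rlnorm(99 * 3), 99, 3,
                                    dimnames = list(paste0("f", 1:99), paste0("S", 1:3))))
  out99 <- normalize_per_array(floor_baseline(expr_mat(v99)))
  expect_equal(unname(apply(em_matrix(out99), 2, median)), rep(1, 3), tolerance = 1e-12)
})

test_that("per-feature scaling makes every row median 1 and stores the medians", {
  v <- matrix(c(2, 4, 8), 1, 3, dimnames = list("f1", paste0("S", 1:3)))
  m <- expr_mat(v)
  attr(m, "stage") <- "array_norm"
  out <- normalize_per_feature(m)
  expect_equal(unname(em_matrix(out)[1, ]), c(0.5, 1, 2))
  expect_equal(norm_params(out)$per_feature_median[["f1"]], 4)

  withr::with_seed(6, vr <- matrix(rlnorm(50 * 7), 50, 7,
                                   dimnames = list(paste0("f", 1:50), paste0("S", 1:7))))
  mr <- expr_mat(vr); attr(mr, "stage") <- "array_norm"
  expect_equal(unname(apply(em_matrix(normalize_per_feature(mr)), 1, median)),
               rep(1, 50), tolerance = 1e-12)
})

test_that("z-scores use the population sd and are idempotent", {
  v <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f1", paste0("S", 1:3)))
  z <- zscore(expr_mat(v))
  expect_equal(unname(em_matrix(z)[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(norm_params(z)$sd[["f1"]], sqrt(2 / 3))
  expect_equal(norm_params(z)$sd_type, "population")

  z2 <- zscore(z)
  expect_equal(em_matrix(z2), em_matrix(z), tolerance = 1e-12)

  const <- matrix(c(2, 2, 2, 1, 2, 3), 2, 3, byrow = TRUE,
                  dimnames = list(c("flat", "ok"), paste0("S", 1:3)))
  expect_error(zscore(expr_mat(const)), "flat", class = "ersvm_constant_feature")
})

test_that("the full chain standardizes every feature", {
  withr::with_seed(7, v <- matrix(rlnorm(200 * 20, 5, 1.5), 200, 20,
                                  dimnames = list(paste0("f", 1:200), paste0("S", 1:20))))
  z <- em_matrix(normalize_chain(expr_mat(v)))
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_equal(unname(sqrt(rowMeans(z^2))), rep(1, 200), tolerance = 1e-9)
})

test_that("z-scores are invariant to positive affine rescaling per feature", {
  withr::with_seed(8, v <- matrix(rlnorm(30 * 12), 30, 12,
                                  dimnames = list(paste0("f", 1:30), paste0("S", 1:12))))
  m <- expr_mat(v)
  gains <- runif(30, 0.5, 3)
  offsets <- runif(30, 0, 10)
  v2 <- v * gains + offsets
  expect_equal(em_matrix(zscore(expr_mat(v2))), em_matrix(zscore(m)), tolerance = 1e-9)
})

test_that("rescaling one array does not change its per-array-normalized column", {
  withr::with_seed(9, v <- matrix(rlnorm(40 * 5, 4, 1), 40, 5,
                                  dimnames = list(paste0("f", 1:40), paste0("S", 1:5))))
  base <- em_matrix(normalize_per_array(floor_baseline(expr_mat(v))))
  v2 <- v; v2[, 3] <- v2[, 3] * 7.5
  scaled <- em_matrix(normalize_per_array(floor_baseline(expr_mat(v2))))
  expect_equal(scaled[, 3], base[, 3], tolerance = 1e-12)
})

test_that("exponentiation is pointwise and composes with z-scoring", {
  v <- matrix(c(3, 0, 1, 2, -1, 4, 0.5, 1.5, 2.5), 3, 3,
              dimnames = list(paste0("f", 1:3), paste0("S", 1:3)))
  m <- make_em(v)  # log-scale cohorts arrive marked raw, values may be signed
  expect_error(exponentiate(m, base = -2), class = "ersvm_config_error")
  out <- exponentiate(m, base = 2)
  expect_equal(em_matrix(out)["f1", "S1"], 8)
  expect_equal(em_matrix(out)["f1", "S2"], 4)
  expect_equal(em_matrix(out)["f2", "S1"], 1)

  # two-step pipeline equals the hand-built oracle table
  oracle <- 2^v
  oz <- (oracle - rowMeans(oracle)) / sqrt(rowMeans((oracle - rowMeans(oracle))^2))
  expect_equal(em_matrix(zscore(out)), oz, tolerance = 1e-12)
})

test_that("housekeeping log-ratios match hand-computed values and cancel sample gains", {
  withr::with_seed(10, v <- matrix(rlnorm(4 * 4, 3, 1), 4, 4,
                                   dimnames = list(c("g1", "g2", "g3", "ACTB"),
                                                   paste0("S", 1:4))))
  v["g1", "S1"] <- v["ACTB", "S1"]            # equal to housekeeping -> 0
  v["g2", "S2"] <- exp(1) * v["ACTB", "S2"]   # e-fold above -> 1
  out <- log_actb_normalize(expr_mat(v), c("g1", "g2", "g3"), "ACTB")
  x <- em_matrix(out)
  expect_equal(nrow(x), 3)
  expect_equal(x["g1", "S1"], 0)
  expect_equal(x["g2", "S2"], 1)
  oracle <- log(v[1:3, , drop = FALSE]) - rep(log(v["ACTB", ]), each = 3)
  expect_equal(unname(x), unname(oracle), tolerance = 1e-12)
  expect_equal(stage(out), "log_actb")

  # a global per-sample factor cancels
  v2 <- sweep(v, 2, c(2, 0.5, 10, 1), "*")
  expect_equal(em_matrix(log_actb_normalize(expr_mat(v2), c("g1", "g2", "g3"), "ACTB")),
               x, tolerance = 1e-12)

  v[2, 2] <- 0
  expect_error(log_actb_normalize(expr_mat(v), c("g1", "g2", "g3"), "ACTB"),
               "positive")
})

test_that("stage preconditions are enforced", {
  v <- matrix(1:4 + 0, 2, 2, dimnames = list(c("f1", "f2"), c("S1", "S2")))
  m <- expr_mat(v)
  expect_error(normalize_per_array(m), class = "ersvm_stage_error")
  expect_error(normalize_per_feature(m), class = "ersvm_stage_error")
  expect_error(floor_baseline(floor_baseline(m)), class = "ersvm_stage_error")
})
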