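test_that("absorptivity matrix carries the system and rejects singular ones", {
  E <- absorptivity_matrix()
  expect_equal(dim(E), c(2, 2))
  expect_equal(E["266", "HMF"], 12.38)
  expect_equal(E["284", "HMF"], 22.7)
  expect_equal(E["266", "LA"], 0.023)
  expect_equal(E["284", "LA"], 0.014)
  # proportional columns make the two wavelengths uninformative
  expect_error(absorptivity_matrix(hmf = c(1, 2), la = c(0.5, 1)), "Singular")
  expect_error(absorptivity_matrix(wavelengths = c(266, 266)), "distinct")
})

test_that("correction coefficient is the before/after absorbance ratio", {
  before <- tiny_spectrum(wl = c(260, 290), ab = c(0.81, 0.81))
  after <- tiny_spectrum(wl = c(260, 290), ab = c(0.50, 0.50))
  expect_equal(correction_coefficient(before, after, 266), 1.62)
  expect_equal(correction_coefficient(before, before, 266), 1)

  zero <- tiny_spectrum(wl = c(260, 290), ab = c(0, 0))
  expect_error(correction_coefficient(before, zero, 266), "undefined")
  expect_warning(correction_coefficient(after, before, 266), "added absorbance")
})

test_that("two-component solve inverts the forward Beer's-law construction", {
  # worked example: C_HMF = 0.05, C_LA = 30
  a <- forward_absorbance(0.05, 30)
  expect_equal(a$a266, 1.309)
  expect_equal(a$a284, 1.555)
  sol <- solve_two_component(a$a266, a$a284)
  expect_equal(sol$HMF, 0.05, tolerance = 1e-12)
  expect_equal(sol$LA, 30, tolerance = 1e-12)

  # zero absorbance and single-analyte cases
  expect_equal(unlist(solve_two_component(0, 0)), c(HMF = 0, LA = 0))
  pure <- forward_absorbance(0.08, 0)
  sol <- solve_two_component(pure$a266, pure$a284)
  expect_equal(sol$HMF, 0.08, tolerance = 1e-12)
  expect_equal(sol$LA, 0, tolerance = 1e-10)

  # path length scales absorbance, not concentration
  a2 <- forward_absorbance(0.05, 30, path = 2)
  sol2 <- solve_two_component(a2$a266, a2$a284, path_length = 2)
  expect_equal(sol2$HMF, 0.05, tolerance = 1e-12)
})

test_that("round trip is exact over the working concentration range", {
  withr::local_seed(101)
  n <- 200
  c_hmf <- runif(n, 0, 0.1)
  c_la <- runif(n, 0, 65)
  a <- forward_absorbance(c_hmf, c_la)
  sol <- solve_two_component(a$a266, a$a284)
  expect_lt(max(abs(sol$HMF - c_hmf) / c_hmf), 1e-9)
  expect_lt(max(abs(sol$LA - c_la) / c_la), 1e-9)
})

test_that("solver agrees with the zooming grid-search oracle", {
  withr::local_seed(202)
  for (i in 1:5) {
    c_true <- c(runif(1, 0.01, 0.1), runif(1, 5, 60))
    a <- forward_absorbance(c_true[1], c_true[2])
    sol <- unlist(solve_two_component(a$a266, a$a284))
    oracle <- grid_solve_oracle(a$a266, a$a284)
    expect_lt(max(abs(sol - oracle)), 1e-6)
  }
})

test_that("contents applies W = C * M * K * R and is linear", {
  expect_equal(contents(1, 1, 1, 1), 1)
  expect_equal(contents(1, 116.12, 1.62, 2), 376.2288)
  expect_equal(contents(0, 126.11, 69.3, 10), 0)
  expect_error(contents(-1, 1), ">= 0")
  # linearity in each argument
  expect_equal(contents(2, 116.12, 1.62, 3), 2 * 3 * contents(1, 116.12, 1.62, 1))
})

test_that("quantify_sample composes read-out, solve, clamp and contents", {
  defs <- method_defaults()
  # noiseless forward spectrum, no treatment: K = 1, R = 1 -> W/M == C
  cfg <- synthetic_config(noise_sd = 0,
                          byproduct = list(center = 400, width = 30, amplitude = 0))
  c_true <- c(HMF = 0.06, LA = 40)
  s <- render_spectrum(c_true, cfg)
  q <- quantify_sample(s, k = c(HMF = 1, LA = 1), loq = defs$loq)
  expect_equal(q$analyte, c("HMF", "LA"))
  expect_equal(q$concentration, unname(c_true), tolerance = 1e-9)
  expect_equal(q$content / q$molar_mass, q$concentration, tolerance = 1e-12)
  expect_equal(q$content, unname(c_true) * unname(defs$molar_mass[c("HMF", "LA")]),
               tolerance = 1e-9)
  expect_false(any(q$below_loq))
  expect_false(any(q$negative_clamped))

  # all-zero spectrum: zero contents, below-LOQ flags set
  z <- tiny_spectrum(wl = c(260, 290), ab = c(0, 0))
  qz <- quantify_sample(z, loq = defs$loq)
  expect_equal(qz$content, c(0, 0))
  expect_true(all(qz$below_loq))

  # absorbances consistent with a slightly negative HMF get clamped + flagged
  a <- forward_absorbance(-0.01, 30)
  neg <- tiny_spectrum(wl = c(266, 284), ab = c(a$a266, a$a284))
  qn <- quantify_sample(neg, k = c(HMF = 1, LA = 1))
  expect_true(qn$negative_clamped[qn$analyte == "HMF"])
  expect_equal(qn$concentration[qn$analyte == "HMF"], 0)
  expect_equal(qn$concentration[qn$analyte == "LA"], 30, tolerance = 1e-9)

  # dilution factor propagates into contents
  s2 <- render_spectrum(c_true, cfg, dilution_factor = 4)
  q2 <- quantify_sample(s2, k = c(HMF = 1, LA = 1))
  expect_equal(q2$content, 4 * q$content, tolerance = 1e-9)
})
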