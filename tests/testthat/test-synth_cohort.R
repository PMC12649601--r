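test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_subjects = 4), "n_subjects")
  expect_error(cohort_spec(n_vertices = 2), "n_vertices")
  expect_error(cohort_spec(n_components = 0), "n_components")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(n_components = 2, component_loadings = c(1, 2)),
               "strictly decreasing")
  expect_error(cohort_spec(age_range = c(37, 22)), "age_range")
})

test_that("same spec + same seed gives bit-identical cohorts", {
  spec <- cohort_spec(n_subjects = 20, n_vertices = 15, n_components = 1,
                      component_loadings = 1, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$myelin, b$myelin)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_spec(n_subjects = 20, n_vertices = 15,
                                    n_components = 1, component_loadings = 1,
                                    seed = 43))
  expect_false(identical(a$myelin, c2$myelin))
})

test_that("noise-free rank-1 limit gives a +/-1 residual correlation matrix", {
  spec <- cohort_spec(n_subjects = 40, n_vertices = 12, n_components = 1,
                      component_loadings = 1, noise_sd = 1e-9,
                      equalize_variance = FALSE,
                      beta_age = 0, beta_age2 = 0, beta_gender = 0,
                      beta_interaction = 0, seed = 5)
  co <- generate_cohort(spec)
  rho <- covariance_network(residualize(co))$rho
  expect_true(all(abs(abs(rho) - 1) < 1e-6))
  # rank-1: second eigenvalue negligible
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-6)
})

test_that("planted components dominate the residual correlation spectrum", {
  # oracle: eigendecomposition of the realized residual correlation matrix
  co <- generate_cohort(cohort_spec(n_subjects = 200, n_vertices = 300,
                                    n_components = 3, seed = 7))
  rho <- covariance_network(residualize(co))$rho
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  shares <- ev / sum(ev)
  expect_true(all(shares[1:3] > shares[4]))
  # planted-structure recoverability: top-3 eigenvectors match the truth
  vec <- eigen(rho, symmetric = TRUE)$vectors[, 1:3]
  r <- abs(diag(cor(vec, co$truth$patterns)))
  expect_true(all(r > 0.95))
})

test_that("injected confounds are removed exactly in the noise-free limit", {
  spec <- cohort_spec(n_subjects = 50, n_vertices = 10, n_components = 1,
                      component_loadings = 1, noise_sd = 1e-12,
                      equalize_variance = FALSE,
                      beta_age = 0.5, beta_age2 = 0.01, beta_gender = 2,
                      beta_interaction = 0.1, seed = 9)
  co <- generate_cohort(spec)
  fit <- residualize(co)
  # recovered per-vertex confound coefficients equal the injected ones
  injected <- t(co$truth$beta)
  recovered <- fit$coefficients[c("age", "age2", "gender", "age_x_gender"), ]
  expect_equal(unname(recovered), unname(injected), tolerance = 1e-6)
})

test_that("generate_parcellation covers modes, determinism and errors", {
  expect_identical(generate_parcellation(10, 5, mode = "block"),
                   rep(1:5, each = 2L))
  expect_identical(generate_parcellation(7, 1, mode = "block"), rep(1L, 7))
  r1 <- generate_parcellation(100, 4, seed = 3, mode = "random")
  r2 <- generate_parcellation(100, 4, seed = 3, mode = "random")
  expect_identical(r1, r2)
  expect_identical(sort(unique(r1)), 1:4)  # every class non-empty
  expect_error(generate_parcellation(3, 5), "exceeds")
})

test_that("term maps honor planting, zeros, and determinism", {
  target <- sin(seq_len(50))
  tm <- generate_term_maps(10, 50, planted = list(list(term = 4, map = target)),
                           zero_fraction = 0, seed = 2)
  expect_equal(unname(tm[4, ]), target)
  dt <- decode_terms(target, tm)
  expect_identical(dt$term[1], "term4")
  expect_equal(dt$r[1], 1, tolerance = 1e-12)

  expect_error(generate_term_maps(5, 10, planted = list(
    list(term = 2, map = 1:10), list(term = 2, map = 1:10))), "duplicate")
  expect_error(generate_term_maps(5, 10, planted = list(
    list(term = 9, map = 1:10))), "out of range")

  all_zero <- generate_term_maps(5, 20, zero_fraction = 1, seed = 1)
  expect_true(all(all_zero == 0))
  expect_error(decode_terms(rnorm(20), all_zero), "empty")

  expect_identical(generate_term_maps(50, 30, seed = 8),
                   generate_term_maps(50, 30, seed = 8))
})

test_that("feature maps realize their planted correlations", {
  ref <- mcnet:::with_seed(1, rnorm(5000))
  fm <- generate_feature_maps(3, 5000, ref,
                              planted_correlation = c(1, 0, -0.5), seed = 4)
  r <- apply(fm, 1, cor, y = ref)
  expect_equal(unname(r[1]), 1, tolerance = 1e-10)   # affine copy
  expect_equal(unname(r[3]), -0.5, tolerance = 0.05)
  # planted r = 0 at large n: |realized r| small across seeds
  r0 <- vapply(1:10, function(s) {
    cor(generate_feature_maps(1, 10000, rep_len(ref, 10000),
                              planted_correlation = 0, seed = s)[1, ],
        rep_len(ref, 10000))
  }, numeric(1))
  expect_true(all(abs(r0) < 0.05))
  expect_error(generate_feature_maps(2, 10, 1:10, planted_correlation = 1.2),
               "<= 1")
})

test_that("cohort round-trips through the TSV writer/reader", {
  co <- make_cohort(n_subjects = 12, n_vertices = 8)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_cohort(paths[["myelin"]], paths[["covariates"]])
  expect_equal(unname(back$myelin), unname(co$myelin), tolerance = 1e-12)
  expect_equal(back$covariates$age, co$covariates$age, tolerance = 1e-12)
  expect_identical(back$covariates$gender, as.numeric(co$covariates$gender))
})
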