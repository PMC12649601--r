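test_that("class means match hand computation and validate inputs", {
  map <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  parc <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2)
  cm <- class_means(map, parc)
  expect_equal(unname(cm$class_means), c(2, 19 / 3, 30 / 4))
  expect_identical(unname(cm$n_per_class), c(3L, 3L, 4L))

  expect_equal(unname(class_means(rep(3.5, 8), rep(1:2, 4))$class_means),
               c(3.5, 3.5))
  expect_equal(unname(class_means(map, rep(1, 10))$class_means), mean(map))
  expect_error(class_means(map, parc[-1]), "length")
  expect_error(class_means(map, c(rep(1, 5), rep(3, 5))), "empty class")
})

test_that("class means are invariant to joint vertex permutation", {
  set.seed(41)
  map <- rnorm(60)
  parc <- generate_parcellation(60, 5, mode = "block")
  perm <- sample(60)
  expect_equal(class_means(map, parc)$class_means,
               class_means(map[perm], parc[perm])$class_means)
})

test_that("profile_dispersion uses the sample (n-1) convention", {
  expect_identical(
    round(profile_dispersion(c(-0.0659, 0.0296, 0.0085, 0.1651, -0.1975)), 4),
    0.1331)
  expect_identical(profile_dispersion(rep(2.3, 4)), 0)
  expect_error(profile_dispersion(1.5), ">= 2")
})

test_that("decode_terms masks jointly non-zero vertices like the hand oracle", {
  # 8 vertices; both maps zero somewhere -> 6-vertex mask
  map <- c(0.5, -1, 2, 0, 1.5, -0.5, 1, 2.5)
  term <- c(1, -2, 1.8, 1.1, 0, -0.7, 0.9, 3)
  # joint non-zero mask excludes vertices 4 (map 0) and 5 (term 0)
  mask <- map != 0 & term != 0
  expect_identical(sum(mask), 6L)
  dt <- decode_terms(map, rbind(t1 = term))
  expect_equal(dt$r, cor(map[mask], term[mask]), tolerance = 1e-12)
  expect_identical(dt$n_used, 6)

  # identical and negated maps rank first with |r| = 1
  tm <- rbind(same = map, neg = -map,
              noise = c(1, 2, -1, 3, 0.5, -2, 1, 0.2))
  dt2 <- decode_terms(map, tm)
  expect_true(all(dt2$term[1:2] %in% c("same", "neg")))
  expect_equal(abs(dt2$r[1:2]), c(1, 1), tolerance = 1e-12)
  expect_identical(dt2$rank, 1:3)

  # a term leaving < 3 jointly non-zero vertices is flagged undefined
  tiny <- rbind(ok = term, degenerate = c(1, 1, 0, 0, 0, 0, 0, 0))
  dt3 <- decode_terms(map, tiny)
  expect_identical(nrow(dt3), 1L)
  expect_identical(attr(dt3, "undefined"), "degenerate")

  # ranking invariance under positive rescaling that keeps the zero mask
  dt4 <- decode_terms(2.5 * map, tm)
  expect_identical(dt4$term, dt2$term)
})

test_that("correlate_features flags by p <= alpha/m and handles degeneracies", {
  set.seed(51)
  v <- 400
  map <- rnorm(v)
  feats <- rbind(affine = 3 * map - 1, noise = rnorm(v), flat = rep(1, v))
  rep1 <- correlate_features(list(g = map), feats, alpha = 0.05)
  expect_equal(rep1$r[rep1$feature == "affine"], 1, tolerance = 1e-12)
  expect_true(rep1$significant[rep1$feature == "affine"])
  expect_identical(rep1$code[rep1$feature == "flat"], "constant")
  expect_false(rep1$significant[rep1$feature == "flat"])
  expect_identical(attr(rep1, "m"), 3L)

  # m = 1 reduces to the raw alpha threshold
  p_noise <- rep1$p[rep1$feature == "noise"]
  rep_m1 <- correlate_features(list(g = map), feats["noise", , drop = FALSE],
                               m = 1)
  expect_identical(rep_m1$significant, p_noise <= 0.05)
})

test_that("Bonferroni type-I error is ~ alpha/m under the global null", {
  # simulation oracle: independent maps and features, expect flag rate a/m
  alpha <- 0.05; m <- 30; reps <- 400; v <- 150
  flags <- 0L; total <- 0L
  set.seed(61)
  for (i in seq_len(reps)) {
    maps <- matrix(rnorm(v * 3), v, 3)
    feats <- matrix(rnorm(10 * v), 10, v)
    rep_i <- correlate_features(maps, feats, alpha = alpha, m = m)
    flags <- flags + sum(rep_i$significant)
    total <- total + nrow(rep_i)
  }
  rate <- flags / total
  expect_lt(rate, 3 * alpha / m)
  expect_gt(rate, alpha / m / 3)
})

test_that("holm_adjust reproduces hand values and the reference implementation", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(0.02, 5)), rep(0.1, 5))
  expect_equal(holm_adjust(rep(0.4, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(holm_adjust(p), stats::p.adjust(p, method = "holm"))
  }
})

test_that("gradient_strength_matrix couples planted structure and nulls correctly", {
  # rank-1 construction: the first gradient IS the strength pattern
  v <- 120
  pat <- sin(seq_len(v) / 5)
  rho <- 0.9 * outer(pat, pat)
  diag(rho) <- 1
  s <- strength_maps(rho)
  g <- exact_gradients(rho, 2)
  rep1 <- gradient_strength_matrix(g, s)
  r_g1_full <- rep1$r[rep1$map == "G1" & rep1$feature == "full"]
  expect_gt(abs(r_g1_full), 0.9)
  expect_identical(attr(rep1, "m"), 6L)
  expect_identical(attr(rep1, "method"), "holm")

  # a gradient column replaced by the full-strength map correlates at 1
  g2 <- g; g2$scores[, 2] <- s$full
  rep2 <- gradient_strength_matrix(g2, s)
  expect_equal(rep2$r[rep2$map == "G2" & rep2$feature == "full"], 1,
               tolerance = 1e-12)

  # permutation null: shuffled strength maps decouple
  set.seed(81)
  co <- generate_cohort(cohort_spec(n_subjects = 100, n_vertices = 200,
                                    n_components = 2,
                                    component_loadings = c(1, 0.5), seed = 5))
  net <- covariance_network(residualize(co))
  g3 <- exact_gradients(net, 3)
  s3 <- strength_maps(net)
  perm <- sample(200)
  s3p <- list(negative = s3$negative[perm], positive = s3$positive[perm],
              full = s3$full[perm])
  rep3 <- gradient_strength_matrix(g3, s3p)
  expect_true(all(abs(rep3$r) < 0.25))
  expect_true(all(rep3$p_adj[abs(rep3$r) < 0.05] > 0.05))
})
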