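test_that("the catalog has 30 connected classes with sizes (1, 2, 6, 21)", {
  cat30 <- build_catalog()
  expect_length(cat30, 30L)
  expect_identical(names(cat30), sprintf("G%d", 0:29))
  sizes <- vapply(unclass(cat30), `[[`, integer(1), "n_nodes")
  expect_identical(as.integer(table(sizes)), c(1L, 2L, 6L, 21L))
  # every catalog graph is connected, simple, and classes are pairwise
  # non-isomorphic (igraph as the independent isomorphism oracle)
  igs <- catalog_igraphs()
  for (g in igs) expect_true(igraph::is_connected(g))
  for (i in 1:29) for (j in (i + 1):30) {
    if (igraph::vcount(igs[[i]]) == igraph::vcount(igs[[j]])) {
      expect_false(igraph::isomorphic(igs[[i]], igs[[j]]))
    }
  }
})

test_that("pinned catalog identities match their named structures", {
  igs <- catalog_igraphs()
  expect_true(igraph::isomorphic(igs$G1,
                                 igraph::make_graph(c(1, 2, 2, 3),
                                                    directed = FALSE)))
  expect_true(igraph::isomorphic(igs$G2, igraph::make_full_graph(3)))
  expect_true(igraph::isomorphic(igs$G3, igraph::make_ring(4, circular = FALSE)))
  expect_true(igraph::isomorphic(igs$G4, igraph::make_star(4, "undirected")))
  expect_true(igraph::isomorphic(igs$G5, igraph::make_ring(4)))
  expect_true(igraph::isomorphic(igs$G8, igraph::make_full_graph(4)))
  expect_true(igraph::isomorphic(igs$G9, igraph::make_ring(5, circular = FALSE)))
  expect_true(igraph::isomorphic(igs$G11, igraph::make_star(5, "undirected")))
  expect_true(igraph::isomorphic(igs$G15, igraph::make_ring(5)))
  expect_true(igraph::isomorphic(igs$G20,
                                 igraph::make_full_bipartite_graph(2, 3)))
  expect_true(igraph::isomorphic(igs$G29, igraph::make_full_graph(5)))
  # G13 is the triangle with a 2-path tail; G16 the 4-cycle with pendant --
  # the classic equal-degree-sequence pair must classify differently
  cat30 <- unclass(build_catalog())
  deg <- function(e) sort(tabulate(c(e$edges), 5))
  expect_identical(deg(cat30$G13), deg(cat30$G16))
  expect_false(igraph::isomorphic(igs$G13, igs$G16))
  expect_true(igraph::isomorphic(
    igs$G13, igraph::make_graph(c(1, 2, 2, 3, 1, 3, 3, 4, 4, 5),
                                directed = FALSE)))
})

test_that("enumerate_connected_classes counts per size are (1, 2, 6, 21)", {
  enum <- enumerate_connected_classes(2:5)
  expect_identical(unname(enum$per_size), c(1L, 2L, 6L, 21L))
  expect_identical(enum$total, 30L)
})

test_that("threshold_graph applies the signed edge rules", {
  rho <- matrix(0.5, 4, 4); diag(rho) <- 1
  expect_identical(nrow(threshold_graph(rho, 0.4)$edges), 6L)  # complete
  expect_identical(nrow(threshold_graph(rho, -0.2)$edges), 0L) # empty
  expect_error(threshold_graph(rho, 0), "undefined")
  expect_error(threshold_graph(rho, 1.5), "<= 1")

  # 5-node toy with mixed signs, checked against hand evaluation
  m <- diag(5)
  vals <- c(-0.5, 0.3, -0.1, 0.25, 0.45, -0.25, 0.05, -0.45, 0.2, -0.05)
  m[upper.tri(m)] <- vals
  m <- m + t(m) - diag(diag(m))
  # upper.tri fill order: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),(1,5),...
  g_pos <- threshold_graph(m, 0.2)
  expect_identical(g_pos$edges,
                   matrix(c(1L, 1L, 2L, 3L,
                            3L, 4L, 4L, 5L), ncol = 2,
                          dimnames = list(NULL, c("i", "j"))))
  g_neg <- threshold_graph(m, -0.25)
  expect_identical(g_neg$edges,
                   matrix(c(1L, 2L, 3L,
                            2L, 5L, 4L), ncol = 2,
                          dimnames = list(NULL, c("i", "j"))))
  expect_identical(g_neg$n_nodes, 5L)  # isolated nodes retained
})

test_that("census_exact matches hand counts on K3 and P4", {
  k3 <- census_exact(as_mcn_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3))))$counts
  expect_identical(unname(k3), c(3, 0, 1, rep(0, 27)))
  p4 <- census_exact(as_mcn_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4))))$counts
  expect_identical(unname(p4), c(3, 2, 0, 1, rep(0, 26)))
})

test_that("census_exact equals the subset-enumeration oracle on random graphs", {
  for (seed in 1:12) {
    n <- sample(c(8, 10, 12), 1)
    g <- make_er_graph(n, p = 0.3, seed = seed)
    expect_equal(census_exact(g)$counts, oracle_census(g), tolerance = 0)
  }
})

test_that("the census is invariant under node relabeling", {
  g <- make_er_graph(12, 0.35, seed = 99)
  perm <- mcnet:::with_seed(7, sample(12))
  g2 <- as_mcn_graph(12, cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]))
  expect_identical(census_exact(g)$counts, census_exact(g2)$counts)
})

test_that("the exact census guardrail aborts very large enumerations", {
  g <- make_er_graph(40, 0.5, seed = 1)
  expect_error(census_exact(g, max_subgraphs = 1000), "census_sampled")
})

test_that("census_sampled converges to the exact counts on K3", {
  k3 <- as_mcn_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  cs <- census_sampled(k3, n_samples = 4000, seed = 2)
  expect_identical(unname(cs$counts["G0"]), 3)  # edge count is exact
  expect_lt(abs(cs$counts["G2"] - 1), max(3 * cs$se["G2"], 1e-9))
  expect_true(all(cs$counts[-c(1, 3)] == 0))
})

test_that("census_sampled is within 3 SE of the exact census", {
  n_seeds <- 12; ok <- 0L; checks <- 0L
  for (seed in seq_len(n_seeds)) {
    g <- make_er_graph(30, 0.2, seed = 200 + seed)
    ex <- census_exact(g)$counts
    cs <- census_sampled(g, n_samples = 60000, seed = seed)
    nz <- ex > 0
    within <- abs(cs$counts[nz] - ex[nz]) <= pmax(3 * cs$se[nz], 1e-9)
    ok <- ok + sum(within); checks <- checks + sum(nz)
  }
  expect_gt(ok / checks, 0.95)
})

test_that("sampling errors shrink like 1/sqrt(2) when samples double", {
  g <- make_er_graph(25, 0.25, seed = 17)
  se1 <- census_sampled(g, n_samples = 20000, seed = 4)$se
  se2 <- census_sampled(g, n_samples = 40000, seed = 4)$se
  big <- se1 > 0 & se2 > 0
  ratio <- median(se1[big] / se2[big])
  expect_equal(ratio, sqrt(2), tolerance = 0.15)
})

test_that("sampled estimates are unbiased across seeds", {
  g <- make_er_graph(20, 0.3, seed = 55)
  ex <- census_exact(g)$counts
  est <- rowMeans(vapply(1:30, function(s)
    census_sampled(g, n_samples = 5000, seed = s)$counts, numeric(30)))
  nz <- ex > 100
  expect_true(all(abs(est[nz] / ex[nz] - 1) < 0.1))
})

test_that("an edgeless graph yields zero estimates with a warning", {
  g <- as_mcn_graph(6, matrix(integer(0), 0, 2))
  expect_warning(cs <- census_sampled(g, n_samples = 10, seed = 1), "no edges")
  expect_true(all(cs$counts == 0))
})

test_that("normalize_census follows the displayed formula", {
  zero <- normalize_census(setNames(rep(0, 30), sprintf("G%d", 0:29)))
  expect_equal(unname(zero$fstar), rep(log10(1 + 1 / 30), 30),
               tolerance = 1e-12)
  expect_equal(unname(zero$fstar[1]), 0.0142405, tolerance = 1e-4)

  k3 <- census_exact(as_mcn_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3))))
  f <- normalize_census(k3)$fstar
  expect_equal(unname(f["G0"]), log10(1 + 4 / 34), tolerance = 1e-12)
  expect_equal(unname(f["G0"]), 0.048305, tolerance = 1e-4)
  expect_equal(unname(f["G2"]), 0.024824, tolerance = 1e-4)
  expect_equal(unname(f["G1"]), log10(1 + 1 / 34), tolerance = 1e-12)
  expect_true(all(f > 0))

  # strict monotonicity in the count at a fixed denominator convention
  a <- rep(2, 30); b <- a; b[5] <- 3
  expect_gt(normalize_census(b)$fstar[5], normalize_census(a)$fstar[5])

  # prose variant is negative everywhere
  prose <- normalize_census(k3, formula = "prose")
  expect_true(all(prose$fstar < 0))
  expect_error(normalize_census(rep(-1, 30)), "non-negative")
  expect_error(normalize_census(rep(0, 29)), "30")
})
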