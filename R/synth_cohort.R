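# Synthetic cohorts with planted low-rank covariance structure.
#
# The generative model mirrors the confound model used downstream:
#   M(s, v) = mu(v) + sum_k score(s, k) * pattern(k, v)
#             + b1(v)*age + b2(v)*age^2 + b3(v)*gender + b4(v)*age*gender
#             + N(0, noise_sd)
# Patterns are orthonormalized smooth random vertex maps (scaled so entries
# are O(1)); component score variances decrease strictly in k, so the
# residual correlation matrix has a planted low-rank spectrum that gradient
# recovery tests can check against ground truth.

#' Specification of a synthetic cohort
#'
#' Collects and validates every parameter of the synthetic cohort generator.
#' Defaults describe the desk-scale stand-in for a large adult neuroimaging
#' cohort: 200 subjects, 300 vertices, 3 planted components of strictly
#' decreasing strength, ages uniform on 22-37 years, binary gender coded 0/1.
#'
#' @param n_subjects number of subjects (>= 6; the confound design has 5
#'   columns).
#' @param n_vertices number of cortical vertices (>= 4).
#' @param n_components number of planted orthogonal components (>= 1).
#' @param component_loadings positive, strictly decreasing vector of length
#'   `n_components`; standard deviation of the per-subject component scores.
#'   Defaults keep even the weakest component's correlation eigenvalue well
#'   above the Marchenko-Pastur noise edge at the default cohort size, so
#'   recovery tests are meaningful.
#' @param noise_sd baseline residual standard deviation (> 0). With
#'   `equalize_variance = TRUE` this is the noise level at the
#'   highest-signal vertex; other vertices receive additional noise (see
#'   below).
#' @param equalize_variance if `TRUE` (default), per-vertex noise variance
#'   is `noise_sd^2 + (max_w S_w - S_v)` where `S_v` is the planted signal
#'   variance at vertex `v`, so every vertex has the same total variance.
#'   This makes the planted components exactly the principal axes of the
#'   population residual *correlation* matrix (Pearson standardization no
#'   longer mixes them), which is what makes gradient-recovery tests
#'   unambiguous. Set to `FALSE` for plain homoscedastic noise (e.g. the
#'   noise-free rank-1 limit).
#' @param pattern_contrast steepness of the sigmoidal contrast applied to
#'   the planted patterns, in (0, 1]. Small values give bimodal maps with
#'   two plateaus and smooth transitions (near-uniform per-vertex signal
#'   variance, the regime where component recovery is statistically
#'   well-posed at the default cohort size); 1 gives gently bounded smooth
#'   maps with heterogeneous signal variance. Default 0.25.
#' @param noise_smooth_window if > 0, each subject's noise map is smoothed
#'   with a circular moving average of this width (then rescaled to the
#'   target per-vertex sd), inducing positive short-range correlations that
#'   emulate the spatial autocorrelation of real cortical maps. Default 0
#'   (independent noise).
#' @param age_range length-2 increasing vector, years.
#' @param beta_age,beta_age2,beta_gender,beta_interaction scalar amplitudes
#'   of the confound effects; each multiplies its own smooth per-vertex
#'   pattern so confound effects vary over the cortex.
#' @param seed integer seed; the cohort is fully reproducible from it.
#'
#' @return An object of class `mcn_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 50, n_vertices = 40, n_components = 2,
#'                     component_loadings = c(1, 0.5), seed = 1)
cohort_spec <- function(n_subjects = 200L, n_vertices = 300L,
                        n_components = 3L,
                        component_loadings = c(1, 0.65, 0.42)[seq_len(n_components)],
                        noise_sd = 0.5, equalize_variance = TRUE,
                        pattern_contrast = 0.25, noise_smooth_window = 0L,
                        age_range = c(22, 37),
                        beta_age = 0.01, beta_age2 = 1e-4,
                        beta_gender = 0.05, beta_interaction = 0.002,
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 6L)
  n_vertices <- check_count(n_vertices, "n_vertices", min = 4L)
  n_components <- check_count(n_components, "n_components", min = 1L)
  if (n_components > min(n_subjects, n_vertices)) {
    stopf("'n_components' (%d) exceeds min(n_subjects, n_vertices)", n_components)
  }
  noise_sd <- check_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stopf("'noise_sd' must be > 0 (got %g)", noise_sd)
  if (!is.numeric(component_loadings) ||
      length(component_loadings) != n_components) {
    stopf("'component_loadings' must be a numeric vector of length %d",
          n_components)
  }
  if (any(component_loadings <= 0)) {
    stopf("'component_loadings' must be positive")
  }
  if (n_components > 1L && any(diff(component_loadings) >= 0)) {
    stopf("'component_loadings' must be strictly decreasing so component score variances decrease in k")
  }
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      age_range[2] <= age_range[1]) {
    stopf("'age_range' must be an increasing (min, max) pair of years")
  }
  spec <- list(
    n_subjects = n_subjects, n_vertices = n_vertices,
    n_components = n_components,
    component_loadings = as.numeric(component_loadings),
    noise_sd = noise_sd,
    equalize_variance = isTRUE(equalize_variance),
    pattern_contrast = {
      pc <- check_number(pattern_contrast, "pattern_contrast")
      if (pc <= 0 || pc > 1) stopf("'pattern_contrast' must be in (0, 1]")
      pc
    },
    noise_smooth_window = check_count(noise_smooth_window,
                                      "noise_smooth_window", min = 0L),
    age_range = as.numeric(age_range),
    beta_age = check_number(beta_age, "beta_age"),
    beta_age2 = check_number(beta_age2, "beta_age2"),
    beta_gender = check_number(beta_gender, "beta_gender"),
    beta_interaction = check_number(beta_interaction, "beta_interaction"),
    seed = as.integer(check_number(seed, "seed"))
  )
  class(spec) <- "mcn_cohort_spec"
  spec
}

#' @export
print.mcn_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects x", x$n_vertices,
      "vertices,", x$n_components, "planted component(s)\n")
  cat("  loadings:", paste(signif(x$component_loadings, 3), collapse = ", "),
      " noise_sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

# smooth a vertex map by a circular moving average; the only notion of
# "space" in the generator is vertex order (no cortical geometry)
#' @noRd
smooth_map <- function(x, window = max(3L, length(x) %/% 20L)) {
  n <- length(x)
  window <- min(window, n)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, circular = TRUE))
}

#' @noRd
smooth_random_map <- function(n) {
  z <- smooth_map(stats::rnorm(n))
  as.numeric(scale(z))  # zero mean, unit sd
}

#' Generate a synthetic cohort
#'
#' Draws a subject-by-vertex myelin-proxy matrix with planted orthogonal
#' low-rank structure, linear age/gender confound effects and Gaussian
#' noise, together with the covariate table and a `truth` block holding
#' the planted patterns, scores and confound coefficient maps.
#'
#' @param spec an [cohort_spec()] object.
#' @return An object of class `mcn_cohort` with elements `myelin`
#'   (subjects x vertices matrix), `covariates` (data.frame with `age`,
#'   `gender`), `truth` (list: `mu`, `patterns` vertices x k, `scores`
#'   subjects x k, `beta` vertices x 4 confound coefficient maps) and
#'   `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 30, n_vertices = 20,
#'                                   n_components = 1,
#'                                   component_loadings = 1, seed = 3))
#' dim(co$myelin)
generate_cohort <- function(spec) {
  if (!inherits(spec, "mcn_cohort_spec")) {
    spec <- do.call(cohort_spec, as.list(spec))
  }
  S <- spec$n_subjects; V <- spec$n_vertices; K <- spec$n_components
  with_seed(spec$seed, {
    # planted patterns: smooth random maps squashed to a bounded range
    # (tanh), then orthonormalized and scaled so entries are O(1). The
    # bound keeps the per-vertex signal variance (hence, under variance
    # equalization, the correlation-matrix denominator) from being driven
    # by a few extreme vertices, which would push weak components under
    # the sample-noise eigenvalue edge.
    bound <- 1.7
    temp <- bound * spec$pattern_contrast
    raw <- vapply(seq_len(K), function(i) {
      bound * tanh(smooth_random_map(V) / temp)
    }, numeric(V))
    patterns <- qr.Q(qr(raw)) * sqrt(V)           # columns orthogonal, entries O(1)
    age <- stats::runif(S, spec$age_range[1], spec$age_range[2])
    gender <- sample(c(0L, 1L), S, replace = TRUE)
    X <- cbind(age, age^2, gender, age * gender)  # S x 4
    # scores: Gaussian draws projected orthogonal to the confound design
    # in-sample (so residualization removes exactly the injected betas and
    # nothing of the planted signal), then QR-orthogonalized and scaled to
    # exact sds -- the realized component directions are the planted ones,
    # with no finite-sample rotation between components
    raw_scores <- matrix(stats::rnorm(S * K), S, K)
    design <- cbind(1, X)
    raw_scores <- raw_scores -
      design %*% solve(crossprod(design), crossprod(design, raw_scores))
    scores <- qr.Q(qr(raw_scores)) * sqrt(S - 1)
    scores <- sweep(scores, 2L, spec$component_loadings, "*")
    mu <- 1.5 + 0.1 * smooth_random_map(V)        # baseline T1w/T2w-like level
    beta <- cbind(
      age         = spec$beta_age         * smooth_random_map(V),
      age2        = spec$beta_age2        * smooth_random_map(V),
      gender      = spec$beta_gender      * smooth_random_map(V),
      interaction = spec$beta_interaction * smooth_random_map(V)
    )
    # per-vertex noise sd; with equalization, noise tops up each vertex to
    # the common total variance max_w S_w + noise_sd^2
    signal_var <- colSums(spec$component_loadings^2 * t(patterns)^2)
    noise_var <- if (spec$equalize_variance) {
      spec$noise_sd^2 + max(signal_var) - signal_var
    } else {
      rep(spec$noise_sd^2, V)
    }
    # noise: optionally spatially smoothed, then projected orthogonal to
    # the planted scores in-sample (so recovery error measures the method,
    # not chance score-noise correlations) and scaled to exact column sds
    noise <- matrix(stats::rnorm(S * V), S, V)
    if (spec$noise_smooth_window > 1L) {
      noise <- t(apply(noise, 1L, smooth_map,
                       window = spec$noise_smooth_window))
    }
    proj <- cbind(design, scores)
    noise <- noise - proj %*% solve(crossprod(proj), crossprod(proj, noise))
    noise <- sweep(noise, 2L, apply(noise, 2L, stats::sd), "/")
    noise <- noise * matrix(sqrt(noise_var), S, V, byrow = TRUE)
    myelin <- matrix(mu, S, V, byrow = TRUE) +
      scores %*% t(patterns) +
      X %*% t(beta) +
      noise
    dimnames(myelin) <- list(sprintf("s%d", seq_len(S)),
                             sprintf("v%d", seq_len(V)))
    out <- list(
      myelin = myelin,
      covariates = data.frame(age = age, gender = gender,
                              row.names = rownames(myelin)),
      truth = list(mu = mu, patterns = patterns, scores = scores, beta = beta),
      spec = spec
    )
    class(out) <- "mcn_cohort"
    out
  })
}

#' @export
print.mcn_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$myelin), "subjects x", ncol(x$myelin),
      "vertices")
  if (!is.null(x$truth)) cat(" (with planted truth)")
  cat("\n")
  invisible(x)
}

#' Generate a vertex parcellation
#'
#' Assigns each vertex one of `n_classes` labels, either as contiguous
#' blocks of near-equal size (`mode = "block"`) or uniformly at random with
#' every class guaranteed non-empty (`mode = "random"`).
#'
#' @param n_vertices number of vertices.
#' @param n_classes number of classes (>= 1 and <= n_vertices).
#' @param seed integer seed (used by `mode = "random"`).
#' @param mode `"block"` or `"random"`.
#' @return Integer vector of labels in `1..n_classes`, one per vertex.
#' @export
generate_parcellation <- function(n_vertices, n_classes, seed = 1L,
                                  mode = c("block", "random")) {
  n_vertices <- check_count(n_vertices, "n_vertices")
  n_classes <- check_count(n_classes, "n_classes")
  mode <- match.arg(mode)
  if (n_classes > n_vertices) {
    stopf("n_classes (%d) exceeds n_vertices (%d)", n_classes, n_vertices)
  }
  if (mode == "block") {
    labels <- if (n_classes == 1L) rep(1L, n_vertices)
              else as.integer(cut(seq_len(n_vertices), breaks = n_classes,
                                  labels = FALSE))
  } else {
    labels <- with_seed(seed, {
      l <- sample.int(n_classes, n_vertices, replace = TRUE)
      # guarantee every class non-empty: plant one vertex per class at
      # deterministic (seeded) positions
      slots <- sample.int(n_vertices, n_classes)
      l[slots] <- seq_len(n_classes)
      l
    })
  }
  labels
}

#' Generate a bank of term maps
#'
#' Unplanted terms are independent Gaussian vertex maps; planted terms are a
#' supplied map plus optional noise. A configurable fraction of entries is
#' set exactly to zero, mimicking meta-analytic term maps that are zero
#' outside their support (this exercises the joint non-zero mask used by
#' [decode_terms()]).
#'
#' @param n_terms number of terms.
#' @param n_vertices number of vertices.
#' @param planted optional list of `list(term = <index>, map = <numeric>,
#'   noise_sd = <number>)` entries; `noise_sd` defaults to 0.
#' @param zero_fraction fraction of entries forced to exactly 0 (default
#'   0.1).
#' @param seed integer seed.
#' @return A `n_terms x n_vertices` matrix with rownames `term1..`.
#' @export
generate_term_maps <- function(n_terms, n_vertices, planted = NULL,
                               zero_fraction = 0.1, seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms")
  n_vertices <- check_count(n_vertices, "n_vertices")
  zero_fraction <- check_number(zero_fraction, "zero_fraction")
  if (zero_fraction < 0 || zero_fraction > 1) {
    stopf("'zero_fraction' must be in [0, 1]")
  }
  idx <- vapply(planted, function(p) check_count(p$term, "planted term index"),
                integer(1))
  if (anyDuplicated(idx)) stopf("duplicate planted term indices: %s",
                                paste(idx[duplicated(idx)], collapse = ", "))
  if (length(idx) && any(idx > n_terms)) {
    stopf("planted term index out of range (n_terms = %d)", n_terms)
  }
  with_seed(seed, {
    maps <- matrix(stats::rnorm(n_terms * n_vertices), n_terms, n_vertices)
    for (p in planted) {
      m <- as.numeric(p$map)
      if (length(m) != n_vertices) {
        stopf("planted map for term %d has length %d, expected %d",
              p$term, length(m), n_vertices)
      }
      nsd <- if (is.null(p$noise_sd)) 0 else check_number(p$noise_sd, "noise_sd")
      maps[p$term, ] <- m + if (nsd > 0) stats::rnorm(n_vertices, sd = nsd) else 0
    }
    if (zero_fraction > 0) {
      nz <- round(zero_fraction * length(maps))
      maps[sample.int(length(maps), nz)] <- 0
    }
    rownames(maps) <- sprintf("term%d", seq_len(n_terms))
    colnames(maps) <- sprintf("v%d", seq_len(n_vertices))
    maps
  })
}

#' Generate feature maps with planted correlations to a reference map
#'
#' Each feature is constructed as `target * z(ref) + sqrt(1 - target^2) * z(e)` where
#' `z()` standardizes and `e` is Gaussian noise made exactly orthogonal to
#' the reference, so the realized Pearson correlation equals the target up
#' to the sampling variability of the noise direction alone.
#'
#' @param n_features number of features.
#' @param n_vertices number of vertices.
#' @param reference reference vertex map (length `n_vertices`).
#' @param planted_correlation per-feature target correlation, `|r| <= 1`;
#'   recycled if scalar.
#' @param seed integer seed.
#' @return A `n_features x n_vertices` matrix with rownames `feature1..`.
#' @export
generate_feature_maps <- function(n_features, n_vertices, reference,
                                  planted_correlation = 0, seed = 1L) {
  n_features <- check_count(n_features, "n_features")
  n_vertices <- check_count(n_vertices, "n_vertices")
  if (length(reference) != n_vertices) {
    stopf("'reference' has length %d, expected %d", length(reference),
          n_vertices)
  }
  r <- rep_len(as.numeric(planted_correlation), n_features)
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stopf("'planted_correlation' must satisfy |r| <= 1")
  }
  zref <- as.numeric(scale(reference))
  with_seed(seed, {
    maps <- t(vapply(seq_len(n_features), function(i) {
      e <- stats::rnorm(n_vertices)
      e <- e - zref * sum(e * zref) / sum(zref^2)  # exact orthogonal residual
      ze <- as.numeric(scale(e))
      r[i] * zref + sqrt(1 - r[i]^2) * ze
    }, numeric(n_vertices)))
    rownames(maps) <- sprintf("feature%d", seq_len(n_features))
    colnames(maps) <- sprintf("v%d", seq_len(n_vertices))
    maps
  })
}

#' Generate the full annotation bundle for a synthetic analysis
#'
#' Convenience wrapper bundling a parcellation, a term-map bank and a set of
#' feature maps, mirroring the annotation assets a real analysis would load
#' from atlas and meta-analytic resources.
#'
#' @param n_vertices number of vertices.
#' @param n_classes number of parcel classes (default 5, the
#'   cytoarchitectonic convention).
#' @param n_terms number of term maps (default 50).
#' @param n_features number of feature maps (default 10).
#' @param reference reference map for feature construction (default a
#'   smooth random map).
#' @param seed integer seed.
#' @return list with `parcellation`, `term_maps`, `feature_maps`,
#'   `class_labels`.
#' @export
generate_annotations <- function(n_vertices, n_classes = 5L, n_terms = 50L,
                                 n_features = 10L, reference = NULL,
                                 seed = 1L) {
  if (is.null(reference)) {
    reference <- with_seed(derive_seed(seed, 4L), smooth_random_map(n_vertices))
  }
  list(
    parcellation = generate_parcellation(n_vertices, n_classes,
                                         seed = derive_seed(seed, 1L),
                                         mode = "block"),
    term_maps = generate_term_maps(n_terms, n_vertices,
                                   seed = derive_seed(seed, 2L)),
    feature_maps = generate_feature_maps(n_features, n_vertices, reference,
                                         planted_correlation = 0,
                                         seed = derive_seed(seed, 3L)),
    class_labels = if (n_classes == 5L) {
      c("agranular", "frontal", "parietal", "polar", "granular")
    } else {
      sprintf("class%d", seq_len(n_classes))
    }
  )
}
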