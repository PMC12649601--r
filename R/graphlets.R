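# Thresholded binary networks and the graphlet census (exact and sampled),
# plus the log-normalization of class frequencies.

#' Threshold a covariance network into a binary graph
#'
#' For a negative cutoff `t < 0`, keeps edges with correlation `rho <= t`;
#' for a positive cutoff `t > 0`, keeps edges with `rho >= t`. `t = 0` is an
#' error (the rule is undefined there). Isolated nodes are retained in the
#' node count. The conventional cutoffs are -0.4, -0.2, 0.2 and 0.4.
#'
#' @param network an `mcn_covnet` or square correlation matrix.
#' @param t signed cutoff, `0 < |t| <= 1`.
#' @return An object of class `mcn_graph`: `n_nodes`, `edges` (2-column
#'   matrix, i < j), `threshold`, `rule`.
#' @export
threshold_graph <- function(network, t) {
  rho <- as_rho(network)
  t <- check_number(t, "t")
  if (t == 0) stopf("t = 0 is not a valid threshold: the edge rule is undefined at zero")
  if (abs(t) > 1) stopf("|t| must be <= 1 (got %g)", t)
  keep <- if (t < 0) rho <= t else rho >= t
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- unname(cbind(as.integer(idx[, 1]), as.integer(idx[, 2])))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  out <- list(n_nodes = ncol(rho),
              edges = edges,
              threshold = t,
              rule = if (t < 0) sprintf("rho <= %g", t) else sprintf("rho >= %g", t))
  class(out) <- "mcn_graph"
  out
}

#' Construct an `mcn_graph` from an explicit edge list
#'
#' @param n_nodes number of nodes.
#' @param edges 2-column matrix or data.frame of node pairs (1-based); self
#'   loops and duplicate (unordered) pairs are errors.
#' @return An `mcn_graph`.
#' @export
as_mcn_graph <- function(n_nodes, edges) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), 0, 2)
  }
  if (ncol(edges) != 2L) stopf("'edges' must have 2 columns")
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes)) stopf("edge endpoints out of range")
    if (any(edges[, 1] == edges[, 2])) stopf("self-loops are not allowed")
    e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(paste(e[, 1], e[, 2]))) stopf("duplicate edges are not allowed")
    edges <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  out <- list(n_nodes = n_nodes, edges = edges, threshold = NA_real_,
              rule = "explicit edge list")
  class(out) <- "mcn_graph"
  out
}

#' @export
print.mcn_graph <- function(x, ...) {
  cat("Binary graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges (",
      x$rule, ")\n")
  invisible(x)
}

#' @noRd
check_graph <- function(graph) {
  if (!inherits(graph, "mcn_graph")) stopf("'graph' must be an mcn_graph")
  graph
}

#' Exact graphlet census
#'
#' Counts every connected induced subgraph on 2-5 nodes exactly once
#' (Wernicke's ESU enumeration, compiled) and classifies it into its
#' catalog class by full-permutation canonical form lookup.
#'
#' @param graph an `mcn_graph`.
#' @param catalog the graphlet catalog (defaults to [build_catalog()]).
#' @param max_subgraphs guardrail: abort if more than this many connected
#'   subgraphs would be enumerated (default 5e7); use [census_sampled()]
#'   beyond desk scale.
#' @return An object of class `mcn_census`: `counts` (named G0-G29,
#'   non-negative integers stored as doubles), `method = "exact"`.
#' @export
#' @examples
#' k3 <- as_mcn_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' census_exact(k3)$counts[c("G0", "G2")] # 3, 1
census_exact <- function(graph, catalog = build_catalog(),
                         max_subgraphs = 5e7) {
  graph <- check_graph(graph)
  if (!inherits(catalog, "mcn_graphlet_catalog")) stopf("invalid catalog")
  lookups <- lapply(2:5, mask_lookup)
  counts <- .esu_census_cpp(graph$n_nodes,
                            graph$edges - 1L,  # 0-based for C++
                            lookups, as.numeric(max_subgraphs))
  names(counts) <- names(catalog)
  out <- list(counts = counts, method = "exact", n_nodes = graph$n_nodes,
              n_edges = nrow(graph$edges))
  class(out) <- "mcn_census"
  out
}

#' Sampled graphlet census
#'
#' Unbiased estimator of the induced-subgraph class counts by randomized
#' subgraph sampling with inclusion-probability reweighting: each draw
#' picks a uniform random edge and completes the node set with uniform
#' distinct non-endpoints, so a k-node subset S containing e(S) edges is
#' drawn with probability `e(S) / (m * choose(n-2, k-2))`. A hit on class c
#' (with known edge count e_c) therefore contributes
#' `m * choose(n-2, k-2) / e_c` to the estimate. Every connected class has
#' at least one edge, so the estimator is unbiased for all 30 classes;
#' per-class standard errors come from the i.i.d. contribution variance.
#'
#' This is a clean-room lift-and-reweight design with documented inclusion
#' probabilities, not a reimplementation of any particular published
#' sampler; its contract is unbiasedness against [census_exact()].
#'
#' @param graph an `mcn_graph` with at least one edge (an edgeless graph
#'   yields all-zero estimates with a warning).
#' @param catalog the graphlet catalog.
#' @param n_samples number of draws per subgraph size (>= 1).
#' @param seed integer seed.
#' @return An `mcn_census` with `counts` (estimates), `se` (per-class
#'   standard errors), `method = "sampled"`, `n_samples`, `seed`.
#' @export
census_sampled <- function(graph, catalog = build_catalog(),
                           n_samples = 10000L, seed = 1L) {
  graph <- check_graph(graph)
  n_samples <- check_count(n_samples, "n_samples")
  n <- graph$n_nodes
  m <- nrow(graph$edges)
  cat_entries <- unclass(catalog)
  counts <- stats::setNames(numeric(30), names(cat_entries))
  se <- counts
  if (m == 0L) {
    warnf("graph has no edges: all graphlet estimates are 0")
    out <- list(counts = counts, se = se, method = "sampled",
                n_samples = n_samples, seed = as.integer(seed),
                n_nodes = n, n_edges = m)
    class(out) <- "mcn_census"
    return(out)
  }
  adj <- matrix(FALSE, n, n)
  adj[graph$edges] <- TRUE
  adj <- adj | t(adj)
  sizes <- vapply(cat_entries, `[[`, integer(1), "n_nodes")
  e_class <- vapply(cat_entries, `[[`, integer(1), "n_edges")
  with_seed(seed, {
    for (k in 2:5) {
      if (k > n) next
      in_k <- sizes == k
      if (k == 2L) {
        # the anchor edge is the whole subset: the count is m, exactly
        counts[in_k] <- m
        se[in_k] <- 0
        next
      }
      eidx <- sample.int(m, n_samples, replace = TRUE)
      anchors <- graph$edges[eidx, , drop = FALSE]
      extras <- matrix(NA_integer_, n_samples, k - 2L)
      todo <- seq_len(n_samples)
      while (length(todo)) {  # rejection sampling of distinct non-endpoints
        draw <- matrix(sample.int(n, length(todo) * (k - 2L), replace = TRUE),
                       ncol = k - 2L)
        cand <- cbind(anchors[todo, , drop = FALSE], draw)
        ok <- apply(cand, 1L, anyDuplicated) == 0L
        extras[todo[ok], ] <- draw[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
      subsets <- cbind(anchors, extras)
      # labeled edge bitmask per sample over combn(k, 2) position pairs
      pr <- utils::combn(k, 2)
      mask <- integer(n_samples)
      for (b in seq_len(ncol(pr))) {
        hit <- adj[cbind(subsets[, pr[1, b]], subsets[, pr[2, b]])]
        mask <- mask + bitwShiftL(as.integer(hit), b - 1L)
      }
      cls <- mask_lookup(k)[mask + 1L]          # 0-based G id or NA
      weight <- m * choose(n - 2, k - 2)
      for (g in which(in_k)) {
        hits <- sum(!is.na(cls) & cls == (g - 1L))
        w <- weight / e_class[g]
        phat <- hits / n_samples
        counts[g] <- w * phat
        se[g] <- w * sqrt(phat * (1 - phat) / n_samples)
      }
    }
  })
  out <- list(counts = counts, se = se, method = "sampled",
              n_samples = n_samples, seed = as.integer(seed),
              n_nodes = n, n_edges = m)
  class(out) <- "mcn_census"
  out
}

#' @export
print.mcn_census <- function(x, ...) {
  cat("Graphlet census (", x$method, "): ", x$n_nodes, " nodes, ",
      x$n_edges, " edges\n", sep = "")
  top <- sort(x$counts, decreasing = TRUE)
  top <- top[top > 0]
  cat("  top classes:",
      paste(sprintf("%s=%.5g", names(head(top, 6L)), head(top, 6L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a graphlet census
#'
#' The default (`formula = "displayed"`) follows the displayed
#' add-one-inside-the-log convention
#' `f*_Gi = log10(1 + (f_Gi + 1) / sum_j (f_Gj + 1))`,
#' which is strictly positive and strictly increasing in the count at fixed
#' denominator. `formula = "prose"` computes the plain
#' `log10((f_Gi + 1) / sum_j (f_Gj + 1))`, which is negative for every
#' class; see the methods vignette for why the displayed form is the
#' default.
#'
#' @param census an `mcn_census` (or a named length-30 count vector).
#' @param formula `"displayed"` (default) or `"prose"`.
#' @return An object of class `mcn_norm_census`: `fstar` (named length-30)
#'   and `formula`.
#' @export
normalize_census <- function(census, formula = c("displayed", "prose")) {
  formula <- match.arg(formula)
  f <- if (inherits(census, "mcn_census")) census$counts else as.numeric(census)
  if (length(f) != 30L) stopf("expected 30 graphlet counts, got %d", length(f))
  if (anyNA(f) || any(f < 0)) stopf("graphlet counts must be non-negative")
  denom <- sum(f + 1)
  fstar <- switch(formula,
                  displayed = log10(1 + (f + 1) / denom),
                  prose = log10((f + 1) / denom))
  names(fstar) <- names(f) %||% sprintf("G%d", 0:29)
  out <- list(fstar = fstar, formula = formula)
  class(out) <- "mcn_norm_census"
  out
}

#' @export
print.mcn_norm_census <- function(x, ...) {
  cat("Normalized graphlet frequencies (", x$formula, " formula)\n", sep = "")
  top <- sort(x$fstar, decreasing = TRUE)
  cat("  top classes:",
      paste(sprintf("%s=%.4f", names(head(top, 6L)), head(top, 6L)),
            collapse = ", "), "\n")
  invisible(x)
}
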