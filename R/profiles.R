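# Class profiles over a parcellation, term-map decoding, multimodal feature
# correlations, and the multiple-comparison machinery (Bonferroni flagging,
# Holm step-down adjustment).

#' Per-class means of a vertex map
#'
#' Unweighted mean of the map within each parcel class. Class means treat
#' every class as its own unit regardless of size; dispersion across classes
#' is computed separately by [profile_dispersion()].
#'
#' @param map numeric vertex map.
#' @param parcellation per-vertex class labels (integer or factor), same
#'   length as `map`; every class must be non-empty.
#' @param class_labels optional class names (defaults to the label values).
#' @return An object of class `mcn_class_profile` with `class_means` (named)
#'   and `n_per_class`.
#' @export
class_means <- function(map, parcellation, class_labels = NULL) {
  if (length(map) != length(parcellation)) {
    stopf("map length (%d) does not match parcellation length (%d)",
          length(map), length(parcellation))
  }
  if (anyNA(map) || anyNA(parcellation)) stopf("map/parcellation contain NA")
  f <- if (is.factor(parcellation)) droplevels(parcellation)
       else factor(parcellation)
  # a factor drops empty classes silently; detect gaps in integer labelling
  if (is.numeric(parcellation)) {
    lev <- sort(unique(as.integer(parcellation)))
    missing <- setdiff(seq_len(max(lev)), lev)
    if (length(missing)) {
      stopf("empty class(es): %s", paste(missing, collapse = ", "))
    }
  }
  means <- tapply(map, f, mean)
  if (!is.null(class_labels)) {
    if (length(class_labels) != length(means)) {
      stopf("class_labels length (%d) does not match number of classes (%d)",
            length(class_labels), length(means))
    }
    names(means) <- class_labels
  }
  out <- list(class_means = c(means),
              n_per_class = c(table(f)))
  class(out) <- "mcn_class_profile"
  out
}

#' @export
print.mcn_class_profile <- function(x, ...) {
  cat("Class profile (", length(x$class_means), " classes):\n", sep = "")
  print(round(x$class_means, 4))
  if (length(x$class_means) >= 2L) {
    cat(sprintf("  across-class dispersion (sample sd): %.4f\n",
                profile_dispersion(x)))
  }
  invisible(x)
}

#' Across-class dispersion of class means
#'
#' Sample standard deviation (n - 1 denominator) of the per-class means;
#' classes are the units, so class size does not enter.
#'
#' @param class_means numeric vector of class means, or an
#'   `mcn_class_profile`.
#' @return Single non-negative number.
#' @export
#' @examples
#' profile_dispersion(c(-0.0659, 0.0296, 0.0085, 0.1651, -0.1975)) # 0.1331
profile_dispersion <- function(class_means) {
  if (inherits(class_means, "mcn_class_profile")) {
    class_means <- class_means$class_means
  }
  if (!is.numeric(class_means) || length(class_means) < 2L) {
    stopf("need >= 2 class means to compute a dispersion")
  }
  stats::sd(class_means)
}

#' Decode a vertex map against a bank of term maps
#'
#' For each term, restricts to the vertices where both the input map and
#' that term map are non-zero (the joint non-zero mask) and computes the
#' Pearson correlation there. Terms whose mask holds fewer than 3 vertices
#' are undefined and excluded from the ranking.
#'
#' @param map numeric vertex map.
#' @param term_maps terms x vertices matrix (rownames are term labels).
#' @param top_n optionally keep only the `top_n` rows by `|r|` (the usual
#'   reporting convention is the top 30).
#' @return data.frame (class `mcn_decoding`) with columns `term`, `r`,
#'   `n_used`, `rank`, sorted by `|r|` descending; excluded terms are in
#'   `attr(, "undefined")`.
#' @export
decode_terms <- function(map, term_maps, top_n = NULL) {
  term_maps <- check_matrix(term_maps, "term_maps")
  if (length(map) != ncol(term_maps)) {
    stopf("map length (%d) does not match term map vertices (%d)",
          length(map), ncol(term_maps))
  }
  labels <- rownames(term_maps)
  if (is.null(labels)) labels <- sprintf("term%d", seq_len(nrow(term_maps)))
  map_nz <- map != 0
  res <- lapply(seq_len(nrow(term_maps)), function(i) {
    tm <- term_maps[i, ]
    mask <- map_nz & tm != 0
    n <- sum(mask)
    if (n < 3L) return(list(r = NA_real_, n = n))
    x <- map[mask]; y <- tm[mask]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(r = NA_real_, n = n))
    list(r = stats::cor(x, y), n = n)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  n_used <- vapply(res, `[[`, numeric(1), "n")
  undefined <- labels[is.na(r)]
  keep <- which(!is.na(r))
  if (!length(keep)) {
    stopf("empty joint non-zero mask: no term has >= 3 jointly non-zero vertices")
  }
  ord <- keep[order(-abs(r[keep]))]
  out <- data.frame(term = labels[ord], r = r[ord], n_used = n_used[ord],
                    rank = seq_along(ord), row.names = NULL)
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), ]
  attr(out, "undefined") <- undefined
  class(out) <- c("mcn_decoding", class(out))
  out
}

#' Correlate vertex maps with multimodal feature maps
#'
#' Pearson correlation and exact-t two-sided p-value for every (map,
#' feature) pair, flagged non-significant iff `p > alpha / m` (Bonferroni).
#' Vertices are treated as independent: no spatial-autocorrelation
#' correction is applied, matching the convention of the analyses this
#' reproduces.
#'
#' @param maps named list of vertex maps, or a vertices x maps matrix.
#' @param features features x vertices matrix (rownames are feature labels).
#' @param alpha significance level (default 0.05).
#' @param m correction family size; defaults to `n_maps * n_features`
#'   (30 in the conventional 3-maps-by-10-features design).
#' @return data.frame (class `mcn_corr_report`) with `map`, `feature`, `r`,
#'   `p`, `significant`, `code` (`"ok"` or `"constant"`); attributes
#'   `alpha`, `m`, `method = "bonferroni"`.
#' @export
correlate_features <- function(maps, features, alpha = 0.05, m = NULL) {
  if (is.matrix(maps)) {
    ml <- lapply(seq_len(ncol(maps)), function(j) maps[, j])
    names(ml) <- colnames(maps) %||% sprintf("map%d", seq_along(ml))
    maps <- ml
  }
  if (is.numeric(maps)) maps <- list(map1 = maps)
  features <- check_matrix(features, "features")
  flabels <- rownames(features) %||% sprintf("feature%d", seq_len(nrow(features)))
  nv <- ncol(features)
  bad_len <- vapply(maps, length, integer(1)) != nv
  if (any(bad_len)) {
    stopf("map(s) %s do not have %d vertices",
          paste(names(maps)[bad_len], collapse = ", "), nv)
  }
  if (is.null(m)) m <- length(maps) * nrow(features)
  m <- check_count(m, "m", min = 1L)
  alpha <- check_number(alpha, "alpha")
  rows <- list()
  for (mi in seq_along(maps)) {
    x <- as.numeric(maps[[mi]])
    for (fi in seq_len(nrow(features))) {
      y <- features[fi, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          map = names(maps)[mi], feature = flabels[fi], r = NA_real_,
          p = NA_real_, significant = FALSE, code = "constant")
        next
      }
      r <- stats::cor(x, y)
      p <- cor_pvalue(r, nv)
      rows[[length(rows) + 1L]] <- data.frame(
        map = names(maps)[mi], feature = flabels[fi], r = r, p = p,
        significant = !is.na(p) && p <= alpha / m, code = "ok")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "method") <- "bonferroni"
  class(out) <- c("mcn_corr_report", class(out))
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm step-down adjustment of p-values
#'
#' Step-down Holm adjustment with monotonicity enforcement; the output is in
#' the input order. Equivalent to `stats::p.adjust(p, "holm")`, implemented
#' directly so the procedure under test is explicit.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
holm_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stopf("p-values must be in [0, 1] with no NA")
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1L) * p[o])
  adj <- cummax(adj)            # enforce monotone non-decreasing in rank
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Correlation matrix between gradients and strength maps
#'
#' Pearson correlations across vertices between each gradient score column
#' and each signed strength map, with Holm-adjusted p-values over the full
#' k x 3 family (9 for the conventional three gradients).
#'
#' @param gradients an `mcn_gradients` (or vertices x k score matrix).
#' @param strengths an `mcn_strength` object (or list with `negative`,
#'   `positive`, `full`).
#' @param alpha significance level (default 0.05).
#' @return data.frame (class `mcn_corr_report`) with `map` (gradient),
#'   `feature` (strength map), `r`, `p`, `p_adj`, `significant`; attribute
#'   `method = "holm"`.
#' @export
gradient_strength_matrix <- function(gradients, strengths, alpha = 0.05) {
  sc <- if (inherits(gradients, "mcn_gradients")) gradients$scores
        else check_matrix(gradients, "gradients")
  sm <- cbind(negative = strengths$negative, positive = strengths$positive,
              full = strengths$full)
  if (nrow(sm) != nrow(sc)) {
    stopf("gradients (%d vertices) and strengths (%d vertices) differ",
          nrow(sc), nrow(sm))
  }
  nv <- nrow(sc)
  grid <- expand.grid(map = colnames(sc) %||% sprintf("G%d", seq_len(ncol(sc))),
                      feature = colnames(sm), stringsAsFactors = FALSE)
  r <- mapply(function(g, s) {
    x <- sc[, g]; y <- sm[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, match(grid$map, colnames(sc)), match(grid$feature, colnames(sm)))
  p <- cor_pvalue(r, nv)
  if (anyNA(p)) stopf("constant gradient or strength map: correlation undefined")
  p_adj <- holm_adjust(p)
  out <- data.frame(grid, r = r, p = p, p_adj = p_adj,
                    significant = p_adj <= alpha)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- nrow(out)
  attr(out, "method") <- "holm"
  class(out) <- c("mcn_corr_report", class(out))
  out
}
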