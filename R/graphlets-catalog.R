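# The 30-class graphlet catalog (G0-G29): all isomorphism classes of
# connected simple undirected graphs on 2-5 nodes, in Przulj order.
#
# Machinery: a k-node graph is encoded as an integer bitmask over the
# C(k,2) vertex pairs in combn(k, 2) column order. The canonical form of a
# mask is the minimum mask over all k! vertex relabelings (full
# permutation canonicalization: degree-sequence shortcuts are never used as
# a final classifier, since non-isomorphic 5-node graphs with identical
# degree sequences exist, e.g. the 4-cycle-with-pendant and the
# triangle-with-2-path-tail). The catalog itself is *derived* by exhaustive
# enumeration with canonical collapse; the shipped table below only fixes
# the published order of the resulting classes.

#' @noRd
all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  out
}

# pair (i, j), i < j, -> bit index (0-based) in combn(k, 2) column order
#' @noRd
pair_bit <- function(k) {
  pr <- utils::combn(k, 2)
  idx <- matrix(NA_integer_, k, k)
  for (b in seq_len(ncol(pr))) {
    idx[pr[1, b], pr[2, b]] <- b - 1L
    idx[pr[2, b], pr[1, b]] <- b - 1L
  }
  idx
}

# permutation machinery for size k, cached: `weights` is a n_perms x n_bits
# matrix with weights[p, b] = 2^(bit index of the image of pair b under
# permutation p); the permuted mask is weights %*% bits
#' @noRd
perm_weights <- function(k) {
  key <- sprintf("perm_weights_%d", k)
  if (!is.null(.mcn_cache[[key]])) return(.mcn_cache[[key]])
  pr <- utils::combn(k, 2)
  pb <- pair_bit(k)
  perms <- all_perms(k)
  W <- matrix(0, nrow(perms), ncol(pr))
  for (p in seq_len(nrow(perms))) {
    for (b in seq_len(ncol(pr))) {
      W[p, b] <- 2^pb[perms[p, pr[1, b]], perms[p, pr[2, b]]]
    }
  }
  .mcn_cache[[key]] <- W
  W
}

#' @noRd
mask_bits <- function(mask, n_bits) {
  as.numeric(bitwAnd(mask, bitwShiftL(1L, 0:(n_bits - 1L))) > 0L)
}

#' @noRd
canon_mask <- function(mask, k) {
  n_bits <- (k * (k - 1L)) %/% 2L
  W <- perm_weights(k)
  min(as.numeric(W %*% mask_bits(mask, n_bits)))
}

#' @noRd
mask_connected <- function(mask, k) {
  pr <- utils::combn(k, 2)
  bits <- mask_bits(mask, ncol(pr)) > 0
  adj <- matrix(FALSE, k, k)
  adj[cbind(pr[1, bits], pr[2, bits])] <- TRUE
  adj <- adj | t(adj)
  seen <- rep(FALSE, k); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Enumerate connected graph isomorphism classes by brute force
#'
#' Enumerates every labeled simple undirected graph on `k` nodes for each
#' requested size, keeps the connected ones, and collapses them by graph
#' isomorphism via canonical labeling over all `k!` node permutations.
#'
#' @param sizes node counts to enumerate (default 2:5).
#' @return A list with `per_size` (named integer vector: classes per size),
#'   `total` (number of classes), and `canonical` (list of sorted canonical
#'   masks per size).
#' @export
#' @examples
#' enumerate_connected_classes(2:4)$total # 9
enumerate_connected_classes <- function(sizes = 2:5) {
  sizes <- vapply(sizes, check_count, integer(1), name = "sizes")
  if (any(sizes < 2L) || any(sizes > 5L)) stopf("sizes must be within 2..5")
  canonical <- lapply(sizes, function(k) {
    n_bits <- (k * (k - 1L)) %/% 2L
    masks <- seq_len(2^n_bits - 1L)
    conn <- masks[vapply(masks, mask_connected, logical(1), k = k)]
    sort(unique(vapply(conn, canon_mask, numeric(1), k = k)))
  })
  names(canonical) <- as.character(sizes)
  per_size <- vapply(canonical, length, integer(1))
  list(per_size = per_size, total = sum(per_size), canonical = canonical)
}

# The shipped Przulj-order table: explicit edge lists, nodes 1-based.
# Within each node count the order is the published one; the classes the
# source text pins by name (G0 edge, G1 path, G2 triangle, the six 4-node
# classes, G9 = P5, G10 = fork, G11 = K1,4, G13 = triangle with 2-path
# tail, G15 = C5, G29 = K5) are exact; see the methods vignette for the
# tie-break convention on the remaining slots.
#' @noRd
przulj_edge_lists <- function() {
  e <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    G0  = list(n = 2L, edges = e(1,2)),
    G1  = list(n = 3L, edges = e(1,2, 2,3)),                       # path P3
    G2  = list(n = 3L, edges = e(1,2, 1,3, 2,3)),                  # triangle
    G3  = list(n = 4L, edges = e(1,2, 2,3, 3,4)),                  # path P4
    G4  = list(n = 4L, edges = e(1,2, 1,3, 1,4)),                  # claw K1,3
    G5  = list(n = 4L, edges = e(1,2, 2,3, 3,4, 1,4)),             # cycle C4
    G6  = list(n = 4L, edges = e(1,2, 1,3, 2,3, 3,4)),             # paw
    G7  = list(n = 4L, edges = e(1,2, 1,3, 2,3, 1,4, 2,4)),        # diamond
    G8  = list(n = 4L, edges = e(1,2, 1,3, 1,4, 2,3, 2,4, 3,4)),   # K4
    G9  = list(n = 5L, edges = e(1,2, 2,3, 3,4, 4,5)),             # path P5
    G10 = list(n = 5L, edges = e(1,2, 2,3, 3,4, 3,5)),             # fork
    G11 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5)),             # star K1,4
    G12 = list(n = 5L, edges = e(1,2, 1,3, 2,3, 1,4, 1,5)),        # cricket
    G13 = list(n = 5L, edges = e(1,2, 1,3, 2,3, 3,4, 4,5)),        # tadpole
    G14 = list(n = 5L, edges = e(1,2, 1,3, 2,3, 2,4, 3,5)),        # bull
    G15 = list(n = 5L, edges = e(1,2, 2,3, 3,4, 4,5, 1,5)),        # cycle C5
    G16 = list(n = 5L, edges = e(1,2, 2,3, 3,4, 1,4, 1,5)),        # banner
    G17 = list(n = 5L, edges = e(1,2, 2,3, 3,4, 1,4, 2,4, 1,5)),   # diamond + pendant (deg-2)
    G18 = list(n = 5L, edges = e(1,2, 1,3, 2,3, 1,4, 1,5, 4,5)),   # bowtie
    G19 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 2,3, 2,4, 1,5)),   # diamond + pendant (deg-3)
    G20 = list(n = 5L, edges = e(1,3, 1,4, 1,5, 2,3, 2,4, 2,5)),   # K2,3
    G21 = list(n = 5L, edges = e(1,2, 2,3, 3,4, 4,5, 1,5, 2,5)),   # house
    G22 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,3, 2,4, 2,5)),         # K5 minus triangle
    G23 = list(n = 5L, edges = e(1,3, 1,4, 1,5, 2,3, 2,4, 2,5, 3,4)),         # K2,3 + edge
    G24 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 2,3, 2,4, 3,4, 1,5)),         # K4 + pendant
    G25 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,3, 3,4, 4,5)),         # gem
    G26 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,3, 2,4, 2,5, 3,4)),    # K5 minus 2-path
    G27 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,4, 2,5, 3,4, 3,5)),    # K5 minus 2 disjoint edges
    G28 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,3, 2,4, 2,5, 3,4, 3,5)), # K5 minus edge
    G29 = list(n = 5L, edges = e(1,2, 1,3, 1,4, 1,5, 2,3, 2,4, 2,5, 3,4, 3,5, 4,5)) # K5
  )
}

#' @noRd
edges_to_mask <- function(edges, k) {
  pb <- pair_bit(k)
  sum(2^pb[cbind(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))])
}

#' Build the graphlet catalog
#'
#' Derives the 30 connected 2-5-node isomorphism classes by brute-force
#' enumeration ([enumerate_connected_classes()]) and orders them per the
#' shipped Przulj table, verifying that the table and the enumeration agree
#' class-for-class. The result is cached for the session.
#'
#' @return An object of class `mcn_graphlet_catalog`: a list of 30 entries
#'   (`name`, `n_nodes`, `n_edges`, `edges`, `canonical`), indexed G0-G29.
#' @export
#' @examples
#' cat30 <- build_catalog()
#' length(cat30) # 30
build_catalog <- function() {
  if (!is.null(.mcn_cache$catalog)) return(.mcn_cache$catalog)
  enum <- enumerate_connected_classes(2:5)
  defs <- przulj_edge_lists()
  entries <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    cm <- canon_mask(edges_to_mask(d$edges, d$n), d$n)
    list(name = nm, n_nodes = d$n, n_edges = nrow(d$edges),
         edges = d$edges, canonical = cm)
  })
  names(entries) <- names(defs)
  # the shipped table must be a reordering of the enumerated classes
  for (k in 2:5) {
    got <- sort(unname(vapply(Filter(function(e) e$n_nodes == k, entries),
                              `[[`, numeric(1), "canonical")))
    want <- unname(as.numeric(enum$canonical[[as.character(k)]]))
    if (!identical(got, want)) {
      stopf("internal catalog table disagrees with enumeration at size %d", k)
    }
  }
  if (anyDuplicated(vapply(entries, function(e)
    sprintf("%d:%0.f", e$n_nodes, e$canonical), character(1)))) {
    stopf("internal catalog table contains duplicate classes")
  }
  class(entries) <- "mcn_graphlet_catalog"
  .mcn_cache$catalog <- entries
  entries
}

#' @rdname build_catalog
#' @export
graphlet_catalog <- build_catalog

#' @export
print.mcn_graphlet_catalog <- function(x, ...) {
  sizes <- vapply(unclass(x), `[[`, integer(1), "n_nodes")
  cat("Graphlet catalog: ", length(x), " classes (",
      paste(sprintf("%d of size %d", table(sizes), as.integer(names(table(sizes)))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# lookup vector for size k: entry mask+1 gives the 0-based class index
# (G number) of that labeled graph, or NA if disconnected; mask 0 is NA
#' @noRd
mask_lookup <- function(k) {
  key <- sprintf("lookup_%d", k)
  if (!is.null(.mcn_cache[[key]])) return(.mcn_cache[[key]])
  cat30 <- build_catalog()
  canon_of_size <- vapply(Filter(function(e) e$n_nodes == k, unclass(cat30)),
                          `[[`, numeric(1), "canonical")
  gid_of_size <- as.integer(sub("^G", "", names(canon_of_size)))
  n_bits <- (k * (k - 1L)) %/% 2L
  lut <- rep(NA_integer_, 2^n_bits)
  for (mask in seq_len(2^n_bits - 1L)) {
    if (!mask_connected(mask, k)) next
    cm <- canon_mask(mask, k)
    lut[mask + 1L] <- gid_of_size[match(cm, canon_of_size)]
  }
  .mcn_cache[[key]] <- lut
  lut
}
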