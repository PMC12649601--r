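# Delimited-text adapters: cohorts, vertex maps, graphs, configs.
# All matrices travel as TSV with explicit subject/vertex IDs so external
# 0-based tools can map rows and columns unambiguously; every cohort write
# is accompanied by a JSON sidecar recording the generating spec and seed.

#' @noRd
read_numeric_tsv <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, check.names = FALSE)
  rn <- NULL
  if (ncol(df) && !is.numeric(df[[1]]) && colnames(df)[1] %in% c("id", "subject", "vertex")) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stopf("%s '%s': non-numeric cell at row %d, column %d ('%s' = %s)",
              what, path, bad[1], j, colnames(df)[j], col[bad[1]])
      }
      df[[j]] <- num
    }
    if (anyNA(df[[j]])) {
      stopf("%s '%s': missing value at row %d, column %d",
            what, path, which(is.na(df[[j]]))[1], j)
    }
  }
  m <- as.matrix(df)
  if (!is.null(rn)) rownames(m) <- rn
  m
}

#' @noRd
write_tsv <- function(x, path, id_col = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(id_col)) df <- cbind(stats::setNames(data.frame(rownames(x)), id_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort as delimited text
#'
#' Writes `<prefix>_myelin.tsv` (subjects as rows, vertex IDs as columns),
#' `<prefix>_covariates.tsv`, and a `<prefix>_meta.json` sidecar recording
#' the generating spec (including seed) when present.
#'
#' @param cohort an `mcn_cohort` (or list with `myelin` and `covariates`).
#' @param dir output directory (created if missing).
#' @param prefix file name prefix (default `"cohort"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- check_matrix(cohort$myelin, "myelin")
  paths <- c(
    myelin = file.path(dir, paste0(prefix, "_myelin.tsv")),
    covariates = file.path(dir, paste0(prefix, "_covariates.tsv")),
    meta = file.path(dir, paste0(prefix, "_meta.json"))
  )
  write_tsv(M, paths["myelin"], id_col = "subject")
  cov <- cohort$covariates
  utils::write.table(cbind(subject = rownames(M), cov), paths["covariates"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_subjects = nrow(M), n_vertices = ncol(M),
               spec = if (!is.null(cohort$spec)) unclass(cohort$spec))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a cohort from delimited text
#'
#' @param myelin_path TSV of the subject x vertex matrix (optionally with a
#'   leading `subject` ID column).
#' @param covariates_path TSV with columns `age` and `gender` (one row per
#'   subject).
#' @return An `mcn_cohort` (without a `truth` block).
#' @export
read_cohort <- function(myelin_path, covariates_path) {
  M <- read_numeric_tsv(myelin_path, "myelin matrix")
  cov <- utils::read.delim(covariates_path, check.names = FALSE)
  if (!all(c("age", "gender") %in% names(cov))) {
    stopf("covariate file '%s' must contain columns 'age' and 'gender'",
          covariates_path)
  }
  if (nrow(cov) != nrow(M)) {
    stopf("dimension mismatch: myelin has %d subjects but covariates have %d rows",
          nrow(M), nrow(cov))
  }
  out <- list(myelin = M,
              covariates = data.frame(age = as.numeric(cov$age),
                                      gender = as.numeric(cov$gender)),
              truth = NULL, spec = NULL)
  class(out) <- "mcn_cohort"
  out
}

#' Read one or more vertex maps from TSV
#'
#' A single numeric column (after an optional `vertex` ID column) returns a
#' vector; several columns return a vertices x maps matrix.
#'
#' @param path TSV path.
#' @return Numeric vector or matrix.
#' @export
read_vertex_map <- function(path) {
  m <- read_numeric_tsv(path, "vertex map")
  if (ncol(m) == 1L) c(m) else m
}

#' Write vertex maps as TSV
#'
#' @param maps numeric vector, or vertices x maps matrix/data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(maps, path) {
  m <- if (is.null(dim(maps))) matrix(maps, ncol = 1,
                                      dimnames = list(NULL, "value"))
       else as.matrix(maps)
  df <- data.frame(vertex = sprintf("v%d", seq_len(nrow(m))), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as an edge-list TSV and (optionally) GraphML
#'
#' @param graph an `mcn_graph`.
#' @param path edge-list TSV path (columns `i`, `j`, 1-based).
#' @param graphml optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path, graphml = NULL) {
  graph <- check_graph(graph)
  utils::write.table(as.data.frame(graph$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    con <- file(graphml, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="G" edgedefault="undirected">',
      sprintf('    <node id="n%d"/>', seq_len(graph$n_nodes)),
      sprintf('    <edge source="n%d" target="n%d"/>',
              graph$edges[, 1], graph$edges[, 2]),
      "  </graph>", "</graphml>"), con)
  }
  invisible(path)
}

#' Read an edge-list TSV into an `mcn_graph`
#'
#' @param path TSV with columns `i`, `j` (1-based node indices).
#' @param n_nodes total node count (isolated nodes are retained); defaults
#'   to the largest index present.
#' @return An `mcn_graph`.
#' @export
read_graph_tsv <- function(path, n_nodes = NULL) {
  e <- read_numeric_tsv(path, "edge list")
  if (is.null(n_nodes)) n_nodes <- if (length(e)) max(e) else 0L
  as_mcn_graph(n_nodes, e)
}
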