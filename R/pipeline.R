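# Orchestration: a validated configuration object, the staged pipeline
# (covariance -> gradients/strength -> class profiles -> decoding ->
# feature correlations -> graphlets), and a run manifest with checksums.

#' Pipeline configuration
#'
#' Validates and assembles every knob of [run_pipeline()]. Defaults encode
#' the conventional analysis choices: `min(3000, n_vertices)` landmarks,
#' three gradients, thresholds -0.4, -0.2, 0.2, 0.4, Bonferroni alpha 0.05.
#' All randomness flows from the single `seed`, split per stage, so one
#' number reproduces the whole run.
#'
#' @param cohort_spec an [cohort_spec()] for a synthetic run, or `NULL`
#'   when `myelin_path`/`covariates_path` point at files.
#' @param myelin_path,covariates_path optional cohort files (TSV).
#' @param n_landmarks landmark count (`NULL` = `min(3000, n_vertices)`).
#' @param k number of gradients (>= 1).
#' @param thresholds nonzero signed cutoffs for the graphlet stage.
#' @param census `"exact"`, `"sampled"`, or `"auto"` (exact below
#'   `max_census_edges`, sampled above).
#' @param n_samples draws per size for the sampled census.
#' @param max_census_edges guardrail for `census = "auto"`.
#' @param alpha significance level.
#' @param n_classes,n_terms,n_features synthetic annotation sizes.
#' @param output_dir where [run_pipeline()] writes its outputs.
#' @param seed master seed.
#' @return An object of class `mcn_config`.
#' @export
pipeline_config <- function(cohort_spec = NULL, myelin_path = NULL,
                            covariates_path = NULL, n_landmarks = NULL,
                            k = 3L, thresholds = c(-0.4, -0.2, 0.2, 0.4),
                            census = c("auto", "exact", "sampled"),
                            n_samples = 20000L, max_census_edges = 3000L,
                            alpha = 0.05, n_classes = 5L, n_terms = 50L,
                            n_features = 10L, output_dir = tempfile("mcn_run_"),
                            seed = 1L) {
  census <- match.arg(census)
  if (is.null(cohort_spec) && (is.null(myelin_path) || is.null(covariates_path))) {
    stopf("provide either 'cohort_spec' or both 'myelin_path' and 'covariates_path'")
  }
  if (!is.null(cohort_spec) && !inherits(cohort_spec, "mcn_cohort_spec")) {
    cohort_spec <- do.call(mcnet::cohort_spec, as.list(cohort_spec))
  }
  k <- check_count(k, "k")
  if (!is.numeric(thresholds) || !length(thresholds)) {
    stopf("'thresholds' must be a non-empty numeric vector")
  }
  if (any(thresholds == 0) || any(abs(thresholds) > 1)) {
    stopf("'thresholds' must be nonzero with |t| <= 1")
  }
  cfg <- list(
    cohort_spec = cohort_spec, myelin_path = myelin_path,
    covariates_path = covariates_path,
    n_landmarks = if (!is.null(n_landmarks)) check_count(n_landmarks, "n_landmarks"),
    k = k, thresholds = as.numeric(thresholds), census = census,
    n_samples = check_count(n_samples, "n_samples"),
    max_census_edges = check_count(max_census_edges, "max_census_edges"),
    alpha = check_number(alpha, "alpha"),
    n_classes = check_count(n_classes, "n_classes"),
    n_terms = check_count(n_terms, "n_terms"),
    n_features = check_count(n_features, "n_features"),
    output_dir = output_dir, seed = as.integer(check_number(seed, "seed"))
  )
  class(cfg) <- "mcn_config"
  cfg
}

#' @export
print.mcn_config <- function(x, ...) {
  src <- if (!is.null(x$cohort_spec)) {
    sprintf("synthetic (%d x %d)", x$cohort_spec$n_subjects,
            x$cohort_spec$n_vertices)
  } else sprintf("files (%s)", x$myelin_path)
  cat("Pipeline config: input", src, "| k =", x$k, "| thresholds",
      paste(x$thresholds, collapse = ", "), "| seed", x$seed, "\n")
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config an `mcn_config`.
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   an `mcn_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "mcn_config")) stopf("'config' must be an mcn_config")
  x <- unclass(config)
  x$cohort_spec <- if (!is.null(x$cohort_spec)) unclass(x$cohort_spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cohort_spec <- if (!is.null(x$cohort_spec)) do.call(cohort_spec, x$cohort_spec)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: cohort (synthetic or read from files),
#' residualization, covariance network + strength maps, landmark gradients,
#' class profiles, term decoding, feature correlations, thresholded
#' graphlet censuses. Every output is written to `config$output_dir` as
#' TSV/JSON and inventoried with an md5 checksum in the returned manifest.
#' Rerunning with the same config reproduces all numeric outputs
#' bit-for-bit.
#'
#' @param config an [pipeline_config()] object.
#' @return An object of class `mcn_manifest` (invisibly): `config`,
#'   `version`, `timings` (seconds per stage), `outputs` (file -> md5).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "mcn_config")) stopf("'config' must be an mcn_config")
  # revalidate up front so no stage runs (and no output appears) on a
  # config edited after construction
  if (any(config$thresholds == 0) || any(abs(config$thresholds) > 1)) {
    stopf("'thresholds' must be nonzero with |t| <= 1")
  }
  if (config$k < 1L) stopf("'k' must be >= 1")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  emit <- function(path) outputs <<- c(outputs, path)

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_spec)) {
      co <- generate_cohort(config$cohort_spec)
      emit(write_cohort(co, config$output_dir))
      co
    } else {
      read_cohort(config$myelin_path, config$covariates_path)
    }
  })
  nv <- ncol(cohort$myelin)
  annotations <- stage("annotations", {
    generate_annotations(nv, n_classes = config$n_classes,
                         n_terms = config$n_terms,
                         n_features = config$n_features,
                         seed = derive_seed(config$seed, 2L))
  })
  resid <- stage("residualize", residualize(cohort))
  network <- stage("covariance_network", {
    net <- covariance_network(resid)
    if (nv <= 500L) {  # persist the dense matrix only at desk scale
      emit(write_vertex_map(net$rho,
                            file.path(config$output_dir, "covnet_rho.tsv")))
    }
    net
  })
  strengths <- stage("strength_maps", {
    s <- strength_maps(network)
    emit(write_vertex_map(as.data.frame(s)[, c("negative", "positive", "full")],
                          file.path(config$output_dir, "strength_maps.tsv")))
    s
  })
  gradients <- stage("gradients", {
    lm <- select_landmarks(nv,
                           n_landmarks = config$n_landmarks %||% min(3000L, nv),
                           seed = derive_seed(config$seed, 1L))
    conn <- landmark_connectivity(resid, lm)
    g <- approximate_gradients(conn, k = config$k, landmarks = lm)
    emit(write_vertex_map(g$scores,
                          file.path(config$output_dir, "gradients.tsv")))
    meta <- file.path(config$output_dir, "gradients_meta.json")
    jsonlite::write_json(list(k = g$k, seed = lm$seed,
                              n_landmarks = lm$n_landmarks,
                              variance_explained = g$variance_explained),
                         meta, auto_unbox = TRUE, digits = NA)
    emit(meta)
    g
  })
  stage("class_profiles", {
    maps <- cbind(gradients$scores, negative = strengths$negative,
                  positive = strengths$positive, full = strengths$full)
    prof <- do.call(rbind, lapply(colnames(maps), function(nm) {
      cm <- class_means(maps[, nm], annotations$parcellation,
                        class_labels = annotations$class_labels)
      data.frame(map = nm, t(cm$class_means),
                 dispersion = profile_dispersion(cm), check.names = FALSE)
    }))
    p <- file.path(config$output_dir, "class_profiles.tsv")
    utils::write.table(prof, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    prof
  })
  stage("decoding", {
    for (j in seq_len(config$k)) {
      dt <- decode_terms(gradients$scores[, j], annotations$term_maps)
      p <- file.path(config$output_dir, sprintf("decoding_G%d.tsv", j))
      utils::write.table(dt, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
    }
  })
  stage("feature_correlations", {
    rep1 <- correlate_features(gradients$scores, annotations$feature_maps,
                               alpha = config$alpha)
    rep2 <- gradient_strength_matrix(gradients, strengths,
                                     alpha = config$alpha)
    p1 <- file.path(config$output_dir, "feature_correlations.tsv")
    p2 <- file.path(config$output_dir, "gradient_strength.tsv")
    utils::write.table(rep1, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p1); emit(p2)
  })
  stage("graphlets", {
    for (t in config$thresholds) {
      g <- threshold_graph(network, t)
      method <- config$census
      if (method == "auto") {
        method <- if (nrow(g$edges) <= config$max_census_edges) "exact" else "sampled"
      }
      cs <- if (method == "exact") census_exact(g)
            else census_sampled(g, n_samples = config$n_samples,
                                seed = derive_seed(config$seed, 3L))
      nc <- normalize_census(cs)
      df <- data.frame(graphlet = names(cs$counts), count = cs$counts,
                       fstar = nc$fstar, row.names = NULL)
      if (method == "sampled") df$se <- cs$se
      p <- file.path(config$output_dir,
                     sprintf("graphlets_t%+0.2f.tsv", t))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      emit(write_graph_tsv(g, file.path(config$output_dir,
                                        sprintf("edges_t%+0.2f.tsv", t))))
    }
  })
  cfg_path <- file.path(config$output_dir, "config.json")
  write_config(config, cfg_path)
  emit(cfg_path)
  outputs <- unique(unname(unlist(outputs)))
  manifest <- list(
    config = config,
    version = as.character(utils::packageVersion("mcnet")),
    seed = config$seed,
    timings = unlist(timings),
    outputs = vapply(outputs, function(p) unname(tools::md5sum(p)),
                     character(1))
  )
  class(manifest) <- "mcn_manifest"
  mpath <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(list(version = manifest$version, seed = manifest$seed,
                            timings = as.list(manifest$timings),
                            outputs = as.list(manifest$outputs)),
                       mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.mcn_manifest <- function(x, ...) {
  cat("Pipeline run (mcnet", x$version, "| seed", x$seed, ")\n")
  cat("  outputs:", length(x$outputs), "files in",
      dirname(names(x$outputs)[1]), "\n")
  invisible(x)
}

#' Verify a run manifest against the files on disk
#'
#' @param manifest an `mcn_manifest`.
#' @return `TRUE` invisibly; errors if a declared output is missing or its
#'   checksum changed.
#' @export
verify_manifest <- function(manifest) {
  for (p in names(manifest$outputs)) {
    if (!file.exists(p)) stopf("declared output missing: %s", p)
    if (!identical(unname(tools::md5sum(p)), manifest$outputs[[p]])) {
      stopf("checksum mismatch for %s", p)
    }
  }
  invisible(TRUE)
}
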