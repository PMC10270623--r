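#' Configure a representation pipeline
#'
#' Four pipelines are available, named for their stages:
#' * `"MCA"` — bin the numeric features, one-hot everything, MCA on the full
#'   feature set, retain components at the variance threshold.
#' * `"MCA/PCA"` — MCA on the discrete features in parallel with PCA on the
#'   numeric features, each retained at the threshold, concatenated on their
#'   native scales (no re-weighting; the third pipeline is the balancing
#'   device).
#' * `"MCA/PCA/PCA"` — as `"MCA/PCA"`, then a second PCA over the
#'   concatenated components, retained at the threshold.
#' * `"AE"` — scale the numerics (standardized by default: min-max scaling
#'   leaves the numeric block with ~1/100 of the indicator block's variance,
#'   so the MSE loss all but ignores it), append the one-hot indicators
#'   unscaled, train an autoencoder and take the bottleneck activations.
#'
#' Default binning for the `"MCA"` pipeline: FEV1 % predicted uses the
#' clinical GOLD stage edges (30/50/80); other numerics use training-set
#' quartiles.
#'
#' @param name Pipeline name.
#' @param variance_threshold Cumulative explained-variance retention
#'   threshold in (0, 1\], applied at every retain step (default 0.75).
#' @param binning Optional named list of [binning_rule()]s overriding the
#'   defaults (MCA pipeline only).
#' @param scaling `"standardize"` (default) or `"minmax"` (AE pipeline).
#' @param ae An [ae_config()] for a fixed-architecture AE fit, or `NULL`.
#' @param ae_grid A list of arguments to [ae_grid_search()] to select the
#'   architecture by test-set reconstruction MSE instead; overrides `ae`.
#' @param seed Integer seed (AE init/shuffling).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(name = c("MCA", "MCA/PCA", "MCA/PCA/PCA", "AE"),
                            variance_threshold = 0.75, binning = NULL,
                            scaling = c("standardize", "minmax"),
                            ae = NULL, ae_grid = NULL, seed = 1L) {
  name <- match.arg(name)
  scaling <- match.arg(scaling)
  if (variance_threshold <= 0 || variance_threshold > 1)
    ps_param_error("variance_threshold must lie in (0, 1]")
  if (is.null(ae) && is.null(ae_grid))
    ae <- ae_config(seed = as.integer(seed))
  structure(list(name = name, variance_threshold = variance_threshold,
                 binning = binning, scaling = scaling, ae = ae,
                 ae_grid = ae_grid, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' The four default pipeline configurations
#' @param seed Master seed shared by all four.
#' @param variance_threshold Retention threshold.
#' @return Named list of `pipeline_config`s.
#' @export
default_pipeline_configs <- function(seed = 1L, variance_threshold = 0.75) {
  nms <- c("MCA", "MCA/PCA", "MCA/PCA/PCA", "AE")
  stats::setNames(lapply(nms, function(nm)
    pipeline_config(nm, variance_threshold = variance_threshold, seed = seed)), nms)
}

default_binning_rules <- function(schema) {
  rules <- list()
  for (nm in schema_features_of(schema, "numeric")) {
    rules[[nm]] <- if (nm == "fev1_pct_pred") {
      binning_rule(nm, "edges", edges = c(30, 50, 80),
                   labels = c("gold4", "gold3", "gold2", "gold1"))
    } else {
      binning_rule(nm, "quantile", n_bins = 4L)
    }
  }
  rules
}

# bin the numeric features of a cohort table with fitted rules and return a
# factor data.frame over all schema features, schema order
binned_table <- function(x, rules) {
  tab <- x$table
  for (nm in names(rules)) tab[[nm]] <- bin_numeric(tab[[nm]], rules[[nm]])
  tab
}

ae_input <- function(x, scaler, numeric_feats, discrete_feats) {
  num <- as.matrix(as.data.frame(lapply(x$table[numeric_feats], as.numeric)))
  scaled <- apply_scaler(scaler, num)
  oh <- one_hot_encode(x, discrete_feats)
  out <- cbind(scaled, oh$values)
  rownames(out) <- x$ids
  out
}

#' Run one representation pipeline on a train/test split
#'
#' All transform state (bin edges, scalers, MCA/PCA bases, autoencoder
#' weights) is fitted on the training set only and applied unchanged to the
#' test set.
#'
#' @param split A `split_cohort`.
#' @param config A `pipeline_config`.
#' @return A `representation_result`: `name`, `train` / `test` coordinate
#'   matrices (row names = patient ids), `retained` width, `state`.
#' @export
run_pipeline <- function(split, config) {
  if (!inherits(split, "split_cohort")) ps_validation_error("split must be a split_cohort")
  if (!inherits(config, "pipeline_config")) ps_validation_error("config must be a pipeline_config")
  tr <- split$train
  te <- split$test
  schema <- tr$schema
  numeric_feats <- schema_features_of(schema, "numeric")
  discrete_feats <- schema_features_of(schema, c("ordinal", "binary", "categorical"))
  thr <- config$variance_threshold
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s:%s] %s", config$name, tag, conditionMessage(e)), call. = FALSE)
    })
  }

  if (config$name == "MCA") {
    rules <- config$binning %||% default_binning_rules(schema)
    rules <- stage("binning", lapply(rules, function(r)
      fit_binning_rule(r, as.numeric(tr$table[[r$feature]]))))
    names(rules) <- vapply(rules, `[[`, character(1), "feature")
    enc_tr <- one_hot_encode(binned_table(tr, rules), schema_names(schema))
    mca <- stage("mca", retain_components(fit_mca(enc_tr), thr))
    coords_tr <- mca$coordinates
    enc_te <- one_hot_encode(binned_table(te, rules), schema_names(schema))
    coords_te <- stage("project", project(mca, enc_te))
    state <- list(binning = rules, mca = mca)
  } else if (config$name %in% c("MCA/PCA", "MCA/PCA/PCA")) {
    enc_tr <- one_hot_encode(tr, discrete_feats)
    mca <- stage("mca", retain_components(fit_mca(enc_tr), thr))
    num_tr <- as.matrix(as.data.frame(lapply(tr$table[numeric_feats], as.numeric)))
    pca <- stage("pca", retain_components(fit_pca(num_tr, standardize = TRUE), thr))
    coords_tr <- cbind(mca$coordinates, pca$coordinates)
    enc_te <- one_hot_encode(te, discrete_feats)
    num_te <- as.matrix(as.data.frame(lapply(te$table[numeric_feats], as.numeric)))
    coords_te <- cbind(stage("project", project(mca, enc_te)),
                       stage("project", project(pca, num_te)))
    state <- list(mca = mca, pca = pca)
    if (config$name == "MCA/PCA/PCA") {
      pca2 <- stage("pca2", retain_components(fit_pca(coords_tr, standardize = TRUE), thr))
      coords_te <- stage("project", project(pca2, coords_te))
      coords_tr <- pca2$coordinates
      state$pca2 <- pca2
    }
  } else {  # AE
    num_tr <- as.matrix(as.data.frame(lapply(tr$table[numeric_feats], as.numeric)))
    scaler <- stage("scaling", fit_scaler(num_tr, config$scaling))
    x_tr <- ae_input(tr, scaler, numeric_feats, discrete_feats)
    x_te <- ae_input(te, scaler, numeric_feats, discrete_feats)
    if (!is.null(config$ae_grid)) {
      gs <- stage("ae", do.call(ae_grid_search,
                                c(list(x_train = x_tr, x_test = x_te), config$ae_grid)))
      fit <- gs$best
      state <- list(scaler = scaler, ae = fit, grid_results = gs$results)
    } else {
      fit <- stage("ae", fit_autoencoder(x_tr, x_te, config$ae))
      if (fit$diverged) stop(sprintf("[%s:ae] training diverged", config$name), call. = FALSE)
      state <- list(scaler = scaler, ae = fit)
    }
    coords_tr <- ae_encode(fit, x_tr)
    coords_te <- ae_encode(fit, x_te)
  }
  rownames(coords_tr) <- tr$ids
  rownames(coords_te) <- te$ids
  structure(list(name = config$name, train = coords_tr, test = coords_te,
                 retained = ncol(coords_tr), state = state, config = config),
            class = "representation_result")
}

#' @export
print.representation_result <- function(x, ...) {
  cat(sprintf("<representation_result:%s> train %d x %d, test %d x %d\n",
              x$name, nrow(x$train), ncol(x$train), nrow(x$test), ncol(x$test)))
  invisible(x)
}

#' Run every pipeline and the full quantitative evaluation
#'
#' For each pipeline: the RV feature-importance table, the MRV triplet and
#' the Hopkins cluster-tendency index, all on the training representation.
#' Across pipelines: a co-assignment congruity matrix per k (k-means under
#' identical seeded initializations; the diagonal holds each pipeline's
#' bootstrap pair-stability). Every source of randomness derives
#' deterministically from `seed`, so two calls with the same inputs produce
#' identical reports.
#'
#' @param split A `split_cohort`.
#' @param configs Named list of `pipeline_config`s (default: the four
#'   standard pipelines under `seed`).
#' @param N Neighbor count for the RV metric (default 20).
#' @param ks k-means cluster counts (default 2:5).
#' @param hopkins_m_h,hopkins_repeats Hopkins sampling parameters.
#' @param bootstrap_fraction,bootstrap_repeats Pair-stability parameters.
#' @param seed Master seed.
#' @return An `evaluation_report` list: `pipelines` (per pipeline: retained
#'   width, `rv_table`, `mrv`, `hopkins`), `congruity` (one matrix per k),
#'   `N`, `ks`, `seed`.
#' @export
evaluate_all <- function(split, configs = NULL, N = 20L, ks = 2:5,
                         hopkins_m_h = 100L, hopkins_repeats = 20L,
                         bootstrap_fraction = 0.1, bootstrap_repeats = 20L,
                         seed = 1L) {
  if (is.null(configs)) configs <- default_pipeline_configs(seed = seed)
  if (!length(configs)) ps_param_error("need at least one pipeline config")
  reps <- lapply(configs, function(cfg) run_pipeline(split, cfg))
  names(reps) <- vapply(reps, `[[`, character(1), "name")
  cvar <- cohort_variability(split$train, seed = derive_seed(seed, 1))

  pipe_blocks <- lapply(reps, function(rep) {
    nb <- nearest_neighbors(pairwise_distances(rep$train), N)
    rv <- relative_variability_table(cvar, neighborhood_variability(split$train, nb), N = N)
    hop <- hopkins_index(rep$train, m_h = min(hopkins_m_h, nrow(rep$train) - 1L),
                         repeats = hopkins_repeats, seed = derive_seed(seed, 31))
    list(name = rep$name, retained = rep$retained, rv_table = rv,
         mrv = mrv_summary(rv), hopkins = hop$H)
  })

  labelings <- lapply(ks, function(k) {
    lapply(reps, function(rep)
      kmeans_partition(rep$train, k, seed = derive_seed(seed, 20 + k)))
  })
  names(labelings) <- as.character(ks)
  congruity_mats <- lapply(seq_along(ks), function(ki) {
    k <- ks[ki]
    labs <- labelings[[ki]]
    np <- length(reps)
    mat <- matrix(NA_real_, np, np, dimnames = list(names(reps), names(reps)))
    for (i in seq_len(np)) {
      for (j in seq_len(np)) {
        if (i == j) next
        mat[i, j] <- congruity(labs[[i]], labs[[j]])
      }
      mat[i, i] <- bootstrap_pair_stability(
        reps[[i]]$train, k, fraction = bootstrap_fraction,
        repeats = bootstrap_repeats, seed = derive_seed(seed, 40 + k))
    }
    mat
  })
  names(congruity_mats) <- as.character(ks)

  structure(list(pipelines = pipe_blocks, congruity = congruity_mats,
                 representations = reps, N = as.integer(N), ks = as.integer(ks),
                 seed = as.integer(seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d pipelines, N = %d, k in {%s}\n",
              length(x$pipelines), x$N, paste(x$ks, collapse = ", ")))
  for (pb in x$pipelines)
    cat(sprintf("  %-12s c = %-2d Hopkins = %.3f MRV overall = %.1f\n",
                pb$name, pb$retained, pb$hopkins, pb$mrv$mrv_overall))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (full machine-readable report), `rv_tables.csv`
#' (long: pipeline, rank, feature, dtype, rv), `mrv.csv`, one
#' `congruity_k<k>.csv` per k (off-diagonal = cross-pipeline co-assignment
#' %, diagonal = bootstrap pair-stability %), and `summary.csv`.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- report_as_list(report)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  rv_long <- do.call(rbind, lapply(report$pipelines, function(pb)
    cbind(pipeline = pb$name, as.data.frame(pb$rv_table))))
  utils::write.csv(rv_long, file.path(dir, "rv_tables.csv"), row.names = FALSE)
  mrv <- do.call(rbind, lapply(report$pipelines, function(pb)
    data.frame(pipeline = pb$name, mrv_categorical = pb$mrv$mrv_categorical,
               mrv_numeric = pb$mrv$mrv_numeric, mrv_overall = pb$mrv$mrv_overall)))
  utils::write.csv(mrv, file.path(dir, "mrv.csv"), row.names = FALSE)
  for (k in names(report$congruity)) {
    utils::write.csv(as.data.frame(report$congruity[[k]]),
                     file.path(dir, paste0("congruity_k", k, ".csv")))
  }
  summ <- do.call(rbind, lapply(report$pipelines, function(pb)
    data.frame(pipeline = pb$name, retained = pb$retained,
               mrv_overall = pb$mrv$mrv_overall, hopkins = pb$hopkins)))
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

# report as plain lists for JSON (excludes the heavyweight representations)
report_as_list <- function(report) {
  list(
    N = report$N, ks = report$ks, seed = report$seed,
    pipelines = lapply(report$pipelines, function(pb)
      list(name = pb$name, retained = pb$retained, hopkins = pb$hopkins,
           mrv = pb$mrv,
           rv = lapply(seq_len(nrow(pb$rv_table)), function(i)
             list(rank = pb$rv_table$rank[i], feature = pb$rv_table$feature[i],
                  dtype = pb$rv_table$dtype[i], rv = pb$rv_table$rv[i])))),
    congruity = lapply(report$congruity, function(mat) {
      l <- as.list(as.data.frame(mat))
      lapply(l, as.numeric)
    })
  )
}
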