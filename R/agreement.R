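#' Export blinded clinical vignettes for expert rating
#'
#' Selects `sample_size` reference patients at random, finds each
#' reference's best non-identical match under every representation (see
#' [best_match_nonidentical()]), and lays the reference's features plus one
#' feature block per match out in a single row. Pipelines are blinded by a
#' shuffled letter code (A, B, ...); the letter-to-pipeline mapping is
#' returned separately so ratings can be unblinded after collection.
#'
#' @param x The `cohort` the representations were built from.
#' @param coord_list Named list of coordinate matrices (one per pipeline),
#'   rows matching the cohort.
#' @param sample_size Number of reference patients (default 125).
#' @param seed Integer seed (references and blinding permutation).
#' @return List with `vignettes` (data.frame, one row per reference),
#'   `blinding` (named character vector letter -> pipeline), `seed`.
#' @export
export_vignettes <- function(x, coord_list, sample_size = 125L, seed = 1L) {
  if (!length(names(coord_list)) || any(!nzchar(names(coord_list))))
    ps_validation_error("coord_list must be a named list of coordinate matrices")
  if (sample_size > x$m) ps_param_error("sample_size cannot exceed cohort size")
  set.seed(as.integer(seed))
  refs <- sample.int(x$m, sample_size)
  letters_code <- LETTERS[seq_along(coord_list)]
  blinding <- stats::setNames(names(coord_list)[sample.int(length(coord_list))],
                              letters_code)
  dists <- lapply(coord_list, function(co) {
    co <- as.matrix(co)
    rownames(co) <- x$ids
    pairwise_distances(co)
  })
  feat_block <- function(idx, prefix) {
    blk <- x$table[idx, , drop = FALSE]
    for (j in seq_along(blk)) if (is.factor(blk[[j]])) blk[[j]] <- as.character(blk[[j]])
    names(blk) <- paste(prefix, names(blk), sep = ".")
    rownames(blk) <- NULL
    blk
  }
  out <- data.frame(case_id = x$ids[refs], stringsAsFactors = FALSE)
  out <- cbind(out, feat_block(refs, "ref"))
  for (lt in letters_code) {
    pl <- blinding[[lt]]
    match_ids <- vapply(refs, function(i)
      best_match_nonidentical(dists[[pl]], x, x$ids[i]), character(1))
    mi <- match(match_ids, x$ids)
    blk <- cbind(stats::setNames(data.frame(match_ids, stringsAsFactors = FALSE),
                                 paste0("match_", lt, ".id")),
                 feat_block(mi, paste0("match_", lt)))
    out <- cbind(out, blk)
  }
  list(vignettes = out, blinding = blinding, seed = as.integer(seed))
}

#' Construct and validate a rating set
#'
#' Ratings are ranks 1 (best proposal) to `n_ranks` (worst proposal) given
#' by each rater to each pipeline for each case. Ties are allowed, but every
#' (case, rater) must assign rank 1 to at least one pipeline and the worst
#' rank to at least one pipeline.
#'
#' @param ratings Long data.frame with columns `case_id`, `rater_id`,
#'   `pipeline`, `rank`.
#' @param n_ranks Number of rank categories (default 4).
#' @return A validated `rating_set`.
#' @export
rating_set <- function(ratings, n_ranks = 4L) {
  need <- c("case_id", "rater_id", "pipeline", "rank")
  if (!all(need %in% names(ratings)))
    ps_validation_error(paste0("ratings need columns: ", paste(need, collapse = ", ")))
  ratings$rank <- as.integer(ratings$rank)
  if (any(is.na(ratings$rank) | ratings$rank < 1L | ratings$rank > n_ranks))
    ps_validation_error(sprintf("ranks must be integers in 1..%d", n_ranks))
  by <- split(ratings$rank, interaction(ratings$case_id, ratings$rater_id, drop = TRUE))
  ok <- vapply(by, function(r) any(r == 1L) && any(r == n_ranks), logical(1))
  if (!all(ok))
    ps_validation_error(sprintf(
      "each (case, rater) must assign a 1 and a %d at least once (violated for %s)",
      n_ranks, names(by)[which(!ok)[1L]]))
  structure(ratings, class = c("rating_set", "data.frame"),
            n_ranks = as.integer(n_ranks))
}

#' Read a rating return file
#'
#' Wide CSV with columns `case_id`, `rater_id` and one `rank_<letter>`
#' column per blinded pipeline; converted to the long form and validated
#' with [rating_set()]. If a blinding map is given, letters are unblinded to
#' pipeline names.
#'
#' @param path CSV path.
#' @param blinding Optional named vector letter -> pipeline (from
#'   [export_vignettes()]).
#' @param n_ranks Number of rank categories.
#' @return A `rating_set`.
#' @export
read_ratings <- function(path, blinding = NULL, n_ranks = 4L) {
  wide <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  rank_cols <- grep("^rank_", names(wide), value = TRUE)
  if (!length(rank_cols)) ps_validation_error("no rank_<letter> columns found")
  long <- do.call(rbind, lapply(rank_cols, function(cn) {
    lt <- sub("^rank_", "", cn)
    pl <- if (!is.null(blinding)) unname(blinding[[lt]]) else lt
    data.frame(case_id = wide$case_id, rater_id = wide$rater_id,
               pipeline = pl, rank = as.integer(wide[[cn]]),
               stringsAsFactors = FALSE)
  }))
  rating_set(long, n_ranks = n_ranks)
}

rating_pair <- function(ratings, pipeline) {
  sub <- ratings[ratings$pipeline == pipeline, , drop = FALSE]
  if (!nrow(sub)) ps_validation_error(sprintf("no ratings for pipeline '%s'", pipeline))
  raters <- sort(unique(sub$rater_id))
  if (length(raters) != 2L)
    ps_stop("agreement statistics require exactly 2 raters", "patsim_design_error")
  a <- sub[sub$rater_id == raters[1L], ]
  b <- sub[sub$rater_id == raters[2L], ]
  cases <- intersect(a$case_id, b$case_id)
  list(a = a$rank[match(cases, a$case_id)],
       b = b$rank[match(cases, b$case_id)],
       n_ranks = attr(ratings, "n_ranks") %||% max(sub$rank))
}

binarize_mode <- function(r, mode, n_ranks) {
  switch(mode,
         overall = r,
         is_best = as.integer(r == 1L),
         is_not_best = as.integer(r != 1L),
         is_worst = as.integer(r == n_ranks),
         is_not_worst = as.integer(r != n_ranks))
}

#' Raw percentage agreement between two raters
#'
#' `overall` counts the cases where both raters gave the pipeline the same
#' rank; the binarized modes compare the indicator labels "ranked best"
#' (rank 1) or "ranked worst" (last rank) and their complements.
#'
#' @param ratings A `rating_set` with exactly 2 raters.
#' @param pipeline Pipeline name to score.
#' @param mode One of `"overall"`, `"is_best"`, `"is_not_best"`,
#'   `"is_worst"`, `"is_not_worst"`.
#' @return Proportion in \[0, 1\].
#' @export
percent_agreement <- function(ratings, pipeline,
                              mode = c("overall", "is_best", "is_not_best",
                                       "is_worst", "is_not_worst")) {
  mode <- match.arg(mode)
  pr <- rating_pair(ratings, pipeline)
  a <- binarize_mode(pr$a, mode, pr$n_ranks)
  b <- binarize_mode(pr$b, mode, pr$n_ranks)
  if (mode == "overall") return(mean(a == b))
  # agreement specific to the positive class: of the cases where either
  # rater applied the label, the fraction where both did
  either <- a == 1L | b == 1L
  if (!any(either)) return(NA_real_)
  mean(a[either] == 1L & b[either] == 1L)
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with chance agreement from the
#' marginal products. The confidence interval uses the large-sample standard
#' error of the kappa estimate (Fleiss, Cohen & Everitt's estimation-form
#' variance; the simpler null-hypothesis form is available via
#' `variance = "null"`) and a normal approximation. When both raters are
#' constant and identical (`p_e = 1`) kappa is undefined and the result is
#' flagged rather than an error.
#'
#' @param ratings A `rating_set` with exactly 2 raters.
#' @param pipeline Pipeline name.
#' @param mode `"overall"` (ranks as unordered categories), `"is_best"` or
#'   `"is_worst"` (binary indicators).
#' @param conf_level Confidence level (default 0.95).
#' @param variance `"estimation"` (default) or `"null"`.
#' @return List: `kappa`, `se`, `ci` (length 2), `p_o`, `p_e`, `n`,
#'   `undefined` flag.
#' @export
cohen_kappa <- function(ratings, pipeline,
                        mode = c("overall", "is_best", "is_worst"),
                        conf_level = 0.95, variance = c("estimation", "null")) {
  mode <- match.arg(mode)
  variance <- match.arg(variance)
  pr <- rating_pair(ratings, pipeline)
  a <- binarize_mode(pr$a, mode, pr$n_ranks)
  b <- binarize_mode(pr$b, mode, pr$n_ranks)
  kappa_from_pair(a, b, conf_level = conf_level, variance = variance)
}

# core kappa computation on two parallel category vectors
kappa_from_pair <- function(a, b, conf_level = 0.95, variance = "estimation") {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- table(factor(a, levels = cats), factor(b, levels = cats))
  p <- tab / n
  p_row <- rowSums(p)
  p_col <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(p_row * p_col)
  if (1 - p_e < 1e-12) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_o = p_o, p_e = p_e, n = n, undefined = TRUE))
  }
  kap <- (p_o - p_e) / (1 - p_e)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (variance == "null") {
    se <- sqrt(p_e / (n * (1 - p_e)))
  } else {
    # Fleiss, Cohen & Everitt large-sample variance of the kappa estimate
    k_ <- length(cats)
    t1 <- 0
    for (i in seq_len(k_))
      t1 <- t1 + p[i, i] * (1 - (p_row[i] + p_col[i]) * (1 - kap))^2
    t2 <- 0
    for (i in seq_len(k_)) for (j in seq_len(k_))
      if (i != j) t2 <- t2 + p[i, j] * (p_col[i] + p_row[j])^2
    t2 <- t2 * (1 - kap)^2
    t3 <- (kap - p_e * (1 - kap))^2
    v <- (t1 + t2 - t3) / (n * (1 - p_e)^2)
    se <- sqrt(max(v, 0))
  }
  list(kappa = unname(kap), se = unname(se),
       ci = unname(c(kap - z * se, kap + z * se)),
       p_o = unname(p_o), p_e = unname(p_e), n = n, undefined = FALSE)
}

#' Best/worst assignment rates per pipeline and rater
#'
#' For every rater and pipeline, the fraction of cases ranked best (rank 1)
#' and worst (last rank), plus the cross-rater average.
#'
#' @param ratings A `rating_set`.
#' @return Data frame: `pipeline`, `rater_id`, `frac_best`, `frac_worst`,
#'   with rows `rater_id = "average"` carrying the cross-rater means.
#' @export
summarize_ratings <- function(ratings) {
  if (!nrow(ratings)) ps_validation_error("rating set is empty")
  n_ranks <- attr(ratings, "n_ranks") %||% max(ratings$rank)
  combos <- unique(ratings[c("pipeline", "rater_id")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- ratings[ratings$pipeline == combos$pipeline[i] &
                   ratings$rater_id == combos$rater_id[i], ]
    data.frame(pipeline = combos$pipeline[i], rater_id = combos$rater_id[i],
               frac_best = mean(sub$rank == 1L),
               frac_worst = mean(sub$rank == n_ranks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(unique(out$pipeline), function(pl) {
    sub <- out[out$pipeline == pl, ]
    data.frame(pipeline = pl, rater_id = "average",
               frac_best = mean(sub$frac_best), frac_worst = mean(sub$frac_worst),
               stringsAsFactors = FALSE)
  }))
  rbind(out, avg)
}

#' Full agreement report for all pipelines
#'
#' Per pipeline: raw percentage agreement in all five modes, and Cohen's
#' kappa (with CI) overall and for the best/worst binarizations.
#'
#' @param ratings A `rating_set` with exactly 2 raters.
#' @param conf_level Confidence level for the kappa CIs.
#' @return Data frame with one row per pipeline.
#' @export
agreement_report <- function(ratings, conf_level = 0.95) {
  pls <- unique(ratings$pipeline)
  rows <- lapply(pls, function(pl) {
    k_all <- cohen_kappa(ratings, pl, "overall", conf_level)
    k_best <- cohen_kappa(ratings, pl, "is_best", conf_level)
    k_worst <- cohen_kappa(ratings, pl, "is_worst", conf_level)
    data.frame(
      pipeline = pl,
      agree_overall = percent_agreement(ratings, pl, "overall"),
      agree_is_best = percent_agreement(ratings, pl, "is_best"),
      agree_is_not_best = percent_agreement(ratings, pl, "is_not_best"),
      agree_is_worst = percent_agreement(ratings, pl, "is_worst"),
      agree_is_not_worst = percent_agreement(ratings, pl, "is_not_worst"),
      kappa_overall = k_all$kappa, kappa_overall_lo = k_all$ci[1L],
      kappa_overall_hi = k_all$ci[2L],
      kappa_best = k_best$kappa, kappa_best_lo = k_best$ci[1L],
      kappa_best_hi = k_best$ci[2L],
      kappa_worst = k_worst$kappa, kappa_worst_lo = k_worst$ci[1L],
      kappa_worst_hi = k_worst$ci[2L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
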