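#' Assemble a predictor table for one predictor group
#'
#' Builds the subjects x predictors matrix for the three nested predictor
#' groups: (1) non-imaging only (demographics + clinical), (2) adding the
#' four conventional imaging features per ROI, (3) adding the remaining
#' radiomic features. In `longitudinal` mode each imaging feature enters at
#' year 0, year 1 and as the year-1 minus year-0 difference; in
#' `baseline_only` mode only year-0 values (and only year-0 clinical
#' measures) are used. Imaging columns are named
#' `<structure>_<m|l>.<y0|y1|diff>.<feature>`.
#'
#' @param features long-format feature table ([extract_cohort_features()]).
#' @param clinical per-subject clinical data.frame
#'   ([cohort_clinical_table()] or equivalent with the same clinical
#'   columns and `outcome_updrs3_y4`).
#' @param group predictor group 1, 2 or 3.
#' @param temporal_mode `"longitudinal"` or `"baseline_only"`.
#' @param registry the feature registry.
#' @return data.frame with a `sex` factor, numeric predictors, the response
#'   column `updrs3_y4`, and attributes `group`, `temporal_mode`,
#'   `clinical_cols`.
#' @export
assemble_predictor_table <- function(features, clinical, group = 3,
                                     temporal_mode = c("longitudinal",
                                                       "baseline_only"),
                                     registry = feature_registry()) {
  temporal_mode <- match.arg(temporal_mode)
  stopifnot(group %in% 1:3)
  clin_cols <- c("age", "sex", "dd_diag", "dd_sympt", "updrs3_y0", "moca_y0")
  if (temporal_mode == "longitudinal") {
    clin_cols <- c(clin_cols, "updrs3_y1", "moca_y1")
  }
  need <- c("subject", clin_cols, "outcome_updrs3_y4")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (cc in need) {
    bad <- is.na(clinical[[cc]])
    if (any(bad)) stop("missing clinical field '", cc, "' for subject(s) ",
                       paste(clinical$subject[bad], collapse = ", "))
  }
  tab <- clinical[, c("subject", clin_cols)]
  tab$sex <- factor(tab$sex, levels = c("F", "M"))

  if (group >= 2) {
    feat_names <- if (group == 2) {
      registry$name[registry$is_conventional]
    } else {
      registry$name
    }
    sel <- features[features$feature %in% feat_names, ]
    sel$colname <- paste0(sel$roi, "_", sel$side_tag, ".", sel$timepoint,
                          ".", sel$feature)
    wide <- stats::reshape(
      sel[, c("subject", "colname", "value")],
      idvar = "subject", timevar = "colname", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    # deterministic column order: roi/side x feature (registry order) x tp
    rois <- sort(unique(paste0(features$roi, "_", features$side_tag)))
    ord <- as.vector(t(outer(rois, feat_names, function(r, f) {
      paste0(r, ".TP.", f)
    })))
    cols_y0 <- sub("TP", "y0", ord, fixed = TRUE)
    cols_y1 <- sub("TP", "y1", ord, fixed = TRUE)
    keep <- if (temporal_mode == "longitudinal") {
      diffs <- as.data.frame(
        as.matrix(wide[cols_y1]) - as.matrix(wide[cols_y0]))
      names(diffs) <- sub("TP", "diff", ord, fixed = TRUE)
      cbind(wide[c("subject", cols_y0, cols_y1)], diffs)
    } else {
      wide[c("subject", cols_y0)]
    }
    tab <- merge(tab, keep, by = "subject", sort = FALSE)
  }
  tab <- merge(tab, clinical[, c("subject", "outcome_updrs3_y4")],
               by = "subject", sort = FALSE)
  names(tab)[names(tab) == "outcome_updrs3_y4"] <- "updrs3_y4"
  rownames(tab) <- tab$subject
  tab$subject <- NULL
  if (anyNA(tab)) stop("predictor table contains missing values")
  n_tp <- if (temporal_mode == "longitudinal") 3L else 1L
  n_feat <- if (group == 1) 0L else if (group == 2) 4L else 92L
  expected <- length(clin_cols) + n_feat * 6L * n_tp + 1L
  if (ncol(tab) != expected) {
    stop(sprintf("predictor table has %d columns, expected %d",
                 ncol(tab), expected))
  }
  structure(tab, group = group, temporal_mode = temporal_mode,
            clinical_cols = clin_cols)
}

#' Unsupervised feature filtering
#'
#' Three passes over the imaging columns (clinical/demographic columns are
#' never dropped): (1) zero-variance columns are removed; (2) columns with
#' low dynamic range, `(p95 - p5) / |median| < dyn_range_min`, are removed;
#' (3) within highly correlated pairs (`|Pearson r| > cor_max`) the later
#' column in table order is removed (greedy, keeping the earliest).
#'
#' @param table a predictor table from [assemble_predictor_table()].
#' @param dyn_range_min dynamic-range threshold (default 0.05).
#' @param cor_max correlation threshold (default 0.95).
#' @return the filtered table (attributes preserved, plus `dropped`).
#' @export
filter_features <- function(table, dyn_range_min = 0.05, cor_max = 0.95) {
  protected <- c(attr(table, "clinical_cols"), "updrs3_y4")
  img <- setdiff(names(table), protected)
  if (!length(img)) return(table)
  kept <- filter_columns(as.matrix(table[img]), dyn_range_min, cor_max)
  if (!length(kept) && length(img)) {
    warning("all imaging columns dropped by filtering; table degenerates ",
            "to non-imaging predictors")
  }
  out <- table[, c(attr(table, "clinical_cols"), kept, "updrs3_y4")]
  structure(out, group = attr(table, "group"),
            temporal_mode = attr(table, "temporal_mode"),
            clinical_cols = attr(table, "clinical_cols"),
            dropped = setdiff(img, kept))
}

# matrix core of the filter; returns the kept column names in order
filter_columns <- function(X, dyn_range_min = 0.05, cor_max = 0.95) {
  n <- nrow(X)
  keep <- rep(TRUE, ncol(X))

  rng <- apply(X, 2, range)
  keep[rng[2, ] - rng[1, ] <= 0 | !is.finite(rng[1, ])] <- FALSE

  if (any(keep)) {
    # type-7 quantiles from one sort per column
    S <- apply(X[, keep, drop = FALSE], 2, sort)
    q7 <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      S[lo, ] + (h - lo) * (S[pmin(lo + 1, n), ] - S[lo, ])
    }
    p5 <- q7(0.05); p50 <- q7(0.5); p95 <- q7(0.95)
    dr <- ifelse(abs(p50) > 0, (p95 - p5) / abs(p50), Inf)
    keep[keep][dr < dyn_range_min] <- FALSE
  }

  if (sum(keep) >= 2) {
    live <- which(keep)
    Z <- scale(X[, live, drop = FALSE])
    C <- abs(crossprod(Z) / (n - 1))
    C[!is.finite(C)] <- 0
    sel <- logical(length(live))
    for (a in seq_along(live)) {
      if (!any(sel)) { sel[a] <- TRUE; next }
      sel[a] <- all(C[a, sel] <= cor_max)
    }
    keep[live[!sel]] <- FALSE
  }
  colnames(X)[keep]
}

#' Forest settings
#'
#' @param n_trees number of bootstrap trees (default 5000; analyses in this
#'   package's examples often use 500 for speed).
#' @param min_node_size minimum node size (default 5).
#' @param candidate_fraction fraction of predictors tried at each split;
#'   `mtry = ceiling(candidate_fraction * p)` (default 1/3).
#' @param seed integer seed making the fit reproducible.
#' @return object of class `forest_settings`.
#' @export
forest_settings <- function(n_trees = 5000L, min_node_size = 5L,
                            candidate_fraction = 1 / 3, seed = 1L) {
  stopifnot(n_trees >= 1, min_node_size >= 1,
            candidate_fraction > 0, candidate_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 candidate_fraction = candidate_fraction,
                 seed = as.integer(seed)),
            class = "forest_settings")
}

#' Fit the random forest
#'
#' Regression forest of `n_trees` trees, each grown on a bootstrap sample
#' of n rows drawn with replacement (so each tree sees ~2/3 unique
#' subjects; the rest are its out-of-bag set, which the model records for
#' permutation importance). Split candidates per node are
#' `ceiling(candidate_fraction * p)`. The tree growing is delegated to
#' ranger; bootstrap bookkeeping and importance are handled by this
#' package.
#'
#' @param table a (filtered) predictor table with response `updrs3_y4`.
#' @param settings a [forest_settings()].
#' @return object of class `dat_forest` wrapping the ranger fit, the inbag
#'   count matrix (rows x trees) and the training table.
#' @export
fit_forest <- function(table, settings = forest_settings()) {
  if (nrow(table) < settings$min_node_size) {
    stop("fewer rows than min_node_size")
  }
  mm <- predictor_matrix(table)
  fit <- fit_forest_xy(mm$X, mm$y, settings)
  inbag <- do.call(cbind, fit$inbag.counts)
  structure(list(fit = fit, inbag = inbag, table = table,
                 predictors = colnames(mm$X), settings = settings),
            class = "dat_forest")
}

# shared ranger call on a numeric predictor matrix
fit_forest_xy <- function(X, y, settings) {
  ranger::ranger(
    x = X, y = y,
    num.trees = settings$n_trees,
    mtry = max(1L, ceiling(settings$candidate_fraction * ncol(X))),
    min.node.size = settings$min_node_size,
    keep.inbag = TRUE, num.threads = 1L, seed = settings$seed)
}

# numeric predictor matrix: the sex factor enters as an indicator column
predictor_matrix <- function(table, predictors = NULL) {
  y <- table[["updrs3_y4"]]
  cols <- if (is.null(predictors)) {
    setdiff(names(table), "updrs3_y4")
  } else predictors
  X <- matrix(0, nrow(table), length(cols),
              dimnames = list(rownames(table), cols))
  for (j in seq_along(cols)) {
    v <- table[[cols[j]]]
    X[, j] <- if (is.factor(v) || is.character(v)) {
      as.numeric(factor(v, levels = c("F", "M"))) - 1
    } else as.numeric(v)
  }
  list(X = X, y = y)
}

#' @export
predict.dat_forest <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    newdata[, object$predictors, drop = FALSE]
  } else {
    predictor_matrix(newdata, object$predictors)$X
  }
  stats::predict(object$fit, data = X, num.threads = 1L,
                 ...)$predictions
}

#' Mean fraction of unique rows per bootstrap sample
#' @param model a `dat_forest`.
#' @return scalar; ~0.632 for n-with-replacement bootstraps.
#' @export
bootstrap_unique_fraction <- function(model) {
  mean(colMeans(model$inbag > 0))
}

#' Out-of-bag permutation importance
#'
#' For each predictor: its values are permuted across subjects (one seeded
#' permutation per predictor), both the permuted and original data are put
#' down all trees, and the score is the average absolute difference between
#' the two predictions over each tree's out-of-bag rows. `%IncMSE` is the
#' companion rendering: the percent increase of out-of-bag MSE under the
#' permutation. Rows are sorted by descending score.
#'
#' @param model a `dat_forest`.
#' @param seed integer seed for the permutations.
#' @return data.frame `predictor`, `score`, `pct_inc_mse`, sorted.
#' @export
permutation_importance <- function(model, seed = 1L) {
  mm <- predictor_matrix(model$table)
  preds <- model$predictors
  y <- mm$y
  oob <- model$inbag == 0
  base <- stats::predict(model$fit, data = mm$X, predict.all = TRUE,
                         num.threads = 1L)$predictions
  base_mse <- mean((rowSums(base * oob) / pmax(1, rowSums(oob)) - y)[
    rowSums(oob) > 0]^2)
  perms <- withr::with_seed(seed, {
    lapply(preds, function(p) sample.int(nrow(mm$X)))
  })
  n <- nrow(mm$X)
  has <- rowSums(oob) > 0
  # batch the permuted datasets so the forest is traversed in few calls
  batches <- split(seq_along(preds), ceiling(seq_along(preds) / 64))
  res <- vector("list", length(preds))
  for (bt in batches) {
    Xb <- mm$X[rep(seq_len(n), length(bt)), , drop = FALSE]
    for (bi in seq_along(bt)) {
      k <- bt[bi]
      rows <- (bi - 1L) * n + seq_len(n)
      Xb[rows, k] <- mm$X[perms[[k]], k]
    }
    pp_all <- stats::predict(model$fit, data = Xb, predict.all = TRUE,
                             num.threads = 1L)$predictions
    for (bi in seq_along(bt)) {
      k <- bt[bi]
      pp <- pp_all[(bi - 1L) * n + seq_len(n), , drop = FALSE]
      dif <- abs(pp - base)
      score <- sum(dif * oob) / sum(oob)
      oobm <- rowSums(pp * oob) / pmax(1, rowSums(oob))
      mse_p <- mean((oobm - y)[has]^2)
      res[[k]] <- c(score = score,
                    pct_inc_mse = 100 * (mse_p - base_mse) / base_mse)
    }
  }
  out <- data.frame(predictor = preds,
                    score = vapply(res, `[[`, 0, "score"),
                    pct_inc_mse = vapply(res, `[[`, 0, "pct_inc_mse"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated absolute prediction errors
#'
#' For each subject the whole modelling pipeline — feature filtering and
#' forest fitting — is re-run on the remaining n-1 subjects (no leakage of
#' the held-out subject into filtering), the held-out subject is predicted,
#' and the absolute error recorded. Delta is the mean absolute error; `se`
#' its standard error over subjects.
#'
#' @param table an (unfiltered) predictor table.
#' @param settings a [forest_settings()]; each fold uses `seed + fold`.
#' @param dyn_range_min,cor_max filtering thresholds, see
#'   [filter_features()].
#' @param filter re-run filtering inside each fold (default TRUE).
#' @return object of class `abs_error_summary`: list with `errors`
#'   (per-subject), `delta`, `se`, `sd`, `n`.
#' @export
loocv_errors <- function(table, settings = forest_settings(),
                         dyn_range_min = 0.05, cor_max = 0.95,
                         filter = TRUE) {
  n <- nrow(table)
  if (n < 2) stop("LOOCV needs at least 2 rows")
  mm <- predictor_matrix(table)
  clin <- intersect(attr(table, "clinical_cols"), colnames(mm$X))
  img <- setdiff(colnames(mm$X), clin)
  errors <- numeric(n)
  for (i in seq_len(n)) {
    kept <- if (filter && length(img)) {
      filter_columns(mm$X[-i, img, drop = FALSE], dyn_range_min, cor_max)
    } else img
    cols <- c(clin, kept)
    fit <- tryCatch(
      fit_forest_xy(mm$X[-i, cols, drop = FALSE], mm$y[-i],
                    forest_settings(settings$n_trees, settings$min_node_size,
                                    settings$candidate_fraction,
                                    settings$seed + i)),
      error = function(e) {
        stop("LOOCV fold ", i, " (", rownames(table)[i], ") failed: ",
             conditionMessage(e))
      })
    pred <- stats::predict(fit, data = mm$X[i, cols, drop = FALSE],
                           num.threads = 1L)$predictions
    errors[i] <- abs(pred - mm$y[i])
  }
  structure(list(errors = errors, delta = mean(errors),
                 se = stats::sd(errors) / sqrt(n), sd = stats::sd(errors),
                 n = n, subjects = rownames(table)),
            class = "abs_error_summary")
}

#' @export
print.abs_error_summary <- function(x, ...) {
  cat(sprintf("LOOCV absolute error: delta = %.2f +/- %.2f (se), n = %d\n",
              x$delta, x$se, x$n))
  invisible(x)
}

#' Compare per-subject absolute errors between two predictor groups
#'
#' Paired two-sided Wilcoxon signed-rank test on the per-subject absolute
#' LOOCV errors (a paired t-test is available via `method`).
#'
#' @param a,b `abs_error_summary` objects over the same subjects in the
#'   same order.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return list with `statistic`, `p_value`, `delta_diff` (delta(a) -
#'   delta(b)) and `method`.
#' @export
compare_error_groups <- function(a, b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(a$errors) != length(b$errors)) {
    stop("error vectors differ in length")
  }
  if (all(a$errors == b$errors)) {
    return(list(statistic = NA_real_, p_value = 1,
                delta_diff = 0, method = method))
  }
  ht <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(a$errors, b$errors, paired = TRUE,
                                        exact = FALSE))
  } else {
    stats::t.test(a$errors, b$errors, paired = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       delta_diff = a$delta - b$delta, method = method)
}

#' Exploratory single regression tree
#'
#' CART-style variance-reduction regression tree, cost-complexity pruned to
#' at most `max_leaves` leaves, with a readable split listing for exploring
#' interactions among predictors.
#'
#' @param table a predictor table.
#' @param max_leaves maximum number of leaves (default 6).
#' @param min_node_size minimum observations per leaf.
#' @return list of class `exploratory_tree` with the pruned `rpart` fit,
#'   `n_leaves`, `root_split` (variable name or NA for a stump), and
#'   `splits` (character rendering).
#' @export
fit_exploratory_tree <- function(table, max_leaves = 6L, min_node_size = 5L) {
  if (nrow(table) < 2 * min_node_size) stop("too few rows for a split")
  fit <- rpart::rpart(updrs3_y4 ~ ., data = table, method = "anova",
                      control = rpart::rpart.control(
                        minbucket = min_node_size, minsplit = 2 * min_node_size,
                        cp = 0, xval = 0, maxsurrogate = 0))
  cps <- fit$cptable
  leaves <- cps[, "nsplit"] + 1
  ok <- which(leaves <= max_leaves)
  target_cp <- cps[max(ok), "CP"]
  pruned <- rpart::prune(fit, cp = target_cp * 1.0000001)
  fr <- pruned$frame
  n_leaves <- sum(fr$var == "<leaf>")
  root_split <- if (fr$var[1] == "<leaf>") NA_character_ else
    as.character(fr$var[1])
  splits <- utils::capture.output(print(pruned))
  structure(list(fit = pruned, n_leaves = n_leaves, root_split = root_split,
                 splits = splits),
            class = "exploratory_tree")
}

#' @export
print.exploratory_tree <- function(x, ...) {
  cat(x$splits, sep = "\n")
  invisible(x)
}
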