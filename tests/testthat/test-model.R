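# model tests run on small synthetic predictor tables built directly,
# plus one tiny imaging cohort for the assembly contract

make_cohort_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(6, small_spec(), seed = 41)
      cache <<- list(features = extract_cohort_features(coh),
                     clinical = cohort_clinical_table(coh))
    }
    cache
  }
})

# plain numeric table for forest-level tests
toy_table <- function(n = 60, p = 5, seed = 1, response = NULL) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n))
    names(X) <- paste0("x", seq_len(p))
    X$updrs3_y4 <- if (is.null(response)) rnorm(n) else response(X)
    attr(X, "clinical_cols") <- names(X)[1]  # protect x1 like a clinical column
    X
  })
}

test_that("predictor tables have the printed column structure and nesting", {
  tb <- make_cohort_tables()
  t1 <- assemble_predictor_table(tb$features, tb$clinical, group = 1)
  t2 <- assemble_predictor_table(tb$features, tb$clinical, group = 2)
  t3 <- assemble_predictor_table(tb$features, tb$clinical, group = 3)
  expect_identical(ncol(t3), 8L + 92L * 6L * 3L + 1L)  # 1664 + response
  expect_identical(ncol(t2), 8L + 4L * 6L * 3L + 1L)
  expect_identical(ncol(t1), 9L)
  expect_true(all(names(t1) %in% names(t2)))
  expect_true(all(names(t2) %in% names(t3)))
  # baseline-only group 1: exactly the six year-0 measures
  b1 <- assemble_predictor_table(tb$features, tb$clinical, group = 1,
                                 temporal_mode = "baseline_only")
  expect_setequal(names(b1), c("age", "sex", "dd_diag", "dd_sympt",
                               "updrs3_y0", "moca_y0", "updrs3_y4"))
  # baseline-only tables carry no diff or y1 columns
  b3 <- assemble_predictor_table(tb$features, tb$clinical, group = 3,
                                 temporal_mode = "baseline_only")
  expect_false(any(grepl("\\.diff\\.|\\.y1\\.", names(b3))))
  # missing clinical field is rejected with the subject id
  cl_bad <- tb$clinical
  cl_bad$moca_y0[2] <- NA
  expect_error(assemble_predictor_table(tb$features, cl_bad, group = 1),
               "moca_y0.*S002")
})

test_that("filtering drops constant, low-range and duplicated columns only", {
  n <- 40
  tab <- withr::with_seed(2, data.frame(
    age = rnorm(n, 60), const = 5,
    narrow = 100 + rnorm(n, sd = 1e-4),
    a = rnorm(n), c = rnorm(n)))
  tab$b <- tab$a  # exact duplicate, later in order
  tab$updrs3_y4 <- withr::with_seed(3, rnorm(n, 27))
  attr(tab, "clinical_cols") <- "age"
  out <- filter_features(tab)
  expect_false("const" %in% names(out))
  expect_false("narrow" %in% names(out))
  expect_true("a" %in% names(out))   # earlier of the pair kept
  expect_false("b" %in% names(out))
  expect_true(all(c("age", "c", "updrs3_y4") %in% names(out)))
  # independent random columns are never removed by the correlation rule
  for (seed in 1:20) {
    t2 <- withr::with_seed(seed, {
      d <- as.data.frame(matrix(rnorm(50 * 8), 50))
      d$updrs3_y4 <- rnorm(50)
      d
    })
    attr(t2, "clinical_cols") <- character(0)
    expect_identical(ncol(filter_features(t2)), 9L)
  }
})

test_that("a constant response yields constant forest predictions", {
  tab <- toy_table(40, response = function(X) rep(27, nrow(X)))
  fit <- fit_forest(tab, forest_settings(n_trees = 100L, seed = 1))
  expect_equal(unname(predict(fit, tab)), rep(27, 40))
})

test_that("bootstrap samples contain about two-thirds unique rows", {
  tab <- toy_table(64)
  fit <- fit_forest(tab, forest_settings(n_trees = 300L, seed = 5))
  expect_equal(bootstrap_unique_fraction(fit), 0.632, tolerance = 0.02)
})

test_that("the forest recovers a pure one-predictor signal", {
  tab <- toy_table(200, p = 5, seed = 6, response = function(X) X$x2)
  fit <- fit_forest(tab, forest_settings(n_trees = 300L, seed = 2))
  oob_pred <- fit$fit$predictions
  r2 <- 1 - mean((oob_pred - tab$updrs3_y4)^2) / var(tab$updrs3_y4)
  expect_gt(r2, 0.9)
})

test_that("permutation importance is seeded, ranks signal, and zeroes unused predictors", {
  tab <- toy_table(120, p = 6, seed = 7,
                   response = function(X) 3 * X$x2 + 0.5 * X$x3)
  tab$x7 <- 5  # constant: no tree can ever split on it
  fit <- fit_forest(tab, forest_settings(n_trees = 200L, seed = 3))
  imp1 <- permutation_importance(fit, seed = 11)
  imp2 <- permutation_importance(fit, seed = 11)
  expect_identical(imp1, imp2)
  expect_identical(imp1$predictor[1], "x2")
  # a predictor used in no tree has exactly zero permutation impact
  expect_identical(imp1$score[imp1$predictor == "x7"], 0)
  # predictors without signal score near zero relative to the top predictor
  irrelevant <- imp1$score[imp1$predictor %in% c("x5", "x6")]
  expect_lt(max(irrelevant), 0.3 * imp1$score[1])
})

test_that("LOOCV: zero error on constant response, null-noise closed form", {
  tab <- toy_table(12, p = 3, response = function(X) rep(10, nrow(X)))
  e <- loocv_errors(tab, forest_settings(n_trees = 50L, seed = 1),
                    filter = FALSE)
  expect_equal(e$delta, 0)
  expect_identical(length(e$errors), 12L)
  # pure-noise response: delta close to E|y - mean| of the noise
  deltas <- vapply(1:5, function(s) {
    tabn <- toy_table(40, p = 3, seed = s + 100)
    loocv_errors(tabn, forest_settings(n_trees = 60L, seed = s),
                 filter = FALSE)$delta
  }, 0)
  # for N(0,1) noise E|err| ~ sqrt(2/pi) ~ 0.8, inflated by forest variance
  expect_gt(mean(deltas), 0.5)
  expect_lt(mean(deltas), 1.4)
})

test_that("in-fold filtering guards against selection leakage", {
  # null response, many noise columns: selecting columns on the full data
  # (outside the folds, using the response) makes LOOCV look optimistic;
  # the honest pipeline must not
  tab <- withr::with_seed(42, {
    d <- as.data.frame(matrix(rnorm(30 * 200), 30))
    d$updrs3_y4 <- rnorm(30)
    d
  })
  attr(tab, "clinical_cols") <- character(0)
  honest <- loocv_errors(tab, forest_settings(n_trees = 100L, seed = 1))
  # deliberately leaked variant: top 20 columns by |cor with the response|,
  # chosen once on all 30 subjects
  cors <- abs(cor(tab[-ncol(tab)], tab$updrs3_y4))
  leaked_cols <- rownames(cors)[order(-cors)][1:20]
  leaked_tab <- tab[, c(leaked_cols, "updrs3_y4")]
  attr(leaked_tab, "clinical_cols") <- character(0)
  leaked <- loocv_errors(leaked_tab, forest_settings(n_trees = 100L, seed = 1),
                         filter = FALSE)
  expect_lt(leaked$delta, honest$delta)
})

test_that("group comparisons behave at the degenerate and shifted extremes", {
  e <- structure(list(errors = c(1, 2, 3, 4), delta = 2.5), class = "abs_error_summary")
  same <- compare_error_groups(e, e)
  expect_equal(same$p_value, 1)
  shifted <- structure(list(errors = e$errors + 5, delta = 7.5),
                       class = "abs_error_summary")
  up <- compare_error_groups(e, shifted)
  # fully consistent shift: minimum attainable p for n = 4 pairs
  expect_equal(up$p_value,
               suppressWarnings(wilcox.test(e$errors, shifted$errors,
                                            paired = TRUE, exact = FALSE)$p.value))
  expect_equal(up$delta_diff, -5)
  expect_error(compare_error_groups(e, structure(list(errors = 1:3),
                                                 class = "abs_error_summary")),
               "length")
  # power at a large, consistent effect: n = 64 pairs, shift ~ N(4, 3)
  hits <- sum(vapply(1:20, function(s) {
    a <- withr::with_seed(s, list(e = abs(rnorm(64, 9, 3))))
    b <- list(errors = a$e + withr::with_seed(s + 500, rnorm(64, 4, 3)))
    a <- structure(list(errors = a$e, delta = mean(a$e)),
                   class = "abs_error_summary")
    b <- structure(list(errors = b$errors, delta = mean(b$errors)),
                   class = "abs_error_summary")
    compare_error_groups(b, a)$p_value < 0.001
  }, TRUE))
  expect_gte(hits, 19)
})

test_that("the exploratory tree prunes to few leaves and finds thresholds", {
  # constant response: a single leaf
  tab <- toy_table(30, p = 3, response = function(X) rep(5, nrow(X)))
  tr <- fit_exploratory_tree(tab)
  expect_identical(tr$n_leaves, 1L)
  expect_true(is.na(tr$root_split))
  # step function: root split recovers the threshold within one gap
  tab2 <- withr::with_seed(8, {
    x <- sort(runif(80, 0, 10))
    d <- data.frame(x1 = x, x2 = rnorm(80),
                    updrs3_y4 = ifelse(x >= 3.6, 40, 15))
    d
  })
  attr(tab2, "clinical_cols") <- character(0)
  tr2 <- fit_exploratory_tree(tab2)
  expect_identical(tr2$root_split, "x1")
  split_val <- tr2$fit$splits[1, "index"]
  below <- max(tab2$x1[tab2$x1 < 3.6]); above <- min(tab2$x1[tab2$x1 >= 3.6])
  expect_gte(split_val, below); expect_lte(split_val, above)
  expect_lte(tr2$n_leaves, 6L)
  # leaf cap respected on a rich response
  tab3 <- toy_table(120, p = 4, seed = 9,
                    response = function(X) X$x1 + X$x2 + rnorm(nrow(X), 0, .2))
  expect_lte(fit_exploratory_tree(tab3, max_leaves = 6L)$n_leaves, 6L)
})

test_that("a dominant baseline motor effect drives the exploratory tree root", {
  tb <- make_cohort_tables()
  cl <- tb$clinical
  # outcome dominated by baseline UPDRS-III
  cl$outcome_updrs3_y4 <- 1.5 * cl$updrs3_y0 + rnorm(nrow(cl), 0, 0.5)
  tab <- assemble_predictor_table(tb$features, cl, group = 1,
                                  temporal_mode = "baseline_only")
  tr <- fit_exploratory_tree(tab, min_node_size = 2L)
  expect_identical(tr$root_split, "updrs3_y0")
})
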