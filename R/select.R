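# Two-stage feature selection: mean-correlation greedy redundancy removal,
# then cross-validated forward selection by training R-squared with
# F-test/VIF reporting.

#' Mean absolute correlation matrix across subjects
#'
#' For each subject a feature-feature Pearson correlation matrix is
#' computed over that subject's windows; entries are averaged (in absolute
#' value) across subjects. A feature constant within a subject contributes
#' missing entries, excluded from the mean. A feature constant for every
#' subject is flagged maximally redundant (correlation 1 with everything).
#'
#' @param table a feature table (see [build_feature_table()]): data frame
#'   with meta columns `subject_id`, `window_index`, `stage`, `severity`,
#'   `label` and one column per feature.
#' @param features optional character vector restricting the columns.
#' @return symmetric matrix with unit diagonal.
#' @export
mean_correlation_matrix <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_columns(table)
  subjects <- unique(table$subject_id)
  p <- length(features)
  acc <- matrix(0, p, p, dimnames = list(features, features))
  cnt <- matrix(0, p, p)
  for (s in subjects) {
    x <- as.matrix(table[table$subject_id == s, features, drop = FALSE])
    if (nrow(x) < 2) next
    cs <- suppressWarnings(abs(cor(x)))
    ok <- is.finite(cs)
    acc[ok] <- acc[ok] + cs[ok]
    cnt <- cnt + ok
  }
  cbar <- acc / cnt
  cbar[cnt == 0] <- 1  # constant-everywhere features: maximally redundant
  diag(cbar) <- 1
  cbar
}

#' Greedy redundancy removal on a mean correlation matrix
#'
#' Iteratively removes the feature with the largest count of
#' above-threshold partners (ties broken by column order, earliest
#' removed first), updating counts after each removal, until no pair
#' exceeds the threshold.
#'
#' @param cbar symmetric mean correlation matrix (e.g. from
#'   [mean_correlation_matrix()]).
#' @param threshold redundancy threshold (default 0.9).
#' @return list `kept`, `removed` (in removal order), `redundancy_counts`
#'   (counts at removal time).
#' @export
greedy_redundancy_removal <- function(cbar, threshold = 0.9) {
  stopifnot(is.matrix(cbar), nrow(cbar) == ncol(cbar))
  p <- nrow(cbar)
  nms <- colnames(cbar)
  adj <- cbar >= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, p)
  removed <- integer(0)
  counts <- integer(0)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    victim <- which.max(deg)  # first index among ties
    removed <- c(removed, victim)
    counts <- c(counts, deg[victim])
    alive[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  list(kept = nms[alive], removed = nms[removed],
       redundancy_counts = as.integer(counts))
}

# Subject-wise fold assignment: all windows of a subject share a fold.
subject_folds <- function(subject_id, k, seed) {
  subjects <- unique(subject_id)
  set.seed(as.integer(seed))
  fold_of <- sample(rep(seq_len(k), length.out = length(subjects)))
  names(fold_of) <- subjects
  fold_of[as.character(subject_id)]
}

rsq <- function(fit, y) {
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Cross-validated forward feature selection
#'
#' Starting from an intercept-only linear model of the response, each step
#' adds the feature maximizing the mean training-fold R-squared across
#' `folds` subject-wise folds, stopping after `k` features. The final
#' model is refit on all rows and reported with per-term coefficient,
#' standard error, t-ratio, p-value and VIF.
#'
#' @param table feature table.
#' @param response `"severity"` (continuous index, default) or `"label"`
#'   (binary coded 0/1).
#' @param features candidate feature names (typically the redundancy-
#'   reduced set); defaults to all feature columns.
#' @param k number of features to select (default 10).
#' @param folds number of subject-wise folds (default 10).
#' @param seed fold-assignment seed.
#' @return `selection_report`: `selected` (entry order), `summary` data
#'   frame (term, estimate, std_error, t_ratio, p_value, vif),
#'   `cv_r2_path` (mean training R-squared at each step) and
#'   `cv_r2_valid` (mean held-out R-squared of the selected model across
#'   the subject-wise folds).
#' @export
forward_select <- function(table, response = c("severity", "label"),
                           features = NULL, k = 10L, folds = 10L, seed = 1L) {
  response <- match.arg(response)
  if (is.null(features)) features <- feature_columns(table)
  if (k > length(features)) stop("k exceeds number of candidate features")
  y <- if (response == "severity") table$severity else
    as.numeric(table$label == "abnormal")
  X <- as.matrix(table[, features, drop = FALSE])
  keep_row <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep_row, , drop = FALSE]
  y <- y[keep_row]
  sid <- table$subject_id[keep_row]
  fold <- subject_folds(sid, folds, seed)
  n <- length(y)

  selected <- character(0)
  path_r2 <- numeric(0)
  train_sets <- lapply(seq_len(folds), function(f) which(fold != f))
  for (step in seq_len(k)) {
    cand <- setdiff(features, selected)
    base_cols <- X[, selected, drop = FALSE]
    best <- NA_character_; best_r2 <- -Inf
    for (f_name in cand) {
      xs <- cbind(1, base_cols, X[, f_name])
      r2s <- vapply(train_sets, function(tr) {
        yy <- y[tr]
        fit <- .lm.fit(xs[tr, , drop = FALSE], yy)
        1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
      }, numeric(1))
      m <- mean(r2s)
      if (is.finite(m) && m > best_r2) { best_r2 <- m; best <- f_name }
    }
    selected <- c(selected, best)
    path_r2 <- c(path_r2, best_r2)
  }

  # held-out performance of the selected model: per-fold validation R^2
  valid_r2 <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (all(tr) || !any(tr)) return(NA_real_)
    xs <- cbind(1, X[, selected, drop = FALSE])
    fit <- .lm.fit(xs[tr, , drop = FALSE], y[tr])
    pred <- xs[!tr, , drop = FALSE] %*% fit$coefficients
    1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[!tr]))^2)
  }, numeric(1))

  # final refit on all rows: Table-style statistics
  Xs <- cbind(`(Intercept)` = 1, X[, selected, drop = FALSE])
  fit <- lm.fit(Xs, y)
  p <- ncol(Xs)
  dfree <- n - p
  sigma2 <- sum(fit$residuals^2) / dfree
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * pt(-abs(tval), dfree)
  vif <- if (length(selected) >= 2) {
    c(NA_real_, compute_vif(table = NULL, selected = selected, X = X))
  } else {
    c(NA_real_, NA_real_)
  }
  summary <- data.frame(
    term = colnames(Xs), estimate = est, std_error = se,
    t_ratio = tval, p_value = pval, vif = vif,
    row.names = NULL
  )
  structure(list(selected = selected, summary = summary,
                 cv_r2_path = path_r2,
                 cv_r2_valid = mean(valid_r2, na.rm = TRUE),
                 response = response),
            class = "selection_report")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing feature
#' `j` on the other selected features. Perfect collinearity is reported as
#' `Inf`.
#'
#' @param table feature table (ignored when `X` is given).
#' @param selected feature names (>= 2).
#' @param X optional numeric matrix with the selected columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(table, selected, X = NULL) {
  if (is.null(X)) X <- as.matrix(table[, selected, drop = FALSE])
  X <- X[stats::complete.cases(X), selected, drop = FALSE]
  if (length(selected) < 2) stop("need at least 2 selected features")
  if (nrow(X) <= length(selected)) stop("need more rows than features")
  out <- vapply(selected, function(j) {
    yy <- X[, j]
    xx <- cbind(1, X[, setdiff(selected, j), drop = FALSE])
    fit <- .lm.fit(xx, yy)
    r2 <- 1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  pmax(out, 1)
}

#' Serialize a selection report as CSV
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_selection_report <- function(report, path) {
  write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}
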