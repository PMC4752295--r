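# Labeling, severity indexing, nested cross-validated linear-SVM
# classification, metric aggregation with confidence intervals, and the
# comparison experiments (feature sets, window sizes, reduced rankings,
# severity regression).

SEVERITY_LEVELS <- c(0, 0.2, 0.4, 0.6, 0.8)

#' Label scheme for a subject's ordered stages
#'
#' With `L` stages indexed 0..L-1 (0 = baseline, recovery excluded
#' upstream): stages `0..ceiling(L/2)-1` are `normal`, stages up to `L-2`
#' are `abnormal`, and the final stage (decompensation onset) is excluded
#' from labeled data (`NA`). The continuous severity index is
#' `stage/(L-1)` (0 at baseline, 1 at the final stage) quantized half-up
#' to the five levels 0, 0.2, ..., 0.8 (capped at 0.8); for stage counts
#' `L >= 5` the final retained stage maps to 0.8.
#'
#' @param stages ordered stage indices present for the subject
#'   (0-based, baseline first), or a single integer stage count.
#' @return data frame: `stage`, `label` (`normal` / `abnormal` / `NA`),
#'   `severity` (quantized), `severity_cont`; attribute `usable` is FALSE
#'   when the abnormal class is empty.
#' @export
make_labels <- function(stages) {
  if (length(stages) == 1L) stages <- 0:(stages - 1L)
  stages <- sort(unique(as.integer(stages)))
  L <- length(stages)
  if (L < 2) stop("need at least 2 stages")
  n_normal <- ceiling(L / 2)
  label <- rep(NA_character_, L)
  label[seq_len(n_normal)] <- "normal"
  if (L - 1 > n_normal) label[(n_normal + 1):(L - 1)] <- "abnormal"
  sev_cont <- (stages - stages[1]) / (stages[L] - stages[1])
  sev <- pmin(floor(sev_cont / 0.2 + 0.5) * 0.2, 0.8)
  sev[1] <- 0
  out <- data.frame(stage = stages, label = label,
                    severity = sev, severity_cont = sev_cont)
  attr(out, "usable") <- any(label == "abnormal", na.rm = TRUE)
  out
}

# ---- linear SVM (L2-regularized squared-hinge primal, L-BFGS) ----------

# Train on standardized x (n x p), y in {-1, +1}. Returns w (p) and b.
# The squared-hinge term is averaged over samples so that duplicating
# every row leaves the fitted machine (and all fold metrics) unchanged.
svm_linear_fit <- function(x, y, cost) {
  n <- nrow(x); p <- ncol(x)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- 1 - y * (x %*% w + b)
    0.5 * sum(w^2) + cost / n * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- as.numeric(1 - y * (x %*% w + b))
    act <- m > 0
    gw <- w - 2 * cost / n * as.numeric(t(x[act, , drop = FALSE]) %*% (y[act] * m[act]))
    gb <- -2 * cost / n * sum(y[act] * m[act])
    c(gw, gb)
  }
  o <- optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
             control = list(maxit = 500, factr = 1e4))
  list(w = o$par[1:p], b = o$par[p + 1])
}

svm_decision <- function(model, x) as.numeric(x %*% model$w + model$b)

standardizer <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
apply_standardizer <- function(std, x) sweep(sweep(x, 2, std$mu), 2, std$sd, "/")

classification_metrics <- function(scores, y01) {
  pred <- as.integer(scores > 0)
  tp <- sum(pred == 1 & y01 == 1); tn <- sum(pred == 0 & y01 == 0)
  fp <- sum(pred == 1 & y01 == 0); fn <- sum(pred == 0 & y01 == 1)
  c(auc = auc_score(scores, y01),
    accuracy = 100 * (tp + tn) / length(y01),
    sensitivity = 100 * tp / max(tp + fn, 1),
    specificity = 100 * tn / max(tn + fp, 1))
}

#' Nested cross-validated linear SVM
#'
#' Outer 10-fold subject-wise cross-validation. Within each outer fold the
#' non-validation subjects are split into inner subject-wise folds over
#' which each cost value in `C_grid` is scored by mean AUC; the winning C
#' is refit on all non-validation rows and evaluated on the held-out
#' fold. Features are standardized with non-validation statistics only.
#' No subject ever crosses a train/validation boundary (hard assertion).
#'
#' @param table feature table with `label` in `normal` / `abnormal`
#'   (rows with `NA` label are dropped).
#' @param feature_group feature names to use.
#' @param seed fold-assignment seed.
#' @param C_grid cost grid (default `2^seq(-6, 8, 2)`; the
#'   squared-hinge loss is per-sample averaged, so C is scale-free in n).
#' @param outer_folds,inner_folds fold counts (default 10).
#' @return `cv_report`: `folds` data frame (fold, auc, accuracy,
#'   sensitivity, specificity, chosen_C, n), `mean`, `ci95` (t-based
#'   half-widths), `n`.
#' @export
nested_cv_svm <- function(table, feature_group = NULL, seed = 1L,
                          C_grid = 2^seq(-6, 8, by = 2),
                          outer_folds = 10L, inner_folds = 10L) {
  if (is.null(feature_group)) feature_group <- feature_columns(table)
  tab <- table[!is.na(table$label), , drop = FALSE]
  X <- as.matrix(tab[, feature_group, drop = FALSE])
  ok <- stats::complete.cases(X)
  tab <- tab[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  y01 <- as.integer(tab$label == "abnormal")
  if (length(unique(y01)) < 2) stop("both classes must be present")
  sid <- as.character(tab$subject_id)
  if (length(unique(sid)) < outer_folds) {
    stop("need at least ", outer_folds, " subjects for subject-wise folds")
  }
  y <- ifelse(y01 == 1, 1, -1)

  fold_ok <- FALSE
  attempt <- 0
  while (!fold_ok) {
    fold <- subject_folds(sid, outer_folds, child_seed(seed, attempt))
    fold_ok <- all(vapply(seq_len(outer_folds), function(f) {
      length(unique(y01[fold == f])) == 2
    }, logical(1)))
    attempt <- attempt + 1
    if (attempt > 50 && !fold_ok) {
      warning("could not balance all outer folds; proceeding")
      break
    }
  }
  if (attempt > 1) message("outer folds reshuffled ", attempt - 1, " time(s)")

  res <- data.frame()
  for (f in seq_len(outer_folds)) {
    val <- fold == f
    stopifnot(length(intersect(unique(sid[val]), unique(sid[!val]))) == 0)
    Xtr <- X[!val, , drop = FALSE]; ytr <- y[!val]
    std <- standardizer(Xtr)
    Xtr_s <- apply_standardizer(std, Xtr)
    if (length(C_grid) > 1L) {
      ifold <- subject_folds(sid[!val], inner_folds, child_seed(seed, 100 + f))
      mean_auc <- vapply(C_grid, function(C) {
        aucs <- vapply(seq_len(inner_folds), function(g) {
          itr <- ifold != g
          if (length(unique(ytr[!itr])) < 2 || length(unique(ytr[itr])) < 2) {
            return(NA_real_)
          }
          m <- svm_linear_fit(Xtr_s[itr, , drop = FALSE], ytr[itr], C)
          auc_score(svm_decision(m, Xtr_s[!itr, , drop = FALSE]),
                    as.integer(ytr[!itr] == 1))
        }, numeric(1))
        mean(aucs, na.rm = TRUE)
      }, numeric(1))
      C_best <- C_grid[which.max(mean_auc)]
    } else {
      C_best <- C_grid[1]
    }
    model <- svm_linear_fit(Xtr_s, ytr, C_best)
    Xva_s <- apply_standardizer(std, X[val, , drop = FALSE])
    met <- classification_metrics(svm_decision(model, Xva_s), y01[val])
    res <- rbind(res, data.frame(fold = f, t(met), chosen_C = C_best,
                                 n = sum(val)))
  }
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  structure(list(
    folds = res,
    mean = vapply(metrics, function(m) mean(res[[m]]), numeric(1)),
    ci95 = vapply(metrics, function(m) t_ci_halfwidth(res[[m]]), numeric(1)),
    n = nrow(tab)
  ), class = "cv_report")
}

#' Compare two cross-validation reports with a Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U on the fold-level AUCs (and accuracies), with
#' a significance flag at `alpha` (default 0.01).
#'
#' @param report_a,report_b `cv_report` objects.
#' @param alpha significance level.
#' @param metric fold metric to compare (default both auc and accuracy).
#' @return data frame: metric, U statistic, p value, significant flag.
#' @export
compare_feature_sets <- function(report_a, report_b, alpha = 0.01,
                                 metric = c("auc", "accuracy")) {
  out <- lapply(metric, function(m) {
    a <- report_a$folds[[m]]; b <- report_b$folds[[m]]
    if (length(a) < 3 || length(b) < 3) stop("need >= 3 folds per side")
    wt <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    data.frame(metric = m, U = unname(wt$statistic), p_value = wt$p.value,
               significant = wt$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Window-size sweep comparison
#'
#' Re-runs the full feature-extraction and nested-CV pipeline for each
#' window size and for both feature groups ("presented" = morphology +
#' taut string + DTCWT; "typical HRV" = the 10 traditional indices).
#' Sizes exceeding the shortest subject's beat count are skipped with a
#' warning.
#'
#' @param cohort list of `ecg_record`.
#' @param sizes beat counts (default `seq(30, 240, 30)`).
#' @param seed seed forwarded to [nested_cv_svm()].
#' @param ... forwarded to [build_feature_table()].
#' @return data frame: size, feature set, n, mean/CI of each metric.
#' @export
evaluate_window_size_sweep <- function(cohort, sizes = seq(30, 240, by = 30),
                                       seed = 1L, ...) {
  out <- data.frame()
  for (sz in sizes) {
    tab <- tryCatch(build_feature_table(cohort, beats_per_window = sz, ...),
                    error = function(e) NULL)
    if (is.null(tab) || sum(!is.na(tab$label)) < 20) {
      warning("window size ", sz, " skipped (insufficient windows)")
      next
    }
    lab <- tab$label[!is.na(tab$label)]
    if (length(unique(lab)) < 2) {
      warning("window size ", sz, " skipped (single labeled class)")
      next
    }
    # use only features observed for every labeled window (higher-moment
    # statistics can be undefined on degenerate components)
    lab_rows <- !is.na(tab$label)
    complete_feat <- function(nms) {
      nms[vapply(nms, function(f) all(is.finite(tab[[f]][lab_rows])),
                 logical(1))]
    }
    groups <- list(
      presented = complete_feat(intersect(presented_feature_names(), names(tab))),
      typical_hrv = complete_feat(intersect(hrv_feature_names(), names(tab)))
    )
    for (g in names(groups)) {
      rep_g <- tryCatch(nested_cv_svm(tab, groups[[g]], seed = seed),
                        error = function(e) {
                          warning("window size ", sz, " (", g, ") skipped: ",
                                  conditionMessage(e))
                          NULL
                        })
      if (is.null(rep_g)) next
      out <- rbind(out, data.frame(
        size = sz, features = g, n = rep_g$n,
        auc = rep_g$mean["auc"], auc_ci = rep_g$ci95["auc"],
        accuracy = rep_g$mean["accuracy"], accuracy_ci = rep_g$ci95["accuracy"],
        sensitivity = rep_g$mean["sensitivity"],
        specificity = rep_g$mean["specificity"],
        row.names = NULL
      ))
    }
  }
  out
}

#' Reduced-feature-set performance curve
#'
#' Re-runs [nested_cv_svm()] on each prefix of a feature ranking
#' (top 2, 4, ..., 10 by default).
#'
#' @param table feature table.
#' @param ranked ranked feature names (best first, length >= max size).
#' @param sizes prefix sizes.
#' @param seed seed.
#' @return named list of `cv_report`, one per size.
#' @export
reduced_featureset_curve <- function(table, ranked, sizes = c(2, 4, 6, 8, 10),
                                     seed = 1L) {
  stopifnot(length(ranked) >= max(sizes))
  out <- lapply(sizes, function(k) {
    nested_cv_svm(table, ranked[seq_len(k)], seed = seed)
  })
  names(out) <- paste0("top", sizes)
  out
}

#' Severity linear-regression analysis
#'
#' Ordinary least squares of the quantized severity index on the selected
#' features; reports the mean predicted severity (with 95% CI) at each
#' actual level. With uninformative features every level's prediction
#' collapses to the grand mean (0.4 for a balanced design).
#'
#' @param table feature table (rows with missing severity dropped).
#' @param selected feature names.
#' @return list: `fit` (lm), `by_level` data frame (severity, n,
#'   predicted, ci95).
#' @export
fit_severity_regression <- function(table, selected) {
  tab <- table[!is.na(table$severity), , drop = FALSE]
  X <- as.matrix(tab[, selected, drop = FALSE])
  ok <- stats::complete.cases(X)
  tab <- tab[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  df <- data.frame(severity = tab$severity, X, check.names = TRUE)
  fit <- lm(severity ~ ., data = df)
  if (any(is.na(coef(fit)))) stop("rank-deficient severity regression")
  pred <- predict(fit)
  lev <- sort(unique(tab$severity))
  by_level <- do.call(rbind, lapply(lev, function(s) {
    p <- pred[tab$severity == s]
    data.frame(severity = s, n = length(p), predicted = mean(p),
               ci95 = t_ci_halfwidth(p))
  }))
  list(fit = fit, by_level = by_level)
}
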