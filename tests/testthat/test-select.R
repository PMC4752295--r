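test_that("mean correlation matrix averages per-subject correlations", {
  tab <- synthetic_table(2, 50, 4, seed = 1)
  # duplicated feature under two names
  tab$f001 <- tab$f002
  cb <- mean_correlation_matrix(tab)
  expect_equal(cb["f001", "f002"], 1, tolerance = 1e-12)

  # hand-made two-subject case with per-subject correlations 0.8 and 0.6
  mk <- function(rho, n = 4000, seed) {
    set.seed(seed)
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cbind(x, y)
  }
  a <- mk(0.8, seed = 2); b <- mk(0.6, seed = 3)
  tab2 <- data.frame(subject_id = rep(c("s1", "s2"), each = 4000),
                     window_index = 1, stage = 0, severity = 0,
                     severity_cont = 0, label = "normal",
                     g1 = c(a[, 1], b[, 1]), g2 = c(a[, 2], b[, 2]))
  cb2 <- mean_correlation_matrix(tab2)
  expect_equal(cb2["g1", "g2"],
               mean(c(abs(cor(a)[1, 2]), abs(cor(b)[1, 2]))),
               tolerance = 1e-12)

  # independent features stay near zero
  tab3 <- synthetic_table(20, 50, 6, seed = 4)
  cb3 <- mean_correlation_matrix(tab3)
  expect_lt(max(abs(cb3[upper.tri(cb3)])), 0.2)
})

test_that("greedy redundancy removal removes the most redundant first", {
  cb <- diag(3)
  dimnames(cb) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cb["A", "B"] <- cb["B", "A"] <- 0.95
  cb["A", "C"] <- cb["C", "A"] <- 0.95
  cb["B", "C"] <- cb["C", "B"] <- 0.2
  out <- greedy_redundancy_removal(cb, 0.9)
  expect_identical(out$removed, "A")
  expect_setequal(out$kept, c("B", "C"))

  # nothing above threshold: nothing removed
  cb0 <- diag(4) * 0 + 0.5; diag(cb0) <- 1
  dimnames(cb0) <- list(letters[1:4], letters[1:4])
  expect_length(greedy_redundancy_removal(cb0, 0.9)$removed, 0)
})

test_that("removal result is clean, idempotent and rescans exhaustively", {
  set.seed(5)
  for (k in 1:5) {
    p <- 60
    base <- matrix(rnorm(500 * 15), 500, 15)
    X <- base[, sample(15, p, replace = TRUE)] + matrix(rnorm(500 * p, 0, 0.2), 500, p)
    colnames(X) <- sprintf("v%02d", 1:p)
    cb <- abs(cor(X)); diag(cb) <- 1
    out <- greedy_redundancy_removal(cb, 0.9)
    sub <- cb[out$kept, out$kept, drop = FALSE]
    diag(sub) <- 0
    expect_lt(max(sub), 0.9)  # exhaustive post-hoc scan
    again <- greedy_redundancy_removal(cb[out$kept, out$kept], 0.9)
    expect_length(again$removed, 0)
    expect_setequal(union(out$kept, out$removed), colnames(cb))
  }
})

test_that("forward selection recovers planted features and reports stats", {
  hits <- 0
  for (seed in 1:10) {
    tab <- synthetic_table(20, 12, 100, seed = seed)
    set.seed(seed + 1000)
    planted <- c("f001", "f002", "f003")
    tab$severity <- 3 * tab$f001 + 3 * tab$f002 + 3 * tab$f003 + rnorm(nrow(tab))
    rep <- forward_select(tab, k = 6, seed = seed)
    if (all(planted %in% rep$selected[1:6])) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # pure-noise response: held-out R2 of the selected model stays near zero
  r2 <- vapply(1:10, function(seed) {
    tab <- synthetic_table(20, 12, 50, seed = 200 + seed)
    set.seed(seed)
    tab$severity <- rnorm(nrow(tab))
    rep <- forward_select(tab, k = 3, seed = seed)
    rep$cv_r2_valid
  }, numeric(1))
  expect_lte(median(r2), 0.05)

  # single candidate, k = 1: OLS slope recovered
  tab1 <- synthetic_table(10, 6, 1, seed = 7)
  tab1$severity <- 2 + 0.5 * tab1$f001 + rnorm(60, 0, 0.1)
  rep1 <- forward_select(tab1, k = 1, folds = 5, seed = 1)
  expect_identical(rep1$selected, "f001")
  ols <- coef(lm(severity ~ f001, data = tab1))
  expect_equal(rep1$summary$estimate, unname(ols), tolerance = 1e-9)
  expect_error(forward_select(tab1, k = 5), "exceeds")
})

test_that("forward selection is deterministic given the seed", {
  tab <- synthetic_table(15, 10, 40, seed = 42)
  tab$severity <- 2 * tab$f005 + rnorm(nrow(tab))
  a <- forward_select(tab, k = 4, seed = 9)
  b <- forward_select(tab, k = 4, seed = 9)
  expect_identical(a$selected, b$selected)
  expect_identical(a$summary, b$summary)
})

test_that("VIF follows the closed form", {
  set.seed(8)
  n <- 5000
  x <- rnorm(n); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  tab <- data.frame(subject_id = "s", window_index = 1, stage = 0,
                    severity = 0, severity_cont = 0, label = "normal",
                    a = x, b = y, c = rnorm(n))
  v <- compute_vif(tab, c("a", "b"))
  r2 <- cor(x, y)^2
  expect_equal(unname(v["a"]), 1 / (1 - r2), tolerance = 1e-9)
  expect_gt(v["a"], 4); expect_lt(v["a"], 7)  # ~5.26 at rho = 0.9

  # orthogonal features: VIF -> 1
  vo <- compute_vif(tab, c("a", "c"))
  expect_lt(max(vo), 1.01)

  # duplicated feature: infinite VIF
  tab$d <- tab$a
  expect_true(all(is.infinite(compute_vif(tab, c("a", "d")))))
  expect_error(compute_vif(tab, "a"), "at least 2")
})
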