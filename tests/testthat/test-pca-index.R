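test_that("PCA solutions match a direct eigendecomposition of the correlation matrix", {
  set.seed(101)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  Z <- standardize_columns(X)
  sol <- fit_pca(Z, 4)

  ed <- eigen(cor(X), symmetric = TRUE)
  expect_equal(sol$eigenvalues, ed$values, tolerance = 1e-8)
  for (a in 1:4) {
    expect_lt(min(sum((sol$loadings[, a] - ed$vectors[, a])^2),
                  sum((sol$loadings[, a] + ed$vectors[, a])^2)), 1e-16)
  }
  expect_equal(crossprod(sol$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(sol$eigenvalues) <= 1e-12))
  expect_error(fit_pca(Z, 7), "k must be")
})

test_that("two perfectly correlated variables put all variance on PC1", {
  x <- rnorm(30)
  Z <- standardize_columns(cbind(a = x, b = 2 * x + 3))
  sol <- fit_pca(Z, 1)
  expect_equal(sol$prop_variance[1], 1, tolerance = 1e-8)
})

test_that("high-loading classification enforces magnitude and separation thresholds", {
  fake <- structure(list(loadings = rbind(v1 = c(0.20, 0.05),
                                          v2 = c(0.20, 0.18),
                                          v3 = c(0.14, 0.01))),
                    class = "pca_solution")
  flags <- classify_high_loading(fake, high_loading_rule())
  expect_equal(unname(flags["v1", ]), c(TRUE, FALSE))
  expect_equal(unname(flags["v2", ]), c(FALSE, FALSE))   # separation 0.02
  expect_equal(unname(flags["v3", ]), c(FALSE, FALSE))   # magnitude 0.14

  one_pc <- structure(list(loadings = rbind(v1 = 0.2, v2 = 0.1)),
                      class = "pca_solution")
  f1 <- classify_high_loading(one_pc, high_loading_rule())
  expect_equal(unname(f1[, 1]), c(TRUE, FALSE))  # separation vacuous with one PC
})

test_that("threshold reduction keeps the two latent blocks and drops noise", {
  Z <- make_two_block_matrix()
  res <- threshold_pca_index(Z)
  defn <- res$index
  expect_equal(defn$n_score_columns, 2)
  expect_setequal(defn$variable_names, c(paste0("a", 1:6), paste0("b", 1:6)))
  dropped <- unlist(lapply(res$trace$iterations, `[[`, "dropped"))
  expect_setequal(dropped, paste0("noise", 1:4))
  # scores are usable downstream
  sc <- apply_index(defn, Z[, defn$variable_names])
  expect_equal(ncol(sc), 2)
})

test_that("threshold reduction is invariant to variable order", {
  Z <- make_two_block_matrix(n = 800, seed = 7)
  res1 <- threshold_pca_index(Z)
  set.seed(1); perm <- sample(ncol(Z))
  res2 <- threshold_pca_index(Z[, perm])
  expect_setequal(res1$index$variable_names, res2$index$variable_names)
  s1 <- apply_index(res1$index, Z[, res1$index$variable_names])
  s2 <- apply_index(res2$index, Z[, res2$index$variable_names])
  for (a in 1:2) {
    expect_equal(abs(cor(s1[, a], s2[, a])), 1, tolerance = 1e-8)
  }
})

test_that("a first pass with no droppable variables terminates immediately", {
  # 6-variable block on PC1 and 3-variable block on PC2: the k = 2 solution
  # already fails (PC2 has < 4 high loadings) but every variable is high on
  # one of the PCs, so nothing is dropped and the 2-PC solution is returned
  set.seed(12)
  n <- 1500
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:6, function(j) 0.95 * f1 + 0.3 * rnorm(n)),
             sapply(1:3, function(j) 0.8 * f2 + 0.5 * rnorm(n)))
  colnames(X) <- paste0("v", 1:9)
  Z <- standardize_columns(X)
  res <- threshold_pca_index(Z)
  expect_equal(length(res$index$variable_names), 9)
  expect_equal(res$index$n_score_columns, 2)
  expect_false(res$trace$warned)
  expect_equal(length(res$trace$iterations), 1)
})

test_that("first-PC index recovers a single generating factor", {
  set.seed(33)
  n <- 300
  f <- rnorm(n)
  X <- sapply(c(1, -2, 0.5, 3), function(a) a * f)
  colnames(X) <- paste0("v", 1:4)
  Z <- standardize_columns(X)
  defn <- first_pc_index(Z)
  sc <- apply_index(defn, Z)
  expect_equal(abs(cor(sc[, 1], f)), 1, tolerance = 1e-8)
  sol <- fit_pca(Z, 1)
  expect_equal(var(sc[, 1]), sol$eigenvalues[1], tolerance = 1e-8)
})

test_that("supervised direction equals the response-covariance closed form", {
  set.seed(44)
  n <- 100
  Z <- standardize_columns(matrix(rnorm(n * 5), n, 5,
                                  dimnames = list(NULL, paste0("v", 1:5))))
  y <- rbinom(n, 1, 0.4)
  defn <- supervised_pca_index(Z, y)
  v <- drop(crossprod(Z, y - mean(y)))
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  expect_equal(drop(defn$loadings), v, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(supervised_pca_index(Z, rep(1, n)), "constant")
})

test_that("supervised PCA loads most on the only informative column", {
  set.seed(55)
  n <- 2000
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rbinom(n, 1, plogis(1.5 * X[, 3]))
  defn <- supervised_pca_index(standardize_columns(X), y)
  expect_equal(which.max(abs(defn$loadings)), 3L, ignore_attr = TRUE)
})

test_that("index application is the stored linear projection", {
  L <- matrix(c(0.5, 0.3, 0.2), ncol = 1,
              dimnames = list(c("a", "b", "c"), "PC1"))
  defn <- aceindex:::new_index_definition("first_pc", L, c("a", "b", "c"))
  Z <- rbind(c(2, 0, 5), c(0, 0, 0))
  colnames(Z) <- c("a", "b", "c")
  sc <- apply_index(defn, Z)
  expect_equal(drop(sc), c(2.0, 0.0))
  expect_equal(apply_index(defn, 3 * Z), 3 * sc)
  colnames(Z) <- c("a", "b", "d")
  expect_error(apply_index(defn, Z), "missing.*c")
})

test_that("all three PCA methods agree on rank-one data with outcome driven by the factor", {
  set.seed(66)
  n <- 400
  f <- rnorm(n)
  X <- outer(f, c(1, 2, -1, 0.5))
  colnames(X) <- paste0("v", 1:4)
  Z <- standardize_columns(X)
  y <- rbinom(n, 1, plogis(f))
  s1 <- apply_index(first_pc_index(Z), Z)[, 1]
  s2 <- apply_index(supervised_pca_index(Z, y), Z)[, 1]
  s3 <- suppressWarnings(apply_index(threshold_pca_index(Z)$index, Z))[, 1]
  expect_equal(abs(cor(s1, s2)), 1, tolerance = 1e-8)
  expect_equal(abs(cor(s1, s3)), 1, tolerance = 1e-8)
})

test_that("index definitions serialize and restore bit-identically", {
  Z <- make_two_block_matrix(n = 300, seed = 2)
  defn <- first_pc_index(Z)
  path <- withr::local_tempfile(fileext = ".json")
  write_index_definition(defn, path)
  back <- read_index_definition(path)
  expect_identical(back$method, defn$method)
  expect_identical(back$variable_names, defn$variable_names)
  expect_identical(unname(back$loadings), unname(defn$loadings))
  expect_identical(apply_index(back, Z), apply_index(defn, Z))
})
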