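test_that("RBF kernel has the required pointwise properties", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.5), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), 0.1), exp(-0.1 * 25))
  # symmetry and decay
  expect_equal(rbf_kernel(c(1, 5), c(-2, 0), 0.3),
               rbf_kernel(c(-2, 0), c(1, 5), 0.3))
  expect_lt(rbf_kernel(0, 100, 1), 1e-100)
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  expect_error(svm_params(-1, 1), "C")
})

test_that("a minimal separable pair is classified correctly at large C", {
  ds <- tibble::tibble(label = c("A", "B"), f1 = c(0, 1))
  m <- train_svm(ds, svm_params(1000, 1))
  expect_equal(predict(m, ds), c("A", "B"))
})

test_that("separable blobs reach 100% training accuracy at large C", {
  ds <- make_blob_dataset(20, list(c(0, 0), c(8, 8)), sd = 0.5, seed = 10)
  m <- train_svm(ds, svm_params(10, 1))
  expect_equal(mean(predict(m, ds) == ds$label), 1)
})

test_that("trained models satisfy the dual box and equality constraints", {
  for (s in 1:5) {
    ds <- make_blob_dataset(15, list(c(0, 0), c(2, 1), c(-2, 3)), sd = 1.2,
                            labels = c("A", "B", "C"), seed = s)
    params <- svm_params(C = c(0.5, 2, 10, 50, 1)[s], gamma = 0.8)
    m <- train_svm(ds, params)
    expect_true(check_dual_constraints(m, tol = 1e-6))
    expect_lte(max(abs(m$dual_coefs)), params$C + 1e-6)
  }
})

test_that("predict agrees with a brute-force dual solution on small instances", {
  skip_if_not_installed("kernlab")
  for (s in 1:6) {
    withr::with_seed(s, {
      n <- sample(8:20, 1)
      x <- matrix(rnorm(n), ncol = 1)
      y <- ifelse(x[, 1] + rnorm(n, sd = 0.3) > 0, "pos", "neg")
    })
    if (length(unique(y)) < 2) next
    C <- c(1, 5, 10, 2, 100, 0.5)[s]
    gamma <- c(1, 0.5, 2, 1, 0.3, 1)[s]
    ds <- tibble::tibble(label = y, f1 = x[, 1])
    m <- train_svm(ds, svm_params(C, gamma))
    # oracle works in the model's standardized space so both solve the
    # same optimization problem
    xs <- (x - m$scaler$center) / m$scaler$scale
    oracle <- oracle_binary_svm(xs, y, C, gamma)
    probe <- matrix(seq(min(x) - 1, max(x) + 1, length.out = 40), ncol = 1)
    probe_s <- (probe - m$scaler$center) / m$scaler$scale
    mine <- predict(m, probe)
    theirs <- oracle$predict(probe_s)
    expect_gte(mean(mine == theirs), 38 / 40)
  }
})

test_that("predictions are invariant to duplication and sample order", {
  ds <- make_blob_dataset(15, list(c(0, 0), c(5, 5)), sd = 0.8, seed = 20)
  m1 <- train_svm(ds, svm_params(5, 0.7))
  probe <- tibble::tibble(f1 = runif(30, -2, 7), f2 = runif(30, -2, 7))
  # duplication of every row
  m2 <- train_svm(dplyr::bind_rows(ds, ds), svm_params(5, 0.7))
  expect_equal(predict(m2, probe), predict(m1, probe))
  # permutation of the sample order
  withr::with_seed(21, perm <- sample.int(nrow(ds)))
  m3 <- train_svm(ds[perm, ], svm_params(5, 0.7))
  expect_equal(predict(m3, probe), predict(m1, probe))
})

test_that("three separable classes are all recovered by one-vs-one voting", {
  ds <- make_blob_dataset(15, list(c(0, 0), c(8, 0), c(0, 8)), sd = 0.6,
                          labels = c("left", "right", "stop"), seed = 30)
  m <- train_svm(ds, svm_params(10, 0.5))
  expect_equal(mean(predict(m, ds) == ds$label), 1)
  sv <- glance(m)
  expect_equal(sv$n_classes, 3L)
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_svm(tibble::tibble(label = c("A", "A"), f1 = 1:2),
                         svm_params(1, 1)), "2 classes")
  expect_error(train_svm(tibble::tibble(label = c("A", "B"), f1 = c(1, Inf)),
                         svm_params(1, 1)), "non-finite")
  ds <- make_blob_dataset(5, seed = 1)
  m <- train_svm(ds, svm_params(1, 1))
  expect_error(predict(m, matrix(1, 1, 5)), "dimension mismatch")
})

test_that("cross-validated fitness is deterministic, perfect on separable data,
           and near chance on shuffled labels", {
  ds <- make_blob_dataset(25, list(c(0, 0), c(9, 9)), sd = 0.5, seed = 40)
  expect_equal(cv_fitness(ds, svm_params(10, 1), 5, seed = 1), 1)
  expect_identical(cv_fitness(ds, svm_params(10, 1), 5, seed = 3),
                   cv_fitness(ds, svm_params(10, 1), 5, seed = 3))

  withr::with_seed(41, {
    null_ds <- tibble::tibble(
      label = sample(rep(c("A", "B"), each = 100)),
      f1 = rnorm(200), f2 = rnorm(200)
    )
  })
  fit <- cv_fitness(null_ds, svm_params(1, 0.5), 5, seed = 2)
  expect_gte(fit, 0.4)
  expect_lte(fit, 0.6)
  expect_error(cv_fitness(ds[1:8, ], svm_params(1, 1), folds = 10), "fewer")
})
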