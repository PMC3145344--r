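# brute-force oracle for the weighted pooled covariance: explicit double sum
sigma_oracle <- function(x, y, w) {
  classes <- names(w)
  num <- matrix(0, ncol(x), ncol(x)); den <- 0
  for (k in classes) {
    xk <- x[y == k, , drop = FALSE]
    mu <- colMeans(xk)
    for (i in seq_len(nrow(xk)))
      num <- num + w[[k]] * tcrossprod(xk[i, ] - mu)
    den <- den + w[[k]] * nrow(xk)
  }
  num / den
}

test_that("equal class weights reproduce the unweighted pooled covariance exactly", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60)
  y <- rep(c("a", "b", "c"), each = 20)
  m_eq <- wlda(x, y, weights = c(a = 1, b = 1, c = 1))
  # unweighted maximum-likelihood pooled covariance, computed directly
  sig <- matrix(0, 3, 3)
  for (k in c("a", "b", "c")) {
    d <- sweep(x[y == k, ], 2, colMeans(x[y == k, ]))
    sig <- sig + crossprod(d)
  }
  expect_equal(m_eq$sigma, sig / 60, tolerance = 1e-14)
})

test_that("weighted covariance matches the brute-force double-sum oracle", {
  set.seed(8)
  x <- matrix(rnorm(50 * 5), 50)
  y <- sample(c("a", "b", "c"), 50, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  w <- c(a = 1, b = 3.5, c = 10)
  m <- wlda(x, y, weights = w)
  expect_equal(m$sigma, sigma_oracle(x, y, w), tolerance = 1e-10)
  expect_equal(m$means["b", ], colMeans(x[y == "b", ]), ignore_attr = TRUE)
})

test_that("degenerate within-class scatter triggers the ridge", {
  x <- matrix(c(0, 0, 2, 2), ncol = 1)
  y <- c("a", "a", "b", "b")
  m <- wlda(x, y, weights = c(a = 1, b = 3))
  expect_true(m$ridge_applied)
  expect_equal(unname(m$means[, 1]), c(0, 2))
  expect_gt(m$sigma[1, 1], 0)
  expect_equal(predict(m, matrix(c(-0.5, 2.4), ncol = 1)), c("a", "b"))
})

test_that("prediction maximizes the linear discriminant (formula oracle)", {
  set.seed(12)
  x <- matrix(rnorm(80 * 2), 80)
  y <- rep(c("a", "b", "c", "d"), each = 20)
  x[y == "b", ] <- x[y == "b", ] + 2
  x[y == "c", 1] <- x[y == "c", 1] - 2
  x[y == "d", 2] <- x[y == "d", 2] + 3
  m <- wlda(x, y)
  xnew <- matrix(rnorm(20 * 2), 20)
  si <- solve(m$sigma)
  f <- sapply(m$classes, function(k) {  # direct evaluation, every class
    mu <- m$means[k, ]
    -0.5 * drop(mu %*% si %*% mu) + xnew %*% si %*% mu
  })
  expect_equal(predict(m, xnew), m$classes[max.col(f, ties.method = "first")])
  expect_equal(unname(predict(m, xnew, type = "scores")), unname(f),
               tolerance = 1e-10)
  # class means classify to their own class when well separated
  expect_equal(predict(m, m$means), m$classes)
})

test_that("identity covariance reduces the rule to nearest class mean", {
  means <- rbind(a = c(0, 0), b = c(4, 0), c = c(0, 4))
  set.seed(3)
  x <- means[rep(1:3, each = 15), ] + matrix(rnorm(90, 0, 0.1), 45)
  y <- rep(c("a", "b", "c"), each = 15)
  m <- wlda(x, y)
  xnew <- matrix(runif(40, -1, 5), 20)
  m$sigma_inv <- diag(2)                 # force Sigma = I in the rule
  nearest <- apply(xnew, 1, function(p)
    rownames(m$means)[which.min(colSums((t(m$means) - p)^2))])
  expect_equal(predict(m, xnew), unname(nearest))
})

test_that("the discriminant rule is translation invariant", {
  set.seed(21)
  x <- matrix(rnorm(60 * 3), 60)
  y <- rep(c("a", "b"), each = 30)
  x[y == "b", ] <- x[y == "b", ] + 1.5
  m1 <- wlda(x, y)
  shift <- c(5, -3, 100)
  m2 <- wlda(sweep(x, 2, shift, "+"), y)
  xnew <- matrix(rnorm(30), 10)
  expect_equal(predict(m1, xnew), predict(m2, sweep(xnew, 2, shift, "+")))
})

test_that("wlda serializes to JSON and back", {
  d <- withr::local_tempdir()
  set.seed(5)
  x <- matrix(rnorm(40 * 2), 40)
  y <- rep(c("N", "V"), each = 20); x[y == "V", ] <- x[y == "V", ] + 2
  m <- wlda(x, y)
  write_wlda_json(m, file.path(d, "m.json"))
  back <- read_wlda_json(file.path(d, "m.json"))
  xnew <- matrix(rnorm(20), 10)
  expect_equal(predict(back, xnew), predict(m, xnew))
  expect_equal(back$sigma, m$sigma, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("missing classes and missing values are refused with names", {
  x <- matrix(rnorm(20), 10); y <- rep("a", 10)
  expect_error(wlda(x, y, weights = c(a = 1, b = 1)), "b")
  x2 <- x; x2[1] <- NA
  expect_error(wlda(x2, rep(c("a", "b"), 5)), "missing")
})

test_that("a separable two-class problem is fit exactly by a linear kernel", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 4, 0.3), ncol = 2))
  y <- rep(c("a", "b"), each = 30)
  m <- wsvm(x, y, degree = 1, cost = 10)
  expect_equal(predict(m, x), y)
})

test_that("one-against-one builds K(K-1)/2 pairwise machines", {
  set.seed(7)
  x <- matrix(rnorm(120 * 2), 120)
  y <- rep(c("a", "b", "c", "d"), each = 30)
  for (k in seq_along(unique(y))) x[y == unique(y)[k], ] <-
    x[y == unique(y)[k], ] + 3 * k
  m <- wsvm(x, y, degree = 1, cost = 1)
  dv <- attr(predict(m$fit, x, decision.values = TRUE), "decision.values")
  expect_equal(ncol(dv), 6)            # 4 classes -> 6 unordered pairs
})

test_that("per-class weighting is equivalent to duplicating minority samples", {
  set.seed(10)
  # overlapping classes so the penalty trade-off actually binds
  x <- rbind(matrix(rnorm(160, 0, 1), ncol = 2),
             matrix(rnorm(24, 1.5, 1), ncol = 2))
  y <- rep(c("a", "b"), c(80, 12))
  mrep <- 5L
  xd <- rbind(x, do.call(rbind, replicate(mrep - 1L, x[y == "b", ], simplify = FALSE)))
  yd <- c(y, rep("b", (mrep - 1L) * 12))
  m_w <- wsvm(x, y, degree = 1, cost = 1, weights = c(a = 1, b = mrep))
  m_d <- wsvm(xd, yd, degree = 1, cost = 1, weights = c(a = 1, b = 1))
  grid <- as.matrix(expand.grid(seq(-2, 3, 0.25), seq(-2, 3, 0.25)))
  colnames(grid) <- colnames(x)
  agree <- mean(predict(m_w, grid) == predict(m_d, grid))
  expect_gt(agree, 0.95)
})

test_that("raising a class weight never hurts that class's training recall", {
  set.seed(1)
  x <- rbind(matrix(rnorm(400, 0), ncol = 2), matrix(rnorm(60, 1.2), ncol = 2))
  y <- rep(c("a", "b"), c(200, 30))
  recalls <- sapply(c(0.2, 1, 5, 25), function(ck) {
    m <- wsvm(x, y, degree = 1, cost = 1, weights = c(a = 1, b = ck))
    mean(predict(m, x)[y == "b"] == "b")
  })
  expect_true(all(diff(recalls) >= -0.02))   # tolerance for solver noise
  # same smoke check for the weighted LDA covariance weighting
  recalls_lda <- sapply(c(1, 5, 25), function(ck) {
    m <- wlda(x, y, weights = c(a = 1, b = ck))
    mean(predict(m, x)[y == "b"] == "b")
  })
  expect_true(all(diff(recalls_lda) >= -0.02))
})

test_that("inverse-prior weights favor minority classes and normalize to K", {
  y <- rep(c("N", "S", "V", "F"), c(900, 20, 70, 10))
  w <- inverse_prior_weights(y, c("N", "S", "V", "F"))
  expect_equal(sum(w), 4)
  expect_true(w[["F"]] > w[["S"]] && w[["S"]] > w[["V"]] && w[["V"]] > w[["N"]])
  expect_error(inverse_prior_weights(y, c("N", "S", "V", "F", "Q")), "Q")
})
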