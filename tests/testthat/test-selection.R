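# discrete plug-in oracle: I = sum_{b,c} p(b,c) log( p(b,c) / (p(b) p(c)) )
mi_plugin_oracle <- function(joint) {
  p <- joint / sum(joint)
  pb <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (b in seq_len(nrow(p))) for (cc in seq_len(ncol(p)))
    if (p[b, cc] > 0) s <- s + p[b, cc] * log(p[b, cc] / (pb[b] * pc[cc]))
  s
}

test_that("histogram MI matches the discrete plug-in double sum exactly", {
  # N = 9 -> 3 bins; x values land in known bins
  x <- c(0, 0, 0, 0.5, 0.5, 0.5, 1, 1, 1)
  y <- c("A", "A", "A", "A", "B", "B", "B", "B", "B")
  joint <- matrix(c(3, 0, 1, 2, 0, 3), nrow = 3, byrow = TRUE)
  got <- histogram_mi(x, y)
  expect_equal(got$n_bins, 3)
  expect_equal(got$mi_nats, mi_plugin_oracle(joint), tolerance = 1e-12)
  # a second joint with a different shape
  x2 <- c(rep(0, 5), rep(0.4, 3), rep(1, 4))
  y2 <- c(rep("A", 4), "B", "A", "B", "B", rep("B", 3), "A")
  j2 <- table(cut(x2, breaks = seq(0, 1, length.out = 4), include.lowest = TRUE), y2)
  expect_equal(histogram_mi(x2, y2)$mi_nats,
               unname(mi_plugin_oracle(unclass(j2))), tolerance = 1e-12)
})

test_that("a deterministic binary relation attains H(y) = ln 2", {
  x <- rep(c(0, 1), each = 100)
  y <- rep(c("n", "v"), each = 100)
  expect_equal(histogram_mi(x, y)$mi_nats, log(2), tolerance = 1e-12)
})

test_that("independent features score below a 3-sigma permutation null", {
  set.seed(42)
  x <- rnorm(2000)
  y <- sample(rep(c("a", "b"), 1000))
  obs <- histogram_mi(x, y)$mi_nats
  null <- replicate(60, histogram_mi(x, sample(y))$mi_nats)
  expect_lt(obs, mean(null) + 3 * sd(null))
})

test_that("MI is nonnegative, bounded by H(y), and zero for constants", {
  expect_equal(histogram_mi(rep(2.5, 50), sample(c("a", "b"), 50, TRUE))$mi_nats, 0)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    x <- rnorm(n)
    y <- sample(c("a", "b", "c"), n, TRUE)
    mi <- histogram_mi(x, y)$mi_nats
    hy <- { p <- table(y) / n; -sum(p * log(p)) }
    expect_gte(mi, 0)
    expect_lte(mi, hy + 1e-12)
  }
  expect_error(histogram_mi(1:3, c("a", "b", "a")), ">= 4")
})

test_that("MI is invariant under strictly monotone affine transforms", {
  set.seed(23)
  x <- rnorm(400)
  y <- ifelse(x + rnorm(400, 0, 0.5) > 0, "p", "q")
  base <- histogram_mi(x, y)$mi_nats
  expect_equal(histogram_mi(3.7 * x + 11, y)$mi_nats, base, tolerance = 1e-12)
  expect_equal(histogram_mi(-2 * x + 5, y)$mi_nats, base, tolerance = 1e-12)
})

test_that("ranking puts a label-encoding feature first; ties keep column order", {
  set.seed(29)
  y <- sample(c("a", "b"), 200, TRUE)
  x <- cbind(n1 = rnorm(200), lab = as.numeric(factor(y)), n2 = rnorm(200),
             lab_dup = as.numeric(factor(y)))
  r <- rank_by_mi(x, y)
  expect_equal(r$name[1], "lab")               # earlier duplicate wins the tie
  expect_equal(r$name[2], "lab_dup")
  expect_equal(r$mi_nats[1], r$mi_nats[2])
})

test_that("stronger class separation wins the MI ranking almost surely", {
  # A: means +/-1, sd 1; B: means +/-0.4, sd 1 -- A separates better
  wins <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    y <- rep(c(0, 1), each = 100)
    a <- rnorm(200, ifelse(y == 1, 1, -1))
    b <- rnorm(200, ifelse(y == 1, 0.4, -0.4))
    r <- rank_by_mi(cbind(A = a, B = b), as.character(y))
    if (r$name[1] == "A") wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("the wrapper picks a perfectly separating feature first", {
  set.seed(33)
  y <- rep(c("a", "b"), each = 60)
  x <- cbind(noise1 = rnorm(120), perfect = ifelse(y == "a", 0, 10) + rnorm(120, 0, 0.01),
             noise2 = rnorm(120), noise3 = rnorm(120))
  tr <- forward_backward(x, y, patient_ids = rep(1:4, 30), seed = 2)
  expect_equal(tr$steps$feature[1], "perfect")
  expect_equal(tr$steps$action[1], "add")
})

test_that("duplicated features are never added (no strict improvement)", {
  set.seed(35)
  y <- rep(c("a", "b"), each = 60)
  f <- ifelse(y == "a", 0, 3) + rnorm(120, 0, 0.5)
  x <- cbind(f1 = f, f1_copy = f, noise = rnorm(120))
  tr <- forward_backward(x, y, patient_ids = rep(1:4, 30), seed = 3)
  expect_false(all(c("f1", "f1_copy") %in% tr$final_set))
})

test_that("accepted wrapper steps never decrease the criterion, and the trace replays", {
  coh <- shared_cohort()
  fm <- coh$fm
  keep <- fm$beats$label %in% c("N", "V")
  x <- fm$x[keep, sample(ncol(fm$x), 40)]
  tr <- forward_backward(x, fm$beats$label[keep], max_features = 5L,
                         patient_ids = fm$beats$record[keep], seed = 4)
  expect_lte(length(tr$final_set), 5L)
  expect_true(all(diff(tr$steps$criterion) >= -1e-12))
  # replaying the steps from the empty set yields final_set
  s <- character(0)
  for (i in seq_len(nrow(tr$steps)))
    s <- if (tr$steps$action[i] == "add") c(s, tr$steps$feature[i]) else
      setdiff(s, tr$steps$feature[i])
  expect_setequal(s, tr$final_set)
})

test_that("selection artifacts serialize to TSV / JSON", {
  d <- withr::local_tempdir()
  set.seed(37)
  y <- rep(c("a", "b"), each = 30)
  x <- cbind(u = rnorm(60), v = ifelse(y == "a", 0, 2) + rnorm(60))
  r <- rank_by_mi(x, y)
  write_mi_ranking(r, file.path(d, "rank.tsv"))
  back <- utils::read.delim(file.path(d, "rank.tsv"))
  expect_equal(back$name, r$name)
  tr <- forward_backward(x, y, patient_ids = rep(1:3, 20), seed = 5,
                         max_features = 2L)
  write_trace_json(tr, file.path(d, "trace.json"))
  j <- jsonlite::read_json(file.path(d, "trace.json"), simplifyVector = TRUE)
  expect_equal(j$final_set, tr$final_set)
})
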