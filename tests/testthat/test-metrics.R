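test_that("sigmoid matches its closed forms and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75, tolerance = 1e-12)
  set.seed(31)
  x <- rnorm(100, sd = 4)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 100), tolerance = 1e-12)
  expect_true(all(diff(sigmoid(seq(-10, 10, 0.1))) > 0))
})

test_that("binary cross-entropy: closed forms, symmetry, shape guard", {
  expect_equal(bce_loss(0.5, 1, "sum"), log(2), tolerance = 1e-9)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5)  # confident & correct, clipped
  set.seed(32)
  p <- runif(50, 0.01, 0.99)
  expect_equal(bce_loss(p, rep(1, 50)), bce_loss(1 - p, rep(0, 50)),
               tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 2, 3)), "shapes differ")
  expect_error(bce_loss(0.5, 0.3), "binary")
})

test_that("mean BCE over constant predictors is minimised at the foreground fraction", {
  set.seed(33)
  y <- as.numeric(runif(200) < 0.3)
  fg <- mean(y)
  grid <- seq(0.05, 0.95, by = 0.005)
  losses <- vapply(grid, function(q) bce_loss(rep(q, 200), y), numeric(1))
  expect_equal(grid[which.min(losses)], grid[which.min(abs(grid - fg))])
})

test_that("binarize uses an inclusive 0.5 boundary and is idempotent", {
  expect_equal(binarize(matrix(0.5, 2, 2), 0.5), matrix(1L, 2, 2))
  expect_equal(as.vector(binarize(c(0.2, 0.8), 0.5)), c(0L, 1L))
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  for (th in c(0.1, 0.5, 1)) expect_equal(binarize(m, th), m)
})

test_that("confusion tallies pixels exhaustively and validates inputs", {
  m <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(unclass(confusion(m, m))[c("fp", "fn")], list(fp = 0, fn = 0))
  cc <- confusion(m, 1 - m)
  expect_equal(cc$tp, 0); expect_equal(cc$tn, 0)
  cc2 <- confusion(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE),
                   matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(unclass(cc2)[1:4], list(tp = 2, fp = 1, fn = 1, tn = 0))
  expect_error(confusion(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("metric formulas and degenerate conventions", {
  c1 <- confusion(matrix(1, 3, 3), matrix(1, 3, 3))
  expect_equal(c(recall(c1), precision(c1), iou(c1), dice(c1)), rep(1, 4))
  disjoint <- confusion(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2))
  expect_equal(iou(disjoint), 0); expect_equal(dice(disjoint), 0)
  cc <- list(tp = 2, fp = 1, fn = 1, tn = 0)
  expect_equal(recall(cc), 2 / 3); expect_equal(precision(cc), 2 / 3)
  expect_equal(iou(cc), 0.5); expect_equal(dice(cc), 2 / 3)
  empty_both <- list(tp = 0, fp = 0, fn = 0, tn = 4)
  expect_equal(c(recall(empty_both), precision(empty_both),
                 iou(empty_both), dice(empty_both)), rep(1, 4))
  empty_pred <- list(tp = 0, fp = 0, fn = 3, tn = 1)
  expect_equal(c(precision(empty_pred), iou(empty_pred), dice(empty_pred)),
               rep(0, 3))
})

test_that("metrics match the brute-force oracle and the Dice/IoU identity holds", {
  set.seed(34)
  for (i in 1:30) {
    pred <- random_mask(16); truth <- random_mask(16)
    o <- oracle_metrics(pred, truth)
    cc <- confusion(pred, truth)
    expect_equal(unclass(cc)[1:4], o[c("tp", "fp", "fn", "tn")])
    expect_equal(dice(cc), o$dice)
    expect_equal(iou(cc), o$iou)
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
    # permutation invariance of pixel order
    perm <- sample(256)
    cp <- confusion(matrix(pred[perm], 16), matrix(truth[perm], 16))
    expect_equal(unclass(cp)[1:4], unclass(cc)[1:4])
  }
})

test_that("dataset evaluation: aggregation modes and pooling arithmetic", {
  p1 <- matrix(c(0.9, 0.9, 0.1, 0.9), 2, 2)
  t1 <- matrix(c(1, 1, 0, 0), 2, 2)
  single_mean <- evaluate_dataset(p1, t1, aggregation = "per-image-mean")
  single_pool <- evaluate_dataset(p1, t1, aggregation = "global-pooled")
  expect_equal(single_mean$dice, single_pool$dice)
  expect_equal(single_mean$dice, dice(confusion(binarize(p1), t1)))

  # two pairs engineered to pool to tp=4, fp=2, fn=2
  pa <- matrix(c(1, 1, 1, 0), 2, 2) * 0.99
  ta <- matrix(c(1, 1, 0, 1), 2, 2)
  pooled <- evaluate_dataset(list(pa, pa), list(ta, ta),
                             aggregation = "global-pooled")
  expect_equal(unclass(pooled$counts)[1:3], list(tp = 4, fp = 2, fn = 2))
  expect_equal(pooled$iou, 0.5)

  # per-image mean of dice 1.0 and dice 0.0
  perfect <- matrix(c(0.9, 0.1), 1, 2); truth <- matrix(c(1, 0), 1, 2)
  wrong <- matrix(c(0.1, 0.9), 1, 2)
  rep2 <- evaluate_dataset(list(perfect, wrong), list(truth, truth))
  expect_equal(rep2$dice, 0.5)
  expect_error(evaluate_dataset(list(p1), list(t1, t1)), "length")
})

test_that("metrics reports serialise to JSON with 4-decimal printing", {
  rep1 <- evaluate_dataset(matrix(0.9, 2, 2), matrix(1, 2, 2))
  js <- jsonlite::fromJSON(metrics_to_json(rep1))
  expect_equal(js$dice, 1)
  expect_equal(js$counts$tp, 4)
  expect_output(print(rep1), "Dice 1\\.0000")
})
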