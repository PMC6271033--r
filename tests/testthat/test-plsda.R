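# two well-separated spectral classes for quick PLS-DA fits
two_class_data <- function(n_per = 40, p = 30, sep = 4, seed = 60) {
  set.seed(seed)
  mu1 <- rnorm(p); mu2 <- mu1; mu2[1:5] <- mu2[1:5] + sep
  X <- rbind(matrix(rnorm(n_per * p), n_per, p) + matrix(mu1, n_per, p, byrow = TRUE),
             matrix(rnorm(n_per * p), n_per, p) + matrix(mu2, n_per, p, byrow = TRUE))
  labels <- rep(c("A", "B"), each = n_per)
  list(X = X, Y = encodeClasses(labels, c("A", "B")), labels = labels)
}

test_that("class encoding is one-hot with the expected counting identities", {
  expect_equal(as.vector(encodeClasses("B", c("A", "B", "C"))), c(0, 1, 0))
  labs <- c("A", "C", "C", "B", "A", "C")
  Y <- encodeClasses(labs, c("A", "B", "C"))
  expect_equal(rowSums(Y), rep(1, 6), ignore_attr = TRUE)
  expect_equal(colSums(Y), c(A = 2, B = 1, C = 3))
  expect_error(encodeClasses("D", c("A", "B")), "unknown label")
  expect_error(encodeClasses("A", "A"), ">= 2")
})

test_that("separable classes give one factor and perfect training accuracy", {
  d <- two_class_data()
  m <- fitPLSDA(d$X, d$Y, max_A = 5, seed = 2)
  expect_equal(nComponents(m), 1L)
  lab <- classifyYhat(predictContinuous(m, d$X))
  expect_equal(m@classes[lab], d$labels)
})

test_that("coefficients reproduce the factorized prediction", {
  d <- two_class_data(sep = 2)
  m <- fitPLSDA(d$X, d$Y, max_A = 4, delta = 0.001, seed = 2)
  A <- nComponents(m)
  # factorized route: T Q' on training rows
  fitted_fact <- tcrossprod(m@scores[, 1:A, drop = FALSE],
                            m@yLoadings[, 1:A, drop = FALSE])
  fitted_fact <- sweep(fitted_fact, 2, m@yMean, "+")
  set.seed(61)
  rows <- sample(nrow(d$X), 10)
  expect_lt(max(abs(predictContinuous(m, d$X[rows, ]) - fitted_fact[rows, ])),
            1e-8)
})

test_that("continuous prediction is the affine map (X - xm) B + ym", {
  d <- two_class_data()
  m <- fitPLSDA(d$X, d$Y, max_A = 3, seed = 2)
  expect_equal(as.vector(predictContinuous(m, matrix(m@xMean, 1))), m@yMean,
               ignore_attr = TRUE)
  Xn <- rand_matrix(5, ncol(d$X), seed = 62)
  oracle <- sweep(Xn, 2, m@xMean) %*% m@coefficients
  oracle <- sweep(oracle, 2, m@yMean, "+")
  expect_equal(predictContinuous(m, Xn), oracle)
  expect_error(predictContinuous(m, Xn[, 1:3]), "band count mismatch")
})

test_that("permuted labels destroy Q2 while Q2 <= R2Y always holds", {
  d <- two_class_data(n_per = 60)
  q2s <- vapply(1:5, function(i) {
    set.seed(200 + i)
    Yp <- d$Y[sample(nrow(d$Y)), ]
    mp <- fitPLSDA(d$X, Yp, max_A = 1, seed = 2)
    q2yCum(mp)[1]
  }, numeric(1))
  expect_lte(median(q2s), 0.05)

  m <- fitPLSDA(d$X, d$Y, max_A = 4, delta = 0.001, seed = 2)
  nEval <- length(q2yCum(m))
  expect_true(all(q2yCum(m) <= m@r2yCum[seq_len(nEval)] + 1e-9))
  expect_true(all(q2yCum(m) <= 1) && all(m@r2yCum <= 1 + 1e-9))
})

test_that("the cut-off rule matches its brute-force oracle, including
           no-class and multi-window ties", {
  expect_equal(classifyYhat(matrix(c(1.02, -0.01, 0.03), 1)), 1L)
  expect_equal(classifyYhat(matrix(c(0.3, 0.4, 0.2), 1)), 0L)
  expect_equal(classifyYhat(matrix(c(0.8, 0.7, 0.1), 1)), 1L)

  vals <- c(-0.5, 0, 0.49, 0.5, 0.8, 1.0, 1.5, 1.51, 2, 0.7)
  grid <- as.matrix(expand.grid(vals, vals, vals))
  got <- classifyYhat(grid, 0.5, 1.5)
  oracle <- apply(grid, 1, function(y) {
    cand <- which(y >= 0.5 & y <= 1.5)
    if (length(cand) == 0) return(0L)
    if (length(cand) == 1) return(cand)
    cand[which.max(y[cand])]
  })
  expect_equal(got, as.integer(oracle))
})

test_that("with infinite cut-offs classification degenerates to argmax", {
  set.seed(63)
  Yh <- matrix(rnorm(300), 100, 3)
  expect_equal(classifyYhat(Yh, -Inf, Inf), max.col(Yh, ties.method = "first"))
})

test_that("composition quantification counts pixels exactly", {
  classes <- c("A", "B", "C")
  labels <- matrix(NA_integer_, 20, 20)
  # region of 100 kept pixels: 90 A, 5 B, 0 C, 5 no_class
  px <- as.vector(outer(1:10, (0:9) * 20, "+"))   # 10x10 block
  labels[px] <- c(rep(1L, 90), rep(2L, 5), rep(0L, 5))
  pred <- new("ClassPredictionImage", classes = classes, labels = labels,
              yhat = array(NA_real_, c(20, 20, 3)))
  lay <- RegionLayout(c("well", "empty"), c("A", "B"), c("rect", "rect"),
                      list(c(0, 0, 10, 10), c(15, 15, 20, 20)))
  rep <- quantifyComposition(pred, lay)
  expect_equal(unlist(rep[1, c("A", "B", "C", "no_class")]),
               c(A = 90, B = 5, C = 0, no_class = 5))
  expect_equal(rep$dominant[1], "A")
  expect_equal(rep$verdict[1], "match")
  expect_equal(sum(rep[1, c("A", "B", "C", "no_class")]), 100, tolerance = 0.01)
  # region with no kept pixels is unevaluable
  expect_equal(rep$verdict[2], "unevaluable")

  # all-no_class region mirrors the "no authentic material" verdict
  labels2 <- labels; labels2[px] <- 0L
  pred2 <- new("ClassPredictionImage", classes = classes, labels = labels2,
               yhat = array(NA_real_, c(20, 20, 3)))
  rep2 <- quantifyComposition(pred2, lay)
  expect_equal(rep2$no_class[1], 100)
  expect_equal(rep2$verdict[1], "no_authentic_material")
})

test_that("composition percentages are equivariant under class relabeling", {
  set.seed(64)
  classes <- c("A", "B", "C")
  labels <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  labels[labels == 3] <- NA_integer_
  lay <- RegionLayout("r", NA, "rect", list(c(2, 2, 18, 18)))
  mk <- function(lv, cls) quantifyComposition(
    new("ClassPredictionImage", classes = cls, labels = lv,
        yhat = array(NA_real_, c(20, 20, 3))), lay)
  r1 <- mk(labels, classes)
  # swap classes 1 and 2
  swapped <- labels
  swapped[labels == 1L] <- 2L; swapped[labels == 2L] <- 1L
  r2 <- mk(swapped, classes)
  expect_equal(r1$A, r2$B)
  expect_equal(r1$B, r2$A)
  expect_equal(r1$no_class, r2$no_class)
})

test_that("external validation summarizes confusion bookkeeping correctly", {
  d <- two_class_data()
  m <- fitPLSDA(d$X, d$Y, max_A = 3, seed = 2)
  val <- externalValidation(m, d$X, region = rep(c("r1", "r2"), each = 40),
                            true_class = d$labels)
  expect_equal(val$region_accuracy, 1)
  expect_equal(val$pixel_accuracy, 1)
  expect_equal(unname(rowSums(val$confusion)), c(40, 40))
  expect_error(externalValidation(m, d$X[0, , drop = FALSE], character(0),
                                  character(0)), "empty test set")
})
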