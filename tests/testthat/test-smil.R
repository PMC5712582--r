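# The sMIL program with all-singleton positive bags reduces to a standard
# soft-margin SVM, and its solver must match an independent generic convex
# solver on random problems; these are the two anchors of correctness.

random_smil_problem <- function(seed) {
  set.seed(seed)
  nb <- sample(4:10, 1)
  p <- sample(2:5, 1)
  X <- NULL; bag <- character(); y <- logical()
  for (b in seq_len(nb)) {
    sz <- sample(1:3, 1)
    pos <- (b %% 2 == 0)
    X <- rbind(X, matrix(stats::rnorm(sz * p, mean = if (pos) 1.2 else -1.2),
                         sz, p))
    bag <- c(bag, rep(paste0("b", b), sz))
    y <- c(y, rep(pos, sz))
  }
  list(X = X, bag = bag, y = y, C = sample(c(0.5, 1, 2), 1))
}

# independent oracle: solve the primal quadratic program over (w, b, slacks)
# with kernlab's generic interior-point QP solver and evaluate its objective
ipop_objective <- function(X, bag, y, C) {
  cons <- ccrel:::smil_constraints(Matrix::Matrix(X, sparse = TRUE), bag, y)
  Z <- as.matrix(cons$Z); yc <- cons$yc; m <- cons$m; mult <- cons$cost
  n <- nrow(Z); p <- ncol(Z)
  # variables v = (w, b, xi): min 1/2 v'Hv + c'v  s.t.  m <= Av
  H <- diag(c(rep(1, p), 1e-8, rep(1e-8, n)))
  cvec <- c(rep(0, p), 0, C * mult)
  A <- cbind(yc * Z, yc, diag(n))
  big <- 1e3
  sol <- kernlab::ipop(c = cvec, H = H, A = A, b = m, r = rep(big, n),
                       l = c(rep(-big, p + 1), rep(0, n)),
                       u = rep(big, p + 1 + n), sigf = 7, maxiter = 400)
  v <- kernlab::primal(sol)
  w <- v[1:p]; b <- v[p + 1]
  slack <- pmax(0, m - yc * (Z %*% w + b))
  0.5 * sum(w^2) + C * sum(mult * slack)
}

test_that("with singleton positive bags the margin constraint reduces to a standard SVM", {
  # (2 - |B|)/|B| = 1 when |B| = 1: identical program to a soft-margin SVM
  set.seed(2)
  n <- 25
  X <- rbind(matrix(stats::rnorm(2 * n, -1.5), n, 2),
             matrix(stats::rnorm(2 * n, 1.5), n, 2))
  y <- rep(c(FALSE, TRUE), each = n)
  fit <- smil(X, bag = as.character(seq_len(2 * n)), y = y, C = 1)

  Xtest <- rbind(matrix(stats::rnorm(50, -1.5), 25, 2),
                 matrix(stats::rnorm(50, 1.5), 25, 2))
  ours <- predict(fit, Xtest, type = "score") > 0

  sv <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  dv <- attr(predict(sv, Xtest, decision.values = TRUE), "decision.values")[, 1]
  sign_flip <- if (colnames(attr(predict(sv, X, decision.values = TRUE),
                                 "decision.values")) == "FALSE/TRUE") -1 else 1
  theirs <- (sign_flip * dv) > 0
  expect_identical(unname(ours), unname(theirs))
  expect_identical(mean(ours == theirs), 1)
})

test_that("solver objective matches the independent QP oracle on random small problems", {
  for (seed in 1:20) {
    prob <- random_smil_problem(seed)
    fit <- smil(prob$X, prob$bag, prob$y, C = prob$C)
    oracle <- ipop_objective(prob$X, prob$bag, prob$y, prob$C)
    expect_lt(abs(fit$objective - oracle), 1e-6)
  }
})

test_that("the 2D toy bag problem is separated correctly", {
  # negatives {(0,0), (0,1)} as singleton-negative instances, one positive
  # bag {(2,0), (2,1)}: boundary must separate the x1 < 1 region
  # bag margin (2 - 2)/2 = 0: the bag mean sits on or above the boundary
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  fit <- smil(X, bag = c("n1", "n2", "p", "p"),
              y = c(FALSE, FALSE, TRUE, TRUE), C = 10)
  s <- as.numeric(X %*% fit$weights) + fit$bias
  expect_true(all(s[1:2] <= -1 + 1e-6))
  expect_gte((s[3] + s[4]) / 2, -1e-8)
  # the separating direction points along x1
  expect_gt(fit$weights[1], 0)
  # and the x1 < 1 region is classified negative
  expect_lt(sum(c(0.99, 0.5) * fit$weights) + fit$bias, 0)
})

test_that("rescaling features rescales weights inversely; predicted signs invariant", {
  # on separable data the solution is the hard-margin one, whose weight
  # vector scales exactly inversely with the feature scale
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(20, -3), 10, 2),
             matrix(stats::rnorm(20, 3), 10, 2))
  bag <- as.character(1:20)
  y <- rep(c(FALSE, TRUE), each = 10)
  f1 <- smil(X, bag, y, C = 100)
  f2 <- smil(X * 5, bag, y, C = 100)
  expect_equal(f2$weights, f1$weights / 5, tolerance = 1e-5)
  s1 <- predict(f1, X, bag, type = "score")
  s2 <- predict(f2, X * 5, bag, type = "score")
  expect_equal(s1, s2, tolerance = 1e-5)
  expect_identical(sign(s1), sign(s2))
})

test_that("training rejects degenerate inputs", {
  X <- matrix(stats::rnorm(10), 5, 2)
  expect_error(smil(X, as.character(1:5), rep(TRUE, 5)), "positive and")
  expect_error(smil(X, c("a", "a", "b", "b", "c"),
                    c(TRUE, FALSE, TRUE, TRUE, FALSE)), "inconsistent")
})

test_that("confidence is a monotone logistic map of hyperplane distance", {
  prob <- random_smil_problem(44)
  fit <- smil(prob$X, prob$bag, prob$y, C = 1)
  s <- seq(-3, 3, by = 0.5)
  conf <- ccrel:::platt_apply(fit$calibration, s)
  expect_true(all(diff(conf) > 0))
  expect_true(all(conf >= 0 & conf <= 1))
})

test_that("a bag on the hyperplane gets confidence 0.5 under symmetric calibration", {
  calib <- ccrel:::platt_fit(c(-2, -1, 1, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ccrel:::platt_apply(calib, 0), 0.5, tolerance = 1e-6)
  # and on separable synthetic data positives average above negatives
  set.seed(5)
  scores <- c(stats::rnorm(30, -1), stats::rnorm(30, 1))
  labs <- rep(c(FALSE, TRUE), each = 30)
  calib2 <- ccrel:::platt_fit(scores, labs)
  conf <- ccrel:::platt_apply(calib2, scores)
  expect_gt(mean(conf[labs]), mean(conf[!labs]))
})

test_that("classification thresholds scores inclusively", {
  expect_identical(classify(0.93, 0.918), "positive")
  expect_identical(classify(0.5, 0.918), "negative")
  expect_identical(classify(0.918, 0.918), "positive")
  expect_identical(unique(classify(stats::runif(20), 0)), "positive")
})

test_that("model accessors and printing behave", {
  prob <- random_smil_problem(3)
  colnames(prob$X) <- paste0("t", seq_len(ncol(prob$X)))
  fit <- smil(prob$X, prob$bag, prob$y, C = 1)
  cf <- coef(fit)
  expect_identical(names(cf)[1], "(bias)")
  expect_length(cf, ncol(prob$X) + 1L)
  expect_output(print(fit), "sMIL linear classifier")
  expect_output(print(summary(fit)), "largest-magnitude weights")
  cls <- predict(fit, prob$X, prob$bag, type = "class", threshold = 0.5)
  expect_true(all(cls %in% c("positive", "negative")))
})
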