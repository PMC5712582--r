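# Sparse multi-instance learning (sMIL): a linear max-margin classifier over
# bags of sentence-level instances. Negative bags expand to one constraint
# per instance (all their instances are negative); each positive bag is
# represented by the mean of its instance vectors with a bag-size-dependent
# margin (2 - |B|) / |B|, encoding that at least one of |B| instances is
# positive, so smaller positive bags are more informative.
#
# Primal program, with yc in {+1, -1} and per-constraint margin m:
#   minimize (1/2)||w||^2 + C * sum(xi)
#   s.t.     yc_i (w . z_i + b) >= m_i - xi_i,   xi_i >= 0
# where z is a negative instance (yc = -1, m = 1) or a positive bag mean
# (yc = +1, m = (2 - |B|)/|B|). With |B| = 1 the program is a standard
# soft-margin SVM.

#' Fit a sparse multi-instance (sMIL) linear classifier
#'
#' @param x Numeric matrix or `dgCMatrix` of instance feature vectors (rows =
#'   instances) sharing one vocabulary.
#' @param bag Vector of bag identifiers, one per row of `x`.
#' @param y Logical vector, one per row, the distant-supervision bag label
#'   (constant within a bag).
#' @param C Soft-margin cost (default 1).
#' @param tol KKT tolerance of the quadratic-program solver (default 1e-8).
#' @param max_iter Iteration cap of the solver; exceeding it is an error.
#' @param calibrate Fit a logistic (Platt-style) mapping from raw hyperplane
#'   distances of training bag means to `[0, 1]` confidences (default TRUE).
#' @return An object of class `smil` with components `weights`, `bias`, `C`,
#'   `calibration` (list `A`, `B`), `training_summary`, and the solver's dual
#'   variables `alpha`.
#' @seealso [predict.smil()], [classify()]
#' @export
smil <- function(x, bag, y, C = 1, tol = 1e-8, max_iter = 500000L,
                 calibrate = TRUE) {
  x <- as_matrix(x)
  stopifnot(nrow(x) == length(bag), nrow(x) == length(y), C > 0)
  bag <- as.character(bag)
  y <- as.logical(y)
  for (b in unique(bag)) {
    if (length(unique(y[bag == b])) != 1L) {
      stop("bag '", b, "' has inconsistent labels")
    }
  }
  bag_label <- tapply(y, bag, `[`, 1L)
  if (!any(bag_label) || all(bag_label)) {
    stop("training requires at least one positive and one negative bag")
  }

  cons <- smil_constraints(x, bag, y)
  sol <- solve_margin_svm(cons$Z, cons$yc, cons$m, cons$cost, C = C,
                          tol = tol, max_iter = max_iter)

  # raw scores of all training bags (mean instance vector)
  means <- bag_means(x, bag)
  raw <- as.numeric(means %*% sol$w) + sol$b
  lab <- as.logical(bag_label[rownames(means)])
  calib <- if (calibrate) platt_fit(raw, lab) else list(A = -1, B = 0)

  structure(
    list(weights = sol$w, bias = sol$b, C = C, alpha = sol$alpha,
         objective = sol$objective, iterations = sol$iterations,
         calibration = calib,
         training_summary = list(
           n_pos_bags = sum(bag_label), n_neg_bags = sum(!bag_label),
           n_instances = nrow(x), n_features = ncol(x)
         ),
         terms = colnames(x)),
    class = "smil"
  )
}

as_matrix <- function(x) {
  if (inherits(x, "Matrix")) x else Matrix::Matrix(as.matrix(x), sparse = TRUE)
}

bag_means <- function(x, bag) {
  ub <- sort(unique(bag))
  ind <- Matrix::sparseMatrix(
    i = match(bag, ub), j = seq_along(bag),
    x = 1 / as.numeric(table(bag)[bag]),
    dims = c(length(ub), length(bag))
  )
  m <- ind %*% x
  rownames(m) <- ub
  m
}

# Build the constraint system: one row per negative instance (margin 1) and
# one per positive bag mean (margin (2-|B|)/|B|). Identical constraints are
# collapsed with summed slack costs, which is exact at the optimum.
smil_constraints <- function(x, bag, y) {
  neg <- which(!y)
  pos_bags <- unique(bag[y])
  Zn <- x[neg, , drop = FALSE]
  Zp <- bag_means(x[y, , drop = FALSE], bag[y])
  sizes <- as.numeric(table(bag[y])[rownames(Zp)])
  Z <- rbind(Zn, Zp)
  yc <- c(rep(-1, nrow(Zn)), rep(1, nrow(Zp)))
  m <- c(rep(1, nrow(Zn)), (2 - sizes) / sizes)
  cost <- rep(1, nrow(Z)) # unit multiplicity; scaled by C in the solver
  # collapse duplicate rows (same vector, same side, same margin)
  key <- apply(cbind(as.matrix(Z), yc, m), 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  mult <- as.numeric(table(key)[key[first]])
  list(Z = Z[first, , drop = FALSE], yc = yc[first], m = m[first],
       cost = mult)
}

# Deterministic SMO (maximal-violating-pair) solver for the dual of a
# soft-margin SVM with per-constraint margins m and per-constraint box
# bounds C_i:
#   max  sum(m * alpha) - (1/2) alpha' (yy' o K) alpha
#   s.t. sum(y * alpha) = 0,  0 <= alpha_i <= C_i
solve_margin_svm <- function(Z, yc, m, mult, C, tol = 1e-8,
                             max_iter = 500000L) {
  Cup <- C * mult
  n <- length(yc)
  K <- as.matrix(Z %*% Matrix::t(Z))
  alpha <- numeric(n)
  f <- numeric(n) # f_i = sum_j alpha_j y_j K_ij = w . z_i
  eps <- 1e-12
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      stop("sMIL solver did not converge within ", max_iter,
           " iterations (KKT gap above ", tol, ")")
    }
    h <- yc * m - f
    up <- (yc > 0 & alpha < Cup - eps) | (yc < 0 & alpha > eps)
    dn <- (yc > 0 & alpha > eps) | (yc < 0 & alpha < Cup - eps)
    if (!any(up) || !any(dn)) break
    i <- which(up)[which.max(h[up])]
    j <- which(dn)[which.min(h[dn])]
    gap <- h[i] - h[j]
    if (gap < tol) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    # feasible step bounds
    dmax_i <- if (yc[i] > 0) Cup[i] - alpha[i] else alpha[i]
    dmax_j <- if (yc[j] > 0) alpha[j] else Cup[j] - alpha[j]
    dmax <- min(dmax_i, dmax_j)
    delta <- if (eta > eps) min(gap / eta, dmax) else dmax
    if (delta <= 0) break
    alpha[i] <- min(max(alpha[i] + yc[i] * delta, 0), Cup[i])
    alpha[j] <- min(max(alpha[j] - yc[j] * delta, 0), Cup[j])
    f <- f + delta * (K[, i] - K[, j])
  }
  w <- as.numeric(Matrix::t(Z) %*% (alpha * yc))
  h <- yc * m - f
  free <- alpha > eps & alpha < Cup - eps
  b <- if (any(free)) {
    mean(h[free])
  } else {
    up <- (yc > 0 & alpha < Cup - eps) | (yc < 0 & alpha > eps)
    dn <- (yc > 0 & alpha > eps) | (yc < 0 & alpha < Cup - eps)
    hi <- if (any(up)) max(h[up]) else max(h)
    lo <- if (any(dn)) min(h[dn]) else min(h)
    (hi + lo) / 2
  }
  slack <- pmax(0, m - yc * (f + b))
  objective <- 0.5 * sum(w^2) + C * sum(mult * slack)
  list(w = w, b = b, alpha = alpha, objective = objective, iterations = it)
}

# Platt-style logistic calibration p(s) = 1 / (1 + exp(A s + B)) fitted by
# minimizing the regularized log-loss with Platt's soft targets; A is
# constrained negative so confidence is monotone increasing in the raw score.
platt_fit <- function(scores, labels) {
  np <- sum(labels)
  nn <- sum(!labels)
  t <- ifelse(labels, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    a <- -exp(par[1]) # A < 0
    p <- 1 / (1 + exp(a * scores + par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(A = -exp(fit$par[1]), B = fit$par[2])
}

platt_apply <- function(calib, s) 1 / (1 + exp(calib$A * s + calib$B))

#' @export
print.smil <- function(x, ...) {
  ts <- x$training_summary
  cat(sprintf("sMIL linear classifier (C = %g)\n", x$C))
  cat(sprintf("  trained on %d positive and %d negative bags (%d instances, %d features)\n",
              ts$n_pos_bags, ts$n_neg_bags, ts$n_instances, ts$n_features))
  cat(sprintf("  primal objective %.6g after %d solver iterations\n",
              x$objective, x$iterations))
  invisible(x)
}

#' @export
summary.smil <- function(object, n_top = 10L, ...) {
  ord <- order(-abs(object$weights))
  top <- data.frame(
    term = (object$terms %||% as.character(seq_along(object$weights)))[ord],
    weight = object$weights[ord]
  )[seq_len(min(n_top, length(object$weights))), ]
  out <- list(model = object, top_terms = top)
  class(out) <- "summary.smil"
  out
}

#' @export
print.summary.smil <- function(x, ...) {
  print(x$model)
  cat("  largest-magnitude weights:\n")
  print(x$top_terms, row.names = FALSE)
  invisible(x)
}

#' @export
coef.smil <- function(object, ...) {
  w <- object$weights
  names(w) <- object$terms %||% NULL
  c("(bias)" = object$bias, w)
}

#' Predict scores, confidences or classes for bags
#'
#' Bags are scored by the signed distance of their mean instance vector to
#' the hyperplane, `s = w . mean(x) + b`; `type = "confidence"` maps the raw
#' score through the logistic calibration fitted at training time (monotone
#' in `s`), `type = "class"` thresholds the confidence.
#'
#' @param object A fitted [smil()] model.
#' @param x Instance feature matrix (same vocabulary as at training).
#' @param bag Bag identifier per row of `x`; rows are averaged per bag and
#'   results are named by bag in lexicographic order. With `bag = NULL` each
#'   row is scored on its own, in row order.
#' @param type `"confidence"` (default), `"score"` (raw distance), or
#'   `"class"`.
#' @param threshold Confidence threshold for `type = "class"` (default 0.5).
#' @param ... Unused.
#' @return Named numeric vector per bag (or character vector of
#'   `"positive"`/`"negative"` for `type = "class"`).
#' @export
predict.smil <- function(object, x, bag = NULL,
                         type = c("confidence", "score", "class"),
                         threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- as_matrix(x)
  if (ncol(x) != length(object$weights)) {
    stop("feature dimension does not match the model vocabulary")
  }
  if (is.null(bag)) {
    # instance-level scoring in row order
    s <- as.numeric(x %*% object$weights) + object$bias
    names(s) <- rownames(x) %||% as.character(seq_len(nrow(x)))
  } else {
    means <- bag_means(x, as.character(bag))
    s <- as.numeric(means %*% object$weights) + object$bias
    names(s) <- rownames(means)
  }
  if (type == "score") return(s)
  conf <- platt_apply(object$calibration, s)
  names(conf) <- rownames(means)
  if (type == "confidence") return(conf)
  stats::setNames(classify(conf, threshold), rownames(means))
}

#' Threshold a score into a positive/negative call
#'
#' A pair is predicted positive iff its score is greater than or equal to the
#' threshold.
#'
#' @param score Numeric vector of scores.
#' @param threshold Scalar threshold.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify <- function(score, threshold) {
  ifelse(score >= threshold, "positive", "negative")
}
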