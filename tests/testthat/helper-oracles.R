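# Independent oracles, deliberately implemented apart from the package:
# Cramer's rule on the normal equations, a plain recursion iterator, and
# the stacked linear systems of each model rebuilt from their
# definitions.

# Cramer's-rule least squares: solve t(X)X b = t(X)y by determinants.
cramer_lsq <- function(X, y) {
  M <- crossprod(X)
  v <- crossprod(X, y)
  d <- det(M)
  vapply(seq_len(ncol(X)), function(j) {
    Mj <- M
    Mj[, j] <- v
    det(Mj) / d
  }, numeric(1))
}

# stacked system (X, y) of each model's estimation step, from scratch
oracle_system <- function(model, x0) {
  n <- length(x0)
  x1 <- cumsum(x0)
  switch(model,
    gm = {
      z <- (x1[-1] + x1[-n]) / 2
      list(X = cbind(-z, 1), y = x0[-1])
    },
    dgm = list(X = cbind(x1[-n], 1), y = x1[-1]),
    dngm = {
      k <- seq_len(n - 1)
      list(X = cbind(x1[k], k, 1), y = x1[k + 1])
    },
    idgm = {
      x2 <- cumsum(x1)
      list(X = cbind(x2[-n], 1), y = x2[-1])
    },
    ddgm = list(X = cbind(x0[-n], 1), y = x0[-1])
  )
}

# iterate x1(t+1) = alpha x1(t) + beta t + gamma
iterate_recursion <- function(alpha, beta, gamma, x1_initial, len) {
  x1 <- numeric(len)
  x1[1] <- x1_initial
  for (t in seq_len(len - 1)) x1[t + 1] <- alpha * x1[t] + beta * t + gamma
  x1
}

# closed-form accumulated value, written out independently
closed_form_x1 <- function(A, B, C, x1_initial, t) {
  K <- x1_initial - B / A + B / A^2 - C / A
  K * exp(-A * (t - 1)) + (B / A) * t - B / A^2 + C / A
}

# random well-posed whitening parameters: A in [-0.5, 1.5] \ {0}
rand_whitening <- function() {
  repeat {
    A <- stats::runif(1, -0.5, 1.5)
    if (abs(A) > 1e-3) break
  }
  list(A = A, B = stats::runif(1, -5, 5), C = stats::runif(1, -5, 5),
       x1_initial = stats::runif(1, 1e-3, 10))
}

# relative deviation with a cancellation-aware floor: when the closed
# form is a near-cancellation of terms of magnitude `scale`, agreement
# can only be judged relative to that scale
rel_dev <- function(a, b, scale) {
  abs(a - b) / pmax(abs(a), abs(b), 1e-9 * scale)
}

# positive random window for oracle comparisons
rand_window <- function(len) {
  grey_series(exp(stats::runif(len, 0, log(10))))
}
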