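# Small study configurations used across tests. Sizes are reduced relative
# to the canonical design only where the property under test does not
# depend on scale.

small_cfg <- function(n_participants = 2, seed = 42, ...) {
  ground_truth_config(n_participants = n_participants, seed = seed, ...)
}

# deterministic item table with a known monotone evidence-outcome link
toy_items <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    e <- runif(n, -1, 1)
    p <- plogis(2 * e)
    tibble::tibble(
      item_id = sprintf("it%02d", seq_len(n)),
      participant_id = rep(1:4, length.out = n),
      evidence = e,
      outcome = round(3 * pmin(pmax(p + rnorm(n, 0, 0.1), 0), 1)) / 3
    )
  })
}

# item table whose outcomes follow a known U-shaped curve of the evidence
u_items <- function(n = 120, seed = 1, noise = 0.1) {
  u <- plasticity_curve(c(-1, -0.2, 0.2, 1), c(0.8, -0.8, -0.8, 0.8))
  withr::with_seed(seed, {
    e1 <- runif(n, -1, 1)
    e2 <- runif(n, -1, 1)
    p <- plogis(0.5 + curve_eval(u, e1) + curve_eval(u, e2))
    s <- pmin(pmax(p + rnorm(n, 0, noise), 0), 1)
    tibble::tibble(
      item_id = sprintf("it%03d", seq_len(n)),
      participant_id = rep(seq_len(max(2, n %/% 20)), length.out = n),
      e_pre = e1, e_post = e2,
      outcome = round(3 * s) / 3
    )
  })
}

# items with outcomes independent of evidence (null generator)
null_items <- function(n = 100, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    item_id = sprintf("it%03d", seq_len(n)),
    participant_id = rep(1:5, length.out = n),
    evidence = runif(n, -1, 1),
    outcome = sample(c(0, 1 / 3, 2 / 3, 1), n, replace = TRUE)
  ))
}

# independent brute-force optimizer for the L2-penalized logistic objective
# (plain gradient descent with backtracking; deliberately not optim)
oracle_l2_logistic <- function(X, y, lambda, iters = 20000, lr = 0.5) {
  par <- rep(0, ncol(X) + 1)
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p)) + lambda / 2 * sum(par[-1]^2)
  }
  cur <- obj(par)
  for (i in seq_len(iters)) {
    r <- as.vector(plogis(par[1] + X %*% par[-1])) - y
    g <- c(sum(r), crossprod(X, r) + lambda * par[-1])
    step <- lr
    repeat {
      cand <- par - step * g
      val <- obj(cand)
      if (val <= cur || step < 1e-12) break
      step <- step / 2
    }
    if (abs(cur - val) < 1e-14 && max(abs(g)) < 1e-10) break
    par <- cand
    cur <- val
  }
  list(par = par, objective = cur)
}

# independent segment-walk consistency oracle for a single curve row
oracle_consistency <- function(row) {
  y <- as.numeric(row[3:6])
  m <- min(y)
  if (!(m < y[1])) return(FALSE)
  first_min <- which(y == m)[1]
  if (first_min == 4) return(FALSE)
  any(y[(first_min + 1):4] > m)
}

# enumeration oracle: all old/new pairs, ties count 1/2
oracle_auc <- function(old, new) {
  tot <- 0
  for (o in old) for (nw in new) {
    tot <- tot + (o > nw) + 0.5 * (o == nw)
  }
  tot / (length(old) * length(new))
}

# enumeration grid over the curve family: interior knots on 5 x-points
# (x1 <= x2), heights on 5 levels each
grid_curve_set <- function() {
  g <- seq(-1, 1, length.out = 5)
  xc <- expand.grid(x1 = g, x2 = g)
  xc <- xc[xc$x1 <= xc$x2, ]
  yc <- expand.grid(y0 = g, y1 = g, y2 = g, y3 = g)
  out <- merge(xc, yc)
  tibble::as_tibble(out[, c("x1", "x2", "y0", "y1", "y2", "y3")])
}

# fully independent P-CIT oracle: plain loops, approx() interpolation,
# optimize() for the intercept
oracle_pcit <- function(curves, items, events, outcome) {
  E <- as.matrix(items[, events, drop = FALSE])
  y <- items[[outcome]]
  m <- as.matrix(curves)
  n <- nrow(m)
  ll <- numeric(n)
  cons <- logical(n)
  for (i in seq_len(n)) {
    kx <- c(-1, m[i, 1], m[i, 2], 1)
    ky <- m[i, 3:6]
    delta <- rowSums(matrix(
      approx(kx, ky, xout = as.vector(E), ties = "ordered")$y,
      nrow = nrow(E)
    ))
    f <- function(b) {
      p <- pmin(pmax(plogis(b + delta), 1e-12), 1 - 1e-12)
      sum(y * log(p) + (1 - y) * log(1 - p))
    }
    ll[i] <- optimize(f, c(-10, 10), maximum = TRUE, tol = 1e-10)$objective
    cons[i] <- oracle_consistency(m[i, ])
  }
  mx <- max(ll)
  post_c <- sum(exp(ll[cons] - mx))
  post_i <- sum(exp(ll[!cons] - mx))
  list(ll = ll, cons = cons,
       log_bf = log(post_c / post_i) - log(mean(cons) / mean(!cons)))
}
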