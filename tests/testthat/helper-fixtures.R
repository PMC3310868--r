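# Shared fixtures, generated in code. The cache keeps the moderately
# expensive synthetic recordings to one generation per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# unidirectionally coupled pair: x2 white, x1(t) = c * x2(t-1) + e(t),
# unit innovation variances; asymptotic GC_{2->1} = ln(1 + c^2)
coupled_pair <- function(n, c = 0.5, seed = 1) {
  set.seed(seed)
  x2 <- rnorm(n + 1)
  x1 <- c * x2[1:n] + rnorm(n)
  list(x1 = x1, x2 = x2[2:(n + 1)])
}

# small synthetic recording shared across ingest/gc tests
small_recording <- function() {
  cached("small_rec", {
    cfg <- sim_config(durations = c(awake_pre = 60, anesth = 390, awake_post = 60),
                      seed = 11)
    generate_recording(cfg)
  })
}

small_window_set <- function() {
  cached("small_ws", {
    rs <- average_regions(small_recording())
    extract_state_segments(rs, post_induction_skip = 300, seed = 5)
  })
}

# brute-force GC oracle: explicit lag-matrix construction, normal-equations
# solve, variance ratio (independent of the qr-based implementation path)
gc_oracle <- function(x1, x2, p) {
  n <- length(x1)
  lagmat <- function(x) {
    out <- matrix(0, n - p, p)
    for (k in 1:p) out[, k] <- x[(p + 1 - k):(n - k)]
    out
  }
  ne_solve <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
  rv <- function(X, y) {
    b <- ne_solve(X, y)
    r <- y - X %*% b
    sum(r^2) / length(y)
  }
  y1 <- x1[(p + 1):n]; y2 <- x2[(p + 1):n]
  X_u1 <- cbind(1, lagmat(x1)); X_u2 <- cbind(1, lagmat(x2))
  X_b <- cbind(1, lagmat(x1), lagmat(x2))
  list(gc_21 = log(rv(X_u1, y1) / rv(X_b, y1)),
       gc_12 = log(rv(X_u2, y2) / rv(X_b, y2)))
}
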