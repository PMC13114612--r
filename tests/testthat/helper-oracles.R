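# Independent reference implementations used as oracles, deliberately
# written in the most literal style possible (scalar loops, textbook
# recursions) so they share no code path with the package internals.

# textbook Cox-de Boor recursion, one basis function at one point
oracleBspline <- function(x, i, p, knots) {
  if (p == 0) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * oracleBspline(x, i, p - 1, knots) else 0
  t2 <- if (d2 > 0) (knots[i + p + 1] - x) / d2 *
          oracleBspline(x, i + 1, p - 1, knots) else 0
  t1 + t2
}

# naive per-step, per-channel, per-state double-loop selective scan
oracleScan <- function(u, delta, B, C, A, method = "euler") {
  K <- nrow(u); di <- ncol(u); ds <- ncol(A)
  y <- matrix(0, K, di)
  for (d in seq_len(di)) {
    h <- numeric(ds)
    for (k in seq_len(K)) {
      for (n in seq_len(ds)) {
        a_bar <- exp(delta[k, d] * A[d, n])
        b_bar <- if (method == "euler") delta[k, d] * B[k, d, n] else
          (a_bar - 1) / A[d, n] * B[k, d, n]
        h[n] <- a_bar * h[n] + b_bar * u[k, d]
      }
      y[k, d] <- sum(C[k, d, ] * h)
    }
  }
  y
}

# definitional Pearson correlation, pairwise double loop
oraclePearson <- function(X) {
  n <- nrow(X)
  R <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
    R[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  R
}

# central finite differences of f with respect to a flat parameter array,
# accessed through getter/setter closures
finiteDiff <- function(getp, setp, f, h = 1e-6) {
  p0 <- getp()
  g <- p0 * 0
  for (k in seq_along(p0)) {
    p <- p0
    p[k] <- p0[k] + h; setp(p); lp <- f()
    p[k] <- p0[k] - h; setp(p); lm <- f()
    g[k] <- (lp - lm) / (2 * h)
  }
  setp(p0)
  g
}

# a micro model configuration that exercises every component quickly
tinyConfig <- function(n_classes = 2L, D = 10L, L = 4L) {
  cfg <- defaultConfig(n_classes, "desk")
  cfg$vae$encoder_dims <- c(D, 6L)
  cfg$vae$latent_dim <- L
  cfg$mamba$d_state <- 2L
  cfg$mamba$d_conv <- 2L
  cfg$mamba$dropout_p <- 0
  cfg$head$hidden <- 3L
  cfg
}

# a small synthetic session list with known labels, bypassing the full
# generator (pure noise, used where only shapes/structure matter)
tinyDFCs <- function(n_sessions = 6L, K = 7L, D = 10L, n_rois = 5L,
                     n_classes = 2L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_sessions), function(i) {
    new("DFCSequence",
        subject_id = sprintf("s%02d", i), session_id = sprintf("s%02d_v1", i),
        label = (i - 1L) %% n_classes,
        vectors = matrix(runif(K * D), K, D),
        window_starts = as.integer(2L * (seq_len(K) - 1L)),
        n_rois = as.integer(n_rois), rescaled = TRUE)
  })
}
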