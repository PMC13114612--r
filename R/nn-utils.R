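# Elementwise nonlinearities, their derivatives, and a generic Adam step.
# Internal building blocks for the hand-written forward/backward passes.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

# d/dx silu(x) = sigmoid(x) * (1 + x * (1 - sigmoid(x)))
siluGrad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# numerically stable softplus; derivative is sigmoid
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

relu <- function(x) pmax(x, 0)

# row-wise stable softmax of a matrix of logits
softmaxRows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# log-sum-exp per row
logSumExpRows <- function(logits) {
  m <- apply(logits, 1L, max)
  m + log(rowSums(exp(logits - m)))
}

# Derive a bounded sub-seed from a run seed and a stream tag so every source
# of randomness (data, init, noise, dropout, shuffling) is independently
# reproducible from one integer.
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483629
  for (t in tags) {
    tv <- if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.double(t)
    h <- (h * 69069 + tv + 1) %% 2147483629
  }
  as.integer(h)
}

# fan-in uniform initialization, the standard dense-layer default
initMatrix <- function(n_in, n_out) {
  a <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

# ---- Adam -------------------------------------------------------------------

# `params` and `grads` are flat named lists of numeric arrays. State carries
# first/second moment estimates and the step counter.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two structurally identical grad lists
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scaleGrads <- function(g, s) lapply(g, function(x) x * s)

zeroGrads <- function(params) lapply(params, function(p) p * 0)

# fast row-wise broadcast ops: add / multiply a length-ncol vector to every
# row of a matrix (replaces sweep on hot paths)
rowPlus <- function(A, b) A + rep(b, each = nrow(A))
rowTimes <- function(A, b) A * rep(b, each = nrow(A))
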