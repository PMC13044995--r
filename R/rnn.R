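# Minimal recurrent-network machinery: a simple tanh recurrent unit with a
# time-distributed linear output head, trained by Adam on analytic gradients
# (backpropagation through time). The visit horizon in this problem class is
# short (a handful of visits), so a gated unit buys nothing here; everything
# is dense base-R linear algebra over subjects-by-hidden matrices.

# seeded parameter initialization; scales ~ 1/sqrt(fan-in)
.rnn_init <- function(p_in, hidden, seed) {
  set.seed(seed)
  ux <- 1 / sqrt(max(1, p_in))
  uh <- 1 / sqrt(hidden)
  list(
    Wx = matrix(stats::runif(hidden * p_in, -ux, ux), hidden, p_in),
    Wh = matrix(stats::runif(hidden * hidden, -uh, uh), hidden, hidden),
    bh = rep(0, hidden),
    Wy = stats::runif(hidden, -uh, uh),
    by = 0
  )
}

# forward pass. x_list: list over visits of n x p input matrices (defined for
# every subject; off-risk cells are masked downstream). Returns hidden states
# and the n x (K+1) output preactivation z.
.rnn_forward <- function(params, x_list) {
  n <- nrow(x_list[[1L]])
  hsz <- length(params$bh)
  Kp1 <- length(x_list)
  h_prev <- matrix(0, n, hsz)
  h_list <- vector("list", Kp1)
  z <- matrix(0, n, Kp1)
  for (k in seq_len(Kp1)) {
    pre <- x_list[[k]] %*% t(params$Wx) + h_prev %*% t(params$Wh)
    pre <- sweep(pre, 2, params$bh, "+")
    h <- tanh(pre)
    h_list[[k]] <- h
    z[, k] <- as.vector(h %*% params$Wy) + params$by
    h_prev <- h
  }
  list(h = h_list, z = z)
}

# backpropagation through time. dZ: n x (K+1) matrix of dLoss/dz.
.rnn_backward <- function(params, x_list, fwd, dZ) {
  Kp1 <- length(x_list)
  n <- nrow(dZ)
  hsz <- length(params$bh)
  g <- list(Wx = params$Wx * 0, Wh = params$Wh * 0, bh = params$bh * 0,
            Wy = params$Wy * 0, by = 0)
  dh_next <- matrix(0, n, hsz)
  for (k in Kp1:1) {
    h <- fwd$h[[k]]
    dz <- dZ[, k]
    g$Wy <- g$Wy + as.vector(t(h) %*% dz)
    g$by <- g$by + sum(dz)
    dh <- outer(dz, params$Wy) + dh_next
    da <- dh * (1 - h * h)
    g$Wx <- g$Wx + t(da) %*% x_list[[k]]
    h_prev <- if (k > 1L) fwd$h[[k - 1L]] else matrix(0, n, hsz)
    g$Wh <- g$Wh + t(da) %*% h_prev
    g$bh <- g$bh + colSums(da)
    dh_next <- da %*% params$Wh
  }
  g
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# network inputs per visit: carried-forward covariates plus previous exposure
# (0 before the first visit). Returns a list over visits of n x p matrices.
.net_inputs <- function(panel, input_cols = NULL) {
  covs <- panel$cov_fill
  if (is.null(input_cols)) input_cols <- names(covs)
  unknown <- setdiff(input_cols, names(covs))
  if (length(unknown))
    stop("unknown input column(s): ", paste(unknown, collapse = ", "))
  K1 <- panel$schedule$K + 1L
  n <- length(panel$subject_id)
  A_prev <- cbind(0, panel$A_fill[, -K1, drop = FALSE])
  lapply(seq_len(K1), function(k) {
    m <- cbind(do.call(cbind, lapply(covs[input_cols], function(cm) cm[, k])),
               A_prev = A_prev[, k])
    colnames(m) <- c(input_cols, ".A_prev")
    m
  })
}
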