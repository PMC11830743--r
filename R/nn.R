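# Minimal dense-network machinery: fully connected and residual blocks with
# hand-derived backpropagation, plus an Adam optimizer. Batches are row-major
# (batch x features). Activations are smooth (tanh/sigmoid) so analytic
# gradients can be validated against central finite differences tightly.

.xavier <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

nn_dense <- function(fan_in, fan_out, act = c("linear", "tanh", "sigmoid")) {
  act <- match.arg(act)
  list(type = "dense", act = act,
       W = .xavier(fan_in, fan_out), b = numeric(fan_out))
}

nn_res <- function(width) {
  list(type = "res",
       W1 = .xavier(width, width), b1 = numeric(width),
       W2 = .xavier(width, width) * 0.1, b2 = numeric(width))
}

.act_fwd <- function(a, act) {
  switch(act, linear = a, tanh = tanh(a), sigmoid = 1 / (1 + exp(-a)))
}
.act_bwd <- function(y, act) {
  switch(act, linear = 1, tanh = 1 - y^2, sigmoid = y * (1 - y))
}

# forward through a list of layers; returns output and per-layer caches
nn_forward <- function(layers, X) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    if (L$type == "dense") {
      Y <- .act_fwd(sweep_add(X %*% L$W, L$b), L$act)
      caches[[i]] <- list(X = X, Y = Y)
    } else {                       # residual: Y = X + tanh(X W1 + b1) W2 + b2
      U <- tanh(sweep_add(X %*% L$W1, L$b1))
      Y <- sweep_add(X + U %*% L$W2, L$b2)
      caches[[i]] <- list(X = X, U = U)
    }
    X <- Y
  }
  list(out = X, caches = caches)
}

# backward; returns gradient list (parallel to layers) and dX
nn_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]; C <- caches[[i]]
    if (L$type == "dense") {
      dA <- dY * .act_bwd(C$Y, L$act)
      grads[[i]] <- list(W = crossprod(C$X, dA), b = colSums(dA))
      dY <- dA %*% t(L$W)
    } else {
      dU <- (dY %*% t(L$W2)) * (1 - C$U^2)
      grads[[i]] <- list(W1 = crossprod(C$X, dU), b1 = colSums(dU),
                         W2 = crossprod(C$U, dY), b2 = colSums(dY))
      dY <- dY + dU %*% t(L$W1)
    }
  }
  list(grads = grads, dX = dY)
}

sweep_add <- function(M, b) M + rep(b, each = nrow(M))

# ---- parameter-tree utilities (nested lists of numeric arrays) ----------

param_names <- c("W", "b", "W1", "b1", "W2", "b2")

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
  out
}

tree_map <- function(f, a) {
  if (is.numeric(a)) return(f(a))
  out <- a
  for (k in seq_along(a)) out[[k]] <- tree_map(f, a[[k]])
  out
}

# extract only numeric leaves named as parameters from layer lists
layers_params <- function(layers) {
  lapply(layers, function(L) L[intersect(names(L), param_names)])
}
layers_set_params <- function(layers, params) {
  for (i in seq_along(layers))
    for (nm in names(params[[i]])) layers[[i]][[nm]] <- params[[i]][[nm]]
  layers
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
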