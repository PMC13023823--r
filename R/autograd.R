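# Minimal tape-based reverse-mode automatic differentiation.
#
# Nodes are environments holding a value matrix, an accumulated gradient and
# a backward closure. Operations record themselves on a tape (an environment
# with a creation-ordered node list); ag_backward() replays the tape in
# reverse. Constants are never recorded, so evaluation with tape = NULL runs
# the same forward code with zero bookkeeping. Sparse `Matrix` operands are
# supported as constant left factors in ag_mm (scatter/pool operators).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$nodes <- vector("list", 256L)
  t
}

dmat <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}

ag_record <- function(tape, val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$needs <- TRUE
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

#' @keywords internal
ag_const <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- NULL
  nd$needs <- FALSE
  nd
}

ag_leaf <- function(tape, val) ag_record(tape, val, bw = NULL)

ag_accum <- function(p, g) {
  if (!p$needs) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) dmat(g) else p$grad + dmat(g)
  invisible(NULL)
}

needs_any <- function(...) any(vapply(list(...), function(p) p$needs,
                                      logical(1)))

ag_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- operations ---------------------------------------------------------

ag_mm <- function(tape, a, b) {
  val <- dmat(a$val %*% b$val)
  if (is.null(tape) || !needs_any(a, b)) return(ag_const(val))
  ag_record(tape, val, function(g) {
    if (a$needs) ag_accum(a, g %*% t(b$val))
    if (b$needs) ag_accum(b, dmat(Matrix::crossprod(a$val, g)))
  })
}

# b may be a 1 x ncol(a) bias row, broadcast over rows of a
ag_add <- function(tape, a, b) {
  bcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  val <- if (bcast)
    a$val + matrix(b$val, nrow(a$val), ncol(a$val), byrow = TRUE)
  else a$val + b$val
  if (is.null(tape) || !needs_any(a, b)) return(ag_const(val))
  ag_record(tape, val, function(g) {
    if (a$needs) ag_accum(a, g)
    if (b$needs) ag_accum(b, if (bcast) matrix(colSums(g), 1) else g)
  })
}

ag_sub <- function(tape, a, b) {
  val <- a$val - b$val
  if (is.null(tape) || !needs_any(a, b)) return(ag_const(val))
  ag_record(tape, val, function(g) {
    if (a$needs) ag_accum(a, g)
    if (b$needs) ag_accum(b, -g)
  })
}

# elementwise; b may be an m x 1 column (broadcast across columns of a)
# or a 1 x 1 scalar
ag_mul <- function(tape, a, b) {
  scalar <- length(b$val) == 1L
  cbcast <- !scalar && ncol(b$val) == 1L && ncol(a$val) > 1L
  bv <- if (cbcast) as.vector(b$val) else b$val
  val <- if (scalar) a$val * bv[1] else a$val * bv
  if (is.null(tape) || !needs_any(a, b)) return(ag_const(val))
  ag_record(tape, val, function(g) {
    if (a$needs) {
      ag_accum(a, if (scalar) g * bv[1] else g * bv)
    }
    if (b$needs) {
      if (scalar) ag_accum(b, matrix(sum(g * a$val), 1, 1))
      else if (cbcast) ag_accum(b, matrix(rowSums(g * a$val), ncol = 1))
      else ag_accum(b, g * a$val)
    }
  })
}

ag_scale <- function(tape, a, s) {
  val <- a$val * s
  if (is.null(tape) || !a$needs) return(ag_const(val))
  ag_record(tape, val, function(g) ag_accum(a, g * s))
}

ag_sigmoid <- function(tape, a) {
  val <- 1 / (1 + exp(-a$val))
  if (is.null(tape) || !a$needs) return(ag_const(val))
  ag_record(tape, val, function(g) ag_accum(a, g * val * (1 - val)))
}

ag_tanh <- function(tape, a) {
  val <- tanh(a$val)
  if (is.null(tape) || !a$needs) return(ag_const(val))
  ag_record(tape, val, function(g) ag_accum(a, g * (1 - val^2)))
}

ag_relu <- function(tape, a) {
  val <- pmax(a$val, 0)
  if (is.null(tape) || !a$needs) return(ag_const(val))
  mask <- a$val > 0
  ag_record(tape, val, function(g) ag_accum(a, g * mask))
}

ag_leakyrelu <- function(tape, a, slope = 0.2) {
  val <- ifelse(a$val > 0, a$val, slope * a$val)
  if (is.null(tape) || !a$needs) return(ag_const(val))
  fac <- ifelse(a$val > 0, 1, slope)
  ag_record(tape, val, function(g) ag_accum(a, g * fac))
}

ag_rows <- function(tape, a, idx) {
  val <- a$val[idx, , drop = FALSE]
  if (is.null(tape) || !a$needs) return(ag_const(val))
  nr <- nrow(a$val)
  ag_record(tape, val, function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nr, ncol(g))
    full[as.integer(rownames(acc)), ] <- acc
    ag_accum(a, full)
  })
}

ag_cols <- function(tape, a, idx) {
  val <- a$val[, idx, drop = FALSE]
  if (is.null(tape) || !a$needs) return(ag_const(val))
  nc <- ncol(a$val)
  ag_record(tape, val, function(g) {
    full <- matrix(0, nrow(g), nc)
    full[, idx] <- g
    ag_accum(a, full)
  })
}

ag_cbind <- function(tape, a, b) {
  val <- cbind(a$val, b$val)
  if (is.null(tape) || !needs_any(a, b)) return(ag_const(val))
  na <- ncol(a$val)
  ag_record(tape, val, function(g) {
    if (a$needs) ag_accum(a, g[, seq_len(na), drop = FALSE])
    if (b$needs) ag_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

ag_sum <- function(tape, a) {
  val <- matrix(sum(a$val), 1, 1)
  if (is.null(tape) || !a$needs) return(ag_const(val))
  dims <- dim(a$val)
  ag_record(tape, val, function(g)
    ag_accum(a, matrix(g[1, 1], dims[1], dims[2])))
}

# softmax within contiguous-index groups (gidx: dense 1..G group id per row),
# applied independently per column. Logits are clamped at +-30 before exp;
# the clamp's gradient is treated as pass-through (a saturation guard, not a
# modelling choice).
ag_segment_softmax <- function(tape, a, gidx) {
  e <- exp(pmin(pmax(a$val, -30), 30))
  den <- rowsum(e, gidx)
  ord <- as.integer(rownames(den))
  den_full <- den[match(gidx, ord), , drop = FALSE]
  val <- e / den_full
  if (is.null(tape) || !a$needs) return(ag_const(val))
  ag_record(tape, val, function(g) {
    tmp <- val * g
    s <- rowsum(tmp, gidx)
    s_full <- s[match(gidx, ord), , drop = FALSE]
    ag_accum(a, tmp - val * s_full)
  })
}

# row-wise layer normalization with learned gain/bias (1 x d each)
ag_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$val)
  bv <- as.vector(beta$val)
  val <- sweep(xhat, 2, gv, `*`)
  val <- sweep(val, 2, bv, `+`)
  if (is.null(tape) || !needs_any(a, gamma, beta)) return(ag_const(val))
  ag_record(tape, val, function(g) {
    if (gamma$needs) ag_accum(gamma, matrix(colSums(g * xhat), 1))
    if (beta$needs) ag_accum(beta, matrix(colSums(g), 1))
    if (a$needs) {
      dxhat <- sweep(g, 2, gv, `*`)
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      ag_accum(a, inv * (dxhat - m1 - xhat * m2))
    }
  })
}

# ---- AdamW optimizer ----------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}
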