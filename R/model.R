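# ---- angle encoding -----------------------------------------------------

#' Encode angles as sine/cosine pairs
#'
#' Maps each angle (degrees) to its unit-circle point, giving the 6-vector
#' `[sin t1, cos t1, sin t2, cos t2, sin t3, cos t3]` used as the regression
#' target. This periodic parameterization avoids the discontinuity of raw
#' angular regression.
#'
#' @param angles an `angle_set`, length-3 numeric, or an n x 3 matrix.
#' @return length-6 numeric vector, or n x 6 matrix for matrix input.
#' @export
encode_angles <- function(angles) {
  if (is.matrix(angles)) {
    r <- angles * pi / 180
    out <- cbind(sin(r[, 1]), cos(r[, 1]), sin(r[, 2]), cos(r[, 2]),
                 sin(r[, 3]), cos(r[, 3]))
    colnames(out) <- c("sin1", "cos1", "sin2", "cos2", "sin3", "cos3")
    return(out)
  }
  r <- as.numeric(angles) * pi / 180
  c(sin(r[1]), cos(r[1]), sin(r[2]), cos(r[2]), sin(r[3]), cos(r[3]))
}

#' Decode sine/cosine pairs back to angles
#'
#' `theta_i = |atan2(s_i, c_i)|` in degrees, in \[0, 180\]. The decoding is
#' invariant to the magnitude of each (sin, cos) pair, so predicted pairs
#' need not lie on the unit circle. Ground truth lies in (0, 180\], so the
#' sign of the decoded angle carries no information and is folded away.
#'
#' @param enc length-6 numeric vector or n x 6 matrix.
#' @return an `angle_set` (or n x 3 matrix for matrix input).
#' @export
decode_angles <- function(enc) {
  if (!is.matrix(enc)) enc <- matrix(enc, 1)
  if (ncol(enc) != 6) stop("encoding must have 6 columns")
  out <- matrix(0, nrow(enc), 3)
  for (k in 1:3) {
    s <- enc[, 2 * k - 1]; cc <- enc[, 2 * k]
    if (any(s^2 + cc^2 < 1e-24))
      stop("cannot decode a null (sin, cos) pair")
    out[, k] <- abs(atan2(s, cc)) * 180 / pi
  }
  colnames(out) <- c("theta1", "theta2", "theta3")
  if (nrow(out) == 1) angle_set(out[1, 1], out[1, 2], out[1, 3]) else out
}

#' Masked sine/cosine regression loss
#'
#' Mean, over valid samples, of the summed squared Euclidean distances
#' between predicted and ground-truth (sin, cos) pairs of the three angles.
#'
#' @param pred n x 6 matrix of predicted encodings.
#' @param truth n x 3 matrix of ground-truth angles (degrees) or n x 6
#'   encodings.
#' @param mask optional logical vector of valid samples.
#' @return scalar loss.
#' @export
angle_loss <- function(pred, truth, mask = NULL) {
  if (!is.matrix(pred)) pred <- matrix(pred, 1)
  if (!is.matrix(truth)) truth <- matrix(truth, 1)
  if (ncol(truth) == 3) truth <- encode_angles(truth)
  if (!is.null(mask)) {
    pred <- pred[mask, , drop = FALSE]
    truth <- truth[mask, , drop = FALSE]
  }
  n <- nrow(pred)
  if (n == 0) stop("loss undefined: no valid samples after masking")
  sum((pred - truth)^2) / n
}

# ---- configuration ------------------------------------------------------

MODEL_VARIANTS <- c("full", "no_tree", "no_nucleotide",
                    "gcn_message_passing", "concat_fusion",
                    "len_only_features")

#' Model configuration
#'
#' Hyperparameters of the dual-resolution junction model. `variant` selects
#' the full model or one ablation: `no_tree` (nucleotide branch only),
#' `no_nucleotide` (tree branch only), `gcn_message_passing` (attention
#' replaced by degree-normalized mean aggregation), `concat_fusion` (gate
#' replaced by concatenation + affine projection), `len_only_features`
#' (tree node features truncated to the raw segment-length group).
#'
#' @param hidden_dim hidden width (must be divisible by `heads`).
#' @param heads attention heads (nucleotide encoder and junction head).
#' @param dropout dropout rate in \[0, 1).
#' @param gate_mode `"per_dimension"` or `"scalar"` gating coefficient.
#' @param variant one of `"full"`, `"no_tree"`, `"no_nucleotide"`,
#'   `"gcn_message_passing"`, `"concat_fusion"`, `"len_only_features"`.
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param plateau_factor,plateau_patience learning-rate decay on a
#'   validation-loss plateau.
#' @param max_epochs,early_stop_patience training length controls.
#' @param val_fraction fraction of chains held out for validation.
#' @param seed integer seed driving init, splits and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(hidden_dim = 64L, heads = 2L, dropout = 0.2,
                         gate_mode = c("per_dimension", "scalar"),
                         variant = "full",
                         lr = 1e-3, weight_decay = 1e-2,
                         plateau_factor = 0.5, plateau_patience = 10L,
                         max_epochs = 500L, early_stop_patience = 30L,
                         val_fraction = 0.15, seed = 1L) {
  gate_mode <- match.arg(gate_mode)
  if (length(variant) != 1 || !variant %in% MODEL_VARIANTS)
    stop("exactly one variant must be chosen from: ",
         paste(MODEL_VARIANTS, collapse = ", "))
  if (hidden_dim <= 0 || hidden_dim %% heads != 0)
    stop("hidden_dim must be a positive multiple of heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 heads = as.integer(heads), dropout = dropout,
                 gate_mode = gate_mode, variant = variant, lr = lr,
                 weight_decay = weight_decay,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "model_config")
}

cfg_use_nuc <- function(cfg) cfg$variant != "no_nucleotide"
cfg_use_tree <- function(cfg) cfg$variant != "no_tree"
cfg_attention <- function(cfg) cfg$variant != "gcn_message_passing"
cfg_tree_in_dim <- function(cfg)
  if (cfg$variant == "len_only_features") 3L else 24L

feature_fingerprint <- function(cfg) {
  paste0("nuc:11;edge:3;tree:", cfg_tree_in_dim(cfg), ";stem:4;groups:",
         paste(TREE_FEATURE_GROUPS, collapse = ","))
}

# ---- parameters ---------------------------------------------------------

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_params <- function(cfg) {
  d <- cfg$hidden_dim
  dh <- d %/% cfg$heads
  p <- list()
  if (cfg_use_nuc(cfg)) {
    p$nuc.Wroot <- glorot(11, d); p$nuc.broot <- matrix(0, 1, d)
    p$nuc.Wv <- glorot(11, d); p$nuc.Wev <- glorot(3, d)
    if (cfg_attention(cfg)) {
      p$nuc.Wq <- glorot(11, d); p$nuc.Wk <- glorot(11, d)
      p$nuc.Wek <- glorot(3, d)
    }
  }
  if (cfg_use_tree(cfg)) {
    k <- cfg_tree_in_dim(cfg)
    p$tree.Wn <- glorot(k, d); p$tree.bn <- matrix(0, 1, d)
    p$tree.We <- glorot(4, d); p$tree.be <- matrix(0, 1, d)
  }
  if (cfg_use_nuc(cfg) && cfg_use_tree(cfg)) {
    if (cfg$variant == "concat_fusion") {
      p$fuse.Wc <- glorot(2 * d, d); p$fuse.bc <- matrix(0, 1, d)
    } else {
      gdim <- if (cfg$gate_mode == "scalar") 1L else d
      p$fuse.Wg <- glorot(2 * d, gdim); p$fuse.bg <- matrix(0, 1, gdim)
    }
  }
  p$ln.gamma <- matrix(1, 1, d); p$ln.beta <- matrix(0, 1, d)
  p$gat.W <- glorot(d, d)
  if (cfg_attention(cfg)) {
    p$gat.a_src <- glorot(dh, cfg$heads) * 0.1
    p$gat.a_dst <- glorot(dh, cfg$heads) * 0.1
    if (cfg_use_tree(cfg)) p$gat.a_e <- glorot(dh, cfg$heads) * 0.1
  }
  p$mlp.W1 <- glorot(d, d); p$mlp.b1 <- matrix(0, 1, d)
  p$mlp.W2 <- glorot(d, 6); p$mlp.b2 <- matrix(0, 1, 6)
  p
}

#' Number of learnable parameters of a model or parameter list
#' @param x an `angle_model` or a named parameter list.
#' @export
count_parameters <- function(x) {
  p <- if (inherits(x, "angle_model")) x$params else x
  sum(vapply(p, length, integer(1)))
}

# ---- batching -----------------------------------------------------------

# one chain -> model-ready tensors
prepare_sample <- function(record) {
  f <- record$features
  ng <- f$nuc_graph
  n <- nrow(ng$node_features)
  e <- ng$edges
  src <- c(e[, 1], e[, 2])         # undirected -> both directions
  dst <- c(e[, 2], e[, 1])
  EF <- rbind(ng$edge_features, ng$edge_features)
  Tn <- length(f$tree$nodes)
  te <- f$tree$edges
  tsrc <- c(te$from, te$to, seq_len(Tn))   # + self-loops
  tdst <- c(te$to, te$from, seq_len(Tn))
  TEF <- rbind(f$tree_edge_features, f$tree_edge_features,
               matrix(0, Tn, 4))
  jnode <- vapply(f$junctions, `[[`, integer(1), "node_id")
  truth <- record$truth
  if (!is.null(truth)) {
    if (!is.matrix(truth)) truth <- matrix(as.numeric(truth), ncol = 3)
    if (nrow(truth) != length(jnode))
      stop("truth rows do not match junction count")
  }
  list(X = ng$node_features, src = src, dst = dst, EF = EF,
       Xt = f$tree_node_features, tsrc = tsrc, tdst = tdst, TEF = TEF,
       members = f$node_members, n = n, Tn = Tn, jnode = jnode,
       truth = truth)
}

build_batch <- function(samples) {
  noff <- cumsum(c(0L, vapply(samples, `[[`, integer(1), "n")))
  toff <- cumsum(c(0L, vapply(samples, function(s) s$Tn, integer(1))))
  N <- noff[length(noff)]
  Tt <- toff[length(toff)]
  src <- integer(0); dst <- integer(0)
  tsrc <- integer(0); tdst <- integer(0)
  pi_ <- integer(0); pj <- integer(0); px <- numeric(0)
  jidx <- integer(0); jchain <- integer(0)
  X <- vector("list", length(samples)); EF <- X; Xt <- X; TEF <- X
  truth <- list()
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    X[[k]] <- s$X; EF[[k]] <- s$EF; Xt[[k]] <- s$Xt; TEF[[k]] <- s$TEF
    src <- c(src, s$src + noff[k]); dst <- c(dst, s$dst + noff[k])
    tsrc <- c(tsrc, s$tsrc + toff[k]); tdst <- c(tdst, s$tdst + toff[k])
    for (t in seq_along(s$members)) {
      mem <- s$members[[t]]
      if (length(mem) > 0) {
        pi_ <- c(pi_, rep(t + toff[k], length(mem)))
        pj <- c(pj, mem + noff[k])
        px <- c(px, rep(1 / length(mem), length(mem)))
      }
    }
    jidx <- c(jidx, s$jnode + toff[k])
    jchain <- c(jchain, rep(k, length(s$jnode)))
    if (!is.null(s$truth)) truth[[length(truth) + 1L]] <- s$truth
  }
  m <- length(src); mt <- length(tsrc)
  list(X = do.call(rbind, X), src = src, dst = dst,
       EF = do.call(rbind, EF),
       S_nuc = Matrix::sparseMatrix(i = dst, j = seq_len(m), x = 1,
                                    dims = c(N, m)),
       gidx = match(dst, sort(unique(dst))),
       indeg = as.vector(table(factor(dst, levels = seq_len(N))))[dst],
       Xt = do.call(rbind, Xt), tsrc = tsrc, tdst = tdst,
       TEF = do.call(rbind, TEF),
       S_tree = Matrix::sparseMatrix(i = tdst, j = seq_len(mt), x = 1,
                                     dims = c(Tt, mt)),
       tgidx = match(tdst, sort(unique(tdst))),
       tindeg = as.vector(table(factor(tdst, levels = seq_len(Tt))))[tdst],
       P = Matrix::sparseMatrix(i = pi_, j = pj, x = px, dims = c(Tt, N)),
       jidx = jidx, jchain = jchain, N = N, Tt = Tt,
       truth = if (length(truth) > 0) do.call(rbind, truth) else NULL)
}

# ---- forward pass -------------------------------------------------------

make_dropout_masks <- function(cfg, batch) {
  p <- cfg$dropout
  if (p <= 0) return(NULL)
  d <- cfg$hidden_dim
  mk <- function(nr) matrix(stats::rbinom(nr * d, 1, 1 - p) / (1 - p), nr, d)
  list(nuc = mk(batch$N), tree = mk(batch$Tt), gat = mk(batch$Tt),
       mlp = mk(length(batch$jidx)))
}

drop_apply <- function(tape, x, mask) {
  if (is.null(mask)) x else ag_mul(tape, x, ag_const(mask))
}

forward_net <- function(params, batch, cfg, tape = NULL, masks = NULL) {
  d <- cfg$hidden_dim
  heads <- cfg$heads
  dh <- d %/% heads
  pl <- lapply(params, function(p)
    if (is.null(tape)) ag_const(p) else ag_leaf(tape, p))
  head_cols <- lapply(seq_len(heads), function(h) ((h - 1) * dh + 1):(h * dh))
  ones_dh <- ag_const(matrix(1, dh, 1))

  h_nuc_tree <- NULL
  if (cfg_use_nuc(cfg)) {
    Xc <- ag_const(batch$X)
    EFc <- ag_const(batch$EF)
    V <- ag_mm(tape, Xc, pl$nuc.Wv)
    VE <- ag_mm(tape, EFc, pl$nuc.Wev)
    att <- cfg_attention(cfg)
    if (att) {
      Q <- ag_mm(tape, Xc, pl$nuc.Wq)
      K <- ag_mm(tape, Xc, pl$nuc.Wk)
      KE <- ag_mm(tape, EFc, pl$nuc.Wek)
    }
    msgs <- vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- head_cols[[h]]
      vsum <- ag_add(tape, ag_rows(tape, ag_cols(tape, V, idx), batch$src),
                     ag_cols(tape, VE, idx))
      if (att) {
        qd <- ag_rows(tape, ag_cols(tape, Q, idx), batch$dst)
        ksum <- ag_add(tape, ag_rows(tape, ag_cols(tape, K, idx), batch$src),
                       ag_cols(tape, KE, idx))
        logit <- ag_scale(tape, ag_mm(tape, ag_mul(tape, qd, ksum), ones_dh),
                          1 / sqrt(dh))
        alpha <- ag_segment_softmax(tape, logit, batch$gidx)
      } else {
        alpha <- ag_const(matrix(1 / batch$indeg, ncol = 1))
      }
      msgs[[h]] <- ag_mm(tape, ag_const(batch$S_nuc),
                         ag_mul(tape, vsum, alpha))
    }
    msg <- Reduce(function(a, b) ag_cbind(tape, a, b), msgs)
    root <- ag_add(tape, ag_mm(tape, Xc, pl$nuc.Wroot), pl$nuc.broot)
    Hnuc <- ag_relu(tape, ag_add(tape, root, msg))
    Hnuc <- drop_apply(tape, Hnuc, masks$nuc)
    h_nuc_tree <- ag_mm(tape, ag_const(batch$P), Hnuc)
  }

  h_tree <- NULL; Eemb <- NULL
  if (cfg_use_tree(cfg)) {
    Xt <- batch$Xt
    if (cfg$variant == "len_only_features") Xt <- Xt[, 1:3, drop = FALSE]
    Xtc <- ag_const(Xt)
    h_tree <- ag_relu(tape, ag_add(tape, ag_mm(tape, Xtc, pl$tree.Wn),
                                   pl$tree.bn))
    h_tree <- drop_apply(tape, h_tree, masks$tree)
    Eemb <- ag_relu(tape, ag_add(tape, ag_mm(tape, ag_const(batch$TEF),
                                             pl$tree.We), pl$tree.be))
  }

  h <- if (is.null(h_tree)) {
    h_nuc_tree
  } else if (is.null(h_nuc_tree)) {
    h_tree
  } else if (cfg$variant == "concat_fusion") {
    both <- ag_cbind(tape, h_nuc_tree, h_tree)
    ag_add(tape, ag_mm(tape, both, pl$fuse.Wc), pl$fuse.bc)
  } else {
    both <- ag_cbind(tape, h_nuc_tree, h_tree)
    z <- ag_sigmoid(tape, ag_add(tape, ag_mm(tape, both, pl$fuse.Wg),
                                 pl$fuse.bg))
    one_minus_z <- ag_sub(tape, ag_const(matrix(1, nrow(z$val), ncol(z$val))),
                          z)
    ag_add(tape, ag_mul(tape, h_nuc_tree, z),
           ag_mul(tape, h_tree, one_minus_z))
  }

  ln <- ag_layernorm(tape, h, pl$ln.gamma, pl$ln.beta)
  Wh <- ag_mm(tape, ln, pl$gat.W)
  att <- cfg_attention(cfg)
  gmsgs <- vector("list", heads)
  for (hh in seq_len(heads)) {
    idx <- head_cols[[hh]]
    Wh_h <- ag_cols(tape, Wh, idx)
    src_rows <- ag_rows(tape, Wh_h, batch$tsrc)
    if (att) {
      logit <- ag_add(tape,
        ag_mm(tape, ag_rows(tape, Wh_h, batch$tdst),
              ag_cols(tape, pl$gat.a_dst, hh)),
        ag_mm(tape, src_rows, ag_cols(tape, pl$gat.a_src, hh)))
      if (!is.null(Eemb))
        logit <- ag_add(tape, logit,
                        ag_mm(tape, ag_cols(tape, Eemb, idx),
                              ag_cols(tape, pl$gat.a_e, hh)))
      logit <- ag_leakyrelu(tape, logit)
      alpha <- ag_segment_softmax(tape, logit, batch$tgidx)
    } else {
      alpha <- ag_const(matrix(1 / batch$tindeg, ncol = 1))
    }
    gmsgs[[hh]] <- ag_mm(tape, ag_const(batch$S_tree),
                         ag_mul(tape, src_rows, alpha))
  }
  gout <- Reduce(function(a, b) ag_cbind(tape, a, b), gmsgs)
  gout <- drop_apply(tape, gout, masks$gat)
  h2 <- ag_add(tape, h, gout)

  Jr <- ag_rows(tape, h2, batch$jidx)
  A1 <- ag_relu(tape, ag_add(tape, ag_mm(tape, Jr, pl$mlp.W1), pl$mlp.b1))
  A1 <- drop_apply(tape, A1, masks$mlp)
  pred <- ag_add(tape, ag_mm(tape, A1, pl$mlp.W2), pl$mlp.b2)
  list(pred = pred, leaves = pl)
}

eval_loss <- function(params, batch, cfg) {
  out <- forward_net(params, batch, cfg, tape = NULL, masks = NULL)
  angle_loss(out$pred$val, batch$truth)
}

# ---- training -----------------------------------------------------------

#' Build a model record from a structure and its junction angles
#'
#' @param ss a `secondary_structure`.
#' @param truth matrix of ground-truth angles (one row per junction,
#'   degrees), or `NULL` for prediction-only records.
#' @return a record list (`features`, `truth`) for [train_angle_model()].
#' @export
make_record <- function(ss, truth = NULL) {
  list(features = featurize_chain(ss), truth = truth)
}

#' Train the junction-angle model
#'
#' Full-batch AdamW training of the dual-resolution network on a set of
#' chains. Chains are split at the chain level into a training and a
#' validation part; the learning rate halves when the validation loss
#' plateaus and training stops early when it no longer improves. The
#' parameters achieving the best validation loss are returned. All
#' randomness (init, split, dropout) derives from `cfg$seed`.
#'
#' @param records list of records from [make_record()]; every record must
#'   carry ground-truth angles.
#' @param cfg a [model_config()].
#' @param quiet suppress the per-epoch progress (default TRUE).
#' @return an `angle_model`: `params`, `cfg`, `history` (per-epoch
#'   data.frame), `fingerprint`, `best_val`.
#' @export
train_angle_model <- function(records, cfg = model_config(), quiet = TRUE) {
  if (length(records) < 2) stop("need at least 2 chains to train")
  set.seed(cfg$seed)
  samples <- lapply(records, prepare_sample)
  if (any(vapply(samples, function(s) is.null(s$truth), logical(1))))
    stop("all training records need ground-truth angles")
  nva <- max(1L, round(cfg$val_fraction * length(samples)))
  if (nva >= length(samples)) stop("validation split leaves no training data")
  perm <- sample(length(samples))
  va_idx <- perm[seq_len(nva)]
  tr <- build_batch(samples[-va_idx])
  va <- build_batch(samples[va_idx])
  tr$truth6 <- encode_angles(tr$truth)
  params <- init_params(cfg)
  state <- adamw_init(params)
  lr <- cfg$lr
  best_val <- Inf; best_params <- params
  since_best <- 0L; since_decay <- 0L
  hist <- list()
  nj <- nrow(tr$truth6)
  for (epoch in seq_len(cfg$max_epochs)) {
    tape <- ag_tape()
    masks <- make_dropout_masks(cfg, tr)
    out <- forward_net(params, tr, cfg, tape = tape, masks = masks)
    diff <- ag_sub(tape, out$pred, ag_const(tr$truth6))
    loss <- ag_scale(tape, ag_sum(tape, ag_mul(tape, diff, diff)), 1 / nj)
    tr_loss <- loss$val[1, 1]
    if (!is.finite(tr_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    ag_backward(tape, loss)
    grads <- lapply(out$leaves, function(l) l$grad)
    st <- adamw_step(params, grads, state, lr, cfg$weight_decay)
    params <- st$params; state <- st$state
    va_loss <- eval_loss(params, va, cfg)
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss,
                       val_loss = va_loss, lr = lr)
    if (!quiet && epoch %% 25 == 0)
      message(sprintf("epoch %d train %.4f val %.4f lr %.2g",
                      epoch, tr_loss, va_loss, lr))
    if (va_loss < best_val - 1e-6) {
      best_val <- va_loss; best_params <- params
      since_best <- 0L; since_decay <- 0L
    } else {
      since_best <- since_best + 1L
      since_decay <- since_decay + 1L
      if (since_decay >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        since_decay <- 0L
      }
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  structure(list(params = best_params, cfg = cfg,
                 history = as.data.frame(do.call(rbind, hist)),
                 fingerprint = feature_fingerprint(cfg),
                 best_val = best_val),
            class = "angle_model")
}

#' @export
print.angle_model <- function(x, ...) {
  cat("Junction angle model (", x$cfg$variant, "), ",
      count_parameters(x), " parameters, ",
      nrow(x$history), " epochs, best val loss ",
      signif(x$best_val, 4), "\n", sep = "")
  invisible(x)
}

predict_batch <- function(model, batch) {
  if (feature_fingerprint(model$cfg) != model$fingerprint)
    stop("model fingerprint does not match its configuration")
  out <- forward_net(model$params, batch, model$cfg, tape = NULL,
                     masks = NULL)
  out$pred$val
}

#' Predict junction angles
#'
#' Runs the trained model in evaluation mode (dropout off) and decodes the
#' sine/cosine head output into degrees.
#'
#' @param model an `angle_model`.
#' @param newdata a `secondary_structure`, a record from [make_record()],
#'   or a list of records.
#' @return data.frame with `chain`, `junction`, `theta1..theta3`. Zero rows
#'   (with a warning) when no chain contains a three-way junction.
#' @export
predict_angles <- function(model, newdata) {
  records <- if (inherits(newdata, "secondary_structure")) {
    list(make_record(newdata))
  } else if (!is.null(newdata$features)) {
    list(newdata)
  } else newdata
  samples <- lapply(records, function(r) {
    r$truth <- NULL
    prepare_sample(r)
  })
  batch <- build_batch(samples)
  if (length(batch$jidx) == 0) {
    warning("no three-way junction in input; empty prediction")
    return(data.frame(chain = integer(0), junction = integer(0),
                      theta1 = numeric(0), theta2 = numeric(0),
                      theta3 = numeric(0)))
  }
  enc <- predict_batch(model, batch)
  ang <- decode_angles(enc)
  if (!is.matrix(ang)) ang <- matrix(as.numeric(ang), 1)
  jn <- stats::ave(batch$jchain, batch$jchain, FUN = seq_along)
  data.frame(chain = batch$jchain, junction = jn,
             theta1 = ang[, 1], theta2 = ang[, 2], theta3 = ang[, 3])
}

#' Chain-level k-fold cross-validation
#'
#' Splits chains (never individual junctions) into k folds, trains on k-1
#' and evaluates accuracy on the held-out fold at each tolerance.
#'
#' @param records list of records with ground truth.
#' @param k number of folds.
#' @param cfg a [model_config()]; fold seeds derive from `cfg$seed`.
#' @param taus tolerance thresholds in degrees.
#' @return list with `folds` (per-fold data.frame of joint/overall ACC per
#'   tau), `mean` (named means), `assignment` (fold id per chain).
#' @export
cross_validate_angles <- function(records, k = 5L, cfg = model_config(),
                                  taus = c(10, 15, 20)) {
  n <- length(records)
  if (k > n) stop("more folds than chains")
  set.seed(cfg$seed)
  assignment <- sample(rep(seq_len(k), length.out = n))
  rows <- list()
  for (f in seq_len(k)) {
    te <- which(assignment == f)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + f
    mod <- train_angle_model(records[-te], cfg_f)
    pred <- predict_angles(mod, records[te])
    truth <- do.call(rbind, lapply(records[te], `[[`, "truth"))
    err <- abs(as.matrix(pred[, c("theta1", "theta2", "theta3")]) - truth)
    row <- c(fold = f)
    for (tau in taus) {
      a <- acc_summary(err, tau)
      row <- c(row, stats::setNames(c(a$joint, a$overall),
                                    paste0(c("joint_acc", "overall_acc"),
                                           tau)))
    }
    rows[[f]] <- row
  }
  folds <- as.data.frame(do.call(rbind, rows))
  list(folds = folds, mean = colMeans(folds[, -1, drop = FALSE]),
       assignment = assignment)
}

# ---- checkpoints --------------------------------------------------------

#' Save a trained model as a JSON checkpoint
#'
#' Weights, configuration and the feature-layout fingerprint are written at
#' full double precision, so a load round-trips bit-identically.
#'
#' @param model an `angle_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    # weights serialized as %.17g strings: exact IEEE double round trip,
    # unlike JSON numeric emission
    params = lapply(model$params, function(m)
      list(dim = dim(m), data = sprintf("%.17g", as.vector(m)))),
    cfg = unclass(model$cfg),
    fingerprint = model$fingerprint,
    best_val = model$best_val,
    history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return an `angle_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p)
    matrix(as.numeric(p$data), p$dim[1], p$dim[2]))
  cfg <- obj$cfg
  class(cfg) <- "model_config"
  model <- structure(list(params = params, cfg = cfg,
                          fingerprint = obj$fingerprint,
                          best_val = obj$best_val,
                          history = as.data.frame(obj$history)),
                     class = "angle_model")
  if (feature_fingerprint(cfg) != model$fingerprint)
    stop("checkpoint fingerprint does not match its configuration ",
         "(feature layout changed)")
  model
}
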