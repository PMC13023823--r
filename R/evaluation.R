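# ---- angular errors and accuracy ---------------------------------------

#' Absolute per-angle errors
#'
#' Plain absolute differences, no circular wrap: both predicted and native
#' angles live on the half-circle \[0, 180\], so 179 vs 1 is an error of
#' 178 degrees, not 2.
#'
#' @param pred,truth `angle_set`s, length-3 vectors, or n x 3 matrices.
#' @return length-3 vector (or n x 3 matrix) of errors in degrees.
#' @export
angular_error <- function(pred, truth) {
  if (is.matrix(pred) || is.matrix(truth)) {
    out <- abs(as.matrix(pred) - as.matrix(truth))
    colnames(out) <- c("theta1", "theta2", "theta3")
    return(out)
  }
  e <- abs(as.numeric(pred) - as.numeric(truth))
  names(e) <- c("theta1", "theta2", "theta3")
  e
}

acc_summary <- function(errors, tau) {
  if (!is.matrix(errors)) errors <- matrix(errors, ncol = 3)
  if (nrow(errors) == 0) stop("accuracy undefined on an empty error set")
  hit <- errors <= tau
  list(per_angle = colMeans(hit),
       overall = mean(hit),
       joint = mean(rowSums(hit) == 3))
}

#' Angle prediction accuracy at a tolerance
#'
#' Per-angle ACC is the fraction of samples with error at most `tau`;
#' overall ACC averages the indicator over all three angles and all samples
#' (the 1/(3N) double sum); joint ACC demands all three angles of a sample
#' pass simultaneously.
#'
#' @param errors n x 3 matrix of absolute angular errors (degrees).
#' @param tau tolerance threshold(s) in degrees.
#' @return data.frame with one row per tau: `tau`, `acc1..acc3`, `overall`,
#'   `joint`.
#' @export
acc <- function(errors, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  rows <- lapply(tau, function(t) {
    a <- acc_summary(errors, t)
    data.frame(tau = t, acc1 = unname(a$per_angle[1]),
               acc2 = unname(a$per_angle[2]),
               acc3 = unname(a$per_angle[3]),
               overall = a$overall, joint = a$joint)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean absolute error of one junction
#'
#' Average of the three per-angle absolute deviations.
#'
#' @param errors length-3 vector of absolute deviations (degrees).
#' @return MAE in degrees.
#' @export
mae <- function(errors) {
  e <- as.numeric(errors)
  if (length(e) != 3) stop("mae expects the three per-angle deviations")
  mean(e)
}

# ---- skeleton RMSD aggregation -----------------------------------------

#' Skeleton RMSD report over matched star pairs
#'
#' @param pairs list of `list(pred = , native = )` skeleton stars.
#' @param breaks histogram bin edges in Angstrom.
#' @return list with `rmsd` (vector), `mean`, `bins` (named counts).
#' @export
rmsd_report <- function(pairs, breaks = c(0, 1, 2, Inf)) {
  if (length(pairs) == 0) stop("rmsd_report needs at least one star pair")
  r <- vapply(pairs, function(p) skeleton_rmsd(p$pred, p$native), numeric(1))
  cut_ <- cut(r, breaks = breaks, include.lowest = TRUE, right = FALSE)
  list(rmsd = r, mean = mean(r), bins = table(cut_))
}

# ---- permutation feature importance ------------------------------------

#' Permutation importance of a tree-node feature group
#'
#' Shuffles the three columns of one loop-descriptor group across all tree
#' nodes of the dataset (keeping the rows of the three columns together),
#' re-predicts, and reports the mean decrease in joint ACC at `tau`
#' relative to the unpermuted model.
#'
#' @param model an `angle_model`.
#' @param records list of records with ground truth.
#' @param group one of `TREE_FEATURE_GROUPS` ("length", "pairwise_min",
#'   "sorted_length", "pairwise_diff", "pairwise_ratio", "fraction",
#'   "max_au_run", "max_a_run").
#' @param repeats number of random permutations averaged.
#' @param seed RNG seed for the permutations.
#' @param tau tolerance (degrees) of the joint accuracy.
#' @return list with `baseline`, `permuted` (per-repeat joint ACC), `drop`.
#' @export
permutation_importance <- function(model, records, group, repeats = 5L,
                                   seed = 1L, tau = 20) {
  gi <- match(group, TREE_FEATURE_GROUPS)
  if (is.na(gi)) stop("unknown feature group '", group, "'")
  cols <- ((gi - 1) * 3 + 1):(gi * 3)
  samples <- lapply(records, function(r) {
    s <- prepare_sample(r)
    if (is.null(s$truth)) stop("records need ground truth")
    s
  })
  truth <- do.call(rbind, lapply(samples, `[[`, "truth"))
  joint_of <- function(batch) {
    enc <- predict_batch(model, batch)
    ang <- decode_angles(enc)
    if (!is.matrix(ang)) ang <- matrix(as.numeric(ang), 1)
    acc_summary(abs(ang - truth), tau)$joint
  }
  baseline <- joint_of(build_batch(samples))
  set.seed(seed)
  nrows <- vapply(samples, function(s) nrow(s$Xt), integer(1))
  permuted <- vapply(seq_len(repeats), function(r) {
    pooled <- do.call(rbind, lapply(samples, function(s)
      s$Xt[, cols, drop = FALSE]))
    pooled <- pooled[sample(nrow(pooled)), , drop = FALSE]
    off <- cumsum(c(0L, nrows))
    perm_samples <- samples
    for (k in seq_along(samples)) {
      rows <- (off[k] + 1):(off[k] + nrows[k])
      perm_samples[[k]]$Xt[, cols] <- pooled[rows, , drop = FALSE]
    }
    joint_of(build_batch(perm_samples))
  }, numeric(1))
  list(baseline = baseline, permuted = permuted,
       drop = baseline - mean(permuted))
}

#' Pearson correlation between per-angle error series (convenience)
#'
#' @param errors n x 3 matrix of absolute errors.
#' @return 3 x 3 correlation matrix with `cor.test` p-values as attribute.
#' @export
error_correlations <- function(errors) {
  cm <- stats::cor(errors)
  pv <- matrix(NA_real_, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    ct <- stats::cor.test(errors[, i], errors[, j])
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  attr(cm, "p.value") <- pv
  cm
}

#' Write a metric report as JSON and CSV
#'
#' @param errors n x 3 matrix of absolute angular errors.
#' @param taus tolerances in degrees.
#' @param rmsd optional vector of skeleton RMSDs.
#' @param path_prefix files `<prefix>.json` and `<prefix>.csv` are written.
#' @return the report list, invisibly.
#' @export
write_metric_report <- function(errors, taus = c(10, 15, 20), rmsd = NULL,
                                path_prefix) {
  tab <- acc(errors, taus)
  report <- list(acc = tab,
                 mae_per_angle = colMeans(errors),
                 mae = mean(errors))
  if (!is.null(rmsd))
    report$rmsd <- list(values = rmsd, mean = mean(rmsd))
  jsonlite::write_json(report, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(tab, paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(report)
}
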