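test_that("angle encoding and decoding are exact inverses", {
  expect_equal(encode_angles(angle_set(90, 90, 90)), c(1, 0, 1, 0, 1, 0))
  expect_equal(encode_angles(angle_set(0, 90, 180)),
               c(0, 1, 1, 0, 0, -1), tolerance = 1e-12)
  expect_equal(encode_angles(angle_set(60, 60, 60)),
               rep(c(sqrt(3) / 2, 0.5), 3), tolerance = 1e-12)

  expect_equal(unname(as.numeric(decode_angles(c(1, 0, 1, 0, 1, 0)))),
               c(90, 90, 90))
  # magnitude invariance of each pair
  expect_equal(decode_angles(c(0.2, 0, 1, 0, 1, 0))[["theta1"]], 90)
  # negative sine folds by absolute value
  expect_equal(decode_angles(c(-0.5, -sqrt(3) / 2, 1, 0, 1, 0))[["theta1"]],
               150, tolerance = 1e-12)
  expect_error(decode_angles(c(0, 0, 1, 0, 1, 0)), "null")

  grid <- seq(0.001, 179.999, length.out = 1000)
  for (t1 in grid[c(1, 250, 500, 750, 1000)]) {
    a <- angle_set(t1, 90, 45)
    expect_equal(as.numeric(decode_angles(encode_angles(a))),
                 as.numeric(a), tolerance = 1e-9)
  }
  dec <- decode_angles(encode_angles(cbind(grid, rev(grid), 90)))
  expect_equal(unname(dec[, 1]), grid, tolerance = 1e-9)
})

test_that("loss reproduces hand-computed values and honors the mask", {
  truth <- matrix(c(90, 90, 90), 1)
  expect_equal(angle_loss(encode_angles(truth), truth), 0)
  pred <- matrix(rep(c(0, 1), 3), 1)   # all pairs at angle 0
  expect_equal(angle_loss(pred, truth), 6)
  preds <- rbind(pred, encode_angles(truth))
  truths <- rbind(truth, truth)
  expect_equal(angle_loss(preds, truths, mask = c(TRUE, FALSE)), 6)
  expect_equal(angle_loss(preds, truths), 3)
  expect_error(angle_loss(preds, truths, mask = c(FALSE, FALSE)),
               "no valid samples")
  # order invariance
  set.seed(9)
  p2 <- matrix(rnorm(12), 2); t2 <- matrix(runif(6, 10, 170), 2, 3)
  expect_equal(angle_loss(p2, t2), angle_loss(p2[2:1, ], t2[2:1, ]))
})

test_that("configuration is validated", {
  expect_error(model_config(variant = "nope"), "variant")
  expect_error(model_config(hidden_dim = 33, heads = 2), "multiple")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("ablation variants ignore the ablated branch", {
  recs <- generate_junction_records(synthetic_spec(count = 4, seed = 21,
                                                  sigma = 0))
  cfg <- model_config(hidden_dim = 16, dropout = 0, seed = 3,
                      variant = "no_nucleotide", max_epochs = 5)
  m <- train_angle_model(recs, cfg)
  base <- predict_angles(m, recs[[1]])
  # scramble every base letter (structure unchanged): tree features that
  # depend on sequence change too, so only nucleotide-graph-only channels
  # are scrambled here: flip base identities but keep A/U and lengths
  rec2 <- recs[[1]]
  seq2 <- chartr("GC", "CG", rec2$sequence)
  ss2 <- parse_dot_bracket(rec2$db, seq2)
  f2 <- featurize_chain(ss2)
  f2$tree_node_features <- recs[[1]]$features$tree_node_features
  f2$tree_edge_features <- recs[[1]]$features$tree_edge_features
  rec2$features <- f2
  got <- predict_angles(m, rec2)
  expect_equal(got$theta1, base$theta1, tolerance = 1e-12)
  expect_equal(got$theta3, base$theta3, tolerance = 1e-12)
})

test_that("a saturated gate reduces fusion to a single branch", {
  recs <- generate_junction_records(synthetic_spec(count = 3, seed = 22,
                                                  sigma = 0))
  cfg <- model_config(hidden_dim = 16, dropout = 0, seed = 3,
                      variant = "full", max_epochs = 2)
  m <- train_angle_model(recs, cfg)
  # force z -> 1: output must ignore tree NODE features entirely
  m$params$fuse.Wg[] <- 0
  m$params$fuse.bg[] <- 50
  rec2 <- recs[[1]]
  rec2$features$tree_node_features <-
    rec2$features$tree_node_features + 3.7
  expect_equal(predict_angles(m, rec2)$theta2,
               predict_angles(m, recs[[1]])$theta2, tolerance = 1e-10)
  # force z -> 0: output must ignore the nucleotide graph entirely
  m$params$fuse.bg[] <- -50
  rec3 <- recs[[1]]
  rec3$features$nuc_graph$node_features[, 1:4] <-
    rec3$features$nuc_graph$node_features[sample(nrow(
      rec3$features$nuc_graph$node_features)), 1:4]
  expect_equal(predict_angles(m, rec3)$theta2,
               predict_angles(m, recs[[1]])$theta2, tolerance = 1e-10)
})

test_that("variant parameter counts differ as the architecture dictates", {
  d <- 16
  n_full <- count_parameters(rna3wj:::init_params(
    model_config(hidden_dim = d, variant = "full")))
  n_notree <- count_parameters(rna3wj:::init_params(
    model_config(hidden_dim = d, variant = "no_tree")))
  n_nonuc <- count_parameters(rna3wj:::init_params(
    model_config(hidden_dim = d, variant = "no_nucleotide")))
  n_gcn <- count_parameters(rna3wj:::init_params(
    model_config(hidden_dim = d, variant = "gcn_message_passing")))
  n_len <- count_parameters(rna3wj:::init_params(
    model_config(hidden_dim = d, variant = "len_only_features")))
  expect_gt(n_full, n_notree)
  expect_gt(n_full, n_nonuc)
  expect_gt(n_full, n_gcn)    # attention weights removed
  expect_equal(n_full - n_len, (24 - 3) * d)  # truncated tree input only
})

test_that("training is deterministic given the seed and records history", {
  recs <- generate_junction_records(synthetic_spec(count = 4, seed = 23,
                                                  sigma = 0))
  cfg <- model_config(hidden_dim = 16, dropout = 0.2, seed = 11,
                      max_epochs = 8)
  m1 <- train_angle_model(recs, cfg)
  m2 <- train_angle_model(recs, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 8)
  expect_named(m1$history, c("epoch", "train_loss", "val_loss", "lr"))
  p1 <- predict_angles(m1, recs[[2]])
  p2 <- predict_angles(m1, recs[[2]])
  expect_identical(p1, p2)
})

test_that("the model overfits a tiny noise-free dataset", {
  recs <- generate_junction_records(synthetic_spec(count = 3, seed = 5,
                                                  sigma = 0))
  cfg <- model_config(hidden_dim = 32, dropout = 0, seed = 1, lr = 3e-3,
                      weight_decay = 0, max_epochs = 400,
                      early_stop_patience = 400, plateau_patience = 60,
                      val_fraction = 0.34)
  m <- train_angle_model(recs, cfg)
  expect_lt(min(m$history$train_loss), 0.01)
  # planted angles recovered on the two fitted chains (one chain of the
  # three is the validation split)
  p <- predict_angles(m, recs)
  truth <- do.call(rbind, lapply(recs, `[[`, "truth"))
  chain_err <- apply(abs(as.matrix(p[, 3:5]) - truth), 1, max)
  expect_lt(sort(chain_err)[2], 5)
})

test_that("prediction on a junction-free chain is empty with a warning", {
  recs <- generate_junction_records(synthetic_spec(count = 4, seed = 23,
                                                  sigma = 0))
  m <- train_angle_model(recs, model_config(hidden_dim = 16, seed = 1,
                                            max_epochs = 2))
  ss <- parse_dot_bracket("((((....))))", "GGGGAAAACCCC")
  expect_warning(p <- predict_angles(m, ss), "no three-way junction")
  expect_equal(nrow(p), 0L)
})

test_that("cross-validation folds partition chains reproducibly", {
  recs <- generate_junction_records(synthetic_spec(count = 4, seed = 29))
  cfg <- model_config(hidden_dim = 16, seed = 2, max_epochs = 3)
  cv1 <- cross_validate_angles(recs, k = 2, cfg = cfg)
  cv2 <- cross_validate_angles(recs, k = 2, cfg = cfg)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_equal(sort(unique(cv1$assignment)), 1:2)
  expect_equal(as.vector(table(cv1$assignment)), c(2L, 2L))
  expect_equal(nrow(cv1$folds), 2L)
  expect_true(all(c("joint_acc20", "overall_acc20") %in%
                  names(cv1$folds)))
  expect_error(cross_validate_angles(recs, k = 9, cfg = cfg),
               "more folds than chains")
})

test_that("checkpoints round-trip bit-identically", {
  recs <- generate_junction_records(synthetic_spec(count = 4, seed = 23))
  m <- train_angle_model(recs, model_config(hidden_dim = 16, seed = 7,
                                            max_epochs = 4))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  expect_identical(lapply(m$params, unname), m2$params)
  p1 <- predict_angles(m, recs[[1]])
  p2 <- predict_angles(m2, recs[[1]])
  expect_identical(p1, p2)
  # a checkpoint whose fingerprint disagrees with its config is rejected
  js <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  js$fingerprint <- sub("tree:24", "tree:3", js$fingerprint)
  jsonlite::write_json(js, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(load_checkpoint(tmp), "fingerprint")
})

test_that("zero-epoch training returns an initialized model", {
  recs <- generate_junction_records(synthetic_spec(count = 3, seed = 24))
  m <- train_angle_model(recs, model_config(hidden_dim = 16, seed = 1,
                                            max_epochs = 0))
  expect_s3_class(m, "angle_model")
  expect_equal(nrow(m$history), 0L)
  expect_equal(count_parameters(m),
               count_parameters(rna3wj:::init_params(m$cfg)))
})
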