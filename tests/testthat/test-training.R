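# Splitting, cross-validation folds, plateau schedule, transfer chain.

test_that("stratified splits take ceiling(fraction * n) per class and partition", {
  manifest <- data.frame(
    subject_id = sprintf("s%02d", 1:16),
    class_label = rep(c("NC", "aAD", "mAD", "ADD"), each = 4),
    stringsAsFactors = FALSE
  )
  sp <- split_cohort(manifest, 0.5, seed = 2)
  expect_length(sp$test_ids, 8)
  expect_length(sp$train_ids, 8)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), manifest$subject_id)
  per_class <- table(manifest$class_label[match(sp$test_ids, manifest$subject_id)])
  expect_true(all(per_class == 2))
  # odd class sizes round the test share up
  m5 <- data.frame(
    subject_id = sprintf("t%02d", 1:10),
    class_label = rep(c("NC", "ADD"), c(5, 5)), stringsAsFactors = FALSE
  )
  sp5 <- split_cohort(m5, 0.5, seed = 3)
  expect_length(sp5$test_ids, 6)
  expect_identical(split_cohort(manifest, 0.5, seed = 2)$test_ids, sp$test_ids)
  expect_error(
    split_cohort(data.frame(subject_id = "a", class_label = "NC"), 0.5, 1),
    "fewer than 2"
  )
})

test_that("training separates well-separated patch classes", {
  ds <- separable_patch_dataset(n_per_class = 48, delta = 2)
  tc <- train_config(epochs = 4, seed = 5)
  fit <- train_task(build_model(seed = 1), ds, c("ADD", "NC"), tc, cv = FALSE)
  p <- predict_patch_scores(fit$model, ds)
  acc <- mean((p[, 1] > 0.5) == (ds$info$class_label == "ADD"))
  expect_gte(acc, 0.95)
  expect_equal(nrow(fit$history), 4)
})

test_that("cross-validation folds partition scans with no leakage", {
  ds <- separable_patch_dataset(n_per_class = 24, delta = 2, n_scans_per_class = 3)
  tc <- train_config(epochs = 1, folds = 3, seed = 8)
  fit <- train_task(build_model(seed = 2), ds, c("ADD", "NC"), tc, cv = TRUE)
  expect_length(fit$cv, 3)
  val_sets <- lapply(fit$cv, `[[`, "val_ids")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_length(intersect(val_sets[[i]], val_sets[[j]]), 0)
    }
  }
  expect_setequal(unlist(val_sets), unique(ds$info$subject_id))
  # every fold recorded a validation loss
  for (cvf in fit$cv) expect_true(all(is.finite(cvf$history$val_loss)))
})

test_that("the plateau schedule cuts the learning rate by a tenth", {
  # frozen training (negligible lr, no dropout) => constant monitored loss
  # => a cut after `patience` flat epochs
  ds <- separable_patch_dataset(n_per_class = 32, delta = 0)
  net <- model_config(dropout_rate = 0)
  tc <- train_config(
    epochs = 4, lr = 1e-12, plateau_patience = 1,
    balance_classes = FALSE, seed = 3
  )
  fit <- tvpstage:::fit_cnn(
    build_model(net, seed = 1), ds$data,
    ifelse(ds$info$class_label == "ADD", 1L, 2L), tc
  )
  lr <- fit$history$lr
  expect_equal(lr[1], 1e-12)
  expect_equal(lr[3] / lr[2], 0.1, tolerance = 1e-6)
})

test_that("single-class patch sets cannot be trained", {
  ds <- separable_patch_dataset(n_per_class = 8)
  keep <- ds$info$class_label == "NC"
  ds$data <- ds$data[, , , keep, drop = FALSE]
  ds$info <- ds$info[keep, , drop = FALSE]
  expect_error(
    train_task(build_model(seed = 1), ds, c("ADD", "NC"), train_config(epochs = 1)),
    "both classes"
  )
})

test_that("class imbalance is evened out by augmentation oversampling", {
  ds <- separable_patch_dataset(n_per_class = 12)
  keep <- c(which(ds$info$class_label == "ADD"), which(ds$info$class_label == "NC")[1:4])
  x <- ds$data[, , , keep, drop = FALSE]
  y <- ifelse(ds$info$class_label[keep] == "ADD", 1L, 2L)
  bal <- with_seed_local(
    4,
    tvpstage:::balance_by_augmentation(x, y, train_config())
  )
  expect_equal(sum(bal$y == 1L), sum(bal$y == 2L))
  expect_equal(dim(bal$x)[4], length(bal$y))
})

test_that("the transfer chain passes trained weights task to task", {
  ds <- separable_patch_dataset(n_per_class = 16)
  # extend to four classes by relabeling copies (weak but sufficient for a
  # chain-mechanics check)
  info2 <- ds$info
  info2$class_label <- ifelse(info2$class_label == "ADD", "mAD", "aAD")
  info2$subject_id <- paste0(info2$subject_id, "_b")
  ds4 <- ds
  ds4$data <- array(c(ds$data, ds$data), c(32, 32, 3, 2 * dim(ds$data)[4]))
  ds4$info <- rbind(ds$info, info2)
  tc <- train_config(epochs = 1, seed = 6)
  chain <- run_transfer_chain(17L, ds4, tc, order = default_transfer_order(),
                              init_seed = 99)
  expect_setequal(names(chain), names(ad_tasks()))
  # retraining the second task from the first task's weights reproduces it
  redo <- train_task(chain[["ADDvNC"]], ds4, ad_tasks()[["mADvNC"]], tc,
                     cv = FALSE)
  expect_equal(redo$model$params, chain[["mADvNC"]]$params, tolerance = 1e-12)
  # and differs from training that task from scratch
  fresh <- train_task(build_model(seed = 99), ds4, ad_tasks()[["mADvNC"]], tc,
                      cv = FALSE)
  expect_false(isTRUE(all.equal(fresh$model$params, chain[["mADvNC"]]$params)))
  expect_error(
    run_transfer_chain(17L, ds, tc),
    "no patches for class"
  )
})
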