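# Training protocol: stratified cohort splitting, per-task CNN training
# with scan-level 3-fold cross-validation and a plateau learning-rate
# schedule, the transfer-learning chain across the six binary tasks, and
# the ensemble fitting front end.

#' Training hyperparameters
#'
#' Defaults: 20 epochs, batch size 32, Adam at learning rate 0.001 with
#' exponential decay rates 0.9/0.999, the learning rate cut to a tenth
#' after the monitored loss fails to improve for three consecutive epochs,
#' and 3-fold cross-validation with folds split at scan level.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param plateau_factor multiplicative learning-rate cut on plateau.
#' @param plateau_patience epochs without improvement before a cut.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param folds cross-validation folds (>= 2).
#' @param balance_classes oversample the minority class with augmented
#'   copies so both classes contribute equally.
#' @param augment_shear_deg,augment_zoom,augment_rescale augmentation
#'   ranges used for the oversampled copies.
#' @param seed RNG seed for shuffling, folds and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20, batch_size = 32, lr = 0.001,
                         plateau_factor = 0.1, plateau_patience = 3,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         folds = 3, balance_classes = TRUE,
                         augment_shear_deg = 10, augment_zoom = 0.1,
                         augment_rescale = 0.1, seed = 1) {
  stopifnot(
    epochs >= 1, batch_size >= 1, lr > 0, plateau_factor > 0,
    plateau_patience >= 1, folds >= 2
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, plateau_factor = plateau_factor,
      plateau_patience = as.integer(plateau_patience),
      adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
      folds = as.integer(folds), balance_classes = balance_classes,
      augment_shear_deg = augment_shear_deg, augment_zoom = augment_zoom,
      augment_rescale = augment_rescale, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Stratified train/test split of a cohort
#'
#' Exactly `ceiling(test_fraction * n_c)` scans of each class go to the
#' test set (rounding up); the split is disjoint, exhaustive and seeded.
#'
#' @param manifest data frame with `subject_id` and `class_label`.
#' @param test_fraction fraction of each class kept for testing.
#' @param seed RNG seed.
#' @return list with `train_ids` and `test_ids`.
#' @export
split_cohort <- function(manifest, test_fraction = 0.5, seed = 1) {
  stopifnot(all(c("subject_id", "class_label") %in% names(manifest)))
  classes <- unique(manifest$class_label)
  test_ids <- character(0)
  with_seed(seed, {
    for (cl in sort_c(classes)) {
      ids <- manifest$subject_id[manifest$class_label == cl]
      if (length(ids) < 2) stopf("class %s has fewer than 2 scans", cl)
      n_test <- ceiling(test_fraction * length(ids))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  })
  list(
    train_ids = setdiff(manifest$subject_id, test_ids),
    test_ids = test_ids
  )
}

# Scan-level fold assignment: scans (not patches) are distributed over
# folds, stratified by class, so no scan's patches sit in two folds.
assign_folds <- function(scan_ids, scan_classes, folds, seed) {
  fold_of <- integer(length(scan_ids))
  names(fold_of) <- scan_ids
  with_seed(seed, {
    for (cl in sort_c(unique(scan_classes))) {
      ids <- scan_ids[scan_classes == cl]
      ids <- sample(ids)
      fold_of[ids] <- rep_len(seq_len(folds), length(ids))
    }
  })
  fold_of
}

# Core minibatch loop: Adam on cross-entropy with the plateau schedule.
# x [a, b, 3, n]; y integer class index (1 = first task class).  The
# monitored loss is validation loss when a validation set is given,
# otherwise the epoch's mean training loss.
fit_cnn <- function(model, x, y, config, x_val = NULL, y_val = NULL,
                    seed = config$seed) {
  n <- dim(x)[4]
  stopifnot(length(y) == n, n >= 2)
  state <- adam_init(model$params)
  lr <- config$lr
  best <- Inf
  wait <- 0L
  hist <- list()
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      at <- 1L
      while (at <= n) {
        take <- ord[at:min(n, at + config$batch_size - 1L)]
        fwd <- cnn_forward(model, x[, , , take, drop = FALSE], training = TRUE)
        bwd <- cnn_backward(model, fwd$cache, y[take])
        model <- bn_update_running(model, fwd$cache)
        upd <- adam_step(model$params, bwd$grads, state, lr,
          beta1 = config$adam_beta1, beta2 = config$adam_beta2
        )
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, bwd$loss)
        at <- at + config$batch_size
      }
      train_loss <- mean(losses)
      if (!is.null(x_val)) {
        pv <- predict_patch_scores(model, x_val)
        val_loss <- -mean(log(pv[cbind(seq_along(y_val), y_val)] + 1e-12))
        val_acc <- mean(max.col(pv) == y_val)
        monitored <- val_loss
      } else {
        val_loss <- NA_real_
        val_acc <- NA_real_
        monitored <- train_loss
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = train_loss,
        val_loss = val_loss, val_acc = val_acc
      )
      if (monitored < best - 1e-8) {
        best <- monitored
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          wait <- 0L
        }
      }
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

# Oversample the minority class to parity using augmented copies of its
# own patches.  Draws flow from the current RNG stream.
balance_by_augmentation <- function(x, y, config) {
  tab <- table(y)
  if (length(tab) < 2 || tab[1] == tab[2]) {
    return(list(x = x, y = y))
  }
  minority <- as.integer(names(tab)[which.min(tab)])
  need <- abs(diff(as.vector(tab)))
  pool <- which(y == minority)
  pick <- sample(pool, need, replace = TRUE)
  extra <- array(0, c(dim(x)[1:3], need))
  for (i in seq_len(need)) {
    extra[, , , i] <- augment_tvp(x[, , , pick[i]],
      seed = NULL,
      shear_deg = config$augment_shear_deg,
      zoom = config$augment_zoom, rescale = config$augment_rescale
    )
  }
  xb <- array(0, c(dim(x)[1:3], dim(x)[4] + need))
  xb[, , , seq_len(dim(x)[4])] <- x
  xb[, , , dim(x)[4] + seq_len(need)] <- extra
  list(x = xb, y = c(y, rep(minority, need)))
}

#' Train one region/task classifier
#'
#' Filters the patch dataset to the task's two classes, optionally runs
#' scan-level k-fold cross-validation (each fold trained from the same
#' initial weights, validation loss driving the plateau schedule), and
#' finally retrains on all patches.  Class imbalance is handled by
#' augmentation oversampling of the minority class.
#'
#' @param model an initialized or pretrained `tvp_cnn` (the chain input).
#' @param dataset a `tvp_dataset` holding this region's training patches
#'   for at least the two task classes.
#' @param task ordered class pair `(c_i, c_j)`; patches of `c_i` get
#'   class index 1.
#' @param config a [train_config()].
#' @param cv run the cross-validation folds (set `FALSE` to train on all
#'   patches directly, e.g. inside a large registry fit).
#' @return list: `model` (trained on all patches), `history` (final fit),
#'   `cv` (per-fold list with `fold`, `val_ids`, `history`), `task`.
#' @export
train_task <- function(model, dataset, task, config = train_config(),
                       cv = TRUE) {
  check_task(task)
  stopifnot(inherits(dataset, "tvp_dataset"))
  keep <- dataset$info$class_label %in% task
  if (!any(keep)) stopf("dataset has no patches for task %s", task_name(task))
  info <- dataset$info[keep, , drop = FALSE]
  x <- dataset$data[, , , keep, drop = FALSE]
  y <- ifelse(info$class_label == task[1], 1L, 2L)
  if (length(unique(y)) < 2) {
    stopf("task %s needs patches from both classes", task_name(task))
  }
  cv_out <- list()
  if (cv) {
    scan_ids <- unique(info$subject_id)
    scan_classes <- info$class_label[match(scan_ids, info$subject_id)]
    fold_of <- assign_folds(scan_ids, scan_classes, config$folds,
      seed = derive_seed(config$seed, 101)
    )
    for (f in seq_len(config$folds)) {
      val_ids <- scan_ids[fold_of[scan_ids] == f]
      val <- info$subject_id %in% val_ids
      if (!any(val) || all(val)) next
      bal <- with_seed(
        derive_seed(config$seed, 200 + f),
        if (config$balance_classes) {
          balance_by_augmentation(x[, , , !val, drop = FALSE], y[!val], config)
        } else {
          list(x = x[, , , !val, drop = FALSE], y = y[!val])
        }
      )
      fit <- fit_cnn(model, bal$x, bal$y, config,
        x_val = x[, , , val, drop = FALSE], y_val = y[val],
        seed = derive_seed(config$seed, 300 + f)
      )
      cv_out[[length(cv_out) + 1]] <- list(
        fold = f, val_ids = val_ids, history = fit$history
      )
    }
  }
  bal <- with_seed(
    derive_seed(config$seed, 400),
    if (config$balance_classes) {
      balance_by_augmentation(x, y, config)
    } else {
      list(x = x, y = y)
    }
  )
  fit <- fit_cnn(model, bal$x, bal$y, config,
    seed = derive_seed(config$seed, 500)
  )
  list(model = fit$model, history = fit$history, cv = cv_out, task = task)
}

#' Default transfer-learning chain order
#'
#' The chain starts from Xavier initialization on ADD/NC and passes the
#' trained weights from task to task:
#' ADD/NC, mAD/NC, ADD/aAD, ADD/mAD, mAD/aAD, aAD/NC.
#'
#' @return character vector of task names.
#' @export
default_transfer_order <- function() {
  c("ADDvNC", "mADvNC", "ADDvaAD", "ADDvmAD", "mADvaAD", "aADvNC")
}

#' Run the transfer chain for one region
#'
#' Trains the six binary tasks in `order`, initializing the first model
#' with Xavier weights and every subsequent task with the previous task's
#' trained weights.  Architecture and hyperparameters are identical along
#' the chain.
#'
#' @param roi_code region code (annotation only; the dataset is assumed
#'   already restricted to this region).
#' @param dataset a `tvp_dataset` with this region's training patches for
#'   all four classes.
#' @param config a [train_config()].
#' @param net a [model_config()].
#' @param order task-name character vector (a permutation of the six).
#' @param cv per-task cross-validation flag (see [train_task()]).
#' @param init_seed seed for the Xavier initialization of the first model.
#' @return named list of six trained `tvp_cnn` models, keyed by task name.
#' @export
run_transfer_chain <- function(roi_code, dataset, config = train_config(),
                               net = model_config(),
                               order = default_transfer_order(),
                               cv = FALSE, init_seed = config$seed) {
  tasks <- ad_tasks()
  if (!setequal(order, names(tasks))) {
    stopf("order must be a permutation of: %s", paste(names(tasks), collapse = ", "))
  }
  present <- unique(dataset$info$class_label)
  missing <- setdiff(PHANTOM_CLASSES, present)
  if (length(missing)) {
    stopf(
      "region %s: no patches for class(es) %s", roi_code,
      paste(missing, collapse = ", ")
    )
  }
  models <- list()
  current <- build_model(net, seed = init_seed)
  for (tn in order) {
    fit <- train_task(current, dataset, tasks[[tn]], config, cv = cv)
    models[[tn]] <- fit$model
    current <- fit$model
  }
  models
}

#' Fit a three-view-patch region ensemble
#'
#' The main fitting function: given a training cohort of labeled scans,
#' z-scores every volume, extracts training TVPs per region, and runs the
#' transfer chain per region, producing the full registry of
#' `6 regions x 6 tasks = 36` binary classifiers.  Predict scans with
#' [predict.tvp_ensemble()].
#'
#' @param scans list of `cohort_scan` objects (training scans).
#' @param config a [train_config()].
#' @param net a [model_config()].
#' @param catalog an `roi_catalog`.
#' @param spec a [patch_spec()].
#' @param order transfer-chain task order.
#' @param cv per-task cross-validation flag (default off for the full
#'   36-model fit; see [train_task()] for fold semantics).
#' @param max_patches_per_scan cap on training patches drawn per scan and
#'   region (uniform subsample of the exhaustive enumeration; `Inf` uses
#'   every in-bounds labeled voxel).
#' @param seed master seed; per-region sub-seeds are derived from it.
#' @return a `tvp_ensemble` object: `registry` (named list keyed
#'   `"<roi_code>_<task>"`), `catalog`, `tasks`, configs, and the training
#'   manifest.
#' @export
tvp_ensemble <- function(scans, config = train_config(), net = model_config(),
                         catalog = default_roi_catalog(), spec = patch_spec(),
                         order = default_transfer_order(), cv = FALSE,
                         max_patches_per_scan = 32, seed = config$seed) {
  stopifnot(length(scans) >= 2)
  classes <- vapply(scans, `[[`, character(1), "class_label")
  ids <- vapply(scans, `[[`, character(1), "subject_id")
  for (s in scans) check_paired(s$volume, s$segmentation)
  # normalize once, up front
  for (i in seq_along(scans)) {
    scans[[i]]$volume <- znormalize_volume(scans[[i]]$volume)
  }
  registry <- list()
  tasks <- ad_tasks()
  for (r in seq_len(nrow(catalog))) {
    code <- catalog$code[r]
    per_scan <- vector("list", length(scans))
    for (i in seq_along(scans)) {
      # exhaustive in-bounds voxel set; optionally a uniform subsample of
      # it, drawn before extraction so only the used patches are cut
      coords <- roi_voxels(scans[[i]]$segmentation, code, spec = spec)
      if (is.finite(max_patches_per_scan) && nrow(coords) > max_patches_per_scan) {
        pick <- with_seed(
          derive_seed(seed, r * 1000L + i),
          sample.int(nrow(coords), max_patches_per_scan)
        )
        coords <- coords[pick, , drop = FALSE]
      }
      per_scan[[i]] <- extract_tvp_dataset(
        scans[[i]]$volume, coords, spec,
        roi_codes = rep(code, nrow(coords)),
        class_label = scans[[i]]$class_label,
        subject_id = scans[[i]]$subject_id
      )
    }
    dataset <- rbind_tvp_datasets(per_scan)
    roi_config <- config
    roi_config$seed <- derive_seed(seed, 7000L + r)
    chain <- run_transfer_chain(code, dataset, roi_config, net,
      order = order,
      cv = cv, init_seed = derive_seed(seed, 9000L + r)
    )
    for (tn in names(chain)) {
      registry[[registry_key(code, tasks[[tn]])]] <- chain[[tn]]
    }
  }
  structure(
    list(
      registry = registry, catalog = catalog, tasks = tasks,
      config = config, net = net, spec = spec, order = order,
      max_patches_per_scan = max_patches_per_scan, seed = seed,
      train_manifest = data.frame(
        subject_id = ids, class_label = classes,
        stringsAsFactors = FALSE
      )
    ),
    class = "tvp_ensemble"
  )
}

#' @export
print.tvp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<tvp_ensemble: %d models (%d regions x %d tasks), trained on %d scans [%s]>\n",
    length(x$registry), nrow(x$catalog), length(x$tasks),
    nrow(x$train_manifest),
    paste(sprintf(
      "%s:%d", names(table(x$train_manifest$class_label)),
      table(x$train_manifest$class_label)
    ), collapse = " ")
  ))
  invisible(x)
}

#' @export
summary.tvp_ensemble <- function(object, ...) {
  pc <- count_parameters(object$registry[[1]])
  cat("Three-view-patch region ensemble\n")
  cat(sprintf(
    "  regions: %s\n",
    paste(object$catalog$abbrev, collapse = ", ")
  ))
  cat(sprintf("  tasks:   %s\n", paste(names(object$tasks), collapse = ", ")))
  cat(sprintf("  transfer order: %s\n", paste(object$order, collapse = " -> ")))
  cat(sprintf(
    "  per-model parameters: %d (%d trainable, %d non-trainable)\n",
    pc$total, pc$trainable, pc$non_trainable
  ))
  cat(sprintf(
    "  training scans: %d (%s)\n", nrow(object$train_manifest),
    paste(sprintf(
      "%s:%d", names(table(object$train_manifest$class_label)),
      table(object$train_manifest$class_label)
    ), collapse = " ")
  ))
  invisible(object)
}

#' Classify scans with a fitted ensemble
#'
#' Applies [classify_scan()] to every scan and requested task, returning
#' one row per scan, task and scoring unit (each region plus the
#' ensemble).
#'
#' @param object a fitted [tvp_ensemble()].
#' @param scans list of `cohort_scan` objects to classify.
#' @param tasks task names to run (default: all six).
#' @param n_patches test patches per region.
#' @param seed RNG seed (per-scan sub-seeds derived).
#' @param method `"score"` or `"vote"` for the scan decision.
#' @param ... unused.
#' @return data frame with columns `subject_id`, `class_label` (truth, NA
#'   if unknown), `task`, `unit` (`"LH"`..`"RI"` or `"ensemble"`), `S_i`,
#'   `S_j`, `predicted`, plus `decision_method` and `margin` on the
#'   ensemble rows.
#' @export
predict.tvp_ensemble <- function(object, scans, tasks = names(object$tasks),
                                 n_patches = 32, seed = 1,
                                 method = c("score", "vote"), ...) {
  method <- match.arg(method)
  if (inherits(scans, "cohort_scan")) scans <- list(scans)
  catalog <- object$catalog
  rows <- list()
  for (si in seq_along(scans)) {
    scan <- scans[[si]]
    scan$volume <- znormalize_volume(scan$volume)
    scan_seed <- derive_seed(seed, si)
    # test patches are sampled once per region and shared across tasks
    # (the sampling seed depends only on scan and region, exactly as in
    # classify_scan)
    tvps <- lapply(catalog$code, function(code) {
      sample_test_tvps(scan, code,
        n = n_patches,
        seed = derive_seed(scan_seed, code), spec = object$spec
      )
    })
    names(tvps) <- as.character(catalog$code)
    for (tn in tasks) {
      task <- object$tasks[[tn]]
      roi_scores <- vector("list", nrow(catalog))
      patch_scores <- vector("list", nrow(catalog))
      for (i in seq_len(nrow(catalog))) {
        code <- catalog$code[i]
        model <- object$registry[[registry_key(code, task)]]
        if (is.null(model)) stopf("registry has no model for %s", registry_key(code, task))
        sc <- predict_patch_scores(model, tvps[[as.character(code)]])
        patch_scores[[i]] <- sc
        roi_scores[[i]] <- aggregate_patch_scores(sc, roi_code = code, task = task)
      }
      ens <- ensemble_roi_scores(roi_scores, catalog)
      decision <- if (method == "score") {
        predicted <- if (ens$S[1] >= ens$S[2]) task[1] else task[2]
        structure(
          list(
            task = task, predicted = predicted,
            margin = unname(abs(ens$S[1] - ens$S[2])),
            method = "score_aggregation"
          ),
          class = "decision"
        )
      } else {
        majority_vote(do.call(rbind, patch_scores), task = task)
      }
      tab <- data.frame(
        unit = c(catalog$abbrev, "ensemble"),
        task = tn,
        S_i = c(vapply(roi_scores, function(r) r$S[1], numeric(1)), ens$S[1]),
        S_j = c(vapply(roi_scores, function(r) r$S[2], numeric(1)), ens$S[2]),
        stringsAsFactors = FALSE
      )
      tab$predicted <- ifelse(tab$S_i >= tab$S_j, task[1], task[2])
      tab$subject_id <- scan$subject_id %||% sprintf("scan%03d", si)
      tab$class_label <- scan$class_label %||% NA_character_
      tab$margin <- NA_real_
      tab$decision_method <- NA_character_
      ens_row <- tab$unit == "ensemble"
      tab$predicted[ens_row] <- decision$predicted
      tab$margin[ens_row] <- decision$margin
      tab$decision_method[ens_row] <- decision$method
      rows[[length(rows) + 1]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c(
    "subject_id", "class_label", "task", "unit", "S_i", "S_j",
    "predicted", "margin", "decision_method"
  )]
  rownames(out) <- NULL
  out
}
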