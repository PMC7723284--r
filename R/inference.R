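# Scan-level inference: per-region SoftMax score aggregation over patch
# scores, cross-region ensembling, and scan decisions (score aggregation
# or per-patch majority vote).

#' The six binary staging tasks
#'
#' Ordered class pairs, first element disease-ward:
#' (ADD,NC), (ADD,mAD), (ADD,aAD), (mAD,NC), (mAD,aAD), (aAD,NC).
#'
#' @return named list of length-2 character vectors.
#' @export
ad_tasks <- function() {
  tasks <- list(
    c("ADD", "NC"), c("ADD", "mAD"), c("ADD", "aAD"),
    c("mAD", "NC"), c("mAD", "aAD"), c("aAD", "NC")
  )
  names(tasks) <- vapply(tasks, task_name, character(1))
  tasks
}

#' @rdname ad_tasks
#' @param task length-2 character vector `(c_i, c_j)`.
#' @export
task_name <- function(task) paste(task, collapse = "v")

check_task <- function(task) {
  if (!(is.character(task) && length(task) == 2 &&
    all(task %in% PHANTOM_CLASSES) && task[1] != task[2])) {
    stopf("task must be an ordered pair of distinct class labels")
  }
  task
}

as_score_matrix <- function(scores) {
  s <- if (is.list(scores) && !is.data.frame(scores)) {
    do.call(rbind, scores)
  } else {
    as.matrix(scores)
  }
  if (ncol(s) != 2) stopf("scores must be pairs (two columns)")
  if (nrow(s) < 1) stopf("at least one score pair is required")
  if (!all(is.finite(s))) stopf("non-finite scores")
  s
}

#' Aggregate patch scores into a region score
#'
#' SoftMax aggregation over the patches of one region:
#' `S_i = sum_k exp(s_ik) / sum_k (exp(s_ik) + exp(s_jk))`, computed under
#' a single global max-shift (exact, by shift invariance of the ratio).
#'
#' @param scores per-patch score pairs: an `n x 2` matrix or a list of
#'   length-2 vectors (columns ordered as the task pair).
#' @param roi_code region code the patches came from.
#' @param task ordered class pair `(c_i, c_j)`.
#' @return an `roi_score` list: `roi_code`, `task`, `S` (named pair
#'   summing to 1).
#' @export
#' @examples
#' aggregate_patch_scores(rbind(c(1, 0)), 17, c("ADD", "NC"))$S[1]  # e/(e+1)
aggregate_patch_scores <- function(scores, roi_code = NA_integer_,
                                   task = c("ADD", "NC")) {
  s <- as_score_matrix(scores)
  check_task(task)
  m <- max(s)
  e <- exp(s - m)
  tot <- sum(e)
  S <- c(sum(e[, 1]) / tot, sum(e[, 2]) / tot)
  names(S) <- task
  structure(list(roi_code = as.integer(roi_code), task = task, S = S),
    class = "roi_score"
  )
}

#' Ensemble region scores across the six regions
#'
#' `S_i = sum_l exp(S_li) / sum_l (exp(S_li) + exp(S_lj))` over the six
#' catalog regions (order-invariant; every region must appear exactly
#' once, all for the same task).
#'
#' @param roi_scores list of six `roi_score` objects.
#' @param catalog an `roi_catalog` defining the required region set.
#' @return an `ensemble_score` list: `task`, `S` (named pair summing to
#'   1), `roi_scores`.
#' @export
ensemble_roi_scores <- function(roi_scores, catalog = default_roi_catalog()) {
  stopifnot(is.list(roi_scores), all(vapply(roi_scores, inherits, logical(1), "roi_score")))
  codes <- vapply(roi_scores, `[[`, integer(1), "roi_code")
  if (anyDuplicated(codes)) {
    stopf("duplicate region in ensemble: %s", codes[duplicated(codes)][1])
  }
  missing <- setdiff(catalog$code, codes)
  if (length(missing)) {
    stopf(
      "missing region(s) in ensemble: %s",
      paste(vapply(missing, function(cd) roi_abbrev(catalog, cd), character(1)),
        collapse = ", "
      )
    )
  }
  tasks <- unique(vapply(roi_scores, function(r) task_name(r$task), character(1)))
  if (length(tasks) != 1) stopf("all region scores must belong to one task")
  smat <- do.call(rbind, lapply(roi_scores, `[[`, "S"))
  e <- exp(smat)
  tot <- sum(e)
  S <- c(sum(e[, 1]) / tot, sum(e[, 2]) / tot)
  names(S) <- roi_scores[[1]]$task
  structure(
    list(task = roi_scores[[1]]$task, S = S, roi_scores = roi_scores),
    class = "ensemble_score"
  )
}

#' Majority vote over patch decisions
#'
#' Each patch votes for its argmax class; the class with most votes wins.
#' A tied vote falls back to SoftMax score aggregation on the same pairs
#' (and an aggregation tie resolves toward the first, disease-ward class).
#'
#' @inheritParams aggregate_patch_scores
#' @return a `decision` list: `task`, `predicted`, `margin` (vote-share
#'   difference, or score margin after a fallback), `method`.
#' @export
majority_vote <- function(scores, task = c("ADD", "NC")) {
  s <- as_score_matrix(scores)
  check_task(task)
  v1 <- sum(s[, 1] > s[, 2])
  v2 <- sum(s[, 2] > s[, 1])
  if (v1 != v2) {
    predicted <- if (v1 > v2) task[1] else task[2]
    margin <- abs(v1 - v2) / nrow(s)
    method <- "majority_vote"
  } else {
    agg <- aggregate_patch_scores(s, task = task)
    predicted <- if (agg$S[1] >= agg$S[2]) task[1] else task[2]
    margin <- abs(agg$S[1] - agg$S[2])
    method <- "majority_vote(score_fallback)"
  }
  structure(
    list(task = task, predicted = predicted, margin = unname(margin), method = method),
    class = "decision"
  )
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf(
    "<decision %s: %s (margin %.4f, %s)>\n",
    task_name(x$task), x$predicted, x$margin, x$method
  ))
  invisible(x)
}

#' Classify one scan for one task
#'
#' For each of the six regions, samples `n_patches` test TVPs (interior
#' voxels only), scores them with the region/task model, and SoftMax
#' aggregates them into a region score; the six region scores are then
#' ensembled into the task score pair and the argmax class is returned
#' (ties resolve toward the first, disease-ward class of the pair).
#' With `method = "vote"` the pooled patches vote instead.
#'
#' @param scan a `cohort_scan` (volume + segmentation).
#' @param registry a model registry: named list with entries
#'   `"<roi_code>_<task_name>"`, as built by [tvp_ensemble()].
#' @param task ordered class pair.
#' @param n_patches test patches per region (default 32).
#' @param seed RNG seed (per-region sub-seeds are derived from it).
#' @param method `"score"` (SoftMax aggregation) or `"vote"`.
#' @param catalog an `roi_catalog`.
#' @param spec a [patch_spec()].
#' @param normalize z-score the volume before patch extraction (set FALSE
#'   if the scan is already normalized).
#' @return a list: `decision` (a `decision`), `ensemble`
#'   (`ensemble_score`), `roi_scores`, `table` (per-region + ensemble
#'   score rows).
#' @export
classify_scan <- function(scan, registry, task, n_patches = 32, seed = 1,
                          method = c("score", "vote"),
                          catalog = default_roi_catalog(),
                          spec = patch_spec(), normalize = TRUE) {
  check_task(task)
  method <- match.arg(method)
  tn <- task_name(task)
  if (normalize) scan$volume <- znormalize_volume(scan$volume)
  roi_scores <- vector("list", nrow(catalog))
  patch_scores <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    code <- catalog$code[i]
    key <- registry_key(code, task)
    model <- registry[[key]]
    if (is.null(model)) stopf("registry has no model for %s", key)
    tvps <- sample_test_tvps(scan, code,
      n = n_patches,
      seed = derive_seed(seed, code), spec = spec
    )
    sc <- predict_patch_scores(model, tvps)
    patch_scores[[i]] <- sc
    roi_scores[[i]] <- aggregate_patch_scores(sc, roi_code = code, task = task)
  }
  ens <- ensemble_roi_scores(roi_scores, catalog)
  if (method == "score") {
    predicted <- if (ens$S[1] >= ens$S[2]) task[1] else task[2]
    decision <- structure(
      list(
        task = task, predicted = predicted,
        margin = unname(abs(ens$S[1] - ens$S[2])), method = "score_aggregation"
      ),
      class = "decision"
    )
  } else {
    decision <- majority_vote(do.call(rbind, patch_scores), task = task)
  }
  tab <- data.frame(
    unit = c(catalog$abbrev, "ensemble"),
    task = tn,
    S_i = c(vapply(roi_scores, function(r) r$S[1], numeric(1)), ens$S[1]),
    S_j = c(vapply(roi_scores, function(r) r$S[2], numeric(1)), ens$S[2]),
    stringsAsFactors = FALSE
  )
  tab$predicted <- ifelse(tab$S_i >= tab$S_j, task[1], task[2])
  list(decision = decision, ensemble = ens, roi_scores = roi_scores, table = tab)
}

registry_key <- function(roi_code, task) {
  sprintf("%d_%s", as.integer(roi_code), task_name(task))
}
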