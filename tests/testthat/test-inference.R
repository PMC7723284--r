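# SoftMax score aggregation (per region and across regions), majority
# vote, and scan classification.

test_that("region aggregation matches closed forms", {
  expect_equal(
    unname(aggregate_patch_scores(rbind(c(0.5, 0.5)))$S),
    c(0.5, 0.5),
    tolerance = 1e-12
  )
  one <- aggregate_patch_scores(rbind(c(1, 0)))
  expect_equal(unname(one$S[1]), exp(1) / (exp(1) + 1), tolerance = 1e-9)
  sym <- aggregate_patch_scores(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(sym$S), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(aggregate_patch_scores(matrix(0, 0, 2)), "at least one")
})

test_that("aggregation is shift-invariant and normalized", {
  set.seed(12)
  for (rep in 1:20) {
    s <- matrix(rnorm(2 * 8), ncol = 2)
    base <- aggregate_patch_scores(s)$S
    expect_equal(sum(base), 1, tolerance = 1e-9)
    shifted <- aggregate_patch_scores(s + rnorm(1, sd = 10))$S
    expect_equal(unname(base), unname(shifted), tolerance = 1e-9)
  }
})

test_that("raising one patch score strictly raises the region score", {
  s <- matrix(runif(16), ncol = 2)
  base <- aggregate_patch_scores(s)$S[1]
  s2 <- s
  s2[3, 1] <- s2[3, 1] + 0.2
  expect_gt(aggregate_patch_scores(s2)$S[1], base)
})

test_that("the six-region ensemble matches closed forms and is order-invariant", {
  task <- c("ADD", "NC")
  cat6 <- default_roi_catalog()
  mk <- function(S1, code) aggregate_patch_scores(rbind(c(S1, 1 - S1) * 2 - 0.5),
                                                  roi_code = code, task = task)
  # direct construction instead: six equal roi_scores
  rs <- lapply(cat6$code, function(cd) {
    structure(list(roi_code = cd, task = task, S = c(ADD = 0.5, NC = 0.5)),
              class = "roi_score")
  })
  expect_equal(unname(ensemble_roi_scores(rs)$S), c(0.5, 0.5), tolerance = 1e-12)

  p <- exp(1) / (exp(1) + 1) # 0.73106
  rs2 <- lapply(cat6$code, function(cd) {
    structure(list(roi_code = cd, task = task, S = c(ADD = p, NC = 1 - p)),
              class = "roi_score")
  })
  ens <- ensemble_roi_scores(rs2)
  expect_equal(unname(ens$S[1]), 1 / (1 + exp(-(2 * p - 1))), tolerance = 1e-9)
  expect_equal(unname(ens$S[1]), 0.6135, tolerance = 1e-4)
  expect_equal(sum(ens$S), 1, tolerance = 1e-9)

  perm <- ensemble_roi_scores(rs2[c(4, 2, 6, 1, 3, 5)])
  expect_equal(perm$S, ens$S, tolerance = 1e-12)
})

test_that("incomplete or duplicated region sets are rejected", {
  task <- c("ADD", "NC")
  rs <- lapply(default_roi_catalog()$code, function(cd) {
    structure(list(roi_code = cd, task = task, S = c(ADD = 0.6, NC = 0.4)),
              class = "roi_score")
  })
  expect_error(ensemble_roi_scores(rs[1:5]), "missing region")
  expect_error(ensemble_roi_scores(c(rs[1:5], rs[5])), "duplicate")
  rs[[1]]$task <- c("ADD", "mAD")
  expect_error(ensemble_roi_scores(rs), "one task")
})

test_that("majority vote counts argmax votes with score-aggregation fallback", {
  d1 <- majority_vote(rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6)), c("ADD", "NC"))
  expect_equal(d1$predicted, "ADD")
  expect_equal(d1$margin, 1 / 3, tolerance = 1e-12)
  expect_equal(d1$method, "majority_vote")

  tie <- majority_vote(rbind(c(0.9, 0.1), c(0.1, 0.9)), c("ADD", "NC"))
  expect_equal(tie$predicted, "ADD") # fallback lands at (0.5, 0.5), disease-ward tie rule
  expect_match(tie$method, "fallback")

  un <- majority_vote(rbind(c(0.8, 0.2), c(0.7, 0.3)), c("mAD", "NC"))
  expect_equal(un$predicted, "mAD")
  expect_equal(un$margin, 1.0)
  expect_error(majority_vote(matrix(0, 0, 2), c("ADD", "NC")), "at least one")
})

test_that("scan classification is deterministic and produces normalized tables", {
  scan <- cached_nc_scan()
  model <- build_model(seed = 1)
  task <- c("ADD", "NC")
  registry <- list()
  for (cd in default_roi_catalog()$code) {
    registry[[tvpstage:::registry_key(cd, task)]] <- model
  }
  r1 <- classify_scan(scan, registry, task, n_patches = 8, seed = 5)
  r2 <- classify_scan(scan, registry, task, n_patches = 8, seed = 5)
  expect_identical(r1$decision$predicted, r2$decision$predicted)
  expect_equal(r1$table$S_i, r2$table$S_i, tolerance = 0)
  expect_equal(r1$table$S_i + r1$table$S_j, rep(1, 7), tolerance = 1e-9)
  expect_equal(nrow(r1$table), 7)
  expect_true(r1$decision$predicted %in% task)
  # vote method runs on the same registry
  rv <- classify_scan(scan, registry, task, n_patches = 8, seed = 5, method = "vote")
  expect_match(rv$decision$method, "vote")
  # missing model is a registry error
  expect_error(
    classify_scan(scan, registry[-1], task, n_patches = 8, seed = 5),
    "registry"
  )
})
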