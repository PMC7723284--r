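# Region-of-interest selection: two-group permutation tests on regional
# morphometry, p-value ranking, and pairwise (bilateral) selection.

#' Two-group permutation test on the absolute difference of means
#'
#' Tests the null hypothesis that the two groups' measures are identically
#' distributed, using `T = |mean(a) - mean(b)|` as the statistic (two-sided
#' by construction).  When the number of distinct label assignments
#' `choose(n_a + n_b, n_a)` is at most `max_exhaustive`, every assignment
#' is enumerated and `p = #\{T_perm >= T_obs\} / total` (the identity
#' assignment counts, so `p > 0`).  Otherwise a seeded Monte-Carlo sample
#' of assignments is drawn and the add-one rule
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)` keeps the p-value valid
#' and strictly positive.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param n_perm number of Monte-Carlo permutations (ignored in exhaustive
#'   mode).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param max_exhaustive largest number of assignments enumerated exactly.
#' @return a `permutation_result` list: `observed_stat`, `p_value`,
#'   `n_permutations`, `mode` (`"exhaustive"` or `"monte_carlo"`).
#' @export
#' @examples
#' permutation_test(c(1, 2, 3), c(4, 5, 6))$p_value   # 2/20
permutation_test <- function(group_a, group_b, n_perm = 9999, seed = 1,
                             max_exhaustive = 20000) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stopf("each group needs at least 2 values")
  }
  if (!all(is.finite(c(group_a, group_b)))) stopf("non-finite values in input")
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb
  pooled <- c(group_a, group_b)
  total_sum <- sum(pooled)
  t_obs <- abs(mean(group_a) - mean(group_b))
  # tolerance so exact ties under permutation are counted as >=
  eps <- 1e-9 * max(1, abs(t_obs))
  stat_for_subset_sum <- function(sa) abs(sa / na - (total_sum - sa) / nb)
  n_comb <- choose(n, na)
  if (n_comb <= max_exhaustive) {
    idx <- utils::combn(n, na)
    sa <- colSums(matrix(pooled[idx], nrow = na))
    t_perm <- stat_for_subset_sum(sa)
    p <- sum(t_perm >= t_obs - eps) / n_comb
    mode <- "exhaustive"
    n_used <- as.integer(n_comb)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (i in seq_len(n_perm)) {
        sa <- sum(pooled[sample.int(n, na)])
        if (stat_for_subset_sum(sa) >= t_obs - eps) h <- h + 1L
      }
      h
    })
    p <- (1 + hits) / (1 + n_perm)
    mode <- "monte_carlo"
    n_used <- as.integer(n_perm)
  }
  structure(
    list(
      region_name = NA_character_, measure = NA_character_,
      observed_stat = t_obs, p_value = p,
      n_permutations = n_used, mode = mode
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result%s: T = %.6g, p = %.4g (%s, %d permutations)>\n",
    if (is.na(x$region_name)) "" else paste0(" ", x$region_name),
    x$observed_stat, x$p_value, x$mode, x$n_permutations
  ))
  invisible(x)
}

#' Rank regions by permutation-test p-value
#'
#' Runs [permutation_test()] per region on one morphometry measure for a
#' pair of classes and returns the regions sorted by ascending p-value
#' (ties broken by larger observed statistic, then region name).  Regions
#' for which either class is absent are dropped with a warning.
#'
#' @param table a morphometry table as from [generate_measure_table()]:
#'   columns `subject_id`, `class_label`, `region_name` and the measure.
#' @param classes length-2 character vector of class labels to compare.
#' @param measure `"V"` (volume percentile of ICV) or `"T"` (thickness).
#' @param n_perm,seed,max_exhaustive passed to [permutation_test()]; each
#'   region gets its own deterministic sub-seed.
#' @return a data frame, one row per region, ordered by rank: columns
#'   `region_name`, `measure`, `observed_stat`, `p_value`,
#'   `n_permutations`, `mode`.
#' @export
rank_regions <- function(table, classes, measure = "V",
                         n_perm = 9999, seed = 1, max_exhaustive = 20000) {
  stopifnot(length(classes) == 2, measure %in% c("V", "T", "P"))
  if (!all(classes %in% table$class_label)) {
    stopf("both classes must be present in the table")
  }
  regions <- sort_c(unique(table$region_name))
  rows <- list()
  for (i in seq_along(regions)) {
    reg <- regions[i]
    sub <- table[table$region_name == reg, ]
    a <- sub[[measure]][sub$class_label == classes[1]]
    b <- sub[[measure]][sub$class_label == classes[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("region %s skipped: a class is missing or too small", reg))
      next
    }
    res <- permutation_test(a, b,
      n_perm = n_perm, seed = derive_seed(seed, i),
      max_exhaustive = max_exhaustive
    )
    rows[[length(rows) + 1]] <- data.frame(
      region_name = reg, measure = measure,
      observed_stat = res$observed_stat, p_value = res$p_value,
      n_permutations = res$n_permutations, mode = res$mode,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stopf("no region had both classes present")
  out <- do.call(rbind, rows)
  ord <- order(out$p_value, -out$observed_stat, out$region_name,
    method = "radix"
  )
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Select the top region pairs from a ranking
#'
#' Walks the ranking from the lowest p-value down; whenever a region is
#' taken its contralateral partner (catalog pairing) is taken with it,
#' until `k_pairs` whole pairs are selected.
#'
#' @param ranked a ranking data frame from [rank_regions()], or a character
#'   vector of region names/abbreviations in rank order.
#' @param catalog an `roi_catalog` supplying the laterality pairing.
#' @param k_pairs number of bilateral pairs to select.
#' @return character vector of `2 * k_pairs` region identifiers, in
#'   selection order, using the same naming style as the input.
#' @export
#' @examples
#' sel <- select_top_pairs(c("LH", "RH", "LI", "RA", "LA", "RI"), k_pairs = 3)
select_top_pairs <- function(ranked, catalog = default_roi_catalog(), k_pairs = 3) {
  names_in <- if (is.data.frame(ranked)) ranked$region_name else as.character(ranked)
  if (!length(names_in)) stopf("ranking is empty")
  codes <- vapply(names_in, function(r) roi_code(catalog, r), integer(1))
  n_pairs_avail <- length(unique(pmin(codes, vapply(codes, function(cd) roi_partner(catalog, cd), integer(1)))))
  if (n_pairs_avail < k_pairs) {
    stopf("ranking holds %d pair(s), %d requested", n_pairs_avail, k_pairs)
  }
  use_abbrev <- all(names_in %in% catalog$abbrev)
  label_of <- function(code) {
    if (use_abbrev) roi_abbrev(catalog, code) else roi_name(catalog, code)
  }
  selected <- integer(0)
  pairs_done <- 0L
  for (cd in codes) {
    if (pairs_done >= k_pairs) break
    if (cd %in% selected) next
    selected <- c(selected, cd, roi_partner(catalog, cd))
    pairs_done <- pairs_done + 1L
  }
  vapply(selected, label_of, character(1))
}
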