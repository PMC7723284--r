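# Shared fixtures: small deterministic phantoms and patch datasets built
# in code at test time.

small_config <- function(n = 2, seed = 42) {
  phantom_config(n_per_class = c(NC = n, aAD = n, mAD = n, ADD = n), seed = seed)
}

# One cached NC scan at the default geometry (generation is ~0.15 s; many
# tests only need to read it).
cached_nc_scan <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_phantom_scan("NC", small_config(), subject_seed = 1234,
                                    subject_id = "nc_fixture")
    }
    val
  }
})

# Tiny separable patch dataset: class means well apart on a noisy
# background, enough for a CNN sanity fit.
separable_patch_dataset <- function(n_per_class = 32, delta = 2, seed = 9,
                                    n_scans_per_class = 2) {
  spec <- patch_spec()
  total <- 2 * n_per_class
  data <- array(0, c(spec$alpha, spec$beta, 3, total))
  cls <- rep(c("ADD", "NC"), each = n_per_class)
  mu <- ifelse(cls == "ADD", delta / 2, -delta / 2)
  with_seed_local(seed, {
    for (i in seq_len(total)) {
      data[, , , i] <- array(rnorm(spec$alpha * spec$beta * 3, mu[i], 1),
                             c(spec$alpha, spec$beta, 3))
    }
  })
  scan_ids <- paste0(
    cls, "_scan",
    rep_len(rep(seq_len(n_scans_per_class), each = ceiling(n_per_class / n_scans_per_class)), total)
  )
  info <- data.frame(
    subject_id = scan_ids,
    x = 17L, y = 17L, z = 17L, roi_code = 17L, class_label = cls,
    stringsAsFactors = FALSE
  )
  structure(list(data = data, info = info, spec = spec), class = "tvp_dataset")
}

# Local copy of the package-internal seed guard for helpers.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
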