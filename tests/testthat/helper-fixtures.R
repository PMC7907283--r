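# In-code fixtures shared across the suite. Everything is generated at test
# time; no binary data.

# A minimal valid cell table. `flags` is a named list marker -> 0/1 vector
# (unlisted markers default to all-zero).
make_cells <- function(x, y, compartment = "epithelial", flags = list(),
                       case_id = "c1", roi_id = "r1") {
  n <- length(x)
  d <- data.frame(
    cell_id = sprintf("%s_%04d", roi_id, seq_len(n)),
    case_id = case_id, roi_id = roi_id, x = x, y = y,
    compartment = rep(compartment, length.out = n),
    stringsAsFactors = FALSE)
  for (m in mif_markers()) {
    d[[m]] <- if (m %in% names(flags)) as.integer(flags[[m]]) else 0L
  }
  d
}

# Uniform random cells in a window, each marker flagged with probability p.
random_cells <- function(n, seed, width = 931, height = 698, p = 0.3,
                         case_id = "c1", roi_id = "r1") {
  set.seed(seed)
  flags <- lapply(mif_markers(), function(m) as.integer(runif(n) < p))
  names(flags) <- mif_markers()
  make_cells(runif(n, 0, width), runif(n, 0, height),
             compartment = sample(c("epithelial", "stroma"), n, replace = TRUE),
             flags = flags, case_id = case_id, roi_id = roi_id)
}

# Independent brute-force oracle: per-query nearest distance via a plain
# double loop over an R distance matrix (sqrt before min, opposite order to
# the package's C code).
oracle_nn_dist <- function(from, to) {
  vapply(seq_along(from$x), function(i) {
    min(sqrt((from$x[i] - to$x)^2 + (from$y[i] - to$y)^2))
  }, 0)
}

# Independent brute-force G function: CDF of oracle NN distances.
oracle_g <- function(reference, target, r_grid) {
  nnd <- oracle_nn_dist(reference, target)
  vapply(r_grid, function(r) mean(nnd <= r), 0)
}

# Independent rule evaluator for phenotype definitions (set-based, no
# matrix algebra shared with call_phenotypes).
oracle_match <- function(flag_vector, positives, negatives) {
  on <- names(flag_vector)[as.logical(flag_vector)]
  all(positives %in% on) && !any(negatives %in% on)
}
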