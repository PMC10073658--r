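# Small programmatic fixtures shared across tests.

random_stack <- function(h = 12, w = 14, n = 5, seed = 1, levels = 0:255) {
  withr::with_seed(seed,
    frame_stack(array(sample(levels, h * w * n, TRUE), c(h, w, n))))
}

# tiny separable feature set: positives carry mass in column `pos_col`,
# negatives in column 1 (mimicking histogram bin structure)
toy_features <- function(n_pos = 20, n_neg = 20, dim = 24, pos_col = 6,
                         seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(abs(rnorm((n_pos + n_neg) * dim, 0, 0.05)), ncol = dim)
    x[seq_len(n_pos), pos_col] <- x[seq_len(n_pos), pos_col] + 1
    x[n_pos + seq_len(n_neg), 1] <- x[n_pos + seq_len(n_neg), 1] + 1
    list(x = x, y = rep(c(1L, 0L), c(n_pos, n_neg)))
  })
}

# segments of linearly separable random features for CV plumbing tests
toy_segments <- function(n_seg = 4, n_frames = 60, dim = 16, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n_seg), function(s) {
    y <- as.integer(runif(n_frames) < 0.3)
    x <- matrix(rnorm(n_frames * dim, 0, 0.2), ncol = dim)
    x[, 2] <- x[, 2] + 2 * y
    list(features = x, labels = y)
  }))
}

# balanced activity table for LMM tests, generated from an explicit linear
# model (used where the truth must be exact rather than scenario-derived)
toy_lmm_data <- function(n_cage = 8, sd_cage = 0, sd_noise = 1, seed = 1,
                         beta_geno = 3) {
  withr::with_seed(seed, {
    d <- expand.grid(cage_id = sprintf("c%02d", seq_len(n_cage)),
                     day = 1:3, KEEP.OUT.ATTRS = FALSE)
    d$Genotype <- factor(ifelse(as.integer(sub("c", "", d$cage_id)) %% 2 == 0,
                                "Hemi", "WT"), levels = c("WT", "Hemi"))
    u <- rnorm(n_cage, 0, sd_cage)
    d$y <- 10 + beta_geno * (d$Genotype == "Hemi") +
      u[as.integer(factor(d$cage_id))] + rnorm(nrow(d), 0, sd_noise)
    d
  })
}
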