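# Independent brute-force reference implementations used to cross-check the
# package. These follow the definitions directly (plain loops, no shared
# code with the implementation under test).

# neighbour offsets clockwise from top-left, (dy, dx) at unit radius
ORACLE_NB <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                    ncol = 2, byrow = TRUE)

oracle_patch_ssd <- function(fa, fb, y, x, dy, dx, ph) {
  s <- 0
  for (oy in -ph:ph) for (ox in -ph:ph)
    s <- s + (fa[y + oy, x + ox] - fb[y + dy + oy, x + dx + ox])^2
  s
}

# trit codes for one frame of a cropped stack (1-based t within the array)
oracle_trit_codes <- function(frames, t, delta, ph, radius, tau) {
  h <- dim(frames)[1]; w <- dim(frames)[2]
  ft <- frames[, , t]; fm <- frames[, , t - delta]; fp <- frames[, , t + delta]
  m <- ph + radius
  bp <- bm <- matrix(NA_integer_, h, w)
  for (x in (m + 1):(w - m)) for (y in (m + 1):(h - m)) {
    cp <- cm <- 0L
    for (i in 1:8) {
      dy <- ORACLE_NB[i, 1] * radius; dx <- ORACLE_NB[i, 2] * radius
      dminus <- oracle_patch_ssd(ft, fm, y, x, dy, dx, ph)
      dplus <- oracle_patch_ssd(ft, fp, y, x, dy, dx, ph)
      if (dminus - dplus > tau) cp <- cp + 2L^(i - 1)
      else if (dplus - dminus > tau) cm <- cm + 2L^(i - 1)
    }
    bp[y, x] <- cp; bm[y, x] <- cm
  }
  list(b_plus = bp, b_minus = bm)
}

# pooled histogram feature from oracle trit codes
oracle_ltp_feature <- function(frames, t, params) {
  h <- dim(frames)[1]; w <- dim(frames)[2]
  tc <- oracle_trit_codes(frames, t, params$delta, params$patch_half,
                          params$neighbor_radius, params$tau)
  gc <- params$grid_cols; gr <- params$grid_rows
  cw <- w %/% gc; ch <- h %/% gr
  out <- numeric(gc * gr * 512)
  for (x in 1:w) for (y in 1:h) {
    if (is.na(tc$b_plus[y, x])) next
    cc <- min((x - 1) %/% cw, gc - 1)
    cr <- min((y - 1) %/% ch, gr - 1)
    cell <- cr * gc + cc
    out[cell * 512 + tc$b_plus[y, x] + 1] <- out[cell * 512 + tc$b_plus[y, x] + 1] + 1
    out[cell * 512 + 256 + tc$b_minus[y, x] + 1] <- out[cell * 512 + 256 + tc$b_minus[y, x] + 1] + 1
  }
  if (params$normalize == "l1") {
    for (k in seq_len(gc * gr * 2)) {
      idx <- (k - 1) * 256 + 1:256
      s <- sum(out[idx])
      if (s > 0) out[idx] <- out[idx] / s
    }
  }
  out
}

# sliding-window majority vote by direct scan
oracle_vote <- function(raw, k, theta) {
  n <- length(raw)
  out <- integer(n)
  for (t in 1:n) {
    win <- raw[max(1, t - k):min(n, t + k)]
    out[t] <- as.integer(sum(win) > theta * length(win))
  }
  out
}

# per-frame counting consensus
oracle_consensus <- function(series, rule) {
  n <- length(series[[1]])
  out <- integer(n)
  for (t in 1:n) {
    v <- sum(vapply(series, function(s) s[t], 0L))
    out[t] <- if (rule == "any") as.integer(v >= 1)
              else as.integer(v > length(series) / 2)
  }
  out
}

# confusion-matrix metrics by direct counting
oracle_metrics <- function(pred, gold) {
  tp <- fp <- tn <- fn <- 0
  for (t in seq_along(gold)) {
    if (gold[t] == 1) { if (pred[t] == 1) tp <- tp + 1 else fn <- fn + 1 }
    else              { if (pred[t] == 0) tn <- tn + 1 else fp <- fp + 1 }
  }
  list(accuracy = (tp + tn) / length(gold),
       recall_climbing = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       recall_nonclimbing = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Spearman rho = Pearson on average ranks, computed by hand
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Benjamini-Hochberg step-up rule applied literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i, 1)
    adj[o[i]] <- running
  }
  adj
}

# union of half-open intervals by frame-fill
oracle_interval_union <- function(start, end, n) {
  cov <- logical(n)
  for (k in seq_along(start)) cov[(start[k] + 1):end[k]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}
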