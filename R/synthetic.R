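#' Synthetic climbing-video scenario
#'
#' Describes a seeded generator for home-cage-like grayscale video with
#' planted climbing bouts. The default frame is 160 x 120 px with a
#' 160 x 96 px lid region of interest across the top (a reduced desk-scale
#' stand-in for full-resolution cage video; the descriptor dimension depends
#' only on the pooling grid, not on the region size). Climbing and
#' non-climbing episodes alternate with gamma-distributed durations (means 8 s
#' on, 60 s off), during which a high-contrast blob oscillates vertically
#' inside the region — the signature the detector must learn. A floor
#' distractor moves below the region throughout, and i.i.d. Gaussian pixel
#' noise (quantized to 8 bits) is added everywhere.
#'
#' @param n_frames frames per segment (default 3000 = 2 min at 25 fps).
#' @param frame_width,frame_height frame size in px.
#' @param region the lid [roi()].
#' @param frame_rate_hz frames per second (default 25).
#' @param off_mean_s,on_mean_s mean non-climbing / climbing episode duration
#'   in seconds.
#' @param gamma_shape shape of the gamma duration distributions.
#' @param blob_w,blob_h,blob_intensity climbing blob size (px) and intensity.
#' @param osc_amp_px,osc_freq_hz vertical oscillation amplitude and frequency
#'   of the climbing blob.
#' @param distractor draw a moving floor distractor below the region.
#' @param noise_sd pixel noise standard deviation in intensity units.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @return An object of class `video_scenario`.
#' @export
video_scenario <- function(n_frames = 3000, frame_width = 160,
                           frame_height = 120,
                           region = roi(0, 0, 160, 96),
                           frame_rate_hz = 25,
                           off_mean_s = 60, on_mean_s = 8, gamma_shape = 2,
                           blob_w = 24, blob_h = 18, blob_intensity = 215,
                           osc_amp_px = 18, osc_freq_hz = 1.5,
                           distractor = TRUE, noise_sd = 1, seed = 1) {
  structure(as.list(environment()), class = "video_scenario")
}

#' Alternating bout process
#'
#' Simulates the gold frame labels of a segment: non-climbing and climbing
#' episodes alternate (starting non-climbing) with independent
#' gamma-distributed durations. The long-run climbing fraction is
#' `on_mean_s / (on_mean_s + off_mean_s)`.
#'
#' @inheritParams video_scenario
#' @return Integer 0/1 vector of length `n_frames`.
#' @export
simulate_bout_labels <- function(n_frames, frame_rate_hz = 25,
                                 off_mean_s = 60, on_mean_s = 8,
                                 gamma_shape = 2) {
  labels <- integer(n_frames)
  t <- 0L
  on <- FALSE
  while (t < n_frames) {
    mean_s <- if (on) on_mean_s else off_mean_s
    dur <- max(1L, as.integer(round(
      rgamma(1, shape = gamma_shape, scale = mean_s / gamma_shape) *
        frame_rate_hz)))
    if (on) labels[(t + 1):min(t + dur, n_frames)] <- 1L
    t <- t + dur
    on <- !on
  }
  labels
}

#' Generate a synthetic climbing video
#'
#' @param scenario a [video_scenario()].
#' @param segment_id identifier for the gold bout table.
#' @return List: `stack` (a [frame_stack()]), `labels` (gold 0/1 per frame),
#'   `bouts` (gold bout table, annotator `"gold"`). The gold bouts are
#'   exactly the frames where the climbing texture is active.
#' @export
generate_video <- function(scenario, segment_id = "seg1") {
  stopifnot(inherits(scenario, "video_scenario"))
  s <- scenario
  rr <- s$region
  if (rr$y0 + rr$height > s$frame_height || rr$x0 + rr$width > s$frame_width)
    stop("roi extends past the frame bounds")
  withr::with_seed(s$seed, {
    h <- s$frame_height; w <- s$frame_width; n <- s$n_frames
    labels <- simulate_bout_labels(n, s$frame_rate_hz, s$off_mean_s,
                                   s$on_mean_s, s$gamma_shape)
    # static background: vertical gradient plus frozen texture
    bg <- 60 + 40 * outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w)) +
      matrix(runif(h * w, -8, 8), h, w)
    bg <- round(bg)
    # one horizontal anchor and oscillation phase per bout
    bouts <- labels_to_bouts(labels, segment_id, "gold")
    if (s$blob_w >= rr$width || s$blob_h > rr$height)
      stop("climb blob does not fit inside the region of interest")
    nb <- nrow(bouts)
    bx <- if (nb) round(runif(nb, rr$x0, rr$x0 + rr$width - s$blob_w - 1))
    bphase <- if (nb) runif(nb, 0, 2 * pi)
    bout_of <- integer(n)
    for (k in seq_len(nb))
      bout_of[(bouts$start_frame[k] + 1):bouts$end_frame[k]] <- k
    # distractor random walk in the floor strip below the region
    floor_top <- rr$y0 + rr$height
    has_floor <- s$distractor && floor_top + 14 < h
    if (has_floor) {
      dx <- cumsum(c(round(runif(1, 0, w - 22)), sample(-3:3, n - 1, TRUE)))
      dx <- pmin(pmax(dx, 0), w - 21)
      dy <- pmin(pmax(cumsum(c(floor_top + 2, sample(-1:1, n - 1, TRUE))),
                      floor_top), h - 15)
    }
    yc_base <- rr$y0 + (rr$height - s$blob_h) / 2
    frames <- array(0L, dim = c(h, w, n))
    for (t in seq_len(n)) {
      f <- bg
      k <- bout_of[t]
      if (k > 0) {
        tt <- (t - 1 - bouts$start_frame[k]) / s$frame_rate_hz
        yc <- yc_base + s$osc_amp_px * sin(2 * pi * s$osc_freq_hz * tt + bphase[k])
        yc <- min(max(round(yc), rr$y0), rr$y0 + rr$height - s$blob_h)
        xs <- bx[k] + seq_len(s$blob_w)
        ys <- yc + seq_len(s$blob_h)
        f[ys, xs] <- s$blob_intensity
      }
      if (has_floor)
        f[dy[t] + seq_len(14), dx[t] + seq_len(20)] <- 25
      if (s$noise_sd > 0)
        f <- f + round(matrix(rnorm(h * w, 0, s$noise_sd), h, w))
      frames[, , t] <- pmin(pmax(f, 0L), 255L)
    }
    list(stack = frame_stack(frames, s$frame_rate_hz), labels = labels,
         bouts = bouts)
  })
}

#' Simulate imperfect human annotators
#'
#' Each annotator independently misses each gold bout with probability
#' `miss_prob`, jitters the surviving bout boundaries by rounded Gaussian
#' noise (clamped to the segment), and adds spurious bouts from a Poisson
#' process (gamma-distributed durations, mean 2 s). Zero-noise annotators
#' reproduce the gold bouts exactly.
#'
#' @param gold gold bout table for one segment.
#' @param n_frames segment length in frames.
#' @param frame_rate_hz frames per second.
#' @param n_annotators number of annotators (default 3).
#' @param jitter_sd boundary jitter standard deviation in frames.
#' @param miss_prob per-bout miss probability.
#' @param false_rate_per_h spurious bouts per hour.
#' @param seed integer seed.
#' @return A bout table with annotator ids `"A1"`, `"A2"`, ...
#' @export
simulate_annotators <- function(gold, n_frames, frame_rate_hz = 25,
                                n_annotators = 3, jitter_sd = 5,
                                miss_prob = 0.05, false_rate_per_h = 2,
                                seed = 1) {
  segment_id <- if (nrow(gold)) gold$segment_id[1] else "seg"
  hours <- n_frames / frame_rate_hz / 3600
  withr::with_seed(seed, {
    tabs <- lapply(seq_len(n_annotators), function(a) {
      rows <- list()
      for (k in seq_len(nrow(gold))) {
        if (runif(1) < miss_prob) next
        st <- gold$start_frame[k] + round(rnorm(1, 0, jitter_sd))
        en <- gold$end_frame[k] + round(rnorm(1, 0, jitter_sd))
        st <- min(max(st, 0L), n_frames - 1L)
        en <- min(max(en, 1L), n_frames)
        if (en > st)
          rows[[length(rows) + 1L]] <- c(st, en)
      }
      nfalse <- rpois(1, false_rate_per_h * hours)
      for (k in seq_len(nfalse)) {
        dur <- max(1L, round(rgamma(1, shape = 2, scale = 1) * frame_rate_hz))
        st <- floor(runif(1, 0, max(n_frames - dur, 1)))
        rows[[length(rows) + 1L]] <- c(st, min(st + dur, n_frames))
      }
      if (!length(rows))
        return(data.frame(segment_id = character(), annotator_id = character(),
                          start_frame = integer(), end_frame = integer(),
                          label = character()))
      m <- do.call(rbind, rows)
      suppressWarnings(normalize_bouts(
        data.frame(segment_id = segment_id,
                   annotator_id = paste0("A", a),
                   start_frame = as.integer(m[, 1]),
                   end_frame = as.integer(m[, 2]),
                   label = "climbing", stringsAsFactors = FALSE)))
    })
    do.call(rbind, tabs)
  })
}

#' Synthetic cage-activity scenario
#'
#' Describes a seeded generator for per-cage 6-min-binned activity with
#' circadian, sex, age and genotype structure: a dark-phase-dominant
#' biphasic baseline (crepuscular peaks at the two ends of the dark phase),
#' multiplicative sex and age effects, and a genotype deficit confined to the
#' last 30 min of darkness (the Huntington's-disease-like signature:
#' hemizygous cages reach only `genotype_deficit` times the wild-type level
#' there). Cages carry random intercepts and random day-of-recording slopes;
#' Gaussian observation noise is added per bin and values are floored at 0.
#' Random-effect and noise scales are expressed as fractions of the
#' channel's dark baseline so both channels are perturbed proportionately.
#'
#' @param baseline_dark_mm,baseline_light_mm mean cage distance per 6-min bin
#'   (mm) in dark / light.
#' @param baseline_dark_s,baseline_light_s mean cage climbing per 6-min bin
#'   (seconds).
#' @param biphasic_amp relative amplitude of the within-dark cosine
#'   modulation (peaks at the dark-phase ends).
#' @param sex_mult,age_mult named multipliers for sex (F, M) and age
#'   (young, old).
#' @param genotype_deficit multiplier (< 1 for a deficit) applied to
#'   hemizygous cages in the end-of-dark window only; 1 disables the effect.
#' @param cage_sd_frac,day_slope_sd_frac,noise_sd_frac random-intercept,
#'   random-slope and observation-noise SDs as fractions of the dark
#'   baseline.
#' @param n_per_group cages per Age x Genotype x Sex cell (default 3, giving
#'   24 cages).
#' @param n_days recording days per cage (default 3).
#' @param bin_length_min bin length (default 6 min).
#' @param seed integer seed.
#' @return An object of class `activity_scenario`.
#' @export
activity_scenario <- function(baseline_dark_mm = 9000, baseline_light_mm = 2500,
                              baseline_dark_s = 60, baseline_light_s = 10,
                              biphasic_amp = 0.3,
                              sex_mult = c(F = 1, M = 0.8),
                              age_mult = c(young = 1, old = 0.7),
                              genotype_deficit = 0.5,
                              cage_sd_frac = 0.06, day_slope_sd_frac = 0.02,
                              noise_sd_frac = 0.08,
                              n_per_group = 3, n_days = 3,
                              bin_length_min = 6, seed = 1) {
  structure(as.list(environment()), class = "activity_scenario")
}

# deterministic per-bin mean for one cell; channel in c("distance","climbing")
activity_mu <- function(scenario, zt, age, sex, genotype, channel) {
  s <- scenario
  dark <- light_phase(zt) == "dark"
  base_d <- if (channel == "distance") s$baseline_dark_mm else s$baseline_dark_s
  base_l <- if (channel == "distance") s$baseline_light_mm else s$baseline_light_s
  frac <- ((zt - 12) %% 24) / 12
  base <- ifelse(dark, base_d * (1 + s$biphasic_amp * cos(2 * pi * frac)), base_l)
  eod <- zt %in% window_bins("end_of_dark", s$bin_length_min)
  deficit <- ifelse(genotype == "Hemi" & eod, s$genotype_deficit, 1)
  base * s$sex_mult[[sex]] * s$age_mult[[age]] * deficit
}

#' Expected window mean of a synthetic activity scenario
#'
#' The noise-free mean of [window_means()] for one Age x Genotype x Sex cell,
#' computed in closed form from the scenario parameters (mean of the
#' deterministic bin means over the 5 window bins). Used as ground truth in
#' parameter-recovery simulations.
#'
#' @param scenario an [activity_scenario()].
#' @param window `"end_of_dark"` or `"end_of_light"`.
#' @param age,sex,genotype cell labels (`"young"`/`"old"`, `"F"`/`"M"`,
#'   `"WT"`/`"Hemi"`).
#' @param channel `"distance"` or `"climbing"`.
#' @return The expected per-cage window mean.
#' @export
expected_window_mean <- function(scenario,
                                 window = c("end_of_dark", "end_of_light"),
                                 age = "young", sex = "F", genotype = "WT",
                                 channel = c("distance", "climbing")) {
  window <- match.arg(window)
  channel <- match.arg(channel)
  wb <- window_bins(window, scenario$bin_length_min)
  mean(activity_mu(scenario, wb, age, sex, genotype, channel))
}

#' Generate synthetic cage-activity series
#'
#' @param scenario an [activity_scenario()].
#' @return Data frame with one row per cage x day x 6-min bin: `cage_id`,
#'   `Age`, `Genotype`, `Sex` (factors), `day`, `bin_start_zt`, `phase`,
#'   `distance_mm`, `climbing_s`. With all multipliers 1 and zero variance
#'   fractions every bin equals its baseline exactly; identical seeds give
#'   identical tables.
#' @export
generate_activity <- function(scenario) {
  stopifnot(inherits(scenario, "activity_scenario"))
  s <- scenario
  cells <- expand.grid(Age = c("young", "old"), Genotype = c("WT", "Hemi"),
                       Sex = c("F", "M"), rep = seq_len(s$n_per_group),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$cage_id <- sprintf("cage%02d", seq_len(nrow(cells)))
  bins <- zt_bins(s$bin_length_min)
  withr::with_seed(s$seed, {
    sds <- vapply(c("distance", "climbing"), function(ch)
      if (ch == "distance") s$baseline_dark_mm else s$baseline_dark_s, 0)
    cage_int <- sapply(c("distance", "climbing"), function(ch)
      rnorm(nrow(cells), 0, s$cage_sd_frac * sds[[ch]]))
    cage_slo <- sapply(c("distance", "climbing"), function(ch)
      rnorm(nrow(cells), 0, s$day_slope_sd_frac * sds[[ch]]))
    out <- vector("list", nrow(cells) * s$n_days)
    idx <- 0L
    for (ci in seq_len(nrow(cells))) {
      mu_d <- activity_mu(s, bins$bin_start_zt, cells$Age[ci], cells$Sex[ci],
                          cells$Genotype[ci], "distance")
      mu_c <- activity_mu(s, bins$bin_start_zt, cells$Age[ci], cells$Sex[ci],
                          cells$Genotype[ci], "climbing")
      for (d in seq_len(s$n_days)) {
        nd <- nrow(bins)
        dist <- mu_d + cage_int[ci, "distance"] +
          cage_slo[ci, "distance"] * (d - 2) +
          rnorm(nd, 0, s$noise_sd_frac * sds[["distance"]])
        climb <- mu_c + cage_int[ci, "climbing"] +
          cage_slo[ci, "climbing"] * (d - 2) +
          rnorm(nd, 0, s$noise_sd_frac * sds[["climbing"]])
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          cage_id = cells$cage_id[ci], Age = cells$Age[ci],
          Genotype = cells$Genotype[ci], Sex = cells$Sex[ci], day = d,
          bin_start_zt = bins$bin_start_zt, phase = bins$phase,
          distance_mm = pmax(dist, 0), climbing_s = pmax(climb, 0),
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    res$Age <- factor(res$Age, levels = c("young", "old"))
    res$Genotype <- factor(res$Genotype, levels = c("WT", "Hemi"))
    res$Sex <- factor(res$Sex, levels = c("F", "M"))
    rownames(res) <- NULL
    res
  })
}
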