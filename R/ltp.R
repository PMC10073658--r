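#' Local trinary pattern parameters
#'
#' The LTP motion descriptor compares, for every pixel `p` of the region of
#' interest and each of the 8 neighbour offsets `n_i` at `neighbor_radius`
#' (ordered clockwise from the top-left, bit `i` = offset `i`), the
#' sum-of-squared-differences (SSD) between the patch around `p` in frame `t`
#' and the patch around `p + n_i` in frame `t - delta` (giving `d_minus_i`)
#' and in frame `t + delta` (`d_plus_i`). The trit is `+1` when
#' `d_minus_i - d_plus_i > tau`, `-1` when `d_plus_i - d_minus_i > tau`, else
#' `0`. The +1 bits pack into a byte `B+`, the -1 bits into `B-`, and the two
#' bytes are histogrammed (256 bins each) over a `grid_cols x grid_rows` cell
#' grid on the region, giving `grid_cols * grid_rows * 512` dimensions —
#' exactly 16,384 with the 8 x 4 default.
#'
#' `tau` is in squared-intensity units and acts as a noise floor: SSD
#' asymmetries smaller than `tau` are coded 0. The default 0 codes any
#' asymmetry; on noisy video a `tau` of a few times the expected
#' noise-induced SSD fluctuation suppresses spurious codes.
#'
#' @param patch_half half-width of the square SSD patch; the patch is
#'   `(2 * patch_half + 1)^2` pixels (default 1, a 3 x 3 patch).
#' @param neighbor_radius offset of the 8 neighbours in pixels (default 2).
#' @param delta temporal gap in frames between the centre frame and the past
#'   and future comparison frames (default 2).
#' @param tau trit threshold in squared-intensity units (default 0).
#' @param grid_cols,grid_rows spatial pooling grid over the region (default
#'   8 x 4).
#' @param normalize `"l1"` (each 256-bin histogram sums to 1; empty cells
#'   stay 0) or `"none"` (raw counts).
#' @return An object of class `ltp_params`.
#' @export
ltp_params <- function(patch_half = 1, neighbor_radius = 2, delta = 2,
                       tau = 0, grid_cols = 8, grid_rows = 4,
                       normalize = c("l1", "none")) {
  normalize <- match.arg(normalize)
  if (delta < 1) stop("delta must be >= 1")
  if (patch_half < 0) stop("patch_half must be >= 0")
  if (tau < 0) stop("tau must be non-negative")
  if (grid_cols < 1 || grid_rows < 1) stop("grid must have >= 1 cell")
  structure(list(patch_half = as.integer(patch_half),
                 neighbor_radius = as.integer(neighbor_radius),
                 delta = as.integer(delta), tau = as.numeric(tau),
                 grid_cols = as.integer(grid_cols),
                 grid_rows = as.integer(grid_rows),
                 normalize = normalize),
            class = "ltp_params")
}

#' Dimension of the LTP feature vector
#' @param params an [ltp_params()].
#' @return `grid_cols * grid_rows * 512`.
#' @export
ltp_dim <- function(params = ltp_params()) {
  params$grid_cols * params$grid_rows * 512L
}

roi_or_full <- function(stack, region) {
  if (is.null(region)) {
    d <- dim(stack$frames)
    region <- roi(0, 0, d[2], d[1])
  }
  region
}

#' Trinary motion codes for one frame
#'
#' Returns the packed positive and negative trit bytes for every pixel of the
#' region at frame `t`. Pixels whose own patch or any neighbour patch would
#' leave the region are not coded (`NA`).
#'
#' @param stack a [frame_stack()].
#' @param region a [roi()], or `NULL` for the full frame.
#' @param t 0-based frame index; must satisfy `delta <= t <= n - 1 - delta`.
#' @param params an [ltp_params()].
#' @return List with integer matrices `b_plus` and `b_minus` (region height x
#'   width, values 0..255 or `NA`); `b_plus` and `b_minus` never share a set
#'   bit at any pixel.
#' @export
trit_codes <- function(stack, region = NULL, t, params = ltp_params()) {
  region <- roi_or_full(stack, region)
  cropped <- crop_frames(stack, region)
  d <- dim(cropped$frames)
  ltp_trit_codes_cpp(cropped$frames, d[1], d[2], d[3], as.integer(t),
                     params$delta, params$patch_half, params$neighbor_radius,
                     params$tau)
}

#' LTP feature vector for one frame
#'
#' @inheritParams trit_codes
#' @return Numeric vector of length [ltp_dim()] with attribute
#'   `frame_index = t`. Cells are concatenated row-major (cell row, then
#'   cell column); within each cell the 256 `B+` bins precede the 256 `B-`
#'   bins. Remainder pixels when the region size is not divisible by the grid
#'   belong to the last row/column of cells.
#' @export
ltp_feature <- function(stack, region = NULL, t, params = ltp_params()) {
  region <- roi_or_full(stack, region)
  t <- as.integer(t)
  n <- n_frames(stack)
  if (t < params$delta || t > n - 1 - params$delta)
    stop("frame index out of temporal range")
  sub <- frame_stack(stack$frames[, , (t - params$delta):(t + params$delta) + 1,
                                  drop = FALSE], stack$frame_rate_hz)
  m <- ltp_features_segment(sub, region, params)  # one interior row
  v <- as.numeric(m[1L, ])
  structure(v, frame_index = t)
}

ltp_features_segment <- function(stack, region, params) {
  cropped <- crop_frames(stack, region)
  d <- dim(cropped$frames)
  trip <- ltp_features_range_cpp(cropped$frames, d[1], d[2], d[3],
                                 params$delta, params$patch_half,
                                 params$neighbor_radius, params$tau,
                                 params$grid_cols, params$grid_rows,
                                 params$normalize == "l1")
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(trip$nrow, trip$dim))
}

#' LTP features for every frame of a segment
#'
#' Computes one descriptor per frame. Interior frames (indices `delta` to
#' `n - 1 - delta`) are computed directly; the first and last `delta` frames,
#' for which no symmetric temporal comparison exists, are assigned the vector
#' of the nearest interior frame so that every frame carries a descriptor.
#'
#' @inheritParams trit_codes
#' @return A sparse matrix (`dgCMatrix`, `n_frames` rows x [ltp_dim()]
#'   columns); row `i` is the descriptor of 0-based frame `i - 1`.
#' @export
ltp_features_for_segment <- function(stack, region = NULL,
                                     params = ltp_params()) {
  region <- roi_or_full(stack, region)
  n <- n_frames(stack)
  if (n < 2 * params$delta + 1)
    stop("stack shorter than 2*delta + 1 frames")
  interior <- ltp_features_segment(stack, region, params)
  ni <- nrow(interior)
  idx <- c(rep(1L, params$delta), seq_len(ni), rep(ni, params$delta))
  interior[idx, , drop = FALSE]
}
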