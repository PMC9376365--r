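#' Expand 6 motion parameters to the 24-parameter set
#'
#' Columns are the 6 raw parameters, their backward-difference temporal
#' derivatives (first row 0), and the squares of those 12.
#'
#' @param motion6 volumes x 6 numeric matrix (3 translations mm, 3
#'   rotations rad).
#' @return volumes x 24 matrix.
#' @export
motion_expand <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) stop("motion matrix must have 6 columns")
  if (nrow(motion6) < 2) stop("need at least 2 volumes")
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("dm", 1:6),
                     paste0("m", 1:6, "_sq"), paste0("dm", 1:6, "_sq"))
  out
}

#' Framewise displacement
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations plus `head_radius` times the sum of absolute rotation
#' differences (rotations converted to arc length at the head surface).
#' FD of the first volume is 0.
#'
#' @param motion6 volumes x 6 matrix (translations mm, rotations rad).
#' @param head_radius Head radius in mm.
#' @return Numeric vector, one FD value (mm) per volume.
#' @export
framewise_displacement <- function(motion6, head_radius = 50) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) stop("motion matrix must have 6 columns")
  if (nrow(motion6) < 2) stop("need at least 2 volumes")
  d <- abs(diff(motion6))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Percentile-based scrubbing mask and spike regressors
#'
#' Volumes with FD strictly above the empirical percentile (per subject)
#' are censored. Censoring is realized as one spike-regressor column per
#' censored volume, so downstream filtering stays on a regular time grid.
#'
#' @param fd FD series from [framewise_displacement()].
#' @param percentile Censoring percentile (default 97, i.e. ~3% of volumes).
#' @return List: `mask` (logical, TRUE = censored) and `spikes` (volumes x
#'   n_censored 0/1 matrix, possibly 0 columns).
#' @export
scrub_mask <- function(fd, percentile = 97) {
  if (length(fd) == 0) stop("empty FD series")
  thr <- stats::quantile(fd, percentile / 100, names = FALSE, type = 7)
  mask <- fd > thr
  idx <- which(mask)
  spikes <- matrix(0, length(fd), length(idx))
  if (length(idx))
    spikes[cbind(idx, seq_along(idx))] <- 1
  colnames(spikes) <- if (length(idx)) sprintf("spike_%03d", idx)
  list(mask = mask, spikes = spikes)
}

#' Anatomical CompCor components
#'
#' Per tissue (white matter, CSF), the top-k principal component time
#' courses of the column-centred noise-ROI block, scaled to unit variance
#' and ordered by explained variance; blocks are concatenated.
#'
#' @param noise_series volumes x noise-ROI matrix.
#' @param tissues Character vector, tissue label per column (defaults to
#'   `attr(noise_series, "tissues")`).
#' @param k_per_tissue Components per tissue (default 5, giving 10 total).
#' @return volumes x (k * n_tissues) matrix with explained-variance
#'   fractions in `attr(, "explained")`.
#' @export
acompcor <- function(noise_series, tissues = attr(noise_series, "tissues"),
                     k_per_tissue = 5) {
  noise_series <- as.matrix(noise_series)
  if (is.null(tissues) || length(tissues) != ncol(noise_series))
    stop("tissue labels must be given for every noise-ROI column")
  if (nrow(noise_series) <= k_per_tissue)
    stop("need more volumes than components per tissue")
  blocks <- list(); expl <- list()
  for (tis in unique(tissues)) {
    x <- noise_series[, tissues == tis, drop = FALSE]
    if (all(apply(x, 2, stats::sd) == 0))
      stop("zero-variance tissue block: ", tis)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(k_per_tissue, ncol(pc$x))
    if (k < k_per_tissue)
      warning("tissue ", tis, " supports only ", k, " components")
    comp <- pc$x[, seq_len(k), drop = FALSE]
    sds <- apply(comp, 2, stats::sd)
    if (any(sds == 0)) stop("degenerate (zero-variance) component in ", tis)
    comp <- sweep(comp, 2, sds, "/")
    colnames(comp) <- sprintf("%s_pc%d", tis, seq_len(k))
    blocks[[tis]] <- comp
    expl[[tis]] <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  }
  out <- do.call(cbind, blocks)
  attr(out, "explained") <- expl
  out
}

#' Assemble the nuisance design for one session
#'
#' 24 motion parameters + 2 x k aCompCor components + one spike regressor
#' per censored volume.
#'
#' @param session A `roi_session`, or pass `motion6`/`noise_series`
#'   directly.
#' @param k_per_tissue aCompCor components per tissue.
#' @param fd_percentile Scrubbing percentile.
#' @param head_radius FD head radius (mm).
#' @return List of class `nuisance_design`: `columns` (volumes x k matrix),
#'   `names`, `censored` (logical mask).
#' @export
nuisance_design <- function(session, k_per_tissue = 5, fd_percentile = 97,
                            head_radius = 50) {
  m24 <- motion_expand(session$motion)
  fd <- framewise_displacement(session$motion, head_radius)
  sc <- scrub_mask(fd, fd_percentile)
  cc <- acompcor(session$noise, k_per_tissue = k_per_tissue)
  X <- cbind(m24, cc, sc$spikes)
  structure(list(columns = X, names = colnames(X), censored = sc$mask,
                 fd = fd),
            class = "nuisance_design")
}

#' Nuisance regression and band-pass filtering of ROI series
#'
#' Each ROI series is regressed on the nuisance design (plus intercept)
#' and the residuals are zero-phase band-pass filtered (Butterworth order
#' `order`, forward-backward) to the resting-state band. Residuals are
#' exactly orthogonal to the design columns before filtering; a
#' rank-deficient design is handled by the least-squares pseudoinverse with
#' a warning.
#'
#' @param roi_series volumes x ROI matrix.
#' @param design A `nuisance_design` (or plain matrix).
#' @param band Pass band in Hz (default 0.01-0.1).
#' @param tr Repetition time (s).
#' @param order Butterworth order (default 2).
#' @return Residual matrix with the censor mask carried in
#'   `attr(, "censored")`.
#' @export
denoise <- function(roi_series, design, band = c(0.01, 0.1), tr,
                    order = 2) {
  roi_series <- as.matrix(roi_series)
  X <- if (inherits(design, "nuisance_design")) design$columns
       else as.matrix(design)
  censored <- if (inherits(design, "nuisance_design")) design$censored
              else rep(FALSE, nrow(roi_series))
  if (nrow(X) != nrow(roi_series))
    stop("design rows must equal ROI volumes")
  stop_if_not_scalar_num(tr, "tr", positive = TRUE)
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
    stop("band must satisfy 0 < low < high < 1/(2 tr)")
  Xi <- cbind(intercept = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi))
    warning("rank-deficient nuisance design; using pseudoinverse solution")
  resid <- qr.resid(qx, roi_series)
  bf <- signal::butter(order, band / nyq, type = "pass")
  out <- apply(resid, 2, function(v) signal::filtfilt(bf, v))
  dimnames(out) <- dimnames(roi_series)
  attr(out, "censored") <- censored
  attr(out, "residuals_prefilter") <- resid
  out
}
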