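#' BOLD generator parameters
#'
#' Parameter bundle for [synth_bold()]. Defaults emulate a resting fMRI
#' session at TR 1.5 s with a small named ROI set containing the regions
#' this analysis cares about: positive interhemispheric couplings of the
#' lateral-visual/parietal-operculum/salience system planted in carriers
#' (E4plus), and a negative hippocampus-posterior-parietal coupling planted
#' only in non-carriers (E4minus). Shared low-frequency nuisance components
#' contaminate ROI and noise-ROI (white matter/CSF) series alike, and head
#' motion is a bounded random walk.
#'
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param roi_labels ROI names.
#' @param noise_roi_counts Named counts `c(wm = ..., csf = ...)`.
#' @param coupling_by_genotype Named list (`E4minus`, `E4plus`) of symmetric
#'   zero-diagonal coupling matrices with entries in (-1, 1); defaults from
#'   [default_coupling_matrices()].
#' @param n_nuisance_components Number of shared nuisance time courses.
#' @param nuisance_amplitude Loading scale of nuisance components on ROI
#'   series (signal series have unit variance).
#' @param motion_scale Random-walk step SD: mm for translations; rotations
#'   use `motion_scale / 50` rad so a 50-mm head radius gives comparable
#'   displacement.
#' @param seed Master seed (per-subject streams as in the EEG generator).
#' @return List of class `bold_gen_params`.
#' @export
bold_gen_params <- function(tr = 1.5, n_volumes = 400,
                            roi_labels = default_roi_labels(),
                            noise_roi_counts = c(wm = 8, csf = 8),
                            coupling_by_genotype =
                              default_coupling_matrices(roi_labels),
                            n_nuisance_components = 2,
                            nuisance_amplitude = 0.7,
                            motion_scale = 0.05,
                            seed = 1L) {
  stop_if_not_scalar_num(tr, "tr", positive = TRUE)
  for (g in names(coupling_by_genotype))
    validate_coupling(coupling_by_genotype[[g]], roi_labels)
  structure(list(tr = tr, n_volumes = n_volumes, roi_labels = roi_labels,
                 noise_roi_counts = noise_roi_counts,
                 coupling_by_genotype = coupling_by_genotype,
                 n_nuisance_components = n_nuisance_components,
                 nuisance_amplitude = nuisance_amplitude,
                 motion_scale = motion_scale, seed = seed),
            class = "bold_gen_params")
}

#' Default ROI label set
#'
#' A compact Harvard-Oxford-style label list covering the regions named in
#' the planted effects (left hippocampus, right posterior parietal cortex,
#' right lateral visual, parietal opercula, right salience supramarginal,
#' left anterior parahippocampal, right superior frontal, left lateral
#' prefrontal, left anterior inferior temporal).
#' @return Character vector.
#' @export
default_roi_labels <- function() {
  c("Hipp_L", "PPC_R", "VisLat_R", "PO_L", "PO_R", "SMG_R",
    "aPaHC_L", "SFG_R", "LPFC_L", "aITG_L")
}

#' Default genotype coupling matrices
#'
#' Carriers (E4plus) get positive interhemispheric couplings
#' (VisLat_R-PO_L/PO_R/SMG_R = 0.25); non-carriers (E4minus) get the
#' negative Hipp_L-PPC_R coupling (-0.25) and aPaHC_L-SFG_R (-0.20).
#'
#' @param roi_labels ROI names the matrices are indexed by.
#' @return Named list of symmetric zero-diagonal matrices.
#' @export
default_coupling_matrices <- function(roi_labels = default_roi_labels()) {
  k <- length(roi_labels)
  base <- matrix(0, k, k, dimnames = list(roi_labels, roi_labels))
  set_edge <- function(m, a, b, v) {
    if (a %in% rownames(m) && b %in% rownames(m)) {
      m[a, b] <- v; m[b, a] <- v
    }
    m
  }
  e4p <- base
  e4p <- set_edge(e4p, "VisLat_R", "PO_L", 0.25)
  e4p <- set_edge(e4p, "VisLat_R", "PO_R", 0.25)
  e4p <- set_edge(e4p, "VisLat_R", "SMG_R", 0.25)
  e4m <- base
  e4m <- set_edge(e4m, "Hipp_L", "PPC_R", -0.25)
  e4m <- set_edge(e4m, "aPaHC_L", "SFG_R", -0.20)
  list(E4minus = e4m, E4plus = e4p)
}

validate_coupling <- function(C, roi_labels = rownames(C)) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("coupling matrix must be square")
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-12)))
    stop("coupling matrix must be symmetric")
  if (any(diag(C) != 0)) stop("coupling matrix diagonal must be zero")
  if (any(abs(C[upper.tri(C)]) >= 1))
    stop("coupling entries must lie in (-1, 1)")
  if (!is.null(roi_labels) && nrow(C) != length(roi_labels))
    stop("coupling matrix size must match roi_labels")
  invisible(C)
}

# Unit-variance AR(1) series, the shared slow physiological drift model.
ar1_series <- function(n, phi = 0.9) {
  x <- stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                     method = "recursive")
  as.numeric(x)
}

#' Synthesize one subject's ROI BOLD session
#'
#' ROI series are drawn from a multivariate normal whose correlation matrix
#' is I + C, with C the genotype's coupling matrix; shared nuisance AR(1)
#' components are added to ROI and noise-ROI series with random loadings;
#' motion is a bounded random walk. The planted coupling matrix is stored
#' in the result for recovery tests.
#'
#' @param subject Cohort row (needs `id`, `genotype`).
#' @param params A [bold_gen_params()] bundle.
#' @return A `roi_session`: list with `roi` (volumes x ROI), `noise`
#'   (volumes x WM+CSF, tissue in `attr(,"tissues")`), `motion` (volumes x
#'   6), `tr`, `labels`, `truth` (coupling matrix).
#' @export
synth_bold <- function(subject, params = bold_gen_params()) {
  n <- params$n_volumes
  if (is.null(n) || n < 50) stop("n_volumes must be at least 50")
  C <- params$coupling_by_genotype[[subject$genotype]]
  if (is.null(C)) stop("no coupling matrix for genotype ", subject$genotype)
  validate_coupling(C, params$roi_labels)
  k <- length(params$roi_labels)
  Sigma <- diag(k) + C
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("coupling matrix not positive definite"))
  n_wm <- params$noise_roi_counts[["wm"]]
  n_csf <- params$noise_roi_counts[["csf"]]
  q <- params$n_nuisance_components
  s <- subject_seed(params$seed, subject$id, "bold")
  out <- with_local_seed(s, {
    roi <- matrix(stats::rnorm(n * k), n, k) %*% R
    nuis <- if (q > 0) sapply(seq_len(q), function(i) ar1_series(n))
            else matrix(0, n, 0)
    nuis <- matrix(nuis, nrow = n)
    load_roi <- matrix(stats::rnorm(k * q), q, k) * params$nuisance_amplitude
    load_noise <- matrix(stats::rnorm((n_wm + n_csf) * q), q,
                         n_wm + n_csf) * 1.0
    roi <- roi + nuis %*% load_roi
    noise <- matrix(stats::rnorm(n * (n_wm + n_csf), sd = 0.5),
                    n, n_wm + n_csf) + nuis %*% load_noise
    steps <- matrix(stats::rnorm(n * 6), n, 6)
    steps[, 1:3] <- steps[, 1:3] * params$motion_scale
    steps[, 4:6] <- steps[, 4:6] * params$motion_scale / 50
    motion <- apply(steps, 2, cumsum)
    motion[, 1:3] <- pmin(pmax(motion[, 1:3], -1), 1)
    motion[, 4:6] <- pmin(pmax(motion[, 4:6], -0.02), 0.02)
    list(roi = roi, noise = noise, motion = motion)
  })
  colnames(out$roi) <- params$roi_labels
  colnames(out$noise) <- c(sprintf("wm_%02d", seq_len(n_wm)),
                           sprintf("csf_%02d", seq_len(n_csf)))
  attr(out$noise, "tissues") <- rep(c("wm", "csf"), c(n_wm, n_csf))
  colnames(out$motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(roi = out$roi, noise = out$noise, motion = out$motion,
                 tr = params$tr, labels = params$roi_labels, truth = C),
            class = "roi_session")
}

#' @export
print.roi_session <- function(x, ...) {
  cat(sprintf("<roi_session> %d volumes x %d ROIs (TR %g s), %d noise ROIs\n",
              nrow(x$roi), ncol(x$roi), x$tr, ncol(x$noise)))
  invisible(x)
}
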