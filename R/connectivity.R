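#' Fisher-z ROI-to-ROI connectivity matrix
#'
#' Pairwise Pearson correlations over the uncensored volumes, Fisher
#' transformed (z = atanh r) and capped at +/- `z_cap`. Zero-variance ROIs
#' yield undefined (NA) entries, flagged in `attr(, "flagged")` together
#' with any capped entries.
#'
#' @param denoised volumes x ROI matrix (e.g. from [denoise()]); a censor
#'   mask may ride along as `attr(, "censored")` or be passed explicitly.
#' @param censored Logical mask of censored volumes (TRUE = drop).
#' @param z_cap Cap on |z| (default 6).
#' @return ROI x ROI symmetric matrix of class `connectivity_matrix`;
#'   diagonal is NA.
#' @export
connectivity <- function(denoised, censored = attr(denoised, "censored"),
                         z_cap = 6) {
  x <- as.matrix(denoised)
  if (!is.null(censored)) {
    stopifnot(length(censored) == nrow(x))
    x <- x[!censored, , drop = FALSE]
  }
  if (nrow(x) < 30) stop("fewer than 30 usable volumes")
  sds <- apply(x, 2, stats::sd)
  degen <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  z <- atanh(pmin(pmax(r, -1), 1))
  capped <- is.infinite(z) | abs(z) > z_cap
  z[z > z_cap] <- z_cap
  z[z < -z_cap] <- -z_cap
  z[degen, ] <- NA_real_
  z[, degen] <- NA_real_
  diag(z) <- NA_real_
  diag(capped) <- FALSE
  attr(z, "flagged") <- capped | outer(degen, degen, `|`)
  attr(z, "n_usable") <- nrow(x)
  class(z) <- c("connectivity_matrix", class(z))
  z
}

#' Long-format edge table of a connectivity matrix
#'
#' @param z A `connectivity_matrix` (or plain symmetric matrix).
#' @return data.frame (roi_i, roi_j, z), upper triangle only.
#' @export
edge_table <- function(z) {
  labs <- rownames(z)
  if (is.null(labs)) labs <- sprintf("ROI%02d", seq_len(nrow(z)))
  ut <- which(upper.tri(z), arr.ind = TRUE)
  data.frame(roi_i = labs[ut[, 1]], roi_j = labs[ut[, 2]],
             z = z[ut], stringsAsFactors = FALSE)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d ROIs, %d usable volumes\n",
              nrow(x), attr(x, "n_usable")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}
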