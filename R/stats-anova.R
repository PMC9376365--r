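#' Mixed repeated-measures ANOVA (univariate, partitioned sums of squares)
#'
#' Classic split-plot decomposition for designs with between-subject
#' factors (full factorial), crossed within-subject factors (balanced:
#' every subject contributes one observation per within cell), and
#' subject-constant covariates. Between-subject effects are tested against
#' the subject-within-groups mean square (computed on subject means);
#' every within effect and its interactions with between factors are
#' tested against the corresponding subject x effect interaction mean
#' square. Type III sums of squares (sum-to-zero contrasts, term-deletion)
#' accommodate unbalanced between cells; covariates enter the
#' between-subject stratum only. No sphericity correction is applied
#' (degrees of freedom are the uncorrected univariate ones).
#'
#' @param data Tidy data.frame, one row per subject x within-cell.
#' @param response Name of the response column.
#' @param between Character vector of between-subject factor names.
#' @param within Character vector of within-subject factor names (may be
#'   empty for a pure between-subject ANOVA).
#' @param covariates Character vector of subject-constant covariates
#'   (numeric, or factors entered through sum contrasts).
#' @param subject Name of the subject-id column.
#' @return data.frame (effect, stratum, df1, df2, ss, F, p) with the error
#'   strata in `attr(, "errors")`.
#' @export
rm_anova <- function(data, response, between, within = character(),
                     covariates = character(), subject = "subject") {
  need <- c(response, between, within, covariates, subject)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data[[subject]] <- factor(data[[subject]])
  for (v in c(between, within)) data[[v]] <- factor(data[[v]])

  # subjects nested in between cells
  bcell <- interaction(data[between], drop = FALSE)
  if (any(tapply(bcell, data[[subject]],
                 function(z) length(unique(z))) != 1L))
    stop("each subject must belong to exactly one between-subject cell")
  subj_tab <- unique(data[c(subject, between, covariates)])
  if (nrow(subj_tab) != nlevels(data[[subject]]))
    stop("covariates must be constant within subject")
  cell_counts <- table(interaction(subj_tab[between], drop = FALSE))
  if (any(cell_counts == 0)) stop("empty between-subject cell")
  if (any(cell_counts < 2)) stop("singleton between-subject cell")

  w_levels <- vapply(within, function(v) nlevels(data[[v]]), integer(1))
  m <- if (length(within)) prod(w_levels) else 1L
  if (length(within)) {
    wcell <- interaction(data[within], drop = FALSE)
    counts <- table(data[[subject]], wcell)
    if (any(counts != 1L))
      stop("design must be balanced: one observation per subject and within cell")
  }

  # sum-to-zero contrast columns for the interaction of `vars`
  term_cols <- function(df, vars) {
    mats <- lapply(vars, function(v) {
      f <- df[[v]]
      stats::contr.sum(nlevels(f))[as.integer(f), , drop = FALSE]
    })
    Reduce(function(A, B)
      do.call(cbind, lapply(seq_len(ncol(A)), function(i) A[, i] * B)),
      mats)
  }
  cov_cols <- function(df, v) {
    x <- df[[v]]
    if (is.numeric(x)) matrix(x, ncol = 1)
    else {
      f <- factor(x)
      stats::contr.sum(nlevels(f))[as.integer(f), , drop = FALSE]
    }
  }
  subsets <- function(vars) {
    if (!length(vars)) return(list())
    idx <- unlist(lapply(seq_along(vars), function(k)
      utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
    idx
  }
  rss_rank <- function(X, y) {
    q <- qr(X)
    list(rss = sum(qr.resid(q, y)^2), rank = q$rank)
  }
  # sums of squares at or below this are numerical zeros (e.g. constant
  # response), not real effects
  tot_ss <- sum((data[[response]] - mean(data[[response]]))^2)
  zero_tol <- 1e-10 * max(tot_ss, .Machine$double.eps)
  f_stat <- function(ss, df1, ms_err) {
    if (ss <= zero_tol) return(0)
    if (ms_err <= zero_tol) return(Inf)
    (ss / df1) / ms_err
  }

  b_terms <- subsets(between)
  results <- list()
  errors <- list()

  ## ---- between-subject stratum (subject means) ----
  agg <- stats::aggregate(data[[response]],
                          by = list(subject = data[[subject]]), FUN = mean)
  names(agg)[2] <- ".y"
  agg <- merge(agg, subj_tab, by.x = "subject", by.y = subject, sort = TRUE)
  blocks <- list(intercept = matrix(1, nrow(agg), 1))
  for (v in covariates) blocks[[v]] <- cov_cols(agg, v)
  for (tv in b_terms) blocks[[paste(tv, collapse = ":")]] <-
    term_cols(agg, tv)
  Xb <- do.call(cbind, blocks)
  fb <- rss_rank(Xb, agg$.y)
  df_err_b <- nrow(agg) - fb$rank
  if (df_err_b < 1) stop("no residual degrees of freedom between subjects")
  ms_err_b <- fb$rss * m / df_err_b
  errors[["between"]] <- data.frame(stratum = "subject", ss = fb$rss * m,
                                    df = df_err_b, ms = ms_err_b)
  testable_b <- c(as.list(covariates), b_terms)
  for (tv in testable_b) {
    lab <- paste(unlist(tv), collapse = ":")
    Xr <- do.call(cbind, blocks[setdiff(names(blocks), lab)])
    fr <- rss_rank(Xr, agg$.y)
    ss <- (fr$rss - fb$rss) * m
    df1 <- fb$rank - fr$rank
    Fv <- f_stat(ss, df1, ms_err_b)
    results[[length(results) + 1L]] <- data.frame(
      effect = lab, stratum = "between", df1 = df1, df2 = df_err_b,
      ss = max(ss, 0), F = Fv,
      p = stats::pf(Fv, df1, df_err_b, lower.tail = FALSE))
  }

  ## ---- within-subject strata ----
  if (length(within)) {
    w_subsets <- subsets(within)
    # order by cardinality so error recursion sees subsets first
    w_subsets <- w_subsets[order(lengths(w_subsets))]
    err_scaled <- list(); err_df <- list()
    key <- function(S) paste(sort(S), collapse = ":")
    for (S in w_subsets) {
      other <- setdiff(within, S)
      aggS <- stats::aggregate(
        data[[response]],
        by = c(stats::setNames(list(data[[subject]]), "subject"),
               lapply(data[S], identity)), FUN = mean)
      names(aggS)[ncol(aggS)] <- ".y"
      aggS <- merge(aggS, subj_tab, by.x = "subject", by.y = subject,
                    sort = TRUE)
      for (v in S) aggS[[v]] <- factor(aggS[[v]])
      scale_S <- m / prod(w_levels[S])
      blocksS <- list(
        subject = stats::model.matrix(~ 0 + subject, aggS))
      for (TT in subsets(S)) {
        wlab <- paste(TT, collapse = ":")
        blocksS[[wlab]] <- term_cols(aggS, TT)
        for (bt in b_terms) {
          lab <- paste(c(TT, bt), collapse = ":")
          A <- term_cols(aggS, TT); B <- term_cols(aggS, bt)
          blocksS[[lab]] <- do.call(cbind, lapply(seq_len(ncol(A)),
                                                  function(i) A[, i] * B))
        }
      }
      XS <- do.call(cbind, blocksS)
      fS <- rss_rank(XS, aggS$.y)
      pooled_ss <- fS$rss * scale_S
      pooled_df <- nrow(aggS) - fS$rank
      ss_S <- pooled_ss; df_S <- pooled_df
      for (TT in subsets(S)) {
        if (key(TT) == key(S)) next
        ss_S <- ss_S - err_scaled[[key(TT)]]
        df_S <- df_S - err_df[[key(TT)]]
      }
      err_scaled[[key(S)]] <- ss_S
      err_df[[key(S)]] <- df_S
      if (df_S < 1) stop("no residual df for stratum subject:",
                         paste(S, collapse = ":"))
      ms_S <- ss_S / df_S
      errors[[paste0("subject:", paste(S, collapse = ":"))]] <- data.frame(
        stratum = paste0("subject:", paste(S, collapse = ":")),
        ss = ss_S, df = df_S, ms = ms_S)
      # effects whose within part is exactly S
      eff_labels <- c(paste(S, collapse = ":"),
                      vapply(b_terms, function(bt)
                        paste(c(S, bt), collapse = ":"), character(1)))
      for (lab in eff_labels) {
        Xr <- do.call(cbind, blocksS[setdiff(names(blocksS), lab)])
        fr <- rss_rank(Xr, aggS$.y)
        ss <- (fr$rss - fS$rss) * scale_S
        df1 <- fS$rank - fr$rank
        Fv <- f_stat(ss, df1, ms_S)
        results[[length(results) + 1L]] <- data.frame(
          effect = lab, stratum = paste0("within:", paste(S, collapse = ":")),
          df1 = df1, df2 = df_S, ss = max(ss, 0), F = Fv,
          p = stats::pf(Fv, df1, df_S, lower.tail = FALSE))
      }
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  attr(out, "errors") <- do.call(rbind, c(errors,
                                          list(make.row.names = FALSE)))
  attr(out, "sphericity_correction") <- "none"
  out
}

#' Duncan's multiple-range post-hoc test
#'
#' Means are ranked; a pair spanning p ranks is declared significant when
#' its difference exceeds the Duncan significant range
#' q(p, df, 1-(1-alpha)^(p-1)) * sqrt(MSE / n~), with n~ the harmonic mean
#' of the two cell sizes, under the usual multiple-range protection: a
#' pair can only be significant if every enclosing range is.
#'
#' @param cell_means Named numeric vector of cell means.
#' @param cell_ns Cell sizes (same order/names).
#' @param ms_error Error mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param alpha Per-comparison protection level (default 0.05).
#' @return data.frame (group1, group2, diff, span, se, q_crit, q_obs, p,
#'   significant), one row per pair.
#' @export
duncan_posthoc <- function(cell_means, cell_ns, ms_error, df_error,
                           alpha = 0.05) {
  k <- length(cell_means)
  if (k < 2) stop("need at least 2 cells")
  if (!is.numeric(ms_error) || ms_error <= 0)
    stop("ms_error must be positive")
  if (length(cell_ns) == 1L) cell_ns <- rep(cell_ns, k)
  stopifnot(length(cell_ns) == k)
  if (is.null(names(cell_means)))
    names(cell_means) <- paste0("cell", seq_len(k))
  ord <- order(cell_means)
  mu <- cell_means[ord]; nn <- cell_ns[ord]
  raw <- matrix(FALSE, k, k); sig <- matrix(FALSE, k, k)
  rows <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      nh <- harmonic_mean(c(nn[i], nn[j]))
      se <- sqrt(ms_error / nh)
      qc <- stats::qtukey((1 - alpha)^(span - 1), span, df_error)
      qo <- abs(mu[j] - mu[i]) / se
      raw[i, j] <- qo > qc
      enclosing_ok <- (i == 1 || sig[i - 1, j]) &&
        (j == k || sig[i, j + 1])
      # widest range has no enclosing range
      if (span == k) enclosing_ok <- TRUE
      sig[i, j] <- raw[i, j] && enclosing_ok
      p_dun <- 1 - stats::ptukey(qo, span, df_error)^(1 / (span - 1))
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = names(mu)[i], group2 = names(mu)[j],
        diff = unname(mu[j] - mu[i]), span = span, se = se,
        q_crit = qc, q_obs = unname(qo), p = unname(p_dun),
        significant = unname(sig[i, j]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
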