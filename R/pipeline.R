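#' Default pipeline configuration
#'
#' The default configuration reproduces the study conditions: a cohort of
#' 91 non-carriers and 46 carriers, 150-s 16-channel EEG at 256 Hz, and an
#' fMRI subset of 23 non-carriers and 14 carriers at TR 1.5 s with 400
#' volumes.
#'
#' @param seed Master seed for every source of randomness.
#' @param mode "joint", "eeg_only", or "fmri_only".
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, mode = "joint") {
  list(
    seed = as.integer(seed),
    mode = mode,
    alpha = 0.05,
    cohort = list(n_e4minus = 91L, n_e4plus = 46L),
    eeg = list(sample_rate = 256, duration = 150, epoch_s = 4,
               band = c(2, 35)),
    bold = list(n_e4minus = 23L, n_e4plus = 14L, n_volumes = 400L,
                tr = 1.5, band = c(0.01, 0.1), k_per_tissue = 5,
                fd_percentile = 97)
  )
}

#' Validate a pipeline configuration
#'
#' @param config Configuration list (see [default_config()]); missing
#'   fields are filled with defaults.
#' @return The completed configuration, or an error naming the bad field.
#' @export
validate_config <- function(config) {
  def <- default_config()
  config <- utils::modifyList(def, config)
  chk <- function(cond, field)
    if (!isTRUE(cond)) stop("invalid config field: ", field, call. = FALSE)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed")
  chk(config$mode %in% c("joint", "eeg_only", "fmri_only"), "mode")
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha")
  chk(config$cohort$n_e4minus >= 0 && config$cohort$n_e4plus >= 0,
      "cohort counts")
  chk(config$eeg$sample_rate > 2 * config$eeg$band[2], "eeg$sample_rate")
  chk(config$eeg$duration >= config$eeg$epoch_s, "eeg$duration")
  chk(config$bold$n_volumes >= 50, "bold$n_volumes")
  chk(config$bold$tr > 0, "bold$tr")
  chk(config$bold$band[1] > 0 &&
        config$bold$band[2] < 1 / (2 * config$bold$tr), "bold$band")
  config
}

#' Read a configuration from YAML or JSON
#' @param path File path (.yaml/.yml or .json).
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

# 10-20 channel -> (scalp region, hemisphere) map used for the IAPF ANOVA.
channel_topography <- function() {
  data.frame(
    channel = c("O2", "O1", "P4", "P3", "C4", "C3", "F4", "F3",
                "Fp2", "Fp1", "T6", "T5", "T4", "T3", "F8", "F7"),
    region = rep(c("occipital", "parietal", "central", "frontal1",
                   "frontal2", "temporal1", "temporal2", "temporal3"),
                 each = 2),
    hemisphere = rep(c("right", "left"), 8),
    stringsAsFactors = FALSE)
}

table_md5 <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(format(df, digits = 12), tmp, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates generate -> extract -> denoise -> connect -> infer.
#' Produces the cohort table; subband and IAPF repeated-measures ANOVA
#' tables; the genotype x subband Duncan post-hoc table; age-IAPF
#' correlations per genotype with their Fisher r-to-z comparison; the
#' edge-wise genotype contrast table with within-group significance; the
#' IAPF-versus-edge-z correlation table; and a machine-readable manifest
#' (seed, config hash, package version, table checksums).
#'
#' @param config Configuration list (see [default_config()]).
#' @param output_dir Optional directory; tables are written as TSV and the
#'   manifest as JSON, atomically.
#' @return An `alphaconn_run` object: list(tables, manifest).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  config <- validate_config(config)
  tables <- list()
  eegp <- eeg_gen_params(sample_rate = config$eeg$sample_rate,
                         duration = config$eeg$duration,
                         seed = config$seed)
  cohort <- run_stage("cohort", generate_cohort(
    config$cohort$n_e4minus, config$cohort$n_e4plus, eegp))
  tables$cohort <- cohort

  if (config$mode != "fmri_only") {
    eeg_res <- run_stage("eeg_spectral", {
      sub_tabs <- list(); iapf_tabs <- list()
      for (i in seq_len(nrow(cohort))) {
        rec <- synth_eeg(cohort[i, ], eegp)
        rec <- bandlimit(rec, config$eeg$band[1], config$eeg$band[2])
        st <- subject_subband_table(rec, epoch_s = config$eeg$epoch_s,
                                    total_band = config$eeg$band)
        st$subject <- cohort$id[i]
        it <- estimate_iapf(rec, epoch_s = config$eeg$epoch_s)
        it$subject <- cohort$id[i]
        sub_tabs[[i]] <- st; iapf_tabs[[i]] <- it
      }
      list(subband = do.call(rbind, sub_tabs),
           iapf = do.call(rbind, iapf_tabs))
    })
    tables$subband_power <- eeg_res$subband
    tables$iapf <- eeg_res$iapf

    run_stage("eeg_stats", {
      # subband ANOVA: channel-averaged logit power, band as within factor
      sb <- stats::aggregate(value ~ subject + band, eeg_res$subband, mean)
      sb <- merge(sb, cohort[c("id", "genotype", "age_group", "sex")],
                  by.x = "subject", by.y = "id")
      tables$anova_subband <- rm_anova(
        sb, "value", between = c("genotype", "age_group"),
        within = "band", covariates = "sex", subject = "subject")

      # Duncan post-hoc on genotype x band cells against the within error
      errs <- attr(tables$anova_subband, "errors")
      werr <- errs[errs$stratum == "subject:band", ]
      cells <- stats::aggregate(value ~ genotype + band, sb, mean)
      cellnames <- paste(cells$genotype, cells$band, sep = "|")
      ns <- table(cohort$genotype)[cells$genotype]
      cm <- stats::setNames(cells$value, cellnames)
      tables$posthoc_genotype_band <- duncan_posthoc(
        cm, as.numeric(ns), werr$ms, werr$df, alpha = config$alpha)

      # IAPF ANOVA: region x hemisphere within, genotype x age between
      topo <- channel_topography()
      ia <- merge(eeg_res$iapf, topo, by = "channel")
      ia <- merge(ia, cohort[c("id", "genotype", "age_group", "sex")],
                  by.x = "subject", by.y = "id")
      tables$anova_iapf <- rm_anova(
        ia, "iapf", between = c("genotype", "age_group"),
        within = c("region", "hemisphere"), covariates = "sex",
        subject = "subject")

      # age-IAPF correlation per genotype + Fisher r-to-z comparison
      im <- stats::aggregate(iapf ~ subject, eeg_res$iapf, mean)
      im <- merge(im, cohort, by.x = "subject", by.y = "id")
      cors <- lapply(split(im, im$genotype), function(d)
        corr_test(d$age, d$iapf, method = "pearson"))
      fz <- compare_correlations_fisher(
        cors$E4plus$r, cors$E4plus$n, cors$E4minus$r, cors$E4minus$n,
        alternative = "less")
      tables$age_iapf_correlation <- data.frame(
        genotype = names(cors),
        r = vapply(cors, `[[`, numeric(1), "r"),
        p = vapply(cors, `[[`, numeric(1), "p"),
        n = vapply(cors, `[[`, numeric(1), "n"),
        fisher_z_vs_other = c(-fz$z, fz$z),
        fisher_p_one_sided = fz$p, row.names = NULL)
      NULL
    })
  }

  if (config$mode != "eeg_only") {
    fmri <- run_stage("fmri_connectivity", {
      sel <- rbind(
        utils::head(cohort[cohort$genotype == "E4minus", ],
                    config$bold$n_e4minus),
        utils::head(cohort[cohort$genotype == "E4plus", ],
                    config$bold$n_e4plus))
      if (any(table(sel$genotype) < 2))
        stop("fMRI subset needs at least 2 subjects per genotype")
      boldp <- bold_gen_params(tr = config$bold$tr,
                               n_volumes = config$bold$n_volumes,
                               seed = config$seed)
      zs <- list()
      for (i in seq_len(nrow(sel))) {
        ses <- synth_bold(sel[i, ], boldp)
        des <- nuisance_design(ses, k_per_tissue = config$bold$k_per_tissue,
                               fd_percentile = config$bold$fd_percentile)
        den <- denoise(ses$roi, des, band = config$bold$band, tr = ses$tr)
        zs[[sel$id[i]]] <- connectivity(den)
      }
      list(subjects = sel, z = zs)
    })
    tables$edge_contrast <- run_stage("edge_stats", edge_group_compare(
      fmri$z, factor(fmri$subjects$genotype,
                     levels = c("E4plus", "E4minus"))))
  }

  if (config$mode == "joint") {
    run_stage("eeg_fmri_link", {
      im <- stats::aggregate(iapf ~ subject, tables$iapf, mean)
      ids <- names(fmri$z)
      im <- im[match(ids, im$subject), ]
      et <- lapply(fmri$z, edge_table)
      edges <- et[[1]][c("roi_i", "roi_j")]
      rows <- lapply(seq_len(nrow(edges)), function(e) {
        zvec <- vapply(et, function(t) t$z[e], numeric(1))
        ct <- corr_test(im$iapf, zvec, method = "auto")
        data.frame(roi_i = edges$roi_i[e], roi_j = edges$roi_j[e],
                   r = ct$r, p = ct$p, n = ct$n, method = ct$method,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tables$iapf_edge_correlation <- tab[order(tab$p), ]
      NULL
    })
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "alphaconn",
    version = as.character(utils::packageVersion("alphaconn")),
    seed = config$seed,
    config = config,
    config_hash = unname(tools::md5sum(tmp)),
    tables = lapply(tables, table_md5))
  unlink(tmp)

  out <- structure(list(tables = tables, manifest = manifest),
                   class = "alphaconn_run")
  if (!is.null(output_dir)) write_run(out, output_dir)
  out
}

#' Write a pipeline run to disk
#' @param run An `alphaconn_run`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run <- function(run, output_dir) {
  stopifnot(inherits(run, "alphaconn_run"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$tables)) {
    atomic_write(file.path(output_dir, paste0(nm, ".tsv")), function(p)
      utils::write.table(run$tables[[nm]], p, sep = "\t",
                         row.names = FALSE, quote = FALSE))
  }
  atomic_write(file.path(output_dir, "manifest.json"), function(p)
    jsonlite::write_json(run$manifest, p, auto_unbox = TRUE, digits = NA))
  invisible(output_dir)
}

#' @export
print.alphaconn_run <- function(x, ...) {
  cat("<alphaconn_run> seed", x$manifest$seed, "| tables:",
      paste(names(x$tables), collapse = ", "), "\n")
  if (!is.null(x$tables$age_iapf_correlation)) {
    cat("\nAge-IAPF correlation by genotype:\n")
    print(x$tables$age_iapf_correlation, digits = 3)
  }
  if (!is.null(x$tables$edge_contrast)) {
    cat("\nTop genotype-contrast edges:\n")
    print(utils::head(x$tables$edge_contrast[, 1:6], 5), digits = 3)
  }
  invisible(x)
}
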