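# Shared fixtures, all generated in code.

# single-channel recording wrapper
mk_rec <- function(x, rate = 256, label = "O2") {
  structure(list(samples = matrix(x, nrow = 1,
                                  dimnames = list(label, NULL)),
                 rate = rate, labels = label),
            class = "eeg_recording")
}

# balanced 2x2-between / L-level-within toy for the ANOVA oracle
mk_rm_toy <- function(n_per_cell = 3, n_within = 5, effect = 0.5) {
  subs <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                      rep = seq_len(n_per_cell))
  subs$subject <- sprintf("s%02d", seq_len(nrow(subs)))
  d <- merge(subs, data.frame(w = paste0("w", seq_len(n_within))))
  d$y <- stats::rnorm(nrow(d)) +
    effect * (d$A == "a2") +
    0.3 * (d$w == "w2") * (d$B == "b2")
  d
}

# independent mixed-ANOVA oracle: base R aov with an Error stratum
aov_oracle <- function(d) {
  fit <- summary(stats::aov(y ~ A * B * w + Error(subject / w), data = d))
  getF <- function(tab, term)
    tab[match(term, trimws(rownames(tab))), "F value"]
  betw <- fit[["Error: subject"]][[1]]
  withn <- fit[["Error: subject:w"]][[1]]
  c(A = getF(betw, "A"), B = getF(betw, "B"), `A:B` = getF(betw, "A:B"),
    w = getF(withn, "w"), `w:A` = getF(withn, "A:w"),
    `w:B` = getF(withn, "B:w"), `w:A:B` = getF(withn, "A:B:w"))
}

# zero-coupling BOLD parameter set without nuisance (pure null sessions)
null_bold_params <- function(n_volumes = 150, n_roi = 8, seed = 1) {
  labs <- sprintf("R%02d", seq_len(n_roi))
  zero <- matrix(0, n_roi, n_roi, dimnames = list(labs, labs))
  bold_gen_params(n_volumes = n_volumes, roi_labels = labs,
                  coupling_by_genotype = list(E4minus = zero, E4plus = zero),
                  n_nuisance_components = 0, nuisance_amplitude = 0,
                  seed = seed)
}
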