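test_that("mixed ANOVA matches the aov oracle on random balanced toys", {
  set.seed(61)
  for (rep in 1:20) {
    d <- mk_rm_toy(n_per_cell = sample(2:4, 1), effect = runif(1, 0, 1))
    mine <- rm_anova(d, "y", between = c("A", "B"), within = "w",
                     subject = "subject")
    oracle <- aov_oracle(d)
    expect_equal(setNames(mine$F, mine$effect)[names(oracle)], oracle,
                 tolerance = 1e-8)
  }
})

test_that("two crossed within factors match aov stratum by stratum", {
  set.seed(62)
  subs <- expand.grid(A = c("a1", "a2"), rep = 1:4)
  subs$subject <- sprintf("s%02d", seq_len(nrow(subs)))
  d <- merge(merge(subs, data.frame(r = paste0("r", 1:3))),
             data.frame(h = c("L", "R")))
  d$y <- rnorm(nrow(d)) + 0.4 * (d$r == "r2") +
    0.5 * (d$h == "L") * (d$A == "a1")
  mine <- rm_anova(d, "y", between = "A", within = c("r", "h"),
                   subject = "subject")
  fit <- summary(aov(y ~ A * r * h + Error(subject / (r * h)), data = d))
  getF <- function(stratum, term) {
    tab <- fit[[paste0("Error: ", stratum)]][[1]]
    tab[match(term, trimws(rownames(tab))), "F value"]
  }
  g <- function(e) mine$F[mine$effect == e]
  expect_equal(g("A"), getF("subject", "A"), tolerance = 1e-8)
  expect_equal(g("r"), getF("subject:r", "r"), tolerance = 1e-8)
  expect_equal(g("r:A"), getF("subject:r", "A:r"), tolerance = 1e-8)
  expect_equal(g("h"), getF("subject:h", "h"), tolerance = 1e-8)
  expect_equal(g("h:A"), getF("subject:h", "A:h"), tolerance = 1e-8)
  expect_equal(g("r:h"), getF("subject:r:h", "r:h"), tolerance = 1e-8)
  expect_equal(g("r:h:A"), getF("subject:r:h", "A:r:h"), tolerance = 1e-8)
})

test_that("degenerate and invalid ANOVA inputs are caught", {
  d <- mk_rm_toy()
  d$y <- 1  # constant response: all F = 0
  mine <- rm_anova(d, "y", between = c("A", "B"), within = "w",
                   subject = "subject")
  expect_true(all(mine$F == 0))
  # one-way toy with hand-computed F(1,4) = 13.5
  toy <- data.frame(subject = paste0("s", 1:6),
                    g = rep(c("g1", "g2"), each = 3), y = 1:6)
  res <- rm_anova(toy, "y", between = "g", subject = "subject")
  expect_equal(res$F, 13.5)
  expect_equal(res$df1, 1); expect_equal(res$df2, 4)
  # singleton group
  bad <- data.frame(subject = paste0("s", 1:4),
                    g = c("g1", "g1", "g1", "g2"), y = rnorm(4))
  expect_error(rm_anova(bad, "y", between = "g", subject = "subject"),
               "singleton")
  # unbalanced within
  d2 <- mk_rm_toy()[-1, ]
  expect_error(rm_anova(d2, "y", between = c("A", "B"), within = "w",
                        subject = "subject"), "balanced")
})

test_that("between-effect F is invariant to subject relabeling in a cell", {
  set.seed(63)
  d <- mk_rm_toy()
  ref <- rm_anova(d, "y", between = c("A", "B"), within = "w",
                  subject = "subject")
  # swap the ids of two subjects in the same (A,B) cell
  s_in_cell <- unique(d$subject[d$A == "a1" & d$B == "b1"])[1:2]
  d2 <- d
  d2$subject[d$subject == s_in_cell[1]] <- "tmp"
  d2$subject[d$subject == s_in_cell[2]] <- s_in_cell[1]
  d2$subject[d2$subject == "tmp"] <- s_in_cell[2]
  out <- rm_anova(d2, "y", between = c("A", "B"), within = "w",
                  subject = "subject")
  expect_equal(out$F[out$effect == "A"], ref$F[ref$effect == "A"],
               tolerance = 1e-10)
})

test_that("covariates are absorbed in the between stratum", {
  set.seed(64)
  d <- mk_rm_toy(n_per_cell = 4)
  sexes <- setNames(sample(c("M", "W"), length(unique(d$subject)), TRUE),
                    unique(d$subject))
  d$sex <- sexes[d$subject]
  res <- rm_anova(d, "y", between = c("A", "B"), within = "w",
                  covariates = "sex", subject = "subject")
  expect_true("sex" %in% res$effect)
  # covariate costs one between-subject error df
  plain <- rm_anova(d, "y", between = c("A", "B"), within = "w",
                    subject = "subject")
  expect_equal(res$df2[res$effect == "A"],
               plain$df2[plain$effect == "A"] - 1)
  # within-stratum df untouched
  expect_equal(res$df2[res$effect == "w"],
               plain$df2[plain$effect == "w"])
})

test_that("Duncan test ranks means and protects nested ranges", {
  # identical means: nothing significant
  dp0 <- duncan_posthoc(c(a = 1, b = 1, c = 1), 5, 1, 12)
  expect_false(any(dp0$significant))
  # huge separation: everything significant
  dp1 <- duncan_posthoc(c(a = 0, b = 20, c = 40), 6, 1, 12)
  expect_true(all(dp1$significant))
  # two cells: agrees with a studentized-range brute check
  m <- c(g1 = 0, g2 = 1.4); nn <- c(8, 8); mse <- 1; df <- 14
  dp2 <- duncan_posthoc(m, nn, mse, df)
  qobs <- abs(diff(m)) / sqrt(mse / 8)
  expect_equal(dp2$significant, unname(qobs > qtukey(0.95, 2, df)))
  expect_equal(dp2$q_obs, unname(qobs))
  # protection: an inner pair cannot be significant when the enclosing
  # range is not
  dp3 <- duncan_posthoc(c(a = 0, b = 1, c = 0.05), 4, 4, 8)
  wide <- dp3$significant[dp3$span == 3]
  if (!wide) expect_false(any(dp3$significant))
  expect_error(duncan_posthoc(c(a = 1, b = 2), 4, -1, 8), "positive")
})
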