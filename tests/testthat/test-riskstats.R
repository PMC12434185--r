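# Group tests, screening, stepwise logistic regression, ROC/DeLong.

test_that("summary t-test reproduces published group comparisons", {
  w <- welch_t_from_summary(320.28, 26.79, 31, 301.32, 35.42, 28)
  expect_equal(round(w$p, 3), 0.026)
  p <- welch_t_from_summary(320.28, 26.79, 31, 301.32, 35.42, 28,
                            variant = "pooled")
  expect_equal(round(p$p, 3), 0.023)
  same <- welch_t_from_summary(10, 2, 20, 10, 2, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # doubling both n at fixed summaries strictly decreases p
  w2 <- welch_t_from_summary(320.28, 26.79, 62, 301.32, 35.42, 56)
  expect_lt(w2$p, w$p)
  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10), "SD")
})

test_that("Fisher exact test matches the enumeration oracle", {
  tab <- matrix(c(1, 27, 9, 22), 2, byrow = TRUE)
  expect_equal(round(fisher_exact(tab), 3), 0.013)
  expect_equal(fisher_exact(tab), fisher_enum_oracle(tab), tolerance = 1e-9)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(0L, 2, 2)), 1)
  set.seed(41)
  for (k in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("Mann-Whitney U relates to ranks and the empirical AUC", {
  x <- c(1, 2, 3, 4)
  tied <- mann_whitney(x, x)
  expect_equal(tied$U, length(x)^2 / 2)
  set.seed(13)
  for (k in 1:10) {
    a <- sample(1:8, 15, replace = TRUE)
    b <- sample(2:9, 11, replace = TRUE)
    mw <- mann_whitney(a, b)
    expect_equal(mw$U / (15 * 11),
                 auc_pairwise_oracle(c(a, b), rep(c(1, 0), c(15, 11))))
  }
})

test_that("chi-square routes to Fisher when an expected count is below 5", {
  tab <- matrix(c(1, 27, 9, 22), 2, byrow = TRUE)
  expect_lt(min(outer(rowSums(tab), colSums(tab)) / sum(tab)), 5)
  out <- chi_square(tab)
  expect_equal(out$method, "fisher")
  expect_equal(out$p, fisher_exact(tab))
  big <- matrix(c(30, 20, 15, 35), 2)
  out2 <- chi_square(big)
  expect_equal(out2$method, "chi-square")
  expect_equal(out2$p, chisq.test(big)$p.value)
})

test_that("univariate screening keeps discriminative variables and drops others", {
  coh <- generate_cohort(cohort_spec(n_control = 400, n_pe = 400, seed = 19))
  sc <- univariate_screen(coh)
  expect_true(all(c("lvet_ms", "htn_history") %in% attr(sc, "selected")))
  expect_false("hr_bpm" %in% attr(sc, "selected"))
  sc0 <- univariate_screen(coh, alpha_in = 0)
  expect_length(attr(sc0, "selected"), 0)
  coh$flat <- 1
  expect_warning(scf <- univariate_screen(coh, candidates = c("lvet_ms", "flat")),
                 "constant")
  expect_false("flat" %in% attr(scf, "selected"))
})

test_that("screening and stepwise entry hold their nominal type-I rates", {
  n_rep <- 500
  hits_screen <- logical(n_rep)
  hits_step <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    coh <- with_seed_local(9000 + s, {
      data.frame(group = rep(c("control", "pe"), c(28, 31)),
                 noise = rnorm(59))
    })
    sc <- univariate_screen(coh, candidates = "noise")
    hits_screen[s] <- "noise" %in% attr(sc, "selected")
    fit <- fit_logistic_forward(coh, "noise")
    hits_step[s] <- "noise" %in% fit$variables
  }
  # screening threshold p < 0.1
  expect_lt(abs(mean(hits_screen) - 0.10), 0.04)
  # stepwise entry threshold p < 0.05
  expect_lt(abs(mean(hits_step) - 0.05), 0.03)
})

test_that("a single binary predictor recovers the log odds ratio of its table", {
  # 2x2: exposed 12/20 cases, unexposed 8/30 cases
  df <- data.frame(
    group = rep(c("pe", "control", "pe", "control"), c(12, 8, 8, 22)),
    exposed = rep(c(1, 1, 0, 0), c(12, 8, 8, 22)))
  fit <- fit_logistic_forward(df, "exposed", alpha_enter = 0.5)
  expect_equal(fit$variables, "exposed")
  or_table <- (12 / 8) / (8 / 22)
  est <- fit$coefficients$estimate[fit$coefficients$term == "exposed"]
  expect_equal(exp(est), or_table, tolerance = 1e-6)
})

test_that("monotone transforms of a sole predictor preserve the probability ranking", {
  coh <- generate_cohort(cohort_spec(seed = 31))
  f1 <- fit_logistic_forward(coh, "lvet_ms", alpha_enter = 0.99)
  coh$lvet_t <- exp(coh$lvet_ms / 50)
  f2 <- fit_logistic_forward(coh, "lvet_t", alpha_enter = 0.99)
  expect_equal(order(f1$probabilities), order(f2$probabilities))
})
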