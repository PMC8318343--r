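test_that("error summaries report per-axis MAE/SD and per-sample norms", {
  zero <- error_summary(tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 0)))
  expect_true(all(zero$mae == 0) && all(zero$sd == 0))
  one <- error_summary(tibble::tibble(x = 3, y = 4, z = 0))
  mag <- one[one$component == "magnitude", ]
  expect_equal(mag$mae, 5)
  expect_equal(mag$sd, 0)
  # the magnitude row averages per-sample Euclidean norms, which exceeds the
  # norm of the per-axis means for any non-degenerate sample
  set.seed(5)
  res <- tibble::tibble(x = rnorm(500), y = rnorm(500), z = rnorm(500))
  s <- error_summary(res)
  norm_of_means <- sqrt(sum(s$mae[s$component %in% c("x", "y", "z")]^2))
  expect_gt(s$mae[s$component == "magnitude"], norm_of_means)
  # c_x/c_y/c_z columns from make_error_record() are accepted
  rec <- make_error_record(position_xyz(0, 0, 0), position_xyz(3, 4, 0),
                           position_xyz(0, 0, 0))
  expect_equal(error_summary(rec)$mae[4], 5)
})

test_that("Fisher's exact test matches its examples and known oracles", {
  # published pipette-detection table: 21/32 vs 36/36 -> p ~ 8e-5
  p <- fisher_exact_2x2(rbind(c(21, 11), c(36, 0)))
  expect_equal(p, 8e-5, tolerance = 0.25)
  expect_equal(p, stats::fisher.test(rbind(c(21, 11), c(36, 0)))$p.value,
               tolerance = 1e-12)
  # identical groups are maximally unsurprising
  expect_equal(fisher_exact_2x2(rbind(c(10, 10), c(10, 10))), 1)
  # small example equals exhaustive enumeration over admissible tables
  expect_equal(fisher_exact_2x2(rbind(c(3, 2), c(1, 3))),
               fisher_enum(3, 2, 1, 3), tolerance = 1e-12)
  # zero margin carries no information
  expect_equal(fisher_exact_2x2(rbind(c(0, 5), c(0, 7))), 1)
})

test_that("Fisher implementation equals enumeration and fisher.test on random tables", {
  set.seed(8)
  for (i in 1:200) {
    cts <- rmultinom(1, sample(4:40, 1), rep(0.25, 4))[, 1]
    tab <- matrix(cts, 2, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_enum(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA and Tukey HSD behave on identical and textbook groups", {
  ident <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  a0 <- one_way_anova(ident)
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p_value, 1)
  # textbook 3 x 5 case: F from hand-computed sums of squares
  g <- list(g1 = c(6, 8, 4, 5, 3), g2 = c(8, 12, 9, 11, 6),
            g3 = c(13, 9, 11, 8, 7))
  grand <- mean(unlist(g))
  ss_b <- 5 * sum((vapply(g, mean, numeric(1)) - grand)^2)
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_hand <- (ss_b / 2) / (ss_w / 12)
  a1 <- one_way_anova(g)
  expect_equal(a1$statistic, f_hand, tolerance = 1e-12)
  expect_equal(a1$df_between, 2)
  expect_equal(a1$df_within, 12)
  tk <- tukey_hsd(g)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$adj_p_value >= 0 & tk$adj_p_value <= 1))
  tk_ident <- tukey_hsd(ident)
  expect_true(all(tk_ident$adj_p_value > 0.999))
  # data-frame interface agrees with the list interface
  df <- tibble::tibble(value = unlist(g),
                       group = rep(names(g), each = 5))
  expect_equal(one_way_anova(df)$statistic, a1$statistic)
})

test_that("D'Agostino K2 matches an independent implementation and is sign-symmetric", {
  # frozen oracle values computed once from scipy.stats.normaltest on the
  # same deterministic samples
  i <- 1:100
  x <- sin(i) * 3 + (i %% 7)
  r <- dagostino_k2(x)
  expect_equal(r$statistic, 4.231848611366423, tolerance = 1e-10)
  expect_equal(r$p_value, 0.1205218390331491, tolerance = 1e-10)
  i <- 1:500
  x2 <- sin(i) * 3 + (i %% 7)
  r2 <- dagostino_k2(x2)
  expect_equal(r2$statistic, 20.80881019077679, tolerance = 1e-10)
  expect_equal(r2$p_value, 3.0298719853878082e-05, tolerance = 1e-8)
  # strong skew is detected with overwhelming evidence
  x3 <- exp(3 * sin(sqrt(1:500)))
  expect_lt(dagostino_k2(x3)$p_value, 1e-6)
  # negating the sample flips the skewness z but not K2
  rneg <- dagostino_k2(-x)
  expect_equal(rneg$statistic, r$statistic, tolerance = 1e-12)
  expect_equal(rneg$z_skewness, -r$z_skewness, tolerance = 1e-12)
  # small samples are refused
  expect_error(dagostino_k2(rnorm(10)), "n >= 20")
})

test_that("success-rate report reproduces the published comparison", {
  rep <- success_rate_report(reference_success_counts())
  # 12/32 = 37.5% rounds half-away to 38; only truncation prints 37
  expect_equal(rep$rate1_pct, c(66, 59, 38)) # cross-correlation
  expect_equal(rep$rate2_pct, c(100, 92, 64)) # CNN
  expect_equal(rep$improvement_pct, c(52, 54, 70))
  expect_equal(rep$fisher_p[1], 8e-5, tolerance = 0.25)
  expect_lt(rep$fisher_p[2], 0.005)
  expect_lt(rep$fisher_p[3], 0.05 * 1.3)
  # equal rates give zero improvement; zero baseline is undefined
  flat <- success_rate_report(tibble::tibble(stage = "s", s1 = 10, n1 = 20,
                                             s2 = 15, n2 = 30))
  expect_equal(flat$improvement_pct, 0)
  undef <- success_rate_report(tibble::tibble(stage = "s", s1 = 0, n1 = 20,
                                              s2 = 15, n2 = 30))
  expect_true(is.na(undef$improvement_pct))
  # truncation mode floors 37.5% to 37 as well
  trunc <- success_rate_report(reference_success_counts(), rounding = "truncate")
  expect_equal(trunc$rate1_pct, c(65, 59, 37))
})
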