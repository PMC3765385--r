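test_that("percent agreement counts matching complete items", {
  m <- rm_from_cols(a = rep(c(0L, 1L, 2L), 10), b = rep(c(0L, 1L, 2L), 10))
  expect_equal(percent_agreement(m), 100)

  a <- rep(c(1L, 2L), c(25, 5))
  b <- c(rep(1L, 25), rep(0L, 5))
  expect_equal(percent_agreement(rm_from_cols(a = a, b = b)), 100 * 25 / 30)

  # missing cells drop the item listwise
  a[3] <- NA
  expect_equal(percent_agreement(rm_from_cols(a = a, b = b)), 100 * 24 / 29)
  expect_error(percent_agreement(rm_from_cols(a = c(NA, 1L), b = c(1L, NA))),
               "no complete items")
})

test_that("multi-column percent agreement equals the pairwise enumeration oracle", {
  withr::local_seed(5)
  for (rep in 1:10) {
    m <- matrix(sample(0:2, 30, replace = TRUE), nrow = 10, ncol = 3)
    expect_equal(percent_agreement(as_rating_matrix(m)),
                 oracle_pairwise_agreement(m))
  }
  # "all columns agree" variant is never above the pairwise mean
  m <- matrix(sample(0:2, 60, replace = TRUE), nrow = 20)
  expect_lte(percent_agreement(as_rating_matrix(m), method = "all"),
             percent_agreement(as_rating_matrix(m)))
})

test_that("Cohen's kappa matches hand-computed and textbook cases", {
  # perfect agreement over >= 2 distinct ratings
  m <- rm_from_cols(a = rep(0:2, 5), b = rep(0:2, 5))
  expect_equal(cohen_kappa(m), 1)

  # contingency counts [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c(0L, 0L, 1L, 1L), c(20, 5, 10, 15))
  b <- rep(c(0L, 1L, 0L, 1L), c(20, 5, 10, 15))
  expect_equal(cohen_kappa(rm_from_cols(a = a, b = b)), 0.4)

  # independence by construction: p_o = p_e -> 0
  a <- rep(c(0L, 1L), each = 2)
  b <- rep(c(0L, 1L), times = 2)
  expect_equal(cohen_kappa(rm_from_cols(a = a, b = b)), 0)

  # both columns constant and equal: undefined, not 1
  expect_warning(k <- cohen_kappa(rm_from_cols(a = rep(2L, 6), b = rep(2L, 6))),
                 "undefined")
  expect_true(is.na(k))

  expect_error(cohen_kappa(as_rating_matrix(matrix(0:2, 3, 3))), "exactly 2")
})

test_that("Cohen's kappa agrees with independent implementations on random data", {
  skip_if_not_installed("e1071")
  withr::local_seed(17)
  for (rep in 1:20) {
    a <- sample(0:2, 40, replace = TRUE)
    b <- ifelse(stats::runif(40) < 0.6, a, sample(0:2, 40, replace = TRUE))
    k <- cohen_kappa(rm_from_cols(a = a, b = b))
    expect_equal(k, oracle_cohen(a, b), tolerance = 1e-12)
    tab <- table(factor(a, levels = 0:2), factor(b, levels = 0:2))
    expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  }
})

test_that("Fleiss' kappa matches the direct-formula oracle", {
  # unanimity across items using >= 2 ratings
  m <- matrix(rep(rep(0:2, 4), 3), ncol = 3)
  expect_equal(fleiss_kappa(as_rating_matrix(m)), 1)

  withr::local_seed(23)
  for (rep in 1:20) {
    m <- matrix(sample(0:2, 36, replace = TRUE), ncol = 3)
    expect_equal(fleiss_kappa(as_rating_matrix(m)), oracle_fleiss(m),
                 tolerance = 1e-12)
  }

  # two columns: finite, but a pooled-marginal statistic (not Cohen's)
  a <- rep(c(0L, 1L, 2L, 2L), 5)
  b <- rep(c(0L, 2L, 2L, 1L), 5)
  expect_true(is.finite(fleiss_kappa(rm_from_cols(a = a, b = b))))

  # incomplete items excluded with a message
  m <- matrix(sample(0:2, 30, replace = TRUE), ncol = 3)
  m[2, 1] <- NA
  expect_message(fleiss_kappa(as_rating_matrix(m)), "excluded")
})

test_that("kappas stay in [-1, 1] and ignore rating relabelling", {
  withr::local_seed(31)
  perms <- list(c(0, 1, 2), c(1, 0, 2), c(2, 1, 0), c(1, 2, 0))
  for (rep in 1:10) {
    m <- matrix(sample(0:2, 24, replace = TRUE), ncol = 2)
    m3 <- matrix(sample(0:2, 36, replace = TRUE), ncol = 3)
    k2 <- cohen_kappa(as_rating_matrix(m))
    k3 <- fleiss_kappa(as_rating_matrix(m3))
    expect_true(is.na(k2) || (k2 >= -1 && k2 <= 1))
    expect_true(is.na(k3) || (k3 >= -1 && k3 <= 1))
    for (p in perms) {
      mm <- matrix(p[m + 1], ncol = 2)
      mm3 <- matrix(p[m3 + 1], ncol = 3)
      expect_equal(cohen_kappa(as_rating_matrix(mm)), k2, tolerance = 1e-12)
      expect_equal(fleiss_kappa(as_rating_matrix(mm3)), k3, tolerance = 1e-12)
      expect_equal(percent_agreement(as_rating_matrix(mm3)),
                   percent_agreement(as_rating_matrix(m3)), tolerance = 1e-12)
    }
  }
})

test_that("kappa interpretation uses the conventional bands", {
  expect_equal(interpret_kappa(0.69), "substantial")
  expect_equal(interpret_kappa(0.90), "almost perfect")
  expect_equal(interpret_kappa(-0.05), "poor/less than chance")
  expect_equal(
    interpret_kappa(c(0.1, 0.3, 0.5, 1, NA)),
    c("slight", "fair", "moderate", "perfect", "undefined")
  )
})

test_that("reliability reports assemble per-category results with summaries", {
  study <- simulate_study(sim_config(seed = 3))
  rep_inter <- reliability_report(study$inter, "inter_rater")
  res <- tidy(rep_inter)
  expect_equal(nrow(res), 9)
  expect_equal(res$kappa_type, rep("fleiss", 9))
  expect_true(all(res$n_items == 54))

  g <- glance(rep_inter)
  expect_equal(g$design, "inter_rater")
  expect_equal(g$mean_agreement, mean(res$percent_agreement))
  expect_equal(g$min_kappa, min(res$kappa))

  rep_intra <- reliability_report(study$intra, "intra_rater")
  expect_equal(tidy(rep_intra)$kappa_type, rep("cohen", 9))

  # single-category report: mean = min = max
  one <- reliability_report(dplyr::filter(study$inter, category == "Lighting"),
                            "inter_rater")
  s <- one$summary
  expect_equal(s$mean_agreement, s$min_agreement)
  expect_equal(s$mean_agreement, s$max_agreement)

  # undefined kappas are skipped in the summary, with a note
  res_na <- res
  res_na$kappa[c(2, 5)] <- NA
  expect_message(s2 <- summarize_reliability(res_na), "skipped")
  expect_equal(s2$n_kappa, 7)
  expect_equal(s2$mean_kappa, mean(res_na$kappa, na.rm = TRUE))
})

test_that("reports render as text, CSV and plots", {
  study <- simulate_study(sim_config(seed = 3))
  rep <- reliability_report(study$criterion, "criterion")
  lines <- format_reliability_report(rep)
  expect_match(lines[1], "criterion")
  expect_length(lines, 1 + 1 + 9 + 1 + 3) # title, header, 9 rows, rule, summary

  path <- withr::local_tempfile(fileext = ".csv")
  write_reliability_report(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 12)
  expect_equal(back$category[10:12], c("mean", "min", "max"))

  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("bundled published scores carry all three designs", {
  pub <- fastview_published_scores()
  expect_equal(nrow(pub), 27)
  expect_equal(sort(unique(pub$design)),
               c("criterion", "inter_rater", "intra_rater"))
  expect_true(all(table(pub$design) == 9))
  # the documented kappa pathology: high agreement, negative kappa
  uc <- pub[pub$category == "User conflict" & pub$design == "intra_rater", ]
  expect_equal(uc$percent_agreement, 90)
  expect_equal(interpret_kappa(uc$kappa), "poor/less than chance")
})
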