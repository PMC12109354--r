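test_that("score summaries use mean and n-1 standard deviation", {
  expect_equal(summarize_scores(c(1, 2, 3)), c(mean = 2, sd = 1))
  expect_equal(summarize_scores(rep(7, 5)), c(mean = 7, sd = 0))
  expect_error(summarize_scores(5), "at least 2")
  set.seed(15)
  s <- summarize_scores(rnorm(1e4, mean = 50, sd = 5))
  expect_equal(unname(s["mean"]), 50, tolerance = 0.2 / 50)
  expect_equal(unname(s["sd"]), 5, tolerance = 0.2 / 5)
})

test_that("the paired t-test matches the closed form to 6 decimals", {
  pre <- c(48, 50, 52, 47, 49)
  post <- c(60, 63, 59, 61, 62)
  cmp <- paired_t_test(pre, post)
  d <- post - pre
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-7)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-7)
  expect_equal(cmp$mean_increase, mean(d))
  expect_equal(cmp$sd_increase, sd(d))
  expect_equal(cmp$n, 5)
})

test_that("degenerate pairings warn and pin the p-value", {
  expect_warning(eq <- paired_t_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_warning(up <- paired_t_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_equal(up$p_value, 0)
  expect_equal(up$t_statistic, Inf)
  expect_error(paired_t_test(1:3, 1:4), "paired")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("closed-form agreement holds on random paired samples", {
  set.seed(16)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    pre <- rnorm(n, 50, 6)
    post <- pre + rnorm(n, 2, 3)
    cmp <- paired_t_test(pre, post)
    d <- post - pre
    expect_equal(cmp$t_statistic, mean(d) / (sd(d) / sqrt(n)),
                 tolerance = 1e-10)
  }
})

test_that("the in-memory pipeline produces full bookkeeping", {
  res <- tiny_study()
  # 3 pre + 3 post subjects in two domains
  expect_equal(nrow(res$scores), 12)
  expect_equal(sum(res$scores$domain == "time"), 6)
  expect_equal(sum(res$scores$phase == "post"), 6)
  expect_true(all(res$scores$composite >= 0 & res$scores$composite <= 100))
  expect_equal(nrow(res$comparisons), 2)
  expect_setequal(res$comparisons$domain, c("time", "frequency"))
  expect_equal(res$comparisons$n, c(3, 3))
  expect_named(res$A, c("time", "frequency"))
  expect_true(all(res$A > 0))
  # calibration floor: the worst pre-cohort modality score is exactly 0
  pre_rows <- res$scores[res$scores$phase == "pre", ]
  expect_equal(min(c(pre_rows$lfp_score, pre_rows$emg_score)), 0)
})

test_that("pipeline runs are deterministic for a fixed seed", {
  a <- tiny_study(seed = 7)
  b <- tiny_study(seed = 7)
  expect_identical(a$scores, b$scores)
  expect_identical(a$comparisons, b$comparisons)
})

test_that("manifest-driven runs reproduce the in-memory pipeline", {
  dir <- withr::local_tempdir()
  reference <- generate_cohort(tiny_spec("normal", 3, 42))
  pre <- generate_cohort(tiny_spec("bcao_pre", 2, 43))
  post <- generate_cohort(tiny_spec("bcao_post", 2, 44))
  manifest <- rbind(write_cohort(reference, file.path(dir, "ref"), "reference"),
                    write_cohort(pre, file.path(dir, "pre"), "pre"),
                    write_cohort(post, file.path(dir, "post"), "post"))
  man_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, man_path, row.names = FALSE)
  cfg <- tiny_cfg()
  res <- run_pipeline(man_path, cfg, out_dir = file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "scores.csv")))
  expect_true(file.exists(file.path(dir, "out", "comparisons.csv")))
  expect_true(file.exists(file.path(dir, "out", "report.txt")))
  mem <- score_cohorts(reference, pre, post, cfg)
  expect_equal(res$scores$composite, mem$scores$composite, tolerance = 1e-9)
  expect_equal(nrow(res$scores), 8)
  # report totals match the emitted table
  expect_true(any(grepl("8 score cards", res$report)))
})

test_that("a reference-only manifest yields an explicit notice", {
  dir <- withr::local_tempdir()
  reference <- generate_cohort(tiny_spec("normal", 2, 42))
  manifest <- write_cohort(reference, dir, "reference")
  res <- run_pipeline(manifest, tiny_cfg(coefficient_A = 1))
  expect_equal(nrow(res$scores), 0)
  expect_null(res$comparisons)
  expect_true(any(grepl("NOTICE", res$report)))
})

test_that("manifest validation names unknown roles and columns", {
  bad <- data.frame(subject_id = "s", role = "mystery", lfp_path = "a",
                    emg_path = "b")
  expect_error(run_pipeline(bad, tiny_cfg()), "mystery")
  expect_error(run_pipeline(data.frame(x = 1), tiny_cfg()), "columns")
})

test_that("subject order does not leak into scores (no hidden state)", {
  cfg <- tiny_cfg(coefficient_A = 2)
  reference <- generate_cohort(tiny_spec("normal", 3, 42))
  pre <- generate_cohort(tiny_spec("bcao_pre", 3, 43))
  post <- generate_cohort(tiny_spec("bcao_post", 3, 44))
  res_fwd <- score_cohorts(reference, pre, post, cfg)
  perm <- c(3, 1, 2)
  res_rev <- score_cohorts(reference, pre[perm], post[perm], cfg)
  fwd <- res_fwd$scores[order(res_fwd$scores$domain, res_fwd$scores$phase,
                              res_fwd$scores$sample_id), ]
  rev_ <- res_rev$scores[order(res_rev$scores$domain, res_rev$scores$phase,
                               res_rev$scores$sample_id), ]
  rownames(fwd) <- rownames(rev_) <- NULL
  expect_equal(fwd, rev_)
})
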