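# Independent brute-force oracle for the 2x2 exact test: enumerate all
# tables with the observed margins via log-factorials (no dhyper).
fisher_oracle <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  lp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(cc + 1) -
      lgamma(d + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logs <- vapply(support, lp, 0)
  p_obs <- exp(lp(tb[1, 1]))
  sum(exp(logs)[exp(logs) <= p_obs * (1 + 1e-7)])
}

test_that("Fisher's exact test matches hand enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))$p_value, 34 / 70)
  expect_equal(round(fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))$p_value, 6),
               0.485714)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))$p_value,
               2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(rbind(c(4, 6), c(4, 6)))$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))),
               class = "zfcardio_degenerate_error")
  expect_error(fisher_exact_2x2(rbind(c(1.5, 1), c(1, 1))),
               class = "zfcardio_invalid_input")
})

test_that("Fisher's exact test agrees with stats::fisher.test", {
  withr::with_seed(11, {
    for (i in 1:50) {
      tb <- matrix(rpois(4, 8) + 1, 2)
      expect_equal(fisher_exact_2x2(tb)$p_value,
                   stats::fisher.test(tb)$p.value, tolerance = 1e-10)
    }
  })
})

test_that("one-way ANOVA has the classic F behaviour", {
  expect_error(one_way_anova(list(c(1, 1, 1), c(1, 1, 1))),
               class = "zfcardio_degenerate_error")
  eq <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(one_way_anova(list(1:3)), class = "zfcardio_invalid_input")
  # cross-check against aov on an arbitrary 3-group sample
  withr::with_seed(4, {
    g <- list(rnorm(8), rnorm(10, 0.5), rnorm(7, 1))
    mine <- one_way_anova(g)
    df <- data.frame(y = unlist(g), grp = factor(rep(1:3, lengths(g))))
    ref <- summary(stats::aov(y ~ grp, df))[[1]]
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  })
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(9, {
    for (i in 1:20) {
      a <- rnorm(6 + i %% 5); b <- rnorm(8, mean = 0.4)
      f <- one_way_anova(list(a, b))$statistic
      t <- t_test_unpaired(a, b)$statistic
      expect_equal(f, t^2, tolerance = 1e-10)
    }
  })
})

test_that("the unpaired t-test handles identical and degenerate samples", {
  same <- t_test_unpaired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  deg <- t_test_unpaired(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_true(is.infinite(deg$statistic))
  expect_error(t_test_unpaired(c(2, 2), c(2, 2)),
               class = "zfcardio_degenerate_error")
  # agreement with stats::t.test (pooled)
  withr::with_seed(2, {
    a <- rnorm(12); b <- rnorm(15, 0.3)
    expect_equal(t_test_unpaired(a, b)$p_value,
                 stats::t.test(a, b, var.equal = TRUE)$p.value)
  })
})

test_that("Mendelian expectations follow the product rule", {
  expect_equal(mendelian_expected_fraction("aabb"), 1 / 16)
  expect_equal(100 * mendelian_expected_fraction("aabb"), 6.25)
  expect_equal(mendelian_expected_fraction("aa"), 1 / 4)
  expect_equal(mendelian_expected_fraction("aabbcc"), 1 / 64)
  expect_equal(mendelian_expected_fraction("AaBb"), 1 / 4)
  expect_error(mendelian_expected_fraction("aXb"),
               class = "zfcardio_invalid_input")
  expect_error(mendelian_expected_fraction("ab"),
               class = "zfcardio_invalid_input")
  # total probability over all 3^n genotype combinations is 1
  for (n in 1:3) {
    combos <- expand.grid(rep(list(c("AA", "Aa", "aa")), n),
                          stringsAsFactors = FALSE)
    total <- sum(apply(combos, 1, function(g) {
      per_locus <- mapply(function(gt, i) {
        chartr("Aa", rawToChar(as.raw(c(64 + i, 96 + i))), gt)
      }, g, seq_len(n))
      mendelian_expected_fraction(paste(per_locus, collapse = ""))
    }))
    expect_equal(total, 1)
  }
})

test_that("observed fractions display at one decimal, keep full precision", {
  x <- observed_fraction(7, 120)
  expect_equal(as.numeric(x), 700 / 120)
  expect_equal(format(x), "5.8%")
  expect_output(print(x), "5.8%", fixed = TRUE)
  expect_equal(as.numeric(observed_fraction(0, 50)), 0)
  expect_equal(as.numeric(observed_fraction(50, 50)), 100)
  expect_error(observed_fraction(3, 0), class = "zfcardio_invalid_input")
  expect_error(observed_fraction(5, 4), class = "zfcardio_invalid_input")
})

test_that("DEG filtering applies inclusive FDR and strict fold-change bounds", {
  genes <- tibble::tibble(
    gene = c("on_fdr", "on_lfc", "both_on", "clear_in", "neg_in", "out"),
    log2FC = c(1.0, 0.4, 0.4, 0.41, -1.2, 0.1),
    FDR = c(0.05, 0.01, 0.05, 0.05, 0.01, 0.5))
  kept <- filter_degs(genes)
  expect_setequal(kept$gene, c("on_fdr", "clear_in", "neg_in"))
  expect_false("on_lfc" %in% kept$gene)   # |lfc| must exceed 0.4
  expect_false("both_on" %in% kept$gene)
  expect_true("on_fdr" %in% kept$gene)    # FDR boundary is inclusive
  expect_equal(nrow(filter_degs(genes, fdr_max = 0.5, lfc_min = 0)), 6L)
})

test_that("DEG set decomposition is exact set arithmetic", {
  same <- deg_set_decomposition(letters[1:5], letters[1:5])
  expect_equal(same$unique_a, 0L); expect_equal(same$unique_b, 0L)
  disj <- deg_set_decomposition(letters[1:5], letters[6:10])
  expect_equal(disj$common, 0L)
  mid <- deg_set_decomposition(as.character(1:10), as.character(6:15))
  expect_equal(c(mid$common, mid$unique_a, mid$unique_b), c(5L, 5L, 5L))
  expect_equal(mid$n_a, mid$common + mid$unique_a)
})

test_that("ventricle classification separates a reduced-EDV subpopulation", {
  ctrl <- withr::with_seed(5, rnorm(100, mean = 2.2e5, sd = 1.2e4))
  expect_equal(classify_ventricle(median(ctrl), ctrl)$label, "NV")
  expect_equal(classify_ventricle(min(ctrl) - 1, ctrl)$label, "SV")
  expect_error(classify_ventricle(2e5, ctrl[1:5]),
               class = "zfcardio_invalid_reference")
  # 30% of fish with 40% reduced EDV: classification accuracy >= 0.9
  cohort <- withr::with_seed(6, {
    truth <- rbinom(200, 1, 0.3) == 1
    edv <- ifelse(truth, rnorm(200, 0.6 * 2.2e5, 1.2e4),
                  rnorm(200, 2.2e5, 1.2e4))
    list(truth = truth, edv = edv)
  })
  lab <- classify_ventricle(cohort$edv, ctrl)$label
  acc <- mean((lab == "SV") == cohort$truth)
  expect_gte(acc, 0.9)
})
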