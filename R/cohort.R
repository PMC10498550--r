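#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 count table,
#' computed by full enumeration of the hypergeometric distribution over
#' every table with the observed margins. Two-sidedness follows the
#' point-probability rule used by the common statistics suites: the
#' p-value is the sum of the probabilities of all tables whose point
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return one-row tibble: `p_value`, `odds_ratio` (sample), `method`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) abort_invalid_input("`table` must be 2x2.")
  if (any(!is.finite(tb)) || any(tb < 0) || any(tb != round(tb))) {
    abort_invalid_input("Counts must be non-negative integers.")
  }
  r <- rowSums(tb); cl <- colSums(tb)
  if (any(r == 0) || any(cl == 0)) {
    abort_degenerate("A zero margin makes the table degenerate; the test is undefined.")
  }
  a_obs <- tb[1, 1]
  support <- max(0, cl[1] - r[2]):min(r[1], cl[1])
  probs <- dhyper(support, r[1], r[2], cl[1])
  p_obs <- dhyper(a_obs, r[1], r[2], cl[1])
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble(
    p_value = min(p, 1),
    odds_ratio = (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1]),
    method = "Fisher's exact test (two-sided, point-probability rule)"
  )
}

#' One-way fixed-effects ANOVA
#'
#' Classic (pooled-variance) one-way ANOVA across two or more groups:
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom.
#' The classic form matches the default of the usual GUI statistics
#' packages; Welch's correction for unequal variances is available with
#' `welch = TRUE`.
#'
#' @param groups list of numeric vectors, one per group (each `n >= 2`).
#' @param welch use Welch's heteroscedastic ANOVA instead of the classic
#'   pooled form.
#' @return one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `method`.
#' @export
one_way_anova <- function(groups, welch = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort_invalid_input("`groups` must be a list of at least 2 numeric samples.")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) abort_invalid_input("Each group needs at least 2 observations.")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  within_ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  means <- vapply(groups, mean, 0)
  if (within_ss == 0 && length(unique(means)) == 1L) {
    abort_degenerate("All observations identical across groups: F is undefined (MS_within = 0, MS_between = 0).")
  }
  ht <- oneway.test(values ~ g, var.equal = !welch)
  tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p_value = unname(ht$p.value),
    method = if (welch) "Welch one-way ANOVA" else "one-way ANOVA (fixed effects)"
  )
}

#' Two-tailed unpaired Student's t-test
#'
#' Pooled-variance Student's t with `n_a + n_b - 2` degrees of freedom and
#' a two-tailed p-value. When the pooled variance is zero the statistic is
#' degenerate: identical means raise an error, different means are
#' reported as `t = +/-Inf`, `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param welch use Welch's unequal-variance t-test instead.
#' @return one-row tibble: `statistic` (t), `df`, `p_value`,
#'   `mean_a`, `mean_b`, `degenerate`, `method`.
#' @export
t_test_unpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_invalid_input("Each sample needs at least 2 observations.")
  }
  pooled_ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (pooled_ss == 0) {
    if (mean(a) == mean(b)) {
      abort_degenerate("Zero variance and equal means: t is undefined.")
    }
    return(tibble(
      statistic = sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2, p_value = 0,
      mean_a = mean(a), mean_b = mean(b), degenerate = TRUE,
      method = "two-tailed unpaired Student's t-test"))
  }
  ht <- t.test(a, b, var.equal = !welch, paired = FALSE)
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    mean_a = mean(a), mean_b = mean(b), degenerate = FALSE,
    method = if (welch) "two-tailed unpaired Welch t-test"
             else "two-tailed unpaired Student's t-test"
  )
}

#' Expected Mendelian fraction of a genotype from a multi-locus in-cross
#'
#' For parents heterozygous at every locus (`Aa x Aa` per locus,
#' independent assortment), the expected offspring fraction of a target
#' genotype is the product over loci of the Punnett-square probabilities
#' 1/4 (`AA`), 1/2 (`Aa`), 1/4 (`aa`). A double-heterozygous in-cross
#' therefore yields 1/16 (6.25%) double homozygotes.
#'
#' @param target genotype string, two letters per locus, e.g. `"aabb"`
#'   (double homozygous mutant) or `"AaBB"`.
#' @param n_loci optional expected number of loci; checked against
#'   `target` when given.
#' @return expected fraction in `[0, 1]`.
#' @export
#' @examples
#' mendelian_expected_fraction("aabb")      # 1/16
#' mendelian_expected_fraction("aa")        # 1/4
mendelian_expected_fraction <- function(target, n_loci = NULL) {
  if (!is.character(target) || length(target) != 1L || !nzchar(target)) {
    abort_invalid_input("`target` must be a non-empty genotype string like \"aabb\".")
  }
  chars <- strsplit(target, "")[[1]]
  if (length(chars) %% 2L != 0L || !all(grepl("^[A-Za-z]$", chars))) {
    abort_invalid_input("`target` must contain two alleles (letters) per locus.")
  }
  k <- length(chars) / 2L
  if (!is.null(n_loci) && n_loci != k) {
    abort_invalid_input(sprintf("`target` encodes %d loci but `n_loci` = %d.", k, n_loci))
  }
  p <- 1
  for (i in seq_len(k)) {
    al <- chars[c(2 * i - 1, 2 * i)]
    if (tolower(al[1]) != tolower(al[2])) {
      abort_invalid_input(sprintf("Locus %d mixes different genes ('%s%s'); alleles of one locus must share a letter.",
                                  i, al[1], al[2]))
    }
    upper <- al == toupper(al) & al != tolower(al)
    p <- p * if (all(upper) || all(!upper)) 1 / 4 else 1 / 2
  }
  p
}

#' Observed fraction of a count, as a percentage
#'
#' `100 * k / n`, kept at full precision; printing rounds to one decimal
#' (so 7 of 120 displays as 5.8%).
#'
#' @param k number of events (`0 <= k <= n`).
#' @param n total count (`>= 1`).
#' @return numeric percentage of class `observed_pct` (full precision;
#'   one-decimal display).
#' @export
#' @examples
#' observed_fraction(7, 120)
observed_fraction <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || !is.finite(k) || !is.finite(n) ||
      n < 1 || k < 0 || k > n) {
    abort_invalid_input("Require 0 <= k <= n and n >= 1.")
  }
  structure(100 * k / n, class = "observed_pct")
}

#' @export
print.observed_pct <- function(x, ...) {
  cat(sprintf("%.1f%%\n", unclass(x)))
  invisible(x)
}

#' @export
format.observed_pct <- function(x, ...) sprintf("%.1f%%", unclass(x))

#' Filter differentially expressed genes
#'
#' Keeps genes with `FDR <= fdr_max` (inclusive) and `|log2FC| > lfc_min`
#' (strict), the stated definition of a DEG with defaults FDR <= 0.05 and
#' |log2FC| > 0.4. A gene sitting exactly on the fold-change boundary is
#' excluded; one exactly on the FDR boundary is included.
#'
#' @param genes data frame with columns `gene`, `log2FC`, `FDR`.
#' @param fdr_max inclusive FDR ceiling (default 0.05).
#' @param lfc_min exclusive absolute log2 fold-change floor (default 0.4).
#' @return the qualifying subset, as a tibble (its `nrow()` is the DEG
#'   count).
#' @export
filter_degs <- function(genes, fdr_max = 0.05, lfc_min = 0.4) {
  if (!is.data.frame(genes) || !all(c("log2FC", "FDR") %in% names(genes))) {
    abort_invalid_input("`genes` needs columns `log2FC` and `FDR`.")
  }
  if (any(genes$FDR < 0 | genes$FDR > 1, na.rm = TRUE)) {
    abort_invalid_input("FDR values must lie in [0, 1].")
  }
  as_tibble(genes[!is.na(genes$FDR) & !is.na(genes$log2FC) &
                    genes$FDR <= fdr_max & abs(genes$log2FC) > lfc_min, ])
}

#' Decompose two DEG sets into shared and unique genes
#'
#' Exact set arithmetic over gene identifiers: the count in common and
#' the counts unique to each set (so `|A| = common + unique_a`).
#'
#' @param set_a,set_b character vectors of gene identifiers (duplicates
#'   ignored).
#' @return one-row tibble: `common`, `unique_a`, `unique_b`, `n_a`, `n_b`.
#' @export
deg_set_decomposition <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  common <- length(intersect(a, b))
  tibble(common = common,
         unique_a = length(a) - common,
         unique_b = length(b) - common,
         n_a = length(a), n_b = length(b))
}

#' Classify ventricles as normal (NV) or small (SV) against a control
#' reference
#'
#' Operational criterion for the small-ventricle phenotype: a fish is
#' labelled SV when its end-diastolic volume falls below the stated
#' quantile of the control EDV distribution. The threshold and quantile
#' are always reported with the labels.
#'
#' @param edv numeric EDV values (um^3) to classify, or a per-fish
#'   parameter table with an `EDV_um3` column.
#' @param control_edv numeric EDV values of at least 10 control fish.
#' @param quantile control-distribution quantile defining the SV cut
#'   (default 0.05).
#' @return tibble: `EDV_um3`, `label` (`"SV"`/`"NV"`), `threshold_um3`,
#'   `quantile` (plus the input columns when a table was given).
#' @export
classify_ventricle <- function(edv, control_edv, quantile = 0.05) {
  tab <- NULL
  if (is.data.frame(edv)) {
    if (!"EDV_um3" %in% names(edv)) {
      abort_invalid_input("Parameter table needs an `EDV_um3` column.")
    }
    tab <- as_tibble(edv)
    edv <- tab$EDV_um3
  }
  if (length(control_edv) < 10L) {
    abort(sprintf("Control reference has %d fish; at least 10 are required.",
                  length(control_edv)),
          class = "zfcardio_invalid_reference")
  }
  if (quantile <= 0 || quantile >= 1) {
    abort_invalid_parameter("`quantile` must lie strictly between 0 and 1.")
  }
  thr <- unname(stats::quantile(control_edv, quantile, type = 7))
  lab <- ifelse(edv < thr, "SV", "NV")
  out <- tibble(EDV_um3 = edv, label = lab,
                threshold_um3 = thr, quantile = quantile)
  if (!is.null(tab)) {
    out <- dplyr::bind_cols(dplyr::select(tab, -dplyr::any_of("EDV_um3")), out)
  }
  out
}
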