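# Test-selection logic: groups are screened with two normality tests
# (D'Agostino-Pearson omnibus K2 and Shapiro-Wilk); the parametric route is
# taken only if every group passes both at alpha = 0.05.  Paired data are
# never routed to unpaired tests.  Corrections follow the conventions of the
# source workflow: Bonferroni after ANOVA, Dunn after Kruskal-Wallis.

#' D'Agostino-Pearson omnibus normality test
#'
#' K2 statistic combining the skewness and kurtosis z-transforms
#' (D'Agostino, Belanger & D'Agostino 1990); K2 ~ chi-squared(2) under
#' normality.  Requires n >= 8.
#'
#' @param x numeric sample.
#' @return list: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  b1 <- mean((x - m)^3) / s2^1.5          # sample skewness g1
  b2 <- mean((x - m)^4) / s2^2            # sample kurtosis g2 (not excess)
  # skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

.normality_verdict <- function(x, alpha = 0.05) {
  n <- length(x)
  sw <- if (n >= 3 && stats::sd(x) > 0) stats::shapiro.test(x)$p.value else NA_real_
  dp <- if (n >= 8 && stats::sd(x) > 0) dagostino_pearson_test(x)$p_value else NA_real_
  # a test that cannot run does not veto; but if neither runs the group is
  # treated as non-normal (nonparametric by default, flagged upstream)
  ran <- c(shapiro = !is.na(sw), dagostino = !is.na(dp))
  pass <- (!ran["shapiro"] | sw >= alpha) & (!ran["dagostino"] | dp >= alpha)
  list(shapiro_p = sw, dagostino_p = dp, any_ran = any(ran),
       normal = unname(pass) && any(ran))
}

#' Select (and run) the statistical test for a comparison
#'
#' Both normality tests are run per group; the parametric route (Student's
#' t / paired t / one-way ANOVA with Bonferroni-corrected pairwise
#' comparisons) is taken only if all groups pass both at `alpha`.
#' Otherwise: Mann-Whitney U for two unpaired groups, Wilcoxon matched-pairs
#' signed-rank for paired data, Kruskal-Wallis with Dunn's correction for
#' more than two groups.  Groups with fewer than 3 observations force the
#' nonparametric route, flagged.
#'
#' @param samples list of numeric vectors (one per group).
#' @param paired logical; paired two-group design (equal lengths required).
#' @param alpha significance level for the normality screen (default 0.05).
#' @return list of class `stat_plan`: `chosen_test`, `normality`
#'   (per group), `parametric`, `flagged_small_n`, `p_value`, and for k > 2
#'   `pairwise` (matrix of corrected p-values).
#' @export
select_test <- function(samples, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (any(vapply(samples, length, integer(1)) == 0)) stop("empty group")
  k <- length(samples)
  if (paired && (k != 2 || length(samples[[1]]) != length(samples[[2]]))) {
    stop("paired designs need exactly two equal-length groups")
  }
  small_n <- any(vapply(samples, length, integer(1)) < 3)
  verdicts <- lapply(samples, .normality_verdict, alpha = alpha)
  parametric <- !small_n && all(vapply(verdicts, `[[`, logical(1), "normal"))
  out <- list(normality = verdicts, parametric = parametric,
              flagged_small_n = small_n, alpha = alpha, paired = paired)
  if (k == 1) {
    out$chosen_test <- if (parametric) "one_sample_t" else "wilcoxon_signed_rank"
    out$p_value <- if (parametric) stats::t.test(samples[[1]])$p.value
                   else suppressWarnings(stats::wilcox.test(samples[[1]],
                                                            exact = FALSE)$p.value)
  } else if (k == 2 && paired) {
    out$chosen_test <- if (parametric) "paired_t" else "wilcoxon_signed_rank"
    out$p_value <- if (parametric) {
      stats::t.test(samples[[1]], samples[[2]], paired = TRUE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]],
                                          paired = TRUE, exact = FALSE)$p.value)
    }
  } else if (k == 2) {
    out$chosen_test <- if (parametric) "t_test" else "mann_whitney"
    out$p_value <- if (parametric) {
      stats::t.test(samples[[1]], samples[[2]])$p.value
    } else {
      suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]],
                                          exact = FALSE)$p.value)
    }
  } else {
    g <- factor(rep(seq_len(k), vapply(samples, length, integer(1))))
    y <- unlist(samples)
    if (parametric) {
      out$chosen_test <- "anova_bonferroni"
      out$p_value <- stats::anova(stats::lm(y ~ g))$`Pr(>F)`[1]
      out$pairwise <- stats::pairwise.t.test(y, g,
                                             p.adjust.method = "bonferroni")$p.value
    } else {
      out$chosen_test <- "kruskal_wallis_dunn"
      out$p_value <- stats::kruskal.test(y, g)$p.value
      out$pairwise <- dunn_test(y, g)
    }
  }
  class(out) <- "stat_plan"
  out
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction,
#' Bonferroni-adjusted over the number of comparisons (Dunn 1964).
#'
#' @param y response vector.
#' @param g grouping factor.
#' @return matrix of adjusted p-values (lower triangle).
#' @export
dunn_test <- function(y, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  n <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  m <- k * (k - 1) / 2
  out <- matrix(NA_real_, k - 1, k - 1,
                dimnames = list(levels(g)[-1], levels(g)[-k]))
  for (i in 2:k) {
    for (j in 1:(i - 1)) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
      z <- (mr[i] - mr[j]) / se
      out[i - 1, j] <- min(1, 2 * stats::pnorm(-abs(z)) * m)
    }
  }
  out
}
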