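#' Two-sample comparison: Welch's t, Mann-Whitney U, or Kolmogorov-Smirnov
#'
#' All p-values are two-sided.
#'
#' * `welch`: unequal-variance t test with Welch-Satterthwaite degrees of
#'   freedom (via [stats::t.test()]).  If both samples are constant and
#'   equal the contract is `t = 0, p = 1`; both constant but different
#'   gives `t = Inf` (or `-Inf`), `p = 0`.
#' * `mannwhitney`: U computed from midranks.  When
#'   `length(x) + length(y) <= 12` the p-value is exact: from the null U
#'   distribution ([stats::pwilcox()]) without ties, or by full
#'   enumeration of all assignments of the pooled ranks when ties are
#'   present.  Larger samples use the normal approximation with the
#'   tie-corrected variance (no continuity correction).
#' * `ks`: two-sample sup-distance D with the asymptotic p-value
#'   (via [stats::ks.test()]).
#'
#' @param x,y Numeric samples (each `n >= 2`; `n >= 1` accepted for `ks`).
#' @param method One of `"welch"`, `"mannwhitney"`, `"ks"`.
#' @param labels Optional length-2 character vector naming the samples in
#'   the descriptives.
#' @return An object of class `bouton_test`: list with `method`,
#'   `statistic` (named), `df` (where defined), `p_value`, `posthoc`
#'   (`NULL` here), `descriptives` (per-sample n, mean, SEM, 95% CI),
#'   `details`.
#' @export
two_sample_test <- function(x, y, method = c("welch", "mannwhitney", "ks"),
                            labels = c("x", "y")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  min_n <- if (method == "ks") 1L else 2L
  if (length(x) < min_n || length(y) < min_n) {
    stop("each sample needs at least ", min_n, " observations")
  }
  desc <- rbind(cbind(group = labels[1],
                      describe_group(x, allow_n1 = TRUE)),
                cbind(group = labels[2],
                      describe_group(y, allow_n1 = TRUE)))
  res <- switch(method,
                welch = welch_t(x, y),
                mannwhitney = mann_whitney_u(x, y),
                ks = {
                  kt <- suppressWarnings(stats::ks.test(x, y,
                                                        exact = FALSE))
                  list(statistic = c(D = unname(kt$statistic)),
                       df = NA_real_,
                       p_value = unname(kt$p.value),
                       details = list())
                })
  structure(
    list(method = method, statistic = res$statistic, df = res$df,
         p_value = res$p_value, posthoc = NULL, descriptives = desc,
         details = res$details),
    class = "bouton_test"
  )
}

welch_t <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = c(t = 0), df = NA_real_, p_value = 1,
                  details = list(degenerate = "both samples constant")))
    }
    return(list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                df = NA_real_, p_value = 0,
                details = list(degenerate = "both samples constant")))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = c(t = unname(tt$statistic)),
       df = unname(tt$parameter),
       p_value = unname(tt$p.value),
       details = list(mean_difference = unname(diff(rev(tt$estimate)))))
}

mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (n1 + n2 <= 12) {
    if (!ties) {
      p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                          1 - stats::pwilcox(u - 1, n1, n2)))
      exact_type <- "null U distribution"
    } else {
      # full enumeration of choose(n1 + n2, n1) rank assignments
      cmb <- utils::combn(n1 + n2, n1)
      us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
      p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
      exact_type <- "enumeration (ties)"
    }
    return(list(statistic = c(U = u), df = NA_real_, p_value = p,
                details = list(exact = TRUE, exact_type = exact_type)))
  }
  n <- n1 + n2
  tt <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = c(U = u), df = NA_real_,
       p_value = min(1, 2 * stats::pnorm(-abs(z))),
       details = list(exact = FALSE, z = z))
}

#' Multi-group comparison with post hoc pairwise tests
#'
#' Omnibus Kruskal-Wallis (with Dunn's z post hoc, Bonferroni family-wise
#' adjustment) or one-way ANOVA (with Tukey's HSD).  Requires at least 3
#' groups with at least 2 observations each; mismatched method/posthoc
#' combinations (`kruskal` + `tukey`, `anova` + `dunn`) are an error.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param method `"kruskal"` or `"anova"`.
#' @param posthoc `"dunn"` (for `kruskal`) or `"tukey"` (for `anova`).
#' @return A `bouton_test` whose `posthoc` element is a data frame with
#'   columns `comparison`, `statistic`, `p_raw`, `p_adj`.
#' @export
multi_group_test <- function(values, groups,
                             method = c("kruskal", "anova"),
                             posthoc = c("dunn", "tukey")) {
  method <- match.arg(method)
  posthoc <- if (missing(posthoc)) {
    if (method == "kruskal") "dunn" else "tukey"
  } else match.arg(posthoc)
  if ((method == "kruskal") != (posthoc == "dunn")) {
    stop("post hoc '", posthoc, "' does not pair with method '", method,
         "' (use kruskal+dunn or anova+tukey)")
  }
  values <- as.numeric(values)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 3) stop("at least 3 groups are required")
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations")
  }
  desc <- do.call(rbind, lapply(levels(groups), function(g) {
    cbind(group = g, describe_group(values[groups == g]))
  }))
  if (method == "kruskal") {
    kt <- stats::kruskal.test(values, groups)
    ph <- dunn_posthoc(values, groups)
    res <- list(statistic = c(H = unname(kt$statistic)),
                df = unname(kt$parameter),
                p_value = unname(kt$p.value),
                details = list(posthoc = "Dunn z with Bonferroni"))
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    lv <- levels(groups)
    # unadjusted pooled-variance pairwise p for the adjusted >= raw
    # invariant; Tukey's studentized-range p is the family-wise version
    mse <- an["Residuals", "Mean Sq"]
    dfe <- an["Residuals", "Df"]
    pairs <- utils::combn(lv, 2)
    p_raw <- apply(pairs, 2, function(pr) {
      ni <- sum(groups == pr[1]); nj <- sum(groups == pr[2])
      se <- sqrt(mse * (1 / ni + 1 / nj))
      tstat <- (mean(values[groups == pr[2]]) -
                  mean(values[groups == pr[1]])) / se
      2 * stats::pt(-abs(tstat), dfe)
    })
    ph <- data.frame(comparison = rownames(tk),
                     statistic = tk[, "diff"],
                     p_raw = p_raw,
                     p_adj = tk[, "p adj"],
                     row.names = NULL,
                     stringsAsFactors = FALSE)
    res <- list(statistic = c(F = an["groups", "F value"]),
                df = c(an["groups", "Df"], dfe),
                p_value = an["groups", "Pr(>F)"],
                details = list(posthoc = "Tukey HSD"))
  }
  structure(
    list(method = method, statistic = res$statistic, df = res$df,
         p_value = res$p_value, posthoc = ph, descriptives = desc,
         details = res$details),
    class = "bouton_test"
  )
}

# Dunn's post hoc z tests on midranks with tie-corrected variance;
# Bonferroni family-wise adjustment.
dunn_posthoc <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  lv <- levels(groups)
  rbar <- tapply(r, groups, mean)
  sizes <- table(groups)
  tt <- table(values)
  tie_term <- sum(tt^3 - tt) / (12 * (n - 1))
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
             statistic = unname(z),
             p_raw = unname(p_raw),
             p_adj = stats::p.adjust(p_raw, method = "bonferroni"),
             stringsAsFactors = FALSE)
}

#' Descriptive statistics for one sample
#'
#' n, mean, SEM (`sd / sqrt(n)`) and the t-based 95% confidence interval
#' `mean +/- t(0.975, n - 1) * SEM`.  A constant sample has SEM 0 and a
#' degenerate CI at the value.
#'
#' @param x Numeric sample with `n >= 2`.
#' @param allow_n1 Internal: allow a single observation (mean only, `NA`
#'   spread), used when descriptives accompany a KS distance on `n = 1`.
#' @return One-row data frame: `n`, `mean`, `sem`, `ci_lo`, `ci_hi`.
#' @export
describe_group <- function(x, allow_n1 = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) {
    if (allow_n1 && n == 1) {
      return(data.frame(n = 1L, mean = x, sem = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    stop("at least 2 observations are required for descriptives")
  }
  sem <- stats::sd(x) / sqrt(n)
  half <- stats::qt(0.975, n - 1) * sem
  data.frame(n = n, mean = mean(x), sem = sem,
             ci_lo = mean(x) - half, ci_hi = mean(x) + half)
}

#' @export
print.bouton_test <- function(x, ...) {
  cat("bouton_test:", x$method, "\n")
  cat(sprintf("  %s = %.5g", names(x$statistic)[1], x$statistic[1]))
  if (length(x$df) && !all(is.na(x$df))) {
    cat(", df =", paste(signif(x$df, 5), collapse = ", "))
  }
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (", x$details$posthoc, "):\n", sep = "")
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
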