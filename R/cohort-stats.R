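## Cohort-level statistics: transforms, outlier screening, group tests,
## Spearman correlogram, Fisher-z comparison of correlations, rank-based
## partial correlation and Braak stratification.

#' Normality transforms for iron variables
#'
#' Applies the variable-specific transforms used before mean testing:
#' Fe(III) concentrations are log10-transformed and magnetite/maghemite
#' concentrations are transformed as \code{log10(x + 100)} (the offset
#' accommodates true zeros from the SNR discard rule).  All other columns
#' are left untouched.  Correlation analyses use untransformed data.
#'
#' @param table Cohort data.frame with columns \code{fe3} and/or
#'   \code{magnetite}.
#' @param magnetite_offset Offset C of the magnetite transform.
#' @return The table with transformed columns; the applied transforms are
#'   recorded in \code{attr(, "transforms")}.
#' @export
#' @examples
#' apply_transforms(data.frame(fe3 = 10, magnetite = 900))
apply_transforms <- function(table, magnetite_offset = 100) {
  tr <- character(0)
  if ("fe3" %in% names(table)) {
    if (any(table$fe3 <= 0, na.rm = TRUE))
      stop("Fe(III) concentrations must be positive for log10 transform")
    table$fe3 <- log10(table$fe3)
    tr <- c(tr, fe3 = "log10")
  }
  if ("magnetite" %in% names(table)) {
    if (any(table$magnetite < 0, na.rm = TRUE))
      stop("magnetite concentrations must be non-negative")
    table$magnetite <- log10(table$magnetite + magnetite_offset)
    tr <- c(tr, magnetite = sprintf("log10(x + %g)", magnetite_offset))
  }
  attr(table, "transforms") <- tr
  table
}

#' Chi-square dispersion screen for outliers
#'
#' Tests the most extreme observation with the dispersion statistic
#' \code{(x_ext - mean)^2 / var}.  Because the statistic is the maximum
#' over the sample, its p-value is computed from the exact Grubbs
#' (maximum studentized deviation) null distribution via the t relation
#' with Bonferroni correction over the n candidate points, giving a
#' calibrated 5% screen.  A flagged point is removed and the screen
#' re-applied, at most \code{max_iter} times.  Zero-variance samples flag
#' nothing.  Flags are reported, never silently deleted: callers decide.
#'
#' @param values Numeric vector, length at least 4.
#' @param alpha Flagging level.
#' @param max_iter Maximum screening iterations.
#' @return List with \code{kept} (values not flagged), \code{flagged}
#'   (logical, per input value) and \code{p_values} of each iteration.
#' @export
#' @examples
#' screen_outliers(c(1, 2, 3, 100))$flagged
screen_outliers <- function(values, alpha = 0.05, max_iter = 2) {
  n0 <- length(values)
  if (n0 < 4) stop("need at least 4 values")
  flagged <- rep(FALSE, n0)
  ps <- numeric(0)
  for (it in seq_len(max_iter)) {
    idx <- which(!flagged)
    x <- values[idx]
    n <- length(x)
    if (n < 4) break
    v <- stats::var(x)
    if (v == 0) break
    stat <- (x - mean(x))^2 / v          # squared studentized deviation
    ext <- which.max(stat)
    G2 <- stat[ext]
    denom <- (n - 1)^2 - n * G2
    if (denom <= 0) {
      p <- 0
    } else {
      tval <- sqrt(n * (n - 2) * G2 / denom)
      p <- min(1, 2 * n * stats::pt(tval, df = n - 2, lower.tail = FALSE))
    }
    ps <- c(ps, p)
    if (p >= alpha) break
    flagged[idx[ext]] <- TRUE
  }
  list(kept = values[!flagged], flagged = flagged, p_values = ps)
}

#' Brown-Forsythe Levene-type variance test
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#'
#' @param x Numeric values.
#' @param g Group factor (two or more levels).
#' @return List with \code{statistic} (F), \code{df}, \code{p_value}.
#' @export
levene_bf <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  meds <- tapply(x, g, stats::median)
  z <- abs(x - meds[g])
  k <- nlevels(g); n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - zg[g])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Group comparison tests for a cohort table
#'
#' For each iron variable: a Student's t-test on the (transformed) values
#' (pooled variance by default, matching the reported tests; Welch via
#' \code{welch = TRUE}) and the Brown-Forsythe variance test.
#' Demographics: Mann-Whitney U for age and a chi-square test for sex,
#' when those columns are present.  Variables with zero within-group
#' variance return \code{NA} p-values with a warning.
#'
#' @param table Cohort data.frame with a \code{group} column (levels
#'   \code{AD}, \code{control}), iron variables, optionally \code{age} and
#'   \code{sex}.
#' @param variables Iron variable columns to test.
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @param transform Apply [apply_transforms()] before mean tests.
#' @return data.frame with one row per (variable, test): columns
#'   \code{variable}, \code{test}, \code{statistic}, \code{df}, \code{p}.
#' @export
group_tests <- function(table,
                        variables = intersect(c("r2star", "fe3",
                                                "ferrihydrite", "magnetite",
                                                "magnetite_moment", "flr"),
                                              names(table)),
                        welch = FALSE, transform = TRUE) {
  if (!all(table$group %in% c("AD", "control")))
    stop("group must be 'AD' or 'control'")
  g <- factor(table$group, levels = c("AD", "control"))
  if (min(table(g)) < 3) stop("both groups need at least 3 subjects")
  tab_t <- if (transform) apply_transforms(table) else table
  rows <- list()
  add <- function(variable, test, statistic, df, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, test = test, statistic = statistic,
      df = paste(signif(df, 6), collapse = ","), p = p,
      stringsAsFactors = FALSE)
  }
  for (v in variables) {
    x <- tab_t[[v]]
    ok <- !is.na(x)
    vars_by_g <- tapply(x[ok], g[ok], stats::var)
    if (any(vars_by_g == 0, na.rm = TRUE)) {
      warning("zero within-group variance for ", v, "; p reported as NA")
      add(v, if (welch) "welch_t" else "student_t", NA_real_, NA_real_,
          NA_real_)
      add(v, "brown_forsythe", NA_real_, NA_real_, NA_real_)
      next
    }
    tt <- stats::t.test(x[ok] ~ g[ok], var.equal = !welch)
    add(v, if (welch) "welch_t" else "student_t",
        unname(tt$statistic), unname(tt$parameter), tt$p.value)
    lv <- levene_bf(x[ok], g[ok])
    add(v, "brown_forsythe", lv$statistic, lv$df, lv$p_value)
  }
  if ("age" %in% names(table)) {
    wt <- stats::wilcox.test(table$age ~ g, exact = FALSE)
    add("age", "mann_whitney", unname(wt$statistic), NA_real_, wt$p.value)
  }
  if ("sex" %in% names(table)) {
    ct <- suppressWarnings(stats::chisq.test(table(g, table$sex)))
    add("sex", "chi_square", unname(ct$statistic), unname(ct$parameter),
        ct$p.value)
  }
  do.call(rbind, rows)
}

## Spearman p-value: t approximation for n >= 10, full permutation
## enumeration below (no-ties rank statistic); permutation sets are cached
## per n.
.perm_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  pm <- if (n == 1) matrix(1L, 1, 1) else {
    sub <- .all_perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  .perm_cache[[key]] <- pm
  pm
}

.spearman_p <- function(rho, x, y) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n >= 10) {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  perms <- .all_perms(n)
  ry_s <- (ry - mean(ry)) / stats::sd(ry)
  rx_s <- (rx - mean(rx)) / stats::sd(rx)
  rhos <- as.numeric(matrix(rx_s[perms], nrow(perms)) %*% ry_s) / (n - 1)
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

#' Spearman correlogram of a cohort group
#'
#' Pairwise-complete Spearman correlations on untransformed values, with
#' two-sided p-values from the t approximation (exact permutation
#' enumeration below n = 10).  Constant columns yield \code{NA}.
#'
#' @param table Cohort data.frame.
#' @param group Optional group label to subset on (\code{table$group}).
#' @param variables Variable columns (default: the measured iron forms).
#' @return List with symmetric matrices \code{rho} (unit diagonal) and
#'   \code{p}, plus \code{n} (pairwise complete counts).
#' @export
correlogram <- function(table, group = NULL,
                        variables = intersect(c("r2star", "fe3",
                                                "ferrihydrite", "magnetite",
                                                "magnetite_moment", "flr"),
                                              names(table))) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  k <- length(variables)
  rho <- diag(k); p <- matrix(NA_real_, k, k); nmat <- matrix(0L, k, k)
  dimnames(rho) <- dimnames(p) <- dimnames(nmat) <-
    list(variables, variables)
  diag(p) <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    ok <- stats::complete.cases(table[[variables[a]]],
                                table[[variables[b]]])
    x <- table[[variables[a]]][ok]; y <- table[[variables[b]]][ok]
    n <- length(x)
    nmat[a, b] <- nmat[b, a] <- n
    if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      rho[a, b] <- rho[b, a] <- NA_real_
      next
    }
    r <- stats::cor(x, y, method = "spearman")
    rho[a, b] <- rho[b, a] <- r
    p[a, b] <- p[b, a] <- .spearman_p(r, x, y)
  }
  list(rho = rho, p = p, n = nmat)
}

#' Fisher-z comparison of two independent correlations
#'
#' Transforms each coefficient with \code{zr = atanh(rho)} and forms the
#' studentized difference
#' \code{z = (zr2 - zr1) / sqrt(1/(N1 - 3) + 1/(N2 - 3))}, referred to the
#' standard normal for a two-tailed p.
#'
#' @param rho1,n1 First group's coefficient (|rho| < 1) and size (>= 4).
#' @param rho2,n2 Second group's coefficient and size.
#' @return Object of class \code{corr_comparison}: \code{rho1}, \code{n1},
#'   \code{rho2}, \code{n2}, \code{zr1}, \code{zr2}, \code{z_diff},
#'   \code{p_value}.
#' @export
#' @examples
#' compare_correlations(-0.629, 18, -0.908, 11)$p_value  # ~0.076
compare_correlations <- function(rho1, n1, rho2, n2) {
  if (abs(rho1) >= 1 || abs(rho2) >= 1)
    stop("|rho| must be < 1 (Fisher z diverges)")
  if (n1 < 4 || n2 < 4) stop("group sizes must be at least 4")
  zr1 <- atanh(rho1); zr2 <- atanh(rho2)
  z <- (zr2 - zr1) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(rho1 = rho1, n1 = n1, rho2 = rho2, n2 = n2,
                 zr1 = zr1, zr2 = zr2, z_diff = z,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf(
    "Fisher-z comparison: rho1=%.3f (N=%d) vs rho2=%.3f (N=%d)\n",
    x$rho1, x$n1, x$rho2, x$n2))
  cat(sprintf("  z_diff = %.3f, two-tailed p = %.4f\n", x$z_diff,
              x$p_value))
  invisible(x)
}

#' First-order partial correlation
#'
#' Rank-based (Spearman) by default, matching the headline correlations:
#' \code{r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))},
#' with a two-sided p from the t distribution on n - 3 degrees of
#' freedom.  Pearson available via \code{method}.
#'
#' @param table Data.frame (typically the pooled cohort).
#' @param x,y,z Column names: correlation of \code{x} and \code{y}
#'   controlling for \code{z}.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return List with \code{estimate}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{n}.
#' @export
partial_correlation <- function(table, x, y, z,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(table[[x]], table[[y]], table[[z]])
  if (sum(ok) < 5) stop("need at least 5 complete triples")
  d <- table[ok, c(x, y, z)]
  r <- stats::cor(d, method = method)
  rxy <- r[1, 2]; rxz <- r[1, 3]; ryz <- r[2, 3]
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control variable is collinear with x or y")
  est <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  n <- sum(ok)
  df <- n - 3
  tstat <- est * sqrt(df / (1 - est^2))
  list(estimate = est, statistic = tstat, df = df,
       p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), n = n)
}

#' Stratify iron measures by Braak stage
#'
#' Controls with Braak stage 3 or lower are pooled into a single
#' \code{"<=3"} stratum; AD subjects form strata 4, 5 and 6.  Per-stratum
#' means, medians and counts are reported for each variable; empty strata
#' are omitted.  No formal trend test is performed.
#'
#' @param table Cohort data.frame with \code{group} and \code{braak}.
#' @param variables Variables to summarize.
#' @return data.frame with columns \code{stratum}, \code{variable},
#'   \code{n}, \code{mean}, \code{median}.
#' @export
braak_stratify <- function(table,
                           variables = intersect(c("r2star", "fe3",
                                                   "ferrihydrite",
                                                   "magnetite",
                                                   "magnetite_moment",
                                                   "flr"),
                                                 names(table))) {
  b <- table$braak
  if (any(is.na(b)) || any(!(b %in% 0:6)))
    stop("Braak stages must be integers 0-6")
  if (any(table$group == "control" & b > 3))
    stop("controls must have Braak stage 3 or lower")
  if (any(table$group == "AD" & b < 4))
    stop("AD subjects must have Braak stage 4 or higher")
  stratum <- ifelse(table$group == "control", "<=3", as.character(b))
  levels_order <- c("<=3", "4", "5", "6")
  out <- list()
  for (s in levels_order) {
    rows <- stratum == s
    if (!any(rows)) next
    for (v in variables) {
      x <- table[[v]][rows]
      x <- x[!is.na(x)]
      if (!length(x)) next
      out[[length(out) + 1]] <- data.frame(
        stratum = s, variable = v, n = length(x), mean = mean(x),
        median = stats::median(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
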