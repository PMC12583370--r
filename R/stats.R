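# Inference layer: balanced two-way fixed-effects ANOVA, gatekept Tukey HSD
# with studentized-range p-values by numerical integration, pooled-variance
# t-tests, Pearson correlation matrices. Implemented from sums of squares up
# so every piece can be checked against independent oracles.

#' Studentized-range distribution function by numerical integration
#'
#' Computes `P(Q <= q)` for the range of `k` independent standard normals
#' divided by an independent chi estimate with `df` degrees of freedom,
#' by direct quadrature of the classical double integral (inner: range of
#' normals; outer: the scaled-chi density). Quadrature tolerance 1e-8.
#'
#' @param q quantile (>= 0).
#' @param k number of groups (>= 2).
#' @param df residual degrees of freedom (may be `Inf`).
#' @return lower-tail probability.
#' @export
ptukey_sr <- function(q, k, df) {
  stopifnot(length(q) == 1, q >= 0, k >= 2)
  if (q == 0) return(0)
  inner <- function(w) {
    k * integrate(function(z) dnorm(z) * (pnorm(z) - pnorm(z - w))^(k - 1),
                  -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  if (!is.finite(df)) return(inner(q))
  ldc <- (df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2)
  dens <- function(u) exp(ldc + (df - 1) * log(u) - df * u^2 / 2)
  integrate(function(us) vapply(us, function(u) dens(u) * inner(q * u), 0),
            0, Inf, rel.tol = 1e-8, abs.tol = 1e-10)$value
}

#' Balanced two-way fixed-effects ANOVA with interaction
#'
#' Classical sums-of-squares decomposition for a complete, balanced
#' two-factor design: `SS_A + SS_B + SS_AB + SS_resid = SS_total`. F
#' statistics are tested against the residual mean square with exact
#' F-distribution p-values. The analysis unit is expected to be the
#' biological replicate (average fields per replicate first; see
#' [aggregate_replicates()]).
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (coerced), same length as `values`.
#' @param term_names labels for the two factors in the output table.
#' @return `data.frame` of class `anova_table` with columns `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p_value`; attributes carry the cell
#'   means and residual quantities used by [gatekept_posthoc()].
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          term_names = c("A", "B")) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b),
            all(is.finite(values)))
  tab <- table(a, b)
  if (any(tab == 0)) stop("incomplete design: empty cells ",
                          paste(which(tab == 0), collapse = ","))
  if (length(unique(as.vector(tab))) != 1) {
    stop("unbalanced design: aggregate per replicate first ",
         "(cell sizes: ", paste(as.vector(tab), collapse = ","), ")")
  }
  n <- unique(as.vector(tab))
  if (n < 2) stop("need >= 2 observations per cell")
  la <- nlevels(a); lb <- nlevels(b)
  g <- mean(values)
  ma <- tapply(values, a, mean)
  mb <- tapply(values, b, mean)
  mc <- tapply(values, list(a, b), mean)

  ss_a <- n * lb * sum((ma - g)^2)
  ss_b <- n * la * sum((mb - g)^2)
  ss_cells <- n * sum((mc - g)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((values - g)^2)
  ss_res <- ss_tot - ss_cells

  df_a <- la - 1; df_b <- lb - 1; df_ab <- df_a * df_b
  df_res <- length(values) - la * lb
  ms_res <- ss_res / df_res
  fstat <- function(ss, df) if (ms_res > 0) (ss / df) / ms_res else 0
  pval <- function(f, df1) {
    if (ms_res > 0) pf(f, df1, df_res, lower.tail = FALSE) else 1
  }
  f <- c(fstat(ss_a, df_a), fstat(ss_b, df_b), fstat(ss_ab, df_ab))
  out <- data.frame(
    term = c(term_names[1], term_names[2],
             paste(term_names, collapse = ":"), "Residuals"),
    df = c(df_a, df_b, df_ab, df_res),
    sumsq = c(ss_a, ss_b, ss_ab, ss_res),
    meansq = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ms_res),
    statistic = c(f, NA),
    p_value = c(pval(f[1], df_a), pval(f[2], df_b), pval(f[3], df_ab), NA),
    stringsAsFactors = FALSE)
  attr(out, "cell_means") <- mc
  attr(out, "n_per_cell") <- n
  attr(out, "ms_resid") <- ms_res
  attr(out, "df_resid") <- df_res
  attr(out, "factors") <- list(a = a, b = b, values = values,
                               names = term_names)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey honestly-significant-difference comparisons
#'
#' All-pairs comparisons of group means with family-wise adjusted p-values
#' from the studentized-range distribution ([ptukey_sr()]). With `k = 2`
#' groups the adjusted p equals the pooled-variance t-test p. `ms_within`
#' and `df_within` default to the pooled within-group variance of the
#' supplied groups; pass the residual mean square of a factorial model to
#' compare its (marginal or cell) means.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param alpha family-wise significance level.
#' @param ms_within,df_within error variance and its degrees of freedom.
#' @return `data.frame` of class `tukey_result`: `group1`, `group2`,
#'   `diff`, `se`, `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05, ms_within = NULL,
                      df_within = NULL) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  ns <- tapply(values, g, length)
  if (is.null(ms_within)) {
    if (any(ns < 2)) stop("each group needs n >= 2")
    devs <- values - ave(values, g)
    df_within <- length(values) - nlevels(g)
    ms_within <- sum(devs^2) / df_within
  }
  if (ms_within <= 0) stop("degenerate groups: zero within-group variance")
  means <- tapply(values, g, mean)
  k <- nlevels(g)
  prs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    diff = NA_real_, se = NA_real_, q = NA_real_,
                    p_adj = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    g1 <- prs[1, i]; g2 <- prs[2, i]
    d <- means[g2] - means[g1]
    se <- sqrt(ms_within / 2 * (1 / ns[g1] + 1 / ns[g2]))
    q <- abs(d) / se
    p <- 1 - ptukey_sr(q, k, df_within)
    out$diff[i] <- d; out$se[i] <- se; out$q[i] <- q
    out$p_adj[i] <- min(max(p, 0), 1)
    out$significant[i] <- out$p_adj[i] < alpha
  }
  attr(out, "k") <- k
  attr(out, "df_within") <- df_within
  attr(out, "ms_within") <- ms_within
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Gatekept post-hoc comparisons after a two-way ANOVA
#'
#' Implements the decision rule used throughout the analysis: when the
#' interaction is significant at `alpha`, Tukey comparisons are run on the
#' cell means; otherwise, for each significant main effect, Tukey
#' comparisons are run on that factor's marginal means (data collapsed over
#' the other factor). In both cases the error term is the two-way model's
#' residual mean square. With nothing significant an empty set is returned
#' with a note.
#'
#' @param anova_table result of [two_way_anova()].
#' @param alpha gatekeeping and family-wise significance level.
#' @return list of class `mn_posthoc`: `interaction_significant`,
#'   `comparisons` (named list of `tukey_result`), `note`.
#' @export
gatekept_posthoc <- function(anova_table, alpha = 0.05) {
  stopifnot(inherits(anova_table, "anova_table"))
  fx <- attr(anova_table, "factors")
  ms <- attr(anova_table, "ms_resid")
  dfr <- attr(anova_table, "df_resid")
  p <- anova_table$p_value
  names(p) <- anova_table$term
  int_term <- anova_table$term[3]
  comparisons <- list()
  note <- ""
  if (isTRUE(p[[int_term]] < alpha)) {
    cells <- interaction(fx$a, fx$b, sep = "/", drop = TRUE)
    comparisons$cells <- tukey_hsd(fx$values, cells, alpha = alpha,
                                   ms_within = ms, df_within = dfr)
  } else {
    for (i in 1:2) {
      if (isTRUE(p[[anova_table$term[i]]] < alpha)) {
        f <- if (i == 1) fx$a else fx$b
        comparisons[[anova_table$term[i]]] <-
          tukey_hsd(fx$values, f, alpha = alpha, ms_within = ms,
                    df_within = dfr)
      }
    }
    if (length(comparisons) == 0) {
      note <- "no significant ANOVA source; no post-hoc comparisons"
    }
  }
  structure(list(interaction_significant = isTRUE(p[[int_term]] < alpha),
                 comparisons = comparisons, note = note, alpha = alpha),
            class = "mn_posthoc")
}

#' @export
print.mn_posthoc <- function(x, ...) {
  cat("gatekept post-hoc (alpha =", x$alpha, "):",
      if (x$interaction_significant) "interaction significant -> cell means"
      else paste(length(x$comparisons), "main-effect families"), "\n")
  if (nzchar(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Student's t-test (pooled variance, two-sided)
#'
#' Independent two-sample t-test with the classical pooled-variance error
#' term; Welch's unequal-variance form is available by flag.
#'
#' @param group,control numeric vectors, each with n >= 2.
#' @param welch use the Welch-Satterthwaite form instead of pooling.
#' @return list with `t`, `df`, `p_value` and `flag` (non-empty when the
#'   pooled variance is zero).
#' @export
students_t <- function(group, control, welch = FALSE) {
  x <- group; y <- control
  stopifnot(length(x) >= 2, length(y) >= 2)
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  flag <- ""
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) {
      if (mx == my) return(list(t = 0, df = nx + ny - 2, p_value = 1,
                                flag = "zero_variance"))
      return(list(t = sign(mx - my) * Inf, df = nx + ny - 2, p_value = 0,
                  flag = "zero_variance"))
    }
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    if (sp2 == 0) {
      if (mx == my) return(list(t = 0, df = df, p_value = 1,
                                flag = "zero_variance"))
      return(list(t = sign(mx - my) * Inf, df = df, p_value = 0,
                  flag = "zero_variance"))
    }
    t <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df), flag = flag)
}

#' Pearson correlation matrix with significance
#'
#' Product-moment correlations over all numeric variable pairs, using
#' pairwise-complete observations; two-sided p-values from
#' `t = r * sqrt((n-2)/(1-r^2))`. Pairs with fewer than 3 complete
#' observations or a constant variable are flagged and reported as `NA`.
#'
#' @param variable_table `data.frame` of numeric variables.
#' @return list of class `correlation_matrix`: `r`, `p`, `n` matrices and
#'   `flags`.
#' @export
pearson_matrix <- function(variable_table) {
  stopifnot(is.data.frame(variable_table))
  num <- variable_table[vapply(variable_table, is.numeric, TRUE)]
  v <- names(num)
  k <- length(v)
  stopifnot(k >= 2)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(v, v))
  diag(r) <- 1
  flags <- character(0)
  for (i in seq_len(k)) {
    n[i, i] <- sum(is.finite(num[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(num[[i]]) & is.finite(num[[j]])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < 3) { flags <- c(flags, paste0(v[i], "~", v[j], ":n<3")); next }
      x <- num[[i]][ok]; y <- num[[j]][ok]
      sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
      if (sx == 0 || sy == 0) {
        flags <- c(flags, paste0(v[i], "~", v[j], ":constant"))
        next
      }
      rr <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
      rr <- max(min(rr, 1), -1)
      r[i, j] <- r[j, i] <- rr
      if (abs(rr) == 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tt <- rr * sqrt((nn - 2) / (1 - rr^2))
        p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), nn - 2)
      }
    }
  }
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, flags = unique(flags)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (", ncol(x$r), "variables )\n")
  print(round(x$r, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
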