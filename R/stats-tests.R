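#' Pooled-variance unpaired t-test
#'
#' Student's two-sided t-test with pooled variance, df = n1 + n2 - 2 (the
#' convention under which groups of 5 and 10 mice give t(13)). The
#' statistical unit is the mouse: callers average slice values per mouse
#' before testing. Degenerate inputs with zero pooled variance return t = 0,
#' p = 1 when the means are equal, otherwise error.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return object of class `clamap_ttest`: t, df, p, mean_diff, n1, n2.
#' @export
unpaired_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values")
  df <- n1 + n2 - 2
  pooled_var <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (pooled_var == 0) {
    if (mean(x) == mean(y))
      return(structure(list(t = 0, df = as.integer(df), p = 1, mean_diff = 0,
                            n1 = n1, n2 = n2), class = "clamap_ttest"))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(t = unname(tt$statistic), df = as.integer(df),
                 p = tt$p.value, mean_diff = mean(x) - mean(y),
                 n1 = n1, n2 = n2), class = "clamap_ttest")
}

#' @export
print.clamap_ttest <- function(x, ...) {
  cat(sprintf("unpaired t-test (pooled): t(%d) = %.3f, p = %.3g, mean diff = %.3g\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-corrected protected post hoc t-tests
#'
#' Standard one-way F test across k >= 3 groups; pairwise comparisons use the
#' pooled within-group mean square with the within df (classical protected
#' post hoc), with Bonferroni scaling p_adj = min(1, m * p_raw) over the
#' m = k(k-1)/2 comparisons.
#'
#' @param groups named list of numeric samples (each n >= 2). Intended for
#'   k >= 3 groups; k = 2 is allowed and reproduces the pooled t-test
#'   (F = t^2).
#' @return object of class `clamap_anova`: F, df_between, df_within, p, and a
#'   `pairwise` data frame (group_i, group_j, mean_diff, t, p_raw,
#'   p_bonferroni).
#' @export
anova_bonferroni <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 0L)),
                levels = names(groups))
  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1]]
  df_b <- as.integer(tab$Df[1]); df_w <- as.integer(tab$Df[2])
  mse <- tab$`Mean Sq`[2]
  Fstat <- if (mse == 0) {
    if (tab$`Mean Sq`[1] == 0) 0 else
      stop("zero within-group variance with unequal means: F undefined")
  } else tab$`F value`[1]
  p <- if (mse == 0) 1 else tab$`Pr(>F)`[1]
  m <- k * (k - 1) / 2
  cmb <- utils::combn(names(groups), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(c2) {
    gi <- cmb[1, c2]; gj <- cmb[2, c2]
    ni <- length(groups[[gi]]); nj <- length(groups[[gj]])
    diff <- mean(groups[[gi]]) - mean(groups[[gj]])
    if (mse == 0) {
      t <- if (diff == 0) 0 else stop("zero within-group variance")
      p_raw <- 1
    } else {
      t <- diff / sqrt(mse * (1 / ni + 1 / nj))
      p_raw <- 2 * stats::pt(-abs(t), df_w)
    }
    data.frame(group_i = gi, group_j = gj, mean_diff = diff, t = t,
               p_raw = p_raw, p_bonferroni = min(1, m * p_raw))
  }))
  structure(list(F = Fstat, df_between = df_b, df_within = df_w, p = p,
                 pairwise = pairwise), class = "clamap_anova")
}

#' @export
print.clamap_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g; %d Bonferroni pairwise tests\n",
              x$df_between, x$df_within, x$F, x$p, nrow(x$pairwise)))
  invisible(x)
}

#' Significance star labels
#'
#' Strict thresholds: "*" p < 0.05, "**" p < 0.01, "***" p < 0.001,
#' "****" p < 0.0001, otherwise "ns".
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}
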