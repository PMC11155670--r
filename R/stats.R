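#' Hierarchical (two-step) OLS regression with R-squared change
#'
#' Fits the control-variables model (step 1) and the full model adding one
#' focal predictor (step 2) by ordinary least squares on complete cases, and
#' reports the increment: `delta_r2 = R2_full - R2_step1`, its F test
#' `F = (delta_r2 / df1) / ((1 - R2_full) / df2)` with `df1 = 1` added
#' predictor and `df2 = n - p_full - 1` residual df, the standardized
#' coefficient of the focal predictor (all variables z-scored), its t value,
#' Cohen's `f2 = delta_r2 / (1 - R2_full)`, and a Bonferroni decision at
#' `alpha / m`.
#'
#' A focal predictor that is exactly collinear with the controls adds no
#' information: the step is reported with `delta_r2 = 0`, `f_change = 0`,
#' `p_change = 1` and an `NA` standardized coefficient. Rank deficiency
#' among the controls themselves is an error naming the offending columns.
#'
#' @param data data frame holding all variables.
#' @param outcome name of the outcome column.
#' @param controls character vector of control-variable column names.
#' @param predictor name of the focal predictor column.
#' @param m Bonferroni family size (default 3: one test per AM index).
#' @param alpha nominal significance level.
#' @return object of class `hier_reg`: a one-row data frame with `outcome`,
#'   `predictor`, `n`, `r2_step1`, `r2_full`, `delta_r2`, `f_change`, `df1`,
#'   `df2`, `p_change`, `b_std`, `t_value`, `t_df`, `f2`, `p_bonferroni`,
#'   `bonferroni_significant`.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rnorm(60), g = rbinom(60, 1, .5), ab = rnorm(60),
#'                 am = rnorm(60))
#' d$y <- d$y + 0.5 * d$am
#' hierarchical_regression(d, "y", c("g", "ab"), "am")
#' @export
hierarchical_regression <- function(data, outcome, controls, predictor,
                                    m = 3L, alpha = 0.05) {
  vars <- c(outcome, controls, predictor)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("column(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (predictor %in% controls) {
    stop("the focal predictor cannot also be a control variable", call. = FALSE)
  }
  d <- data[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p_full <- length(controls) + 1L
  if (n <= p_full + 2L) {
    stop("too few complete cases (n = ", n, ") for ", p_full,
         " predictors", call. = FALSE)
  }
  const <- vapply(vars, function(v) var(as.numeric(d[[v]])) == 0, logical(1))
  if (any(const)) {
    stop("constant-valued column(s): ", paste(vars[const], collapse = ", "),
         call. = FALSE)
  }

  f1 <- stats::reformulate(controls, response = outcome)
  f2_form <- stats::reformulate(c(controls, predictor), response = outcome)
  fit1 <- lm(f1, data = d)
  if (anyNA(coef(fit1))) {
    bad <- names(coef(fit1))[is.na(coef(fit1))]
    stop("control variables are rank deficient (collinear): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit2 <- lm(f2_form, data = d)
  if (summary(fit2)$sigma == 0 && !anyNA(coef(fit2))) {
    stop("zero residual variance in the full model", call. = FALSE)
  }

  r2_1 <- summary(fit1)$r.squared
  collinear <- is.na(coef(fit2)[predictor])
  df1 <- 1L
  df2 <- n - p_full - 1L
  if (collinear) {
    r2_2 <- r2_1
    delta <- 0; f_change <- 0; p_change <- 1
    b_std <- NA_real_; t_value <- NA_real_
  } else {
    r2_2 <- summary(fit2)$r.squared
    delta <- r2_2 - r2_1
    f_change <- (delta / df1) / ((1 - r2_2) / df2)
    p_change <- pf(f_change, df1, df2, lower.tail = FALSE)
    zd <- as.data.frame(lapply(d, function(x) as.numeric(scale(as.numeric(x)))))
    names(zd) <- names(d)
    fitz <- lm(f2_form, data = zd)
    b_std <- unname(coef(fitz)[predictor])
    t_value <- unname(coef(summary(fit2))[predictor, "t value"])
  }
  f2_eff <- delta / (1 - r2_2)
  p_bonf <- min(1, p_change * m)

  out <- data.frame(outcome = outcome, predictor = predictor, n = n,
                    r2_step1 = r2_1, r2_full = r2_2, delta_r2 = delta,
                    f_change = f_change, df1 = df1, df2 = df2,
                    p_change = p_change, b_std = b_std, t_value = t_value,
                    t_df = df2, f2 = f2_eff, p_bonferroni = p_bonf,
                    bonferroni_significant = p_change < alpha / m,
                    stringsAsFactors = FALSE)
  class(out) <- c("hier_reg", "data.frame")
  out
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf(
    "%s ~ step 2 + %s: dR2 = %.2f, F(%d,%d) = %.2f, p = %.3f, b* = %s, f2 = %.2f%s\n",
    x$outcome, x$predictor, x$delta_r2, x$df1, x$df2, x$f_change, x$p_change,
    ifelse(is.na(x$b_std), "NA", sprintf("%.2f", x$b_std)), x$f2,
    ifelse(x$bonferroni_significant, " *(Bonferroni)", "")))
  invisible(x)
}

#' Pearson correlations between attention indices and trait measures
#'
#' Pairwise-complete Pearson correlations with two-sided p values from the t
#' transform on n - 2 df, plus significance stars at .05 / .01. A
#' zero-variance column yields `NA` cells (flagged), never zero.
#'
#' @param indices data frame (or named columns) of attention indices.
#' @param traits data frame of individual-difference scores.
#' @return list of class `cor_table` with matrices `r`, `p`, `n` and `stars`.
#' @export
correlate_indices <- function(indices, traits) {
  indices <- as.data.frame(indices)
  traits <- as.data.frame(traits)
  stopifnot(nrow(indices) == nrow(traits))
  rn <- names(indices); cn <- names(traits)
  r <- p <- nm <- matrix(NA_real_, length(rn), length(cn),
                         dimnames = list(rn, cn))
  for (i in seq_along(rn)) {
    for (j in seq_along(cn)) {
      x <- as.numeric(indices[[i]]); y <- as.numeric(traits[[j]])
      ok <- complete.cases(x, y)
      nn <- sum(ok)
      nm[i, j] <- nn
      if (nn < 3L) next
      if (var(x[ok]) == 0 || var(y[ok]) == 0) next  # undefined, stays NA
      rij <- cor(x[ok], y[ok])
      r[i, j] <- rij
      tt <- rij * sqrt((nn - 2) / (1 - rij^2))
      p[i, j] <- if (abs(rij) == 1) 0 else 2 * pt(-abs(tt), nn - 2)
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < .01, "**", ifelse(p < .05, "*", "")))
  structure(list(r = r, p = p, n = nm, stars = stars), class = "cor_table")
}

#' @export
print.cor_table <- function(x, digits = 2, ...) {
  fmt <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  fmt[is.na(x$r)] <- "NA"
  print(as.data.frame(fmt), ...)
  cat("* p < .05, ** p < .01 (two-sided)\n")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p value by the family size `m` and caps at 1; the decision
#' compares the adjusted value against `alpha`.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param m family size; must be at least `length(p_values)`.
#' @param alpha significance level for the decisions.
#' @return data frame with `p`, `p_adjusted`, `significant`.
#' @examples
#' bonferroni_adjust(c(.02, .9), m = 3)
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("`m` must be at least the number of p values supplied", call. = FALSE)
  }
  adj <- pmin(1, p_values * m)
  data.frame(p = p_values, p_adjusted = adj, significant = adj < alpha)
}
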