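## Treatment-discrimination statistics: one-way ANOVA, Tukey HSD on the
## studentized range, polynomial growth regressions with R^2, classical
## boxplot summaries and functional boxplots over weekly trajectories.
## The trial design is four treatments (T0-T3) with six replicate plants,
## compared week by week and pooled; confidence level 99% (alpha = 0.01)
## throughout by default.

#' One-way fixed-effects ANOVA
#'
#' Classical F test from the between/within sum-of-squares decomposition.
#' Degenerate inputs where all values are identical give F = 0, p = 1;
#' zero within-group variance with distinct group means gives F = Inf,
#' p = 0.
#'
#' @param values list of numeric vectors, one per group (>= 2 groups,
#'   each >= 2 values).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values) {
  if (!is.list(values) || length(values) < 2L)
    stop_arg("need at least two groups")
  n <- vapply(values, length, integer(1))
  if (any(n < 2L)) stop_arg("each group needs at least two values")
  all_v <- unlist(values, use.names = FALSE)
  if (anyNA(all_v)) stop_arg("NA values not allowed")
  k <- length(values); N <- sum(n)
  gm <- mean(all_v)
  means <- vapply(values, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1,
                                        df_between = df1, df_within = df2))
  if (ssw == 0) return(list(F = Inf, p = 0,
                            df_between = df1, df_within = df2))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Tukey honest significant difference test
#'
#' All pairwise group comparisons with simultaneous confidence intervals
#' from the studentized range distribution and the pooled within-group
#' variance (Tukey-Kramer for unequal group sizes). A pair is significant
#' exactly when its interval excludes zero.
#'
#' @param values named list of numeric vectors, one per group.
#' @param alpha family-wise error rate; default 0.01 (99% confidence).
#' @return object of class `tukey_result`: data.frame `pairs` with columns
#'   `group_a, group_b, mean_diff, interval_low, interval_high, p,
#'   significant`, plus `alpha`.
#' @export
tukey_hsd <- function(values, alpha = 0.01) {
  if (!(alpha > 0 && alpha < 1)) stop_arg("alpha must be in (0, 1)")
  if (is.null(names(values)))
    names(values) <- paste0("g", seq_along(values))
  a <- anova_oneway(values)            # validates input
  n <- vapply(values, length, integer(1))
  k <- length(values); df <- sum(n) - k
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1))) / df
  means <- vapply(values, mean, numeric(1))
  cmb <- utils::combn(k, 2)
  qc <- stats::qtukey(1 - alpha, k, df)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    ia <- cmb[1, i]; ib <- cmb[2, i]
    diff <- means[ia] - means[ib]
    se <- sqrt(mse / 2 * (1 / n[ia] + 1 / n[ib]))
    p <- if (se == 0) as.numeric(diff == 0)
         else stats::ptukey(abs(diff) / se, k, df, lower.tail = FALSE)
    lo <- diff - qc * se; hi <- diff + qc * se
    data.frame(group_a = names(values)[ia], group_b = names(values)[ib],
               mean_diff = diff, interval_low = lo, interval_high = hi,
               p = p, significant = !(lo <= 0 & hi >= 0),
               stringsAsFactors = FALSE)
  })
  structure(list(pairs = do.call(rbind, rows), alpha = alpha,
                 anova = a), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD, alpha = %g (%.0f%% confidence)\n", x$alpha,
              100 * (1 - x$alpha)))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Polynomial growth regression on weekly means
#'
#' Least-squares fit of degree 1 or 2 to per-week treatment means, the
#' usual way camera-derived pixel features are modelled against weeks after
#' transplant. Constant data has SS_tot = 0; R^2 is reported as 0 with a
#' warning in that degenerate case.
#'
#' @param weeks numeric predictor (weeks after transplant).
#' @param means numeric response (per-week means of a feature).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return object of class `growth_fit`: `degree`, `coefficients` (highest
#'   degree first), `r_squared`, `std_errors` (same order) and the `lm` fit.
#' @export
fit_growth_regression <- function(weeks, means, degree = 1L) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop_arg("degree must be 1 or 2")
  if (length(weeks) != length(means)) stop_arg("weeks/means length mismatch")
  if (length(weeks) < degree + 2L)
    stop_arg("need at least degree + 2 points")
  fit <- stats::lm(means ~ stats::poly(weeks, degree, raw = TRUE))
  co <- rev(unname(stats::coef(fit)))          # highest degree first
  ## summary.lm warns on noiseless data ("essentially perfect fit");
  ## expected here, the SEs are simply ~0
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  se <- rev(unname(sm$coefficients[, "Std. Error"]))
  ss_tot <- sum((means - mean(means))^2)
  if (ss_tot == 0) {
    warning("constant response: R^2 reported as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  structure(list(degree = degree, coefficients = co, std_errors = se,
                 r_squared = r2, fit = fit), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  terms <- rev(paste0(c("", "x", "x^2")[seq_len(x$degree + 1)]))
  eq <- paste(sprintf("%.4g%s", x$coefficients, terms), collapse = " + ")
  cat(sprintf("growth fit (degree %d): f(x) = %s,  R^2 = %.3f\n",
              x$degree, eq, x$r_squared))
  invisible(x)
}

#' Evaluate a growth fit
#' @param object a `growth_fit`.
#' @param newdata numeric vector of weeks.
#' @param ... ignored.
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  co <- rev(object$coefficients)       # constant first
  vapply(newdata, function(x) sum(co * x^(seq_along(co) - 1L)), numeric(1))
}

#' Classical boxplot summary
#'
#' Quartiles by linear interpolation of order statistics (type 7);
#' whiskers at the most extreme observations within 1.5 IQR of the
#' quartiles; everything beyond is an outlier.
#'
#' @param values numeric vector (>= 1 value).
#' @return list with `quartiles` (Q1, median, Q3), `whiskers` (low, high),
#'   `outliers`.
#' @export
summarize_boxplot <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_arg("no values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(quartiles = c(Q1 = q[1], median = q[2], Q3 = q[3]),
       whiskers = c(low = min(values[in_fence]), high = max(values[in_fence])),
       outliers = sort(values[!in_fence]))
}

#' Modified band depth of a sample of curves
#'
#' For each curve, the proportion of time points at which it lies inside
#' the band of a pair of sample curves, averaged over all unordered pairs
#' (pairs containing the curve itself included). Deeper = more central.
#'
#' @param curves numeric matrix, rows = curves, columns = time points.
#' @return numeric vector of depths, one per row.
#' @export
band_depth <- function(curves) {
  if (!is.matrix(curves) || nrow(curves) < 2L)
    stop_arg("curves must be a matrix with >= 2 rows")
  n <- nrow(curves)
  pairs <- utils::combn(n, 2)
  depth <- numeric(n)
  for (i in seq_len(ncol(pairs))) {
    lo <- pmin(curves[pairs[1, i], ], curves[pairs[2, i], ])
    hi <- pmax(curves[pairs[1, i], ], curves[pairs[2, i], ])
    inside <- sweep(curves, 2, lo, ">=") & sweep(curves, 2, hi, "<=")
    depth <- depth + rowMeans(inside)
  }
  depth / ncol(pairs)
}

#' Functional boxplot of weekly trajectories
#'
#' Curves are ranked by modified band depth. The deepest curve is the
#' central curve; the pointwise envelope of the deepest half is the central
#' 50% band. Curves escaping the central band inflated by `inflation`
#' times its height at any week are outliers and are excluded before the
#' outer envelope (nominal coverage `level`) is formed from the remaining
#' curves.
#'
#' @param trajectories numeric matrix, rows = plants (rownames = plant
#'   ids), columns = weeks (colnames = week numbers); no missing values
#'   (incomplete trajectories are an error, not imputed).
#' @param level nominal coverage of the outer envelope, default 0.95.
#' @param inflation fence inflation factor, default 1.5.
#' @param depth `"mbd"` (modified band depth, default) or `"pointwise"`
#'   (rank of absolute deviation from the pointwise median; simpler
#'   alternative).
#' @return object of class `functional_boxplot`: `weeks`, `central_curve`,
#'   `central_lower`/`central_upper` (50% band), `envelope_lower`/
#'   `envelope_upper`, `outliers` (plant ids), `depths`.
#' @export
functional_boxplot <- function(trajectories, level = 0.95, inflation = 1.5,
                               depth = c("mbd", "pointwise")) {
  depth <- match.arg(depth)
  m <- as.matrix(trajectories)
  if (nrow(m) < 3L) stop_arg("need at least 3 complete trajectories")
  if (anyNA(m)) stop_arg("incomplete trajectories are not allowed")
  if (is.null(rownames(m))) rownames(m) <- paste0("plant", seq_len(nrow(m)))
  weeks <- if (is.null(colnames(m))) seq_len(ncol(m)) - 1L
           else as.numeric(colnames(m))
  d <- if (depth == "mbd") band_depth(m) else {
    med <- apply(m, 2, stats::median)
    -rowMeans(abs(sweep(m, 2, med)))
  }
  ord <- order(d, decreasing = TRUE)
  central_n <- ceiling(nrow(m) / 2)
  central <- m[ord[seq_len(central_n)], , drop = FALSE]
  c_lo <- apply(central, 2, min); c_hi <- apply(central, 2, max)
  h <- c_hi - c_lo
  fence_lo <- c_lo - inflation * h; fence_hi <- c_hi + inflation * h
  is_out <- apply(m, 1, function(v) any(v < fence_lo | v > fence_hi))
  keep <- m[!is_out, , drop = FALSE]
  structure(list(
    weeks = weeks,
    central_curve = m[ord[1], ],
    central_lower = c_lo, central_upper = c_hi,
    envelope_lower = apply(keep, 2, min),
    envelope_upper = apply(keep, 2, max),
    outliers = rownames(m)[is_out],
    depths = stats::setNames(d, rownames(m)),
    level = level
  ), class = "functional_boxplot")
}

#' @export
print.functional_boxplot <- function(x, ...) {
  cat(sprintf("functional boxplot over weeks %s; %d outlier(s)%s\n",
              paste(range(x$weeks), collapse = "-"), length(x$outliers),
              if (length(x$outliers))
                paste0(": ", paste(x$outliers, collapse = ", ")) else ""))
  invisible(x)
}

#' @export
plot.functional_boxplot <- function(x, main = "Functional boxplot",
                                    ylab = "value", ...) {
  graphics::plot(range(x$weeks), range(x$envelope_lower, x$envelope_upper),
                 type = "n", xlab = "week", ylab = ylab, main = main, ...)
  graphics::polygon(c(x$weeks, rev(x$weeks)),
                    c(x$envelope_lower, rev(x$envelope_upper)),
                    col = "grey90", border = "grey60")
  graphics::polygon(c(x$weeks, rev(x$weeks)),
                    c(x$central_lower, rev(x$central_upper)),
                    col = "grey70", border = "grey40")
  graphics::lines(x$weeks, x$central_curve, lwd = 2)
  invisible(x)
}

#' Per-week treatment comparison over a trial table
#'
#' Runs [anova_oneway()] and [tukey_hsd()] for one variable at each week of
#' a long-format trial table.
#'
#' @param table trial table data.frame (`plant_id, treatment, week,
#'   variable, value`).
#' @param variable variable name to test.
#' @param alpha significance level, default 0.01.
#' @return data.frame with one row per (week, pair) holding the Tukey
#'   comparison and the week's ANOVA F and p.
#' @export
weekly_comparisons <- function(table, variable, alpha = 0.01) {
  sub <- table[table$variable == variable & !is.na(table$value), ]
  if (!nrow(sub)) stop_arg("no data for variable ", variable)
  out <- lapply(sort(unique(sub$week)), function(w) {
    sw <- sub[sub$week == w, ]
    groups <- split(sw$value, sw$treatment)
    groups <- groups[vapply(groups, length, integer(1)) >= 2L]
    if (length(groups) < 2L) return(NULL)
    a <- anova_oneway(groups)
    tk <- tukey_hsd(groups, alpha)
    cbind(week = w, variable = variable, tk$pairs,
          anova_F = a$F, anova_p = a$p)
  })
  do.call(rbind, out)
}
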