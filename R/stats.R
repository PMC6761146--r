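#' Fit the Hill equation to a titration table
#'
#' Least-squares fit of `y = y_max * ca^n / (k_half^n + ca^n)` to a
#' statistic-versus-Ca2+ table, weighted by 1/SEM^2 when SEMs are available
#' and unweighted otherwise. `k_half` and `n` are optimized in log space
#' (positivity without constraints; the model is a logistic in log
#' concentration), with up to `max_restarts` jittered restarts of the
#' Levenberg-Marquardt optimizer. `ca = 0` rows are excluded (the model
#' forces y = 0 there). The reported SE of the Hill coefficient comes from
#' the fit covariance via the delta method; R^2 is computed on weighted
#' residuals. A failed fit is reported with `converged = FALSE`, never with
#' a fabricated estimate.
#'
#' @param table data.frame with columns `ca_mm`, `value`, and optionally
#'   `sem` (> 0) and `n`; needs >= 4 distinct positive concentrations.
#' @param fix_n fix the Hill coefficient at this value instead of fitting it
#'   (e.g. `fix_n = 1` for a rectangular hyperbola).
#' @param max_restarts restarts with jittered starting values.
#' @return an object of class `hill_fit`: `y_max`, `k_half`, `n_hill`,
#'   `se_n`, `se_k`, `r2`, `converged`, `n_points`, `weighted`.
#' @export
hill_fit <- function(table, fix_n = NULL, max_restarts = 20) {
  stopifnot(is.data.frame(table), all(c("ca_mm", "value") %in% names(table)))
  tb <- table[is.finite(table$ca_mm) & table$ca_mm > 0 &
                is.finite(table$value), , drop = FALSE]
  if (length(unique(tb$ca_mm)) < 4) {
    stop("parameter error: Hill fit needs >= 4 distinct positive Ca2+ values")
  }
  weighted <- "sem" %in% names(tb) && all(is.finite(tb$sem)) && all(tb$sem > 0)
  w <- if (weighted) 1 / tb$sem^2 else rep(1, nrow(tb))
  x <- tb$ca_mm; y <- tb$value
  # starts: y_max from the data top, k_half by interpolating to half-max
  ymax0 <- max(y)
  ord <- order(x)
  k0 <- tryCatch(stats::approx(y[ord], x[ord], xout = ymax0 / 2,
                               ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(x)
  fit <- NULL
  for (r in 0:max_restarts) {
    st <- if (r == 0) c(1, 1, 1) else with_seed(1000 + r, exp(stats::rnorm(3, 0, 0.5)))
    start <- list(ymax = ymax0 * st[1], lk = log(k0 * st[2]))
    if (is.null(fix_n)) start$ln <- log(1 * st[3])
    form <- if (is.null(fix_n)) {
      value ~ ymax / (1 + exp(exp(ln) * (lk - log(ca_mm))))
    } else {
      value ~ ymax / (1 + exp(fix_n * (lk - log(ca_mm))))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(ca_mm = x, value = y),
                        start = start, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(y_max = NA_real_, k_half = NA_real_,
                          n_hill = NA_real_, se_n = NA_real_,
                          se_k = NA_real_, r2 = NA_real_, converged = FALSE,
                          n_points = nrow(tb), weighted = weighted),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  k_half <- exp(cf[["lk"]])
  n_hill <- if (is.null(fix_n)) exp(cf[["ln"]]) else fix_n
  se_n <- se_k <- NA_real_
  if (!is.null(vc)) {
    se_k <- k_half * sqrt(vc["lk", "lk"])
    if (is.null(fix_n)) se_n <- n_hill * sqrt(vc["ln", "ln"])
  }
  res <- y - stats::fitted(fit)
  ybar <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else NA_real_
  structure(list(y_max = cf[["ymax"]], k_half = k_half, n_hill = n_hill,
                 se_n = se_n, se_k = se_k, r2 = r2, converged = TRUE,
                 n_points = nrow(tb), weighted = weighted),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "hill_fit: y_max %.4g, k_half %.4g mM, n %.3g +/- %.2g, R^2 %.4g (%s, %d pts%s)\n",
    x$y_max, x$k_half, x$n_hill, x$se_n, x$r2,
    if (x$converged) "converged" else "NOT converged", x$n_points,
    if (x$weighted) ", SEM-weighted" else ""))
  invisible(x)
}

#' Linear current-voltage fit with constant-offset correction
#'
#' Ordinary least squares of current on voltage. With
#' `gradient_offset = "auto"` the fitted intercept is the offset (e.g. the
#' constant shift imposed by an ionic gradient); with a numeric
#' `gradient_offset` that constant is subtracted from the currents before
#' fitting. The slope conductance is `1000 * slope` (pA/mV -> pS).
#'
#' @param points data.frame with columns `v_mv` and `i_pa` (>= 3 distinct
#'   voltages).
#' @param gradient_offset "auto" or a constant offset (pA).
#' @return an object of class `iv_fit`: `slope_conductance_ps`, `offset_pa`,
#'   `r2`, and `points` with an `i_corrected_pa` column.
#' @export
iv_fit <- function(points, gradient_offset = "auto") {
  stopifnot(is.data.frame(points), all(c("v_mv", "i_pa") %in% names(points)))
  if (length(unique(points$v_mv)) < 3) {
    stop("rank error: need >= 3 distinct voltages")
  }
  auto <- identical(gradient_offset, "auto")
  i <- points$i_pa
  if (!auto) i <- i - gradient_offset
  fit <- stats::lm(i ~ v, data = data.frame(v = points$v_mv, i = i))
  cf <- stats::coef(fit)
  offset <- if (auto) unname(cf[1]) else gradient_offset
  # summary.lm warns on numerically perfect fits; exact linear inputs are a
  # legitimate use here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  out <- points
  out$i_corrected_pa <- points$i_pa - offset
  structure(list(slope_conductance_ps = 1000 * unname(cf[2]),
                 offset_pa = offset, r2 = r2, points = out),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("iv_fit: slope %.4g pS, offset %.4g pA, R^2 %s\n",
              x$slope_conductance_ps, x$offset_pa, format(x$r2)))
  invisible(x)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U is computed by rank summation with midranks for ties. The two-sided p
#' value is exact -- full enumeration of all arrangements of group labels --
#' when `n1 + n2 <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used. The
#' `method` field reports which route was taken.
#'
#' @param a,b numeric samples (each non-empty).
#' @return an object of class `mw_result`: `u_statistic`, `p_two_sided`,
#'   `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("parameter error: empty group")
  if (any(!is.finite(c(a, b)))) stop("parameter error: non-finite values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && N <= 12) {
    combs <- utils::combn(N, n1)
    us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u1), mean(us >= u1))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sd_u <- sqrt(n1 * n2 / 12 * ((N + 1) - corr))
    if (sd_u == 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - mu) - 0.5) / sd_u
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal-approx"
  }
  structure(list(u_statistic = u1, p_two_sided = p, n1 = n1, n2 = n2,
                 method = method),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("mann_whitney: U = %g, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$u_statistic, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' Pairwise Mann-Whitney comparison of condition groups
#'
#' Compares PSA and Po between every pair of condition groups in a metrics
#' table. No multiplicity adjustment is applied (the output carries an
#' explicit "unadjusted" flag so downstream users are not misled).
#'
#' @param metrics a data.frame of stacked [analyze_trace()] rows.
#' @param grouping name of the metrics column that defines groups (e.g.
#'   `"ca_mm"`), or the name `"condition"` to use the combined
#'   Ca/Bz-423/PhAsO/inhibitor label.
#' @param statistics metric columns to compare.
#' @return data.frame with one row per group pair and statistic: `group_a`,
#'   `group_b`, `statistic`, `u`, `p`, `n1`, `n2`, `method`, `adjusted`.
#' @export
compare_conditions <- function(metrics, grouping = "condition",
                               statistics = c("psa_pa2", "po")) {
  stopifnot(is.data.frame(metrics))
  if (grouping == "condition") {
    lab <- sprintf("Ca%g/Bz%g/PhAsO%g/%s", metrics$ca_mm, metrics$bz423_mm,
                   metrics$phaso_mm, metrics$inhibitor)
  } else {
    if (!grouping %in% names(metrics)) {
      stop("parameter error: unknown grouping field '", grouping, "'")
    }
    lab <- as.character(metrics[[grouping]])
  }
  groups <- unique(lab)
  if (length(groups) < 2) stop("parameter error: need >= 2 groups")
  out <- list()
  for (stat in statistics) {
    if (!stat %in% names(metrics)) next
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        va <- metrics[[stat]][lab == groups[i]]
        vb <- metrics[[stat]][lab == groups[j]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (!length(va) || !length(vb)) next
        mw <- mann_whitney(va, vb)
        out[[length(out) + 1L]] <-
          data.frame(group_a = groups[i], group_b = groups[j],
                     statistic = stat, u = mw$u_statistic,
                     p = mw$p_two_sided, n1 = mw$n1, n2 = mw$n2,
                     method = mw$method, adjusted = "none")
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate per-trace metrics into a titration table
#'
#' Mean, SEM and replicate count of one statistic per Ca2+ concentration --
#' the input shape [hill_fit()] expects.
#'
#' @param metrics stacked [analyze_trace()] rows.
#' @param statistic metric column to aggregate.
#' @return data.frame `ca_mm`, `value`, `sem`, `n`.
#' @export
titration_table <- function(metrics, statistic = "psa_pa2") {
  stopifnot(statistic %in% names(metrics))
  sp <- split(metrics[[statistic]], metrics$ca_mm)
  ca <- as.numeric(names(sp))
  val <- vapply(sp, function(v) mean(v[is.finite(v)]), numeric(1))
  n <- vapply(sp, function(v) sum(is.finite(v)), numeric(1))
  sem <- vapply(sp, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  out <- data.frame(ca_mm = ca, value = val, sem = sem, n = n)
  out <- out[order(out$ca_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
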