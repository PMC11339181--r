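#' Enumerate the simulation study design
#'
#' Builds the run plan: the cartesian product of the deployment scenarios and
#' the geometries (one posttreatment run per pair), plus one pretreatment run
#' per geometry.
#'
#' @param scenarios an [hr_scenarios] data frame.
#' @param geometry_ids character vector of geometry identifiers.
#' @return a `data.frame` with columns `geometry_id`, `scenario_id` (`NA` for
#'   pretreatment rows), `device`, `wire_count`, `deployment`, `l_c`, `q_c`.
#' @examples
#' plan <- enumerate_runs(hr_scenarios(), paste0("G", 1:5))
#' table(is.na(plan$scenario_id))  # 5 pretreatment, 80 posttreatment
#' @export
enumerate_runs <- function(scenarios, geometry_ids) {
  stopifnot(is.data.frame(scenarios))
  if (nrow(scenarios) == 0) stop("empty scenario table")
  if (anyDuplicated(scenarios$scenario_id)) stop("duplicate scenario ids")
  geometry_ids <- as.character(geometry_ids)
  if (length(geometry_ids) == 0) {
    return(data.frame(geometry_id = character(0), scenario_id = integer(0),
                      device = character(0), wire_count = integer(0),
                      deployment = character(0), l_c = numeric(0), q_c = numeric(0)))
  }
  pre <- data.frame(geometry_id = geometry_ids, scenario_id = NA_integer_,
                    device = NA_character_, wire_count = NA_integer_,
                    deployment = "pretreatment", l_c = 0, q_c = 0)
  sc <- scenarios[, c("scenario_id", "device", "wire_count", "deployment",
                      "l_c", "q_c")]
  post <- cbind(geometry_id = rep(geometry_ids, each = nrow(sc)),
                sc[rep(seq_len(nrow(sc)), times = length(geometry_ids)), ])
  post <- post[order(post$geometry_id, post$scenario_id), ]
  out <- rbind(pre, post)
  rownames(out) <- NULL
  out
}

#' Fit the power-law AMVR versus linear-resistance relationship
#'
#' Ordinary least squares of `log(AMVR) ~ log(l_c)`, i.e. the model
#' `AMVR = a * l_c^b`. The coefficient of determination is reported in log
#' space. Points with non-positive AMVR carry no information for the
#' log-space model and are excluded with a warning.
#'
#' @param l_c linear resistance coefficients (positive).
#' @param amvr aneurysmal mean velocity reductions (fractions, positive).
#' @param refine if `TRUE`, refine `(a, b)` by nonlinear least squares in
#'   linear space (Gauss-Newton via [stats::nls]); R-squared stays log-space.
#' @return object of class `power_law_fit` with elements `a`, `b`,
#'   `r_squared`, `n`, `lc_range`.
#' @examples
#' lc <- c(5, 20, 60, 140, 180)
#' fit_power_law(lc, 0.1 * lc^0.3)
#' @export
fit_power_law <- function(l_c, amvr, refine = FALSE) {
  if (length(l_c) != length(amvr)) stop("l_c and amvr must have equal length")
  if (any(l_c <= 0)) stop("all l_c must be positive")
  bad <- amvr <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with AMVR <= 0 excluded from the power-law fit")
    l_c <- l_c[!bad]; amvr <- amvr[!bad]
  }
  if (length(l_c) < 3) stop("at least 3 usable points are required")
  lx <- log(l_c); ly <- log(amvr)
  fit <- lm(ly ~ lx)
  a <- exp(unname(coef(fit)[1])); b <- unname(coef(fit)[2])
  ss_res <- sum(residuals(fit)^2); ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  if (refine) {
    nl <- try(stats::nls(amvr ~ a * l_c^b, start = list(a = a, b = b)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      a <- coef(nl)[["a"]]; b <- coef(nl)[["b"]]
    }
  }
  structure(list(a = a, b = b, r_squared = r2, n = length(l_c),
                 lc_range = range(l_c)), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> AMVR = %.4g * l_c^%.4g  (R2 = %.3f, n = %d, l_c in [%.3g, %.3g])\n",
              x$a, x$b, x$r_squared, x$n, x$lc_range[1], x$lc_range[2]))
  invisible(x)
}

#' Welch's two-sided t-test from group summaries
#'
#' Unequal-variance (Welch) two-sample t-test computed from summary
#' statistics, with Welch-Satterthwaite degrees of freedom. Useful for
#' checking published group means/SDs without per-run values.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df`, `p_value` (two-sided).
#' @examples
#' welch_from_summaries(51.9, 11.8, 20, 60.3, 9.5, 15)$p_value
#' @export
welch_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

#' Group statistics of a study result table
#'
#' Summarizes AMVR (in percent) per device x deployment group, tests the two
#' device types against each other within each deployment class with Welch's
#' two-sided t-test, and reports the nominal-to-oversized mean difference and
#' relative decrease per device.
#'
#' @param results a study result `data.frame` with columns `device`,
#'   `deployment` and `amvr` (fraction); pretreatment rows
#'   (`deployment == "pretreatment"`) are ignored.
#' @return object of class `group_stats`: `groups` (per-group n/mean/sd in
#'   percent), `tests` (per deployment class: Welch t, df, p), `device_effects`
#'   (per device: nominal and oversized means, difference in percentage
#'   points, relative decrease).
#' @export
group_stats <- function(results) {
  stopifnot(is.data.frame(results), all(c("device", "deployment", "amvr") %in% names(results)))
  x <- results[results$deployment %in% c("nominal", "oversized"), ]
  if (nrow(x) == 0) stop("no posttreatment rows")
  x$amvr_pct <- 100 * x$amvr
  groups <- aggregate(amvr_pct ~ device + deployment, x,
                      function(v) c(n = length(v), mean = mean(v), sd = sd(v)))
  groups <- cbind(groups[, 1:2], as.data.frame(groups$amvr_pct))
  tests <- list()
  for (dep in unique(x$deployment)) {
    sub <- x[x$deployment == dep, ]
    devs <- sort(unique(sub$device))
    if (length(devs) != 2) next
    g1 <- sub$amvr_pct[sub$device == devs[1]]
    g2 <- sub$amvr_pct[sub$device == devs[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      warning("group with n < 2 excluded from testing (", dep, ")")
      next
    }
    w <- welch_from_summaries(mean(g1), sd(g1), length(g1),
                              mean(g2), sd(g2), length(g2))
    tests[[dep]] <- c(list(devices = devs), w)
  }
  effects <- list()
  for (dev in unique(x$device)) {
    mn <- mean(x$amvr_pct[x$device == dev & x$deployment == "nominal"])
    mo <- mean(x$amvr_pct[x$device == dev & x$deployment == "oversized"])
    effects[[dev]] <- list(nominal = mn, oversized = mo, diff_pp = mn - mo,
                           relative_decrease = (mn - mo) / mn)
  }
  structure(list(groups = groups, tests = tests, device_effects = effects),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats>\n")
  print(x$groups)
  for (dep in names(x$tests)) {
    tst <- x$tests[[dep]]
    cat(sprintf("  %s: %s vs %s  Welch t = %.3f, df = %.1f, p = %.4f\n",
                dep, tst$devices[1], tst$devices[2], tst$t, tst$df, tst$p_value))
  }
  for (dev in names(x$device_effects)) {
    ef <- x$device_effects[[dev]]
    cat(sprintf("  %s: nominal %.1f%% -> oversized %.1f%% (rel. decrease %.0f%%)\n",
                dev, ef$nominal, ef$oversized, 100 * ef$relative_decrease))
  }
  invisible(x)
}

#' Classify runs against the AMVR surrogate endpoint
#'
#' Marks each posttreatment run as pass/fail against a velocity-reduction
#' threshold (default 35% AMVR, the published surrogate for angiographic
#' occlusion) and reports pass fractions per device x deployment group.
#' The comparison is inclusive: `AMVR >= threshold` passes.
#'
#' @param results study result `data.frame` (see [group_stats()]).
#' @param threshold AMVR pass threshold as a fraction, default `0.35`.
#' @return list with `runs` (the input plus a logical `pass`) and `group_rates`
#'   (pass fraction per device x deployment).
#' @export
threshold_classification <- function(results, threshold = 0.35) {
  stopifnot(is.data.frame(results), "amvr" %in% names(results))
  x <- results[results$deployment %in% c("nominal", "oversized"), ]
  x$pass <- x$amvr >= threshold
  rates <- aggregate(pass ~ device + deployment, x, mean)
  list(runs = x, group_rates = rates)
}
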