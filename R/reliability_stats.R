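# Reliability statistics for repeated DBHF measurements: intraclass
# correlation (two-way random effects, absolute agreement, single measure,
# i.e. ICC(2,1) in Shrout-Fleiss notation) and two-way ANOVA for
# gender x side comparisons.

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` where MSR, MSC and
#' MSE are the rows (subjects), columns (raters/repetitions) and error mean
#' squares of the two-way layout. The confidence interval uses the
#' F-distribution bounds with Satterthwaite degrees of freedom.
#'
#' @param table n x k numeric matrix or data frame: one row per subject, one
#'   column per rater (inter-observer) or repetition (intra-observer). No
#'   missing cells.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model` tag, the mean squares (`msr`, `msc`, `mse`), and the design
#'   size (`n`, `k`).
#' @export
icc <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (!is.numeric(x) || anyNA(x))
    fna_stop("fna_bad_table", "measurement table must be numeric and complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    fna_stop("fna_bad_table", "need >= 2 subjects and >= 2 columns")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot < 1e-12)
    fna_stop("fna_undefined_icc", "zero total variance; ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI for ICC(A,1) (McGraw & Wong), Satterthwaite df for the
  # denominator composite
  alpha <- 1 - conf_level
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (!is.finite(lower)) lower <- est
  if (!is.finite(upper)) upper <- est
  structure(list(icc = est, ci_low = min(lower, est), ci_high = max(upper, est),
                 conf_level = conf_level,
                 model = "two-way random, absolute agreement, single measure (ICC(2,1))",
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (%d%% CI %.3f-%.3f)\n", x$icc, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  cat(sprintf("  %s; n = %d subjects, k = %d measurements\n", x$model, x$n, x$k))
  cat(sprintf("  MSR %.4g  MSC %.4g  MSE %.4g\n", x$msr, x$msc, x$mse))
  invisible(x)
}

#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Compares a response (DBHF, mm) across two crossed factors such as gender
#' and side. Unbalanced designs are handled with Type II sums of squares
#' (via [car::Anova()] on a [stats::lm()] fit); for balanced designs these
#' coincide with the classical decomposition.
#'
#' @param table data frame with columns `value` (numeric) plus two factor
#'   columns named by `factors`.
#' @param factors character length-2: the two factor column names. Default
#'   `c("gender", "side")`.
#' @param alpha significance level reported alongside (default 0.05).
#' @return An object of class `anova2_result`: data frame `terms` with one
#'   row per term (factor A, factor B, interaction, residuals) carrying
#'   `ss`, `df`, `ms`, `F`, `p`, plus `ss_total` and `alpha`.
#' @export
two_way_anova <- function(table, factors = c("gender", "side"), alpha = 0.05) {
  if (!is.data.frame(table) || !all(c("value", factors) %in% names(table)))
    fna_stop("fna_bad_table", "table needs columns value, %s, %s",
             factors[1], factors[2])
  df <- data.frame(value = as.numeric(table$value),
                   a = factor(table[[factors[1]]]),
                   b = factor(table[[factors[2]]]))
  if (nlevels(df$a) < 2L || nlevels(df$b) < 2L)
    fna_stop("fna_bad_table", "both factors need >= 2 levels")
  if (any(table(df$a, df$b) == 0L))
    fna_stop("fna_bad_design",
             "empty factor cell; interaction not estimable")
  fit <- stats::lm(value ~ a * b, data = df)
  aov2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  term_names <- c(factors[1], factors[2],
                  paste(factors[1], factors[2], sep = ":"), "residuals")
  if (!is.null(aov2)) {
    idx <- c("a", "b", "a:b", "Residuals")
    terms <- data.frame(term = term_names,
                        ss = aov2[idx, "Sum Sq"], df = aov2[idx, "Df"],
                        F = aov2[idx, "F value"], p = aov2[idx, "Pr(>F)"],
                        row.names = NULL)
  } else {
    # zero-residual designs (noise-free constructed effects): Type II SS by
    # model comparison, with F reported as Inf/0 and p as 0/1
    rss <- function(form) sum(stats::residuals(stats::lm(form, data = df))^2)
    r_ab <- rss(value ~ a + b)
    ss <- c(rss(value ~ b) - r_ab, rss(value ~ a) - r_ab,
            r_ab - rss(value ~ a * b), rss(value ~ a * b))
    ss <- pmax(ss, 0)
    dfs <- c(nlevels(df$a) - 1L, nlevels(df$b) - 1L,
             (nlevels(df$a) - 1L) * (nlevels(df$b) - 1L),
             nrow(df) - nlevels(df$a) * nlevels(df$b))
    terms <- data.frame(term = term_names, ss = ss, df = dfs,
                        F = c(ifelse(ss[1:3] > 1e-12, Inf, 0), NA),
                        p = c(ifelse(ss[1:3] > 1e-12, 0, 1), NA),
                        row.names = NULL)
  }
  terms$ms <- terms$ss / terms$df
  terms <- terms[, c("term", "ss", "df", "ms", "F", "p")]
  structure(list(terms = terms,
                 ss_total = sum((df$value - mean(df$value))^2),
                 alpha = alpha),
            class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat("Two-way ANOVA (Type II SS)\n")
  tt <- x$terms
  tt$signif <- ifelse(!is.na(tt$p) & tt$p < x$alpha, "*", "")
  print(format(tt, digits = 4), row.names = FALSE)
  cat(sprintf("Total SS %.4g; significance level %.2f\n", x$ss_total, x$alpha))
  invisible(x)
}

#' Simulate a repeated-measurement reliability study
#'
#' Generates `n_cases` synthetic femurs (with case-level jitter of head
#' offset and neck-shaft angle, providing between-case variance), then for
#' every case, rater and repetition perturbs the landmarks with isotropic
#' Gaussian noise of `sigma_rater` and runs the full axis-fitting pipeline.
#' The resulting DBHF table feeds [icc()].
#'
#' @param spec base [femur_spec()]; per-case jitter is applied on top. The
#'   default spec here uses a 1.8 mm voxel pitch: a reliability study runs
#'   the pipeline dozens of times, relative variance components are
#'   insensitive to meshing resolution, and the coarser grid keeps a study
#'   to a few seconds.
#' @param n_cases number of cases (subjects), `>= 2`.
#' @param n_raters number of raters (use 1 with `n_reps > 1` for an
#'   intra-observer design).
#' @param n_reps repetitions per rater.
#' @param sigma_rater landmark-perturbation standard deviation (mm).
#' @param case_offset_sd standard deviation of the per-case head-offset
#'   jitter (mm), the main source of between-case DBHF variance.
#' @param seed integer seed.
#' @return A list: `measurements` (data frame `case`, `rater`, `rep`,
#'   `dbhf`), `table` (cases x (rater,rep) matrix for [icc()]), `failed`
#'   (data frame of failed runs, if any) and the simulation settings.
#' @export
simulate_reliability_study <- function(spec = femur_spec(voxel_pitch = 1.8),
                                       n_cases = 10L, n_raters = 1L,
                                       n_reps = 3L, sigma_rater = 0.5,
                                       case_offset_sd = 1.0,
                                       seed = 20190101L) {
  if (n_cases < 2L || n_raters < 1L || n_reps < 1L)
    fna_stop("fna_bad_config", "need n_cases >= 2, n_raters >= 1, n_reps >= 1")
  draws <- with_seed(seed, list(
    offs = abs(stats::rnorm(n_cases, sd = case_offset_sd)),
    nsa = stats::rnorm(n_cases, sd = 3),
    lmseeds = matrix(sample.int(.Machine$integer.max,
                                n_cases * n_raters * n_reps),
                     nrow = n_cases)
  ))
  rows <- list()
  failed <- list()
  for (ci in seq_len(n_cases)) {
    sp <- spec
    sp$head_offset <- spec$head_offset + draws$offs[ci]
    sp$neck_shaft_angle <- spec$neck_shaft_angle + draws$nsa[ci]
    sp$seed <- draws$lmseeds[ci, 1]
    fem <- generate_femur(sp)
    j <- 0L
    for (ri in seq_len(n_raters)) for (pi in seq_len(n_reps)) {
      j <- j + 1L
      lm_p <- perturb_landmarks(fem$truth$landmarks, sigma_rater,
                                seed = draws$lmseeds[ci, j])
      res <- tryCatch(fit_fna(fem$mesh, lm_p),
                      fnaxis_error = function(e) e)
      if (inherits(res, "error")) {
        failed[[length(failed) + 1L]] <-
          data.frame(case = ci, rater = ri, rep = pi,
                     error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(case = ci, rater = ri, rep = pi, dbhf = res$dbhf)
      }
    }
  }
  meas <- do.call(rbind, rows)
  failed <- if (length(failed)) do.call(rbind, failed) else NULL
  tab <- NULL
  if (!is.null(meas)) {
    tab <- matrix(NA_real_, n_cases, n_raters * n_reps)
    for (r in seq_len(nrow(meas)))
      tab[meas$case[r], (meas$rater[r] - 1L) * n_reps + meas$rep[r]] <-
        meas$dbhf[r]
    colnames(tab) <- paste0("r", rep(seq_len(n_raters), each = n_reps),
                            "_m", rep(seq_len(n_reps), n_raters))
  }
  list(measurements = meas, table = tab, failed = failed,
       settings = list(n_cases = n_cases, n_raters = n_raters,
                       n_reps = n_reps, sigma_rater = sigma_rater,
                       case_offset_sd = case_offset_sd, seed = seed))
}
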