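#' Bootstrap bias relative to the final estimate
#'
#' `100 * (bootstrap median - final estimate) / final estimate`, in percent.
#'
#' @param boot_median Median estimate over bootstrap replicates.
#' @param estimate Final-model estimate.
#' @return Bias in percent.
#' @export
bootstrap_bias <- function(boot_median, estimate) {
  100 * (boot_median - estimate) / estimate
}

#' Nonparametric bootstrap of a fitted model
#'
#' Resamples subjects with replacement (each with all their dosing and
#' concentration records) to the original cohort size, refits the model on
#' each replicate, and summarizes converged replicates by the median and the
#' 2.5th/97.5th percentiles, with bias relative to the reference fit by
#' [bootstrap_bias()]. The result is flagged when fewer than 80% of
#' replicates converge.
#'
#' @param dataset A [pk_dataset()].
#' @param fit Reference `pk_fit` (its spec and estimates warm-start the
#'   replicates).
#' @param n_replicates Number of resampled datasets (the study used 1,000).
#' @param seed Integer seed.
#' @return List of class `pk_bootstrap`: per-parameter summary table,
#'   replicate matrix, convergence counts.
#' @export
bootstrap_model <- function(dataset, fit, n_replicates = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(fit, "pk_fit"))
  set.seed(seed)
  s <- dataset$subjects
  n <- nrow(s)
  est_mat <- matrix(NA_real_, n_replicates, length(fit$estimates),
                    dimnames = list(NULL, names(fit$estimates)))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    pick <- sample.int(n, n, replace = TRUE)
    new_ids <- sprintf("B%04d", seq_len(n))
    subj_r <- s[pick, c("id", "wt", "height", "age", "sex", "scr", "egfr")]
    doses_r <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- dataset$doses[dataset$doses$id == s$id[pick[i]], , drop = FALSE]
      d$id <- new_ids[i]
      d
    }))
    obs_r <- do.call(rbind, lapply(seq_len(n), function(i) {
      o <- dataset$observations[dataset$observations$id == s$id[pick[i]],
                                c("id", "time", "conc"), drop = FALSE]
      if (nrow(o)) o$id <- new_ids[i]
      o
    }))
    subj_r$id <- new_ids
    ds_r <- pk_dataset(subj_r, doses_r, obs_r)
    fit_r <- tryCatch(
      fit_foce(ds_r, fit$spec, inits = fit$params, seed = seed + r,
               compute_se = FALSE, compute_residuals = FALSE),
      error = function(e) NULL)
    if (!is.null(fit_r) && fit_r$converged) {
      est_mat[r, ] <- fit_r$estimates
      conv[r] <- TRUE
    }
  }
  ok <- est_mat[conv, , drop = FALSE]
  summary <- data.frame(
    parameter = names(fit$estimates),
    estimate = unname(fit$estimates),
    boot_median = apply(ok, 2, stats::median),
    p2.5 = apply(ok, 2, stats::quantile, probs = 0.025),
    p97.5 = apply(ok, 2, stats::quantile, probs = 0.975),
    stringsAsFactors = FALSE)
  summary$bias_pct <- bootstrap_bias(summary$boot_median, summary$estimate)
  structure(list(summary = summary, replicates = est_mat,
                 n_converged = sum(conv), n_replicates = n_replicates,
                 flagged = sum(conv) < 0.8 * n_replicates),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("bootstrap: %d/%d replicates converged%s\n", x$n_converged,
              x$n_replicates,
              if (x$flagged) "  [FLAGGED: <80% convergence]" else ""))
  print(transform(x$summary, boot_median = signif(boot_median, 4),
                  p2.5 = signif(p2.5, 4), p97.5 = signif(p97.5, 4),
                  bias_pct = round(bias_pct, 2)))
  invisible(x)
}

## equal-count bins on time after the most recent dose
bin_by_tad <- function(dataset, n_bins = 6L, min_per_bin = 5L) {
  obs <- dataset$observations[!dataset$observations$below_loq, , drop = FALSE]
  tad <- vapply(seq_len(nrow(obs)), function(k) {
    d <- dataset$doses[dataset$doses$id == obs$id[k], "time"]
    obs$time[k] - max(d[d < obs$time[k]])
  }, numeric(1))
  qs <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(tad, qs, include.lowest = TRUE)
  ## merge undersized bins with their left neighbor
  repeat {
    tab <- table(bin)
    small <- which(tab < min_per_bin)
    if (!length(small) || length(tab) == 1) break
    j <- small[1]
    lv <- levels(bin)
    merge_into <- if (j == 1) 2 else j - 1
    levels(bin)[j] <- lv[merge_into]
    bin <- droplevels(bin)
  }
  list(tad = tad, bin = bin)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model (same design
#' and covariates), then compares the observed 2.5th/50th/97.5th percentiles
#' per time-after-dose bin with the 95% band of the same percentiles across
#' simulations. Bins are equal-count on time after the most recent dose;
#' bins with fewer than 5 observations are merged with a neighbor.
#'
#' The observed dataset contains only quantifiable concentrations (values
#' below the limit of quantification never enter it), so the simulated
#' percentiles are computed on the same support: simulated values below
#' `lloq` are dropped replicate-wise before taking percentiles. Without this
#' conditioning the lower band is systematically too low and the check is
#' miscalibrated.
#'
#' @param dataset A [pk_dataset()].
#' @param fit A `pk_fit` (or a list with `spec` and `params`).
#' @param n_sim Number of simulation replicates (the study used 1,000).
#' @param seed Integer seed.
#' @param n_bins Number of time bins (default 6).
#' @param probs Percentiles tracked (default 2.5/50/97.5).
#' @param lloq Lower limit of quantification applied to the simulations
#'   (default 0.1 ug/mL, the assay limit).
#' @return List of class `pk_vpc`: per-bin observed percentiles, simulated
#'   band limits, bin definitions, and the fraction of observed percentile
#'   points inside their bands (`coverage`).
#' @export
vpc <- function(dataset, fit, n_sim = 1000L, seed = 1L, n_bins = 6L,
                probs = c(0.025, 0.5, 0.975), lloq = GCV_LLOQ) {
  set.seed(seed)
  bins <- bin_by_tad(dataset, n_bins)
  obs <- dataset$observations[!dataset$observations$below_loq, , drop = FALSE]
  sims <- simulate_replicates(dataset, fit$spec, fit$params, n_sim)
  lv <- levels(bins$bin)
  rows <- list()
  for (b in lv) {
    idx <- which(bins$bin == b)
    obs_q <- stats::quantile(obs$conc[idx], probs)
    sim_q <- apply(sims[idx, , drop = FALSE], 2, function(v) {
      vq <- v[v >= lloq]
      if (length(vq) < 2) vq <- v  # degenerate bin: fall back to all values
      stats::quantile(vq, probs)
    })
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = 1)
    for (p in seq_along(probs)) {
      band <- stats::quantile(sim_q[p, ], c(0.025, 0.975))
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, tad_mid = stats::median(bins$tad[idx]), n = length(idx),
        percentile = 100 * probs[p], observed = unname(obs_q[p]),
        band_lo = unname(band[1]), band_hi = unname(band[2]),
        sim_median = stats::median(sim_q[p, ]), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$inside <- tab$observed >= tab$band_lo & tab$observed <= tab$band_hi
  structure(list(table = tab, coverage = mean(tab$inside), n_sim = n_sim,
                 probs = probs), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC (%d simulations): %.0f%% of observed percentile points inside their 95%% bands\n",
              x$n_sim, 100 * x$coverage))
  print(x$table, digits = 3)
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' For each subject, `n_sim` replicate observation vectors are simulated
#' under the model; the observed vector and the simulations are decorrelated
#' with the Cholesky factor of the simulated covariance, the rank of each
#' decorrelated observation within its simulated distribution is computed
#' (with a `(r + 0.5)/(K + 1)` continuity correction), and the inverse-normal
#' transform gives the NPDE, standard normal under a correct model. Four
#' tests are reported: Wilcoxon signed rank (mean 0), a chi-square variance
#' test against 1 (Fisher-type), Shapiro-Wilk normality, and a Bonferroni
#' global test (`min(p) * 3`, capped at 1).
#'
#' @inheritParams vpc
#' @return List of class `pk_npde`: per-observation NPDE values and the four
#'   p-values.
#' @export
npde <- function(dataset, fit, n_sim = 1000L, seed = 1L) {
  set.seed(seed)
  design <- build_design(dataset)
  obs <- design$obs
  sims <- simulate_replicates(dataset, fit$spec, fit$params, n_sim)
  val <- rep(NA_real_, nrow(obs))
  for (i in unique(design$obs_subj)) {
    rows <- which(design$obs_subj == i)
    Si <- sims[rows, , drop = FALSE]
    mu <- rowMeans(Si)
    if (length(rows) > 1) {
      V <- stats::cov(t(Si))
      L <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(L)) next  # singular simulated covariance: subject excluded
      y_star <- backsolve(L, obs$conc[rows] - mu, transpose = TRUE)
      S_star <- backsolve(L, Si - mu, transpose = TRUE)
    } else {
      y_star <- obs$conc[rows] - mu
      S_star <- Si - mu
    }
    r <- rowSums(S_star < y_star)
    val[rows] <- stats::qnorm((r + 0.5) / (n_sim + 1))
  }
  keep <- !is.na(val)
  v <- val[keep]
  p_wilcox <- stats::wilcox.test(v, mu = 0)$p.value
  ## variance-against-1 test: (n-1) s^2 ~ chi^2(n-1) under the null
  nv <- length(v)
  stat <- (nv - 1) * stats::var(v)
  p_var <- 2 * min(stats::pchisq(stat, nv - 1),
                   1 - stats::pchisq(stat, nv - 1))
  p_shapiro <- stats::shapiro.test(v)$p.value
  p_global <- min(1, 3 * min(p_wilcox, p_var, p_shapiro))
  structure(list(npde = val, n_excluded = sum(!keep),
                 p_wilcoxon = p_wilcox, p_variance = p_var,
                 p_shapiro = p_shapiro, p_global = p_global, n_sim = n_sim),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf(
    "NPDE (%d simulations): mean %.3f, var %.3f\n  p: Wilcoxon %.3f, variance %.3f, Shapiro-Wilk %.3f, global %.3f\n",
    x$n_sim, mean(x$npde, na.rm = TRUE), stats::var(x$npde[!is.na(x$npde)]),
    x$p_wilcoxon, x$p_variance, x$p_shapiro, x$p_global))
  invisible(x)
}
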