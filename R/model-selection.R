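#' Stepwise OFV thresholds
#'
#' Chi-square(1 df) critical values used by the stepwise search: 3.84
#' (p < 0.05) for forward inclusion and 6.63 (p < 0.01) for backward
#' retention, computed from [stats::qchisq()] rather than hard-coded.
#'
#' @name ofv_thresholds
#' @export
OFV_FORWARD <- qchisq(0.95, df = 1)

#' @rdname ofv_thresholds
#' @export
OFV_BACKWARD <- qchisq(0.99, df = 1)

#' Collinearity pre-screen for covariates
#'
#' Pairwise Pearson correlations of the candidate covariate columns; pairs
#' with `|r| > threshold` are marked mutually exclusive so the stepwise search
#' never carries both at once. Constant columns have undefined correlation
#' and are dropped with a warning.
#'
#' @param covariates data.frame of numeric covariate columns.
#' @param threshold Exclusion threshold on `|r|` (default 0.5).
#' @return List with the correlation matrix and a data.frame of excluded
#'   pairs.
#' @export
correlation_screen <- function(covariates, threshold = 0.5) {
  stopifnot(is.data.frame(covariates), ncol(covariates) >= 2)
  sds <- vapply(covariates, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("constant covariate column(s) excluded from screen: ",
            paste(names(covariates)[sds == 0], collapse = ", "))
    covariates <- covariates[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(as.matrix(covariates))
  ut <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  excl <- data.frame(cov1 = rownames(r)[ut[, 1]], cov2 = colnames(r)[ut[, 2]],
                     r = r[ut], stringsAsFactors = FALSE)
  list(correlation = r, exclusive_pairs = excl, threshold = threshold)
}

#' Enumerate covariate candidates
#'
#' One candidate per (parameter, covariate) pair: continuous covariates in
#' power form centered at the cohort median, categorical (here sex) in
#' exponential form.
#'
#' @param subjects Subject table (for centering medians).
#' @param covariates Character vector of covariate column names.
#' @param parameters Targets, subset of `c("cl", "vd")`.
#' @return data.frame of candidates (param, cov, form, ref).
#' @export
candidate_pool <- function(subjects, covariates = c("wt", "age", "kf", "scr"),
                           parameters = c("cl", "vd")) {
  out <- expand.grid(param = parameters, cov = covariates,
                     stringsAsFactors = FALSE)
  out$form <- ifelse(out$cov == "sex", "exponential", "power")
  out$ref <- vapply(seq_len(nrow(out)), function(k) {
    if (out$form[k] == "exponential") return(0)
    stats::median(subjects[[out$cov[k]]])
  }, numeric(1))
  out
}

add_candidate <- function(spec, cand) {
  tm <- cov_term(cand$cov, cand$form, cand$ref)
  if (cand$param == "cl") {
    spec$cl_terms <- rbind(spec$cl_terms, tm)
  } else {
    spec$vd_terms <- rbind(spec$vd_terms, tm)
  }
  spec
}

drop_covariate <- function(spec, param, cov) {
  if (param == "cl") {
    spec$cl_terms <- spec$cl_terms[spec$cl_terms$cov != cov, , drop = FALSE]
  } else {
    spec$vd_terms <- spec$vd_terms[spec$vd_terms$cov != cov, , drop = FALSE]
  }
  spec
}

spec_covariates <- function(spec) {
  rbind(if (nrow(spec$cl_terms))
          data.frame(param = "cl", spec$cl_terms, stringsAsFactors = FALSE),
        if (nrow(spec$vd_terms))
          data.frame(param = "vd", spec$vd_terms, stringsAsFactors = FALSE))
}

model_label <- function(spec) {
  covs <- spec_covariates(spec)
  if (is.null(covs) || !nrow(covs)) return("base")
  paste(toupper(paste0(covs$param, "-", covs$cov)), collapse = "/")
}

## warm-start inits for a child model from its parent's estimates
warm_inits <- function(parent_fit, spec) {
  ini <- default_inits(spec)
  p <- parent_fit$params
  ini$theta[["tv_cl"]] <- p$theta[["tv_cl"]]
  ini$theta[["tv_vd"]] <- p$theta[["tv_vd"]]
  shared <- intersect(names(ini$theta), names(p$theta))
  ini$theta[shared] <- p$theta[shared]
  ini$omega <- pmax(p$omega, 0.02)
  ini$sigma <- pmax(p$sigma, 0.02)
  ini
}

admissible <- function(cand, spec, exclusive_pairs) {
  if (is.null(exclusive_pairs) || !nrow(exclusive_pairs)) return(TRUE)
  present <- unique(spec_covariates(spec)$cov)
  if (is.null(present)) return(TRUE)
  for (k in seq_len(nrow(exclusive_pairs))) {
    pr <- c(exclusive_pairs$cov1[k], exclusive_pairs$cov2[k])
    if (cand$cov %in% pr && any(setdiff(pr, cand$cov) %in% present)) {
      return(FALSE)
    }
  }
  TRUE
}

#' One forward-inclusion step
#'
#' Fits every admissible candidate extension of the current model (warm
#' started from the parent) and returns the one with the largest OFV drop,
#' provided the drop reaches the inclusion threshold of 3.84 (chi-square, 1
#' df, p < 0.05). Candidate fits that fail are skipped.
#'
#' @param dataset A [pk_dataset()].
#' @param current_fit Fit of the current model (`pk_fit`).
#' @param candidates Candidate data.frame from [candidate_pool()].
#' @param exclusive_pairs From [correlation_screen()]; may be `NULL`.
#' @param threshold OFV-drop threshold (default 3.84).
#' @param seed Seed passed to the candidate fits.
#' @return List with `selected` (candidate row or NULL), `fit`, and a
#'   per-candidate `trace` data.frame.
#' @export
forward_step <- function(dataset, current_fit, candidates,
                         exclusive_pairs = NULL, threshold = OFV_FORWARD,
                         seed = 1L) {
  best <- NULL
  rows <- list()
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    if (!admissible(cand, current_fit$spec, exclusive_pairs)) next
    spec_k <- add_candidate(current_fit$spec, cand)
    fit_k <- tryCatch(
      fit_foce(dataset, spec_k, inits = warm_inits(current_fit, spec_k),
               seed = seed, compute_se = FALSE, compute_residuals = FALSE),
      error = function(e) NULL)
    if (is.null(fit_k)) {
      message("forward_step: candidate ", cand$param, "-", cand$cov,
              " failed to fit; skipped")
      next
    }
    dofv <- fit_k$ofv - current_fit$ofv
    rows[[length(rows) + 1]] <- data.frame(param = cand$param, cov = cand$cov,
                                           ofv = fit_k$ofv, delta_ofv = dofv,
                                           stringsAsFactors = FALSE)
    better <- is.null(best) || dofv < best$dofv - 1e-9 ||
      (abs(dofv - best$dofv) <= 1e-9 && cand$cov < best$cand$cov)
    if (dofv <= -threshold && better) {
      best <- list(cand = cand, fit = fit_k, dofv = dofv)
    }
  }
  list(selected = if (is.null(best)) NULL else best$cand,
       fit = if (is.null(best)) NULL else best$fit,
       trace = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Stepwise forward-inclusion / backward-elimination covariate search
#'
#' Repeats [forward_step()] until no candidate reduces the OFV by at least
#' 3.84 (full model), then removes each covariate in turn, retaining only
#' those whose removal raises the OFV by at least 6.63 (chi-square, 1 df,
#' p < 0.01). Ties break on the larger OFV drop, then lexicographic covariate
#' name. Emits a selection trace (step, model, OFV, delta, decision).
#'
#' @param dataset A [pk_dataset()].
#' @param base_spec Starting [pk_model_spec()] (typically [base_model_spec()]).
#' @param candidates From [candidate_pool()].
#' @param exclusive_pairs From [correlation_screen()]; may be `NULL`.
#' @param forward_threshold,backward_threshold OFV thresholds (3.84 / 6.63).
#' @param seed Seed for all fits (deterministic inits make the trace
#'   reproducible).
#' @return List with `final_fit`, `final_spec`, and the `trace` data.frame.
#' @export
stepwise_search <- function(dataset, base_spec = base_model_spec(),
                            candidates, exclusive_pairs = NULL,
                            forward_threshold = OFV_FORWARD,
                            backward_threshold = OFV_BACKWARD, seed = 1L) {
  fit <- fit_foce(dataset, base_spec, seed = seed, compute_se = FALSE,
                  compute_residuals = FALSE)
  trace <- data.frame(step = 1L, model = model_label(base_spec),
                      ofv = fit$ofv, delta_ofv = NA_real_,
                      decision = "base model", stringsAsFactors = FALSE)
  remaining <- candidates
  step <- 1L
  max_steps <- 2L * nrow(candidates) + 4L  # cycle guard
  repeat {
    step <- step + 1L
    if (step > max_steps) {
      warning("stepwise_search: step limit reached; terminating search")
      break
    }
    if (!nrow(remaining)) break
    fs <- forward_step(dataset, fit, remaining, exclusive_pairs,
                       forward_threshold, seed = seed)
    if (is.null(fs$selected)) break
    dofv <- fs$fit$ofv - fit$ofv
    fit <- fs$fit
    remaining <- remaining[!(remaining$param == fs$selected$param &
                               remaining$cov == fs$selected$cov), ,
                           drop = FALSE]
    trace <- rbind(trace, data.frame(
      step = step, model = model_label(fit$spec), ofv = fit$ofv,
      delta_ofv = dofv, decision = "forward inclusion (p < 0.05)",
      stringsAsFactors = FALSE))
  }
  ## backward elimination from the full model
  covs <- spec_covariates(fit$spec)
  if (!is.null(covs) && nrow(covs)) {
    for (k in seq_len(nrow(covs))) {
      spec_red <- drop_covariate(fit$spec, covs$param[k], covs$cov[k])
      fit_red <- tryCatch(
        fit_foce(dataset, spec_red, inits = warm_inits(fit, spec_red),
                 seed = seed, compute_se = FALSE, compute_residuals = FALSE),
        error = function(e) NULL)
      if (is.null(fit_red)) next
      rise <- fit_red$ofv - fit$ofv
      step <- step + 1L
      if (rise < backward_threshold) {
        fit <- fit_red
        trace <- rbind(trace, data.frame(
          step = step, model = model_label(fit$spec), ofv = fit$ofv,
          delta_ofv = rise,
          decision = sprintf("backward elimination: dropped %s-%s (p > 0.01)",
                             toupper(covs$param[k]), covs$cov[k]),
          stringsAsFactors = FALSE))
      } else {
        trace <- rbind(trace, data.frame(
          step = step, model = model_label(fit$spec), ofv = fit$ofv,
          delta_ofv = rise,
          decision = sprintf("retained %s-%s (removal +%.2f >= %.2f)",
                             toupper(covs$param[k]), covs$cov[k], rise,
                             backward_threshold),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(final_fit = fit, final_spec = fit$spec, trace = trace)
}
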