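#' @keywords internal
"_PACKAGE"

## Lower limit of quantification of the ganciclovir HPLC-UV assay (ug/mL).
GCV_LLOQ <- 0.1

## Normal renal function reference used for the kidney-function ratio
## (mL/min/1.73 m^2).
EGFR_NORMAL <- 120

#' Body surface area by the Mosteller formula
#'
#' `BSA = sqrt(height * weight / 3600)` with height in cm and weight in kg.
#'
#' @param height Height in cm (positive).
#' @param wt Body weight in kg (positive).
#' @return Body surface area in m^2.
#' @examples
#' compute_bsa(90, 12)   # 0.548 m^2, a typical 12-kg toddler
#' @export
compute_bsa <- function(height, wt) {
  if (any(!is.finite(height)) || any(!is.finite(wt)) ||
      any(height <= 0) || any(wt <= 0)) {
    stop("compute_bsa(): height and wt must be positive and finite")
  }
  sqrt(height * wt / 3600)
}

#' Kidney-function ratio
#'
#' Individual eGFR divided by the normal renal function reference of
#' 120 mL/min/1.73 m^2; a dimensionless scaling used as a clearance covariate.
#'
#' @param egfr Estimated glomerular filtration rate (mL/min/1.73 m^2).
#' @return Dimensionless kidney-function ratio KF.
#' @export
compute_kf <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("compute_kf(): egfr must be positive and finite")
  }
  egfr / EGFR_NORMAL
}

RENAL_CLASSES <- c("severe", "moderate", "mild", "normal", "elevated")

#' Classify renal function from eGFR
#'
#' Five half-open bands with cutoffs 30/60/90/120 mL/min/1.73 m^2; a boundary
#' value belongs to the upper band (e.g. 120 is "elevated", 90 is "normal").
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (positive).
#' @return Factor with levels severe < moderate < mild < normal < elevated.
#' @export
classify_renal <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("classify_renal(): egfr must be positive and finite")
  }
  cut(egfr, breaks = c(0, 30, 60, 90, 120, Inf),
      labels = RENAL_CLASSES, right = FALSE, ordered_result = TRUE)
}

#' Identity eGFR calculator
#'
#' eGFR enters the dataset as a pre-computed column; this pass-through is the
#' default of the pluggable calculator interface so that an alternative
#' pediatric formula (e.g. from serum creatinine and height) can be swapped in.
#'
#' @return A function `(scr, height, age, sex, egfr) -> egfr`.
#' @export
egfr_identity <- function() {
  function(scr = NULL, height = NULL, age = NULL, sex = NULL, egfr) egfr
}

finalize_subjects <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  need <- c("id", "wt", "height", "age", "sex", "scr", "egfr")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  }
  with(subjects, {
    if (any(wt <= 0)) stop("subject weights must be positive")
    if (any(height <= 0)) stop("subject heights must be positive")
    if (any(age < 0)) stop("subject ages must be non-negative")
    if (any(egfr <= 0)) stop("subject eGFR must be positive")
  })
  subjects$sex <- as.character(subjects$sex)
  if (!all(subjects$sex %in% c("M", "F"))) {
    stop("sex must be coded M/F")
  }
  subjects$bsa <- compute_bsa(subjects$height, subjects$wt)
  subjects$kf <- compute_kf(subjects$egfr)
  subjects$renal_class <- classify_renal(subjects$egfr)
  subjects
}

#' Construct a sparse-sampling PK dataset
#'
#' Bundles the subject covariate table, per-subject dosing events and timed
#' concentration observations into a validated `pk_dataset` object. Derived
#' covariates (BSA by Mosteller, kidney-function ratio, renal class) are
#' computed here so every downstream stage sees one consistent table.
#'
#' @param subjects data.frame with columns id, wt (kg), height (cm),
#'   age (years), sex ("M"/"F"), scr (umol/L), egfr (mL/min/1.73 m^2).
#' @param doses data.frame with columns id, time (h since the subject's first
#'   dose), amount (mg), duration (h, > 0: zero-order infusion).
#' @param observations data.frame with columns id, time (h), conc (ug/mL).
#' @return Object of class `pk_dataset` with elements `subjects`, `doses`,
#'   `observations` (the latter gains a `below_loq` flag at 0.1 ug/mL).
#' @export
pk_dataset <- function(subjects, doses, observations) {
  subjects <- finalize_subjects(subjects)
  if (anyDuplicated(subjects$id)) stop("duplicate subject ids")
  for (nm in c("id", "time", "amount", "duration")) {
    if (!nm %in% names(doses)) stop("dose table missing column: ", nm)
  }
  for (nm in c("id", "time", "conc")) {
    if (!nm %in% names(observations)) {
      stop("observation table missing column: ", nm)
    }
  }
  if (any(doses$time < 0)) stop("dose times must be >= 0")
  if (any(doses$amount < 0)) stop("dose amounts must be >= 0")
  if (any(doses$duration <= 0)) stop("infusion durations must be > 0")
  if (any(observations$time < 0)) stop("observation times must be >= 0")
  if (any(observations$conc < 0)) stop("concentrations must be >= 0")
  if (!all(doses$id %in% subjects$id) ||
      !all(observations$id %in% subjects$id)) {
    stop("dose/observation rows reference unknown subject ids")
  }
  ## every observation needs at least one prior (or simultaneous-start) dose
  first_dose <- tapply(doses$time, doses$id, min)
  fd <- first_dose[as.character(observations$id)]
  bad <- is.na(fd) | observations$time < fd
  if (any(bad)) {
    stop("observation before any dose for subject(s): ",
         paste(unique(observations$id[bad]), collapse = ", "))
  }
  ## strictly increasing observation times within subject
  ord <- order(match(observations$id, subjects$id), observations$time)
  observations <- observations[ord, , drop = FALSE]
  split_t <- split(observations$time, observations$id)
  if (any(vapply(split_t, function(t) any(diff(t) <= 0), logical(1)))) {
    stop("observation times must be strictly increasing within a subject")
  }
  observations$below_loq <- observations$conc < GCV_LLOQ
  doses <- doses[order(match(doses$id, subjects$id), doses$time), , drop = FALSE]
  rownames(subjects) <- rownames(doses) <- rownames(observations) <- NULL
  structure(list(subjects = subjects, doses = doses,
                 observations = observations),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("pk_dataset: %d subjects, %d doses, %d observations (%d BLQ)\n",
              nrow(x$subjects), nrow(x$doses), nrow(x$observations),
              sum(x$observations$below_loq)))
  cat(sprintf("  WT %.1f-%.1f kg (median %.1f), eGFR %.1f-%.1f\n",
              min(x$subjects$wt), max(x$subjects$wt),
              stats::median(x$subjects$wt),
              min(x$subjects$egfr), max(x$subjects$egfr)))
  invisible(x)
}

NONMEM_COLUMNS <- c("ID", "TIME", "AMT", "DV", "WT", "HT", "AGE",
                    "SEX", "SCR", "EGFR")

#' Read a NONMEM-dialect rectangular dataset
#'
#' Expects a CSV with one row per event: dose rows (`EVID == 1`, or
#' `MDV == 1` with `AMT > 0` when EVID is absent) and observation rows
#' (`EVID == 0` / `MDV == 0`). Infusion length is taken from `DUR` (hours);
#' a `RATE` column (mg/h) is accepted instead, with `DUR = AMT / RATE`.
#' Covariates are constant per subject; on conflict the first value wins with
#' a warning. Units are fixed: hours, mg, ug/mL.
#'
#' @param path Path to the CSV file.
#' @return A [pk_dataset()].
#' @export
read_pkdata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  miss <- setdiff(NONMEM_COLUMNS, names(raw))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!("DUR" %in% names(raw)) && !("RATE" %in% names(raw))) {
    stop("missing mandatory column(s): DUR (or RATE)")
  }
  if (!("EVID" %in% names(raw)) && !("MDV" %in% names(raw))) {
    stop("missing mandatory column(s): EVID (or MDV)")
  }
  num_cols <- setdiff(intersect(c(NONMEM_COLUMNS, "DUR", "RATE", "EVID", "MDV"),
                                names(raw)), c("ID", "SEX"))
  for (nm in num_cols) {
    v <- raw[[nm]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & v != "." & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column %s at data row %d: '%s'",
                     nm, bad[1], v[bad[1]]))
      }
      raw[[nm]] <- conv
    }
  }
  evid <- if ("EVID" %in% names(raw)) raw$EVID else
    as.integer(raw$MDV == 1 & !is.na(raw$AMT) & raw$AMT > 0)
  is_dose <- evid == 1
  is_obs <- if ("MDV" %in% names(raw)) evid == 0 & raw$MDV == 0 else evid == 0

  sex <- raw$SEX
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "M", "F")
  first_rows <- !duplicated(raw$ID)
  subjects <- data.frame(id = as.character(raw$ID[first_rows]),
                         wt = raw$WT[first_rows],
                         height = raw$HT[first_rows],
                         age = raw$AGE[first_rows],
                         sex = sex[first_rows],
                         scr = raw$SCR[first_rows],
                         egfr = raw$EGFR[first_rows],
                         stringsAsFactors = FALSE)
  ## covariates must be constant within subject; first value wins
  for (nm in c("WT", "HT", "AGE", "SCR", "EGFR")) {
    rng <- tapply(raw[[nm]], raw$ID, function(v) diff(range(v, na.rm = TRUE)))
    if (any(rng > 0, na.rm = TRUE)) {
      warning("covariate ", nm, " varies within subject; first value used")
    }
  }
  dur <- if ("DUR" %in% names(raw)) raw$DUR else raw$AMT / raw$RATE
  doses <- data.frame(id = as.character(raw$ID[is_dose]),
                      time = raw$TIME[is_dose],
                      amount = raw$AMT[is_dose],
                      duration = dur[is_dose],
                      stringsAsFactors = FALSE)
  observations <- data.frame(id = as.character(raw$ID[is_obs]),
                             time = raw$TIME[is_obs],
                             conc = raw$DV[is_obs],
                             stringsAsFactors = FALSE)
  pk_dataset(subjects, doses, observations)
}

#' Write a dataset in the canonical NONMEM dialect
#'
#' Inverse of [read_pkdata()]: dose rows get `EVID = 1`, `MDV = 1`; observation
#' rows `EVID = 0`, `MDV = 0`. Numeric fields round-trip bit-exactly (written
#' with full precision).
#'
#' @param dataset A [pk_dataset()].
#' @param path Output CSV path.
#' @export
write_pkdata <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  s <- dataset$subjects
  row_for <- function(id, time, amt, dur, dv, evid, mdv) {
    i <- match(id, s$id)
    data.frame(ID = id, TIME = time, AMT = amt, DUR = dur, DV = dv,
               EVID = evid, MDV = mdv, WT = s$wt[i], HT = s$height[i],
               AGE = s$age[i], SEX = s$sex[i], SCR = s$scr[i],
               EGFR = s$egfr[i], stringsAsFactors = FALSE)
  }
  d <- dataset$doses
  o <- dataset$observations
  out <- rbind(row_for(d$id, d$time, d$amount, d$duration, NA_real_, 1L, 1L),
               row_for(o$id, o$time, 0, NA_real_, o$conc, 0L, 0L))
  out <- out[order(match(out$ID, s$id), out$TIME, -out$EVID), ]
  ## format = 22 significant digits guarantees exact double round-trip
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Summarise a dataset as a JSON-able manifest
#'
#' Counts plus covariate summaries (mean, SD, median, range) in the layout of
#' a demographics table; used as the sidecar for generated cohorts.
#'
#' @param dataset A [pk_dataset()].
#' @param path Optional path; when given the manifest is written as JSON.
#' @return Invisibly, the manifest list.
#' @export
dataset_manifest <- function(dataset, path = NULL) {
  stopifnot(inherits(dataset, "pk_dataset"))
  s <- dataset$subjects
  summ <- function(v) {
    list(mean = mean(v), sd = stats::sd(v), median = stats::median(v),
         min = min(v), max = max(v))
  }
  man <- list(
    n_subjects = nrow(s),
    n_observations = nrow(dataset$observations),
    n_doses = nrow(dataset$doses),
    n_below_loq = sum(dataset$observations$below_loq),
    sex = as.list(table(s$sex)),
    renal_class = as.list(table(s$renal_class)),
    covariates = list(age = summ(s$age), wt = summ(s$wt),
                      height = summ(s$height), bsa = summ(s$bsa),
                      scr = summ(s$scr), egfr = summ(s$egfr)),
    concentration = summ(dataset$observations$conc)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(man)
}
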