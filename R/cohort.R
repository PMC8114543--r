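# Synthetic trough-monitoring cohorts with the demographic structure of
# the study population (n = 80, weights 8-68 kg, sparse troughs, seven
# concomitant antiepileptics), generated from the final model as truth.

#' Specification of a synthetic TDM cohort
#'
#' Defaults emulate the study demographics: 80 subjects; weight
#' log-normal moment-matched to mean 23.50 / SD 11.71 kg and truncated
#' to the observed 8-68 kg range; oxcarbazepine prevalence 23/80; the
#' other comedication prevalences as observed; on average 2.35 trough
#' samples per subject (minimum 1).  Troughs are generated as
#' steady-state troughs under sampled individual parameters plus
#' residual error.  All covariates other than weight and oxcarbazepine
#' are generated but inert (no effect on the truth model), so covariate
#' screening has true negatives to reject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param weight_mean,weight_sd,weight_range moment targets (kg) and
#'   truncation bounds of the log-normal weight distribution.
#' @param oxc_prevalence probability of oxcarbazepine comedication.
#' @param comed_prevalence named prevalences of the inert comedications.
#' @param samples_mean mean troughs per subject (min 1; 1 + Poisson).
#' @param interval dosing interval in h (study drug was once daily).
#' @param dose_policy `list(type = "target_trough", range = c(lo, hi))`
#'   draws each subject's daily dose so the typical steady-state trough
#'   is uniform on `range` (ng/ml), emulating titration toward the
#'   therapeutic window within the assay's linear range;
#'   `list(type = "fixed", dose_mg = x)` gives every subject `x` mg per
#'   administration.
#' @param fx,var,err true model parameters ([fixed_effects()],
#'   [variability_params()], [residual_error()]).
#' @param blq_limit lower limit of the assay's linear response (ng/ml),
#'   carried as metadata and used for the BLQ flag.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 80,
                        weight_mean = 23.50, weight_sd = 11.71,
                        weight_range = c(8, 68),
                        oxc_prevalence = 23 / 80,
                        comed_prevalence = c(cbz = 2, ltg = 4, lev = 10,
                                             tpm = 8, vpa = 40, vgb = 12) / 80,
                        samples_mean = 2.35,
                        interval = 24,
                        dose_policy = list(type = "target_trough",
                                           range = c(4, 25)),
                        fx = fixed_effects(),
                        var = variability_params(),
                        err = residual_error(),
                        blq_limit = 3.5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(c(oxc_prevalence, comed_prevalence) < 0) ||
      any(c(oxc_prevalence, comed_prevalence) > 1))
    stop("prevalences must lie in [0, 1]")
  if (weight_range[1] >= weight_range[2] || weight_range[1] <= 0)
    stop("infeasible weight truncation bounds")
  if (samples_mean < 1) stop("samples_mean must be >= 1")
  structure(list(n_subjects = n_subjects, weight_mean = weight_mean,
                 weight_sd = weight_sd, weight_range = weight_range,
                 oxc_prevalence = oxc_prevalence,
                 comed_prevalence = comed_prevalence,
                 samples_mean = samples_mean, interval = interval,
                 dose_policy = dose_policy,
                 fx = fx, var = var, err = err, blq_limit = blq_limit),
            class = "cohort_spec")
}

# truncated log-normal sampler via inverse CDF; moment-matched to the
# untruncated mean/sd
.sample_weights <- function(n, mean, sd, range) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  plo <- stats::plnorm(range[1], meanlog, sdlog)
  phi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# inert demographics/labs with the study's summary statistics (mean, sd,
# min, max); truncated-normal via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

.LAB_TABLE <- list(
  AGE  = c(6.35, 3.83, 0.61, 16.61),
  ALB  = c(43.00, 3.41, 36.0, 51.6),
  ALT  = c(11.67, 9.13, 1.0, 50.0),
  AST  = c(28.35, 9.23, 9.0, 68.3),
  CREA = c(34.35, 10.81, 20.0, 89.0),
  UREA = c(4.53, 1.19, 2.0, 8.3),
  TP   = c(70.71, 5.81, 59.3, 80.5),
  TBA  = c(4.03, 3.31, 0.05, 14.0),
  DBIL = c(2.05, 0.78, 0.7, 4.0),
  TBIL = c(5.54, 2.17, 2.1, 12.6),
  HCT  = c(37.66, 3.75, 29.5, 49.4),
  HGB  = c(125.96, 12.51, 96.0, 161.0),
  MCH  = c(27.20, 1.74, 23.1, 31.0),
  MCHC = c(334.59, 11.44, 305.0, 370.0))

#' Generate a synthetic therapeutic-drug-monitoring dataset
#'
#' Draws subjects per the [cohort_spec()], realizes individual clearances
#' under lognormal IIV, computes steady-state troughs for each subject's
#' dose and applies residual error.  Observed concentrations are floored
#' at 0.1 ng/ml (an additive-error draw can be negative; a recorded
#' assay result cannot).  Rows follow the NONMEM dataset dialect:
#' a dose row (`EVID = 1`, `AMT` mg per administration, `II` h) at time
#' 0 per subject, then observation rows (`EVID = 0`, `DV` ng/ml,
#' `MDV = 0`) at steady-state trough times.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return a `tdm_data` data.frame.
#' @examples
#' d <- generate_cohort(cohort_spec(n_subjects = 4), seed = 1)
#' table(d$EVID)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- spec$n_subjects
  wt <- round(.sample_weights(n, spec$weight_mean, spec$weight_sd,
                              spec$weight_range), 1)
  oxc <- stats::rbinom(n, 1, spec$oxc_prevalence)
  sex <- stats::rbinom(n, 1, 35 / 80) # 1 = boy
  form <- stats::rbinom(n, 1, 0.5)    # 1 = tablet
  comeds <- vapply(spec$comed_prevalence,
                   function(p) stats::rbinom(n, 1, p), integer(n))
  if (n == 1L) comeds <- matrix(comeds, nrow = 1,
                                dimnames = list(NULL, names(spec$comed_prevalence)))
  labs <- vapply(.LAB_TABLE, function(m) round(.rtnorm(n, m[1], m[2], m[3], m[4]), 2),
                 numeric(n))
  if (n == 1L) labs <- matrix(labs, nrow = 1, dimnames = list(NULL, names(.LAB_TABLE)))

  ind <- sample_individuals(wt, oxc, spec$fx, spec$var, n = n)
  tau <- spec$interval

  # per-subject dose (mg per administration)
  if (spec$dose_policy$type == "fixed") {
    dose <- rep_len(spec$dose_policy$dose_mg, n)
  } else {
    target <- stats::runif(n, spec$dose_policy$range[1], spec$dose_policy$range[2])
    per_mg <- trough_steady_state(typical_clearance(wt, oxc, spec$fx),
                                  typical_volume(wt, spec$fx),
                                  dose_mg = 1, interval = tau,
                                  ka = spec$fx$ka_fixed)
    dose <- round(target / per_mg, 2)
  }

  n_obs <- 1L + stats::rpois(n, spec$samples_mean - 1)

  rows <- lapply(seq_len(n), function(i) {
    days <- sort(sample(14:180, n_obs[i]))
    t_obs <- days * 24
    pred <- trough_steady_state(ind$cl[i], ind$v[i], dose[i], tau,
                                ka = spec$fx$ka_fixed)
    dv <- apply_residual_error(rep(pred, n_obs[i]), spec$err)
    dv <- pmax(round(dv, 2), 0.1)
    covs <- data.frame(WT = wt[i], OXC = oxc[i], SEX = sex[i], FORM = form[i],
                       labs[i, , drop = FALSE], comeds[i, , drop = FALSE])
    names(covs)[5:(4 + ncol(labs))] <- colnames(labs)
    names(covs)[(5 + ncol(labs)):ncol(covs)] <- toupper(colnames(comeds))
    base <- data.frame(ID = i,
                       TIME = c(0, t_obs),
                       EVID = c(1L, rep(0L, n_obs[i])),
                       AMT = c(dose[i], rep(NA_real_, n_obs[i])),
                       DV = c(NA_real_, dv),
                       MDV = c(1L, rep(0L, n_obs[i])),
                       II = tau)
    cbind(base, covs[rep(1, nrow(base)), , drop = FALSE], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$BLQ <- ifelse(out$EVID == 0L & out$DV < spec$blq_limit, 1L, 0L)
  class(out) <- c("tdm_data", "data.frame")
  attr(out, "interval") <- tau
  attr(out, "blq_limit") <- spec$blq_limit
  validate_tdm(out)
}

#' Validate a TDM dataset
#'
#' Checks the dataset invariants: per-subject times sorted and
#' non-negative, every observation preceded by a dose row, `DV` present
#' exactly on observation rows and strictly positive, `AMT` positive on
#' dose rows, weights positive, indicator columns 0/1.
#'
#' @param data a data.frame in the NONMEM dialect.
#' @return the validated `tdm_data` object (invisibly classed).
#' @export
validate_tdm <- function(data) {
  req <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "WT")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!nrow(data)) stop("empty dataset")
  for (id in unique(data$ID)) {
    sub <- data[data$ID == id, ]
    ln <- which(data$ID == id)
    if (any(sub$TIME < 0))
      stop("negative time for subject ", id, " (row ", ln[which(sub$TIME < 0)[1]], ")")
    if (is.unsorted(sub$TIME))
      stop("times not sorted for subject ", id)
    obs <- sub$EVID == 0
    if (any(obs) && !any(sub$EVID == 1))
      stop("subject ", id, " has observations but no dose row")
    if (any(obs)) {
      first_dose <- min(sub$TIME[sub$EVID == 1])
      bad <- obs & sub$TIME <= first_dose
      if (any(bad))
        stop("observation before any dose for subject ", id,
             " (row ", ln[which(bad)[1]], ")")
    }
    if (any(!is.na(sub$DV[sub$EVID == 1])))
      stop("DV present on a dose row for subject ", id,
           " (row ", ln[which(sub$EVID == 1 & !is.na(sub$DV))[1]], ")")
    if (any(is.na(sub$DV[obs])))
      stop("missing DV on an observation row for subject ", id)
    if (any(sub$DV[obs] <= 0))
      stop("non-positive DV for subject ", id)
    if (any(is.na(sub$AMT[sub$EVID == 1])) || any(sub$AMT[sub$EVID == 1] <= 0))
      stop("dose rows need positive AMT for subject ", id)
  }
  if (any(data$WT <= 0)) stop("weights must be positive")
  if ("OXC" %in% names(data) && !all(data$OXC %in% c(0, 1)))
    stop("OXC must be a 0/1 indicator")
  if (!inherits(data, "tdm_data")) class(data) <- c("tdm_data", "data.frame")
  data
}

#' Write / read a TDM dataset as delimited text
#'
#' Comma-separated NONMEM dialect with a mandatory header; round-trips
#' losslessly through [read_tdm()].
#'
#' @param data a validated `tdm_data` data.frame.
#' @param path file path.
#' @return `write_tdm()`: the path, invisibly.  `read_tdm()`: a
#'   validated `tdm_data` object.
#' @export
write_tdm <- function(data, path) {
  validate_tdm(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tdm
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty dataset file: ", path)
  data <- utils::read.csv(path)
  if (!nrow(data)) stop("empty dataset file: ", path)
  validate_tdm(data)
}

#' @export
print.tdm_data <- function(x, ...) {
  n_sub <- length(unique(x$ID))
  n_obs <- sum(x$EVID == 0)
  cat(sprintf("TDM dataset: %d subjects, %d trough observations (%.2f per subject)\n",
              n_sub, n_obs, n_obs / n_sub))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

# internal: one row per observation with its governing dose and interval
.obs_table <- function(data) {
  data <- as.data.frame(data)
  obs <- data[data$EVID == 0, , drop = FALSE]
  doses <- data[data$EVID == 1, , drop = FALSE]
  amt <- doses$AMT[match(obs$ID, doses$ID)]
  ii <- if ("II" %in% names(doses)) doses$II[match(obs$ID, doses$ID)] else 24
  out <- data.frame(id = obs$ID, dv = obs$DV, amt = amt, ii = ii,
                    wt = obs$WT)
  extra <- setdiff(names(obs), c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "II", "WT"))
  for (nm in extra) out[[tolower(nm)]] <- obs[[nm]]
  out
}
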