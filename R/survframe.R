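## Discovery -> validation prognostic-biomarker framework: quantile cutoff
## scan on a discovery cohort, frozen cutoffs applied within platform x
## subtype strata, Benjamini-Hochberg control in validation, multivariable
## Cox proportional-hazards confirmation.

QUANTILE_SET <- c(0.33, 0.5, 0.66)

#' Binarize metric values within strata at a quantile cutoff
#'
#' Within each stratum (platform x subtype), values strictly above the
#' stratum's q-quantile (linear-interpolation quantile) are labeled high;
#' ties at the cutoff are low. Missing values yield missing labels.
#'
#' @param values numeric metric values.
#' @param q quantile in (0, 1).
#' @param strata stratum label per value.
#' @param min_stratum minimum non-missing values a stratum must carry.
#' @return character vector `"high"`/`"low"` (NA for missing input).
#' @export
binarize <- function(values, q, strata, min_stratum = 3L) {
  if (length(values) != length(strata))
    stopf("values and strata must have equal length")
  out <- rep(NA_character_, length(values))
  for (s in unique(strata)) {
    sel <- which(strata == s & !is.na(values))
    if (length(sel) < min_stratum)
      stopf("stratum '%s' has fewer than %d non-missing values", s,
            min_stratum)
    cut <- stats::quantile(values[sel], q, type = 7, names = FALSE)
    out[sel] <- ifelse(values[sel] > cut, "high", "low")
  }
  out
}

.logrank_p <- function(time, event, labels, min_arm = 5L, min_events = 3L) {
  ok <- !is.na(labels)
  time <- time[ok]; event <- event[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    return(list(p = NA_real_, reason = "single arm"))
  arm_n <- table(labels)
  if (any(arm_n < min_arm))
    return(list(p = NA_real_, reason = sprintf("arm below %d patients", min_arm)))
  arm_ev <- tapply(event, labels, sum)
  if (any(arm_ev < min_events))
    return(list(p = NA_real_, reason = sprintf("fewer than %d events per arm",
                                               min_events)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  ## direction: fewer observed than expected events in the high arm means
  ## high = better (longer survival)
  hi <- which(grepl("high", names(sd$n)))
  dir <- if (length(hi) == 1L && sd$obs[hi] < sd$exp[hi]) "high_better"
         else "high_worse"
  list(p = p, reason = NULL, direction = dir)
}

.endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(endpoint, c("OS", "RFS"))
  if (endpoint == "OS") c("os_time", "os_event") else c("rfs_time", "rfs_event")
}

#' Discovery scan over quantile cutoffs
#'
#' For each metric, binarizes the discovery cohort within platform x subtype
#' strata at each candidate quantile and computes the log-rank p-value.
#' Metrics whose best (minimum) p-value is below `alpha` are retained as
#' candidates, with the arg-min quantile frozen (exact ties resolved to the
#' median cutoff, 0.5). Metrics that cannot be tested (constant values,
#' small arms, too few events) are skipped with a reason.
#'
#' @param metrics data frame with `patient_id` and one column per metric.
#' @param clinical clinical data frame (`patient_id`, `platform`, `subtype`,
#'   endpoint columns).
#' @param endpoint `"OS"` or `"RFS"`.
#' @param quantiles candidate quantiles (default 0.33, 0.5, 0.66).
#' @param alpha retention threshold on the best p-value (default 0.05).
#' @param min_arm,min_events guards for any log-rank test.
#' @return data frame of candidates (`metric`, `endpoint`, `subtype`,
#'   `quantile`, `discovery_p`, `direction`); skipped metrics are reported
#'   in attribute `skipped`.
#' @export
discovery_scan <- function(metrics, clinical, endpoint = "OS",
                           quantiles = QUANTILE_SET, alpha = 0.05,
                           min_arm = 5L, min_events = 3L) {
  ec <- .endpoint_cols(endpoint)
  dat <- merge(clinical, metrics, by = "patient_id")
  strata <- paste(dat$platform, dat$subtype, sep = ":")
  subtype_lab <- if (length(unique(dat$subtype)) == 1L)
    unique(dat$subtype) else "all"
  metric_cols <- setdiff(names(metrics), "patient_id")
  cands <- list(); skipped <- list()
  for (m in metric_cols) {
    v <- dat[[m]]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) {
      skipped[[m]] <- "constant or missing metric"
      next
    }
    ps <- rep(NA_real_, length(quantiles))
    dirs <- rep(NA_character_, length(quantiles))
    reason <- NULL
    for (k in seq_along(quantiles)) {
      lab <- tryCatch(binarize(v, quantiles[k], strata),
                      error = function(e) conditionMessage(e))
      if (is.character(lab) && length(lab) == 1L) { reason <- lab; next }
      lr <- .logrank_p(dat[[ec[1]]], dat[[ec[2]]], lab, min_arm, min_events)
      if (is.null(lr$reason)) { ps[k] <- lr$p; dirs[k] <- lr$direction }
      else reason <- lr$reason
    }
    if (all(is.na(ps))) {
      skipped[[m]] <- reason %||% "untestable"
      next
    }
    best_p <- min(ps, na.rm = TRUE)
    if (best_p >= alpha) next
    winners <- which(!is.na(ps) & ps == best_p)
    qstar <- if (length(winners) > 1L && 0.5 %in% quantiles[winners]) 0.5
             else quantiles[winners[1L]]
    cands[[m]] <- data.frame(metric = m, endpoint = endpoint,
                             subtype = subtype_lab, quantile = qstar,
                             discovery_p = best_p,
                             direction = dirs[quantiles == qstar][1L],
                             stringsAsFactors = FALSE)
  }
  out <- if (length(cands)) do.call(rbind, cands) else
    data.frame(metric = character(0), endpoint = character(0),
               subtype = character(0), quantile = numeric(0),
               discovery_p = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Validate frozen candidates with Benjamini-Hochberg control
#'
#' Applies each candidate's frozen quantile within the validation cohort's
#' platform x subtype strata, computes the log-rank p-value, and adjusts
#' p-values with the Benjamini-Hochberg method over the candidate family
#' within each endpoint x subtype. The discovery and validation patient
#' sets must be disjoint.
#'
#' @param candidates data frame from [discovery_scan()].
#' @param metrics validation metric table.
#' @param clinical validation clinical table.
#' @param endpoint `"OS"` or `"RFS"`.
#' @param fdr_threshold significance threshold on the adjusted p (default
#'   0.05; 0.1 is used for neighborhood metrics).
#' @param discovery_ids optional patient ids used in discovery; overlap with
#'   the validation cohort aborts.
#' @return candidates with `validation_p`, `validation_fdr`, `significant`.
#' @export
validate <- function(candidates, metrics, clinical, endpoint = "OS",
                     fdr_threshold = 0.05, discovery_ids = NULL) {
  if (!is.null(discovery_ids)) {
    overlap <- intersect(discovery_ids, clinical$patient_id)
    if (length(overlap))
      stopf("discovery and validation cohorts overlap: %s",
            paste(utils::head(overlap, 5), collapse = ", "))
  }
  if (!nrow(candidates)) {
    candidates$validation_p <- numeric(0)
    candidates$validation_fdr <- numeric(0)
    candidates$significant <- logical(0)
    return(candidates)
  }
  ec <- .endpoint_cols(endpoint)
  dat <- merge(clinical, metrics, by = "patient_id")
  strata <- paste(dat$platform, dat$subtype, sep = ":")
  candidates$validation_p <- NA_real_
  for (i in seq_len(nrow(candidates))) {
    m <- candidates$metric[i]
    if (!m %in% names(dat)) next
    lab <- tryCatch(binarize(dat[[m]], candidates$quantile[i], strata),
                    error = function(e) NULL)
    if (is.null(lab)) next
    lr <- .logrank_p(dat[[ec[1]]], dat[[ec[2]]], lab)
    candidates$validation_p[i] <- lr$p
  }
  candidates$validation_fdr <- NA_real_
  fam <- paste(candidates$endpoint, candidates$subtype)
  for (f in unique(fam)) {
    sel <- which(fam == f & !is.na(candidates$validation_p))
    if (length(sel))
      candidates$validation_fdr[sel] <-
        stats::p.adjust(candidates$validation_p[sel], method = "BH")
  }
  candidates$significant <- !is.na(candidates$validation_fdr) &
    candidates$validation_fdr < fdr_threshold
  candidates
}

#' Multivariable Cox proportional-hazards confirmation
#'
#' Fits the endpoint on biomarker-high plus patient age, tumor size and
#' clinical stage (ordinal numeric by default). Patients with incomplete
#' covariates are dropped and counted. Degenerate designs (constant
#' covariates, monotone-likelihood separation) raise an error with a
#' diagnostic.
#'
#' @param biomarker_high `"high"`/`"low"` (or logical) label per clinical
#'   row.
#' @param clinical clinical data frame with `age_years`, `tumor_size`,
#'   `stage` and the endpoint columns.
#' @param endpoint `"OS"` or `"RFS"`.
#' @param stage_as_factor treat stage as categorical instead of ordinal
#'   numeric.
#' @return a `cph_result`: data frame (`variable`, `hr`, `lo95`, `hi95`,
#'   `p`), with `n_used` and `n_dropped` attributes.
#' @export
cph_multivariable <- function(biomarker_high, clinical, endpoint = "OS",
                              stage_as_factor = FALSE) {
  ec <- .endpoint_cols(endpoint)
  if (is.logical(biomarker_high))
    biomarker_high <- ifelse(biomarker_high, "high", "low")
  df <- data.frame(time = clinical[[ec[1]]], event = clinical[[ec[2]]],
                   biomarker = factor(biomarker_high, levels = c("low", "high")),
                   age = clinical$age_years, size = clinical$tumor_size,
                   stage = if (stage_as_factor) factor(clinical$stage)
                           else as.numeric(clinical$stage))
  complete <- stats::complete.cases(df)
  n_drop <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  for (v in c("age", "size")) {
    if (stats::sd(df[[v]]) == 0)
      stopf("degenerate covariate '%s' (constant); cannot fit CPH", v)
  }
  if (length(unique(df$biomarker)) < 2L)
    stopf("biomarker label is constant in the complete cases")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ biomarker + age + size +
                      stage, data = df),
    warning = function(w) stopf("CPH fit unstable: %s", conditionMessage(w)),
    error = function(e) stopf("CPH fit failed: %s", conditionMessage(e)))
  if (any(!is.finite(stats::coef(fit))) ||
      any(abs(stats::coef(fit)) > 15))
    stopf("CPH coefficients diverged (likely separation)")
  s <- summary(fit)
  out <- data.frame(variable = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lo95 = s$conf.int[, "lower .95"],
                    hi95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_used") <- nrow(df)
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("cph_result", class(out))
  out
}

#' @export
print.cph_result <- function(x, ...) {
  cat(sprintf("Multivariable CPH (n = %d, %d dropped)\n",
              attr(x, "n_used"), attr(x, "n_dropped")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Run the full discovery -> validation biomarker study
#'
#' Orchestrates the framework over one or more endpoints: quantile scan on
#' the discovery cohort, frozen-cutoff validation with Benjamini-Hochberg
#' control, multivariable CPH on FDR-passing candidates, and Kaplan-Meier
#' curve data for reporting. Discovery and validation patient sets must be
#' disjoint; the run is deterministic.
#'
#' @param config list with `metrics` (wide data frame), `clinical`,
#'   `discovery_ids`, `validation_ids`, optional `endpoints` (default OS and
#'   RFS), `quantiles`, `alpha`, `fdr_threshold` (default 0.05),
#'   `fdr_threshold_neighborhood` (default 0.1, applied to metrics whose
#'   name starts with `nbhood_`), `stage_as_factor`.
#' @return a `biomarker_report`: list with `candidates`, `validation`,
#'   `cph` (per passing candidate), `km` (curve data), `config_digest`.
#' @export
run_study <- function(config) {
  metrics <- config$metrics; clinical <- config$clinical
  endpoints <- config$endpoints %||% c("OS", "RFS")
  quantiles <- config$quantiles %||% QUANTILE_SET
  alpha <- config$alpha %||% 0.05
  fdr_main <- config$fdr_threshold %||% 0.05
  fdr_nb <- config$fdr_threshold_neighborhood %||% 0.1
  overlap <- intersect(config$discovery_ids, config$validation_ids)
  if (length(overlap))
    stopf("discovery and validation cohorts overlap (%d patients)",
          length(overlap))
  disc_clin <- clinical[clinical$patient_id %in% config$discovery_ids, ]
  val_clin <- clinical[clinical$patient_id %in% config$validation_ids, ]
  all_cand <- list(); all_val <- list(); cph_tabs <- list(); km <- list()
  for (ep in endpoints) {
    cand <- discovery_scan(metrics, disc_clin, endpoint = ep,
                           quantiles = quantiles, alpha = alpha)
    all_cand[[ep]] <- cand
    if (!nrow(cand)) { all_val[[ep]] <- validate(cand, metrics, val_clin, ep); next }
    is_nb <- grepl("^nbhood_", cand$metric)
    v <- validate(cand, metrics, val_clin, endpoint = ep,
                  fdr_threshold = fdr_main,
                  discovery_ids = config$discovery_ids)
    v$significant[is_nb] <- !is.na(v$validation_fdr[is_nb]) &
      v$validation_fdr[is_nb] < fdr_nb
    all_val[[ep]] <- v
    ec <- .endpoint_cols(ep)
    dat <- merge(val_clin, metrics, by = "patient_id")
    strata <- paste(dat$platform, dat$subtype, sep = ":")
    for (i in which(v$significant)) {
      lab <- tryCatch(binarize(dat[[v$metric[i]]], v$quantile[i], strata),
                      error = function(e) NULL)
      if (is.null(lab)) next
      key <- paste(ep, v$metric[i], sep = "|")
      if (all(c("age_years", "tumor_size", "stage") %in% names(dat))) {
        cph_tabs[[key]] <- tryCatch(
          cph_multivariable(lab, dat, endpoint = ep,
                            stage_as_factor = isTRUE(config$stage_as_factor)),
          error = function(e) conditionMessage(e))
      }
      sf <- survival::survfit(
        survival::Surv(dat[[ec[1]]], dat[[ec[2]]]) ~ lab)
      grp <- rep(sub("^lab=", "", names(sf$strata)), sf$strata)
      km[[key]] <- data.frame(time = sf$time, surv = sf$surv,
                              n_risk = sf$n.risk, group = grp,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(candidates = all_cand, validation = all_val,
                 cph = cph_tabs, km = km,
                 n_discovery = nrow(disc_clin),
                 n_validation = nrow(val_clin)),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("Biomarker study: %d discovery / %d validation patients\n",
              x$n_discovery, x$n_validation))
  for (ep in names(x$validation)) {
    v <- x$validation[[ep]]
    if (!nrow(v)) {
      cat(sprintf("%s: no candidates passed discovery\n", ep))
      next
    }
    cat(sprintf("%s: %d candidate(s), %d significant after BH\n",
                ep, nrow(v), sum(v$significant)))
    if (any(v$significant))
      print.data.frame(v[v$significant,
                         c("metric", "quantile", "discovery_p",
                           "validation_fdr", "direction")],
                       digits = 3, row.names = FALSE)
  }
  invisible(x)
}
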