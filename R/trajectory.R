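# Per-patient trajectory features and the descriptive/association analyses:
# a linear model of the complaint-to-diagnosis interval (days) and a logistic
# model of pre-diagnosis cognition-enhancing medication use.

age_group_levels <- c("<65", "65-74", "75-84", "85+")
location_levels <- c("primary_care", "geriatrics", "neurology", "other")
caregiver_group_levels <- c("husband", "wife", "daughter",
                            "other_adult_children", "other_family_support")
insurance_levels <- c("commercial", "medicare", "medicaid", "none")

age_group_at <- function(birth_year, date) {
  age <- as.integer(format(as.Date(date), "%Y")) - birth_year
  cut(age, breaks = c(-Inf, 64, 74, 84, Inf), labels = age_group_levels)
}

#' Build per-patient trajectory records
#'
#' One record per analysis patient: index dates, the interval in whole days,
#' the number of complaints (distinct note dates carrying a memory-loss SX
#' strictly before the diagnosis date), pre-diagnosis medication use (any
#' normalized cognition-enhancing order or RX mention strictly before the
#' diagnosis date), the departments of the first complaint and of the
#' diagnosis, age group at diagnosis, insurance, and the caregiver group
#' from the earliest caregiver mention (NA when absent, an expected state).
#'
#' @param cohort A `cohort_result` from [select_cohort()].
#' @param data The EHR bundle passed to [select_cohort()].
#' @param extractions Extraction table from [normalize_extractions()].
#' @param lexicons A `concept_lexicon` (for structured drug normalization).
#' @return Data frame of class `trajectory_records`.
#' @export
build_trajectories <- function(cohort, data, extractions,
                               lexicons = load_lexicons()) {
  ext_by <- split(extractions, extractions$patient_id)
  med_by <- split(data$medications, data$medications$patient_id)
  vis_by <- split(data$visits, data$visits$patient_id)
  pat <- data$patients
  ix_row <- match(cohort$analysis_ids, cohort$index_dates$patient_id)
  pat_row <- match(cohort$analysis_ids, pat$patient_id)
  rows <- lapply(seq_along(cohort$analysis_ids), function(k) {
    pid <- cohort$analysis_ids[k]
    ext <- ext_by[[pid]]
    c_date <- cohort$index_dates$first_complaint_date[ix_row[k]]
    d_date <- cohort$index_dates$first_dx_date[ix_row[k]]
    sx <- ext$label == "SX" & ext$canonical %in% memory_loss_concepts()
    sx_dates <- unique(as.Date(ext$note_date[sx]))
    n_complaints <- sum(sx_dates < d_date)
    med <- med_by[[pid]]
    prior_struct <- if (!is.null(med) && nrow(med)) {
      gen <- normalize_medication(med$drug, lexicons)
      any(gen != UNMAPPED & as.Date(med$date) < d_date)
    } else FALSE
    rx_note <- ext$label == "RX" & ext$canonical %in%
      c("donepezil", "memantine", "rivastigmine", "galantamine")
    prior_note <- any(rx_note & as.Date(ext$note_date) < d_date)
    # department of the first-complaint note / of the diagnosis event
    first_sx_rows <- ext[sx & as.Date(ext$note_date) == c_date, , drop = FALSE]
    complaint_loc <- first_sx_rows$department[1]
    dx_rows <- ext[ext$label == "DX" & as.Date(ext$note_date) == d_date, , drop = FALSE]
    dx_loc <- dx_rows$department[1]
    if (is.na(dx_loc)) {
      vis <- vis_by[[pid]]
      hit <- vis[as.Date(vis$date) == d_date, , drop = FALSE]
      dx_loc <- hit$department[1]
    }
    cg <- ext[ext$label == "CAREGIVER_RELATION", , drop = FALSE]
    caregiver_group <- NA_character_
    if (nrow(cg)) {
      cg <- cg[order(as.Date(cg$note_date)), , drop = FALSE]
      mapped <- cg$canonical[cg$canonical %in% names(caregiver_group_map)]
      if (length(mapped)) caregiver_group <- group_caregiver(mapped[1])
    }
    p <- pat[pat_row[k], ]
    data.frame(patient_id = pid,
               first_complaint_date = c_date,
               first_dx_date = d_date,
               interval_days = as.integer(d_date - c_date),
               n_complaints = n_complaints,
               prior_med = prior_struct || prior_note,
               complaint_location = ifelse(is.na(complaint_loc), "other", complaint_loc),
               dx_location = ifelse(is.na(dx_loc), "other", dx_loc),
               age_group = as.character(age_group_at(p$birth_year, d_date)),
               insurance = p$insurance,
               caregiver_group = caregiver_group,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no analysis patients")
  class(out) <- c("trajectory_records", "data.frame")
  out
}

#' Describe interval and complaint-count distributions
#'
#' Median and quartiles by the Tukey five-number method (hinges), with exact
#' min/max, for `interval_days` and `n_complaints`.
#'
#' @param records Trajectory records.
#' @return List with elements `interval_days` and `n_complaints`, each
#'   `c(min, q1, median, q3, max)`.
#' @export
describe_intervals <- function(records) {
  if (nrow(records) == 0) stop("no records")
  f <- function(x) {
    fv <- fivenum(x)
    c(min = fv[1], q1 = fv[2], median = fv[3], q3 = fv[4], max = fv[5])
  }
  list(interval_days = f(records$interval_days),
       n_complaints = f(records$n_complaints))
}

# Shared factor preparation with the analysis reference levels:
# age 85+, commercial insurance, primary care for both locations, husband.
prep_factors <- function(records) {
  df <- as.data.frame(records)
  df$age_group <- factor(df$age_group, levels = c("85+", setdiff(age_group_levels, "85+")))
  df$insurance <- factor(df$insurance, levels = insurance_levels)
  df$complaint_location <- factor(df$complaint_location, levels = location_levels)
  df$dx_location <- factor(df$dx_location, levels = location_levels)
  df$caregiver_group <- factor(df$caregiver_group,
                               levels = caregiver_group_levels)
  df
}

# Tidy per-level results with explicit reference rows.
tidy_association <- function(fit, df, terms, exponentiate = FALSE) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  rows <- list()
  for (tm in terms) {
    if (is.factor(df[[tm]])) {
      levs <- levels(droplevels(df[[tm]]))
      for (lv in levs) {
        nm <- paste0(tm, lv)
        if (lv == levs[1]) {
          rows[[length(rows) + 1]] <- data.frame(
            factor = tm, level = lv, estimate = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, statistic = NA_real_, p = NA_real_,
            reference = TRUE, stringsAsFactors = FALSE)
        } else if (nm %in% names(cf) && !is.na(cf[nm])) {
          est <- cf[nm]; s <- se[nm]
          chisq <- (est / s)^2
          lo <- est - 1.96 * s; hi <- est + 1.96 * s
          if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
          rows[[length(rows) + 1]] <- data.frame(
            factor = tm, level = lv, estimate = unname(est),
            ci_low = unname(lo), ci_high = unname(hi),
            statistic = unname(chisq),
            p = unname(pchisq(chisq, 1, lower.tail = FALSE)),
            reference = FALSE, stringsAsFactors = FALSE)
        }
      }
    } else {
      est <- cf[tm]; s <- se[tm]
      chisq <- (est / s)^2
      lo <- est - 1.96 * s; hi <- est + 1.96 * s
      if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
      rows[[length(rows) + 1]] <- data.frame(
        factor = tm, level = "", estimate = unname(est), ci_low = unname(lo),
        ci_high = unname(hi), statistic = unname(chisq),
        p = unname(pchisq(chisq, 1, lower.tail = FALSE)),
        reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(list(table = out, fit = fit, n = nrow(df)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> n =", x$n, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Linear model of the complaint-to-diagnosis interval
#'
#' Fits `interval_days` (untransformed, in days) on age group, primary
#' insurance, complaint location, diagnosis location and caregiver group,
#' with reference levels 85+, commercial, primary care (both locations) and
#' husband. Per-coefficient Wald chi-square tests and 95\% Wald CIs are
#' reported; reference levels carry no estimate. Records with missing
#' caregiver group are excluded (complete-case for that factor). Empty
#' factor levels are dropped with a warning.
#'
#' @param records Trajectory records.
#' @param include_caregiver Include the caregiver-group factor (complete
#'   cases only).
#' @param log_scale Model `log(interval_days)` instead of days.
#' @return An `association_result`.
#' @export
fit_interval_model <- function(records, include_caregiver = TRUE,
                               log_scale = FALSE) {
  df <- prep_factors(records)
  terms <- c("age_group", "insurance", "complaint_location", "dx_location")
  if (include_caregiver) {
    df <- df[!is.na(df$caregiver_group), , drop = FALSE]
    terms <- c(terms, "caregiver_group")
  }
  if (nrow(df) < 30) stop("need at least 30 complete records")
  for (tm in terms) {
    if (any(table(df[[tm]]) == 0)) {
      warning("dropping empty levels of ", tm)
      df[[tm]] <- droplevels(df[[tm]])
    }
  }
  y <- if (log_scale) log(df$interval_days) else df$interval_days
  df$.y <- y
  fit <- lm(reformulate(terms, ".y"), data = df)
  tidy_association(fit, df, terms, exponentiate = FALSE)
}

#' Logistic model of pre-diagnosis medication use
#'
#' Fits `prior_med` on age group, complaint location, diagnosis location,
#' caregiver group and the number of complaints; reports odds ratios
#' (exponentiated coefficients) with 95\% Wald CIs. Complete-case on the
#' caregiver factor. Stops if only one outcome class is present; complete
#' separation is flagged and refit with a small ridge penalty.
#'
#' @param records Trajectory records.
#' @param include_caregiver Include the caregiver-group factor.
#' @return An `association_result`; odds ratios in the `estimate` column.
#' @export
fit_medication_model <- function(records, include_caregiver = TRUE) {
  df <- prep_factors(records)
  terms <- c("age_group", "complaint_location", "dx_location")
  if (include_caregiver) {
    df <- df[!is.na(df$caregiver_group), , drop = FALSE]
    terms <- c(terms, "caregiver_group")
  }
  terms <- c(terms, "n_complaints")
  if (length(unique(df$prior_med)) < 2)
    stop("both outcome classes must be present (complete separation)")
  for (tm in setdiff(terms, "n_complaints")) {
    if (any(table(df[[tm]]) == 0)) {
      warning("dropping empty levels of ", tm)
      df[[tm]] <- droplevels(df[[tm]])
    }
  }
  fml <- reformulate(terms, "prior_med")
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    warning("possible complete separation; refitting with a ridge penalty")
    fit <- ridge_logistic(fml, df)
  }
  tidy_association(fit, df, terms, exponentiate = TRUE)
}

# Minimal ridge-penalized logistic fit (penalty on non-intercept terms)
# returning an object with coef/vcov methods compatible with tidy_association.
ridge_logistic <- function(formula, data, lambda = 1e-2) {
  X <- model.matrix(formula, data)
  y <- as.numeric(model.response(model.frame(formula, data)))
  pen <- rep(lambda, ncol(X)); pen[1] <- 0
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(pen * b^2) / 2
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    drop(crossprod(X, mu - y)) + pen * b
  }
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 500))
  b <- setNames(opt$par, colnames(X))
  mu <- plogis(drop(X %*% b))
  W <- mu * (1 - mu)
  H <- crossprod(X * W, X) + diag(pen)
  V <- solve(H)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = b, vcov = V, converged = TRUE),
            class = "ridge_logistic")
}

#' @export
coef.ridge_logistic <- function(object, ...) object$coefficients
#' @export
vcov.ridge_logistic <- function(object, ...) object$vcov

#' Write trajectory analysis outputs
#'
#' Writes `trajectories.csv`, `descriptives.json` and the two association
#' tables as JSON mirroring the factor/level/estimate/CI structure.
#'
#' @param records Trajectory records.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trajectory_report <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(records), file.path(dir, "trajectories.csv"),
            row.names = FALSE)
  desc <- describe_intervals(records)
  jsonlite::write_json(lapply(desc, as.list), file.path(dir, "descriptives.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list(interval_model = fit_interval_model(records)$table,
              medication_model = fit_medication_model(records)$table)
  jsonlite::write_json(res, file.path(dir, "association_models.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
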