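# Survival and motor-behavior inference with censoring-aware encodings.

#' Encode motor-task trials as survival records
#'
#' Translates task latencies with their cutoff semantics into
#' time-to-event records for proportional-hazards modeling. The modeled
#' event follows the task's direction of impairment:
#' \describe{
#'   \item{wirehang}{the event is a fall before the success cap; a trial
#'     reaching the cap (recorded as a success at the cap, 150 s by
#'     default) is censored.}
#'   \item{pole}{the event is a successful descent; a failure (recorded at
#'     the 120 s maximum, or a partial fall at its recorded time) is
#'     censored.}
#' }
#' Trial number and body weight ride along as covariates.
#'
#' @param trials A behavior table (see [generate_behavior()]).
#' @param task `"pole"` or `"wirehang"`.
#' @param caps Named cutoff times in seconds.
#' @return Tibble of survival records: `subject_id`, `time`, `event`
#'   (0/1), `group`, `sex`, `trial`, `weight_g`, `dpi`, `task`.
#' @export
encode_task <- function(trials, task = c("wirehang", "pole"),
                        caps = c(pole = 120, wirehang = 150)) {
  task <- match.arg(task)
  tr <- dplyr::filter(tibble::as_tibble(trials), .data$task == !!task)
  if (nrow(tr) == 0L) {
    stop_dbmcov(paste0("No trials for task ", task, "."), "dbmcov_encode_error")
  }
  cap <- caps[[task]]
  if (any(tr$latency_s > cap)) {
    stop_dbmcov(sprintf("Latency above the %gs cap for task %s: generator contract violated.",
                        cap, task), "dbmcov_encode_error")
  }
  event <- if (task == "wirehang") {
    as.integer(tr$outcome == "failure")
  } else {
    as.integer(tr$outcome == "success")
  }
  tibble::tibble(
    subject_id = tr$subject_id, time = tr$latency_s, event = event,
    group = tr$group, sex = tr$sex, trial = tr$trial,
    weight_g = tr$weight_g, dpi = tr$dpi, task = task
  )
}

#' Cox proportional-hazards fit for task or survival records
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios are
#' `exp(coef)`. At least one event is required; monotone likelihood
#' (separation) aborts with advice.
#'
#' @param records Survival records with `time`, `event` and covariates.
#' @param formula Model formula; the default tests the
#'   injection-group-by-sex interaction with trial number and weight as
#'   covariates.
#' @return Object of class `cox_fit` wrapping the `survival::coxph` fit,
#'   with a tidy coefficient table (`term`, `estimate`, `hazard_ratio`,
#'   `std.error`, `statistic`, `p.value`) and `n`, `n_event`.
#' @export
fit_cox <- function(records,
                    formula = survival::Surv(time, event) ~ group * sex + trial + weight_g) {
  records <- prepare_meta(records)
  y <- stats::model.response(stats::model.frame(formula, data = records))
  if (!survival::is.Surv(y)) {
    stop_dbmcov("`formula` must have a survival::Surv response.", "dbmcov_cox_error")
  }
  if (any(y[, "time"] <= 0)) {
    stop_dbmcov("Event/censoring times must be positive.", "dbmcov_cox_error")
  }
  if (sum(y[, "status"]) < 1) {
    stop_dbmcov("No events: every record is censored, the partial likelihood is empty.",
                "dbmcov_cox_error")
  }
  fit <- withCallingHandlers(
    survival::coxph(formula, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged before", conditionMessage(w))) {
        stop_dbmcov(paste0("Cox fit did not converge (possible separation / monotone likelihood): ",
                           conditionMessage(w),
                           " Consider penalization or pooling levels."),
                    "dbmcov_cox_error")
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  structure(
    list(
      model = fit,
      coefficients = tibble::tibble(
        term = rownames(sm), estimate = unname(sm[, "coef"]),
        hazard_ratio = exp(unname(sm[, "coef"])),
        std.error = unname(sm[, "se(coef)"]),
        statistic = unname(sm[, "z"]), p.value = unname(sm[, "Pr(>|z|)"])
      ),
      n = fit$n, n_event = fit$nevent, formula = deparse(formula)
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", x$formula, "|", x$n, "records,", x$n_event, "events\n")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @rdname fit_cox
#' @param object A `cox_fit`.
#' @export
glance.cox_fit <- function(object, ...) {
  fit <- object$model
  tibble::tibble(
    n = object$n, n_event = object$n_event,
    concordance = unname(fit$concordance["concordance"]),
    logLik = as.numeric(stats::logLik(fit)),
    p.value.lrt = pchisq(2 * diff(fit$loglik), df = sum(!is.na(coef(fit))),
                         lower.tail = FALSE)
  )
}

#' Survival analysis of humane-endpoint times
#'
#' Cox model of per-subject survival (humane endpoint as the event,
#' administrative censoring at the experimental endpoint) with the
#' group-by-sex interaction, plus Kaplan-Meier survivor curves per
#' sex-by-group cell.
#'
#' @param cohort Cohort scan table or per-subject table with
#'   `survival_dpi`, `event_flag`, `group`, `sex`.
#' @return List of class `survival_analysis`: `cox` (a `cox_fit`), `km`
#'   (tibble `group`, `sex`, `time`, `surv`, `n.risk`, `n.event`), and
#'   the underlying `survfit`.
#' @export
fit_survival <- function(cohort) {
  subj <- dplyr::distinct(
    tibble::as_tibble(cohort),
    .data$subject_id, .data$sex, .data$group,
    .data$survival_dpi, .data$event_flag
  )
  subj <- prepare_meta(subj)
  cox <- fit_cox(subj, survival::Surv(survival_dpi, event_flag) ~ group * sex)
  sf <- survival::survfit(
    survival::Surv(survival_dpi, event_flag) ~ group + sex, data = subj
  )
  strata_names <- rep(names(sf$strata), sf$strata)
  km <- tibble::tibble(
    stratum = strata_names, time = sf$time, surv = sf$surv,
    n.risk = sf$n.risk, n.event = sf$n.event
  ) |>
    tidyr::separate_wider_delim("stratum", delim = ", ",
                                names = c("group", "sex")) |>
    dplyr::mutate(group = sub("group=", "", .data$group),
                  sex = sub("sex=", "", .data$sex))
  structure(list(cox = cox, km = km, survfit = sf), class = "survival_analysis")
}

#' @export
print.survival_analysis <- function(x, ...) {
  print(x$cox)
  invisible(x)
}

#' Plot Kaplan-Meier survivor curves
#'
#' @param object A [fit_survival()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_analysis <- function(object, ...) {
  km0 <- object$km |>
    dplyr::group_by(.data$group, .data$sex) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1, n.risk = max(.x$n.risk), n.event = 0), .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(km0, ggplot2::aes(x = .data$time, y = .data$surv,
                                    color = .data$group, linetype = .data$sex)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days post-injection", y = "survival",
                  title = "Kaplan-Meier survivor curves") +
    ggplot2::theme_minimal()
}

#' Longitudinal mixed model for weight or rotarod performance
#'
#' The voxel-wise random-intercept engine applied to a single series:
#' `measure ~ group * sex * dpi + (1 | subject_id)`, with rotarod
#' latencies first averaged across the three trials at each timepoint.
#' `dpi_coding = "quadratic"` adds `dpi^2` and its interactions, which
#' captures inverted-U weight trajectories.
#'
#' @param data Cohort scan table (for `measure = "weight"`) or behavior
#'   table (for `measure = "rotarod"`).
#' @param measure `"weight"` or `"rotarod"`.
#' @param dpi_coding `"linear"` or `"quadratic"`.
#' @return A tibble of model terms (`term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`).
#' @export
fit_longitudinal_lme <- function(data, measure = c("weight", "rotarod"),
                                 dpi_coding = c("linear", "quadratic")) {
  measure <- match.arg(measure)
  dpi_coding <- match.arg(dpi_coding)
  data <- tibble::as_tibble(data)
  if (measure == "weight") {
    dat <- dplyr::distinct(data, .data$subject_id, .data$sex, .data$group,
                           .data$dpi, .data$weight_g)
    dat$response <- dat$weight_g
  } else {
    dat <- data |>
      dplyr::filter(.data$task == "rotarod") |>
      dplyr::group_by(.data$subject_id, .data$sex, .data$group, .data$dpi) |>
      dplyr::summarise(response = mean(.data$latency_s), .groups = "drop")
    if (nrow(dat) == 0L) {
      stop_dbmcov("No rotarod trials in `data`.", "dbmcov_lme_error")
    }
  }
  if (dplyr::n_distinct(dat$subject_id) < 2L) {
    stop_dbmcov("At least 2 subjects required.", "dbmcov_lme_error")
  }
  fixed <- if (dpi_coding == "quadratic") {
    dat$dpi2 <- dat$dpi^2
    ~ group * sex * (dpi + dpi2)
  } else {
    ~ group * sex * dpi
  }
  fit <- fit_voxelwise_lme(matrix(dat$response, nrow = 1), meta = dat, fixed = fixed)
  dplyr::select(fit$table, -"voxel")
}

#' Motor-onset general linear model
#'
#' Ordinary least squares on the motor-onset day among symptomatic mice:
#' `onset_dpi ~ group * sex`. Terms whose cells are empty (e.g. no
#' symptomatic control mice) are dropped with a warning, and single-mouse
#' cells flag the standard errors as unreliable.
#'
#' @param cohort Cohort scan table or per-subject table with
#'   `motor_onset_dpi`.
#' @return A `glm_result` (see [subject_weight_glm()]).
#' @export
motor_onset_glm <- function(cohort) {
  subj <- dplyr::distinct(tibble::as_tibble(cohort), .data$subject_id,
                          .data$sex, .data$group, .data$motor_onset_dpi) |>
    dplyr::filter(!is.na(.data$motor_onset_dpi))
  if (nrow(subj) == 0L) {
    stop_dbmcov("No symptomatic mice: motor-onset model is empty.",
                "dbmcov_onset_error")
  }
  subj <- prepare_meta(subj)
  subj$group <- droplevels(subj$group)
  subj$sex <- droplevels(subj$sex)
  cell <- table(subj$group, subj$sex)
  if (any(cell == 1)) {
    warn("Cells with a single symptomatic mouse: standard errors unreliable.",
         class = "dbmcov_small_cells")
  }
  rhs <- c(if (nlevels(subj$group) > 1) "group", if (nlevels(subj$sex) > 1) "sex")
  form <- if (length(rhs) == 2 && all(cell > 0)) {
    motor_onset_dpi ~ group * sex
  } else {
    if (length(rhs) < 2 || any(cell == 0)) {
      warn("Empty cells; reduced motor-onset model fitted.",
           class = "dbmcov_empty_cell")
    }
    as.formula(paste("motor_onset_dpi ~",
                     if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
  }
  mod <- lm(form, data = subj)
  sm <- summary(mod)$coefficients
  ds <- tibble::tibble(contrast = character(), d = numeric(), variant = character())
  if (nlevels(subj$sex) > 1 && all(table(subj$sex) >= 2)) {
    ds <- tibble::tibble(
      contrast = "sex_M_minus_F",
      d = as.numeric(cohens_d(subj$motor_onset_dpi[subj$sex == "M"],
                              subj$motor_onset_dpi[subj$sex == "F"])),
      variant = "pooled"
    )
  }
  structure(
    list(model = mod,
         coefficients = tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                                       std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
                                       p.value = unname(sm[, 4])),
         cohens_d = ds, formula = deparse(form)),
    class = "glm_result"
  )
}

#' Bonferroni correction
#'
#' Significance under `p < alpha / m` (strict inequality at the boundary)
#' with adjusted p-values `min(1, m * p)`. The study-scale default is
#' `m = 8` (two cutoff-limited motor tasks at four timepoints).
#'
#' @param p P-values.
#' @param m Number of comparisons (> 0).
#' @param alpha Family-wise error level.
#' @return Tibble `p`, `p_adjusted`, `significant`.
#' @export
bonferroni <- function(p, m = 8, alpha = 0.05) {
  if (m <= 0) stop_dbmcov("`m` must be positive.", "dbmcov_bonferroni_error")
  tibble::tibble(p = p, p_adjusted = pmin(1, m * p), significant = p < alpha / m)
}
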