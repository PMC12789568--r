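#' Stratify a cohort by the triple IHC marker rule
#'
#' A patient carries the uncommon-TME phenotype when CD68 and CD163 are
#' strictly above their cut points and CD40LG is at or below its cut point
#' (CD68-high / CD163-high / CD40LG-low). Default cut points are the
#' per-marker cohort medians; explicit cut points can be supplied as a named
#' vector `c(CD68=, CD163=, CD40LG=)`. Patients missing a marker are
#' excluded with a warning.
#'
#' @param cohort data.frame with columns `patient_id`, `CD68`, `CD163`,
#'   `CD40LG`.
#' @param cutpoints optional named cut-point vector; `NULL` = medians.
#' @return list with `groups` (patient_id, group) and `cutpoints` used.
#' @export
stratify <- function(cohort, cutpoints = NULL) {
  req <- c("patient_id", "CD68", "CD163", "CD40LG")
  stop_if_not(all(req %in% names(cohort)), "cohort lacks column(s): ",
              paste(setdiff(req, names(cohort)), collapse = ", "))
  ok <- stats::complete.cases(cohort[, c("CD68", "CD163", "CD40LG")])
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) excluded for missing marker scores",
            call. = FALSE)
  }
  co <- cohort[ok, , drop = FALSE]
  if (is.null(cutpoints)) {
    cutpoints <- c(CD68 = stats::median(co$CD68),
                   CD163 = stats::median(co$CD163),
                   CD40LG = stats::median(co$CD40LG))
  }
  stop_if_not(all(c("CD68", "CD163", "CD40LG") %in% names(cutpoints)),
              "cutpoints must be named over CD68, CD163, CD40LG")
  grp <- ifelse(co$CD68 > cutpoints[["CD68"]] &
                  co$CD163 > cutpoints[["CD163"]] &
                  co$CD40LG <= cutpoints[["CD40LG"]],
                "uncommon_TME", "other")
  list(groups = data.frame(patient_id = co$patient_id, group = grp,
                           stringsAsFactors = FALSE),
       cutpoints = cutpoints)
}

endpoint_columns <- function(endpoint) {
  endpoint <- match.arg(tolower(endpoint), c("efs", "os"))
  list(time = paste0(endpoint, "_days"), event = paste0(endpoint, "_event"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the Mantel-Haenszel
#' log-rank test (hypergeometric variance; tied event times share one risk
#' set). With no censoring the estimate equals the empirical survival
#' function.
#'
#' @param cohort patient data.frame with `<endpoint>_days` and
#'   `<endpoint>_event` columns.
#' @param groups data.frame (patient_id, group) as from [stratify()], with
#'   exactly two groups represented.
#' @param endpoint `"efs"` or `"os"`.
#' @return list with `curves` (group, time, n_risk, n_event, n_censor,
#'   survival), `observed`, `expected` (first group), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(cohort, groups, endpoint = "efs") {
  cols <- endpoint_columns(endpoint)
  df <- merge(cohort, groups, by = "patient_id")
  lv <- sort(unique(df$group))
  stop_if_not(length(lv) == 2, "need exactly two groups, found ", length(lv))
  for (g in lv) stop_if_not(sum(df$group == g) > 0, "empty group ", g)
  time <- df[[cols$time]]; event <- df[[cols$event]]
  stop_if_not(sum(event) >= 1, "no events observed")

  curves <- do.call(rbind, lapply(lv, function(g) {
    tt <- time[df$group == g]; ee <- event[df$group == g]
    ut <- sort(unique(tt[ee == 1]))
    if (length(ut) == 0) {
      return(data.frame(group = g, time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), n_censor = integer(0),
                        survival = numeric(0)))
    }
    n_risk <- vapply(ut, function(t) sum(tt >= t), 0)
    n_event <- vapply(ut, function(t) sum(tt == t & ee == 1), 0)
    n_censor <- vapply(ut, function(t) sum(tt == t & ee == 0), 0)
    data.frame(group = g, time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor,
               survival = cumprod(1 - n_event / n_risk))
  }))

  is1 <- df$group == lv[1]
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    n_j <- sum(time >= t)
    n1_j <- sum(time >= t & is1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & is1)
    O1 <- O1 + d1_j
    E1 <- E1 + d_j * n1_j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  list(curves = curves, groups = lv, observed = O1, expected = E1,
       chisq = chisq, df = 1, p = p)
}

#' Fisher exact test of relapse by group
#'
#' Two-sided Fisher exact test on the relapse x group 2x2 table.
#' Zero-margin tables report p = 1 with a warning.
#'
#' @param cohort patient data.frame with a binary `relapse` column.
#' @param groups data.frame (patient_id, group).
#' @return list with `table`, `odds_ratio`, `p`.
#' @export
relapse_test <- function(cohort, groups) {
  df <- merge(cohort, groups, by = "patient_id")
  stop_if_not(!anyNA(df$relapse), "relapse flags missing")
  tab <- table(group = df$group, relapse = factor(df$relapse,
                                                  levels = c(1, 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p set to 1", call. = FALSE)
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Multivariate Cox regression of group and covariates
#'
#' Partial-likelihood fit via [survival::coxph()] behind a thin contract:
#' the group indicator plus any covariate columns enter additively; hazard
#' ratios with Wald confidence intervals are returned per term.
#' Non-convergence or inestimable coefficients raise an error.
#'
#' @param cohort patient data.frame.
#' @param groups data.frame (patient_id, group).
#' @param covariates character vector of cohort column names.
#' @param endpoint `"efs"` or `"os"`.
#' @param ties tie-handling method passed to the fitter; Efron (default) is
#'   the better approximation, Breslow makes the fit exactly invariant to
#'   duplicating subjects.
#' @return data.frame: term, hr, lower95, upper95, p.
#' @export
cox_multivariate <- function(cohort, groups, covariates = character(),
                             endpoint = "efs", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cols <- endpoint_columns(endpoint)
  df <- merge(cohort, groups, by = "patient_id")
  stop_if_not(sum(df[[cols$event]]) >= length(covariates) + 1,
              "too few events for the number of covariates")
  for (cv in covariates) {
    stop_if_not(cv %in% names(df), "covariate '", cv, "' absent from cohort")
    stop_if_not(length(unique(df[[cv]])) > 1,
                "covariate '", cv, "' is constant")
  }
  df$group <- factor(df$group, levels = sort(unique(df$group)))
  fm <- stats::as.formula(paste0(
    "survival::Surv(", cols$time, ", ", cols$event, ") ~ ",
    paste(c("group", covariates), collapse = " + ")
  ))
  fit <- tryCatch(
    survival::coxph(fm, data = df, ties = ties),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE)
  )
  if (anyNA(stats::coef(fit))) {
    stop("Cox fit produced inestimable coefficients", call. = FALSE)
  }
  sm <- summary(fit)
  data.frame(
    term = rownames(sm$coefficients),
    hr = sm$conf.int[, "exp(coef)"],
    lower95 = sm$conf.int[, "lower .95"],
    upper95 = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
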