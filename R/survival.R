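# Clinical-relevance utilities: Kaplan-Meier estimates, k-group log-rank
# tests and proportional-hazards summaries, wrapping the survival package.

#' Kaplan-Meier estimates and k-group log-rank test
#'
#' Product-limit estimates per group and the k-group log-rank chi-square
#' statistic with k-1 degrees of freedom.
#'
#' @param times positive follow-up times.
#' @param events event indicators in `{0,1}`.
#' @param groups group labels (>= 1 subject per group).
#' @return List with `per_group` (n, events, median survival), `chisq`,
#'   `df`, `p`, and the underlying [survival::survfit()] object (`fit`).
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("every group needs at least one subject and >= 2 groups")
  df_surv <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           data = df_surv)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups,
                            data = df_surv)
  df <- nlevels(groups) - 1L
  chisq <- unname(sd_$chisq)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(levels(groups),
                                                       names(tab)))
  per_group <- data.frame(group = sub("^groups=", "", rownames(tab)),
                          n = tab[, "records"],
                          events = tab[, "events"],
                          median = tab[, "median"],
                          row.names = NULL)
  list(per_group = per_group, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE), fit = fit)
}

#' Univariate and adjusted Cox proportional-hazards summaries
#'
#' Complete-case partial-likelihood fits with Efron tie handling (Breslow
#' selectable). Each covariate is fitted alone (univariate) and jointly with
#' the others plus any adjustment covariates (multivariate). Convergence or
#' separation warnings are captured and flagged.
#'
#' @param times,events survival outcome.
#' @param covariates data frame of covariates of interest.
#' @param adjust optional data frame of adjustment covariates
#'   (multivariate model only).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List with `univariate` and `multivariate` data frames (term,
#'   hr, lower95, upper95, loghr, se, p), `n_used`, `n_dropped`, `flags`.
#' @export
cox_fit <- function(times, events, covariates, adjust = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  dat <- data.frame(.time = times, .event = events, covariates)
  if (!is.null(adjust)) dat <- cbind(dat, as.data.frame(adjust))
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  flags <- character(0)
  fit_one <- function(terms) {
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(terms, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = ties),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               lower95 = s$conf.int[, "lower .95"],
               upper95 = s$conf.int[, "upper .95"],
               loghr = s$coefficients[, "coef"],
               se = s$coefficients[, "se(coef)"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }
  uni <- do.call(rbind, lapply(names(covariates), fit_one))
  multi_terms <- c(names(covariates),
                   if (!is.null(adjust)) names(as.data.frame(adjust)))
  multi <- fit_one(multi_terms)
  list(univariate = uni, multivariate = multi,
       n_used = nrow(dat), n_dropped = n_dropped,
       ties = ties, flags = unique(flags))
}
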