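#' Immunohistochemistry product score
#'
#' The final IHC score is staining intensity (none 0, weak 1, moderate 2,
#' strong 3) times the positive-cell percentage bin (1-25% -> 1, 26-50% ->
#' 2, 51-75% -> 3, 76-100% -> 4), dichotomized as low (0-4) versus high
#' (5-12).
#'
#' @param intensity Integer vector in `0:3`.
#' @param percentage_bin Integer vector in `1:4`.
#' @return A tibble: `intensity`, `percentage_bin`, `score`, `category`.
#' @export
#' @examples
#' ihc_score(2, 2)  # score 4 -> low
#' ihc_score(3, 2)  # score 6 -> high
ihc_score <- function(intensity, percentage_bin) {
  if (!all(intensity %in% 0:3)) {
    stop("intensity must be in 0..3", call. = FALSE)
  }
  if (!all(percentage_bin %in% 1:4)) {
    stop("percentage_bin must be in 1..4", call. = FALSE)
  }
  n <- max(length(intensity), length(percentage_bin))
  intensity <- rep_len(as.integer(intensity), n)
  percentage_bin <- rep_len(as.integer(percentage_bin), n)
  score <- intensity * percentage_bin
  tibble::tibble(
    intensity = intensity,
    percentage_bin = percentage_bin,
    score = score,
    category = ifelse(score <= 4, "low", "high")
  )
}

#' Tie-corrected Spearman association for an ordinal contingency table
#'
#' Expands a (expression category x ordinal clinical variable) contingency
#' table to per-patient ordinal pairs - expression coded low (0) < high
#' (1), clinical levels in the ascending order given - assigns midranks
#' within ties, and returns the Pearson correlation of the midranks
#' (Spearman's rs) with a two-sided p-value from the t approximation
#' `t = rs * sqrt(n - 2) / sqrt(1 - rs^2)` on `n - 2` degrees of freedom.
#'
#' @param table Tibble with one row per ascending clinical level and
#'   columns `high` and `low` holding patient counts.
#' @return A one-row tibble: `n`, `rs`, `statistic`, `p_value`.
#' @export
#' @examples
#' spearman_ordinal(tibble::tibble(level = c("T1", "T2", "T3"),
#'                                 high = c(0, 2, 28), low = c(1, 11, 37)))
spearman_ordinal <- function(table) {
  stopifnot(all(c("high", "low") %in% names(table)))
  if (nrow(table) < 2) stop("need at least two clinical levels", call. = FALSE)
  lv <- seq_len(nrow(table))
  clin <- rep(lv, times = table$high + table$low)
  expr <- unlist(lapply(lv, function(i) {
    rep(c(1L, 0L), times = c(table$high[i], table$low[i]))
  }))
  n <- length(clin)
  if (length(unique(clin)) < 2 || length(unique(expr)) < 2) {
    stop("zero variance in a margin; association undefined", call. = FALSE)
  }
  rs <- cor(rank(expr), rank(clin))
  stat <- rs * sqrt((n - 2) / (1 - rs^2))
  tibble::tibble(n = n, rs = rs, statistic = stat,
                 p_value = 2 * pt(-abs(stat), n - 2))
}

#' Associations between expression category and several clinical variables
#'
#' Applies [spearman_ordinal()] per variable of a stacked contingency
#' table. Rows with missing level (recorded as `"Null"` or `NA`) are
#' excluded listwise per variable.
#'
#' @param table Tibble with columns `variable`, `level` (ascending within
#'   variable), `high`, `low`.
#' @return A tibble with one row per variable: `variable`, `n`, `rs`,
#'   `p_value`.
#' @export
ihc_association_table <- function(table) {
  stopifnot(all(c("variable", "level", "high", "low") %in% names(table)))
  table |>
    dplyr::filter(!is.na(.data$level), .data$level != "Null") |>
    dplyr::group_by(variable = factor(.data$variable,
                                      levels = unique(.data$variable))) |>
    dplyr::group_modify(function(d, key) {
      spearman_ordinal(d)[, c("n", "rs", "p_value")]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = as.character(.data$variable))
}

#' Bundled IHC/stage contingency table
#'
#' CDCP1 IHC expression category (low/high) cross-tabulated against age
#' group, histological grade and T/N/M/TNM stage for a 79-patient
#' ovarian-cancer tissue-microarray cohort.
#'
#' @return Tibble with columns `variable`, `level`, `high`, `low`.
#' @export
ihc_cohort_table <- function() {
  path <- system.file("extdata", "ihc_stage_table.tsv", package = "evscope")
  readr::read_tsv(path, col_types = "ccii")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per stratum, right-censoring handled (fitted via
#' the survival package).
#'
#' @param records Tibble with columns `time`, `event` (1 = event,
#'   0 = censored) and optionally `stratum`.
#' @return A tibble: `stratum`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)), nrow(records) >= 1,
            all(records$time >= 0))
  if (!"stratum" %in% names(records)) records$stratum <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ stratum,
    data = records
  )
  strata <- if (is.null(fit$strata)) {
    rep(unique(records$stratum), length(fit$time))
  } else {
    rep(sub("^stratum=", "", names(fit$strata)), fit$strata)
  }
  tibble::tibble(
    stratum = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
}

#' Log-rank comparison of two survival strata
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times (hypergeometric variance, no continuity correction), with a
#' 1-df chi-square p-value.
#'
#' @param records Tibble with columns `time`, `event`, `stratum` (two
#'   strata).
#' @return A one-row tibble: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  stopifnot(all(c("time", "event", "stratum") %in% names(records)))
  if (length(unique(records$stratum)) != 2) {
    stop("exactly two strata are required", call. = FALSE)
  }
  if (sum(records$event) < 1) stop("at least one event is required", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ stratum, data = records, rho = 0
  )
  tibble::tibble(
    chisq = sd$chisq, df = 1,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Fit an ELISA standard curve
#'
#' Fits either a four-parameter logistic (4PL)
#' `OD = d + (a - d) / (1 + (conc / c)^b)` or a linear model in
#' log10-concentration to the calibrator points. Standards must respond
#' monotonically in concentration.
#'
#' @param standards Tibble with columns `concentration` (> 0) and `od`.
#' @param method `"4pl"` (default) or `"loglinear"`.
#' @return An object of class `elisa_curve`.
#' @export
elisa_standard_curve <- function(standards, method = c("4pl", "loglinear")) {
  method <- match.arg(method)
  stopifnot(all(c("concentration", "od") %in% names(standards)))
  s <- dplyr::arrange(standards, .data$concentration)
  if (nrow(s) < 3) stop("need at least 3 standards", call. = FALSE)
  if (any(s$concentration <= 0)) stop("standard concentrations must be > 0", call. = FALSE)
  d_od <- diff(s$od)
  if (!(all(d_od > 0) || all(d_od < 0))) {
    stop("standards must respond monotonically", call. = FALSE)
  }

  if (method == "4pl") {
    # a = zero-concentration asymptote, d = saturation asymptote (b > 0)
    start <- list(
      a = s$od[1] - sign(d_od[1]) * 1e-3,
      b = 1,
      cc = exp(mean(log(s$concentration))),
      d = s$od[nrow(s)] + sign(d_od[1]) * 1e-3
    )
    fit <- minpack.lm::nlsLM(
      od ~ d + (a - d) / (1 + (concentration / cc)^b),
      data = s, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    pars <- as.list(coef(fit))
  } else {
    fit <- stats::lm(od ~ log10(concentration), data = s)
    pars <- list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  }
  structure(
    list(method = method, pars = pars, standards = s, fit = fit),
    class = "elisa_curve"
  )
}

#' Read sample concentrations off an ELISA standard curve
#'
#' Inverts the fitted standard curve at each sample OD. ODs outside the
#' quantifiable range (beyond the 4PL asymptotes, or outside the standard
#' OD span for the log-linear fit) get `NA` with an explanatory flag.
#'
#' @param curve An `elisa_curve`, or a standards tibble (then a 4PL curve
#'   is fitted first).
#' @param od Numeric vector of sample optical densities.
#' @return A tibble: `od`, `concentration`, `flag` (`"ok"`,
#'   `"above_range"`, `"below_range"`).
#' @export
elisa_readout <- function(curve, od) {
  if (!inherits(curve, "elisa_curve")) curve <- elisa_standard_curve(curve)
  p <- curve$pars
  if (curve$method == "4pl") {
    lo <- min(p$a, p$d); hi <- max(p$a, p$d)
    s <- curve$standards
    increasing <- s$od[1] < s$od[nrow(s)]
    flag <- dplyr::case_when(
      od >= hi ~ if (increasing) "above_range" else "below_range",
      od <= lo ~ if (increasing) "below_range" else "above_range",
      TRUE ~ "ok"
    )
    conc <- ifelse(flag == "ok",
                   p$cc * ((p$a - od) / (od - p$d))^(1 / p$b),
                   NA_real_)
  } else {
    rng <- range(curve$standards$od)
    flag <- dplyr::case_when(
      od > rng[2] ~ "above_range",
      od < rng[1] ~ "below_range",
      TRUE ~ "ok"
    )
    conc <- ifelse(flag == "ok", 10^((od - p$intercept) / p$slope), NA_real_)
  }
  tibble::tibble(od = od, concentration = conc, flag = flag)
}
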