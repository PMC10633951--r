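#' Body-weight bins used in the attainment analysis
#'
#' Ten bins partitioning the adult weight line above 40 kg. The published
#' bin labels overlap ambiguously ("60-70" followed by "71-80", "91-100"
#' followed by "100-110"); the convention here partitions the line while
#' reproducing the printed integer counts: \[40,60), \[60,70\], then
#' left-open right-closed decades up to (140, Inf).
#'
#' @return A `data.frame` with columns `label`, `lower`, `upper` and the
#'   boundary convention columns `lower_closed`, `upper_closed`.
#' @export
weight_bins <- function() {
  data.frame(
    label = c("< 60", "60-70", "71-80", "81-90", "91-100", "100-110",
              "110-120", "120-130", "130-140", "> 140"),
    lower = c(40, 60, 70, 80, 90, 100, 110, 120, 130, 140),
    upper = c(60, 70, 80, 90, 100, 110, 120, 130, 140, Inf),
    lower_closed = c(TRUE, TRUE, rep(FALSE, 8)),
    upper_closed = c(FALSE, rep(TRUE, 8), FALSE)
  )
}

#' Assign weights to bins
#'
#' @param weights Body weights in kg (> 40).
#' @return An integer vector of bin indices into [weight_bins()].
#' @examples
#' bins <- weight_bins()
#' bins$label[assign_bins(c(59.9, 70, 70.5, 141))]
#' @export
assign_bins <- function(weights) {
  if (any(weights <= 40)) stop("weights must exceed the 40 kg adult floor")
  # [40,60) -> 1; [60,70] -> 2; (70,80] -> 3; ...; (140,Inf) -> 10
  ifelse(weights < 60, 1L,
         2L + findInterval(weights, c(70, 80, 90, 100, 110, 120, 130, 140),
                           left.open = TRUE))
}

#' Tabulate attainment by weight bin
#'
#' @param attained Logical vector: did each patient attain the target?
#' @param weights Matching body weights in kg.
#' @return A `data.frame` of class `weight_bin_table` with columns `label`,
#'   `n_fail`, `n_attain` (one row per bin, zeros for unoccupied bins).
#' @export
weight_bin_table <- function(attained, weights) {
  stopifnot(is.logical(attained), length(attained) == length(weights))
  idx <- assign_bins(weights)
  bins <- weight_bins()
  out <- data.frame(
    label = bins$label,
    n_fail = vapply(seq_len(nrow(bins)),
                    function(b) sum(idx == b & !attained), integer(1)),
    n_attain = vapply(seq_len(nrow(bins)),
                      function(b) sum(idx == b & attained), integer(1))
  )
  class(out) <- c("weight_bin_table", "data.frame")
  out
}

#' Construct a weight-bin table from counts
#'
#' @param label Bin labels.
#' @param n_fail,n_attain Non-negative integer counts per bin.
#' @return A `weight_bin_table`.
#' @export
weight_counts <- function(label, n_fail, n_attain) {
  stopifnot(length(label) == length(n_fail),
            length(label) == length(n_attain),
            all(n_fail >= 0), all(n_attain >= 0))
  out <- data.frame(label = label, n_fail = as.numeric(n_fail),
                    n_attain = as.numeric(n_attain))
  class(out) <- c("weight_bin_table", "data.frame")
  out
}

#' Reference weight-bin attainment counts
#'
#' The published 10,000-patient attainment-by-weight table from the study
#' this package reimplements (failures / attainers per bin). Used to
#' validate the risk-ratio arithmetic against the printed results.
#'
#' @return A `weight_bin_table` with 10 rows summing to 10,000 patients.
#' @export
reference_weight_counts <- function() {
  weight_counts(
    label = weight_bins()$label,
    n_fail = c(828, 384, 147, 33, 3, 8, 8, 13, 4, 9),
    n_attain = c(1142, 1924, 2088, 1545, 968, 511, 230, 92, 42, 21)
  )
}

#' Risk ratio of target non-attainment: rest of cohort vs one bin
#'
#' With failure (not attaining the target) as the outcome and the chosen
#' bin as the reference group, the risk ratio is
#' `RR = (F - f_b) / (N - n_b) / (f_b / n_b)` where `f_b`, `n_b` are the
#' bin's failures and size and `F`, `N` the table totals. The 95% CI is the
#' Wald interval on the log scale with
#' `SE = sqrt(1/f_rest - 1/n_rest + 1/f_b - 1/n_b)`, and the p value comes
#' from the Wald z statistic. This orientation (bin as denominator)
#' reproduces the published unadjusted RRs.
#'
#' @param table A `weight_bin_table`.
#' @param bin Bin index or label.
#' @param conf_level Confidence level, default 0.95.
#' @return A `data.frame` with `label`, `rr`, `ci_low`, `ci_high`, `se_log`,
#'   `p`.
#' @examples
#' rr_vs_rest(reference_weight_counts(), "71-80")  # RR 2.526 (2.144-2.976)
#' @export
rr_vs_rest <- function(table, bin, conf_level = 0.95) {
  stopifnot(inherits(table, "weight_bin_table"))
  if (is.character(bin)) bin <- match(bin, table$label)
  stopifnot(!is.na(bin), bin >= 1, bin <= nrow(table))
  f_b <- table$n_fail[bin]
  n_b <- table$n_fail[bin] + table$n_attain[bin]
  f_r <- sum(table$n_fail) - f_b
  n_r <- sum(table$n_fail + table$n_attain) - n_b
  if (f_b < 1 || f_r < 1) {
    stop("undefined risk ratio: zero failures in bin '", table$label[bin],
         "' or in the rest of the cohort")
  }
  rr <- (f_r / n_r) / (f_b / n_b)
  se <- sqrt(1 / f_r - 1 / n_r + 1 / f_b - 1 / n_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(label = table$label[bin], rr = rr,
             ci_low = exp(log(rr) - z * se),
             ci_high = exp(log(rr) + z * se),
             se_log = se,
             p = 2 * stats::pnorm(-abs(log(rr) / se)))
}

#' Risk ratios for every computable bin
#'
#' @param table A `weight_bin_table`.
#' @param conf_level Confidence level.
#' @return A `data.frame` with one row per bin; bins with zero failures (in
#'   the bin or its complement) carry `NA` and a note in `flag`.
#' @export
rr_table <- function(table, conf_level = 0.95) {
  rows <- lapply(seq_len(nrow(table)), function(b) {
    res <- tryCatch(rr_vs_rest(table, b, conf_level), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(label = table$label[b], rr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, se_log = NA_real_, p = NA_real_,
                 flag = "undefined (zero failures)")
    } else {
      cbind(res, flag = "")
    }
  })
  do.call(rbind, rows)
}

#' Per-patient attainment from a simulated scenario
#'
#' Applies an attainment rule to a scenario's per-patient metrics and
#' tabulates the result by weight bin. The default rule follows the
#' package's headline classification: a patient attains iff the 72-h
#' summary metric is in range (`"horizon"`); `"day3"` uses the day-3 daily
#' metric instead.
#'
#' @param cohort The `virtual_cohort` the scenario was run on.
#' @param scenario A `pta_summary` from [run_scenario()] on that cohort.
#' @param rule `"horizon"` or `"day3"`.
#' @return A list with `attained` (logical per patient) and `table`
#'   (a `weight_bin_table` whose totals equal the cohort size).
#' @export
attainment_from_simulation <- function(cohort, scenario,
                                       rule = c("horizon", "day3")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "virtual_cohort"),
            inherits(scenario, "pta_summary"),
            nrow(cohort) == scenario$n)
  attained <- if (rule == "horizon") scenario$metrics$attained_horizon
              else scenario$metrics$attained_day3
  list(attained = attained,
       table = weight_bin_table(attained, cohort$weight_kg))
}

#' Log-binomial regression risk ratios
#'
#' Fits a binomial GLM with a log link by maximum likelihood; the
#' exponentiated coefficients are risk ratios. On a single two-level
#' covariate this agrees with the closed-form 2x2 risk ratio. Log-link
#' binomial fits can fail to converge (fitted risks near 1); failures are
#' reported and, for a single binary covariate, the closed-form 2x2
#' estimate is returned as a fallback.
#'
#' @param outcome Logical/0-1 vector (1 = event).
#' @param design A `data.frame` of covariates (factors or indicators); an
#'   intercept-only model when omitted.
#' @param conf_level Confidence level.
#' @return A `data.frame` with one row per non-intercept coefficient:
#'   `term`, `rr`, `ci_low`, `ci_high`, `p`, `converged`, plus an attribute
#'   `baseline_risk` (the exponentiated intercept). Intercept-only fits
#'   return zero rows with the baseline risk attribute set.
#' @examples
#' set.seed(1)
#' g <- rep(c(0, 1), each = 200)
#' y <- rbinom(400, 1, ifelse(g == 1, 0.5, 0.25))
#' log_binomial_fit(y, data.frame(g = g))
#' @export
log_binomial_fit <- function(outcome, design = NULL, conf_level = 0.95) {
  y <- as.integer(as.logical(outcome))
  stopifnot(any(y == 1), any(y == 0))
  df <- if (is.null(design) || ncol(as.data.frame(design)) == 0) {
    data.frame(y = y)
  } else {
    cbind(data.frame(y = y), as.data.frame(design))
  }
  form <- if (ncol(df) == 1L) y ~ 1 else y ~ .
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, family = stats::binomial("log"),
                                data = df,
                                start = .log_binomial_start(df))),
    error = function(e) NULL)
  converged <- !is.null(fit) && isTRUE(fit$converged)

  if (!converged) {
    # closed-form 2x2 fallback for a single binary covariate
    fallback <- .rr_2x2_fallback(df, conf_level)
    if (!is.null(fallback)) return(fallback)
    stop("log-binomial fit failed to converge and no 2x2 fallback applies")
  }

  est <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- setdiff(rownames(est), "(Intercept)")
  out <- data.frame(
    term = keep,
    rr = exp(est[keep, "Estimate"]),
    ci_low = exp(est[keep, "Estimate"] - z * est[keep, "Std. Error"]),
    ci_high = exp(est[keep, "Estimate"] + z * est[keep, "Std. Error"]),
    p = unname(est[keep, "Pr(>|z|)"]),
    converged = rep(TRUE, length(keep)),
    row.names = NULL
  )
  attr(out, "baseline_risk") <- unname(exp(est["(Intercept)", "Estimate"]))
  out
}

.log_binomial_start <- function(df) {
  p <- max(min(mean(df$y), 0.99), 0.01)
  k <- ncol(stats::model.matrix(
    if (ncol(df) == 1L) y ~ 1 else y ~ ., df))
  c(log(p) - 1e-4, rep(0, k - 1L))
}

.rr_2x2_fallback <- function(df, conf_level) {
  covs <- df[setdiff(names(df), "y")]
  if (ncol(covs) != 1L) return(NULL)
  g <- covs[[1L]]
  lv <- sort(unique(g))
  if (length(lv) != 2L) return(NULL)
  y <- df$y
  f0 <- sum(y[g == lv[1L]]); n0 <- sum(g == lv[1L])
  f1 <- sum(y[g == lv[2L]]); n1 <- sum(g == lv[2L])
  if (f0 < 1 || f1 < 1) return(NULL)
  rr <- (f1 / n1) / (f0 / n0)
  se <- sqrt(1 / f1 - 1 / n1 + 1 / f0 - 1 / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = paste0(names(covs), lv[2L]), rr = rr,
                    ci_low = exp(log(rr) - z * se),
                    ci_high = exp(log(rr) + z * se),
                    p = 2 * stats::pnorm(-abs(log(rr) / se)),
                    converged = FALSE)
  attr(out, "baseline_risk") <- f0 / n0
  out
}
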