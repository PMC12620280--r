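#' Expressor binning of cohort expression values
#'
#' Partitions non-negative log2(CPM+1) values into the four cohort bins:
#' exact zeros (`zero`), `(0, 0.5]` (`low_nonexpr`), `(0.5, 2]`
#' (`expressor_low`) and `(2, Inf)` (`expressor_high`). The first two bins
#' are the non-expressors, the last two the expressors. Boundaries are
#' left-open / right-closed.
#'
#' @param values Non-negative numeric vector.
#' @return Factor of bin labels with attributes `counts`, `fractions` and
#'   `expressor` (logical vector).
#' @export
bin_expressors <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  labels <- c("zero", "low_nonexpr", "expressor_low", "expressor_high")
  bin <- cut(values, breaks = c(-Inf, 0, 0.5, 2, Inf), labels = labels,
             right = TRUE)
  counts <- table(bin)
  structure(bin,
            counts = counts,
            fractions = counts / sum(counts),
            expressor = bin %in% c("expressor_low", "expressor_high"))
}

#' Kruskal-Wallis group association with Dunn's pairwise post-hoc test
#'
#' The omnibus test is the tie-corrected Kruskal-Wallis H
#' (via [stats::kruskal.test()]); pairwise comparisons use Dunn's z test on
#' mean ranks with the pooled tie correction, Holm-adjusted. When every value
#' is tied across all groups the omnibus result is H = 0, p = 1 (not an
#' error).
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 non-empty groups).
#' @return List: `H`, `df`, `p`, `pairwise` (data.frame `group_a`, `group_b`,
#'   `z`, `p`, `p_adj`).
#' @export
group_association <- function(values, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  stopifnot(length(values) == length(groups), !anyNA(values))

  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  # Dunn's pooled variance term with tie correction
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)

  if (all(values == values[1])) {
    H <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(values, groups)
    H <- unname(kw$statistic); p <- kw$p.value
  }
  z <- p_pair <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(s2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p_pair[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                         z = z, p = p_pair,
                         p_adj = stats::p.adjust(p_pair, method = "holm"),
                         stringsAsFactors = FALSE)
  list(H = H, df = nlevels(groups) - 1L, p = p, pairwise = pairwise)
}

#' Rank genes by Pearson correlation with a target expression profile
#'
#' Correlates each row of an expression matrix against a target vector over
#' samples, with two-sided t-distribution p-values and BH q-values, sorted by
#' decreasing r. Zero-variance genes have undefined correlation; they are
#' reported with `r = NA` at the bottom and excluded from ranking and the
#' multiplicity correction.
#'
#' @param target Numeric vector (one value per sample).
#' @param expr Gene x sample numeric matrix with matching columns.
#' @return data.frame `gene`, `r`, `p`, `q`, `rank` (NA for zero-variance
#'   genes).
#' @export
correlation_rank <- function(target, expr) {
  stopifnot(is.matrix(expr), length(target) == ncol(expr))
  n <- length(target)
  if (n < 3L) stop("need >= 3 samples")
  if (stats::sd(target) == 0) stop("target has zero variance")
  r <- suppressWarnings(as.vector(stats::cor(t(expr), target)))
  ok <- !is.na(r)
  tstat <- r * sqrt((n - 2) / (1 - pmin(r^2, 1)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[ok & abs(r) >= 1] <- 0
  q <- rep(NA_real_, length(r))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = rownames(expr), r = r, p = p, q = q,
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$r), -out$r), ]
  out$rank <- ifelse(is.na(out$r), NA_integer_, seq_len(nrow(out)))
  out$rank[!is.na(out$r)] <- seq_len(sum(!is.na(out$r)))
  rownames(out) <- NULL
  out
}

#' Extract the top and bottom correlated genes
#'
#' @param ranked Output of [correlation_rank()].
#' @param n_top,n_bottom How many genes from each end (ranked genes only).
#' @return data.frame subset with an `end` column (`"top"`/`"bottom"`).
#' @export
correlation_extremes <- function(ranked, n_top = 10L, n_bottom = 2L) {
  ok <- ranked[!is.na(ranked$r), ]
  top <- utils::head(ok, n_top); top$end <- "top"
  bot <- utils::tail(ok, n_bottom); bot$end <- "bottom"
  rbind(top, bot)
}

#' Apply transplant censoring to survival records
#'
#' Records with a transplant date earlier than the observed time are censored
#' at the transplant date (the allo-HSCT censoring rule).
#'
#' @param time,event Observed time (days) and event indicator.
#' @param transplant_time Transplant day or NA.
#' @return data.frame `time`, `event` after censoring.
#' @export
censor_at_transplant <- function(time, event, transplant_time) {
  stopifnot(length(time) == length(event))
  cut <- !is.na(transplant_time) & transplant_time < time
  data.frame(time = ifelse(cut, transplant_time, time),
             event = ifelse(cut, FALSE, as.logical(event)))
}

#' Median split of an expression vector
#'
#' Dichotomizes at the cohort median; values exactly at the median go to the
#' `"high"` group (deterministic tie rule).
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  m <- stats::median(values)
  factor(ifelse(values >= m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test between strata
#'
#' Product-limit curves per stratum (after applying transplant censoring when
#' `transplant_time` is supplied) and the log-rank test across strata. With
#' no events the test is undefined and `p` is NA.
#'
#' @param time,event Survival time (days) and event indicator.
#' @param strata Stratum label per record (every stratum non-empty).
#' @param transplant_time Optional transplant day per record (NA = none).
#' @return List: `fit` ([survival::survfit] object), `chisq`, `df`, `p`,
#'   `n_events`.
#' @export
km_logrank <- function(time, event, strata, transplant_time = NULL) {
  strata <- as.factor(strata)
  if (any(table(strata) == 0L)) stop("empty stratum")
  if (!is.null(transplant_time)) {
    cens <- censor_at_transplant(time, event, transplant_time)
    time <- cens$time; event <- cens$event
  }
  stopifnot(all(time > 0))
  df <- data.frame(time = time, event = as.integer(event), strata = strata)
  fit <- survival::survfit(survival::Surv(time, event) ~ strata, data = df)
  n_events <- sum(df$event)
  if (n_events == 0L || nlevels(strata) < 2L) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(strata) - 1L,
                p = NA_real_, n_events = n_events))
  }
  lr <- survival::survdiff(survival::Surv(time, event) ~ strata, data = df)
  p <- stats::pchisq(lr$chisq, df = nlevels(strata) - 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(lr$chisq), df = nlevels(strata) - 1L,
       p = p, n_events = n_events)
}

#' Multivariable proportional-hazards model
#'
#' Cox partial-likelihood fit (Efron tie handling) over the requested
#' covariates, reporting hazard ratios with Wald 95% confidence intervals
#' and p-values. Constant covariates are an error; non-convergence and
#' suspected complete separation (|coef| extremely large) are flagged.
#'
#' @param data data.frame with columns `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param transplant_time Optional transplant day per record.
#' @return data.frame: `covariate`, `coef`, `HR`, `ci_lower`, `ci_upper`,
#'   `p`, `flagged`.
#' @export
ph_multivariable <- function(data, covariates, transplant_time = NULL) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (!is.null(transplant_time)) {
    cens <- censor_at_transplant(data$time, data$event, transplant_time)
    data$time <- cens$time; data$event <- cens$event
  }
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) stop("constant covariate: ", cv)
  }
  if (sum(data$event) < length(covariates)) {
    stop("fewer events (", sum(data$event), ") than covariates (",
         length(covariates), ")")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence != 0)) {
    stop("proportional-hazards fit did not converge")
  }
  s <- summary(fit)
  co <- s$coefficients
  data.frame(
    covariate = rownames(co),
    coef = co[, "coef"],
    HR = exp(co[, "coef"]),
    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    flagged = abs(co[, "coef"]) > 15,  # likely separation
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Relative quantitation by the delta-delta-Ct method
#'
#' `RQ = 2^-((ct_target - ct_control) - (ct_target_ref - ct_control_ref))`,
#' i.e. fold change of the target gene relative to an endogenous control
#' gene and a reference sample.
#'
#' @param ct_target,ct_control Ct of target and endogenous control gene in
#'   the sample of interest.
#' @param ct_target_ref,ct_control_ref Same pair in the reference sample.
#' @return Relative quantity (vectorized).
#' @export
ddct <- function(ct_target, ct_control, ct_target_ref, ct_control_ref) {
  stopifnot(all(is.finite(c(ct_target, ct_control,
                            ct_target_ref, ct_control_ref))))
  2^-((ct_target - ct_control) - (ct_target_ref - ct_control_ref))
}

#' Spike-normalized percent-of-total across gradient fractions
#'
#' Each fraction's signal is normalized to its spike-in, then expressed as a
#' percentage of the summed normalized signal; output sums to 100.
#'
#' @param signal Signal per fraction.
#' @param spike Spike-in signal per fraction (all > 0).
#' @return Numeric vector of percentages summing to 100.
#' @export
fraction_distribution <- function(signal, spike) {
  stopifnot(length(signal) == length(spike))
  if (any(spike <= 0)) {
    stop("non-positive spike in fraction(s): ",
         paste(which(spike <= 0), collapse = ", "))
  }
  norm <- signal / spike
  100 * norm / sum(norm)
}
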