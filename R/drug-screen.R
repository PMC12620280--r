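#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom)/(1 + (c/ic50)^hill)`
#' (Levenberg-Marquardt via minpack.lm). For inhibition data that rises with
#' dose the fitted `hill` is negative under this parameterization. Flat or
#' non-convergent data give `fit_ok = FALSE`.
#'
#' @param conc Concentrations (strictly positive, same unit throughout).
#' @param response Response at each concentration (% inhibition).
#' @return List: `bottom`, `top`, `ic50`, `hill`, `fit_ok`.
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("non-positive concentration")
  if (length(conc) < 4L) stop("need >= 4 dose points")
  if (stats::sd(response) < 1e-9) {
    return(list(bottom = mean(response), top = mean(response),
                ic50 = NA_real_, hill = NA_real_, fit_ok = FALSE))
  }
  df <- data.frame(c = conc, y = response)
  mid <- (max(response) + min(response)) / 2
  ic50_0 <- conc[which.min(abs(response - mid))]
  try_fit <- function(hill0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (c / ic50)^hill),
        data = df,
        start = list(bottom = min(response), top = max(response),
                     ic50 = ic50_0, hill = hill0),
        lower = c(-Inf, -Inf, min(conc) / 1e4, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  best <- NULL
  for (h0 in c(-1, 1, -3, 3)) {
    fit <- try_fit(h0)
    if (is.null(fit)) next
    if (is.null(best) ||
        sum(stats::resid(fit)^2) < sum(stats::resid(best)^2)) best <- fit
  }
  if (is.null(best)) {
    return(list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, fit_ok = FALSE))
  }
  cf <- stats::coef(best)
  # orient so 'top' is the high-dose asymptote side-agnostically
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]), fit_ok = TRUE)
}

#' Drug sensitivity score from a dose-response curve
#'
#' Normalized area of the fitted inhibition curve above an activity
#' threshold, over the log10 concentration range of the plate, scaled to
#' 0..100: 0 means no activity above the threshold anywhere, 100 complete
#' inhibition over the whole range. Degenerate or unfittable curves fall
#' back to a trapezoidal area over the observed responses (so a constant
#' 100% inhibition plate scores exactly 100 and a constant 0% plate 0); a
#' warning is emitted when a non-flat curve could not be fitted.
#'
#' @param conc Concentrations (strictly positive).
#' @param response % inhibition at each concentration.
#' @param activity_threshold Baseline activity level (% inhibition) below
#'   which response does not count (default 10).
#' @return DSS in `[0, 100]`.
#' @export
dss <- function(conc, response, activity_threshold = 10) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("non-positive concentration")
  o <- order(conc)
  conc <- conc[o]; response <- response[o]
  x <- log10(conc)
  xr <- range(x)
  if (diff(xr) == 0) stop("need more than one distinct concentration")
  t0 <- activity_threshold
  norm_area <- function(fy) {
    # fy: function of x returning % inhibition
    val <- stats::integrate(function(z) pmax(0, fy(z) - t0), xr[1], xr[2],
                            subdivisions = 500L, rel.tol = 1e-9)$value
    min(100, max(0, 100 * val / ((100 - t0) * diff(xr))))
  }
  flat <- stats::sd(response) < 1e-9
  fit <- if (flat) list(fit_ok = FALSE) else fit_4pl(conc, response)
  if (!fit$fit_ok) {
    if (!flat) warning("unfittable dose-response curve; using observed points")
    fy <- stats::approxfun(x, response, rule = 2)
    return(norm_area(fy))
  }
  fy <- function(z) fit$bottom + (fit$top - fit$bottom) /
    (1 + (10^z / fit$ic50)^fit$hill)
  norm_area(fy)
}

#' Differential drug-sensitivity screen between two groups
#'
#' Averages replicate responses per drug, group and concentration, scores
#' each group's curve with [dss()], and reports the selective score
#' `sdss = DSS(group_a) - DSS(group_b)` per drug with the `|sdss| >=
#' threshold` filter. Drugs present in only one group are excluded with a
#' warning. The sign convention (group_a minus group_b) is recorded in the
#' result.
#'
#' @param plates data.frame with columns `drug`, `group`, `conc_uM`,
#'   `response`, `replicate`.
#' @param group_a,group_b Group labels (defaults KO and WT).
#' @param threshold Selectivity filter (default 1).
#' @param activity_threshold Passed to [dss()].
#' @return data.frame sorted by decreasing `|sdss|`: `drug`, `dss_a`,
#'   `dss_b`, `sdss`, `passes_filter`; attribute `direction` documents the
#'   sign convention.
#' @export
sdss_screen <- function(plates, group_a = "KO", group_b = "WT",
                        threshold = 1.0, activity_threshold = 10) {
  need <- c("drug", "group", "conc_uM", "response")
  stopifnot(all(need %in% names(plates)))
  drugs <- sort(unique(plates$drug))
  rows <- list()
  for (d in drugs) {
    pd <- plates[plates$drug == d, ]
    if (!all(c(group_a, group_b) %in% pd$group)) {
      warning("drug '", d, "' missing a group; excluded")
      next
    }
    score <- function(grp) {
      pg <- pd[pd$group == grp, ]
      avg <- stats::aggregate(response ~ conc_uM, data = pg, FUN = mean)
      dss(avg$conc_uM, avg$response, activity_threshold)
    }
    da <- score(group_a); db <- score(group_b)
    rows[[d]] <- data.frame(drug = d, dss_a = da, dss_b = db,
                            sdss = da - db,
                            passes_filter = abs(da - db) >= threshold,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug = character(0), dss_a = numeric(0),
                      dss_b = numeric(0), sdss = numeric(0),
                      passes_filter = logical(0))
  }
  out <- out[order(-abs(out$sdss)), ]
  rownames(out) <- NULL
  attr(out, "direction") <- sprintf("sdss = DSS(%s) - DSS(%s)",
                                    group_a, group_b)
  out
}
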