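test_that("expressor bins use left-open right-closed boundaries", {
  b <- bin_expressors(c(0, 0.4, 0.5, 2, 2.0001, 2.5))
  expect_equal(as.character(b),
               c("zero", "low_nonexpr", "low_nonexpr", "expressor_low",
                 "expressor_high", "expressor_high"))
  expect_equal(attr(b, "expressor"),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(bin_expressors(c(1, -0.1)), ">= 0")
  # every non-negative value gets exactly one bin
  set.seed(2)
  v <- c(0, rexp(500, 1))
  bb <- bin_expressors(v)
  expect_false(anyNA(bb))
  expect_equal(sum(attr(bb, "counts")), length(v))
  expect_equal(sum(attr(bb, "fractions")), 1)
})

test_that("Kruskal-Wallis + Dunn agree with oracles", {
  # all tied -> H = 0, p = 1, not an error
  tied <- group_association(rep(3.3, 9), rep(c("a", "b", "c"), 3))
  expect_equal(tied$H, 0)
  expect_equal(tied$p, 1)
  # two groups: KW p equals the two-sided normal-approximation Wilcoxon p
  set.seed(5)
  x <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  res <- group_association(x, g)
  w <- stats::wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE,
                          correct = FALSE)
  expect_equal(res$p, w$p.value, tolerance = 1e-10)
  # 3 x 4 fixture: H matches the hand-computed rank formula
  vals <- c(2.1, 3.5, 1.2, 4.4,  5.0, 6.1, 5.5, 7.2,  0.3, 2.8, 1.9, 3.1)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  res3 <- group_association(vals, grp)
  r <- rank(vals); N <- length(vals)
  H_hand <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(z) length(z) * mean(z)^2)) - 3 * (N + 1)
  expect_equal(res3$H, H_hand, tolerance = 1e-12)
  expect_equal(nrow(res3$pairwise), 3L)
  expect_equal(res3$pairwise$p_adj,
               stats::p.adjust(res3$pairwise$p, "holm"))
  expect_error(group_association(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("correlation ranking matches the covariance formula", {
  set.seed(9)
  target <- rnorm(5)
  expr <- rbind(same = target, anti = -target,
                noise1 = rnorm(5), noise2 = rnorm(5),
                flat = rep(2, 5))
  colnames(expr) <- paste0("s", 1:5)
  res <- correlation_rank(target, expr)
  expect_equal(res$gene[1], "same")
  expect_equal(res$r[1], 1)
  ranked <- res[!is.na(res$r), ]
  expect_equal(ranked$gene[nrow(ranked)], "anti")
  expect_equal(ranked$r[nrow(ranked)], -1)
  # textbook formula on a 5-point vector
  x <- expr["noise1", ]
  r_hand <- sum((x - mean(x)) * (target - mean(target))) /
    sqrt(sum((x - mean(x))^2) * sum((target - mean(target))^2))
  expect_equal(res$r[res$gene == "noise1"], r_hand, tolerance = 1e-12)
  # zero-variance gene excluded from ranking, reported as NA
  expect_true(is.na(res$r[res$gene == "flat"]))
  expect_true(is.na(res$rank[res$gene == "flat"]))
  ext <- correlation_extremes(res, n_top = 1, n_bottom = 1)
  expect_equal(ext$gene, c("same", "anti"))
  expect_error(correlation_rank(target[1:2], expr[, 1:2]), ">= 3")
})

test_that("KM product-limit fixture and log-rank edge cases", {
  # 4 subjects, events at t=1 and t=2, no censoring
  km <- km_logrank(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                   rep("all", 4) , transplant_time = NULL)
  s <- summary(km$fit, times = c(1, 2))
  expect_equal(s$surv, c(0.75, 0.5))
  expect_true(is.na(km$p))  # single stratum: no test
  # no events at all -> curves at 1, p NA
  km0 <- km_logrank(c(5, 6, 7, 8), rep(FALSE, 4), rep(c("a", "b"), 2))
  expect_true(all(km0$fit$surv == 1))
  expect_true(is.na(km0$p))
  # identical strata -> p ~ 1
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km1 <- km_logrank(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_gt(km1$p, 0.99)
  expect_error(km_logrank(tm, ev, factor(rep("a", 6), levels = c("a", "b"))),
               "empty stratum")
})

test_that("transplant censoring rewrites time and event", {
  cens <- censor_at_transplant(time = c(100, 200, 300),
                               event = c(TRUE, TRUE, FALSE),
                               transplant_time = c(NA, 150, 400))
  expect_equal(cens$time, c(100, 150, 300))
  expect_equal(cens$event, c(TRUE, FALSE, FALSE))
  # feeding it through km_logrank shifts the curve
  km <- km_logrank(c(100, 200, 300), c(TRUE, TRUE, FALSE),
                   rep("all", 3), transplant_time = c(NA, 150, 400))
  expect_equal(km$n_events, 1L)
})

test_that("median split rule sends exact-median values high", {
  v <- c(1, 2, 3, 4, 5)
  ms <- median_split(v)
  expect_equal(as.character(ms), c("low", "low", "high", "high", "high"))
  expect_equal(sum(ms == "high"), 3L)  # ceiling(n/2) for odd n, no ties
  v2 <- c(1, 2, 3, 4)
  expect_equal(sum(median_split(v2) == "high"), 2L)
})

test_that("proportional-hazards fit matches a grid-search partial likelihood", {
  # 5 subjects, one binary covariate, no tied event times
  d <- data.frame(time = c(2, 4, 5, 7, 9),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  x = c(1, 0, 1, 1, 0))
  fit <- ph_multivariable(d, "x")
  grid <- seq(-4, 4, by = 1e-4)
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(d$event)) {
      risk <- d$time >= d$time[i]
      ll <- ll + b * d$x[i] - log(sum(exp(b * d$x[risk])))
    }
    ll
  }, numeric(1))
  b_grid <- grid[which.max(loglik)]
  expect_equal(fit$coef, b_grid, tolerance = 1e-3)
  expect_equal(fit$HR, exp(fit$coef))
  # identical event patterns in both levels -> HR ~ 1
  d2 <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                   event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                   x = rep(c(0, 1), each = 4))
  expect_equal(ph_multivariable(d2, "x")$HR, 1, tolerance = 1e-6)
  expect_error(ph_multivariable(data.frame(time = 1:3, event = c(TRUE, TRUE,
                                                                 FALSE),
                                           x = c(1, 1, 1)), "x"),
               "constant covariate")
})

test_that("PH Wald p-values are uniform under the null", {
  p_vals <- vapply(1:150, function(r) {
    d <- simulate_survival(120, beta = 0, seed = 9000 + r)
    ph_multivariable(d, c("group", "age"))$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(p_vals, "punif")$p.value, 0.01)
})

test_that("ddct follows the 2^-ddCt rule", {
  expect_equal(ddct(20, 18, 22, 20), 1)    # ddCt = 0
  expect_equal(ddct(21, 18, 22, 20), 0.5)  # ddCt = 1
  expect_equal(ddct(18, 18, 22, 20), 4)    # ddCt = -2
  expect_equal(ddct(c(20, 21), c(18, 18), 22, 20), c(1, 0.5))
  expect_error(ddct(NA, 1, 2, 3), "finite")
})

test_that("fraction distributions renormalize to exactly 100", {
  equal <- fraction_distribution(rep(5, 13), rep(2, 13))
  expect_equal(equal, rep(100 / 13, 13))
  # doubling one fraction's spike halves its pre-normalization share
  s <- c(10, 10); sp <- c(1, 2)
  out <- fraction_distribution(s, sp)
  expect_equal(out[2] / out[1], 0.5)
  expect_error(fraction_distribution(c(1, 2), c(1, 0)), "fraction")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:13, 1)
    out <- fraction_distribution(runif(n, 0, 50), runif(n, 0.5, 3))
    expect_equal(sum(out), 100, tolerance = 1e-9)
  }
})
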