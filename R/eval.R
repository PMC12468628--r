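# Stratified evaluation battery: per-lesion metric errors, group-wise MAE
# and mean tables, box statistics, and paired Wilcoxon signed-rank tests.

#' Per-lesion evaluation records
#'
#' Computes plan-quality metrics for predicted and ground-truth dose
#' volumes, signed errors (predicted minus truth, with coverage in
#' percentage points), absolute errors, isodose Dice scores at the 100%
#' and 50% levels, and the collimator-derived volume group.
#'
#' @param predictions named list of predicted normalized dose arrays.
#' @param truth_spaces list of [TumorSpace-class] with matching ids.
#' @param bounds volume-group boundaries, default [volumeGroupBounds()].
#' @return data.frame with one row per lesion.
#' @export
evaluatePredictions <- function(predictions, truth_spaces,
                                bounds = volumeGroupBounds()) {
  ids <- vapply(truth_spaces, function(s) s@lesion_id, character(1))
  if (!setequal(names(predictions), ids) ||
      length(predictions) != length(truth_spaces))
    stop("prediction and truth lesion ids do not match")
  rows <- lapply(truth_spaces, function(sp) {
    pred <- predictions[[sp@lesion_id]]
    vv <- voxelVolume(sp@spacing_mm)
    tum <- sp@input_mask == 2L
    mt <- planMetrics(sp@dose_norm, tum, vv)
    mp <- planMetrics(pred, tum, vv)
    vals <- function(m) c(coverage = 100 * m@coverage,
                          selectivity = m@selectivity, gi = m@gi,
                          ci50 = m@ci50)
    vt <- vals(mt)
    vp <- vals(mp)
    err <- vp - vt
    data.frame(lesion_id = sp@lesion_id, tv_mm3 = mt@tv_mm3,
               group = volumeGroup(mt@tv_mm3, bounds),
               metric = names(vt), truth = unname(vt), pred = unname(vp),
               error = unname(err), abs_error = abs(unname(err)),
               dsc_100 = isodoseDSC(pred, sp@dose_norm, 1.0),
               dsc_50 = isodoseDSC(pred, sp@dose_norm, 0.5),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Group-stratified mean absolute error table
#'
#' @param records data.frame from [evaluatePredictions()].
#' @return data.frame of MAE +/- SD per metric and volume group, plus the
#'   overall column.
#' @export
maeTable <- function(records) {
  agg <- function(sub) c(mae = mean(sub$abs_error), sd = sd(sub$abs_error))
  out <- list()
  for (m in unique(records$metric)) {
    rm_ <- records[records$metric == m, ]
    for (grp in c(sort(unique(rm_$group)), "all")) {
      sub <- if (grp == "all") rm_ else rm_[rm_$group == grp, ]
      a <- agg(sub)
      out[[length(out) + 1L]] <- data.frame(metric = m, group = grp,
                                            mae = a[["mae"]],
                                            sd = a[["sd"]],
                                            n = nrow(sub))
    }
  }
  do.call(rbind, out)
}

#' Group-stratified mean metric values
#'
#' Mean +/- SD of the ground-truth and predicted metric values per volume
#' group (the trend-level comparison table).
#'
#' @param records data.frame from [evaluatePredictions()].
#' @return data.frame in long format.
#' @export
meanValueTable <- function(records) {
  out <- list()
  for (m in unique(records$metric)) {
    rm_ <- records[records$metric == m, ]
    for (grp in c(sort(unique(rm_$group)), "all")) {
      sub <- if (grp == "all") rm_ else rm_[rm_$group == grp, ]
      out[[length(out) + 1L]] <-
        data.frame(metric = m, group = grp,
                   truth_mean = mean(sub$truth), truth_sd = sd(sub$truth),
                   pred_mean = mean(sub$pred), pred_sd = sd(sub$pred),
                   n = nrow(sub))
    }
  }
  do.call(rbind, out)
}

#' Box-plot statistics of a sample
#'
#' Median, mean, quartiles, whiskers extending to the furthest points
#' within 1.5 x IQR of the quartiles, and the outliers beyond them.
#'
#' @param x numeric vector.
#' @return list with `median`, `mean`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high` and `outliers`.
#' @export
boxStats <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_lim & x <= hi_lim]
  list(median = q[2], mean = mean(x), q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(x[x < lo_lim | x > hi_lim]))
}

#' Box statistics per metric and volume group
#'
#' @param records data.frame from [evaluatePredictions()].
#' @param value column to summarize ("error" or "abs_error").
#' @return Nested list `[[metric]][[group]]` of [boxStats()] results.
#' @export
groupBoxStats <- function(records, value = "error") {
  out <- list()
  for (m in unique(records$metric)) {
    rm_ <- records[records$metric == m, ]
    out[[m]] <- lapply(split(rm_[[value]], rm_$group), boxStats)
  }
  out
}

# exact null distribution of the signed-rank statistic W+ for given
# |d|-ranks (average ranks, so possibly half-integers): dynamic programming
# over doubled ranks
wilcoxExactP <- function(w, ranks, alternative) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  # f[j+1] = number of sign assignments with doubled statistic j
  f <- numeric(tot + 1)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(tot + 1)] <- g[(r + 1):(tot + 1)] + f[1:(tot + 1 - r)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- round(2 * w)
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(tot + 1)])
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests the paired differences `a - b`. Zero differences are discarded
#' (classic treatment); when all differences are zero the p-value is 1
#' with a warning. For n <= 25 retained pairs the exact null distribution
#' of the signed-rank statistic is enumerated by dynamic programming
#' (valid under ties in the absolute ranks); for larger n a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param errors_a,errors_b paired numeric vectors of equal length.
#' @param alternative "two.sided", "greater" (a tends larger) or "less".
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `p.value`, `statistic` (W+, sum of positive-difference
#'   ranks), `n` (retained pairs) and `method`.
#' @export
pairedWilcoxon <- function(errors_a, errors_b,
                           alternative = c("two.sided", "greater", "less"),
                           exact_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(errors_a) != length(errors_b) || length(errors_a) < 1)
    stop("need paired vectors of equal positive length")
  d <- errors_a - errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(list(p.value = 1.0, statistic = 0, n = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- wilcoxExactP(w, r, alternative)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z <- switch(alternative,
                two.sided = (w - mu - sign(w - mu) * cc) / sqrt(sig2),
                greater = (w - mu - cc) / sqrt(sig2),
                less = (w - mu + cc) / sqrt(sig2))
    p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(p.value = p, statistic = w, n = n, method = method)
}

#' Method-comparison tests per metric and volume group
#'
#' Runs the paired Wilcoxon battery comparing two methods' evaluation
#' records: two-sided tests on signed errors and one-sided tests on
#' absolute errors (alternative: method A has smaller absolute error).
#'
#' @param records_a,records_b data.frames from [evaluatePredictions()] for
#'   the two methods, on identical lesions.
#' @return data.frame with metric, group, p_signed_two_sided,
#'   p_abs_one_sided and n.
#' @export
compareMethods <- function(records_a, records_b) {
  key <- function(r) paste(r$lesion_id, r$metric)
  if (!identical(key(records_a), key(records_b)))
    stop("records are not aligned")
  out <- list()
  for (m in unique(records_a$metric)) {
    ia <- records_a$metric == m
    for (grp in c(sort(unique(records_a$group[ia])), "all")) {
      sel <- ia & (if (grp == "all") TRUE else records_a$group == grp)
      if (sum(sel) < 1) next
      p2 <- pairedWilcoxon(records_a$error[sel], records_b$error[sel],
                           "two.sided")
      p1 <- pairedWilcoxon(records_a$abs_error[sel],
                           records_b$abs_error[sel], "less")
      out[[length(out) + 1L]] <-
        data.frame(metric = m, group = grp,
                   p_signed_two_sided = p2$p.value,
                   p_abs_one_sided = p1$p.value, n = sum(sel))
    }
  }
  do.call(rbind, out)
}
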