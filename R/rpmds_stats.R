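## Lognormal modelling of deviation scores, goodness of fit, cut-off scan and
## the binary RP-MDS call ("deleterious" vs "unknown").

#' Maximum-likelihood lognormal fit
#'
#' Closed-form MLE on the log scale: `mu = mean(log x)`,
#' `sigma = population SD of log x` (n divisor).
#'
#' @param scores Strictly positive numeric vector, length >= 3.
#' @return An object of class `lognormal_fit` with `mu`, `sigma`, `n`.
#' @export
fit_lognormal <- function(scores) {
  if (length(scores) < 3) stop_dlrpmds("need at least 3 scores to fit")
  if (any(!is.finite(scores)) || any(scores <= 0))
    stop_dlrpmds("lognormal fit requires strictly positive finite scores")
  lx <- log(scores)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma <= 0)
    stop_dlrpmds("degenerate sample: all scores identical (sigma = 0)")
  structure(list(mu = mu, sigma = sigma, n = length(scores)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("lognormal_fit: mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Goodness of fit of a lognormal model
#'
#' One-sample Kolmogorov-Smirnov test against the fitted lognormal CDF and
#' Anderson-Darling test of the log-scores against normality with estimated
#' parameters (the case-3 composite test, which is exactly the composite
#' lognormality test). The K-S p-value uses the standard asymptotic formula
#' against the fitted CDF; because the parameters were estimated from the same
#' sample it is conservative (biased upward) — acceptance decisions should
#' lean on the A-D case-3 p-value for borderline samples.
#'
#' @param scores Strictly positive numeric vector.
#' @param fit A [fit_lognormal()] result (default: fitted from `scores`).
#' @param alpha Significance level for the `accepted` flags (default 0.05).
#' @return An object of class `gof_result` with `ks_stat`, `ks_p`,
#'   `ad_stat`, `ad_p`, `accepted_ks`, `accepted_ad`, `accepted`.
#' @export
gof_tests <- function(scores, fit = fit_lognormal(scores), alpha = 0.05) {
  if (any(scores <= 0)) stop_dlrpmds("scores must be strictly positive")
  ks <- suppressWarnings(
    stats::ks.test(scores, "plnorm", meanlog = fit$mu, sdlog = fit$sigma))
  ad <- nortest::ad.test(log(scores))
  structure(list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 ad_stat = unname(ad$statistic), ad_p = ad$p.value,
                 accepted_ks = ks$p.value > alpha,
                 accepted_ad = ad$p.value > alpha,
                 accepted = ks$p.value > alpha && ad$p.value > alpha,
                 alpha = alpha),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("gof_result: K-S D = %.4f (p = %.3g), A-D A = %.4f (p = %.3g); %s at alpha = %g\n",
              x$ks_stat, x$ks_p, x$ad_stat, x$ad_p,
              if (x$accepted) "lognormal accepted" else "lognormal rejected",
              x$alpha))
  invisible(x)
}

# Candidate cut-off grid: lo + (0:n)*bin, n = round((hi-lo)/bin).
# Candidates are rounded to 10 decimals so accumulated floating-point error
# cannot move a candidate across a score that sits exactly on the grid.
cutoff_grid <- function(range, bin) {
  if (bin <= 0) stop_dlrpmds("bin must be positive")
  if (range[2] <= range[1]) stop_dlrpmds("invalid cutoff range")
  round(range[1] + bin * (0:round((range[2] - range[1]) / bin)), 10)
}

# Confusion counts of the rule "deleterious iff score > c" at every cut-off.
scan_cutoffs <- function(benign_scores, pathogenic_scores, cutoffs) {
  tp <- vapply(cutoffs, function(c) sum(pathogenic_scores > c), integer(1))
  fp <- vapply(cutoffs, function(c) sum(benign_scores > c), integer(1))
  data.frame(cutoff = cutoffs, tp = tp, fn = length(pathogenic_scores) - tp,
             fp = fp, tn = length(benign_scores) - fp,
             tp_rate = tp / length(pathogenic_scores),
             tn_rate = (length(benign_scores) - fp) / length(benign_scores))
}

#' Optimal cut-off scan
#'
#' Sweeps candidate cut-offs `lo + i*bin` over `range`; at each, a variant is
#' called deleterious iff its score exceeds the cut-off and TP/TN/FP/FN are
#' tabulated. The optimum is where the true-positive and true-negative
#' percentages overlap, formalized as minimizing `|TP% - TN%|` (ties broken
#' toward the smallest cut-off). Raw-count balance (`|TP - TN|`) is computed
#' alongside.
#'
#' @param benign_scores,pathogenic_scores Non-empty score vectors.
#' @param range Scan range, default `c(2.7, 4.0)`.
#' @param bin Scan step, default 0.01 (131 candidates at the default range).
#' @param balance Balance criterion: `"rates"` (default) or `"counts"`.
#' @return An object of class `cutoff_result` with `cutoff`, `tp_rate`,
#'   `tn_rate` at the optimum and the full `scan` table.
#' @export
optimize_cutoff <- function(benign_scores, pathogenic_scores,
                            range = c(2.7, 4.0), bin = 0.01,
                            balance = c("rates", "counts")) {
  balance <- match.arg(balance)
  if (!length(benign_scores) || !length(pathogenic_scores))
    stop_dlrpmds("both score sets must be non-empty")
  scan <- scan_cutoffs(benign_scores, pathogenic_scores, cutoff_grid(range, bin))
  gap <- if (balance == "rates") abs(scan$tp_rate - scan$tn_rate)
         else abs(scan$tp - scan$tn)
  best <- which.min(gap)   # which.min takes the first minimum: lowest cut-off
  structure(list(cutoff = scan$cutoff[best],
                 tp_rate = scan$tp_rate[best],
                 tn_rate = scan$tn_rate[best],
                 balance = balance, scan = scan),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result: optimal cut-off %.2f (TP%% = %.1f, TN%% = %.1f; %d candidates)\n",
              x$cutoff, 100 * x$tp_rate, 100 * x$tn_rate, nrow(x$scan)))
  invisible(x)
}

#' RP-MDS binary classification
#'
#' Deleterious iff `score > cutoff`; the boundary goes to "unknown"
#' (conservative).
#'
#' @param score Numeric vector of deviation scores.
#' @param cutoff Scalar cut-off.
#' @return Character vector in `{"deleterious", "unknown"}`.
#' @export
classify_rpmds <- function(score, cutoff) {
  ifelse(score > cutoff, "deleterious", "unknown")
}

#' ROC curve by cut-off sweep
#'
#' Sweeps cut-offs on an equal grid of step `bin`. By default the grid spans
#' the data (padded by one bin on each side) so the curve reaches (0,0) and
#' (1,1); pass `range` to mirror a fixed scan window. AUC by the trapezoid
#' rule.
#'
#' @param benign_scores,pathogenic_scores Non-empty score vectors.
#' @param bin Grid step, default 0.01.
#' @param range Optional fixed sweep range; default spans the pooled scores.
#' @return List with `points` (data.frame fpr, tpr, cutoff, sorted by
#'   descending cut-off) and `auc`.
#' @export
roc_by_cutoff <- function(benign_scores, pathogenic_scores, bin = 0.01,
                          range = NULL) {
  if (!length(benign_scores) || !length(pathogenic_scores))
    stop_dlrpmds("both score sets must be non-empty")
  all_s <- c(benign_scores, pathogenic_scores)
  if (is.null(range)) range <- c(min(all_s) - bin, max(all_s) + bin)
  cuts <- cutoff_grid(range, bin)
  scan <- scan_cutoffs(benign_scores, pathogenic_scores, cuts)
  pts <- data.frame(fpr = 1 - scan$tn_rate, tpr = scan$tp_rate,
                    cutoff = scan$cutoff)
  pts <- pts[order(-pts$cutoff), ]
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  list(points = pts, auc = auc)
}
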