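#' @include AllClasses.R
NULL

.parameterNames <- function() c("rms_fT", "total_power", "rpsd_L", "rpsd_M", "rpsd_H")

#' Grand-average features per subject and session
#'
#' Arithmetic mean of every parameter across a subject's kept
#' moderate-Kegel epochs, one row per (subject, session). Subjects listed
#' in `exclude` (e.g. flagged by the SNR quality gate) are omitted
#' entirely.
#'
#' @param features epoch-level feature data.frame (see [epochSetFeatures()]).
#' @param exclude character vector of subject ids to drop.
#' @return data.frame: subject, session, n_epochs, and the mean of each
#'   parameter.
#' @export
grandAverage <- function(features, exclude = character()) {
  f <- features[!features$subject %in% exclude, , drop = FALSE]
  if (!nrow(f))
    return(data.frame(subject = character(), session = character(),
                      n_epochs = integer()))
  key <- interaction(f$subject, f$session, drop = TRUE)
  rows <- lapply(split(f, key), function(g) {
    out <- data.frame(subject = g$subject[1], session = g$session[1],
                      n_epochs = nrow(g), stringsAsFactors = FALSE)
    for (p in .parameterNames()) out[[p]] <- mean(g[[p]])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$subject, res$session), , drop = FALSE]
}

#' Paired Student t-test from the closed form
#'
#' On differences `d = pre - post`: `t = mean(d) / (sd(d) / sqrt(n))`, with
#' `n - 1` degrees of freedom and a two-sided p-value. Zero difference
#' variance is a degenerate case and is flagged rather than reported as a
#' (meaningless) test.
#'
#' @param pre,post equal-length paired samples (third trimester, postpartum).
#' @return list: n, df, meanDiff, sdDiff, t, p, degenerate.
#' @export
pairedTTest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- pre - post
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero variance of paired differences: t-test degenerate")
    return(list(n = n, df = n - 1, meanDiff = mean(d), sdDiff = 0,
                t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  list(n = n, df = n - 1, meanDiff = mean(d), sdDiff = sdd, t = tstat,
       p = 2 * stats::pt(-abs(tstat), df = n - 1), degenerate = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W and p-value (delegates to
#' [stats::shapiro.test()]); applied to the paired differences of each
#' parameter before the t-test. Constant samples are degenerate and
#' reported as `NA` with a warning.
#'
#' @param values numeric sample, `3 <= n <= 5000`.
#' @return list: W, p.
#' @export
shapiroWilk <- function(values) {
  if (length(values) < 3) stop("Shapiro-Wilk requires n >= 3")
  if (stats::sd(values) == 0) {
    warning("constant sample: Shapiro-Wilk undefined")
    return(list(W = NA_real_, p = NA_real_))
  }
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = unname(s$p.value))
}

#' Paired third-trimester vs postpartum comparison of all parameters
#'
#' For each parameter (RMS, total power, rPSD low/middle/high): session
#' means and SDs, Shapiro-Wilk on the paired differences, the paired
#' t-test, and a significance flag at `alpha`. Subjects lacking either
#' session are dropped with a logged count. When the normality check fails
#' (Shapiro p < 0.05) a warning is emitted and a Wilcoxon signed-rank
#' p-value is reported alongside as a supplementary check; the t-test
#' remains the primary analysis.
#'
#' @param summaries per-subject summary table from [grandAverage()].
#' @param alpha significance level (study value 0.05).
#' @return data.frame, one row per parameter: parameter, n_pairs, df,
#'   mean_3t, sd_3t, mean_ppt, sd_ppt, mean_diff, shapiro_W, shapiro_p,
#'   t, p, significant, direction, wilcoxon_p.
#' @export
compareSessions <- function(summaries, alpha = 0.05) {
  pre <- summaries[summaries$session == "third_trimester", , drop = FALSE]
  post <- summaries[summaries$session == "postpartum", , drop = FALSE]
  common <- intersect(pre$subject, post$subject)
  nDropped <- length(unique(summaries$subject)) - length(common)
  if (nDropped > 0)
    .log("dropping %d subject(s) lacking a complete session pair", nDropped)
  if (length(common) < 2) stop("fewer than 2 complete subject pairs")
  pre <- pre[match(common, pre$subject), , drop = FALSE]
  post <- post[match(common, post$subject), , drop = FALSE]

  rows <- lapply(.parameterNames(), function(p) {
    x <- pre[[p]]; y <- post[[p]]
    tt <- pairedTTest(x, y)
    sw <- if (tt$degenerate || tt$n < 3) list(W = NA_real_, p = NA_real_)
          else shapiroWilk(x - y)
    wilcox <- NA_real_
    if (!tt$degenerate) {
      if (is.finite(sw$p) && sw$p < 0.05)
        warning(sprintf("parameter %s: paired differences fail normality (Shapiro p = %.3g)",
                        p, sw$p))
      wilcox <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
    }
    data.frame(parameter = p, n_pairs = tt$n, df = tt$df,
               mean_3t = mean(x), sd_3t = stats::sd(x),
               mean_ppt = mean(y), sd_ppt = stats::sd(y),
               mean_diff = tt$meanDiff,
               shapiro_W = sw$W, shapiro_p = sw$p,
               t = tt$t, p = tt$p,
               significant = !tt$degenerate && tt$p < alpha,
               direction = sign(tt$meanDiff),
               wilcoxon_p = wilcox, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
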