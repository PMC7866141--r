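#' @include cohort.R
NULL

# subjects x timepoints matrix of pct_colder for one session; errors list
# the missing cells.
.cohortWide <- function(tab, sessionId) {
  validateCohortTable(tab, allowIncomplete = TRUE)
  s <- tab[tab$session == sessionId, , drop = FALSE]
  if (nrow(s) == 0L) stop("no data for session ", sessionId)
  subjects <- sort(unique(s$subject))
  tps <- timepointLevels()[timepointLevels() %in% unique(s$timepoint)]
  m <- matrix(NA_real_, length(subjects), length(tps),
              dimnames = list(subjects, tps))
  idx <- cbind(match(s$subject, subjects), match(s$timepoint, tps))
  m[idx] <- s$pct_colder
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete timepoint grid for session ", sessionId,
         "; missing cell(s): ",
         paste(sprintf("%s/%s", subjects[miss[, 1]], tps[miss[, 2]]),
               collapse = ", "))
  }
  if (nrow(m) < 2L) stop("need >= 2 subjects with complete data")
  m
}

#' One-way repeated-measures ANOVA on percent time (colder plate)
#'
#' Tests whether the cohort's percent time on the colder plate differs
#' across the three timepoints, with subject as the repeated-measures
#' blocking factor. Computed from the classical sums-of-squares
#' decomposition (SS_timepoint / SS_subject x timepoint); an optional
#' Greenhouse-Geisser correction adjusts the degrees of freedom for
#' sphericity violations. A cohort with zero within-subject variance is a
#' degenerate test: it is flagged and its p reported as 1.
#'
#' @param tab tidy cohort table (see [validateCohortTable()])
#' @param sessionId session to test
#' @param correction "none" (default; three levels, small cohorts) or "gg"
#' @return List with elements `F`, `df1`, `df2`, `p`, `degenerate`, and the
#'   mean per timepoint.
#' @export
#' @examples
#' sc <- simulateCohort(6, standardProtocol(durationS = 30), seed = 4)
#' rmAnova(cohortTable(sc), sessionId = 1)$p
rmAnova <- function(tab, sessionId, correction = c("none", "gg")) {
  correction <- match.arg(correction)
  m <- .cohortWide(tab, sessionId)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssSubj <- k * sum((rowMeans(m) - grand)^2)
  ssTime <- n * sum((colMeans(m) - grand)^2)
  ssTot <- sum((m - grand)^2)
  ssErr <- ssTot - ssSubj - ssTime
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  eps <- 1
  if (correction == "gg") eps <- .ggEpsilon(m)
  msErr <- ssErr / df2
  if (msErr <= .Machine$double.eps * max(1, abs(grand))^2) {
    if (ssTime <= .Machine$double.eps)
      return(list(F = NaN, df1 = df1, df2 = df2, p = 1, degenerate = TRUE,
                  means = colMeans(m)))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE,
                means = colMeans(m)))
  }
  Fv <- (ssTime / df1) / msErr
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, p = p, degenerate = FALSE,
       means = colMeans(m), epsilon = eps)
}

# Greenhouse-Geisser epsilon from the sample covariance of the wide matrix
.ggEpsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Tukey multiple comparisons for a session
#'
#' Two comparison families, matching the two annotation families of the
#' assay's figures:
#' * `family = "plate"` (the star family): percent time on the colder vs
#'   the warmer plate within each timepoint. Because the two plate times of
#'   a mouse are complementary (they sum to 100), this is the paired
#'   contrast of `pct_colder` against `pct_warmer`, a two-level family, so
#'   the Tukey-adjusted p equals the paired comparison's p.
#' * `family = "timepoint"` (the hash family): percent time on the same
#'   (colder) plate compared across the three timepoints, Tukey HSD using
#'   the repeated-measures error mean square.
#'
#' In both cases adjusted p-values use the studentized range distribution,
#' so `pAdj >= p` element-wise for the timepoint family.
#'
#' @param tab tidy cohort table
#' @param sessionId session to test
#' @param family "plate" or "timepoint"
#' @return data.frame of contrasts with estimates and adjusted p-values.
#' @export
tukeyPairwise <- function(tab, sessionId,
                          family = c("timepoint", "plate")) {
  family <- match.arg(family)
  m <- .cohortWide(tab, sessionId)
  n <- nrow(m); k <- ncol(m)
  if (family == "plate") {
    res <- lapply(colnames(m), function(tp) {
      d <- 2 * (m[, tp] - 50)          # pct_colder - pct_warmer per subject
      sdd <- stats::sd(d)
      if (sdd <= .Machine$double.eps * 100) {
        p <- if (abs(mean(d)) <= .Machine$double.eps * 100) 1 else 0
        tv <- if (p == 1) 0 else Inf
      } else {
        tv <- mean(d) / (sdd / sqrt(n))
        # a 2-level studentized range is the paired t: use its exact p
        p <- 2 * stats::pt(-abs(tv), n - 1)
      }
      data.frame(timepoint = tp, estimate = mean(d),
                 meanPctColder = mean(m[, tp]), t = tv, df = n - 1,
                 pAdj = p, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, res))
  }
  # timepoint family: Tukey HSD with the RM error mean square
  a <- rmAnova(tab, sessionId)
  msErr <- if (a$degenerate) 0 else
    (sum((m - mean(m))^2) -
       k * sum((rowMeans(m) - mean(m))^2) -
       n * sum((colMeans(m) - mean(m))^2)) / ((n - 1) * (k - 1))
  pairs <- utils::combn(colnames(m), 2)
  res <- apply(pairs, 2, function(pr) {
    diff <- mean(m[, pr[2]]) - mean(m[, pr[1]])
    if (msErr <= .Machine$double.eps * 100) {
      p <- if (abs(diff) <= .Machine$double.eps * 100) 1 else 0
    } else {
      q <- abs(diff) / sqrt(msErr / n)
      p <- stats::ptukey(q, k, (n - 1) * (k - 1), lower.tail = FALSE)
    }
    data.frame(lhs = pr[1], rhs = pr[2], estimate = diff,
               df = (n - 1) * (k - 1), pAdj = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Significance labels from p-values
#'
#' Strict-inequality thresholds: `* p < 0.05`, `** p < 0.01`,
#' `*** p < 0.001`, `**** p < 0.0001`; `p = 0.05` itself is "ns".
#' `hashes()` uses the same thresholds with `#` marks (the same-plate
#' across-timepoint family).
#'
#' @param p p-value(s) in \[0, 1\] (vectorized)
#' @return Character vector of labels.
#' @export
#' @examples
#' stars(c(0.03, 0.05, 0.00009))
stars <- function(p) .sigMarks(p, "*")

#' @rdname stars
#' @export
hashes <- function(p) .sigMarks(p, "#")

.sigMarks <- function(p, sym) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  vapply(p, function(pp) {
    nsym <- sum(pp < c(0.05, 0.01, 0.001, 0.0001))
    if (nsym == 0) "ns" else strrep(sym, nsym)
  }, character(1))
}

#' Call the plate preference at one session and timepoint
#'
#' The cohort prefers the warmer plate when its mean percent time on the
#' colder plate is below 50 and the plate-vs-plate adjusted p is below
#' `alpha`; the colder plate when above 50 with p below `alpha`; otherwise
#' no preference (a mean of exactly 50 is "none" regardless of p).
#'
#' @param tab tidy cohort table
#' @param sessionId session
#' @param timepoint one of [timepointLevels()]
#' @param alpha significance level (0.05)
#' @return A [PreferenceCall-class].
#' @export
callPreference <- function(tab, sessionId, timepoint, alpha = 0.05) {
  tp <- .validTimepoint(timepoint)
  pl <- tukeyPairwise(tab, sessionId, family = "plate")
  row <- pl[pl$timepoint == tp, ]
  if (nrow(row) != 1L) stop("timepoint ", tp, " absent from session ",
                            sessionId)
  dir <- "none"
  if (row$pAdj < alpha && row$meanPctColder != 50)
    dir <- if (row$meanPctColder > 50) "colder" else "warmer"
  new("PreferenceCall", sessionId = as.integer(sessionId), timepoint = tp,
      direction = dir, meanPctColder = row$meanPctColder,
      pAdj = row$pAdj, stars = stars(row$pAdj))
}

#' @describeIn PreferenceCall-class preference direction
#' @param x object
#' @export
setMethod("direction", "PreferenceCall", function(x) x@direction)

#' @describeIn PreferenceCall-class adjusted p-value
#' @export
setMethod("pAdj", "PreferenceCall", function(x) x@pAdj)

setMethod("show", "PreferenceCall", function(object) {
  cat(sprintf(
    "PreferenceCall [session %d, %s]: %s (colder %.1f%%, p_adj %.4g %s)\n",
    object@sessionId, object@timepoint, object@direction,
    object@meanPctColder, object@pAdj, object@stars))
})

#' Classify the drug effect from pre- and post-drug preference calls
#'
#' The analgesia readout: a significant pre-drug preference that disappears
#' post-drug is "lost"; one that flips to the opposite plate is "reversed";
#' one that persists in the same direction is "maintained". When there was
#' no pre-drug preference the session carries no baseline and is classified
#' "no_baseline", excluded from analgesia claims.
#'
#' @param pre,post [PreferenceCall-class]s from the same session (pre-drug
#'   and post-drug timepoints)
#' @param crossPAdj optional Tukey-adjusted p of the same-plate pre- vs
#'   post-drug comparison (the hash family)
#' @return A [DrugEffectCall-class].
#' @export
#' @examples
#' # see analyzeCohort() for the full pipeline
callDrugEffect <- function(pre, post, crossPAdj = NA_real_) {
  stopifnot(is(pre, "PreferenceCall"), is(post, "PreferenceCall"))
  if (pre@sessionId != post@sessionId)
    stop("pre and post calls come from different sessions (",
         pre@sessionId, " vs ", post@sessionId, ")")
  cat_ <- if (pre@direction == "none") "no_baseline"
    else if (post@direction == "none") "lost"
    else if (post@direction == pre@direction) "maintained"
    else "reversed"
  new("DrugEffectCall", sessionId = pre@sessionId, category = cat_,
      pre = pre, post = post, crossPAdj = crossPAdj,
      hashes = if (is.na(crossPAdj)) "ns" else hashes(crossPAdj))
}

#' @describeIn DrugEffectCall-class the classification
#' @param x object
#' @export
setMethod("category", "DrugEffectCall", function(x) x@category)

setMethod("show", "DrugEffectCall", function(object) {
  cat(sprintf(
    "DrugEffectCall [session %d]: %s (pre %s, post %s; same-plate p_adj %.4g %s)\n",
    object@sessionId, object@category, object@pre@direction,
    object@post@direction, object@crossPAdj, object@hashes))
})

#' Analyze a full cohort: preference and drug-effect calls per session
#'
#' For every session, runs the repeated-measures ANOVA across timepoints,
#' the plate-vs-plate comparison at each timepoint, and the pre- vs
#' post-drug classification, with the same-plate cross-timepoint Tukey p
#' (hash family) attached.
#'
#' @param tab tidy cohort table (validated; complete grid required)
#' @param alpha significance level
#' @return data.frame with one row per session (means, adjusted p-values,
#'   directions, category, hash level); the full [DrugEffectCall-class]
#'   objects are attached as attribute `"calls"`.
#' @export
#' @examples
#' sc <- simulateCohort(6, standardProtocol(durationS = 60),
#'                      effects = duloxetineProfile(), seed = 2)
#' analyzeCohort(cohortTable(sc))[, c("session", "category")]
analyzeCohort <- function(tab, alpha = 0.05) {
  validateCohortTable(tab)
  sessionsIds <- sort(unique(tab$session))
  calls <- list()
  rows <- lapply(sessionsIds, function(sid) {
    an <- rmAnova(tab, sid)
    tk <- tukeyPairwise(tab, sid, family = "timepoint")
    crossP <- tk$pAdj[tk$lhs == "pre_drug" & tk$rhs == "post_drug"]
    if (!length(crossP)) crossP <- NA_real_
    pcs <- lapply(timepointLevels(), function(tp)
      callPreference(tab, sid, tp, alpha))
    names(pcs) <- timepointLevels()
    de <- callDrugEffect(pcs$pre_drug, pcs$post_drug, crossP)
    calls[[as.character(sid)]] <<- de
    lows <- tab[tab$session == sid, c("t_low", "t_high")]
    data.frame(
      session = sid,
      t_low = if ("t_low" %in% names(tab)) lows$t_low[1] else NA_real_,
      t_high = if ("t_high" %in% names(tab)) lows$t_high[1] else NA_real_,
      anova_F = an$F, anova_p = an$p,
      mean_before = pcs$before_oxa@meanPctColder,
      mean_pre = pcs$pre_drug@meanPctColder,
      mean_post = pcs$post_drug@meanPctColder,
      p_before = pcs$before_oxa@pAdj, p_pre = pcs$pre_drug@pAdj,
      p_post = pcs$post_drug@pAdj,
      dir_before = pcs$before_oxa@direction,
      dir_pre = pcs$pre_drug@direction,
      dir_post = pcs$post_drug@direction,
      stars_pre = pcs$pre_drug@stars, stars_post = pcs$post_drug@stars,
      category = de@category, cross_p = crossP, hash = de@hashes,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "calls") <- calls
  out
}

#' Plain-text report of an analyzed cohort
#'
#' @param analysis the data.frame returned by [analyzeCohort()]
#' @return Character vector of report lines.
#' @export
summaryReport <- function(analysis) {
  hdr <- "session  pair(degC)   pre-drug           post-drug          effect"
  lines <- vapply(seq_len(nrow(analysis)), function(i) {
    r <- analysis[i, ]
    sprintf("%7d  %4g-%-6g  %-6s %-10s  %-6s %-10s  %s %s",
            r$session, r$t_low, r$t_high,
            r$dir_pre, paste0("(", r$stars_pre, ")"),
            r$dir_post, paste0("(", r$stars_post, ")"),
            r$category, r$hash)
  }, character(1))
  c(hdr, lines,
    sprintf("analgesia-indicating sessions (lost or reversed): %s",
            paste(analysis$session[analysis$category %in%
                                     c("lost", "reversed")],
                  collapse = ", ")))
}

#' Bar plot of one session's percent time per plate and timepoint
#'
#' @param tab tidy cohort table
#' @param sessionId session to plot
#' @param alpha significance level for the star annotations
#' @return Invisibly, the plotted mean matrix.
#' @export
plotSession <- function(tab, sessionId, alpha = 0.05) {
  m <- .cohortWide(tab, sessionId)
  mean_ <- rbind(colder = colMeans(m), warmer = 100 - colMeans(m))
  pl <- tukeyPairwise(tab, sessionId, family = "plate")
  bp <- graphics::barplot(mean_, beside = TRUE,
                          ylim = c(0, 115), ylab = "% time in zone",
                          legend.text = rownames(mean_),
                          main = sprintf("session %d", sessionId))
  lab <- stars(pl$pAdj[match(colnames(m), pl$timepoint)])
  graphics::text(colMeans(bp), apply(mean_, 2, max) + 6, lab)
  invisible(mean_)
}
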