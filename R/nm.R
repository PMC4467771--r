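# Normalized ERP magnitude (NM) and its relationship to behavioral
# performance. NM = (correct-condition ERP mean over the CMPT-selected
# region) / (attended-condition ERP mean over the same region, from the AT
# task); under the linear performance-scaling model NM estimates the
# participant's accuracy.

#' Mean ERP voltage over a spatiotemporal region
#'
#' @param erp an "ERP" (see \code{\link{erpAverage}}) or a channels x time
#'   matrix.
#' @param region logical channels x time matrix, e.g.
#'   \code{selectedRegion(result)}.
#' @return Mean voltage (microvolts) over the region's member points.
#' @export
regionMean <- function(erp, region) {
  m <- if (inherits(erp, "ERP")) erp$mean else erp
  if (!is.matrix(region) || !any(region)) stop("region must be nonempty")
  if (!identical(dim(m), dim(region)))
    stop("region dimensions must match the ERP")
  mean(m[region])
}

#' Predicted correct-condition magnitude under the performance-scaling model
#'
#' A participant performing at accuracy a attends the correct word in a
#' fraction a of trials; the correct-condition average then mixes P300b
#' responses (fraction a) with zero-mean non-P300b responses (fraction
#' 1 - a), so its magnitude is the attended-condition magnitude times a.
#' E.g. 4 microvolts attended at 75% performance predicts 3 microvolts.
#'
#' @param attendedMagnitude attended-condition ERP magnitude (microvolts).
#' @param performance accuracy in [0, 1].
#' @return Predicted correct-condition magnitude (microvolts).
#' @export
#' @examples
#' predictedCorrectMagnitude(4, 0.75)   # 3
predictedCorrectMagnitude <- function(attendedMagnitude, performance) {
  if (any(performance < 0 | performance > 1))
    stop("performance must lie in [0, 1]")
  attendedMagnitude * performance
}

#' Compute normalized magnitudes for one participant
#'
#' For each WM set size: the region mean of the correct-condition ERP,
#' divided by the region mean of the AT attended-condition ERP. Also attaches
#' the behavioral performance (fraction of correct recall answers) per set
#' size. Participants whose attended magnitude is not positive are flagged
#' and excluded (the ratio is unstable).
#'
#' @param epochs baseline-corrected \linkS4class{EpochSet} of the session.
#' @param schedule the \linkS4class{BatterySchedule}.
#' @param behavior behavioral log (e.g. \code{\link{simulateAgent}} output)
#'   with \code{trial} and \code{correct}.
#' @param region logical channels x time matrix from the group AT CMPT.
#' @param participant participant identifier carried into the records.
#' @return data.frame with one row per set size: participant, set_size,
#'   correct_magnitude, attended_magnitude, nm, performance.
#' @export
computeNM <- function(epochs, schedule, behavior, region,
                      participant = "P01") {
  atBin <- binSession(epochs, schedule, "AT")
  attERP <- erpAverage(epochs, atBin$positive, "attended")
  attMag <- regionMean(attERP, region)
  tr <- schedule@trials
  out <- lapply(c(4L, 6L, 8L), function(sz) {
    trials <- restrictSetSizes(schedule, sz)
    wmBin <- binSession(epochs, schedule, "WM", trials = trials)
    corMag <- if (length(wmBin$positive))
      regionMean(erpAverage(epochs, wmBin$positive, "correct"), region)
    else NA_real_
    beh <- behavior[behavior$trial %in% trials, ]
    data.frame(participant = participant, set_size = sz,
               correct_magnitude = corMag, attended_magnitude = attMag,
               nm = corMag / attMag, performance = mean(beh$correct))
  })
  out <- do.call(rbind, out)
  if (attMag <= 0) {
    warning("attended magnitude <= 0 for ", participant,
            "; NM records flagged and excluded")
    out <- out[0, ]
  }
  out
}

#' GLM of performance on set size and normalized magnitude
#'
#' Fits performance ~ set_size (categorical) + nm + set_size:nm and reports
#' sequential likelihood-ratio chi-squares for each term. Performance is
#' treated as a binomial proportion (logit link) with \code{trialsPerCell}
#' trials per record; \code{family = "gaussian"} gives an identity-link
#' comparison fit.
#'
#' @param records NM record data.frame (\code{\link{computeNM}} rows pooled
#'   across participants).
#' @param family "binomial" (default) or "gaussian".
#' @param trialsPerCell trials behind each performance score (default 8).
#' @return list: \code{fit} (the glm), \code{anova} (data.frame: term,
#'   df, chisq, p).
#' @export
glmPerformance <- function(records, family = c("binomial", "gaussian"),
                           trialsPerCell = 8) {
  family <- match.arg(family)
  if (length(unique(records$set_size)) < 2 || nrow(records) < 3)
    stop("need records at >= 2 set sizes and >= 3 rows")
  d <- records
  d$set_size <- factor(d$set_size)
  if (family == "binomial") {
    fit <- stats::glm(performance ~ set_size + nm + set_size:nm,
                      family = stats::binomial(),
                      weights = rep(trialsPerCell, nrow(d)), data = d)
  } else {
    fit <- stats::glm(performance ~ set_size + nm + set_size:nm,
                      family = stats::gaussian(), data = d)
  }
  an <- stats::anova(fit, test = "LRT")
  out <- data.frame(term = rownames(an)[-1], df = an$Df[-1],
                    chisq = an$Deviance[-1], p = an[["Pr(>Chi)"]][-1])
  if (family == "gaussian") {
    # scale deviance drops to chi-squares using the residual dispersion
    disp <- summary(fit)$dispersion
    out$chisq <- out$chisq / disp
    out$p <- stats::pchisq(out$chisq, out$df, lower.tail = FALSE)
  }
  list(fit = fit, anova = out)
}

#' Correlation between NM and performance at one set size
#'
#' @param records NM record data.frame.
#' @param setSize 4, 6 or 8.
#' @return list: r, p, n (Pearson, two-sided).
#' @export
perSetSizeCorrelation <- function(records, setSize) {
  d <- records[records$set_size == setSize, ]
  if (nrow(d) < 3) stop("need at least 3 records at set size ", setSize)
  if (stats::sd(d$nm) == 0 || stats::sd(d$performance) == 0)
    stop("zero variance at set size ", setSize,
         " (ceiling performance?); correlation undefined")
  ct <- stats::cor.test(d$nm, d$performance)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
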