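# Downstream comparisons: goodness-of-fit thresholding, blank-period
# truncation, pRF size versus eccentricity curves and slopes, and the
# comparison of model-based and phase-encoded eccentricity estimates.

#' Threshold a fit table on goodness of fit
#'
#' Strictly greater-than filter on the chosen R-squared column.
#'
#' @param fits fit table from \code{\link{fit_prf}}.
#' @param r2_min threshold (vertices with r2 strictly above it survive).
#' @param column which goodness-of-fit column to threshold.
#' @return filtered table; attribute \code{n_surviving} gives the count.
#' @export
threshold_fits <- function(fits, r2_min = 0.1, column = "r2_fine") {
  r2 <- fits[[column]]
  keep <- !is.na(r2) & r2 > r2_min
  out <- fits[keep, , drop = FALSE]
  attr(out, "n_surviving") <- nrow(out)
  out
}

#' Truncate mean-luminance blank volumes
#'
#' Reduces a run's blank volumes to \code{keep}, dropping the earliest
#' blank volumes first (so the first trial's blank period goes and the
#' final one is retained), with apertures and data kept aligned.
#'
#' @param apertures an \code{aperture_sequence}.
#' @param data vertices x time matrix aligned with the run.
#' @param keep number of blank volumes to retain.
#' @return list with truncated \code{apertures} and \code{data}.
#' @export
truncate_blanks <- function(apertures, data, keep = 24) {
  Tn <- n_volumes(apertures)
  if (ncol(data) != Tn) stop("data columns must match aperture volumes")
  blanks <- which(apertures$is_blank)
  if (length(blanks) < keep) stop("run has fewer blank volumes than 'keep'")
  drop_idx <- utils::head(blanks, length(blanks) - keep)
  if (length(drop_idx) == 0) {
    return(list(apertures = apertures, data = data))
  }
  sel <- setdiff(seq_len(Tn), drop_idx)
  apertures$masks <- apertures$masks[sel, , drop = FALSE]
  apertures$is_blank <- apertures$is_blank[sel]
  list(apertures = apertures, data = data[, sel, drop = FALSE])
}

#' Mean pRF size by eccentricity bin
#'
#' Bins thresholded fits into half-open eccentricity bins [k, k+bin) and
#' averages sigma, first within participant and then across participants
#' (the SEM is across participants). Vertices beyond the maximum stimulated
#' eccentricity are excluded; empty bins are simply absent.
#'
#' @param fits fit table with columns x0, y0, sigma and optionally
#'   \code{roi} and \code{subject}.
#' @param bin_deg bin width in degrees.
#' @param max_ecc maximum stimulated eccentricity.
#' @return data frame: roi, bin_lo, bin_mid, mean_sigma, sem, n_subjects.
#' @export
bin_sigma_by_eccentricity <- function(fits, bin_deg = 1, max_ecc) {
  f <- fits
  f$ecc <- sqrt(f$x0^2 + f$y0^2)
  f <- f[f$ecc < max_ecc, , drop = FALSE]
  if (is.null(f$roi)) f$roi <- "all"
  if (is.null(f$subject)) f$subject <- 1L
  f$bin_lo <- floor(f$ecc / bin_deg) * bin_deg
  per_subj <- stats::aggregate(sigma ~ roi + bin_lo + subject, data = f,
                               FUN = mean)
  agg <- do.call(rbind, lapply(
    split(per_subj, list(per_subj$roi, per_subj$bin_lo), drop = TRUE),
    function(d) data.frame(
      roi = d$roi[1], bin_lo = d$bin_lo[1],
      bin_mid = d$bin_lo[1] + bin_deg / 2,
      mean_sigma = mean(d$sigma),
      sem = if (nrow(d) > 1) stats::sd(d$sigma) / sqrt(nrow(d)) else NA_real_,
      n_subjects = nrow(d))
  ))
  agg <- agg[order(agg$roi, agg$bin_lo), ]
  rownames(agg) <- NULL
  agg
}

#' Size-eccentricity slopes and their comparison across conditions
#'
#' Ordinary least-squares regression of pRF size on eccentricity per
#' subject, region and condition, followed (when two conditions are
#' present) by a per-region paired t-test on the subject slopes. The slope
#' difference is condition 1 minus condition 2 in the order given by
#' \code{conditions} (or first appearance).
#'
#' @param fits fit table with columns x0, y0, sigma plus \code{subject},
#'   \code{roi} and \code{condition} identifiers.
#' @param conditions optional length-2 character vector fixing the
#'   comparison order.
#' @return list with \code{slopes} (subject x roi x condition slope table)
#'   and \code{comparison} (per-roi mean_diff, sem, t, df, p; NULL when
#'   fewer than two conditions).
#' @export
sigma_ecc_slope <- function(fits, conditions = NULL) {
  f <- fits
  f$ecc <- sqrt(f$x0^2 + f$y0^2)
  if (is.null(f$roi)) f$roi <- "all"
  if (is.null(f$subject)) f$subject <- 1L
  if (is.null(f$condition)) f$condition <- "all"
  slopes <- do.call(rbind, lapply(
    split(f, list(f$subject, f$roi, f$condition), drop = TRUE),
    function(d) {
      if (nrow(d) < 3) stop("need at least 3 vertices per cell")
      if (stats::var(d$ecc) == 0) stop("degenerate eccentricity variance")
      co <- stats::coef(stats::lm(sigma ~ ecc, data = d))
      data.frame(subject = d$subject[1], roi = d$roi[1],
                 condition = d$condition[1],
                 intercept = co[1], slope = co[2], n_vertices = nrow(d))
    }))
  rownames(slopes) <- NULL

  comparison <- NULL
  conds <- if (is.null(conditions)) unique(slopes$condition) else conditions
  if (length(conds) == 2) {
    comparison <- do.call(rbind, lapply(split(slopes, slopes$roi),
                                        function(d) {
      s1 <- d$slope[d$condition == conds[1]][order(d$subject[d$condition == conds[1]])]
      s2 <- d$slope[d$condition == conds[2]][order(d$subject[d$condition == conds[2]])]
      if (length(s1) != length(s2) || length(s1) < 2) {
        stop("paired slope comparison needs matched subjects per condition")
      }
      dd <- s1 - s2
      sd_d <- stats::sd(dd)
      n <- length(dd)
      t_stat <- if (sd_d == 0) {
        if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
      } else mean(dd) / (sd_d / sqrt(n))
      data.frame(roi = d$roi[1], mean_diff = mean(dd),
                 sem = sd_d / sqrt(n), t = t_stat, df = n - 1,
                 p = 2 * stats::pt(-abs(t_stat), n - 1))
    }))
    rownames(comparison) <- NULL
    attr(comparison, "conditions") <- conds
  }
  list(slopes = slopes, comparison = comparison)
}

#' Compare model-based and phase-encoded eccentricity estimates
#'
#' Pairs the pRF-model eccentricity with the phase-decoded eccentricity at
#' shared vertices (both thresholded at goodness of fit above
#' \code{r2_min}; the phase side uses the coherence-squared at the ring
#' fundamental), normalizes both by the maximum stimulated eccentricity,
#' fits a degree-2 polynomial of the phase estimate on the model estimate
#' and reports the signed mean discrepancy (phase minus model).
#'
#' @param prf_fits fit table from \code{\link{fit_prf}}.
#' @param phase_map decoded combined \code{phase_map}.
#' @param max_ecc maximum stimulated eccentricity (degrees).
#' @param r2_min inclusion threshold for both estimates.
#' @return list: \code{pairs} (vertex, prf_ecc_norm, phase_ecc_norm),
#'   \code{poly_coef} (intercept, linear, quadratic),
#'   \code{mean_discrepancy}.
#' @export
compare_ecc_estimates <- function(prf_fits, phase_map, max_ecc,
                                  r2_min = 0.05) {
  pf <- prf_fits[!is.na(prf_fits$r2_fine) & prf_fits$r2_fine > r2_min, ]
  pm <- phase_map[phase_map$coh2_ecc > r2_min, ]
  shared <- intersect(pf$vertex_id, pm$vertex)
  if (length(shared) < 10) stop("fewer than 10 shared vertices")
  pf <- pf[match(shared, pf$vertex_id), ]
  pm <- pm[match(shared, pm$vertex), ]
  pairs <- data.frame(
    vertex = shared,
    prf_ecc_norm = sqrt(pf$x0^2 + pf$y0^2) / max_ecc,
    phase_ecc_norm = pm$eccentricity_deg / max_ecc
  )
  fit <- stats::lm(phase_ecc_norm ~ prf_ecc_norm + I(prf_ecc_norm^2),
                   data = pairs)
  list(pairs = pairs,
       poly_coef = stats::coef(fit),
       mean_discrepancy = mean(pairs$phase_ecc_norm - pairs$prf_ecc_norm))
}

#' Repeated-measures comparison of goodness of fit across conditions
#'
#' Classical two-way repeated-measures ANOVA (condition as treatment,
#' subject as block) on per-subject mean goodness-of-fit values.
#'
#' @param gof data frame with columns \code{subject}, \code{condition},
#'   \code{r2}.
#' @return data frame with the condition effect: F, df, p.
#' @export
gof_anova <- function(gof) {
  gof$subject <- factor(gof$subject)
  gof$condition <- factor(gof$condition)
  fit <- stats::aov(r2 ~ condition + subject, data = gof)
  tab <- summary(fit)[[1]]
  i <- grep("^condition", rownames(tab))
  data.frame(effect = "condition", F = tab$`F value`[i],
             df = tab$Df[i], df_resid = tab$Df[nrow(tab)],
             p = tab$`Pr(>F)`[i])
}
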