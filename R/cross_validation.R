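# Cross-validated model comparison: predict held-out stimulus conditions
# from pRF models trained on an independent condition.

#' Predict a held-out condition from fitted pRFs
#'
#' Evaluates the forward model with each vertex's trained parameters on the
#' apertures of an independent target condition. Vertices with missing
#' (unfitted) parameters are skipped and their count reported as an
#' attribute.
#'
#' @param fits fit table from \code{\link{fit_prf}} (needs x0, y0, sigma,
#'   beta and vertex_id).
#' @param target_apertures the target condition's \code{aperture_sequence}
#'   or list of runs.
#' @param hrf an \code{hrf_kernel} or \code{hrf_params}.
#' @return matrix vertices x time of predicted series (rows align with
#'   \code{fits}); unfitted vertices are all-NA rows. Attribute
#'   \code{n_skipped} counts them.
#' @export
predict_heldout <- function(fits, target_apertures, hrf) {
  stacked <- stack_runs(target_apertures)
  kernel <- as_hrf_kernel(hrf)
  ok <- is.finite(fits$x0) & is.finite(fits$y0) &
    is.finite(fits$sigma) & fits$sigma > 0 & is.finite(fits$beta)
  out <- matrix(NA_real_, nrow(fits), stacked$n_volumes)
  if (any(ok)) {
    g <- stacked$grid
    d2 <- outer(g$x, fits$x0[ok], "-")^2 + outer(g$y, fits$y0[ok], "-")^2
    W <- exp(-sweep(d2, 2, 2 * fits$sigma[ok]^2, "/"))
    pred <- conv_by_run(stacked$masks %*% W, stacked, kernel)
    pred <- sweep(pred, 2, fits$beta[ok], "*")
    out[ok, ] <- t(pred)
  }
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Fisher-z prediction accuracy per region
#'
#' Per-vertex Pearson correlation between predicted and observed series,
#' variance-stabilized with Fisher's z = atanh(r) and averaged across the
#' vertices of each region. Correlations of exactly +/-1 are clipped to
#' +/-(1 - 1e-7) before the transform and flagged.
#'
#' @param predictions,observed matrices vertices x time.
#' @param roi_labels per-vertex region labels.
#' @return list with \code{by_roi} (roi, mean_z, n) and \code{per_vertex}
#'   (vertex, roi, r, z, clipped).
#' @export
fisher_z_scores <- function(predictions, observed, roi_labels) {
  if (!all(dim(predictions) == dim(observed))) {
    stop("predictions and observed must have matching dimensions")
  }
  r <- vapply(seq_len(nrow(observed)), function(i) {
    p <- predictions[i, ]
    if (anyNA(p) || stats::sd(p) == 0 || stats::sd(observed[i, ]) == 0) {
      return(NA_real_)
    }
    stats::cor(p, observed[i, ])
  }, numeric(1))
  clipped <- is.finite(r) & abs(r) >= 1
  r_c <- ifelse(clipped, sign(r) * (1 - 1e-7), r)
  z <- atanh(r_c)
  per_vertex <- data.frame(vertex = seq_along(r), roi = roi_labels,
                           r = r, z = z, clipped = clipped)
  ok <- is.finite(z)
  by_roi <- stats::aggregate(z ~ roi, data = per_vertex[ok, ], FUN = mean)
  names(by_roi)[2] <- "mean_z"
  by_roi$n <- as.vector(table(per_vertex$roi[ok])[by_roi$roi])
  list(by_roi = by_roi, per_vertex = per_vertex)
}

#' Compare two training conditions by paired test
#'
#' For each region, a paired t-test on the per-unit (subject-by-hemisphere)
#' mean Fisher-z scores between the two training conditions. The reported
#' difference is condition 1 minus condition 2 (first factor level or first
#' unique value); swapping the labels negates both difference and t.
#'
#' @param z_table data frame with columns \code{roi}, \code{unit} (pairing
#'   unit), \code{condition} (exactly two levels) and \code{z}.
#' @return data frame per region: mean z per condition, z_diff, t, df, p.
#' @export
compare_training_conditions <- function(z_table) {
  conds <- unique(as.character(z_table$condition))
  if (length(conds) != 2) stop("exactly two training conditions required")
  out <- lapply(split(z_table, z_table$roi), function(d) {
    w <- stats::reshape(d[, c("roi", "unit", "condition", "z")],
                        idvar = "unit", timevar = "condition",
                        direction = "wide")
    z1 <- w[[paste0("z.", conds[1])]]
    z2 <- w[[paste0("z.", conds[2])]]
    ok <- stats::complete.cases(z1, z2)
    if (sum(ok) < 2) stop("need at least 2 complete pairs per region")
    dd <- z1[ok] - z2[ok]
    n <- length(dd)
    sd_d <- stats::sd(dd)
    t_stat <- if (sd_d == 0) {
      if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
    } else mean(dd) / (sd_d / sqrt(n))
    data.frame(roi = d$roi[1],
               mean_z_1 = mean(z1[ok]), mean_z_2 = mean(z2[ok]),
               z_diff = mean(dd), t = t_stat, df = n - 1,
               p = 2 * stats::pt(-abs(t_stat), n - 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "conditions") <- conds
  out
}
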