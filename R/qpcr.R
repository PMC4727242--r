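#' Fit a qPCR standard curve
#'
#' Fits the least-squares line of Ct on log10(template quantity) from a
#' dilution series measured on the same plate, and derives the amplification
#' efficiency from the slope. Quantification of unknowns against the curve
#' (see [invert_quantity()]) is how absolute picogram amounts are obtained
#' from BAC control-template dilutions.
#'
#' Efficiency is expressed as a fraction `E` (1.0 = perfect doubling per
#' cycle), with amplification factor `1 + E = 10^(-1/slope)`; a perfect
#' 10-fold dilution series therefore spans `log2(10) ~ 3.32` cycles per
#' decade.
#'
#' @param points data.frame with columns `quantity_pg` (> 0) and `ct`
#'   (cycles; `NA` = undetermined well, dropped before fitting).
#' @return An object of class `standard_curve`: list with `slope` (cycles per
#'   log10 pg, negative), `intercept` (Ct at 1 pg), `efficiency` (fraction),
#'   `r2`, and `n_points` used.
#' @examples
#' d <- data.frame(quantity_pg = 10^(3:-2), ct = 30 - log2(10) * (3:-2))
#' crv <- fit_standard_curve(d)
#' crv$efficiency  # 1.0
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("quantity_pg", "ct") %in% names(points)))
  pts <- points[!is.na(points$ct), , drop = FALSE]
  if (any(pts$quantity_pg <= 0)) {
    stop("standard-curve quantities must be positive (picograms)")
  }
  if (length(unique(pts$quantity_pg)) < 3L) {
    stop("standard curve needs >= 3 distinct template quantities")
  }
  lq <- log10(pts$quantity_pg)
  fit <- stats::lm(ct ~ lq, data = data.frame(ct = pts$ct, lq = lq))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve slope must be negative (Ct decreases with quantity)")
  }
  sst <- sum((pts$ct - mean(pts$ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(
    list(slope = slope,
         intercept = intercept,
         efficiency = 10^(-1 / slope) - 1,
         r2 = r2,
         n_points = nrow(pts)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.4f cycles/log10(pg), intercept %.3f,\n",
    x$slope, x$intercept))
  cat(sprintf("  efficiency E = %.4f (amplification factor %.4f), R^2 = %.5f, n = %d\n",
              x$efficiency, 1 + x$efficiency, x$r2, x$n_points))
  invisible(x)
}

#' Predict Ct from quantity under a standard curve
#'
#' Forward model `ct = intercept + slope * log10(quantity_pg)`.
#'
#' @param curve a `standard_curve`.
#' @param quantity_pg template quantities in picograms (> 0).
#' @return predicted Ct values (cycles).
#' @export
predict_ct <- function(curve, quantity_pg) {
  stopifnot(inherits(curve, "standard_curve"), all(quantity_pg > 0))
  curve$intercept + curve$slope * log10(quantity_pg)
}

#' Invert a Ct to an absolute template quantity
#'
#' `q = 10^((ct - intercept) / slope)`. Censored (missing) Cts propagate as
#' `NA` picograms rather than an error, so undetermined wells stay flagged
#' through the pipeline.
#'
#' @param ct Ct values (cycles); `NA` = censored/undetermined.
#' @param curve a `standard_curve`.
#' @return quantities in picograms (`NA` where ct was missing).
#' @export
invert_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Aggregate technical replicate Cts
#'
#' Arithmetic mean of uncensored wells per (assay, sample); at least one
#' uncensored well is required, otherwise the aggregate is `NA` (flagged
#' missing, never silently dropped).
#'
#' @param plate data.frame with columns `assay`, `sample`, `replicate`, `ct`.
#' @return data.frame with one row per (assay, sample): `ct` (mean of
#'   uncensored wells or `NA`), `n_wells` used, `ct_sd` across wells.
#' @export
aggregate_replicates <- function(plate) {
  stopifnot(all(c("assay", "sample", "ct") %in% names(plate)))
  key <- interaction(plate$assay, plate$sample, drop = TRUE, sep = "\r")
  agg <- lapply(split(plate, key), function(d) {
    ok <- !is.na(d$ct)
    data.frame(assay = d$assay[1L], sample = d$sample[1L],
               ct = if (any(ok)) mean(d$ct[ok]) else NA_real_,
               n_wells = sum(ok),
               ct_sd = if (sum(ok) > 1L) stats::sd(d$ct[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$assay, out$sample), , drop = FALSE]
}

#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' `ddct = (target_treated - ref_treated) - (target_control - ref_control)`;
#' fold change is `2^-ddct`. The reference assay is a loading control
#' (e.g. GAPDH, U6 snRNA, cyclophilin B). Missing inputs propagate as a
#' flagged missing result with a reason code rather than an error.
#'
#' @param target_treated,ref_treated,target_control,ref_control aggregated
#'   Cts (cycles) of the target and reference assays in the treated and
#'   control conditions.
#' @return list of class `relative_expression`: `ddct`, `fold_change`
#'   (`2^-ddct`), `log2_fold`, and `reason` (`NA` unless missing input).
#' @examples
#' ddct_fold_change(24, 20, 25, 20)$fold_change  # 2
#' @export
ddct_fold_change <- function(target_treated, ref_treated,
                             target_control, ref_control) {
  cts <- c(target_treated, ref_treated, target_control, ref_control)
  if (length(cts) != 4L || anyNA(cts)) {
    return(structure(list(ddct = NA_real_, fold_change = NA_real_,
                          log2_fold = NA_real_, reason = "missing_ct"),
                     class = "relative_expression"))
  }
  ddct <- (target_treated - ref_treated) - (target_control - ref_control)
  structure(list(ddct = ddct, fold_change = 2^(-ddct), log2_fold = -ddct,
                 reason = NA_character_),
            class = "relative_expression")
}

#' Centre per-sample normalized Cts to their mean
#'
#' The centred delta-Ct representation used for cross-sample scatter plots:
#' each sample's normalized Ct minus the mean over samples, so the output
#' always averages zero.
#'
#' @param delta_cts numeric vector of per-sample normalized Cts (length >= 2).
#' @return centred values, same length.
#' @export
center_delta_ct <- function(delta_cts) {
  if (length(delta_cts) < 2L) stop("need >= 2 values to centre")
  delta_cts - mean(delta_cts)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks for ties; missing pairs are dropped pairwise. The p-value is
#' exact (permutation distribution) for n < 10 and uses the t approximation
#' otherwise. Zero rank variance in either variable yields an `NA` rho with a
#' reason flag.
#'
#' @param x,y paired numeric vectors.
#' @return list: `rho`, `p_value`, `n` (pairs used), `reason` (`NA` or
#'   `"zero_rank_variance"` / `"too_few_pairs"`).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "too_few_pairs"))
  }
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "zero_rank_variance"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n < 10L)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       reason = NA_character_)
}

#' Relative DNA copy number by 2^-ddCt genotyping
#'
#' Copy number of a genomic region relative to a reference amplicon
#' (e.g. GAPDH intron 1) and a calibrator sample (parental line):
#' `2^-((ct_region - ct_reference) - calibrator_delta_ct)`. A clone with two
#' of four alleles deleted gives 0.5.
#'
#' @param ct_region,ct_reference Cts of the target region and the reference
#'   amplicon in the clone under test.
#' @param calibrator_delta_ct `ct_region - ct_reference` measured in the
#'   calibrator (parental) sample.
#' @return relative copy number (unitless).
#' @export
copy_number_ratio <- function(ct_region, ct_reference, calibrator_delta_ct) {
  if (anyNA(c(ct_region, ct_reference, calibrator_delta_ct))) {
    stop("copy_number_ratio requires all Cts and the calibrator delta-Ct")
  }
  2^(-((ct_region - ct_reference) - calibrator_delta_ct))
}

#' Combine fold changes normalized to several loading controls
#'
#' When expression is normalized to more than one loading control the
#' per-control fold changes are combined by geometric mean (folds are
#' multiplicative).
#'
#' @param folds numeric vector of per-control fold changes (> 0).
#' @return a single combined fold change.
#' @export
combine_control_folds <- function(folds) {
  stopifnot(length(folds) >= 1L, all(folds > 0))
  exp(mean(log(folds)))
}
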