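# MeDIP and ChIP enrichment normalization: spike-in-calibrated percent
# methylation, percent-of-input with dilution correction, histone-H3
# normalization, and cross-region methylation correlation.

#' Spike-in immunoprecipitation controls
#'
#' Recovery fractions (IP/input) of the fully methylated positive control
#' and the unmethylated negative control added to each MeDIP reaction; they
#' calibrate immunoprecipitation efficiency.
#'
#' @param meth_recovery recovery of the methylated control, in (0, 1].
#' @param unmeth_recovery recovery of the unmethylated control,
#'   `0 <= unmeth_recovery < meth_recovery`.
#' @return object of class `spike_in_controls`.
#' @export
spike_in_controls <- function(meth_recovery, unmeth_recovery) {
  if (!(unmeth_recovery >= 0 && unmeth_recovery < meth_recovery &&
          meth_recovery <= 1)) {
    stop("need 0 <= unmeth_recovery < meth_recovery <= 1")
  }
  structure(list(meth_recovery = meth_recovery,
                 unmeth_recovery = unmeth_recovery),
            class = "spike_in_controls")
}

#' MeDIP percent methylation with spike-in calibration
#'
#' Linear two-point interpolation between the control recoveries:
#' `%meth = (ip/input - unmeth) / (meth - unmeth)`, clipped to `[0, 1]`
#' (with a warning when the observed recovery exceeds the methylated
#' control by more than `tolerance`). Exact at both controls by
#' construction. The raw IP/input recovery is returned alongside.
#'
#' @param ip_pg,input_pg immunoprecipitated and input DNA quantities (pg);
#'   `input_pg > 0`.
#' @param controls a [spike_in_controls()].
#' @param tolerance slack above the methylated-control recovery before
#'   warning (default 0.05 of the control range).
#' @return list: `percent_methylation` (fraction in `[0, 1]`), `recovery`
#'   (raw IP/input).
#' @export
medip_percent_methylation <- function(ip_pg, input_pg, controls,
                                      tolerance = 0.05) {
  stopifnot(inherits(controls, "spike_in_controls"), input_pg > 0,
            ip_pg >= 0)
  recovery <- ip_pg / input_pg
  span <- controls$meth_recovery - controls$unmeth_recovery
  frac <- (recovery - controls$unmeth_recovery) / span
  if (frac > 1 + tolerance) {
    warning("recovery exceeds the methylated control; clipped to 100%")
  }
  list(percent_methylation = min(max(frac, 0), 1), recovery = recovery)
}

#' ChIP signal as percent of input
#'
#' `%input = 100 * 2^((input_ct - log2(1/dilution)) - ip_ct)`: the input Ct
#' is first adjusted for the fraction of chromatin it represents, then the
#' IP is expressed relative to it assuming perfect doubling. Invariant to
#' adding a constant to both Cts. Missing Cts propagate as `NA`.
#'
#' @param ip_ct,input_ct Cts of the IP and the diluted input.
#' @param input_dilution fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. a 1% input).
#' @return percent of input (numeric, `NA` if a Ct is missing).
#' @export
chip_percent_input <- function(ip_ct, input_ct, input_dilution = 0.01) {
  stopifnot(input_dilution > 0, input_dilution <= 1)
  if (anyNA(c(ip_ct, input_ct))) return(NA_real_)
  100 * 2^((input_ct - log2(1 / input_dilution)) - ip_ct)
}

#' Normalize a ChIP signal to the histone H3 signal
#'
#' Target percent-of-input divided by the anti-H3 percent-of-input at the
#' same region, correcting for nucleosome density.
#'
#' @param target_percent_input,h3_percent_input percent-of-input values.
#' @return unitless ratio (`NA` with a warning when H3 is 0 or missing).
#' @export
normalize_to_h3 <- function(target_percent_input, h3_percent_input) {
  if (is.na(h3_percent_input) || h3_percent_input == 0) {
    warning("H3 signal missing or zero; normalized value undefined")
    return(NA_real_)
  }
  target_percent_input / h3_percent_input
}

#' Pairwise Spearman correlation of region methylation across samples
#'
#' @param methylation regions x samples numeric matrix (region ids as row
#'   names, >= 5 samples).
#' @return list: `rho` and `p_value` matrices (regions x regions; `NA` on
#'   the diagonal-complement where a region is constant).
#' @export
region_methylation_correlation <- function(methylation) {
  stopifnot(is.matrix(methylation), !is.null(rownames(methylation)),
            ncol(methylation) >= 5L)
  regions <- rownames(methylation)
  k <- length(regions)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      sc <- spearman_cor(methylation[i, ], methylation[j, ])
      rho[i, j] <- rho[j, i] <- sc$rho
      p[i, j] <- p[j, i] <- sc$p_value
    }
  }
  list(rho = rho, p_value = p)
}
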