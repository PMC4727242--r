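# Synthetic 3C scenario: distance-decay background, optional
# promoter-promoter loops, per-primer bias, and qPCR rendering of junction
# quantities alongside the equimolar BAC control.

#' Generate a random locus sequence with restriction sites
#'
#' Random DNA with the recognition motif inserted at roughly even spacings;
#' additional chance occurrences of the motif in the random background are
#' legitimate sites (the truth fragment map is always obtained by digesting
#' the returned sequence).
#'
#' @param length sequence length (bp).
#' @param n_sites number of motifs inserted.
#' @param site motif to insert (default NcoI, `"CCATGG"`).
#' @param seed integer seed.
#' @return a character DNA sequence.
#' @export
make_locus_sequence <- function(length = 20000L, n_sites = 13L,
                                site = "CCATGG", seed = 1L) {
  stopifnot(length > (n_sites + 1L) * nchar(site))
  withr::with_seed(as.integer(seed), {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    at <- round(seq_len(n_sites) * length / (n_sites + 1L))
    for (p in at) {
      s[p:(p + nchar(site) - 1L)] <- strsplit(site, "")[[1L]]
    }
    paste(s, collapse = "")
  })
}

#' Specify a synthetic 3C scenario
#'
#' Junction quantities follow a power-law distance decay from the anchor,
#' optionally enriched `fold`-times at loop partner fragments, and
#' multiplied by an arbitrary per-primer bias. The BAC control carries the
#' same per-primer bias on equimolar junctions, so BAC normalization
#' cancels the bias exactly in the noise-free limit.
#'
#' @param fragment_map a [digest_sequence()] map.
#' @param anchor anchor fragment id (e.g. the miR-200c/141 promoter
#'   fragment).
#' @param background_alpha decay exponent (> 0).
#' @param loops `NULL` or data.frame with columns `anchor`, `partner`,
#'   `fold` (all folds > 1; fragments must exist in the map).
#' @param primer_bias `NULL` (no bias) or named multiplicative factors per
#'   fragment id.
#' @param noise a [qpcr_noise_model()] used to render Cts.
#' @param base_pg sample junction quantity at the reference distance.
#' @param bac_pg BAC control junction quantity (equimolar).
#' @param seed integer seed.
#' @return object of class `three_c_scenario`.
#' @export
three_c_scenario <- function(fragment_map, anchor, background_alpha = 1,
                             loops = NULL, primer_bias = NULL,
                             noise = qpcr_noise_model(ct_sd = 0.2),
                             base_pg = 50, bac_pg = 10, seed = 1L) {
  stopifnot(inherits(fragment_map, "fragment_map"), background_alpha > 0,
            base_pg > 0, bac_pg > 0)
  ids <- fragment_map$fragments$id
  if (!anchor %in% ids) stop("anchor fragment not in map: ", anchor)
  if (!is.null(loops)) {
    stopifnot(all(c("anchor", "partner", "fold") %in% names(loops)))
    bad <- setdiff(c(loops$anchor, loops$partner), ids)
    if (length(bad)) stop("loop fragment(s) not in map: ",
                          paste(bad, collapse = ", "))
    if (any(loops$fold <= 1)) stop("loop enrichment folds must be > 1")
  }
  if (!is.null(primer_bias)) {
    stopifnot(!is.null(names(primer_bias)), all(primer_bias > 0))
  }
  structure(list(fragment_map = fragment_map, anchor = anchor,
                 background_alpha = background_alpha, loops = loops,
                 primer_bias = primer_bias, noise = noise,
                 base_pg = base_pg, bac_pg = bac_pg,
                 seed = as.integer(seed)),
            class = "three_c_scenario")
}

# True (noise-free) junction quantities of a scenario, one per non-anchor
# fragment; the decay is relative to the closest 3' fragment's distance.
.scenario_truth <- function(sc) {
  fr <- sc$fragment_map$fragments
  mid_anchor <- fr$midpoint[fr$id == sc$anchor]
  others <- fr[fr$id != sc$anchor, , drop = FALSE]
  d <- abs(others$midpoint - mid_anchor)
  d_ref <- min(d[others$midpoint > mid_anchor])
  q <- sc$base_pg * (d / d_ref)^(-sc$background_alpha)
  fold <- rep(1, nrow(others))
  if (!is.null(sc$loops)) {
    for (i in seq_len(nrow(sc$loops))) {
      hit <- (sc$loops$anchor[i] == sc$anchor &
                others$id == sc$loops$partner[i]) |
             (sc$loops$partner[i] == sc$anchor &
                others$id == sc$loops$anchor[i])
      fold[hit] <- fold[hit] * sc$loops$fold[i]
    }
  }
  bias <- rep(1, nrow(others))
  if (!is.null(sc$primer_bias)) {
    hit <- others$id %in% names(sc$primer_bias)
    bias[hit] <- sc$primer_bias[others$id[hit]]
  }
  data.frame(fragment = others$id, sample_pg = q * fold * bias,
             bac_pg = sc$bac_pg * bias, stringsAsFactors = FALSE)
}

#' Simulate 3C junction qPCR tables
#'
#' Renders the scenario's junction quantities as Cts under the qPCR noise
#' model (one junction assay per non-anchor fragment), for both the 3C
#' sample and the digested-and-ligated BAC control, plus the 6-point BAC
#' dilution series per assay used for standard-curve quantification.
#'
#' @param scenario a [three_c_scenario()].
#' @param n_technical technical replicate wells per assay.
#' @return list: `sample_plate`, `bac_plate` (assay, sample, replicate,
#'   ct), `dilutions` (assay, quantity_pg, ct), `truth` (noise-free
#'   quantities), `scenario`.
#' @export
make_3c_tables <- function(scenario, n_technical = 3L) {
  stopifnot(inherits(scenario, "three_c_scenario"), n_technical >= 1L)
  truth <- .scenario_truth(scenario)
  noise <- scenario$noise
  dq <- bac_dilution_series()
  withr::with_seed(scenario$seed, {
    mk_plate <- function(q, label) {
      do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
        a <- truth$fragment[i]
        ct <- .model_ct(q[i], noise, a) +
          stats::rnorm(n_technical, 0, noise$ct_sd)
        data.frame(assay = a, sample = label,
                   replicate = seq_len(n_technical),
                   ct = .censor_ct(ct, noise$max_cycles),
                   stringsAsFactors = FALSE)
      }))
    }
    sample_plate <- mk_plate(truth$sample_pg, "sample_3c")
    bac_plate <- mk_plate(truth$bac_pg, "bac_control")
    dil <- do.call(rbind, lapply(truth$fragment, function(a) {
      ct <- .model_ct(dq, noise, a) + stats::rnorm(length(dq), 0, noise$ct_sd)
      data.frame(assay = a, quantity_pg = dq,
                 ct = .censor_ct(ct, noise$max_cycles),
                 stringsAsFactors = FALSE)
    }))
    list(sample_plate = sample_plate, bac_plate = bac_plate,
         dilutions = dil, truth = truth, scenario = scenario)
  })
}

#' End-to-end 3C profile from a scenario
#'
#' Convenience wrapper: simulate tables, normalize against the BAC control,
#' and compute the relative interaction profile over the closest 3'
#' fragment from the anchor.
#'
#' @param scenario a [three_c_scenario()].
#' @param n_technical technical replicates per assay.
#' @return an `interaction_profile`.
#' @export
profile_3c_scenario <- function(scenario, n_technical = 3L) {
  tabs <- make_3c_tables(scenario, n_technical)
  nz <- normalize_junctions(tabs$sample_plate, tabs$bac_plate,
                            tabs$dilutions)
  relative_profile(nz, scenario$fragment_map, scenario$anchor)
}
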