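# Synthetic qPCR plate generator for the PTPN6--miR-200c/141 locus.
# The measurement model is the standard log-linear qPCR response:
#   Ct = intercept - log10(q_pg) / log10(1 + E) + N(0, ct_sd),
# censored at max_cycles (undetermined wells carried as NA).

#' Transcript entities quantified along the locus
#'
#' The five RNA entities detected along the PTPN6--miR-200c/141 genomic
#' locus: the pri-PTPN6 primary transcript, the assay spanning the PTPN6
#' polyadenylation signal (PTPN6_dpA), the intermediate read-through
#' transcript, the intronic pri-miR-200c-141 primary transcript, and its
#' stabilized exonic (EST) isoform.
#' @export
locus_entities <- function() {
  c("pri_PTPN6", "PTPN6_dpA", "intermediate", "pri_miR", "pri_miR_EST")
}

#' Default assay-to-entity map for the locus
#'
#' Two independent primer pairs detect pri-PTPN6 (their picogram estimates
#' are averaged downstream); `intermediate_set1` is the qPCR-compatible
#' assay for the intermediate transcript; the loading-control assay maps to
#' no entity.
#'
#' @return data.frame with columns `assay`, `entity` (`NA` for controls).
#' @export
locus_assay_map <- function() {
  data.frame(
    assay = c("pri_PTPN6_1", "pri_PTPN6_2", "PTPN6_dpA",
              "intermediate_set1", "pri_miR", "pri_miR_EST", "GAPDH"),
    entity = c("pri_PTPN6", "pri_PTPN6", "PTPN6_dpA",
               "intermediate", "pri_miR", "pri_miR_EST", NA),
    stringsAsFactors = FALSE
  )
}

#' Construct a locus preset (true picogram amounts per entity)
#'
#' @param name preset identifier.
#' @param true_pg named numeric vector over the five [locus_entities()],
#'   picograms per reaction; all > 0.
#' @param loading_control_pg picograms for the loading-control assay.
#' @return object of class `locus_preset`.
#' @export
locus_preset <- function(name, true_pg, loading_control_pg = 10) {
  ents <- locus_entities()
  if (!setequal(names(true_pg), ents)) {
    stop("true_pg must be named over exactly the five locus entities")
  }
  true_pg <- true_pg[ents]
  if (any(true_pg <= 0) || loading_control_pg <= 0) {
    stop("all preset quantities must be positive")
  }
  structure(list(name = name, true_pg = true_pg,
                 loading_control_pg = loading_control_pg),
            class = "locus_preset")
}

#' Built-in condition presets
#'
#' Absolute picogram scales are arbitrary constants; only their ratios are
#' anchored to the measured biology: in untreated SKOV3 every pri-PTPN6
#' molecule bypasses the polyadenylation signal (bypass ratio 1) and every
#' intermediate yields a pri-miR (yield 1); under H2O2 stress pri-PTPN6
#' initiation rises fivefold while only 56% bypasses (0.14/0.25); the EST
#' isoform is >= 10-fold above the intronic pri-miR everywhere and 2.4-fold
#' higher in IGROV-1 than in stressed SKOV3.
#'
#' @param name one of `"SKOV3_NT"`, `"SKOV3_H2O2"`, `"IGROV1"`; omit to get
#'   the named list of all three.
#' @return a `locus_preset`, or a named list of the three presets.
#' @export
locus_presets <- function(name = NULL) {
  ents <- locus_entities()
  all <- list(
    SKOV3_NT   = locus_preset("SKOV3_NT",
      stats::setNames(c(0.05, 0.05, 0.05, 0.05, 0.625), ents)),
    SKOV3_H2O2 = locus_preset("SKOV3_H2O2",
      stats::setNames(c(0.25, 0.14, 0.14, 0.14, 1.75), ents)),
    IGROV1     = locus_preset("IGROV1",
      stats::setNames(c(0.35, 0.35, 0.35, 0.35, 4.2), ents))
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop("unknown preset: ", name, " (expected SKOV3_NT, SKOV3_H2O2, IGROV1)")
  }
  all[[name]]
}

#' qPCR noise / response model
#'
#' Per-assay log-linear Ct response with Gaussian cycle noise and censoring.
#' `efficiency` and `intercept` may be scalars (recycled over assays) or
#' named vectors; assays absent from a named vector are rejected at
#' simulation time.
#'
#' @param ct_sd cycle noise s.d. (>= 0; 0 gives deterministic plates).
#' @param max_cycles censoring limit; wells with Ct above it are reported
#'   undetermined (`NA`).
#' @param efficiency per-assay amplification efficiency fraction in (0, 1].
#' @param intercept per-assay Ct at 1 pg.
#' @return object of class `qpcr_noise_model`.
#' @export
qpcr_noise_model <- function(ct_sd = 0.2, max_cycles = 40,
                             efficiency = 1, intercept = 30) {
  stopifnot(ct_sd >= 0, max_cycles > 0,
            all(efficiency > 0), all(efficiency <= 1))
  structure(list(ct_sd = ct_sd, max_cycles = max_cycles,
                 efficiency = efficiency, intercept = intercept),
            class = "qpcr_noise_model")
}

#' Default noise model for the locus assays
#'
#' Mildly heterogeneous per-assay efficiencies and intercepts, so that the
#' per-assay standard-curve normalization is actually exercised.
#' @param ct_sd cycle noise s.d. (default 0.2 cycles).
#' @return a [qpcr_noise_model()].
#' @export
locus_noise_model <- function(ct_sd = 0.2) {
  assays <- locus_assay_map()$assay
  qpcr_noise_model(
    ct_sd = ct_sd,
    efficiency = stats::setNames(
      c(0.96, 0.94, 0.95, 0.92, 0.97, 0.93, 0.98), assays),
    intercept = stats::setNames(
      c(30.0, 30.2, 29.8, 30.5, 29.6, 30.1, 29.4), assays)
  )
}

.assay_param <- function(par, assay) {
  if (is.null(names(par))) return(par[1L])
  if (!assay %in% names(par)) {
    stop("assay not covered by the noise model: ", assay)
  }
  unname(par[[assay]])
}

# Noise-free Ct under the model; vectorized over quantity.
.model_ct <- function(quantity_pg, noise, assay) {
  if (any(quantity_pg <= 0)) stop("template quantity must be positive")
  e <- .assay_param(noise$efficiency, assay)
  b <- .assay_param(noise$intercept, assay)
  b - log10(quantity_pg) / log10(1 + e)
}

.censor_ct <- function(ct, max_cycles) ifelse(ct > max_cycles, NA_real_, ct)

#' Standard BAC dilution series quantities
#'
#' Six ten-fold dilutions, 1000 pg down to 0.01 pg.
#' @export
bac_dilution_series <- function() 10^(3:-2)

#' Simulate qPCR plates for a locus condition
#'
#' Generates, under one fixed seed, (i) a sample plate of technical-replicate
#' Cts for every locus assay over `n_biological` independent experiments and
#' (ii) a 6-point ten-fold BAC control-template dilution series measured
#' under the same per-assay response, as used for absolute quantification on
#' the same plate. With `ct_sd = 0` the output is deterministic and the
#' downstream pipeline recovers the preset ratios exactly.
#'
#' @param preset a [locus_preset()] or a preset name.
#' @param noise a [qpcr_noise_model()]; default [locus_noise_model()].
#' @param seed integer seed (RNG state is restored afterwards).
#' @param n_technical technical replicate wells per assay and sample.
#' @param n_biological independent biological replicates (samples).
#' @return list with `plate` (assay, sample, replicate, ct), `dilutions`
#'   (assay, quantity_pg, ct), `preset`.
#' @export
make_locus_plates <- function(preset, noise = locus_noise_model(),
                              seed = 1L, n_technical = 3L,
                              n_biological = 6L) {
  if (is.character(preset)) preset <- locus_presets(preset)
  stopifnot(inherits(preset, "locus_preset"),
            inherits(noise, "qpcr_noise_model"),
            n_technical >= 1L, n_biological >= 1L)
  amap <- locus_assay_map()
  truth <- c(preset$true_pg,
             stats::setNames(preset$loading_control_pg, "GAPDH"))
  entity_of <- stats::setNames(amap$entity, amap$assay)

  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (assay in amap$assay) {
      ent <- entity_of[[assay]]
      q <- if (is.na(ent)) truth[["GAPDH"]] else truth[[ent]]
      base_ct <- .model_ct(q, noise, assay)
      for (b in seq_len(n_biological)) {
        ct <- base_ct + stats::rnorm(n_technical, 0, noise$ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          assay = assay,
          sample = sprintf("%s_rep%d", preset$name, b),
          replicate = seq_len(n_technical),
          ct = .censor_ct(ct, noise$max_cycles),
          stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, rows)

    dq <- bac_dilution_series()
    dil <- do.call(rbind, lapply(amap$assay, function(assay) {
      ct <- .model_ct(dq, noise, assay) +
        stats::rnorm(length(dq), 0, noise$ct_sd)
      data.frame(assay = assay, quantity_pg = dq,
                 ct = .censor_ct(ct, noise$max_cycles),
                 stringsAsFactors = FALSE)
    }))
    list(plate = plate, dilutions = dil, preset = preset)
  })
}
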