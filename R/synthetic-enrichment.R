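# Synthetic MeDIP / ChIP qPCR tables with spike-in controls.

#' Simulate MeDIP and ChIP qPCR tables
#'
#' Region IP recovery follows the two-point spike-in model
#' `recovery = unmeth + truth * (meth - unmeth)`; ChIP recovery is the
#' truth occupancy times the histone H3 reference recovery. Quantities are
#' rendered as (ip_ct, input_ct) pairs under the qPCR response, with the
#' spike-in controls measured on the same plate.
#'
#' @param truth_methylation named fractions in `[0, 1]` per region, or a
#'   regions x samples matrix of fractions (row names = regions).
#' @param controls a [spike_in_controls()] (true IP efficiencies).
#' @param truth_occupancy named fractions per region for the ChIP target
#'   antibody (`NULL` to skip the ChIP table).
#' @param h3_recovery IP/input recovery of the anti-H3 reference.
#' @param input_pg input DNA per reaction (pg).
#' @param input_dilution fraction of chromatin measured as ChIP input.
#' @param noise a [qpcr_noise_model()].
#' @param n_replicates independent replicates per region and sample.
#' @param seed integer seed.
#' @return list: `medip` (region, sample, replicate, ip_ct, input_ct; the
#'   spike-in controls appear as regions `spike_meth` / `spike_unmeth`),
#'   `chip` (adds `antibody` in target/H3, or `NULL`), `controls`,
#'   `truth_methylation`, `truth_occupancy`.
#' @export
make_enrichment_tables <- function(truth_methylation, controls,
                                   truth_occupancy = NULL,
                                   h3_recovery = 0.10,
                                   input_pg = 10, input_dilution = 0.01,
                                   noise = qpcr_noise_model(ct_sd = 0.1),
                                   n_replicates = 6L, seed = 1L) {
  stopifnot(inherits(controls, "spike_in_controls"), input_pg > 0,
            h3_recovery > 0, h3_recovery <= 1)
  tm <- if (is.matrix(truth_methylation)) truth_methylation else
    matrix(truth_methylation, ncol = 1,
           dimnames = list(names(truth_methylation), "s1"))
  if (any(tm < 0 | tm > 1)) stop("truth methylation fractions must be in [0, 1]")
  if (!is.null(truth_occupancy) &&
        any(truth_occupancy < 0 | truth_occupancy > 1)) {
    stop("truth occupancy fractions must be in [0, 1]")
  }

  span <- controls$meth_recovery - controls$unmeth_recovery
  ct_pair <- function(ip_pg, nm) {
    c(ip = .model_ct(ip_pg, nm, "enrichment") + stats::rnorm(1, 0, nm$ct_sd),
      input = .model_ct(input_pg, nm, "enrichment") +
        stats::rnorm(1, 0, nm$ct_sd))
  }

  withr::with_seed(as.integer(seed), {
    rows <- list()
    emit <- function(region, sample, rep, truth) {
      ip_pg <- input_pg * (controls$unmeth_recovery + truth * span)
      cts <- ct_pair(ip_pg, noise)
      rows[[length(rows) + 1L]] <<- data.frame(
        region = region, sample = sample, replicate = rep,
        ip_ct = .censor_ct(cts[["ip"]], noise$max_cycles),
        input_ct = .censor_ct(cts[["input"]], noise$max_cycles),
        stringsAsFactors = FALSE)
    }
    for (s in colnames(tm)) {
      for (r in rownames(tm)) {
        for (b in seq_len(n_replicates)) emit(r, s, b, tm[r, s])
      }
      for (b in seq_len(n_replicates)) {
        emit("spike_meth", s, b, 1)
        emit("spike_unmeth", s, b, 0)
      }
    }
    medip <- do.call(rbind, rows)

    chip <- NULL
    if (!is.null(truth_occupancy)) {
      crows <- list()
      for (r in names(truth_occupancy)) {
        for (ab in c("target", "H3")) {
          frac <- if (ab == "H3") h3_recovery else
            truth_occupancy[[r]] * h3_recovery
          for (b in seq_len(n_replicates)) {
            ip_ct <- .model_ct(input_pg * frac, noise, "enrichment") +
              stats::rnorm(1, 0, noise$ct_sd)
            input_ct <- .model_ct(input_pg * input_dilution, noise,
                                  "enrichment") +
              stats::rnorm(1, 0, noise$ct_sd)
            crows[[length(crows) + 1L]] <- data.frame(
              region = r, sample = "s1", replicate = b, antibody = ab,
              ip_ct = .censor_ct(ip_ct, noise$max_cycles),
              input_ct = .censor_ct(input_ct, noise$max_cycles),
              stringsAsFactors = FALSE)
          }
        }
      }
      chip <- do.call(rbind, crows)
    }
    list(medip = medip, chip = chip, controls = controls,
         truth_methylation = tm, truth_occupancy = truth_occupancy,
         input_dilution = input_dilution)
  })
}

#' IP/input recovery from a Ct pair
#'
#' `recovery = (1 + E)^(input_ct - ip_ct)` for amplification efficiency `E`.
#'
#' @param ip_ct,input_ct Cts of the IP and undiluted input reactions.
#' @param efficiency amplification efficiency fraction (default 1).
#' @return recovery fraction (`NA` when a Ct is missing).
#' @export
recovery_from_cts <- function(ip_ct, input_ct, efficiency = 1) {
  stopifnot(efficiency > 0, efficiency <= 1)
  (1 + efficiency)^(input_ct - ip_ct)
}

#' Analyze a simulated MeDIP table
#'
#' Aggregates replicate Cts per region and sample (mean of uncensored
#' wells), measures the spike-in control recoveries from their own wells,
#' and converts each region's recovery to percent methylation by the
#' two-point interpolation of [medip_percent_methylation()].
#'
#' @param medip MeDIP table from [make_enrichment_tables()].
#' @param efficiency assumed amplification efficiency (default 1).
#' @return data.frame: `region`, `sample`, `recovery`,
#'   `percent_methylation` (spike-in rows are consumed, not reported).
#' @export
analyze_medip_table <- function(medip, efficiency = 1) {
  agg_ct <- function(x) if (any(!is.na(x))) mean(x[!is.na(x)]) else NA_real_
  key <- interaction(medip$region, medip$sample, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(medip, key), function(d) {
    data.frame(region = d$region[1L], sample = d$sample[1L],
               recovery = recovery_from_cts(agg_ct(d$ip_ct),
                                            agg_ct(d$input_ct), efficiency),
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (s in unique(agg$sample)) {
    a <- agg[agg$sample == s, , drop = FALSE]
    meth <- a$recovery[a$region == "spike_meth"]
    unmeth <- a$recovery[a$region == "spike_unmeth"]
    if (!length(meth) || !length(unmeth)) {
      stop("spike-in control wells missing for sample ", s)
    }
    ctl <- spike_in_controls(meth, unmeth)
    reg <- a[!a$region %in% c("spike_meth", "spike_unmeth"), , drop = FALSE]
    reg$percent_methylation <- vapply(reg$recovery, function(rv) {
      medip_percent_methylation(rv, 1, ctl)$percent_methylation
    }, numeric(1))
    out[[s]] <- reg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analyze a simulated ChIP table
#'
#' Aggregates replicate Cts, computes percent of input with the dilution
#' correction, and normalizes the target antibody to H3 per region.
#'
#' @param chip ChIP table from [make_enrichment_tables()].
#' @param input_dilution input chromatin fraction (default 0.01).
#' @return data.frame: `region`, `target_percent_input`,
#'   `h3_percent_input`, `h3_normalized`.
#' @export
analyze_chip_table <- function(chip, input_dilution = 0.01) {
  agg_ct <- function(x) if (any(!is.na(x))) mean(x[!is.na(x)]) else NA_real_
  rows <- lapply(split(chip, chip$region), function(d) {
    pi <- vapply(c("target", "H3"), function(ab) {
      sub <- d[d$antibody == ab, , drop = FALSE]
      chip_percent_input(agg_ct(sub$ip_ct), agg_ct(sub$input_ct),
                         input_dilution)
    }, numeric(1))
    data.frame(region = d$region[1L], target_percent_input = pi[["target"]],
               h3_percent_input = pi[["H3"]],
               h3_normalized = normalize_to_h3(pi[["target"]], pi[["H3"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
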