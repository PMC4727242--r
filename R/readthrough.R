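# Absolute quantification of the five transcript entities along the
# PTPN6--miR-200c/141 locus and the derived read-through ratios.

#' Absolute quantification of locus transcript entities
#'
#' For each assay, fits a standard curve from the plate's own BAC dilution
#' series, aggregates technical-replicate Cts (mean of uncensored wells per
#' biological replicate), inverts to picograms, and averages per-replicate
#' picogram estimates per entity. When two assays detect the same entity
#' (the two pri-PTPN6 primer pairs) their picogram estimates are averaged.
#' Entities with no passing wells are flagged missing (`NA`), never dropped.
#'
#' All entities are compared within one plate sharing a single dilution
#' series per assay; supplying plates from different runs without a shared
#' calibrator is refused by construction of the input contract.
#'
#' @param plates sample plate data.frame (`assay`, `sample`, `replicate`,
#'   `ct`) or the list returned by [make_locus_plates()].
#' @param dilutions dilution-series data.frame (`assay`, `quantity_pg`,
#'   `ct`); ignored if `plates` is a `make_locus_plates()` list.
#' @param assay_map data.frame mapping `assay` to `entity`
#'   (default [locus_assay_map()]); assays with `NA` entity (loading
#'   controls) are quantified but not reported as entities.
#' @param condition condition label; defaults to the preset name if known.
#' @return object of class `locus_quantities`: list with `condition`, `pg`
#'   (named vector over [locus_entities()], `NA` = flagged missing), `se`
#'   (s.e.m. over biological replicates), `n_reps`, and `curves` (per-assay
#'   `standard_curve` fits).
#' @export
quantify_locus <- function(plates, dilutions = NULL,
                           assay_map = locus_assay_map(),
                           condition = NULL) {
  if (is.list(plates) && !is.data.frame(plates) && "plate" %in% names(plates)) {
    if (is.null(condition) && !is.null(plates$preset)) {
      condition <- plates$preset$name
    }
    dilutions <- plates$dilutions
    plates <- plates$plate
  }
  stopifnot(is.data.frame(plates), is.data.frame(dilutions))
  if (is.null(condition)) condition <- "unknown"

  assays <- unique(plates$assay)
  missing_curve <- setdiff(assays, unique(dilutions$assay))
  if (length(missing_curve)) {
    stop("no dilution series on this plate for assay(s): ",
         paste(missing_curve, collapse = ", "))
  }
  curves <- lapply(stats::setNames(assays, assays), function(a) {
    fit_standard_curve(dilutions[dilutions$assay == a, , drop = FALSE])
  })

  agg <- aggregate_replicates(plates)
  agg$pg <- NA_real_
  for (a in assays) {
    idx <- agg$assay == a
    agg$pg[idx] <- invert_quantity(agg$ct[idx], curves[[a]])
  }

  ents <- locus_entities()
  pg <- se <- stats::setNames(rep(NA_real_, length(ents)), ents)
  n_reps <- stats::setNames(rep(0L, length(ents)), ents)
  for (ent in ents) {
    ent_assays <- assay_map$assay[!is.na(assay_map$entity) &
                                    assay_map$entity == ent]
    sub <- agg[agg$assay %in% ent_assays & !is.na(agg$pg), , drop = FALSE]
    if (!nrow(sub)) next
    # average the assays' estimates within each biological replicate first
    per_rep <- tapply(sub$pg, sub$sample, mean)
    pg[ent] <- mean(per_rep)
    n_reps[ent] <- length(per_rep)
    if (length(per_rep) > 1L) {
      se[ent] <- stats::sd(per_rep) / sqrt(length(per_rep))
    }
  }
  structure(list(condition = condition, pg = pg, se = se, n_reps = n_reps,
                 curves = curves),
            class = "locus_quantities")
}

#' @export
print.locus_quantities <- function(x, ...) {
  cat(sprintf("Locus quantities [%s] (pg per reaction):\n", x$condition))
  for (ent in names(x$pg)) {
    cat(sprintf("  %-12s %s%s\n", ent,
                if (is.na(x$pg[ent])) "missing" else sprintf("%.4g", x$pg[ent]),
                if (is.na(x$se[ent])) "" else sprintf(" (sem %.2g, n=%d)",
                                                      x$se[ent], x$n_reps[ent])))
  }
  invisible(x)
}

.ratio_or_flag <- function(num, den, what) {
  if (is.na(num) || is.na(den)) {
    warning(what, ": input quantity missing; ratio undefined")
    return(NA_real_)
  }
  if (den == 0) {
    warning(what, ": zero denominator; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Polyadenylation-signal bypass fraction
#'
#' Ratio of the intermediate (read-through) transcript quantity to the
#' pri-PTPN6 primary-transcript quantity. A value of 1 means every primary
#' transcript bypasses the polyadenylation signal; 0.56 means 56% do. The
#' numerator is the intermediate (Set 1) assay; the dpA-spanning assay is
#' reported but not used here.
#'
#' @param q a `locus_quantities` object.
#' @return unitless ratio (`NA` with a warning if undefined).
#' @export
bypass_fraction <- function(q) {
  stopifnot(inherits(q, "locus_quantities"))
  .ratio_or_flag(q$pg[["intermediate"]], q$pg[["pri_PTPN6"]],
                 "bypass_fraction")
}

#' Read-through yield
#'
#' Ratio of the pri-miR-200c-141 primary-transcript quantity to the
#' intermediate-transcript quantity: the fraction of read-through molecules
#' that reach the miRNA transcription unit.
#'
#' @param q a `locus_quantities` object.
#' @return unitless ratio (`NA` with a warning if undefined).
#' @export
readthrough_yield <- function(q) {
  stopifnot(inherits(q, "locus_quantities"))
  .ratio_or_flag(q$pg[["pri_miR"]], q$pg[["intermediate"]],
                 "readthrough_yield")
}

#' EST (exonic) over intronic pri-miR ratio
#'
#' Ratio of the stabilized exonic pri-miR(EST) isoform to the intronic
#' pri-miR-200c-141 primary transcript; the EST accumulates because it is
#' stabilized, so this ratio is expected to be large (>= 10-fold).
#'
#' @param q a `locus_quantities` object.
#' @return unitless ratio (`NA` with a warning if undefined).
#' @export
est_ratio <- function(q) {
  stopifnot(inherits(q, "locus_quantities"))
  .ratio_or_flag(q$pg[["pri_miR_EST"]], q$pg[["pri_miR"]], "est_ratio")
}

#' Per-entity fold changes between two conditions
#'
#' Stressed over basal picogram ratio per entity (e.g. SKOV3+H2O2 versus
#' untreated SKOV3), with log2 also reported. Entities undefined in either
#' condition (missing or zero basal) propagate as `NA`.
#'
#' @param basal,stressed `locus_quantities` for the two conditions.
#' @return data.frame: `entity`, `fold` (stressed/basal), `log2_fold`.
#' @export
stress_fold_changes <- function(basal, stressed) {
  stopifnot(inherits(basal, "locus_quantities"),
            inherits(stressed, "locus_quantities"))
  ents <- locus_entities()
  fold <- vapply(ents, function(e) {
    b <- basal$pg[[e]]; s <- stressed$pg[[e]]
    if (is.na(b) || is.na(s) || b == 0) NA_real_ else s / b
  }, numeric(1))
  data.frame(entity = ents, fold = unname(fold),
             log2_fold = log2(unname(fold)), stringsAsFactors = FALSE)
}

#' Fold difference of one entity between two cell lines
#'
#' @param a,b `locus_quantities` for the two cell lines (numerator `a`).
#' @param entity one of [locus_entities()].
#' @return fold `a/b` for the entity.
#' @export
compare_cell_lines <- function(a, b, entity) {
  stopifnot(inherits(a, "locus_quantities"), inherits(b, "locus_quantities"),
            entity %in% locus_entities())
  if (is.na(a$pg[[entity]]) || is.na(b$pg[[entity]])) {
    stop("entity ", entity, " missing in one of the conditions")
  }
  .ratio_or_flag(a$pg[[entity]], b$pg[[entity]], "compare_cell_lines")
}

#' Summary of read-through ratios for one or two conditions
#'
#' Convenience wrapper collecting [bypass_fraction()], [readthrough_yield()]
#' and [est_ratio()] (plus per-entity stress folds when a basal condition is
#' supplied), with delta-method standard errors on the log scale propagated
#' from replicate s.e.m.
#'
#' @param q `locus_quantities`; @param basal optional basal condition.
#' @return data.frame: `quantity`, `value`, `se`.
#' @export
readthrough_summary <- function(q, basal = NULL) {
  stopifnot(inherits(q, "locus_quantities"))
  # delta method on log scale: var(log r) ~ (se_num/num)^2 + (se_den/den)^2
  ratio_se <- function(num, den, se_num, se_den) {
    r <- num / den
    if (anyNA(c(num, den, se_num, se_den)) || den == 0 || num == 0) {
      return(NA_real_)
    }
    r * sqrt((se_num / num)^2 + (se_den / den)^2)
  }
  rows <- data.frame(
    quantity = c("bypass_fraction", "readthrough_yield", "est_ratio"),
    value = c(bypass_fraction(q), readthrough_yield(q), est_ratio(q)),
    se = c(
      ratio_se(q$pg[["intermediate"]], q$pg[["pri_PTPN6"]],
               q$se[["intermediate"]], q$se[["pri_PTPN6"]]),
      ratio_se(q$pg[["pri_miR"]], q$pg[["intermediate"]],
               q$se[["pri_miR"]], q$se[["intermediate"]]),
      ratio_se(q$pg[["pri_miR_EST"]], q$pg[["pri_miR"]],
               q$se[["pri_miR_EST"]], q$se[["pri_miR"]])),
    stringsAsFactors = FALSE)
  if (!is.null(basal)) {
    sf <- stress_fold_changes(basal, q)
    fold_se <- vapply(seq_len(nrow(sf)), function(i) {
      e <- sf$entity[i]
      ratio_se(q$pg[[e]], basal$pg[[e]], q$se[[e]], basal$se[[e]])
    }, numeric(1))
    rows <- rbind(rows, data.frame(
      quantity = paste0("fold_", sf$entity), value = sf$fold, se = fold_se,
      stringsAsFactors = FALSE))
  }
  rows
}
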