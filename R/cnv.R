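# Copy-number subgrouping: classify samples as amplified / deleted /
# unchanged from segment means over a locus window, and correlate gene
# pairs within the resulting subgroups.

#' Define a genomic locus window
#'
#' Default window: 150 kb on chromosome 12p13 covering PTPN6 and
#' miR-200c/141 (toy coordinates; only width and overlap semantics matter).
#'
#' @param chrom chromosome identifier.
#' @param start,end 0-based half-open coordinates, `end > start`.
#' @return object of class `locus_window`.
#' @export
locus_window <- function(chrom = "chr12", start = 0L, end = 150000L) {
  stopifnot(end > start)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), width = as.numeric(end - start)),
            class = "locus_window")
}

#' Classify one sample from its copy-number segments
#'
#' A sample is `amplified` if any segment overlapping the window (any
#' base-pair overlap counts) has segment mean above `+threshold`, else
#' `deleted` if any is below `-threshold`, else `unchanged`. When both
#' thresholds are crossed, amplified takes precedence (downstream analyses
#' pool amplified and deleted into one altered group, so the precedence
#' never affects the unchanged-versus-altered contrast). No overlapping
#' segment at all yields `unchanged` with a coverage warning.
#'
#' @param segments data.frame of one sample's segments: `chrom`, `start`,
#'   `end`, `seg_mean` (log-ratio); a `sample` column, if present, must be
#'   constant.
#' @param window a [locus_window()].
#' @param threshold log-ratio cutoff (default 0.3, i.e. the +/-0.3 rule).
#' @return list of class `sample_label`: `sample`, `label`, `max_seg`,
#'   `min_seg` (over window-overlapping segments; `NA` if no coverage),
#'   `n_overlapping`.
#' @export
classify_sample <- function(segments, window, threshold = 0.3) {
  stopifnot(inherits(window, "locus_window"), threshold >= 0,
            all(c("chrom", "start", "end", "seg_mean") %in% names(segments)))
  id <- if ("sample" %in% names(segments) && nrow(segments)) {
    u <- unique(segments$sample)
    if (length(u) > 1L) stop("classify_sample expects a single sample")
    u
  } else NA_character_
  ov <- segments$chrom == window$chrom &
    segments$start < window$end & segments$end > window$start
  ovseg <- segments$seg_mean[ov]
  if (!length(ovseg)) {
    warning("no segment overlaps the locus window; labelling unchanged")
    return(structure(list(sample = id, label = "unchanged",
                          max_seg = NA_real_, min_seg = NA_real_,
                          n_overlapping = 0L),
                     class = "sample_label"))
  }
  label <- if (any(ovseg > threshold)) "amplified"
           else if (any(ovseg < -threshold)) "deleted"
           else "unchanged"
  structure(list(sample = id, label = label, max_seg = max(ovseg),
                 min_seg = min(ovseg), n_overlapping = length(ovseg)),
            class = "sample_label")
}

#' Classify every sample of a cohort
#'
#' @param segments SEG-like data.frame (`sample`, `chrom`, `start`, `end`,
#'   `seg_mean`).
#' @param window a [locus_window()].
#' @param threshold log-ratio cutoff (default 0.3).
#' @return data.frame: `sample`, `label`, `max_seg`, `min_seg`,
#'   `n_overlapping`; exactly one row (one label) per sample.
#' @export
classify_cohort <- function(segments, window, threshold = 0.3) {
  stopifnot("sample" %in% names(segments))
  rows <- lapply(split(segments, segments$sample), function(d) {
    cl <- suppressWarnings(classify_sample(d, window, threshold))
    data.frame(sample = cl$sample, label = cl$label, max_seg = cl$max_seg,
               min_seg = cl$min_seg, n_overlapping = cl$n_overlapping,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-pair Spearman correlations within copy-number subgroups
#'
#' Correlates each requested gene pair across samples within each subgroup:
#' `all` samples, the pooled `altered` group (amplified plus deleted), and
#' the `unchanged` group. A correlation driven purely by co-amplification
#' disappears in the unchanged subgroup; a CNV-independent co-regulation
#' survives there.
#'
#' @param expression genes x samples matrix (gene ids as row names).
#' @param labels data.frame `sample`, `label` (from [classify_cohort()] or
#'   generator truth).
#' @param gene_pairs data.frame with columns `gene_a`, `gene_b`.
#' @param subgroups character subset of `c("all", "altered", "unchanged",
#'   "amplified", "deleted")`.
#' @param min_n minimum samples per subgroup; smaller subgroups are
#'   reported with `flagged = TRUE`, never silently dropped.
#' @return data.frame: `subgroup`, `gene_a`, `gene_b`, `rho`, `p_value`,
#'   `n`, `flagged`.
#' @export
subgroup_correlations <- function(expression, labels, gene_pairs,
                                  subgroups = c("all", "altered",
                                                "unchanged"),
                                  min_n = 5L) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            all(c("gene_a", "gene_b") %in% names(gene_pairs)))
  labels <- labels[match(colnames(expression), labels$sample), , drop = FALSE]
  if (anyNA(labels$label)) stop("every expression sample needs a label")
  members <- list(
    all = colnames(expression),
    altered = colnames(expression)[labels$label %in% c("amplified",
                                                       "deleted")],
    unchanged = colnames(expression)[labels$label == "unchanged"],
    amplified = colnames(expression)[labels$label == "amplified"],
    deleted = colnames(expression)[labels$label == "deleted"])
  rows <- list()
  for (sg in subgroups) {
    cols <- members[[sg]]
    for (i in seq_len(nrow(gene_pairs))) {
      ga <- gene_pairs$gene_a[i]; gb <- gene_pairs$gene_b[i]
      if (!ga %in% rownames(expression) || !gb %in% rownames(expression)) {
        stop("gene pair not in expression matrix: ", ga, " / ", gb)
      }
      sc <- if (length(cols) >= 3L) {
        spearman_cor(expression[ga, cols], expression[gb, cols])
      } else {
        list(rho = NA_real_, p_value = NA_real_, n = length(cols))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, gene_a = ga, gene_b = gb, rho = sc$rho,
        p_value = sc$p_value, n = length(cols),
        flagged = length(cols) < min_n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
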