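# Synthetic expression cohort with genomic-neighbourhood correlation blocks
# and CNV-driven shifts, feeding the TCS and copy-number subgrouping stages.

#' Specify a synthetic expression cohort
#'
#' Genes are laid out in genomic order on a toy chromosome. Co-expression
#' blocks share a latent per-sample factor giving a chosen pairwise
#' correlation; an optional CNV block adds (subtracts) a log-scale segment
#' mean to the expression of block genes in amplified (deleted) samples and
#' is emitted as SEG-format segments for subgrouping.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param coexpression_blocks list of `list(genes = i:j, rho = r)` with
#'   `r` in `[-1, 1]` and gene indices in `1..n_genes`; blocks share a
#'   CNV-independent latent factor.
#' @param cnv_block `list(genes = i:j, frac_amp = a, frac_del = d,
#'   magnitude = m)` or `NULL`; `a + d <= 1`.
#' @param noise_sd per-gene expression noise s.d. (log-scale units).
#' @param seg_noise_sd segment-mean noise s.d. for background segments.
#' @param chrom,gene_spacing,gene_width toy genome layout (bp).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_genes,
                        coexpression_blocks = list(),
                        cnv_block = NULL,
                        noise_sd = 1, seg_noise_sd = 0.05,
                        chrom = "chr12", gene_spacing = 10000L,
                        gene_width = 2000L, seed = 1L) {
  stopifnot(n_samples >= 3L, n_genes >= 1L, noise_sd > 0)
  for (b in coexpression_blocks) {
    stopifnot(all(b$genes >= 1L), all(b$genes <= n_genes),
              b$rho >= -1, b$rho <= 1)
  }
  if (!is.null(cnv_block)) {
    stopifnot(all(cnv_block$genes >= 1L), all(cnv_block$genes <= n_genes),
              cnv_block$frac_amp >= 0, cnv_block$frac_del >= 0,
              cnv_block$frac_amp + cnv_block$frac_del <= 1,
              cnv_block$magnitude > 0)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 coexpression_blocks = coexpression_blocks,
                 cnv_block = cnv_block, noise_sd = noise_sd,
                 seg_noise_sd = seg_noise_sd, chrom = chrom,
                 gene_spacing = as.integer(gene_spacing),
                 gene_width = as.integer(gene_width),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `expression` (genes x samples matrix, gene ids as row
#'   names), `positions` (BED-like data.frame: `chrom`, `start`, `end`,
#'   `gene`; 0-based half-open, genomic order), `segments` (SEG-like
#'   data.frame: `sample`, `chrom`, `start`, `end`, `seg_mean`), `labels`
#'   (data.frame `sample`, `label` — the generator truth), and `cnv_window`
#'   (the genomic window covering the CNV block, or `NULL`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ng <- spec$n_genes; ns <- spec$n_samples
  genes <- sprintf("gene_%04d", seq_len(ng))
  samples <- sprintf("sample_%03d", seq_len(ns))
  starts <- (seq_len(ng) - 1L) * spec$gene_spacing
  positions <- data.frame(chrom = spec$chrom, start = starts,
                          end = starts + spec$gene_width, gene = genes,
                          stringsAsFactors = FALSE)

  withr::with_seed(spec$seed, {
    expr <- matrix(stats::rnorm(ng * ns, 0, spec$noise_sd), nrow = ng,
                   dimnames = list(genes, samples))
    for (b in spec$coexpression_blocks) {
      latent <- stats::rnorm(ns)
      r <- b$rho
      for (g in b$genes) {
        expr[g, ] <- spec$noise_sd *
          (sqrt(abs(r)) * sign(r) * latent +
             sqrt(1 - abs(r)) * stats::rnorm(ns))
      }
    }

    labels <- rep("unchanged", ns)
    cnv_window <- NULL
    if (!is.null(spec$cnv_block)) {
      cb <- spec$cnv_block
      n_amp <- round(cb$frac_amp * ns)
      n_del <- round(cb$frac_del * ns)
      altered <- sample(ns, n_amp + n_del)
      labels[altered[seq_len(n_amp)]] <- "amplified"
      if (n_del > 0) labels[altered[n_amp + seq_len(n_del)]] <- "deleted"
      shift <- ifelse(labels == "amplified", cb$magnitude,
                      ifelse(labels == "deleted", -cb$magnitude, 0))
      expr[cb$genes, ] <- sweep(expr[cb$genes, , drop = FALSE], 2, shift, "+")
      cnv_window <- list(chrom = spec$chrom,
                         start = positions$start[min(cb$genes)],
                         end = positions$end[max(cb$genes)])
    }

    chrom_end <- max(positions$end)
    seg_rows <- lapply(seq_len(ns), function(i) {
      base <- stats::rnorm(1, 0, spec$seg_noise_sd)
      if (labels[i] == "unchanged" || is.null(cnv_window)) {
        data.frame(sample = samples[i], chrom = spec$chrom, start = 0L,
                   end = chrom_end, seg_mean = base,
                   stringsAsFactors = FALSE)
      } else {
        m <- if (labels[i] == "amplified") spec$cnv_block$magnitude else
          -spec$cnv_block$magnitude
        data.frame(
          sample = samples[i], chrom = spec$chrom,
          start = c(0L, cnv_window$start, cnv_window$end),
          end = c(cnv_window$start, cnv_window$end, chrom_end),
          seg_mean = c(base, m + stats::rnorm(1, 0, spec$seg_noise_sd),
                       stats::rnorm(1, 0, spec$seg_noise_sd)),
          stringsAsFactors = FALSE)
      }
    })
    segments <- do.call(rbind, seg_rows)
    segments <- segments[segments$end > segments$start, , drop = FALSE]
    rownames(segments) <- NULL

    list(expression = expr, positions = positions, segments = segments,
         labels = data.frame(sample = samples, label = labels,
                             stringsAsFactors = FALSE),
         cnv_window = cnv_window)
  })
}
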