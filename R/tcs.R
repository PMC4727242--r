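# Transcription Correlation Score (TCS): per-gene sum of Spearman
# correlations with its 2n genomic neighbours (n per side, same chromosome),
# with a randomized-position permutation null for significance.

#' Reduce a probeset-level matrix to one probeset per gene
#'
#' Keeps, for each gene, the probeset with the largest interquartile range
#' across samples (a robust variance proxy); ties are broken by the
#' lexicographically smallest probeset id. Genes without a genomic position
#' are excluded with a warning. Output rows are ordered by genomic position
#' (chromosome, then start).
#'
#' @param matrix probesets x samples numeric matrix (probeset ids as row
#'   names).
#' @param probeset_map data.frame with columns `probeset`, `gene`.
#' @param positions BED-like data.frame (`chrom`, `start`, `end`, `gene`).
#' @return list of class `ordered_expression`: `matrix` (genes x samples,
#'   position-ordered), `positions` (same order).
#' @export
reduce_to_one_probeset <- function(matrix, probeset_map, positions) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            all(c("probeset", "gene") %in% names(probeset_map)))
  pm <- probeset_map[probeset_map$probeset %in% rownames(matrix), ,
                     drop = FALSE]
  iqr <- apply(matrix, 1, stats::IQR)
  keep <- vapply(split(pm$probeset, pm$gene), function(ps) {
    ps <- sort(ps)                      # lexicographic tie-break
    ps[which.max(iqr[ps])]
  }, character(1))
  genes <- names(keep)
  no_pos <- setdiff(genes, positions$gene)
  if (length(no_pos)) {
    warning("excluding ", length(no_pos), " gene(s) with no genomic position")
    genes <- setdiff(genes, no_pos)
  }
  m <- matrix[keep[genes], , drop = FALSE]
  rownames(m) <- genes
  order_expression(m, positions)
}

#' Order an expression matrix by genomic position
#'
#' @param matrix genes x samples matrix with gene ids as row names.
#' @param positions BED-like data.frame (`chrom`, `start`, `end`, `gene`)
#'   covering every row of `matrix`.
#' @return list of class `ordered_expression`.
#' @export
order_expression <- function(matrix, positions) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  pos <- positions[match(rownames(matrix), positions$gene), , drop = FALSE]
  if (anyNA(pos$gene)) stop("every gene needs a genomic position")
  o <- order(pos$chrom, pos$start)
  structure(list(matrix = matrix[o, , drop = FALSE],
                 positions = pos[o, , drop = FALSE]),
            class = "ordered_expression")
}

# Rank-transform rows and return the gene-gene Spearman correlation matrix.
.rank_cor <- function(m) {
  ranks <- t(apply(m, 1, rank))
  suppressWarnings(stats::cor(t(ranks)))   # NA for zero-variance genes
}

# Neighbour index list: for each position slot i, the indices of up to n
# positions per side on the same chromosome (no wrap, truncated at ends).
.neighbour_index <- function(chrom, n) {
  ng <- length(chrom)
  lapply(seq_len(ng), function(i) {
    lo <- max(1L, i - n); hi <- min(ng, i + n)
    idx <- setdiff(lo:hi, i)
    idx[chrom[idx] == chrom[i]]
  })
}

# TCS for rows assigned to position slots by `perm` (perm[i] = row at slot i).
.tcs_scores <- function(R, nb, perm) {
  vapply(seq_along(nb), function(i) {
    r <- R[perm[i], perm[nb[[i]]]]
    sum(r, na.rm = TRUE)
  }, numeric(1))
}

#' Compute per-gene Transcription Correlation Scores
#'
#' For each gene, the TCS is the sum of Spearman rank correlations between
#' the gene and its `n` upstream plus `n` downstream genomic neighbours on
#' the same chromosome (truncated at chromosome ends, no rescaling). Being
#' rank-based, the score is invariant to any monotone transform of each
#' gene's expression.
#'
#' @param expr an `ordered_expression` (or a genes x samples matrix, with
#'   `positions` supplied).
#' @param positions required if `expr` is a bare matrix.
#' @param n neighbours per side (default 10, i.e. 2n = 20 neighbours).
#' @return object of class `tcs_result`: data.frame `scores` (`gene`,
#'   `chrom`, `start`, `tcs`, `n_neighbours` actually used) plus `n` and the
#'   sample count.
#' @export
compute_tcs <- function(expr, positions = NULL, n = 10L) {
  if (!inherits(expr, "ordered_expression")) {
    expr <- order_expression(expr, positions)
  }
  m <- expr$matrix
  if (ncol(m) < 3L) stop("need >= 3 samples to compute rank correlations")
  n <- as.integer(n)
  R <- .rank_cor(m)
  nb <- .neighbour_index(expr$positions$chrom, n)
  n_used <- vapply(seq_along(nb), function(i) {
    sum(!is.na(R[i, nb[[i]]]))
  }, integer(1))
  tcs <- .tcs_scores(R, nb, seq_len(nrow(m)))
  tcs[lengths(nb) == 0L] <- NA_real_   # single-gene chromosome: undefined
  structure(list(
    scores = data.frame(gene = rownames(m), chrom = expr$positions$chrom,
                        start = expr$positions$start, tcs = tcs,
                        n_neighbours = n_used, stringsAsFactors = FALSE),
    n = n, n_samples = ncol(m)),
    class = "tcs_result")
}

#' Permutation significance threshold for TCS
#'
#' Recomputes TCS after randomizing the gene-to-position assignment
#' (expression rows shuffled over the position ordering, genome-wide by
#' default), pools all null scores over randomizations, and returns the
#' empirical `1 - p` quantile (inclusive linear interpolation). At
#' `p = 0.001` this is the score of the 1,000th quantile of the null.
#'
#' @param expr an `ordered_expression` (or matrix plus `positions`).
#' @param positions required if `expr` is a bare matrix.
#' @param n neighbours per side.
#' @param p significance level (default 0.001).
#' @param n_randomizations number of position randomizations; the pooled
#'   null must satisfy `n_randomizations * n_genes >= 1/p`.
#' @param seed integer seed for the permutations.
#' @param within_chrom shuffle gene positions within each chromosome
#'   instead of genome-wide (default `FALSE`).
#' @return list of class `tcs_threshold`: `threshold`, `p`,
#'   `n_randomizations`, `n_null` (pooled null size), `seed`.
#' @export
tcs_threshold <- function(expr, positions = NULL, n = 10L, p = 0.001,
                          n_randomizations = 10L, seed = 1L,
                          within_chrom = FALSE) {
  if (!inherits(expr, "ordered_expression")) {
    expr <- order_expression(expr, positions)
  }
  ng <- nrow(expr$matrix)
  if (n_randomizations * ng < 1 / p) {
    stop(sprintf(
      "pooled null too small: %d randomizations x %d genes < 1/p = %g; need >= %d randomizations",
      n_randomizations, ng, 1 / p, ceiling(1 / (p * ng))))
  }
  R <- .rank_cor(expr$matrix)
  chrom <- expr$positions$chrom
  nb <- .neighbour_index(chrom, as.integer(n))
  null_scores <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_len(n_randomizations), function(k) {
      perm <- if (within_chrom) {
        idx <- seq_len(ng)
        for (ch in unique(chrom)) {
          i <- which(chrom == ch)
          idx[i] <- i[sample.int(length(i))]
        }
        idx
      } else {
        sample.int(ng)
      }
      .tcs_scores(R, nb, perm)
    }))
  })
  structure(list(threshold = unname(
                   stats::quantile(null_scores, 1 - p, type = 7,
                                   na.rm = TRUE)),
                 p = p, n_randomizations = n_randomizations,
                 n_null = length(null_scores), seed = as.integer(seed)),
            class = "tcs_threshold")
}

#' Position-ordered TCS map with significance calls
#'
#' Plotting-ready table of TCS against genomic position, flagging genes
#' above the permutation threshold and annotating contiguous above-threshold
#' runs as numbered peak regions.
#'
#' @param result a `tcs_result`.
#' @param threshold a `tcs_threshold` or a bare numeric score.
#' @return data.frame: `chrom`, `start`, `gene`, `tcs`, `above_threshold`,
#'   `peak_region` (0 = none, 1,2,... contiguous runs in position order).
#' @export
tcs_map <- function(result, threshold) {
  stopifnot(inherits(result, "tcs_result"))
  thr <- if (inherits(threshold, "tcs_threshold")) threshold$threshold
         else as.numeric(threshold)
  s <- result$scores
  above <- !is.na(s$tcs) & s$tcs > thr
  peak <- integer(nrow(s))
  if (any(above)) {
    r <- rle(above)
    run_id <- cumsum(r$values)        # numbers TRUE runs 1, 2, ...
    peak <- rep(ifelse(r$values, run_id, 0L), r$lengths)
  }
  data.frame(chrom = s$chrom, start = s$start, gene = s$gene, tcs = s$tcs,
             above_threshold = above, peak_region = peak,
             stringsAsFactors = FALSE)
}
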