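# Shared fixtures built in code.

# Noise-free locus quantification for a preset.
quantify_preset_noisefree <- function(preset, seed = 1L) {
  quantify_locus(make_locus_plates(preset, locus_noise_model(ct_sd = 0),
                                   seed = seed))
}

# Closed-form Spearman rho for untied data: 1 - 6 * sum(d^2) / (n (n^2 - 1)).
spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Naive double-loop TCS: for each gene, sum cor(gene, neighbour,
# method = "spearman") over up to n positions per side on the same chromosome.
naive_tcs <- function(m, chrom, n) {
  ng <- nrow(m)
  vapply(seq_len(ng), function(i) {
    idx <- setdiff(max(1, i - n):min(ng, i + n), i)
    idx <- idx[chrom[idx] == chrom[i]]
    if (!length(idx)) return(NA_real_)
    sum(vapply(idx, function(j) {
      suppressWarnings(stats::cor(m[i, ], m[j, ], method = "spearman"))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
}

# Naive motif scan returning 0-based cut positions.
naive_cut_positions <- function(seq_str, site = "CCATGG", cut_offset = 1L) {
  w <- nchar(site)
  hits <- integer(0)
  for (p in seq_len(nchar(seq_str) - w + 1L)) {
    if (substr(seq_str, p, p + w - 1L) == site) hits <- c(hits, p)
  }
  hits - 1L + cut_offset
}

# Default small 3C fixture: ~16 fragments, anchor mid-locus.
make_3c_fixture <- function(ct_sd = 0, seed = 1L, loops = NULL,
                            primer_bias = NULL, alpha = 1) {
  fm <- digest_sequence(make_locus_sequence(20000L, 13L, seed = 42L))
  anchor <- fm$fragments$id[ceiling(nrow(fm$fragments) / 2)]
  three_c_scenario(fm, anchor, background_alpha = alpha, loops = loops,
                   primer_bias = primer_bias,
                   noise = qpcr_noise_model(ct_sd = ct_sd), seed = seed)
}
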