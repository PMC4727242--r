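# Copy-number classification: boundary cases, invariants, subgroup
# correlations.

win <- locus_window("chr12", 100000, 250000)

seg1 <- function(seg_mean, start = 50000, end = 300000, sample = "s1") {
  data.frame(sample = sample, chrom = "chr12", start = start, end = end,
             seg_mean = seg_mean)
}

test_that("threshold boundaries: +/-0.3 is strict, epsilon beyond flips the label", {
  eps <- 1e-9
  expect_identical(classify_sample(seg1(0.5), win)$label, "amplified")
  expect_identical(classify_sample(seg1(0.3), win)$label, "unchanged")
  expect_identical(classify_sample(seg1(0.3 + eps), win)$label, "amplified")
  expect_identical(classify_sample(seg1(-0.3), win)$label, "unchanged")
  expect_identical(classify_sample(seg1(-0.3 - eps), win)$label, "deleted")
  expect_identical(classify_sample(seg1(0), win)$label, "unchanged")
})

test_that("any base-pair overlap counts; zero coverage warns and labels unchanged", {
  # one-bp overlap at the window edge still counts
  touching <- seg1(1.0, start = 99999, end = 100001)
  expect_identical(classify_sample(touching, win)$label, "amplified")
  # abutting half-open interval does not overlap
  outside <- seg1(1.0, start = 0, end = 100000)
  expect_warning(cl <- classify_sample(outside, win), "no segment overlaps")
  expect_identical(cl$label, "unchanged")
  expect_identical(cl$n_overlapping, 0L)
  # wrong chromosome never overlaps
  other <- seg1(1.0); other$chrom <- "chr1"
  expect_warning(classify_sample(other, win), "no segment overlaps")
})

test_that("amplified takes precedence when both thresholds are crossed", {
  both <- rbind(seg1(0.4, start = 100000, end = 150000),
                seg1(-0.4, start = 150000, end = 250000))
  expect_identical(classify_sample(both, win)$label, "amplified")
  # either precedence order lands in the altered group, never unchanged
  expect_true(classify_sample(both, win)$label %in%
                c("amplified", "deleted"))
})

test_that("classification is monotone in segment means and partitions the cohort", {
  set.seed(9)
  for (rep in 1:20) {
    n_seg <- sample(1:4, 1)
    segs <- data.frame(sample = "s", chrom = "chr12",
                       start = sort(sample(0:300000, n_seg)),
                       end = 0, seg_mean = rnorm(n_seg, 0, 0.4))
    segs$end <- segs$start + sample(20000:100000, n_seg, replace = TRUE)
    before <- classify_sample(segs, win) |> suppressWarnings()
    # raising any one segment mean never moves amplified toward unchanged
    i <- sample(n_seg, 1)
    segs2 <- segs
    segs2$seg_mean[i] <- segs2$seg_mean[i] + abs(rnorm(1, 0, 0.5))
    after <- classify_sample(segs2, win) |> suppressWarnings()
    rank_of <- c(deleted = 0, unchanged = 1, amplified = 2)
    if (before$label == "amplified") {
      expect_identical(after$label, "amplified")
    }
    expect_gte(rank_of[[after$label]] - rank_of[[before$label]] +
                 (before$label == "deleted"), 0)
  }
  # partition: every sample gets exactly one label
  co <- make_cohort(cohort_spec(50, 40,
                                cnv_block = list(genes = 10:20,
                                                 frac_amp = 0.3,
                                                 frac_del = 0.2,
                                                 magnitude = 1),
                                seed = 4))
  w <- locus_window(co$cnv_window$chrom, co$cnv_window$start,
                    co$cnv_window$end)
  labs <- classify_cohort(co$segments, w)
  expect_identical(nrow(labs), 50L)
  expect_identical(sort(unique(labs$sample)), sort(co$labels$sample))
  expect_identical(sum(table(labs$label)), 50L)
})

test_that("threshold extremes: infinite keeps all unchanged, zero only exact zeros", {
  segs <- seg1(c(0.2, -0.1), start = c(100000, 200000),
               end = c(150000, 240000))
  expect_identical(classify_sample(segs, win, threshold = Inf)$label,
                   "unchanged")
  expect_identical(classify_sample(segs, win, threshold = 0)$label,
                   "amplified")
  expect_identical(classify_sample(seg1(0), win, threshold = 0)$label,
                   "unchanged")
})

test_that("classifier recovers generator truth labels", {
  co <- make_cohort(cohort_spec(80, 60,
                                cnv_block = list(genes = 20:40,
                                                 frac_amp = 0.25,
                                                 frac_del = 0.25,
                                                 magnitude = 1),
                                seed = 12))
  w <- locus_window(co$cnv_window$chrom, co$cnv_window$start,
                    co$cnv_window$end)
  labs <- classify_cohort(co$segments, w)
  merged <- merge(labs, co$labels, by = "sample")
  expect_identical(merged$label.x, merged$label.y)
})

test_that("CNV-fraction-zero cohorts classify entirely unchanged", {
  co <- make_cohort(cohort_spec(30, 40,
                                cnv_block = list(genes = 10:20,
                                                 frac_amp = 0, frac_del = 0,
                                                 magnitude = 1),
                                seed = 5))
  w <- locus_window(co$cnv_window$chrom, co$cnv_window$start,
                    co$cnv_window$end)
  labs <- classify_cohort(co$segments, w)
  expect_true(all(labs$label == "unchanged"))
})

test_that("CNV-driven pair correlation vanishes in the unchanged subgroup, shared-factor correlation survives", {
  # correlation driven purely by co-amplification
  co <- make_cohort(cohort_spec(200, 60,
                                cnv_block = list(genes = 20:40,
                                                 frac_amp = 0.25,
                                                 frac_del = 0.25,
                                                 magnitude = 2),
                                seed = 21))
  pair <- data.frame(gene_a = rownames(co$expression)[25],
                     gene_b = rownames(co$expression)[35])
  sc <- subgroup_correlations(co$expression, co$labels, pair)
  expect_gt(sc$rho[sc$subgroup == "all"], 0.4)
  expect_lt(abs(sc$rho[sc$subgroup == "unchanged"]), 0.25)
  # CNV-independent shared factor across the same pair persists
  co2 <- make_cohort(cohort_spec(
    200, 60,
    coexpression_blocks = list(list(genes = 20:40, rho = 0.8)),
    cnv_block = list(genes = 20:40, frac_amp = 0.25, frac_del = 0.25,
                     magnitude = 2),
    seed = 22))
  sc2 <- subgroup_correlations(co2$expression, co2$labels, pair)
  expect_gt(sc2$rho[sc2$subgroup == "unchanged"], 0.5)
  # identical gene duplicated as a pair: rho = 1 in every subgroup
  dup <- co$expression
  dup <- rbind(dup, dup_gene = dup[25, ])
  pair_dup <- data.frame(gene_a = rownames(co$expression)[25],
                         gene_b = "dup_gene")
  sc3 <- subgroup_correlations(dup, co$labels, pair_dup)
  expect_true(all(sc3$rho == 1))
  # undersized subgroups are flagged, not dropped
  tiny_labels <- co$labels
  tiny_labels$label <- c(rep("amplified", 2),
                         rep("unchanged", nrow(tiny_labels) - 2))
  sc4 <- subgroup_correlations(co$expression, tiny_labels, pair,
                               subgroups = "altered")
  expect_true(sc4$flagged)
  expect_true(is.na(sc4$rho))
})

test_that("generator coexpression block hits its target correlation", {
  co <- make_cohort(cohort_spec(
    200, 40, coexpression_blocks = list(list(genes = 10:30, rho = 0.9)),
    seed = 13))
  block <- co$expression[10:30, ]
  cors <- cor(t(block), method = "spearman")
  off <- cors[upper.tri(cors)]
  expect_gt(mean(off), 0.8)
  expect_lt(mean(off), 0.95)
})
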