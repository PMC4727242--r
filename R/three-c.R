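# Chromosome conformation capture (3C) quantification: in-silico
# restriction digestion, BAC-control primer normalization, relative
# interaction frequency over the closest 3' fragment from the anchor,
# restriction-efficiency QC, and loop-peak calling.

#' In-silico restriction digestion of a locus sequence
#'
#' Cuts at `site start + cut_offset` for every exact forward-strand match of
#' the recognition motif (NcoI C^CATGG by default; the motif is its own
#' reverse complement, so one strand suffices). Ambiguous bases inside a
#' candidate site never match. Fragments are the 0-based half-open intervals
#' between successive cuts and tile the locus exactly; the reported middle
#' position is `floor((start + end) / 2)`.
#'
#' @param sequence a character string, `Biostrings::DNAString`, or a
#'   `DNAStringSet` of length 1 (e.g. one FASTA record).
#' @param site recognition motif (default `"CCATGG"`, NcoI).
#' @param cut_offset bases from motif start to the cut (default 1, C^CATGG).
#' @return object of class `fragment_map`: data.frame `fragments` (`id`,
#'   `start`, `end`, `midpoint`), plus `site`, `cut_offset`, `locus_length`.
#' @examples
#' digest_sequence("AAACCATGGTTT")$fragments  # lengths 4 and 8
#' @export
digest_sequence <- function(sequence, site = "CCATGG", cut_offset = 1L) {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- sequence[[1L]]
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  stopifnot(nchar(site) >= 4L, length(sequence) > 0L,
            cut_offset >= 0L, cut_offset <= nchar(site))
  m <- Biostrings::matchPattern(Biostrings::DNAString(site), sequence,
                                fixed = TRUE)
  cuts <- Biostrings::start(m) - 1L + as.integer(cut_offset)  # 0-based
  bounds <- unique(c(0L, cuts, length(sequence)))
  bounds <- sort(bounds[bounds >= 0L & bounds <= length(sequence)])
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  frags <- data.frame(
    id = sprintf("frag_%02d", seq_along(starts)),
    start = starts, end = ends,
    midpoint = floor((starts + ends) / 2),
    stringsAsFactors = FALSE)
  structure(list(fragments = frags, site = site,
                 cut_offset = as.integer(cut_offset),
                 locus_length = length(sequence)),
            class = "fragment_map")
}

#' Restriction efficiency from non-ligated controls
#'
#' Fraction cut at each site: `1 - across_site / reference`, where
#' `across_site` is the quantity of an amplicon spanning the site in the
#' non-ligated control and `reference` an amplicon away from any site.
#' Values are clipped to `[0, 1]` (with a warning when the across-site
#' signal exceeds the reference).
#'
#' @param across_site_pg per-site across-site amplicon quantities (named
#'   vector, pg).
#' @param reference_pg reference amplicon quantity (> 0, pg).
#' @return named numeric vector of per-site efficiencies in `[0, 1]`.
#' @export
restriction_efficiency <- function(across_site_pg, reference_pg) {
  stopifnot(reference_pg > 0, all(across_site_pg >= 0))
  eff <- 1 - across_site_pg / reference_pg
  if (any(eff < 0)) {
    warning("across-site signal exceeds reference; efficiency clipped to 0")
    eff[eff < 0] <- 0
  }
  eff
}

#' Normalize 3C junction quantities to the BAC control template
#'
#' Both the sample and the digested-and-ligated BAC control are quantified
#' by standard-curve inversion against the dilution series measured on the
#' same plate; the normalized interaction frequency of a fragment is
#' `quantity_sample / quantity_bac`, which cancels per-primer-pair
#' efficiency bias exactly (all BAC junctions are equimolar).
#'
#' @param sample_plate,bac_plate junction plate data.frames (`assay`,
#'   `sample`, `replicate`, `ct`), one assay per tested fragment.
#' @param dilutions dilution-series data.frame (`assay`, `quantity_pg`,
#'   `ct`) shared by both plates.
#' @return data.frame: `fragment`, `sample_pg`, `bac_pg`, `normalized`
#'   (`NA` flagged when the BAC quantity is unusable).
#' @export
normalize_junctions <- function(sample_plate, bac_plate, dilutions) {
  assays <- sort(unique(sample_plate$assay))
  if (!all(assays %in% bac_plate$assay)) {
    stop("every junction assay must be present in the BAC control plate")
  }
  curves <- lapply(stats::setNames(assays, assays), function(a) {
    fit_standard_curve(dilutions[dilutions$assay == a, , drop = FALSE])
  })
  qs <- aggregate_replicates(sample_plate)
  qb <- aggregate_replicates(bac_plate)
  out <- data.frame(fragment = assays, sample_pg = NA_real_,
                    bac_pg = NA_real_, normalized = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(assays)) {
    a <- assays[i]
    out$sample_pg[i] <- invert_quantity(qs$ct[qs$assay == a][1L], curves[[a]])
    out$bac_pg[i] <- invert_quantity(qb$ct[qb$assay == a][1L], curves[[a]])
    if (!is.na(out$bac_pg[i]) && out$bac_pg[i] > 0) {
      out$normalized[i] <- out$sample_pg[i] / out$bac_pg[i]
    } else {
      warning("unusable BAC quantity for fragment ", a, "; flagged NA")
    }
  }
  out
}

#' Relative interaction profile over the closest 3' fragment
#'
#' Divides every fragment's normalized interaction frequency by that of the
#' first fragment 3' of the anchor, so the closest 3' fragment has relative
#' frequency 1 by construction; distances are from the anchor midpoint.
#' The profile is scale-invariant in the normalized frequencies.
#'
#' @param normalized data.frame from [normalize_junctions()] (columns
#'   `fragment`, `normalized`), covering non-anchor fragments.
#' @param fragment_map a [digest_sequence()] map.
#' @param anchor fragment id of the anchor.
#' @return object of class `interaction_profile`: data.frame `profile`
#'   (`fragment`, `midpoint`, `distance`, `normalized`, `relative`, sorted
#'   by position), plus `anchor` and `reference` fragment ids.
#' @export
relative_profile <- function(normalized, fragment_map, anchor) {
  stopifnot(inherits(fragment_map, "fragment_map"))
  fr <- fragment_map$fragments
  if (!anchor %in% fr$id) stop("anchor fragment not in map: ", anchor)
  mid_anchor <- fr$midpoint[fr$id == anchor]
  d <- normalized[normalized$fragment != anchor, , drop = FALSE]
  idx <- match(d$fragment, fr$id)
  if (anyNA(idx)) stop("junction fragment(s) absent from the fragment map")
  d$midpoint <- fr$midpoint[idx]
  d$distance <- d$midpoint - mid_anchor
  three_prime <- d[d$distance > 0, , drop = FALSE]
  if (!nrow(three_prime)) {
    stop("anchor is the 3'-most fragment: no reference fragment exists")
  }
  ref <- three_prime$fragment[which.min(three_prime$distance)]
  ref_val <- d$normalized[d$fragment == ref]
  if (is.na(ref_val) || ref_val <= 0) {
    stop("reference fragment has no usable normalized frequency")
  }
  d$relative <- d$normalized / ref_val
  d <- d[order(d$midpoint),
         c("fragment", "midpoint", "distance", "normalized", "relative")]
  rownames(d) <- NULL
  structure(list(profile = d, anchor = anchor, reference = ref),
            class = "interaction_profile")
}

#' Call interaction peaks (candidate loops) on a relative profile
#'
#' A fragment is called when its relative interaction frequency is at least
#' `min_fold` times the median of its flanking fragments (`flank` per side,
#' itself excluded); contiguous calls are merged into regions. Fragments
#' within `exclude_near` positions of the anchor are never called: so close
#' to the anchor the background decay gradient and religation artifacts
#' dominate any flanking-median contrast.
#'
#' @param profile an [relative_profile()] result.
#' @param min_fold fold over the flanking median required (default 2).
#' @param flank flanking fragments per side for the local median (default 2).
#' @param exclude_near fragments per side of the anchor excluded from
#'   calling (default 1).
#' @return data.frame of called fragments: `fragment`, `midpoint`,
#'   `distance`, `relative`, `fold_over_flank`, `region` (contiguous calls
#'   share a region id); zero rows when nothing is called.
#' @export
detect_interaction_peaks <- function(profile, min_fold = 2, flank = 2L,
                                     exclude_near = 1L) {
  stopifnot(inherits(profile, "interaction_profile"), min_fold > 0,
            flank >= 1L)
  d <- profile$profile
  m <- nrow(d)
  if (m < 2L * flank + 1L) {
    stop("need at least 2*flank + 1 fragments to call peaks")
  }
  # index of the anchor gap in the position-sorted profile
  g <- sum(d$distance < 0)
  near <- integer(0)
  if (exclude_near > 0L) {
    near <- c(g - seq_len(exclude_near) + 1L, g + seq_len(exclude_near))
    near <- near[near >= 1L & near <= m]
  }
  fold <- rep(NA_real_, m)
  called <- rep(FALSE, m)
  for (i in setdiff(seq_len(m), near)) {
    fl <- setdiff(max(1L, i - flank):min(m, i + flank), i)
    med <- stats::median(d$relative[fl], na.rm = TRUE)
    if (is.na(med) || med <= 0 || is.na(d$relative[i])) next
    fold[i] <- d$relative[i] / med
    called[i] <- fold[i] >= min_fold
  }
  if (!any(called)) {
    return(data.frame(fragment = character(0), midpoint = integer(0),
                      distance = integer(0), relative = numeric(0),
                      fold_over_flank = numeric(0), region = integer(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(called)
  region_all <- rep(ifelse(r$values, cumsum(r$values), 0L), r$lengths)
  out <- d[called, c("fragment", "midpoint", "distance", "relative")]
  out$fold_over_flank <- fold[called]
  out$region <- region_all[called]
  rownames(out) <- NULL
  out
}
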