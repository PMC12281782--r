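# Enrichment of CpG sets in collapsed chromatin states and in padded,
# merged transcription-factor binding regions, against the array background.
#
# This is the single place where the two coordinate conventions meet:
# manifest positions are 1-based, BED segments 0-based half-open; a CpG at
# 1-based position p lies in segment [start, end) iff start <= p-1 < end.

STATE_GROUPS <- list(
  promoter = c("TssA", "TssBiv", "TssFlnk", "TssFlnkD", "TssFlnkU"),
  enhancer = c("EnhA1", "EnhA2", "EnhBiv", "EnhG1", "EnhG2", "EnhWk"),
  PRC = c("ReprPC", "ReprPCWk"),
  transcribed = c("Tx", "TxWk"),
  heterochromatin = "Het",
  quiescent = "Quies"
)

#' Collapse a 17-state ChromHMM label to its functional group
#'
#' Promoters are the five Tss* states; enhancers the six Enh* states;
#' polycomb repressive complex (PRC) ReprPC/ReprPCWk; transcribed Tx/TxWk;
#' Het and Quies map to heterochromatin and quiescent unchanged.
#'
#' @param raw_label Character vector of ChromHMM state labels.
#' @return Character vector of group names.
#' @export
collapse_state <- function(raw_label) {
  map <- stats::setNames(rep(names(STATE_GROUPS), lengths(STATE_GROUPS)),
                         unlist(STATE_GROUPS))
  out <- map[raw_label]
  if (anyNA(out)) {
    stop("unknown chromatin state ",
         paste(sQuote(unique(raw_label[is.na(out)])), collapse = ", "),
         "; valid labels: ", paste(names(map), collapse = ", "))
  }
  unname(out)
}

track_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    label = track$label)
}

#' Assign CpGs to the segments of one track
#'
#' @param cpgs Data frame with columns `probe_id`, `chrom`, `pos` (1-based).
#' @param track BED-style data frame (chrom, start, end, label) with
#'   non-overlapping segments per chromosome.
#' @return Character vector of labels, named by probe_id; CpGs not covered
#'   by any segment are labeled `"none"`.
#' @export
assign_cpgs_to_segments <- function(cpgs, track) {
  gr_track <- track_granges(track)
  gr_cpg <- GenomicRanges::GRanges(
    seqnames = cpgs$chrom,
    ranges = IRanges::IRanges(start = cpgs$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_cpg, gr_track, select = "first")
  lab <- ifelse(is.na(hits), "none",
                S4Vectors::mcols(gr_track)$label[hits])
  stats::setNames(lab, cpgs$probe_id)
}

enrichment_table <- function(categories, fg_lab, bg_lab) {
  fg_total <- length(fg_lab)
  bg_total <- length(bg_lab)
  rows <- lapply(categories, function(cat) {
    fg_in <- sum(fg_lab == cat)
    bg_in <- sum(bg_lab == cat)
    fold <- if (bg_in > 0) (fg_in / fg_total) / (bg_in / bg_total) else NA_real_
    p <- if (bg_in > 0) {
      hypergeometric_upper_tail(bg_total, bg_in, fg_total, fg_in)
    } else NA_real_
    data.frame(category = cat, fg_in = fg_in, fg_total = fg_total,
               bg_in = bg_in, bg_total = bg_total, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Chromatin-state enrichment of a CpG set
#'
#' Hypergeometric upper-tail test, per collapsed state group, of the query
#' CpGs against the array background, with BH adjustment across the six
#' groups of one track. Tracks of different cell lines are analyzed
#' separately, never unioned.
#'
#' @param query_cpgs,background_cpgs Annotation-style data frames
#'   (`probe_id`, `chrom`, `pos`); the query must be a subset of the
#'   background.
#' @param track Chromatin segmentation track (chrom, start, end, label).
#' @return Data frame with one row per state group: category, fg_in,
#'   fg_total, bg_in, bg_total, fold, p, q.
#' @export
state_enrichment <- function(query_cpgs, background_cpgs, track) {
  if (!all(query_cpgs$probe_id %in% background_cpgs$probe_id)) {
    stop("query CpGs must be a subset of the background")
  }
  bg_lab <- collapse_state_or_none(assign_cpgs_to_segments(background_cpgs, track))
  fg_lab <- bg_lab[query_cpgs$probe_id]
  enrichment_table(names(STATE_GROUPS), fg_lab, bg_lab)
}

collapse_state_or_none <- function(lab) {
  out <- lab
  cov <- lab != "none"
  out[cov] <- collapse_state(lab[cov])
  out
}

#' Build transcription-factor binding regions
#'
#' Each binding site `[s, e)` is extended to `[max(0, s - pad), e + pad)`
#' and, per TF and chromosome, overlapping or touching intervals are merged
#' into maximal disjoint regions.
#'
#' @param tfbs_track BED-style data frame whose labels are TF names.
#' @param pad Non-negative extension in bp (default 150).
#' @return Data frame (chrom, start, end, label) of merged regions,
#'   0-based half-open.
#' @export
build_tfbr <- function(tfbs_track, pad = 150L) {
  if (pad < 0) stop("pad must be non-negative")
  padded <- tfbs_track
  padded$start <- pmax(0, padded$start - pad)
  padded$end <- padded$end + pad
  merged <- lapply(split(padded, padded$label), function(tr) {
    gr <- GenomicRanges::reduce(track_granges(tr))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               label = tr$label[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Transcription-factor binding-region enrichment of a CpG set
#'
#' Per TF: a CpG counts once if it lies inside any of that TF's merged
#' regions; hypergeometric upper-tail p against the array background, BH
#' across all TFs tested. TFs whose regions contain no background CpG are
#' dropped (listed in the `dropped_tfs` attribute).
#'
#' @inheritParams state_enrichment
#' @param tfbr Merged region data frame from [build_tfbr()].
#' @return Data frame with one row per TF (category = TF name), ordered by
#'   ascending p.
#' @export
tf_enrichment <- function(query_cpgs, background_cpgs, tfbr) {
  if (!all(query_cpgs$probe_id %in% background_cpgs$probe_id)) {
    stop("query CpGs must be a subset of the background")
  }
  gr_bg <- GenomicRanges::GRanges(
    seqnames = background_cpgs$chrom,
    ranges = IRanges::IRanges(start = background_cpgs$pos, width = 1L))
  fg_total <- nrow(query_cpgs)
  bg_total <- nrow(background_cpgs)
  in_query <- background_cpgs$probe_id %in% query_cpgs$probe_id
  tfs <- sort(unique(tfbr$label))
  # one overlap pass over all TFs; a CpG counts once per TF even when it
  # lies in several of that TF's regions
  gr_all <- track_granges(tfbr)
  hits <- GenomicRanges::findOverlaps(gr_bg, gr_all)
  tf_of_hit <- S4Vectors::mcols(gr_all)$label[S4Vectors::subjectHits(hits)]
  cpg_of_hit <- S4Vectors::queryHits(hits)
  rows <- lapply(tfs, function(tf) {
    cpg <- unique(cpg_of_hit[tf_of_hit == tf])
    bg_in <- length(cpg)
    if (bg_in == 0L) return(NULL)
    fg_in <- sum(in_query[cpg])
    data.frame(category = tf, fg_in = fg_in, fg_total = fg_total,
               bg_in = bg_in, bg_total = bg_total,
               fold = (fg_in / fg_total) / (bg_in / bg_total),
               p = hypergeometric_upper_tail(bg_total, bg_in, fg_total, fg_in),
               stringsAsFactors = FALSE)
  })
  dropped <- tfs[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no TF region contains a background CpG")
  out$q <- benjamini_hochberg(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "dropped_tfs") <- dropped
  out
}
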