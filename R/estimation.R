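#' Find encompassment pairs for cut-efficiency estimation
#'
#' A fully digested fragment `[a, b)` (no internal cut sites) is paired
#' with the larger, singly partial fragments immediately encompassing it:
#' `[a', b)` and `[a, b')`, where `a'`/`b'` are the cut positions adjacent
#' beyond `a`/`b` on the same contig. Under the partial-digestion model the
#' inner fragment occurs `1/(1-c)` times as often as each encompassing
#' fragment, so the observed count ratio `r = count(inner)/count(outer)`
#' carries the cut efficiency.
#'
#' Only inner fragments within the estimation window are used (100-450 bp
#' by default: lengths there are least distorted by size selection), and
#' only inner fragments with at least `min_inner_count` reads (ratio
#' stability). Outer fragments with zero observed count contribute no pair.
#'
#' @param counts fragment count `data.frame` with columns `genome_id`,
#'   `contig_id`, `start`, `end`, `i`, `read_count`.
#' @param cut_sites in-silico cut-site `data.frame` from
#'   [communityCutSites()] for the same references.
#' @param window inner-fragment length window, `c(min, max)` in bp.
#' @param min_inner_count minimum inner read count for a pair to qualify.
#' @return `data.frame(contig_id, inner_start, inner_end, outer_start,
#'   outer_end, r)`.
#' @export
findEncompassmentPairs <- function(counts, cut_sites,
                                   window = c(100L, 450L),
                                   min_inner_count = 5L) {
  pairs <- list(); np <- 0L
  for (cid in unique(counts$contig_id)) {
    tab <- counts[counts$contig_id == cid, , drop = FALSE]
    cuts <- sort(unique(cut_sites$position[cut_sites$contig_id == cid]))
    if (!length(cuts)) next
    key <- paste(tab$start, tab$end)
    cnt <- setNames(tab$read_count, key)
    inner <- tab[tab$i == 0L & tab$read_count >= min_inner_count &
                   (tab$end - tab$start) >= window[1L] &
                   (tab$end - tab$start) <= window[2L], , drop = FALSE]
    for (j in seq_len(nrow(inner))) {
      a <- inner$start[j]; b <- inner$end[j]
      ia <- match(a, cuts); ib <- match(b, cuts)
      if (is.na(ia) || is.na(ib))
        stop(sprintf("fragment [%d,%d) on %s does not align to cut sites",
                     a, b, cid))
      outers <- list()
      if (ia > 1L) outers <- c(outers, list(c(cuts[ia - 1L], b)))
      if (ib < length(cuts)) outers <- c(outers, list(c(a, cuts[ib + 1L])))
      for (o in outers) {
        oc <- cnt[paste(o[1L], o[2L])]
        if (!is.na(oc) && oc > 0) {
          np <- np + 1L
          pairs[[np]] <- data.frame(
            contig_id = cid, inner_start = a, inner_end = b,
            outer_start = o[1L], outer_end = o[2L],
            r = inner$read_count[j] / as.numeric(oc),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!np)
    return(data.frame(contig_id = character(), inner_start = integer(),
                      inner_end = integer(), outer_start = integer(),
                      outer_end = integer(), r = numeric()))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Estimate enzyme cut efficiency from encompassment ratios
#'
#' Aggregates the pair ratios (ratios `r > 1`, consistent with the model)
#' into a single `r_hat` by median (default; robust to low-count outer
#' fragments) or mean, and maps it to the cut efficiency via
#' `c = (r_hat - 1) / r_hat`. With no pairs at all the digestion is
#' complete and `c = 1`; when pairs exist but all have `r <= 1` the
#' efficiency is flagged inestimable.
#'
#' @param pairs output of [findEncompassmentPairs()] (or any data frame
#'   with an `r` column).
#' @param stat `"median"` or `"mean"` aggregation of the ratios.
#' @return list with `c` (the estimate, `NA` when inestimable), `status`
#'   (`"estimated"`, `"complete_digestion"` or `"inestimable"`), `r_hat`
#'   and `n_pairs`.
#' @examples
#' estimateCutEfficiency(data.frame(r = c(2, 4, 5)))  # c = 0.75
#' estimateCutEfficiency(data.frame(r = numeric()))   # complete digestion
#' @export
estimateCutEfficiency <- function(pairs, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  r <- pairs$r
  if (!length(r))
    return(list(c = 1, status = "complete_digestion",
                r_hat = NA_real_, n_pairs = 0L))
  usable <- r[r > 1]
  if (!length(usable))
    return(list(c = NA_real_, status = "inestimable",
                r_hat = NA_real_, n_pairs = length(r)))
  r_hat <- if (stat == "median") median(usable) else mean(usable)
  list(c = (r_hat - 1) / r_hat, status = "estimated",
       r_hat = r_hat, n_pairs = length(r))
}

#' Empirical fragment-length distribution from observed counts
#'
#' Sums read counts by fragment length, yielding the observed length
#' distribution of a sequenced digest. Written as the JSON dialect of
#' [writeLengthWeights()], it can drive re-simulation through
#' [gaussianEnvelope()]'s `custom_weights` mode.
#'
#' @param counts fragment count `data.frame` (columns `start`, `end`,
#'   `read_count`).
#' @param json optional output path for the JSON export.
#' @return a [lengthDistribution()]; zero-count-only input yields an empty
#'   distribution with a warning.
#' @export
extractLengthDistribution <- function(counts, json = NULL) {
  if (!nrow(counts)) stop("empty fragment count table")
  lens <- counts$end - counts$start
  keep <- counts$read_count > 0
  if (!any(keep)) {
    warning("all fragment counts are zero; empty distribution")
    d <- lengthDistribution(integer(), numeric())
  } else {
    w <- tapply(counts$read_count[keep], lens[keep], sum)
    d <- lengthDistribution(as.integer(names(w)), as.numeric(w))
  }
  if (!is.null(json)) writeLengthWeights(d, json)
  d
}
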