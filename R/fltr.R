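#' Recreate source fragments from reads and tally counts
#'
#' Reconstructs the digestion fragment behind each read pair and applies
#' the quantification filters: both fragment endpoints must coincide
#' exactly with expected (in-silico) cut positions, and fragments spanning
#' one or more expected cut sites strictly inside are discarded — only
#' fully digested fragments are quantifiable, since partial fragments
#' distort per-locus depth unpredictably. Surviving fragments are tallied
#' into a count table.
#'
#' Two input modes:
#' * `"provenance"`: reads carry their source interval in the FASTQ header
#'   (see [writeFastq()]); `x` is a FASTQ path or a [parseProvenance()]
#'   data frame. No alignment is needed.
#' * `"sam"`: `x` is a SAM file of paired alignments against the same
#'   references. Only proper pairs are used, any pair with a mate of MAPQ 0
#'   (multi-mapping) is dropped, and the fragment interval is
#'   `[leftmost mate start, rightmost mate end)`.
#'
#' @param x FASTQ path, provenance `data.frame`, or SAM path.
#' @param cut_sites cut-site `data.frame` from [communityCutSites()] built
#'   on the same references.
#' @param mode `"provenance"` or `"sam"`.
#' @return fragment count `data.frame(genome_id, contig_id, start, end, i,
#'   read_count)` with `i = 0` for all kept fragments.
#' @export
recreateFragments <- function(x, cut_sites,
                              mode = c("provenance", "sam")) {
  tab <- tallyFragments(x, cut_sites, mode = mode)
  res <- tab[tab$i == 0L, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tally read-pair fragments against expected cut positions
#'
#' Shared machinery behind [recreateFragments()] and the cut-efficiency
#' workflow: reconstructs each read pair's fragment interval, keeps only
#' fragments whose endpoints coincide exactly with expected cut positions,
#' and tallies counts *per fragment including partial fragments*, recording
#' each fragment's internal-cut-site count `i`. The cut-efficiency
#' estimator needs the `i = 1` rows that [recreateFragments()] discards.
#'
#' @inheritParams recreateFragments
#' @return fragment count `data.frame(genome_id, contig_id, start, end, i,
#'   read_count)`.
#' @export
tallyFragments <- function(x, cut_sites, mode = c("provenance", "sam")) {
  mode <- match.arg(mode)
  if (mode == "provenance") {
    prov <- if (is.character(x)) parseProvenance(x) else x
    frag <- data.frame(contig_id = prov$contig_id, start = prov$start,
                       end = prov$end, stringsAsFactors = FALSE)
  } else {
    frag <- .samFragments(x)
  }
  genome_of <- cut_sites$genome_id[!duplicated(cut_sites$contig_id)]
  names(genome_of) <- cut_sites$contig_id[!duplicated(cut_sites$contig_id)]
  unknown <- setdiff(unique(frag$contig_id), names(genome_of))
  if (length(unknown))
    stop("reads reference unknown contig(s): ",
         paste(unknown, collapse = ", "))

  out <- list(); no <- 0L
  for (cid in unique(frag$contig_id)) {
    f <- frag[frag$contig_id == cid, , drop = FALSE]
    cuts <- sort(unique(cut_sites$position[cut_sites$contig_id == cid]))
    keep <- f$start %in% cuts & f$end %in% cuts
    if (!any(keep)) next
    key <- paste(f$start[keep], f$end[keep])
    tab <- table(key)
    se <- matrix(as.integer(unlist(strsplit(names(tab), " ", fixed = TRUE))),
                 ncol = 2L, byrow = TRUE)
    internal <- findInterval(se[, 2L] - 0.5, cuts) -
      findInterval(se[, 1L] + 0.5, cuts)
    no <- no + 1L
    out[[no]] <- data.frame(
      genome_id = unname(genome_of[cid]), contig_id = cid,
      start = se[, 1L], end = se[, 2L], i = as.integer(internal),
      read_count = as.integer(tab), stringsAsFactors = FALSE)
  }
  if (!no)
    return(data.frame(genome_id = character(), contig_id = character(),
                      start = integer(), end = integer(), i = integer(),
                      read_count = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Paired SAM alignments -> 0-based fragment intervals, filtering out
# improper pairs and pairs with a MAPQ-0 (multi-mapping) mate.
.samFragments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = "mapq",
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gp <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
  if (!length(gp))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer()))
  m1 <- S4Vectors::mcols(GenomicAlignments::first(gp))$mapq
  m2 <- S4Vectors::mcols(GenomicAlignments::last(gp))$mapq
  keep <- !is.na(m1) & !is.na(m2) & m1 > 0L & m2 > 0L
  gp <- gp[keep]
  f <- GenomicAlignments::first(gp)
  l <- GenomicAlignments::last(gp)
  data.frame(
    contig_id = as.character(GenomicAlignments::seqnames(gp)),
    start = pmin(GenomicAlignments::start(f), GenomicAlignments::start(l)) - 1L,
    end = pmax(GenomicAlignments::end(f), GenomicAlignments::end(l)),
    stringsAsFactors = FALSE)
}

#' Mean per-fragment read depth by taxon and fragment length
#'
#' For every taxon and fragment length, the mean depth is the total read
#' count assigned to that taxon's kept fragments of that length divided by
#' the number of the taxon's *distinct expected* fully digested fragments
#' of that length — expected fragments that received zero reads still
#' count in the denominator. Cells where a taxon has no expected fragment
#' of a length are undefined (`NA`).
#'
#' @param counts fragment count table from [recreateFragments()].
#' @param expected expected-fragment `data.frame` from [digestGenome()]
#'   (its `i = 0` rows define the enumerable fragment universe).
#' @param taxon_of optional named character vector mapping genome id to
#'   taxon; defaults to genome id = taxon.
#' @return numeric matrix, taxa in rows, fragment lengths (as character
#'   column names) ascending.
#' @export
depthByLength <- function(counts, expected, taxon_of = NULL) {
  exp0 <- expected[expected$i == 0L, , drop = FALSE]
  exp0 <- exp0[!duplicated(exp0[c("contig_id", "start", "end")]), ,
               drop = FALSE]
  if (is.null(taxon_of)) {
    gids <- unique(exp0$genome_id)
    taxon_of <- setNames(gids, gids)
  }
  unmapped <- setdiff(unique(exp0$genome_id), names(taxon_of))
  if (length(unmapped))
    stop("genome(s) without taxon mapping: ", paste(unmapped, collapse = ", "))
  taxon <- unname(taxon_of[exp0$genome_id])
  len <- exp0$end - exp0$start
  key <- paste(exp0$contig_id, exp0$start, exp0$end)
  cnt <- setNames(counts$read_count,
                  paste(counts$contig_id, counts$start, counts$end))
  reads <- unname(cnt[key])
  reads[is.na(reads)] <- 0L

  taxa <- unique(taxon)
  lens <- sort(unique(len))
  D <- matrix(NA_real_, nrow = length(taxa), ncol = length(lens),
              dimnames = list(taxa, as.character(lens)))
  tot <- tapply(reads, list(taxon, len), sum)
  nfr <- tapply(rep(1L, length(len)), list(taxon, len), sum)
  D[rownames(tot), colnames(tot)] <- tot / nfr
  D
}

#' Average pairwise per-length depth ratios into a RatioMatrix
#'
#' Within each fragment length, the depth ratio between every ordered pair
#' of taxa present is computed; ratios are then averaged (unweighted) over
#' all lengths where both taxa are defined and the denominator taxon has
#' positive depth.
#'
#' @param D depth matrix from [depthByLength()] (taxa x lengths, `NA` for
#'   undefined cells).
#' @return a [RatioMatrix-class].
#' @export
computeRatioMatrix <- function(D) {
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 2L) stop("at least two taxa required")
  R <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  diag(R) <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- !is.na(D[i, ]) & !is.na(D[j, ]) & D[j, ] > 0
      if (any(ok)) R[i, j] <- mean(D[i, ok] / D[j, ok])
    }
  }
  new("RatioMatrix", R)
}

#' Fixed length taxonomic ratio (FLTR) abundance estimate
#'
#' Anchors the ratio matrix to the taxon with the greatest number of
#' defined relationships (ties broken by input order): every column `j`
#' whose reference entry `R[k, j]` is defined is divided by it, putting
#' all entries in units of "depth relative to the reference"; columns
#' without a reference entry are excluded. Each taxon's abundance is the
#' mean of its defined scaled row entries, normalized to sum to one over
#' the quantified taxa. Taxa with no defined scaled entries cannot be
#' placed on the reference scale and are reported as unquantified.
#'
#' @param R a [RatioMatrix-class] from [computeRatioMatrix()].
#' @return list with `abundance` (named vector over all taxa, `NA` for
#'   unquantified; quantified entries sum to 1), `unquantified` (character
#'   vector) and `reference` (the anchor taxon).
#' @export
fltrEstimate <- function(R) {
  stopifnot(is(R, "RatioMatrix"))
  m <- R@.Data
  taxa <- rownames(m)
  rel <- relationshipCounts(R)
  k <- which.max(rel)  # ties: first in input order
  scale_row <- m[k, ]
  keep_col <- !is.na(scale_row)
  scaled <- sweep(m[, keep_col, drop = FALSE], 2L, scale_row[keep_col], "/")
  est <- rowMeans(scaled, na.rm = TRUE)
  est[is.nan(est)] <- NA_real_
  unq <- taxa[is.na(est)]
  est[!is.na(est)] <- est[!is.na(est)] / sum(est, na.rm = TRUE)
  list(abundance = setNames(as.numeric(est), taxa),
       unquantified = unq, reference = taxa[k])
}

#' Mean- and median-depth baseline abundance estimates
#'
#' Classical per-taxon depth summaries for comparison with FLTR: each
#' taxon's mean (and median) read count over its distinct expected fully
#' digested fragments (zero-count fragments included), normalized across
#' taxa to sum to one. These baselines ignore the fragment-length
#' composition of each genome's digest and are therefore biased whenever
#' size selection or PCR skews depth by length.
#'
#' @inheritParams depthByLength
#' @return `data.frame(taxon, mean_depth_abundance, median_depth_abundance,
#'   n_fragments)`.
#' @export
baselineEstimates <- function(counts, expected, taxon_of = NULL) {
  exp0 <- expected[expected$i == 0L, , drop = FALSE]
  exp0 <- exp0[!duplicated(exp0[c("contig_id", "start", "end")]), ,
               drop = FALSE]
  if (is.null(taxon_of)) {
    gids <- unique(exp0$genome_id)
    taxon_of <- setNames(gids, gids)
  }
  taxon <- unname(taxon_of[exp0$genome_id])
  key <- paste(exp0$contig_id, exp0$start, exp0$end)
  cnt <- setNames(counts$read_count,
                  paste(counts$contig_id, counts$start, counts$end))
  reads <- unname(cnt[key])
  reads[is.na(reads)] <- 0L
  mu <- tapply(reads, taxon, mean)
  md <- tapply(reads, taxon, median)
  nf <- tapply(reads, taxon, length)
  data.frame(taxon = names(mu),
             mean_depth_abundance = as.numeric(mu) / sum(mu),
             median_depth_abundance =
               if (sum(md) > 0) as.numeric(md) / sum(md) else as.numeric(md),
             n_fragments = as.integer(nf),
             stringsAsFactors = FALSE, row.names = NULL)
}
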