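#' @importFrom Biostrings matchPattern
#' @importFrom IRanges start
NULL

#' Digestion parameters
#'
#' @param cut_efficiency per-site cleavage probability `c` in `(0, 1]`.
#' @param length_min,length_max fragment length window (bp) within which
#'   candidate fragments are enumerated. Fragments far beyond the
#'   size-selection envelope never survive selection, so enumeration is
#'   bounded to this window.
#' @param ddrad_strict when `TRUE`, keep only fragments whose two ends were
#'   produced by different enzymes (double-digest chemistry: the two
#'   adapters ligate to different overhangs).
#' @param max_internal maximum number of internal (uncut) sites a candidate
#'   fragment may span; survival decays as `(1-c)^i`, so deeply partial
#'   fragments are negligible.
#' @return validated parameter list used by the digestion functions.
#' @export
digestionParams <- function(cut_efficiency = 0.9, length_min = 1L,
                            length_max = 1000L, ddrad_strict = FALSE,
                            max_internal = 5L) {
  if (!is.numeric(cut_efficiency) || length(cut_efficiency) != 1L ||
      cut_efficiency <= 0 || cut_efficiency > 1)
    stop("cut_efficiency must lie in (0, 1]")
  length_min <- as.integer(length_min); length_max <- as.integer(length_max)
  if (length_min > length_max) stop("length_min > length_max")
  max_internal <- as.integer(max_internal)
  if (max_internal < 0L) stop("max_internal must be >= 0")
  list(cut_efficiency = cut_efficiency, length_min = length_min,
       length_max = length_max, ddrad_strict = isTRUE(ddrad_strict),
       max_internal = max_internal)
}

#' Survival probability of a digestion fragment
#'
#' Probability that a fragment spanning `i` internal (uncut) recognition
#' sites survives partial digestion intact with both of its boundary sites
#' cleaved, at per-site cut efficiency `c`:
#' complete digestion (`c = 1`, `i = 0`) gives 1, otherwise
#' `c^2 * (1 - c)^i`.
#'
#' @param c cut efficiency in `(0, 1]`.
#' @param i non-negative integer count of internal cut sites (vectorized).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' fragmentProbability(1, 0)        # 1
#' fragmentProbability(0.8, 0:2)    # 0.64 0.128 0.0256
#' @export
fragmentProbability <- function(c, i) {
  if (any(!is.finite(c)) || any(c <= 0) || any(c > 1))
    stop("c must lie in (0, 1]")
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 0)) stop("i must be a non-negative integer")
  p <- c^2 * (1 - c)^i
  p[c == 1 & i == 0L] <- 1
  p
}

#' Locate all cleavage sites of a standard motif
#'
#' Scans every contig with an overlap-tolerant, IUPAC-degenerate sliding
#' window: every offset at which the recognition sequence matches
#' contributes one cut, including overlapping matches. Genome `N` bases
#' never satisfy a motif position. Non-palindromic motifs are additionally
#' scanned as their reverse complement; a bottom-strand match at offset `s`
#' cuts the top strand at `s + (|motif| - cutOffset)`.
#'
#' Cut positions are 0-based: a cut at position `k` falls between bases
#' `k-1` and `k`, so `0 <= k <= contig length`.
#'
#' @param genomes a `DNAStringSet` from [loadGenomes()].
#' @param motif a standard-kind [EnzymeMotif-class].
#' @return `data.frame(genome_id, contig_id, position, enzyme, strand)`,
#'   sorted by contig and position, deduplicated per (position, enzyme).
#' @export
findCutSites <- function(genomes, motif) {
  stopifnot(is(motif, "EnzymeMotif"))
  if (motif@kind != "standard")
    stop("findCutSites handles standard motifs; see digestTypeIIB")
  rec <- motif@recognition
  wid <- nchar(rec)
  meta <- S4Vectors::mcols(genomes)
  out <- vector("list", length(genomes))
  pat_f <- Biostrings::DNAString(rec)
  pat_r <- if (!motif@palindromic) Biostrings::DNAString(revComp(rec)) else NULL
  for (k in seq_along(genomes)) {
    subj <- genomes[[k]]
    s_f <- IRanges::start(Biostrings::matchPattern(
      pat_f, subj, fixed = c(pattern = FALSE, subject = TRUE))) - 1L
    pos <- s_f + motif@cutOffset
    strand <- rep("+", length(pos))
    if (!is.null(pat_r)) {
      s_r <- IRanges::start(Biostrings::matchPattern(
        pat_r, subj, fixed = c(pattern = FALSE, subject = TRUE))) - 1L
      pos_r <- s_r + (wid - motif@cutOffset)
      pos <- c(pos, pos_r)
      strand <- c(strand, rep("-", length(pos_r)))
    }
    o <- order(pos, strand)
    pos <- pos[o]; strand <- strand[o]
    keep <- !duplicated(pos)
    out[[k]] <- data.frame(
      genome_id = rep(meta$genome_id[k], sum(keep)),
      contig_id = rep(meta$contig_id[k], sum(keep)),
      position = pos[keep], enzyme = rep(motif@name, sum(keep)),
      strand = strand[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cut sites for a panel of motifs across a community
#'
#' @param genomes a `DNAStringSet` from [loadGenomes()].
#' @param motifs list of standard-kind [EnzymeMotif-class] objects.
#' @return combined cut-site `data.frame` (see [findCutSites()]), sorted by
#'   contig and position.
#' @export
communityCutSites <- function(genomes, motifs) {
  if (is(motifs, "EnzymeMotif")) motifs <- list(motifs)
  sites <- do.call(rbind, lapply(motifs, findCutSites, genomes = genomes))
  sites[order(sites$contig_id, sites$position, sites$enzyme), , drop = FALSE]
}

#' Enumerate candidate fragments between cut sites
#'
#' Every ordered pair of cut positions `(a, b)` on the same contig with
#' `b - a` inside the length window and at most `max_internal` cuts
#' strictly between them yields one candidate fragment `[a, b)` with
#' internal-site count `i` and survival probability
#' [fragmentProbability()]`(c, i)`. Contig-terminal pieces (before the
#' first or after the last cut) are not fragments: they lack one
#' enzyme-generated end and can never receive both adapters.
#'
#' @param sites cut-site `data.frame` from [communityCutSites()] (any
#'   number of contigs/enzymes).
#' @param params a [digestionParams()] list.
#' @return `data.frame(genome_id, contig_id, start, end, length,
#'   left_enzyme, right_enzyme, i, p)`. Where several enzymes cut at one
#'   position the end label joins them with `","`.
#' @export
enumerateFragments <- function(sites, params) {
  if (is.null(sites) || nrow(sites) == 0L) return(.emptyFragments())
  pieces <- lapply(split(sites, sites$contig_id), function(s) {
    pos <- sort(unique(s$position))
    enz <- vapply(split(s$enzyme, s$position),
                  function(e) paste(sort(unique(e)), collapse = ","),
                  character(1))
    enz <- enz[as.character(pos)]
    m <- length(pos)
    if (m < 2L) return(NULL)
    rows <- list(); nr <- 0L
    for (j in seq_len(m - 1L)) {
      k <- j + 1L
      while (k <= m && pos[k] - pos[j] <= params$length_max) {
        i_int <- k - j - 1L
        if (i_int > params$max_internal) break
        len <- pos[k] - pos[j]
        if (len >= params$length_min) {
          ok <- TRUE
          if (params$ddrad_strict) {
            ends <- unique(c(strsplit(enz[j], ",")[[1]],
                             strsplit(enz[k], ",")[[1]]))
            ok <- length(ends) > 1L
          }
          if (ok) {
            nr <- nr + 1L
            rows[[nr]] <- c(pos[j], pos[k], i_int, j, k)
          }
        }
        k <- k + 1L
      }
    }
    if (nr == 0L) return(NULL)
    mat <- do.call(rbind, rows)
    data.frame(genome_id = s$genome_id[1L], contig_id = s$contig_id[1L],
               start = mat[, 1L], end = mat[, 2L],
               length = mat[, 2L] - mat[, 1L],
               left_enzyme = enz[mat[, 4L]], right_enzyme = enz[mat[, 5L]],
               i = mat[, 3L],
               p = fragmentProbability(params$cut_efficiency, mat[, 3L]),
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(.emptyFragments())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.emptyFragments <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             start = integer(), end = integer(), length = integer(),
             left_enzyme = character(), right_enzyme = character(),
             i = integer(), p = numeric(), stringsAsFactors = FALSE)
}

#' Digest with a type IIB (isolength) enzyme
#'
#' Type IIB enzymes such as BcgI cut on both sides of their recognition
#' site, excising the site plus fixed upstream/downstream flanks, so every
#' fragment has the same length `|motif| + upstream + downstream`. Both
#' strands are scanned; for bottom-strand matches the flanks swap sides.
#' Excisions exceeding the contig bounds are dropped. Each fragment has
#' `i = 0` and survival probability `c^2` (both flanking cuts must occur).
#'
#' @param genomes a `DNAStringSet` from [loadGenomes()].
#' @param motif a type IIB [EnzymeMotif-class].
#' @param cut_efficiency per-site cleavage probability in `(0, 1]`.
#' @return fragment `data.frame` in the [enumerateFragments()] layout.
#' @export
digestTypeIIB <- function(genomes, motif, cut_efficiency = 0.9) {
  stopifnot(is(motif, "EnzymeMotif"))
  if (motif@kind != "type_iib") stop("motif is not type IIB")
  rec <- motif@recognition
  wid <- nchar(rec)
  p <- fragmentProbability(cut_efficiency, 0L)
  meta <- S4Vectors::mcols(genomes)
  pat_f <- Biostrings::DNAString(rec)
  pal <- identical(rec, revComp(rec))
  pat_r <- if (!pal) Biostrings::DNAString(revComp(rec)) else NULL
  out <- vector("list", length(genomes))
  for (k in seq_along(genomes)) {
    subj <- genomes[[k]]
    L <- length(subj)
    s_f <- IRanges::start(Biostrings::matchPattern(
      pat_f, subj, fixed = c(pattern = FALSE, subject = TRUE))) - 1L
    starts <- s_f - motif@iibUpstream
    ends <- s_f + wid + motif@iibDownstream
    if (!is.null(pat_r)) {
      s_r <- IRanges::start(Biostrings::matchPattern(
        pat_r, subj, fixed = c(pattern = FALSE, subject = TRUE))) - 1L
      starts <- c(starts, s_r - motif@iibDownstream)
      ends <- c(ends, s_r + wid + motif@iibUpstream)
    }
    keep <- starts >= 0L & ends <= L
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    o <- order(starts)
    out[[k]] <- data.frame(
      genome_id = meta$genome_id[k], contig_id = meta$contig_id[k],
      start = starts[o], end = ends[o], length = ends[o] - starts[o],
      left_enzyme = motif@name, right_enzyme = motif@name,
      i = 0L, p = p, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyFragments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Digest genomes and tally the expected fragment-length distribution
#'
#' Runs the full per-genome digestion: cut-site detection for every motif,
#' candidate-fragment enumeration with survival probabilities, and the
#' per-genome expected length distribution
#' `D_g(x) = sum of p over fragments of length x` — the expected number of
#' surviving fragments of each length per single genome copy.
#'
#' @param genomes a `DNAStringSet` from [loadGenomes()] (one or more
#'   genomes; contigs are digested independently as linear molecules).
#' @param motifs list of [EnzymeMotif-class] (standard and/or type IIB).
#' @param params a [digestionParams()] list.
#' @return list with `fragments` (combined fragment `data.frame`) and
#'   `dist` (named list: genome id -> [lengthDistribution()]).
#' @export
digestGenome <- function(genomes, motifs, params = digestionParams()) {
  if (is(motifs, "EnzymeMotif")) motifs <- list(motifs)
  if (!length(motifs)) stop("at least one motif required")
  kinds <- vapply(motifs, function(m) m@kind, character(1))
  frags <- .emptyFragments()
  std <- motifs[kinds == "standard"]
  if (length(std)) {
    sites <- communityCutSites(genomes, std)
    frags <- enumerateFragments(sites, params)
  }
  for (m in motifs[kinds == "type_iib"]) {
    fb <- digestTypeIIB(genomes, m, params$cut_efficiency)
    fb <- fb[fb$length >= params$length_min & fb$length <= params$length_max, ,
             drop = FALSE]
    frags <- rbind(frags, fb)
  }
  gids <- unique(S4Vectors::mcols(genomes)$genome_id)
  dist <- lapply(setNames(gids, gids), function(g) {
    f <- frags[frags$genome_id == g, , drop = FALSE]
    if (!nrow(f)) return(lengthDistribution(integer(), numeric()))
    w <- tapply(f$p, f$length, sum)
    w <- w[w > 0]  # zero-probability lengths carry no expected fragments
    lengthDistribution(as.integer(names(w)), as.numeric(w))
  })
  list(fragments = frags, dist = dist)
}
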