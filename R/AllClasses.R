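#' @import methods
#' @importFrom stats dnorm median rmultinom runif rlnorm rnorm rpois setNames
#' @importFrom utils read.table write.table
NULL

#' EnzymeMotif: a restriction enzyme recognition motif with cut geometry
#'
#' Holds an IUPAC recognition sequence together with the information needed
#' to place cuts on a genome. Standard (type IIP-style) motifs cut once
#' within the recognition sequence at `cutOffset` bases from its 5' end on
#' the top strand (the position of the `/` in notations such as
#' `"G/AATTC"`). Type IIB (isolength) motifs excise the recognition site
#' together with fixed flanks of `iibUpstream` bp upstream and
#' `iibDownstream` bp downstream, so every fragment they produce has the
#' same length.
#'
#' @slot name single character, the enzyme name (e.g. `"EcoRI"`).
#' @slot recognition IUPAC recognition sequence, `/` removed.
#' @slot cutOffset integer in `[0, nchar(recognition)]`; top-strand cut
#'   position (standard motifs only).
#' @slot kind `"standard"` or `"type_iib"`.
#' @slot iibUpstream,iibDownstream non-negative integers, excision flanks
#'   (type IIB only; ignored for standard motifs).
#' @slot palindromic derived flag: `TRUE` when the recognition sequence
#'   equals its IUPAC reverse complement.
#'
#' @seealso [parseMotif()] for the user-facing constructor.
#' @exportClass EnzymeMotif
setClass("EnzymeMotif",
  representation(
    name = "character",
    recognition = "character",
    cutOffset = "integer",
    kind = "character",
    iibUpstream = "integer",
    iibDownstream = "integer",
    palindromic = "logical"
  ),
  prototype(
    kind = "standard",
    iibUpstream = 0L,
    iibDownstream = 0L
  )
)

setValidity("EnzymeMotif", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || !nzchar(rec)) {
    msg <- c(msg, "'recognition' must be a single non-empty string")
  } else if (!all(strsplit(rec, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP))) {
    msg <- c(msg, sprintf("invalid IUPAC character in recognition '%s'", rec))
  }
  if (!object@kind %in% c("standard", "type_iib"))
    msg <- c(msg, "'kind' must be \"standard\" or \"type_iib\"")
  if (object@kind == "standard") {
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L || object@cutOffset > nchar(rec))
      msg <- c(msg, "'cutOffset' must lie in [0, nchar(recognition)]")
  } else {
    if (object@iibUpstream < 0L || object@iibDownstream < 0L)
      msg <- c(msg, "type IIB flanks must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EnzymeMotif-class display method
#' @param object an `EnzymeMotif`
#' @export
setMethod("show", "EnzymeMotif", function(object) {
  if (object@kind == "standard") {
    rec <- object@recognition
    pretty <- paste0(substr(rec, 1L, object@cutOffset), "/",
                     substr(rec, object@cutOffset + 1L, nchar(rec)))
    cat(sprintf("EnzymeMotif %s (%s)%s\n", object@name, pretty,
                if (object@palindromic) " [palindromic]" else ""))
  } else {
    cat(sprintf("EnzymeMotif %s (%s) type IIB, flanks %d/%d bp\n",
                object@name, object@recognition,
                object@iibUpstream, object@iibDownstream))
  }
})

#' CommunityProfile: relative genome-copy abundances of community members
#'
#' A named set of strictly positive relative abundances, one per genome,
#' normalized to sum to one. Abundances are genome-copy proportions (how
#' many copies of each genome are present in the DNA pool), not target read
#' fractions: the read share a genome finally receives also depends on how
#' its digest interacts with size selection.
#'
#' @slot genomeId character vector of unique genome identifiers.
#' @slot abundance numeric vector, positive, summing to one.
#'
#' @exportClass CommunityProfile
setClass("CommunityProfile",
  representation(genomeId = "character", abundance = "numeric")
)

setValidity("CommunityProfile", function(object) {
  msg <- character()
  if (length(object@genomeId) != length(object@abundance))
    msg <- c(msg, "genomeId and abundance lengths differ")
  if (anyDuplicated(object@genomeId))
    msg <- c(msg, "duplicate genome ids")
  if (any(!is.finite(object@abundance)) || any(object@abundance <= 0))
    msg <- c(msg, "abundances must be positive and finite")
  if (length(object@abundance) &&
      abs(sum(object@abundance) - 1) > 1e-12)
    msg <- c(msg, "abundances must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityProfile-class display method
#' @param object a `CommunityProfile`
#' @export
setMethod("show", "CommunityProfile", function(object) {
  cat(sprintf("CommunityProfile with %d genomes\n", length(object@genomeId)))
  df <- data.frame(genome_id = object@genomeId, abundance = object@abundance)
  print(utils::head(df, 8L), row.names = FALSE)
  if (nrow(df) > 8L) cat(sprintf("  ... and %d more\n", nrow(df) - 8L))
})

#' @rdname CommunityProfile-class
#' @param x a `CommunityProfile`
#' @export
genomeIds <- function(x) {
  stopifnot(is(x, "CommunityProfile"))
  x@genomeId
}

#' @rdname CommunityProfile-class
#' @export
abundances <- function(x) {
  stopifnot(is(x, "CommunityProfile"))
  setNames(x@abundance, x@genomeId)
}

#' Construct a CommunityProfile from ids and raw abundances
#'
#' Raw abundances are normalized to sum to one.
#'
#' @param genome_id character vector of unique genome ids.
#' @param abundance positive numeric vector of relative genome-copy numbers.
#' @return a [CommunityProfile-class] object.
#' @examples
#' communityProfile(c("g1", "g2"), c(1, 3))
#' @export
communityProfile <- function(genome_id, abundance) {
  genome_id <- as.character(genome_id)
  abundance <- as.numeric(abundance)
  if (length(genome_id) != length(abundance))
    stop("genome_id and abundance must have the same length")
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("abundances must be positive finite numbers")
  new("CommunityProfile", genomeId = genome_id,
      abundance = abundance / sum(abundance))
}

#' RatioMatrix: averaged pairwise per-length depth ratios between taxa
#'
#' A square taxa-by-taxa matrix in which entry `[i, j]` is the arithmetic
#' mean, over fragment lengths where both taxa have defined mean depth and
#' taxon `j`'s depth is positive, of `depth(i, L) / depth(j, L)`. Entries
#' are `NA` where the two taxa share no informative fragment length; the
#' diagonal is 1. This is the central object of the fixed length taxonomic
#' ratio (FLTR) abundance estimator.
#'
#' @seealso [computeRatioMatrix()], [fltrEstimate()]
#' @exportClass RatioMatrix
setClass("RatioMatrix", contains = "matrix")

setValidity("RatioMatrix", function(object) {
  m <- object@.Data
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "must carry identical row and column taxon names")
  offd <- m[row(m) != col(m)]
  if (any(!is.na(offd) & offd <= 0))
    msg <- c(msg, "defined ratios must be positive")
  if (nrow(m) && any(abs(diag(m) - 1) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn RatioMatrix-class display method
#' @param object a `RatioMatrix`
#' @export
setMethod("show", "RatioMatrix", function(object) {
  cat(sprintf("RatioMatrix over %d taxa (%d of %d off-diagonal ratios defined)\n",
              nrow(object), sum(!is.na(object[row(object) != col(object)])),
              nrow(object) * (nrow(object) - 1L)))
  print(round(object@.Data[seq_len(min(6L, nrow(object))),
                           seq_len(min(6L, ncol(object))), drop = FALSE], 4))
})

#' Number of defined off-diagonal relationships per taxon
#'
#' @param x a [RatioMatrix-class]
#' @return named integer vector: for each taxon, how many other taxa it
#'   shares at least one informative fragment length with.
#' @export
relationshipCounts <- function(x) {
  stopifnot(is(x, "RatioMatrix"))
  m <- x@.Data
  diag(m) <- NA
  rowSums(!is.na(m))
}
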