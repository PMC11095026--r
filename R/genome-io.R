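#' @importFrom Biostrings readBStringSet readDNAStringSet writeXStringSet
#'   DNAStringSet DNAString reverseComplement IUPAC_CODE_MAP
#' @importFrom S4Vectors mcols mcols<-
NULL

.IUPAC <- names(Biostrings::IUPAC_CODE_MAP)
.AMBIG_NOT_N <- setdiff(.IUPAC, c("A", "C", "G", "T", "N"))

#' Load community genomes from FASTA files
#'
#' Reads one FASTA file (plain or gzip) per community member. Each FASTA
#' record becomes one contig; all contigs of a file share the file's genome
#' id. Sequences are upper-cased; IUPAC ambiguity codes other than N are
#' folded to N (with a warning), and any non-IUPAC character is an error
#' naming the offending record.
#'
#' @param paths character vector of FASTA file paths.
#' @param genome_ids optional character vector of genome ids, one per path;
#'   defaults to the file names stripped of their extensions.
#' @return a [Biostrings::DNAStringSet] named by contig id (the first
#'   whitespace-delimited token of each header), with `mcols()` columns
#'   `genome_id` and `contig_id`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 circularised", "acgtACGT"), fa)
#' loadGenomes(fa, genome_ids = "g1")
#' @export
loadGenomes <- function(paths, genome_ids = NULL) {
  if (is.null(genome_ids)) {
    genome_ids <- vapply(basename(paths), function(b) {
      b <- sub("\\.gz$", "", b)
      tools::file_path_sans_ext(b)
    }, character(1), USE.NAMES = FALSE)
  }
  if (length(genome_ids) != length(paths))
    stop("genome_ids must match paths in length")
  if (anyDuplicated(genome_ids))
    stop("duplicate genome ids: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "))

  pieces <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    path <- paths[[k]]
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
      stop("empty FASTA file: ", path)
    contig_id <- vapply(strsplit(names(raw), "[ \t]"), `[`, character(1), 1L)
    seqs <- toupper(as.character(raw))
    for (j in seq_along(seqs)) {
      chars <- unique(strsplit(seqs[[j]], "")[[1]])
      bad <- setdiff(chars, .IUPAC)
      if (length(bad))
        stop(sprintf("illegal character(s) %s in record '%s' of %s",
                     paste(sQuote(bad), collapse = ", "), contig_id[j], path))
      amb <- intersect(chars, .AMBIG_NOT_N)
      if (length(amb)) {
        warning(sprintf("record '%s' of %s: ambiguity codes %s folded to N",
                        contig_id[j], path, paste(amb, collapse = ",")))
        seqs[[j]] <- chartr(paste(amb, collapse = ""),
                            strrep("N", length(amb)), seqs[[j]])
      }
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- contig_id
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
      genome_id = rep(genome_ids[[k]], length(x)),
      contig_id = contig_id)
    pieces[[k]] <- x
  }
  out <- do.call(c, pieces)
  if (anyDuplicated(names(out)))
    stop("duplicate contig ids across inputs: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Write genomes back to FASTA
#'
#' @param genomes a `DNAStringSet` as returned by [loadGenomes()].
#' @param path output FASTA path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeGenomes <- function(genomes, path) {
  Biostrings::writeXStringSet(genomes, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Load a relative abundance table
#'
#' Reads a two-column tab-separated table (genome id, abundance). Lines
#' starting with `#` are comments; there is no header. Abundances are
#' relative genome-copy numbers and are normalized to sum to one.
#'
#' @param path TSV file path.
#' @param genomes optional: a `DNAStringSet` from [loadGenomes()] or a
#'   character vector of known genome ids; every table row must name one.
#' @return a [CommunityProfile-class].
#' @export
loadAbundanceTable <- function(path, genomes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L)
    stop("abundance table must have exactly two tab-separated columns")
  ab <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(ab)))
    stop("non-numeric abundance for: ",
         paste(tab[[1L]][is.na(ab)], collapse = ", "))
  if (any(ab <= 0))
    stop("nonpositive abundance for: ",
         paste(tab[[1L]][ab <= 0], collapse = ", "))
  if (!is.null(genomes)) {
    known <- if (is.character(genomes)) genomes else
      unique(S4Vectors::mcols(genomes)$genome_id)
    missing <- setdiff(tab[[1L]], known)
    if (length(missing))
      stop("abundance table names unknown genome(s): ",
           paste(missing, collapse = ", "))
  }
  communityProfile(tab[[1L]], ab)
}

#' Parse a restriction enzyme motif definition
#'
#' Standard motifs use cut-position notation with a single `/` marking the
#' top-strand cut, e.g. `"G/AATTC"` (EcoRI) or `"GCG/C"` (HhaI). Type IIB
#' (isolength) motifs have no `/` and instead carry two excision flank
#' widths, either via the `iib` argument or inline as
#' `"NAME=CGANNNNNNTGC;iib=12,12"`. A leading `"NAME="` sets the enzyme
#' name in either form.
#'
#' @param spec motif string, optionally `"NAME=..."` prefixed.
#' @param name enzyme name; required when not embedded in `spec`.
#' @param iib optional integer pair `c(upstream, downstream)` of excision
#'   flank widths, marking the motif as type IIB.
#' @return an [EnzymeMotif-class].
#' @examples
#' parseMotif("EcoRI=G/AATTC")
#' parseMotif("GCG/C", name = "HhaI")
#' parseMotif("BcgI=CGANNNNNNTGC;iib=12,12")
#' @export
parseMotif <- function(spec, name = NULL, iib = NULL) {
  if (grepl("=", spec, fixed = TRUE)) {
    parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
    if (length(parts) == 3L && grepl(";iib$", parts[2L])) {
      # NAME=MOTIF;iib=a,b
      name <- parts[1L]
      spec <- sub(";iib$", "", parts[2L])
      iib <- as.integer(strsplit(parts[3L], ",", fixed = TRUE)[[1]])
    } else if (length(parts) == 2L) {
      name <- parts[1L]
      spec <- parts[2L]
    } else stop("malformed motif spec: ", spec)
  }
  if (is.null(name)) stop("enzyme name required")
  nslash <- lengths(regmatches(spec, gregexpr("/", spec, fixed = TRUE)))
  if (is.null(iib)) {
    if (nslash != 1L)
      stop(sprintf("motif '%s' must contain exactly one '/', found %d",
                   spec, nslash))
    cut_offset <- as.integer(regexpr("/", spec, fixed = TRUE)) - 1L
    rec <- sub("/", "", spec, fixed = TRUE)
    kind <- "standard"
    up <- down <- 0L
  } else {
    if (nslash != 0L)
      stop("type IIB motifs take flank widths, not '/' notation: ", spec)
    if (length(iib) != 2L || any(is.na(iib)) || any(iib < 0))
      stop("iib must be two non-negative integers")
    rec <- spec
    cut_offset <- 0L
    kind <- "type_iib"
    up <- as.integer(iib[1L]); down <- as.integer(iib[2L])
  }
  bad <- setdiff(unique(strsplit(rec, "")[[1]]), .IUPAC)
  if (length(bad))
    stop(sprintf("invalid IUPAC character(s) %s in motif '%s'",
                 paste(sQuote(bad), collapse = ", "), spec))
  new("EnzymeMotif", name = name, recognition = rec,
      cutOffset = cut_offset, kind = kind,
      iibUpstream = up, iibDownstream = down,
      palindromic = identical(rec, revComp(rec)))
}

#' Does an IUPAC code match a concrete base?
#'
#' @param code single IUPAC symbol (possibly degenerate).
#' @param base single base in `A`, `C`, `G`, `T`.
#' @return `TRUE` iff `base` belongs to `code`'s degeneracy set.
#' @examples
#' iupacMatches("R", "A")  # TRUE: R = A/G
#' iupacMatches("W", "C")  # FALSE
#' @export
iupacMatches <- function(code, base) {
  if (!code %in% .IUPAC) stop("invalid IUPAC code: ", code)
  if (!base %in% c("A", "C", "G", "T")) stop("base must be one of A,C,G,T")
  grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE)
}

#' Reverse complement of an IUPAC string
#'
#' Degenerate codes complement set-wise (R <-> Y, S <-> S, W <-> W,
#' K <-> M, N <-> N).
#'
#' @param seq IUPAC character string.
#' @return the reverse complement, as a character string.
#' @examples
#' revComp("GAATTC")  # palindromic
#' revComp("GACN")
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# ---- length distributions ---------------------------------------------------

#' Fragment length distributions
#'
#' A length distribution maps integer fragment lengths (bp) to non-negative
#' expected counts or weights. It is represented as a named numeric vector
#' whose names are the lengths. The JSON dialect used on disk is a flat
#' object `{"<length>": weight, ...}` — the same format the estimation step
#' exports for re-simulation from an observed digest.
#'
#' @param lengths integer vector of fragment lengths (bp).
#' @param weights non-negative numeric vector of the same length.
#' @return named numeric vector sorted by length.
#' @examples
#' d <- lengthDistribution(c(100, 150, 200), c(10, 20, 10))
#' tf <- tempfile(fileext = ".json")
#' writeLengthWeights(d, tf)
#' identical(readLengthWeights(tf), d)
#' @export
lengthDistribution <- function(lengths, weights) {
  lengths <- as.integer(lengths)
  weights <- as.numeric(weights)
  if (length(lengths) != length(weights))
    stop("lengths and weights must have equal length")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and >= 0")
  if (anyDuplicated(lengths)) {
    weights <- as.numeric(tapply(weights, lengths, sum))
    lengths <- sort(unique(lengths))
  }
  o <- order(lengths)
  setNames(weights[o], lengths[o])
}

#' @rdname lengthDistribution
#' @param path JSON file path.
#' @export
readLengthWeights <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!length(obj)) return(lengthDistribution(integer(), numeric()))
  lengthDistribution(as.integer(names(obj)), as.numeric(unlist(obj)))
}

#' @rdname lengthDistribution
#' @param d a length distribution (named numeric vector).
#' @export
writeLengthWeights <- function(d, path) {
  jsonlite::write_json(as.list(d), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
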