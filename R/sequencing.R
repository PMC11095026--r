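#' Adapter sequences appended beyond the insert
#'
#' Read 1 runs insert -> `r1` adapter; read 2 runs the reverse-complemented
#' insert -> `r2` adapter. Inserts shorter than the read length therefore
#' show adapter read-through, exactly as in a real short-insert library.
#'
#' @param r1,r2 adapter sequences over `A`,`C`,`G`,`T` (may be empty).
#' @return adapter set list used by [buildReadPairs()].
#' @export
adapterSet <- function(r1 = "", r2 = "") {
  for (a in c(r1, r2))
    if (nzchar(a) && grepl("[^ACGT]", a))
      stop("adapters must be plain A/C/G/T sequences")
  list(r1 = r1, r2 = r2)
}

#' Build paired read templates from insert sequences
#'
#' For each insert, read 1 is the first `read_length` bases of
#' `insert + r1_adapter` and read 2 the first `read_length` bases of
#' `reverse_complement(insert) + r2_adapter`; templates still shorter than
#' the read length are padded with `A` (a deliberately artificial filler).
#' Orientation `-` reverse-complements the insert first, swapping which
#' fragment end seeds read 1.
#'
#' @param inserts character vector of fragment sequences.
#' @param adapters an [adapterSet()].
#' @param read_length read length in bp.
#' @param orientation character vector of `"+"`/`"-"` per insert (recycled).
#' @return list of character vectors `r1` and `r2`.
#' @examples
#' buildReadPairs("ACGT", adapterSet(), read_length = 8)$r1  # "ACGTAAAA"
#' @export
buildReadPairs <- function(inserts, adapters = adapterSet(),
                           read_length, orientation = "+") {
  if (!length(inserts)) return(list(r1 = character(), r2 = character()))
  orientation <- rep_len(orientation, length(inserts))
  flip <- orientation == "-"
  if (any(flip)) inserts[flip] <- .revCompVec(inserts[flip])
  rc <- .revCompVec(inserts)
  pad <- strrep("A", read_length)
  r1 <- substr(paste0(inserts, adapters$r1, pad), 1L, read_length)
  r2 <- substr(paste0(rc, adapters$r2, pad), 1L, read_length)
  list(r1 = r1, r2 = r2)
}

.revCompVec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Load a base-quality profile from a donor FASTQ
#'
#' Harvests the Phred+33 quality strings of an existing FASTQ file (plain
#' or gzip) to serve as the empirical quality pool for simulation.
#'
#' @param path donor FASTQ path.
#' @param read_length required read length; every donor string must be at
#'   least this long (checked at load time).
#' @return list with `pool` (character vector of quality strings) and
#'   `source`.
#' @export
loadQualityProfile <- function(path, read_length) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (!length(x)) stop("empty donor FASTQ: ", path)
  pool <- as.character(S4Vectors::mcols(x)$qualities)
  short <- nchar(pool) < read_length
  if (any(short))
    stop(sum(short), " donor quality string(s) shorter than read_length in ",
         path)
  list(pool = pool, source = path)
}

#' Sample quality strings from a profile
#'
#' @param profile a [loadQualityProfile()] result.
#' @param read_length truncation length.
#' @param n number of strings to draw.
#' @param seed optional integer seed.
#' @return character vector of `n` quality strings of `read_length`.
#' @export
sampleQuality <- function(profile, read_length, n = 1L, seed = NULL) {
  idx <- .withSeed(seed, sample.int(length(profile$pool), n, replace = TRUE))
  substr(profile$pool[idx], 1L, read_length)
}

#' Apply Phred-driven substitution errors
#'
#' Each base is substituted with probability `10^(-Q/10)` given its Phred+33
#' quality, choosing uniformly among the three other bases; `N` positions
#' are left untouched. Substitution is the only error mode modeled (no
#' indels).
#'
#' @param seqs character vector of read sequences.
#' @param quals matching character vector of quality strings (equal widths).
#' @param seed optional integer seed.
#' @return mutated sequences.
#' @export
applyErrors <- function(seqs, quals, seed = NULL) {
  if (!length(seqs)) return(seqs)
  wid <- nchar(seqs)
  if (length(quals) != length(seqs) || any(nchar(quals) != wid))
    stop("seqs and quals must match in number and width")
  s <- charToRaw(paste(seqs, collapse = ""))
  q <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  if (any(q < 0L)) stop("quality characters below '!' (Phred+33)")
  p <- 10^(-q / 10)
  bases <- charToRaw("ACGT")
  idx <- match(s, bases)                       # NA for N etc.
  .withSeed(seed, {
    hit <- which(!is.na(idx) & runif(length(s)) < p)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      s[hit] <- bases[((idx[hit] - 1L + shift) %% 4L) + 1L]
    }
  })
  big <- rawToChar(s)
  ends <- cumsum(wid)
  substring(big, ends - wid + 1L, ends)
}

#' Write paired reads as FASTQ
#'
#' Headers follow the provenance dialect
#' `@<genome_id>:<contig_id>:<start>:<end>:<orientation>:<serial>` with
#' `/1` / `/2` mate suffixes, so source fragments can be recreated from
#' headers alone without alignment.
#'
#' @param reads `data.frame` with columns `genome_id`, `contig_id`,
#'   `start`, `end`, `orientation`, `serial`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`.
#' @param out_r1,out_r2 output FASTQ paths (`.gz` suffix compresses).
#' @param append open in append mode (used by the chunked simulator).
#' @return invisible `c(out_r1, out_r2)`.
#' @export
writeFastq <- function(reads, out_r1, out_r2, append = FALSE) {
  hdr <- sprintf("%s:%s:%d:%d:%s:%d", reads$genome_id, reads$contig_id,
                 reads$start, reads$end, reads$orientation, reads$serial)
  mode <- if (append) "ab" else "wb"
  openOut <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
  }
  con1 <- openOut(out_r1); on.exit(close(con1), add = TRUE)
  con2 <- openOut(out_r2); on.exit(close(con2), add = TRUE)
  writeLines(as.vector(rbind(paste0("@", hdr, "/1"), reads$r1_seq,
                             "+", reads$r1_qual)), con1)
  writeLines(as.vector(rbind(paste0("@", hdr, "/2"), reads$r2_seq,
                             "+", reads$r2_qual)), con2)
  invisible(c(out_r1, out_r2))
}

#' Parse provenance FASTQ headers back into fragment coordinates
#'
#' @param path FASTQ path written by [writeFastq()] (R1 or R2).
#' @return `data.frame(genome_id, contig_id, start, end, orientation,
#'   serial)` with one row per read.
#' @export
parseProvenance <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^@", "", sub("/[12]$", "", lines[seq(1L, length(lines), by = 4L)]))
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 6L)) stop("malformed provenance header in ", path)
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  data.frame(genome_id = m[, 1L], contig_id = m[, 2L],
             start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
             orientation = m[, 5L], serial = as.integer(m[, 6L]),
             stringsAsFactors = FALSE)
}

#' Turn allocated fragments into paired-end reads
#'
#' Expands each fragment into its allocated number of read pairs, extracts
#' insert sequences from the genomes, assigns orientations (read 1 starts
#' at the forward-enzyme end for double-digest fragments, uniformly at
#' random otherwise), samples qualities from the donor profile (constant
#' Q40 when none is supplied) and applies substitution errors. Reads are
#' processed in chunks to bound memory; when `out_r1`/`out_r2` are given
#' they are streamed to FASTQ.
#'
#' @param alloc fragment `data.frame` from [allocateReads()] (column
#'   `reads`).
#' @param genomes the digested `DNAStringSet`.
#' @param read_length read length in bp.
#' @param adapters an [adapterSet()].
#' @param quality_profile optional [loadQualityProfile()] result (one
#'   profile reused for both mates, or a list of two as `list(r1=, r2=)`).
#' @param forward_enzyme name of the enzyme whose end seeds read 1 in
#'   double-digest fragments; defaults to the lexicographically first left
#'   enzyme.
#' @param seed optional integer seed driving orientation, quality sampling
#'   and errors.
#' @param out_r1,out_r2 optional FASTQ output paths.
#' @param chunk_size read pairs per processing chunk.
#' @return `data.frame` of read provenance (one row per pair:
#'   `genome_id`, `contig_id`, `start`, `end`, `orientation`, `serial`),
#'   invisibly when FASTQ output was requested.
#' @export
simulateReads <- function(alloc, genomes, read_length = 150L,
                          adapters = adapterSet(), quality_profile = NULL,
                          forward_enzyme = NULL, seed = NULL,
                          out_r1 = NULL, out_r2 = NULL,
                          chunk_size = 100000L) {
  alloc <- alloc[alloc$reads > 0L, , drop = FALSE]
  write_out <- !is.null(out_r1)
  if (write_out && is.null(out_r2)) stop("both out_r1 and out_r2 required")
  if (is.null(forward_enzyme) && nrow(alloc))
    forward_enzyme <- sort(unique(unlist(
      strsplit(alloc$left_enzyme, ",", fixed = TRUE))))[1L]
  qp1 <- qp2 <- quality_profile
  if (!is.null(quality_profile) &&
      all(c("r1", "r2") %in% names(quality_profile))) {
    qp1 <- quality_profile$r1; qp2 <- quality_profile$r2
  }

  idx <- rep.int(seq_len(nrow(alloc)), alloc$reads)
  n_total <- length(idx)
  if (n_total == 0L) {
    out <- data.frame(genome_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      orientation = character(), serial = integer())
    return(out)
  }
  inserts <- .extractInserts(alloc, genomes)

  runner <- function() {
    res <- vector("list", ceiling(n_total / chunk_size))
    serial0 <- 0L
    for (ch in seq_along(res)) {
      take <- idx[(serial0 + 1L):min(serial0 + chunk_size, n_total)]
      nr <- length(take)
      f <- alloc[take, , drop = FALSE]
      same_end <- f$left_enzyme == f$right_enzyme
      orient <- ifelse(grepl(forward_enzyme, f$left_enzyme, fixed = TRUE) &
                         !same_end, "+",
                       ifelse(same_end, NA, "-"))
      if (anyNA(orient))
        orient[is.na(orient)] <- sample(c("+", "-"), sum(is.na(orient)),
                                        replace = TRUE)
      pairs <- buildReadPairs(inserts[take], adapters, read_length, orient)
      if (is.null(qp1)) {
        q1 <- q2 <- rep(strrep("I", read_length), nr)
      } else {
        q1 <- sampleQuality(qp1, read_length, nr)
        q2 <- sampleQuality(qp2, read_length, nr)
      }
      reads <- data.frame(
        genome_id = f$genome_id, contig_id = f$contig_id,
        start = f$start, end = f$end, orientation = orient,
        serial = serial0 + seq_len(nr),
        r1_seq = applyErrors(pairs$r1, q1), r1_qual = q1,
        r2_seq = applyErrors(pairs$r2, q2), r2_qual = q2,
        stringsAsFactors = FALSE)
      if (write_out) {
        writeFastq(reads, out_r1, out_r2, append = ch > 1L)
        res[[ch]] <- reads[, 1:6]
      } else res[[ch]] <- reads
      serial0 <- serial0 + nr
    }
    do.call(rbind, res)
  }
  out <- .withSeed(seed, runner())
  if (write_out) invisible(out) else out
}

# Extract [start, end) insert sequences (0-based half-open) per fragment.
.extractInserts <- function(frags, genomes) {
  inserts <- character(nrow(frags))
  for (cid in unique(frags$contig_id)) {
    rows <- which(frags$contig_id == cid)
    subj <- genomes[[match(cid, names(genomes))]]
    v <- Biostrings::extractAt(
      subj, IRanges::IRanges(frags$start[rows] + 1L, frags$end[rows]))
    inserts[rows] <- as.character(v)
  }
  inserts
}
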