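#' Generate a synthetic genome, optionally with planted restriction sites
#'
#' Draws i.i.d. bases at a target GC content. When `planted` motifs are
#' given, exact (concretely instantiated) recognition-site copies are
#' inserted at fixed spacings and all *accidental* occurrences of the
#' planted motifs elsewhere (either strand) are scrubbed away by point
#' mutation, so the expected cut positions — and hence fragment lengths
#' under complete digestion — are known in closed form.
#'
#' @param genome_id id for the generated (single-contig) genome.
#' @param length genome length in bp.
#' @param gc target GC content in `(0, 1)`.
#' @param planted optional list of `list(motif = <EnzymeMotif>, spacing =
#'   <bp>)`; each motif is planted at `spacing, 2*spacing, ...` (0-based
#'   start offsets). `spacing` must be at least the motif length.
#' @param seed optional integer seed (fixed seed gives identical bytes).
#' @return a `DNAStringSet` of one contig with [loadGenomes()]-style
#'   `mcols`.
#' @export
generateGenome <- function(genome_id, length, gc = 0.5, planted = NULL,
                           seed = NULL) {
  length <- as.integer(length)
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  seqchar <- .withSeed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    base <- sample(names(probs), length, replace = TRUE, prob = probs)
    if (!is.null(planted)) {
      for (pl in planted) {
        motif <- pl$motif
        inst <- .instantiateMotif(motif@recognition)
        wid <- nchar(inst)
        if (pl$spacing < wid)
          stop("spacing shorter than motif length for ", motif@name)
        starts0 <- seq(pl$spacing, length - wid, by = pl$spacing)
        for (s in starts0)
          base[(s + 1L):(s + wid)] <- strsplit(inst, "")[[1]]
      }
      s <- paste(base, collapse = "")
      s <- .scrubAccidental(s, planted)
      s
    } else paste(base, collapse = "")
  })
  x <- Biostrings::DNAStringSet(seqchar)
  names(x) <- genome_id
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(genome_id = genome_id,
                                              contig_id = genome_id)
  x
}

# Replace degenerate IUPAC codes by the first base of their set.
.instantiateMotif <- function(rec) {
  paste(vapply(strsplit(rec, "")[[1]],
               function(ch) substr(Biostrings::IUPAC_CODE_MAP[[ch]], 1L, 1L),
               character(1)),
        collapse = "")
}

# Mutate away motif occurrences not at the planted offsets (both strands),
# taking care never to touch a base inside a planted site and never to
# mutate into a base the motif position still accepts.
.scrubAccidental <- function(s, planted) {
  protected <- unlist(lapply(planted, function(pl) {
    wid <- nchar(pl$motif@recognition)
    starts0 <- seq(pl$spacing, nchar(s) - wid, by = pl$spacing)
    unlist(lapply(starts0, function(a) (a + 1L):(a + wid)))
  }))
  for (iter in seq_len(50L)) {
    subj <- Biostrings::DNAString(s)
    dirty <- FALSE
    for (pl in planted) {
      motif <- pl$motif
      wid <- nchar(motif@recognition)
      want <- seq(pl$spacing, nchar(s) - wid, by = pl$spacing)
      recs <- motif@recognition
      if (!motif@palindromic) recs <- c(recs, revComp(motif@recognition))
      for (rec in recs) {
        hits <- IRanges::start(Biostrings::matchPattern(
          Biostrings::DNAString(rec), subj,
          fixed = c(pattern = FALSE, subject = TRUE))) - 1L
        bad <- if (identical(rec, motif@recognition))
          setdiff(hits, want) else hits
        for (b in bad) {
          fixed_one <- FALSE
          for (off in seq_len(wid)) {
            pos <- b + off
            if (pos %in% protected) next
            allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[
              substr(rec, off, off)]], "")[[1]]
            repl <- setdiff(c("A", "C", "G", "T"), allowed)
            if (!length(repl)) next
            substr(s, pos, pos) <- repl[1L]
            fixed_one <- TRUE
            break
          }
          if (!fixed_one)
            stop("accidental site at ", b, " overlaps planted sites")
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(s)
  }
  stop("could not scrub accidental motif occurrences")
}

#' Generate a synthetic community abundance profile
#'
#' @param genome_ids character vector of at least two genome ids.
#' @param model `"uniform"` or `"lognormal"` relative genome-copy numbers.
#' @param meanlog,sdlog log-normal parameters (lognormal model).
#' @param seed optional integer seed.
#' @return a [CommunityProfile-class].
#' @export
generateCommunity <- function(genome_ids, model = c("uniform", "lognormal"),
                              meanlog = 0, sdlog = 1, seed = NULL) {
  model <- match.arg(model)
  if (length(genome_ids) < 2L) stop("need at least two genomes")
  ab <- switch(model,
    uniform = rep(1, length(genome_ids)),
    lognormal = .withSeed(seed, rlnorm(length(genome_ids), meanlog, sdlog)))
  communityProfile(genome_ids, ab)
}

#' Generate a synthetic donor base-quality FASTQ
#'
#' Writes a small FASTQ whose per-position qualities are Gaussian draws
#' clamped to `[0, 41]`, for use as a [loadQualityProfile()] donor when no
#' real run is at hand.
#'
#' @param path output FASTQ path.
#' @param read_length read length in bp.
#' @param q_mean,q_sd mean and SD of the per-position Phred quality.
#' @param n_reads number of donor records.
#' @param seed optional integer seed.
#' @return `path`, invisibly.
#' @export
generateQualityProfile <- function(path, read_length, q_mean = 35,
                                   q_sd = 3, n_reads = 50L, seed = NULL) {
  .withSeed(seed, {
    q <- matrix(round(rnorm(n_reads * read_length, q_mean, q_sd)),
                nrow = n_reads)
    q[q < 0] <- 0; q[q > 41] <- 41
    quals <- apply(q, 1L, function(row) intToUtf8(row + 33L))
    seqs <- vapply(seq_len(n_reads), function(i)
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = ""), character(1))
    writeLines(as.vector(rbind(paste0("@donor", seq_len(n_reads)),
                               seqs, "+", quals)), path)
  })
  invisible(path)
}
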