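# Shared fixture builders (all inputs generated in code at test time).

ECO <- parseMotif("EcoRI=G/AATTC")
MSE <- parseMotif("MseI=T/TAA")
HHA <- parseMotif("HhaI=GCG/C")
AGE <- parseMotif("AgeI=A/CCGGT")
BCG <- parseMotif("BcgI=CGANNNNNNTGC;iib=12,12")

# DNAStringSet with loadGenomes-style metadata from raw strings
as_genomes <- function(seqs, genome_ids = names(seqs),
                       contig_ids = names(seqs)) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- contig_ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(genome_id = genome_ids,
                                              contig_id = contig_ids)
  x
}

random_genome_string <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_fasta <- function(records, path) {
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}

# a cut-site table in the communityCutSites layout
cut_table <- function(contig_id, positions, genome_id = contig_id,
                      enzyme = "enz") {
  data.frame(genome_id = genome_id, contig_id = contig_id,
             position = positions, enzyme = enzyme, strand = "+",
             stringsAsFactors = FALSE)
}

# a fragment count table row set
count_table <- function(contig_id, start, end, i, read_count,
                        genome_id = contig_id) {
  data.frame(genome_id = genome_id, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             i = as.integer(i), read_count = as.integer(read_count),
             stringsAsFactors = FALSE)
}

# minimal properly-paired SAM text for given fragments; mapq per pair
write_sam <- function(path, contigs, frags) {
  # frags: data.frame(contig, start0, end0, mapq1, mapq2)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  rl <- 50L
  recs <- unlist(lapply(seq_len(nrow(frags)), function(k) {
    f <- frags[k, ]
    pos1 <- f$start0 + 1L
    pos2 <- f$end0 - rl + 1L
    tlen <- f$end0 - f$start0
    qn <- sprintf("pair%d", k)
    seq <- strrep("A", rl); qual <- strrep("I", rl)
    c(paste(qn, 99L, f$contig, pos1, f$mapq1, paste0(rl, "M"), "=",
            pos2, tlen, seq, qual, sep = "\t"),
      paste(qn, 147L, f$contig, pos2, f$mapq2, paste0(rl, "M"), "=",
            pos1, -tlen, seq, qual, sep = "\t"))
  }))
  writeLines(c(hdr, recs), path)
  path
}
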