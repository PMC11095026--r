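# Independent brute-force oracles for motif scanning and fragment
# enumeration. Deliberately share no code with the package: hand-coded
# IUPAC sets, per-offset window tests, all-pairs fragment enumeration.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                 V = "B", H = "D", D = "H", B = "V", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(x, "")[[1]]])), collapse = "")
}

# every 0-based offset where `rec` (IUPAC) matches `seq` (ACGTN; N in the
# genome never matches), overlaps allowed
oracle_match_offsets <- function(seq, rec) {
  w <- nchar(rec)
  L <- nchar(seq)
  if (L < w) return(integer())
  offs <- 0:(L - w)
  keep <- rep(TRUE, length(offs))
  recc <- strsplit(rec, "")[[1]]
  for (k in seq_len(w)) {
    ch <- substring(seq, offs + k, offs + k)
    keep <- keep & ch %in% ORACLE_IUPAC[[recc[k]]]
  }
  offs[keep]
}

# all top-strand cut positions of a standard motif, both strands when
# non-palindromic, deduplicated and sorted
oracle_cut_positions <- function(seq, rec, cut_offset) {
  pos <- oracle_match_offsets(seq, rec) + cut_offset
  rc <- oracle_revcomp(rec)
  if (!identical(rc, rec))
    pos <- c(pos, oracle_match_offsets(seq, rc) + (nchar(rec) - cut_offset))
  sort(unique(pos))
}

# all-pairs fragment enumeration over sorted cut positions
oracle_fragments <- function(pos, cmin, cmax, max_internal, c_eff) {
  pos <- sort(unique(pos))
  out <- list(); n <- 0L
  for (a_idx in seq_along(pos)) {
    for (b_idx in seq_along(pos)) {
      if (b_idx <= a_idx) next
      a <- pos[a_idx]; b <- pos[b_idx]
      len <- b - a
      i <- sum(pos > a & pos < b)
      if (len < cmin || len > cmax || i > max_internal) next
      p <- if (c_eff == 1 && i == 0) 1 else c_eff^2 * (1 - c_eff)^i
      n <- n + 1L
      out[[n]] <- data.frame(start = a, end = b, i = i, p = p)
    }
  }
  if (!n) return(data.frame(start = integer(), end = integer(),
                            i = integer(), p = numeric()))
  df <- do.call(rbind, out)
  df[order(df$start, df$end), ]
}
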