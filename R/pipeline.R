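#' Run the full library simulation
#'
#' End-to-end simulator: digest every genome with the motif panel under the
#' partial-digestion model, pool the expected fragment distributions by
#' community abundance, intersect with the size-selection envelope,
#' allocate the read budget, and (optionally) write provenance-annotated
#' paired-end FASTQ. All randomness (allocation, orientations, quality
#' sampling, substitution errors) derives from one master seed.
#'
#' @param genomes a `DNAStringSet` from [loadGenomes()].
#' @param profile a [CommunityProfile-class].
#' @param motifs list of [EnzymeMotif-class].
#' @param n_reads total read pairs to simulate.
#' @param cut_efficiency per-site cleavage probability in `(0, 1]`.
#' @param size_mean,size_sd Gaussian size-selection envelope (bp).
#' @param anchor envelope anchor length or `"auto"` (see
#'   [gaussianEnvelope()]).
#' @param custom_weights optional custom envelope [lengthDistribution()].
#' @param read_length read length in bp.
#' @param adapters an [adapterSet()].
#' @param quality_profile optional [loadQualityProfile()] result.
#' @param ddrad_strict require different enzymes at the two fragment ends.
#' @param max_internal maximum internal cut sites per candidate fragment.
#' @param length_range digest enumeration window `c(min, max)` bp; default
#'   spans `size_mean - 6 * size_sd` (at least 1) to
#'   `size_mean + 6 * size_sd`, or the support of `custom_weights`.
#' @param rounding read-allocation mode, `"multinomial"` or
#'   `"largest_remainder"`.
#' @param seed master integer seed; fixed seed gives byte-identical output.
#' @param out_dir optional output directory: writes `sim_R1.fastq` /
#'   `sim_R2.fastq`, `fragments.tsv`, `size_selection.tsv` and
#'   `manifest.json`.
#' @return list with `digest`, `combined`, `selection`, `alloc` (fragments
#'   with read counts), `reads` (per-pair provenance), and `paths` /
#'   `manifest` when `out_dir` is given.
#' @export
simulateRms <- function(genomes, profile, motifs, n_reads,
                        cut_efficiency = 0.9, size_mean = 150, size_sd = 50,
                        anchor = "auto", custom_weights = NULL,
                        read_length = 150L, adapters = adapterSet(),
                        quality_profile = NULL, ddrad_strict = FALSE,
                        max_internal = 5L, length_range = NULL,
                        rounding = "multinomial", seed = NULL,
                        out_dir = NULL) {
  if (is.null(length_range)) {
    length_range <- if (is.null(custom_weights))
      c(max(1, floor(size_mean - 6 * size_sd)),
        ceiling(size_mean + 6 * size_sd))
    else range(as.integer(names(custom_weights)))
  }
  params <- digestionParams(cut_efficiency = cut_efficiency,
                            length_min = length_range[1L],
                            length_max = length_range[2L],
                            ddrad_strict = ddrad_strict,
                            max_internal = max_internal)
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    list(seed %% .Machine$integer.max, (seed + 1L) %% .Machine$integer.max)

  digest <- digestGenome(genomes, motifs, params)
  combined <- combineByAbundance(digest, profile)
  selection <- gaussianEnvelope(combined$dist, mean = size_mean,
                                sd = size_sd, anchor = anchor,
                                custom_weights = custom_weights)
  alloc <- allocateReads(combined$fragments, selection, n = n_reads,
                         rounding = rounding, seed = seeds[[1L]])
  out_r1 <- out_r2 <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out_r1 <- file.path(out_dir, "sim_R1.fastq")
    out_r2 <- file.path(out_dir, "sim_R2.fastq")
  }
  reads <- simulateReads(alloc, genomes, read_length = read_length,
                         adapters = adapters,
                         quality_profile = quality_profile,
                         seed = seeds[[2L]], out_r1 = out_r1, out_r2 = out_r2)
  res <- list(digest = digest, combined = combined, selection = selection,
              alloc = alloc, reads = reads)
  if (!is.null(out_dir)) {
    frag_path <- file.path(out_dir, "fragments.tsv")
    utils::write.table(alloc, frag_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sel_path <- file.path(out_dir, "size_selection.tsv")
    utils::write.table(selection, sel_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(
      package = "rmsim",
      version = as.character(utils::packageVersion("rmsim")),
      seed = seed,
      parameters = list(
        n_reads = n_reads, cut_efficiency = cut_efficiency,
        size_mean = size_mean, size_sd = size_sd,
        anchor = attr(selection, "anchor"),
        envelope_mode = attr(selection, "mode"),
        read_length = read_length, ddrad_strict = ddrad_strict,
        max_internal = max_internal, length_range = length_range,
        rounding = rounding,
        motifs = vapply(motifs, function(m) m@name, character(1)),
        genomes = genomeIds(profile), abundances = unname(abundances(profile))),
      outputs = {
        files <- c(out_r1, out_r2, frag_path, sel_path)
        as.list(setNames(tools::md5sum(files), basename(files)))
      })
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$paths <- list(r1 = out_r1, r2 = out_r2, fragments = frag_path,
                      selection = sel_path, manifest = manifest_path)
    res$manifest <- manifest
  }
  res
}

#' Quantify a community from reads: FLTR plus depth baselines
#'
#' Recreates fully digested fragments from reads (provenance FASTQ or
#' paired SAM), tallies them against the expected fragment universe of the
#' references, and estimates relative abundances by fixed length taxonomic
#' ratios alongside mean- and median-depth baselines.
#'
#' @param x reads: provenance FASTQ path, provenance `data.frame`, or SAM
#'   path (see [recreateFragments()]).
#' @param genomes the reference `DNAStringSet`.
#' @param motifs motif panel used for the library.
#' @param taxon_of optional named map genome id -> taxon.
#' @param mode `"provenance"` or `"sam"`.
#' @param length_range expected-fragment enumeration window `c(min, max)`
#'   bp; use the window the library was simulated/selected with.
#' @param max_internal passed to the expected-fragment enumeration.
#' @return list with `counts` (fragment count table), `depth` (taxa x
#'   length matrix), `ratio_matrix` ([RatioMatrix-class]), `fltr`
#'   ([fltrEstimate()] result) and `estimates` (per-taxon `data.frame`:
#'   `taxon`, `fltr_abundance`, `mean_depth_abundance`,
#'   `median_depth_abundance`, `n_fragments`, `quantified`).
#' @export
quantifyRms <- function(x, genomes, motifs, taxon_of = NULL,
                        mode = c("provenance", "sam"),
                        length_range = c(1L, 1000L), max_internal = 5L) {
  mode <- match.arg(mode)
  if (is(motifs, "EnzymeMotif")) motifs <- list(motifs)
  std <- motifs[vapply(motifs, function(m) m@kind, character(1)) == "standard"]
  cut_sites <- communityCutSites(genomes, std)
  counts <- recreateFragments(x, cut_sites, mode = mode)
  params <- digestionParams(cut_efficiency = 1,
                            length_min = length_range[1L],
                            length_max = length_range[2L],
                            max_internal = max_internal)
  expected <- digestGenome(genomes, motifs, params)$fragments
  depth <- depthByLength(counts, expected, taxon_of)
  R <- computeRatioMatrix(depth)
  flt <- fltrEstimate(R)
  base <- baselineEstimates(counts, expected, taxon_of)
  est <- data.frame(taxon = names(flt$abundance),
                    fltr_abundance = unname(flt$abundance),
                    stringsAsFactors = FALSE)
  est <- merge(est, base, by = "taxon", all.x = TRUE, sort = FALSE)
  est$quantified <- !est$taxon %in% flt$unquantified
  list(counts = counts, depth = depth, ratio_matrix = R, fltr = flt,
       estimates = est)
}
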