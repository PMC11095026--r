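#' Combine per-genome digests by community abundance
#'
#' Scales each genome's expected fragment counts by its proportional
#' genome-copy abundance and pools them into one community-wide digest
#' distribution. Each fragment's weight becomes `p * abundance(genome)`.
#'
#' @param digest result of [digestGenome()] run on the community genomes.
#' @param profile a [CommunityProfile-class]; every profiled genome must
#'   have been digested.
#' @return list with `fragments` (fragment `data.frame` plus a `weight`
#'   column; genomes absent from the profile are dropped) and `dist` (the
#'   pooled [lengthDistribution()] `D(x) = sum of weights at length x`).
#' @export
combineByAbundance <- function(digest, profile) {
  stopifnot(is(profile, "CommunityProfile"))
  ab <- abundances(profile)
  missing <- setdiff(names(ab), names(digest$dist))
  if (length(missing))
    stop("profiled genome(s) not digested: ", paste(missing, collapse = ", "))
  frags <- digest$fragments
  frags <- frags[frags$genome_id %in% names(ab), , drop = FALSE]
  frags$weight <- frags$p * ab[frags$genome_id]
  if (nrow(frags)) {
    w <- tapply(frags$weight, frags$length, sum)
    dist <- lengthDistribution(as.integer(names(w)), as.numeric(w))
  } else {
    dist <- lengthDistribution(integer(), numeric())
  }
  rownames(frags) <- NULL
  list(fragments = frags, dist = dist)
}

#' Size-selection envelope over a digest distribution
#'
#' Models gel/bead size selection as the intersection of the community
#' digest distribution `D(x)` with a Gaussian envelope anchored to `D`:
#' the normal density `phi(x; mean, sd)` is scaled by
#' `k = D(anchor) / phi(anchor)` and the selected distribution is the
#' pointwise minimum `S(x) = min(D(x), k * phi(x))`. Taking the minimum
#' keeps selection from inflating lengths that the digest cannot supply,
#' while the anchor (by default `mean - sd`) fixes the envelope's height to
#' the digest. A custom (e.g. empirically observed) weight function can
#' replace the Gaussian: then `S(x) = min(D(x), k * W(x))` with `k`
#' anchored the same way.
#'
#' @param D pooled digest [lengthDistribution()].
#' @param mean,sd Gaussian envelope parameters (bp); defaults 150 and 50.
#' @param anchor integer length at which `S` equals `D`, or `"auto"` for
#'   `round(mean - sd)` (falling back to the nearest supported length with
#'   positive weight).
#' @param custom_weights optional [lengthDistribution()] replacing the
#'   Gaussian envelope shape.
#' @return `data.frame(length, digest_count, envelope, selected)` over the
#'   support of `D`, with attributes `k` (envelope scale) and `anchor`.
#' @examples
#' D <- lengthDistribution(c(100, 150, 200), c(10, 20, 10))
#' gaussianEnvelope(D, mean = 150, sd = 50, anchor = 100)
#' @export
gaussianEnvelope <- function(D, mean = 150, sd = 50, anchor = "auto",
                             custom_weights = NULL) {
  if (!length(D) || sum(D) == 0) stop("empty digest distribution")
  lens <- as.integer(names(D))
  if (is.null(custom_weights)) {
    if (sd <= 0) stop("sd must be positive")
    env_at <- function(x) dnorm(x, mean = mean, sd = sd)
  } else {
    env_at <- function(x) {
      w <- custom_weights[as.character(x)]
      w[is.na(w)] <- 0
      as.numeric(w)
    }
  }
  if (identical(anchor, "auto")) {
    target <- round(mean - sd)
    ok <- lens[D > 0 & env_at(lens) > 0]
    if (!length(ok)) stop("no length with positive digest and envelope weight")
    anchor <- if (target %in% ok) target else ok[which.min(abs(ok - target))]
  }
  anchor <- as.integer(anchor)
  Da <- D[as.character(anchor)]
  if (is.na(Da) || Da <= 0)
    stop("anchor length ", anchor, " has no digest weight")
  ea <- env_at(anchor)
  if (ea <= 0) stop("envelope is zero at the anchor length")
  k <- as.numeric(Da) / ea
  env <- k * env_at(lens)
  sel <- pmin(as.numeric(D), env)
  out <- data.frame(length = lens, digest_count = as.numeric(D),
                    envelope = env, selected = sel)
  attr(out, "k") <- k
  attr(out, "anchor") <- anchor
  attr(out, "mode") <- if (is.null(custom_weights)) "gaussian" else "custom"
  out
}

#' Allocate the read budget across size-selected fragments
#'
#' Distributes the total read-pair budget `n` over the surviving fragments
#' in proportion to each fragment's abundance-scaled survival weight times
#' the envelope acceptance at its length,
#' `q_f = weight_f * S(x_f)/D(x_f) / Z`. Two rounding modes are available:
#' seeded multinomial sampling (the stochastic default) and deterministic
#' largest-remainder rounding of `n * q_f`. Both return counts summing to
#' `n` exactly.
#'
#' @param fragments weighted fragment `data.frame` from
#'   [combineByAbundance()] (columns `length`, `weight`).
#' @param selection envelope `data.frame` from [gaussianEnvelope()].
#' @param n total number of read pairs to allocate.
#' @param rounding `"multinomial"` or `"largest_remainder"`.
#' @param seed optional integer seed for the multinomial draw.
#' @return `fragments` with a `reads` integer column appended.
#' @export
allocateReads <- function(fragments, selection, n,
                          rounding = c("multinomial", "largest_remainder"),
                          seed = NULL) {
  rounding <- match.arg(rounding)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  accept <- selection$selected / selection$digest_count
  accept[!is.finite(accept)] <- 0
  acc <- accept[match(fragments$length, selection$length)]
  acc[is.na(acc)] <- 0
  q <- fragments$weight * acc
  Z <- sum(q)
  if (Z <= 0) stop("no fragment survives size selection")
  q <- q / Z
  if (rounding == "multinomial") {
    counts <- .withSeed(seed, as.integer(rmultinom(1L, size = n, prob = q)))
  } else {
    raw <- n * q
    counts <- floor(raw)
    left <- n - sum(counts)
    if (left > 0) {
      frac <- raw - counts
      bump <- order(frac, decreasing = TRUE)[seq_len(left)]
      counts[bump] <- counts[bump] + 1
    }
    counts <- as.integer(counts)
  }
  fragments$reads <- counts
  fragments
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (restores the caller's .Random.seed); NULL seed uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
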