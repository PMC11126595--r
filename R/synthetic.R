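## Seeded generators for synthetic bipartite networks.
##
## Edges are drawn independently with pair probability
##   p[a, b] = targetDensity * w_a * w_b * blockBoost(a, b) / mean(all weights)
## where the node weights w are 1 (skew = 0) or heavy-tailed log-normal draws
## whose log-scale sd is `skew` (winsorized at 3 sd so the normalized pair
## probabilities stay bounded), and blockBoost multiplies same-block pairs by
## `withinBlockOdds` when planted communities are requested.  The
## normalization makes the expected density exactly `targetDensity`; any pair
## probability that would exceed 1 is a hard configuration error, never a
## silent truncation.

.nodeNames <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic bipartite network
#'
#' Draws a random two-mode network with the given part sizes and expected
#' density.  \code{skew = 0} gives a homogeneous (Erdos-Renyi style) bipartite
#' graph; larger \code{skew} gives heavier-tailed degree weights (a few hubs,
#' many low-degree nodes).  \code{blocks > 0} plants hidden communities: each
#' node of either part is assigned one of \code{blocks} labels and same-block
#' pairs get their edge probability multiplied by \code{withinBlockOdds},
#' which gives neighbourhood-based scores a recoverable signal.  The result is
#' fully determined by \code{seed}.
#'
#' @param nA,nB part sizes.
#' @param targetDensity expected edge density, in (0, 1).
#' @param skew log-scale standard deviation of the log-normal node weights
#'   (0 = homogeneous).
#' @param blocks number of planted communities (0 = none).
#' @param withinBlockOdds edge-probability multiplier inside a block (>= 1).
#' @param seed RNG seed.
#' @return a \code{BipartiteNetwork} whose part-A nodes are named
#'   \code{A...} and part-B nodes \code{B...}.
#' @examples
#' net <- generateBipartite(30, 40, 0.1, seed = 7)
#' networkSummary(net)
#' @export
generateBipartite <- function(nA, nB, targetDensity, skew = 0, blocks = 0L,
                              withinBlockOdds = 1, seed = 1L) {
  nA <- as.integer(nA); nB <- as.integer(nB)
  if (nA < 1L || nB < 1L) stop("part sizes must be >= 1")
  if (!(targetDensity > 0 && targetDensity < 1))
    stop("targetDensity must lie strictly in (0, 1), got ", targetDensity)
  if (skew < 0) stop("skew must be >= 0")
  blocks <- as.integer(blocks)
  if (blocks < 0L) stop("blocks must be >= 0")
  if (withinBlockOdds < 1) stop("withinBlockOdds must be >= 1")
  ra <- .nodeNames("A", nA); cb <- .nodeNames("B", nB)
  .withSeed(seed, {
    drawW <- function(n) {
      if (skew == 0) return(rep(1, n))
      z <- pmin(pmax(stats::rnorm(n), -3), 3)   # winsorize: bounded tails
      exp(skew * z)
    }
    wA <- drawW(nA); wB <- drawW(nB)
    W <- outer(wA, wB)
    if (blocks > 0L) {
      blockA <- sample(rep_len(seq_len(blocks), nA))
      blockB <- sample(rep_len(seq_len(blocks), nB))
      same <- outer(blockA, blockB, `==`)
      W[same] <- W[same] * withinBlockOdds
    }
    p <- targetDensity * W / mean(W)
    if (any(p > 1))
      stop("infeasible configuration: normalized pair probability exceeds 1 ",
           "(max ", format(max(p), digits = 4), ") for targetDensity=",
           targetDensity, ", skew=", skew, ", blocks=", blocks,
           ", withinBlockOdds=", withinBlockOdds)
    hit <- which(matrix(stats::runif(length(p)), nA, nB) < p)
    edges <- if (length(hit))
      data.frame(a = ra[(hit - 1L) %% nA + 1L],
                 b = cb[(hit - 1L) %/% nA + 1L],
                 stringsAsFactors = FALSE)
    else NULL
    BipartiteNetwork(edges, partA = ra, partB = cb)
  })
}

#' Preset emulating the gross statistics of a probiotic-disease network
#'
#' A convenience preset for a network shaped like a scraped probiotic-disease
#' association database: two parts of 640 and 3884 nodes (64 and 388 at the
#' default reduced scale) with expected density 0.08899, and skewed degree
#' weights (skew 0.4) so that low-degree nodes are common on the larger part
#' and a handful of better-connected hubs arise.  The reduced scale keeps the
#' same density so density-based checks transfer.
#'
#' @param seed RNG seed.
#' @param scale \code{"reduced"} (64 x 388, default) or \code{"full"}
#'   (640 x 3884, expected edge count about 221,216).
#' @return a \code{BipartiteNetwork}.
#' @export
probioLike <- function(seed = 1L, scale = c("reduced", "full")) {
  cfg <- probioLikeConfig(scale)
  generateBipartite(cfg$nA, cfg$nB, cfg$targetDensity, skew = cfg$skew,
                    blocks = cfg$blocks, withinBlockOdds = cfg$withinBlockOdds,
                    seed = seed)
}

#' @rdname probioLike
#' @return \code{probioLikeConfig} returns the preset parameter list
#'   (without a seed).
#' @export
probioLikeConfig <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full")
    list(nA = 640L, nB = 3884L, targetDensity = 0.08899, skew = 0.4,
         blocks = 0L, withinBlockOdds = 1)
  else
    list(nA = 64L, nB = 388L, targetDensity = 0.08899, skew = 0.4,
         blocks = 0L, withinBlockOdds = 1)
}

#' Preset with planted block structure for evaluation exercises
#'
#' A small bipartite network with hidden communities (4 blocks, within-block
#' odds 20) on which neighbourhood-based link prediction is meaningfully
#' solvable: held-out within-block edges tend to outrank cross-block
#' non-edges under the common-neighbours score.  This planted structure is a
#' testing device, not a model of any real association database.
#'
#' @param seed RNG seed.
#' @return a \code{BipartiteNetwork}.
#' @export
plantedBlockPreset <- function(seed = 1L) {
  cfg <- plantedBlockConfig()
  generateBipartite(cfg$nA, cfg$nB, cfg$targetDensity, skew = cfg$skew,
                    blocks = cfg$blocks, withinBlockOdds = cfg$withinBlockOdds,
                    seed = seed)
}

#' @rdname plantedBlockPreset
#' @export
plantedBlockConfig <- function() {
  list(nA = 40L, nB = 60L, targetDensity = 0.08899, skew = 0,
       blocks = 4L, withinBlockOdds = 20)
}
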