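## Detection-based sequencing-depth saturation. The reference workflow
## re-assembles reads at each subsampled depth; re-assembly is out of scope
## here, so saturation is reframed as detection-at-breadth on known genomes:
## reads are allocated multinomially to contigs by abundance x length,
## per-bp depth gives Lander-Waterman breadth, and a contig counts as
## detected when breadth >= 0.75. Knee locations and diminishing-returns
## shapes are preserved; absolute assembly yields are not claimed.

#' Default read-pair depth grid
#' @return Numeric vector from 1e4 to 1e8 read pairs.
#' @export
default_depth_grid <- function() c(1e4, 1e5, 1e6, 2e6, 1e7, 2e7, 5e7, 1e8)

#' Subsample-and-detect depth saturation curve
#'
#' Subsamples are nested: reads are drawn incrementally between grid points
#' from one multinomial pool, so the detected set can only grow with depth
#' for a fixed seed.
#'
#' @param community data.frame with one row per contig: `contig_id`,
#'   `abundance` (relative), `length_bp`, `quality`, and logical `annotated`
#'   (has a taxonomic annotation).
#' @param depth_grid Increasing vector of read-pair depths (default
#'   [default_depth_grid()]).
#' @param breadth_min Detection rule (default breadth >= 0.75).
#' @param read_length Read length in bp per read pair end (default 150; a
#'   pair contributes `2 * read_length` bases).
#' @param seed Integer seed.
#' @return data.frame of class `depth_curve`: per depth, `n_vc_detected`,
#'   `yield_per_million` (new detections per additional million read pairs),
#'   `mean_len_kb`, `max_len_kb`, per-quality-tier fractions
#'   (`frac_<tier>`), and `frac_annotated`.
#' @export
subsample_detect <- function(community, depth_grid = default_depth_grid(),
                             breadth_min = 0.75, read_length = 150,
                             seed = 1) {
  stopifnot(all(diff(depth_grid) > 0), all(depth_grid >= 0))
  if (max(depth_grid) > 2^31 - 1) stop("depth exceeds supported pool size")
  set.seed(seed)
  w <- community$abundance * community$length_bp
  p <- w / sum(w)
  counts <- numeric(nrow(community))
  prev_depth <- 0
  rows <- list()
  for (d in depth_grid) {
    inc <- d - prev_depth
    if (inc > 0)
      counts <- counts + as.numeric(rmultinom(1, inc, p))
    prev_depth <- d
    depth_per_bp <- counts * 2 * read_length / community$length_bp
    breadth <- 1 - exp(-depth_per_bp)
    det <- breadth >= breadth_min
    n <- sum(det)
    lens <- community$length_bp[det]
    qual <- factor(community$quality[det], levels = QUALITY_TIERS)
    qf <- if (n) as.numeric(table(qual)) / n else rep(NA_real_, 5)
    rows[[length(rows) + 1L]] <- data.frame(
      depth = d, n_vc_detected = n,
      mean_len_kb = if (n) mean(lens) / 1000 else NA_real_,
      max_len_kb = if (n) max(lens) / 1000 else NA_real_,
      t(setNames(qf, paste0("frac_", QUALITY_TIERS))),
      frac_annotated = if (n) mean(community$annotated[det]) else NA_real_)
  }
  out <- do.call(rbind, rows)
  out$yield_per_million <- c(out$n_vc_detected[1] / (out$depth[1] / 1e6),
                             diff(out$n_vc_detected) / (diff(out$depth) / 1e6))
  class(out) <- c("depth_curve", "data.frame")
  out
}

#' Summarize a depth curve: knee and tier stability
#'
#' The knee is the first depth at which the marginal yield falls below
#' `epsilon` new VCs per million read pairs; a curve whose yield never falls
#' below `epsilon` has no knee (flagged). A flat curve (no new detections
#' after the first grid point) puts the knee at the first point.
#'
#' @param curve A [subsample_detect()] result with at least 3 grid points.
#' @param epsilon Marginal-yield threshold (VCs per million read pairs,
#'   default 1).
#' @return list with `knee_depth` (NA when no knee), `has_knee`,
#'   `tier_fractions_stable` (max change of any tier fraction over the top
#'   half of the grid < 0.05).
#' @export
curve_summary <- function(curve, epsilon = 1) {
  if (nrow(curve) < 3) stop("depth grid too short (< 3 points)")
  below <- which(curve$yield_per_million < epsilon)
  has_knee <- length(below) > 0
  top <- curve[curve$depth >= median(curve$depth), , drop = FALSE]
  tier_cols <- grep("^frac_", names(curve), value = TRUE)
  stable <- all(vapply(tier_cols, function(cn) {
    v <- top[[cn]]
    v <- v[!is.na(v)]
    length(v) < 2 || diff(range(v)) < 0.05
  }, logical(1)))
  list(knee_depth = if (has_knee) curve$depth[below[1]] else NA_real_,
       has_knee = has_knee, tier_fractions_stable = stable)
}

#' Build a depth-saturation community from synthetic ground truth
#'
#' Convenience bridge from [generate_genomes()] output (or any truth label
#' table) to the [subsample_detect()] input, using a log-normal abundance
#' profile.
#'
#' @param truth_labels The `truth$labels` table of [generate_genomes()].
#' @param sdlog Log-normal abundance sd (default 2, a heavy-tailed virome).
#' @param seed Seed for the abundance draw.
#' @return data.frame suitable for [subsample_detect()].
#' @export
depth_community <- function(truth_labels, sdlog = 2, seed = 1) {
  set.seed(seed)
  data.frame(contig_id = truth_labels$vc_id,
             abundance = exp(rnorm(nrow(truth_labels), 0, sdlog)),
             length_bp = truth_labels$length_bp,
             quality = truth_labels$quality,
             annotated = truth_labels$taxonomy_order != "unassigned",
             stringsAsFactors = FALSE)
}
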