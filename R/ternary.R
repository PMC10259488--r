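#' Pseudo-ternary representation of two-bottle choice behavior
#'
#' Side-wise percent drug consumption (`c1` on the left side, `c2` on the
#' right) is folded into its minimum `a` and maximum `b` and mapped to a
#' triangle: the consumption index `x = (a + b) / 2` runs along the base
#' from 0% (active avoidance on both sides) to 100% (active tracking on
#' both sides), and the side-bias index `y = b - a` rises toward the top
#' apex (drinking one physical side only, regardless of content). Before
#' computing distances the side-bias axis is scaled by `side_scale`
#' (default `sqrt(3)/2`) so the three apices — (0, 0), (100, 0) and
#' (50, 100 * side_scale) — form an equilateral triangle and distances are
#' comparable across apices.
#'
#' @param c1,c2 Percent drug consumption on the left and right physical
#'   side (0-100). Vectorised.
#' @param side_scale Vertical scaling of the side-bias axis applied before
#'   distance computation; `sqrt(3)/2` for an equilateral triangle, 1 for
#'   the raw index.
#' @return Data frame: `c1`, `c2`, `a`, `b`, `x` (consumption index), `y`
#'   (side-bias index, unscaled), `d_zero`, `d_full`, `d_side` (Euclidean
#'   distances in the scaled plane to the 0%-consumption, 100%-consumption
#'   and full-side-bias apices). Rows with undefined `c1` or `c2` carry
#'   `NA` throughout.
#' @examples
#' ternary_point(100, 0)  # pure side bias: d_side = 0
#' @export
ternary_point <- function(c1, c2, side_scale = sqrt(3) / 2) {
  ok <- is.finite(c1) & is.finite(c2)
  if (any(c1[ok] < 0 | c1[ok] > 100 | c2[ok] < 0 | c2[ok] > 100))
    stop("side-wise percents must lie in [0, 100]")
  a <- pmin(c1, c2)
  b <- pmax(c1, c2)
  x <- (a + b) / 2
  y <- b - a
  ys <- y * side_scale
  top <- 100 * side_scale
  data.frame(
    c1 = c1, c2 = c2, a = a, b = b, x = x, y = y,
    d_zero = sqrt(x^2 + ys^2),
    d_full = sqrt((x - 100)^2 + ys^2),
    d_side = sqrt((x - 50)^2 + (ys - top)^2))
}

#' Pseudo-ternary points for a table of condition summaries
#'
#' One point per mouse x condition, built from the side-wise percents
#' `pct_c1` / `pct_c2` of [condition_summaries()]. Conditions in which one
#' physical side was never sampled yield a flagged (all-`NA`) point.
#'
#' @param summaries Output of [condition_summaries()].
#' @inheritParams ternary_point
#' @return Data frame: `mouse_id`, `condition_id`, `concentration`, then
#'   the [ternary_point()] columns.
#' @export
ternary_points <- function(summaries, side_scale = sqrt(3) / 2) {
  pt <- ternary_point(summaries$pct_c1, summaries$pct_c2,
                      side_scale = side_scale)
  cbind(summaries[c("mouse_id", "condition_id", "concentration")], pt)
}

#' Per-mouse trajectory through the pseudo-ternary plane
#'
#' Orders one mouse's points by condition (schedule order) and summarises
#' the displacement as the signed change in each apex distance from the
#' first to the last condition. An avoider's trajectory typically shows
#' `d_zero` shrinking toward the 0%-consumption apex as concentration
#' rises.
#'
#' @param points Rows of [ternary_points()] for a single mouse.
#' @param condition_order Optional character vector giving the condition
#'   order; defaults to order of first appearance.
#' @return List of class `ternary_trajectory`: `mouse_id`, `points`
#'   (ordered, flagged rows dropped), `displacement` (named numeric:
#'   `d_zero`, `d_full`, `d_side`, last minus first).
#' @export
trajectory <- function(points, condition_order = NULL) {
  stopifnot(length(unique(points$mouse_id)) == 1L)
  if (is.null(condition_order))
    condition_order <- unique(points$condition_id)
  points <- points[match(condition_order, points$condition_id), ,
                   drop = FALSE]
  points <- points[!is.na(points$d_zero), , drop = FALSE]
  if (nrow(points) < 2L)
    stop("trajectory needs at least 2 conditions with defined points")
  first <- points[1L, ]; last <- points[nrow(points), ]
  structure(list(
    mouse_id = points$mouse_id[1L], points = points,
    displacement = c(d_zero = last$d_zero - first$d_zero,
                     d_full = last$d_full - first$d_full,
                     d_side = last$d_side - first$d_side)),
    class = "ternary_trajectory")
}

#' Group-level apex distances per condition
#'
#' Mean, s.e.m. and n of each apex distance per (group, condition), in
#' long format — the quantity plotted when comparing how far each
#' phenotype group sits from the avoidance, consumption and side-bias
#' apices across the task.
#'
#' @param points Output of [ternary_points()] for a cohort.
#' @param grouping Named character vector mapping `mouse_id` to group
#'   label, or a data frame with columns `mouse_id`, `group`.
#' @return Data frame: `group`, `condition_id`, `concentration`, `apex`
#'   (`zero`, `full`, `side`), `mean`, `sem`, `n`.
#' @export
group_apex_distances <- function(points, grouping) {
  if (is.data.frame(grouping)) {
    g <- grouping$group
    names(g) <- grouping$mouse_id
    grouping <- g
  }
  points$group <- unname(grouping[points$mouse_id])
  points <- points[!is.na(points$group) & !is.na(points$d_zero), ,
                   drop = FALSE]
  long <- do.call(rbind, lapply(c("zero", "full", "side"), function(ap) {
    data.frame(group = points$group, condition_id = points$condition_id,
               concentration = points$concentration, apex = ap,
               d = points[[paste0("d_", ap)]], stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(
    split(long, list(long$group, long$condition_id, long$apex),
          drop = TRUE),
    function(s) data.frame(
      group = s$group[1L], condition_id = s$condition_id[1L],
      concentration = s$concentration[1L], apex = s$apex[1L],
      mean = mean(s$d),
      sem = if (nrow(s) > 1L) stats::sd(s$d) / sqrt(nrow(s)) else 0,
      n = nrow(s), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$group, agg$concentration, agg$apex), ]
}
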