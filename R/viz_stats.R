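#' @include utils.R
NULL

#' Map orientation angles to RGB colours
#'
#' Deterministic HSV mapping for volumetric orientation rendering: hue encodes
#' azimuth (`hue = (theta + 90) / 180`, so the hue circle runs once over the
#' azimuth range), saturation is 1, and value encodes elevation
#' (`value = 0.3 + 0.7 * phi / 90`; the 0.3 floor keeps in-plane fibers
#' visible). Distinct orientations map to distinct colours except at the hue
#' wrap theta = -90 ~ +90, which is the same axis anyway.
#'
#' @param thetaDeg azimuth in (-90, 90\] degrees (vectorized).
#' @param phiDeg elevation in \[0, 90\] degrees (vectorized).
#' @return data.frame with columns `r`, `g`, `b` in \[0, 1\].
#' @examples
#' geo2rgb(0, 90) # cyan
#' @export
geo2rgb <- function(thetaDeg, phiDeg) {
  if (any(thetaDeg <= -90) || any(thetaDeg > 90))
    stop("thetaDeg must be in (-90, 90]")
  if (any(phiDeg < 0) || any(phiDeg > 90))
    stop("phiDeg must be in [0, 90]")
  hue <- (thetaDeg + 90) / 180
  val <- 0.3 + 0.7 * phiDeg / 90
  # standard HSV -> RGB at saturation 1, kept in double precision (the
  # grDevices path quantizes through 8-bit hex strings)
  h6 <- (hue %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  q <- val * (1 - f)
  t <- val * f
  z <- numeric(length(h6))
  r <- ifelse(i == 0 | i == 5, val, ifelse(i == 1, q, ifelse(i == 4, t, z)))
  g <- ifelse(i == 1 | i == 2, val, ifelse(i == 0, t, ifelse(i == 3, q, z)))
  b <- ifelse(i == 3 | i == 4, val, ifelse(i == 2, t, ifelse(i == 5, q, z)))
  data.frame(r = pmin(1, pmax(0, r)), g = pmin(1, pmax(0, g)),
             b = pmin(1, pmax(0, b)))
}

#' Per-voxel RGB overlay for an orientation field
#'
#' @param orientation an [OrientationField-class].
#' @return data.frame `x,y,z,r,g,b` consumable by any volume renderer.
#' @export
colorizeOrientation <- function(orientation) {
  tab <- orientationTable(orientation)
  cbind(tab[, c("x", "y", "z")], geo2rgb(tab$theta_deg, tab$phi_deg))
}

#' Tukey HSD post-hoc comparison of group means
#'
#' All-pairs comparison of group means after one-way ANOVA, using the
#' studentized range distribution (`stats::TukeyHSD`). Typical use: comparing
#' a morphometric characteristic (porosity, diameter, ...) across biomaterial
#' types.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`; at least 2 groups
#'   with at least 2 observations each.
#' @param alpha family-wise significance level.
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `mean_diff` (mean of `group_b` minus mean of `group_a`), `p_adj`,
#'   `reject`.
#' @export
tukeyPosthoc <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(grepl("-", levels(g), fixed = TRUE)))
    stop("group labels must not contain '-'")
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("groups with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = g))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  data.frame(group_a = pairs[, 2], group_b = pairs[, 1],
             mean_diff = tk[, "diff"], p_adj = tk[, "p adj"],
             reject = tk[, "p adj"] < alpha, row.names = NULL)
}
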