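# AFM force-curve processing: baseline flattening, contact-point
# estimation, tip-sample separation, Sneddon conical-indenter fitting,
# adhesion filtering and per-region medians.
#
# Height convention: `height` is the piezo displacement along the
# approach direction, increasing as the tip advances toward and into
# the sample. The non-contact part of a segment therefore sits at the
# smallest heights and the trigger force at the largest.

sneddon_prefactor <- function(E, alpha = 18 * pi / 180, nu = 0.5) {
  E / (1 - nu^2) * 2 * tan(alpha) / pi
}

#' Construct an AFM force curve
#'
#' @param height piezo position along the approach direction (m).
#' @param force measured force (N).
#' @param segment segment label per sample; the canonical 7-segment
#'   cycle is `extend1, retract1, extend2, retract2, extend3, pause,
#'   retract_final` and the final segment must be a retraction.
#' @param spring_constant cantilever spring constant (N/m).
#' @param trigger_force trigger force (N).
#' @param region,sample optional tissue-region and sample labels.
#' @return object of class `force_curve` (a data frame with metadata
#'   attributes).
#' @export
force_curve <- function(height, force, segment, spring_constant = 40,
                        trigger_force = 3e-6, region = NA_character_,
                        sample = NA_character_) {
  stopifnot(length(height) == length(force),
            length(segment) == length(force))
  segment <- as.character(segment)
  last <- segment[length(segment)]
  if (!grepl("retract", last))
    stop("the final segment must be a retraction", call. = FALSE)
  out <- data.frame(height = height, force = force, segment = segment)
  attr(out, "spring_constant") <- spring_constant
  attr(out, "trigger_force") <- trigger_force
  attr(out, "region") <- region
  attr(out, "sample") <- sample
  class(out) <- c("force_curve", class(out))
  out
}

curve_segment <- function(curve, segment) {
  seg <- curve[curve$segment == segment, , drop = FALSE]
  if (nrow(seg) == 0) stop("segment not found: ", segment, call. = FALSE)
  seg
}

last_retraction <- function(curve) {
  segs <- unique(curve$segment)
  ret <- segs[grepl("retract", segs)]
  curve_segment(curve, ret[length(ret)])
}

#' Flatten the baseline of a force-curve segment
#'
#' Fits a line to the non-contact part (the `window` fraction of samples
#' farthest from the surface, i.e. at the smallest heights) and removes
#' it from the whole segment, setting the free-air level to zero force.
#'
#' @param curve a [force_curve()] or a single-segment data frame.
#' @param segment segment to flatten (default: all segments, each with
#'   the same line fitted on the first extend's non-contact part is NOT
#'   done - each segment is flattened with its own fit).
#' @param window non-contact fraction used for the fit.
#' @return the curve with flattened forces (same class and attributes).
#' @export
flatten_baseline <- function(curve, segment = NULL, window = 0.30) {
  segs <- if (is.null(segment)) unique(curve$segment) else segment
  for (sg in segs) {
    sel <- curve$segment == sg
    n <- sum(sel)
    if (n < 10)
      stop("segment too short to flatten: ", sg, call. = FALSE)
    h <- curve$height[sel]; f <- curve$force[sel]
    if (diff(range(h)) < 1e-15) next  # constant-height (pause) segment
    k <- max(5L, floor(window * n))
    idx <- order(h)[seq_len(k)]   # farthest from the surface
    fit <- lm(f[idx] ~ h[idx])
    curve$force[sel] <- f - (coef(fit)[1] + coef(fit)[2] * h)
  }
  curve
}

#' Estimate the point of contact
#'
#' Scans the (flattened) first extend segment from the trigger-force end
#' toward the baseline and returns the height of the first zero crossing
#' of the force, linearly interpolated between samples.
#'
#' @param curve a flattened [force_curve()].
#' @param segment segment to scan (default the first extend segment).
#' @return contact height (m).
#' @export
estimate_poc <- function(curve, segment = NULL) {
  if (is.null(segment)) {
    segs <- unique(curve$segment)
    segment <- segs[grepl("extend", segs)][1]
  }
  seg <- curve_segment(curve, segment)
  o <- order(seg$height, decreasing = TRUE)  # from deepest indentation out
  h <- seg$height[o]; f <- seg$force[o]
  if (max(f) <= 0)
    stop("no-contact: the segment never reaches positive force", call. = FALSE)
  below <- which(f <= 0)
  if (!length(below))
    stop("no-contact: no zero crossing found on the segment", call. = FALSE)
  i <- below[1]
  if (i == 1) return(h[1])
  # interpolate between samples i-1 (f>0) and i (f<=0)
  t <- f[i - 1] / (f[i - 1] - f[i])
  h[i - 1] + t * (h[i] - h[i - 1])
}

#' Convert a segment to the tip-sample separation domain
#'
#' Replaces the height axis by `height - deflection`, with deflection =
#' force / spring constant; on the approach convention used here this
#' compresses the contact branch by the load-sharing factor.
#'
#' @param curve a [force_curve()].
#' @param spring_constant overrides the curve's stored constant.
#' @return the curve with a `separation` column added.
#' @export
tip_sample_distance <- function(curve,
                                spring_constant = attr(curve, "spring_constant")) {
  curve$separation <- curve$height - curve$force / spring_constant
  curve
}

#' Fit the Sneddon conical-indenter model to the last retraction
#'
#' Least squares of `F = E/(1-nu^2) * 2 tan(alpha)/pi * delta^2` on the
#' separation-domain last retraction, with the effective Young's
#' modulus, the point of contact and a force offset free; the
#' indentation `delta` counts only where positive. The contact point is
#' profiled on a grid seeded at the zero-crossing estimate and refined
#' by golden-section search; for fixed contact point the remaining
#' parameters are linear.
#'
#' @param curve a [force_curve()]; flattening and the separation
#'   transform are applied internally if absent.
#' @param alpha tip half angle (radians; default 18 degrees).
#' @param nu sample Poisson ratio used in the contact model (0.5).
#' @param min_points minimum number of contact-side samples.
#' @return object of class `sneddon_fit`: `E` (Pa), `contact` (m),
#'   `offset` (N), `residual` (RMS, N), `adhesion` (N), `region`,
#'   `sample`.
#' @export
fit_sneddon <- function(curve, alpha = 18 * pi / 180, nu = 0.5,
                        min_points = 10) {
  curve <- flatten_baseline(curve)
  curve <- tip_sample_distance(curve)
  seg <- last_retraction(curve)
  x <- seg$separation; f <- seg$force
  adhesion <- abs(min(f))
  pre <- 2 * tan(alpha) / pi / (1 - nu^2)

  # First estimate of the point of contact: the first zero crossing of
  # the flattened force, scanning from the trigger-force end. It fixes
  # the fitting range (the indentation side); the contact point itself
  # then remains a free parameter of the least-squares fit within that
  # range, so the profiled objective carries no incentive to shrink the
  # fitted domain.
  o <- order(x, decreasing = TRUE)
  fz <- f[o]
  cross <- which(fz <= 0)[1]
  x0_seed <- if (is.na(cross) || cross == 1) stats::median(x) else x[o][cross]
  dom <- x >= x0_seed
  if (sum(dom) < min_points)
    stop("insufficient-data: fewer than ", min_points,
         " contact-side samples", call. = FALSE)
  xd <- x[dom]; fd <- f[dom]
  # force noise in these curves is predominantly multiplicative, so the
  # profiled least squares is weighted by the relative-error model (with
  # a floor that keeps near-zero forces from dominating)
  wt <- 1 / pmax(abs(fd), 0.02 * max(fd))^2
  sw <- sqrt(wt)
  big <- sum(wt * fd^2) + 1
  sse <- function(x0) {
    X <- cbind(pmax(xd - x0, 0)^2, 1)
    cf <- tryCatch(qr.coef(qr(X * sw), fd * sw), error = function(e) NULL)
    if (is.null(cf) || !all(is.finite(cf))) return(big)
    sum(wt * (fd - X %*% cf)^2)
  }
  span <- diff(range(x))
  halfwin <- max(0.02 * span, 10 * span / max(length(x) - 1, 1))
  grid <- x0_seed + seq(-halfwin, halfwin, length.out = 81)
  gv <- vapply(grid, sse, numeric(1))
  gbest <- grid[which.min(gv)]
  step <- grid[2] - grid[1]
  grid2 <- gbest + seq(-1.2 * step, 1.2 * step, length.out = 97)
  gv2 <- vapply(grid2, sse, numeric(1))
  gbest2 <- grid2[which.min(gv2)]
  step2 <- grid2[2] - grid2[1]
  opt <- optimize(sse, interval = c(gbest2 - 1.2 * step2, gbest2 + 1.2 * step2),
                  tol = max(span * 1e-10, 1e-16))
  x0 <- if (opt$objective < min(gv2)) opt$minimum else gbest2
  on <- pmax(xd - x0, 0) > 0
  X <- cbind(pmax(xd - x0, 0)^2, 1)
  cf <- qr.coef(qr(X * sw), fd * sw)
  A <- cf[1]
  if (!is.finite(A) || A <= 0)
    stop("non-convergence: fitted contact stiffness is not positive",
         call. = FALSE)
  E <- A / pre
  structure(list(E = unname(E), contact = unname(x0), offset = unname(cf[2]),
                 residual = sqrt(mean((fd - X %*% cf)^2)),
                 n_contact = sum(on), adhesion = adhesion,
                 alpha = alpha, nu = nu,
                 region = attr(curve, "region"),
                 sample = attr(curve, "sample")),
            class = "sneddon_fit")
}

#' @export
print.sneddon_fit <- function(x, ...) {
  cat(sprintf("Sneddon fit: E = %.4g Pa, contact = %.4g m, offset = %.3g N\n",
              x$E, x$contact, x$offset))
  cat(sprintf("  adhesion %.3g N, %d contact-side samples, RMS %.3g N\n",
              x$adhesion, x$n_contact, x$residual))
  invisible(x)
}

#' Filter curves by adhesion force
#'
#' Adhesion is the magnitude of the minimum force on the (flattened)
#' last retraction. Curves with adhesion strictly below the threshold
#' are retained; high-adhesion curves are typically acquired on
#' embedding wax rather than on the sample.
#'
#' @param curves list of [force_curve()] objects.
#' @param threshold adhesion threshold in N (default 160 nN).
#' @return list with `retained` and `rejected` curve lists and
#'   `adhesion`, the per-curve values (N).
#' @export
adhesion_filter <- function(curves, threshold = 160e-9) {
  adh <- vapply(curves, function(cv) {
    cv <- flatten_baseline(cv)
    abs(min(last_retraction(cv)$force))
  }, numeric(1))
  keep <- adh < threshold
  list(retained = curves[keep], rejected = curves[!keep], adhesion = adh)
}

#' Median effective Young's modulus per region (and sample)
#'
#' @param fits list of `sneddon_fit` objects.
#' @return data frame `sample`, `region`, `median_E`, `n`; regions with
#'   no valid fit are absent (missing, not zero).
#' @export
region_median_modulus <- function(fits) {
  df <- data.frame(
    sample = vapply(fits, function(f) as.character(f$sample), character(1)),
    region = vapply(fits, function(f) as.character(f$region), character(1)),
    E = vapply(fits, `[[`, numeric(1), "E"))
  agg <- aggregate(E ~ sample + region, data = df, FUN = median)
  n <- aggregate(E ~ sample + region, data = df, FUN = length)
  names(agg)[3] <- "median_E"
  agg$n <- n$E
  agg
}
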