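#' Voxel classification of a test mask against a reference mask
#'
#' Counts true positives (voxels segmented in both), false positives
#' (segmented on the test but not the reference) and false negatives
#' (segmented on the reference but not the test), plus the same quantities
#' as fractions of the reference mask size.  By construction
#' `TP + FN = |reference|` and `TP + FP = |test|`.
#'
#' @param test,ref same-shape [binary_mask()]s or logical arrays.
#' @return An object of class `classification_counts` with fields `tp`,
#'   `fp`, `fn`, `tp_frac`, `fp_frac`, `fn_frac`, `n_ref`.
#' @export
classify_voxels <- function(test, ref) {
  a <- mask_values(test)
  b <- mask_values(ref)
  if (!identical(dim(a), dim(b)))
    stop("test and reference masks must have the same shape", call. = FALSE)
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  n_ref <- sum(b)
  structure(list(tp = tp, fp = fp, fn = fn, n_ref = n_ref,
                 tp_frac = tp / n_ref, fp_frac = fp / n_ref,
                 fn_frac = fn / n_ref),
            class = "classification_counts")
}

#' @export
print.classification_counts <- function(x, ...) {
  cat(sprintf("<classification> TP %d (%.3f), FP %d (%.3f), FN %d (%.3f) of %d reference voxels\n",
              x$tp, x$tp_frac, x$fp, x$fp_frac, x$fn, x$fn_frac, x$n_ref))
  invisible(x)
}

#' Match centerline control points to a reference centerline
#'
#' For every control point of `cl`, finds the closest reference control
#' point in the Euclidean (L2) sense; ties are broken toward the lower
#' reference index.  The matching is point-to-point.
#'
#' @param cl,ref [centerline()] objects.
#' @return A data frame with columns `index`, `ref_index`, `distance` (mm).
#' @export
match_points <- function(cl, ref) {
  stopifnot(inherits(cl, "centerline"), inherits(ref, "centerline"))
  p <- cl$points; q <- ref$points
  d2 <- outer(rowSums(p^2), rowSums(q^2), `+`) - 2 * p %*% t(q)
  j <- apply(d2, 1, which.min)
  data.frame(index = seq_len(nrow(p)), ref_index = j,
             distance = sqrt(pmax(d2[cbind(seq_len(nrow(p)), j)], 0)))
}

#' Mean relative diameter error between two centerlines
#'
#' Each control point of `cl` is matched to its closest reference point
#' ([match_points()]); the relative diameter error `|d - d_ref| / d_ref` is
#' averaged over all pairs and reported in percent.  A mean error of 13.7%
#' against a 1.2 mm reference lumen corresponds to a 164 um mean absolute
#' diameter difference (see [diameter_difference_um()]).
#'
#' @param cl,ref [centerline()] objects carrying per-point diameters.
#' @return Mean relative error in percent.
#' @export
relative_diameter_error <- function(cl, ref) {
  m <- match_points(cl, ref)
  dref <- ref$diameters[m$ref_index]
  if (any(dref <= 0)) stop("reference diameters must be positive", call. = FALSE)
  mean(abs(cl$diameters - dref) / dref) * 100
}

#' Mean Euclidean distance between matched centerlines
#'
#' The average distance between each control point of `cl` and its closest
#' point on the reference centerline.
#'
#' @param cl,ref [centerline()] objects.
#' @return Mean distance in mm.
#' @export
centerline_distance <- function(cl, ref) {
  mean(match_points(cl, ref)$distance)
}

#' Worked diameter-difference arithmetic
#'
#' Converts a mean relative diameter error (percent) at a given reference
#' diameter into the implied mean absolute diameter difference in
#' micrometres: `error/100 * d_ref * 1000`.
#'
#' @param rel_error_pct relative diameter error in percent.
#' @param ref_diameter_mm reference diameter in mm (default 1.2, the mean
#'   aortic diameter of the reference segmentations).
#' @return Diameter difference in micrometres.
#' @examples
#' diameter_difference_um(13.66)  # ~164 um
#' @export
diameter_difference_um <- function(rel_error_pct, ref_diameter_mm = 1.2) {
  rel_error_pct / 100 * ref_diameter_mm * 1000
}

#' Significance test between per-subject error sets
#'
#' Two-tailed Student's t-test comparing the per-subject errors of a
#' condition against those of the reference condition, paired across
#' subjects by default (each subject contributes one value per condition).
#' Raw p-values are compared against the 0.05 level; no multiple-testing
#' correction is applied.
#'
#' @param errors_condition,errors_reference numeric vectors of per-subject
#'   values (at least 2 each; equal length when `paired`).
#' @param paired logical; paired test by default.
#' @param alpha significance level reported alongside the p-value.
#' @return An object of class `condition_test` with fields `p_value`,
#'   `significant`, `estimate` (mean difference / mean of differences),
#'   `method`.
#' @export
compare_conditions <- function(errors_condition, errors_reference,
                               paired = TRUE, alpha = 0.05) {
  x <- as.numeric(errors_condition)
  y <- as.numeric(errors_reference)
  if (length(x) < 2 || length(y) < 2)
    stop("at least 2 subjects per condition are required", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired comparison needs equal-length samples", call. = FALSE)
  if (paired && all(x - y == 0)) {
    warning("all paired differences are zero; p-value set to 1")
    out <- list(p_value = 1, significant = FALSE, estimate = 0,
                method = "Paired t-test (degenerate: zero differences)",
                alpha = alpha)
    class(out) <- "condition_test"
    return(out)
  }
  tt <- stats::t.test(x, y, paired = paired, alternative = "two.sided")
  out <- list(p_value = tt$p.value,
              significant = tt$p.value < alpha,
              estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
              method = tt$method, alpha = alpha)
  class(out) <- "condition_test"
  out
}

#' @export
print.condition_test <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%ssignificant at %.2g), mean difference %.4g\n",
              x$method, x$p_value, if (x$significant) "" else "not ",
              x$alpha, x$estimate))
  invisible(x)
}
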