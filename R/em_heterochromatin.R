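# Heterochromatin quantification in electron-microscopy nucleus images:
# range-relative threshold binarization of the nucleus (minus the nucleolus)
# and the dark-area percentage.

#' Construct a nucleus image
#'
#' @param pixels numeric matrix of grayscale intensities in `[0, 1]`.
#' @param nucleus_mask logical matrix, same shape, marking the nucleus.
#' @param nucleolus_mask logical matrix marking the nucleolus; must be a
#'   subset of the nucleus mask (defaults to all-FALSE).
#' @return a list of class `nucleus_image`.
#' @export
nucleus_image <- function(pixels, nucleus_mask,
                          nucleolus_mask = array(FALSE, dim(pixels))) {
  pixels <- as.matrix(pixels)
  if (!identical(dim(pixels), dim(nucleus_mask)) ||
      !identical(dim(pixels), dim(nucleolus_mask)))
    stop_cellsig("masks must have the same shape as the image")
  if (any(pixels < 0 | pixels > 1)) stop_cellsig("intensities must lie in [0, 1]")
  if (any(nucleolus_mask & !nucleus_mask))
    stop_cellsig("nucleolus mask must lie inside the nucleus mask")
  structure(list(pixels = pixels, nucleus_mask = nucleus_mask,
                 nucleolus_mask = nucleolus_mask),
            class = "nucleus_image")
}

#' Quantify the heterochromatin fraction of one nucleus
#'
#' The evaluation region is the nucleus minus the nucleolus. In `"range"`
#' mode (the default, FIJI-style percentage threshold) a pixel is
#' heterochromatin when its intensity is at most
#' `min + threshold_frac * (max - min)`, with `min`/`max` taken over the
#' evaluation region; a flat region (`max == min`) yields 0%. In
#' `"quantile"` mode the darkest `threshold_frac` of evaluation pixels are
#' counted instead.
#'
#' @param img a `nucleus_image`.
#' @param threshold_frac threshold as a fraction of the dynamic range (or the
#'   pixel quantile), default 0.15.
#' @param mode `"range"` (default) or `"quantile"`.
#' @return a list of class `het_result`: `het_area`, `eval_area`, `pct`.
#' @export
quantify_heterochromatin <- function(img, threshold_frac = 0.15,
                                     mode = c("range", "quantile")) {
  mode <- match.arg(mode)
  eval_mask <- img$nucleus_mask & !img$nucleolus_mask
  eval_area <- sum(eval_mask)
  if (eval_area == 0L) stop_cellsig("empty evaluation region")
  v <- img$pixels[eval_mask]
  het <- switch(mode,
    range = {
      lo <- min(v); hi <- max(v)
      if (hi == lo) 0L else sum(v <= lo + threshold_frac * (hi - lo))
    },
    quantile = {
      thr <- stats::quantile(v, threshold_frac, names = FALSE, type = 1)
      min(sum(v <= thr), ceiling(threshold_frac * eval_area))
    })
  structure(list(het_area = as.integer(het), eval_area = as.integer(eval_area),
                 pct = 100 * het / eval_area),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("heterochromatin: %d / %d evaluation pixels = %.1f%%\n",
              x$het_area, x$eval_area, x$pct))
  invisible(x)
}

#' Quantify a batch of nucleus images, with an optional group comparison
#'
#' @param images non-empty list of `nucleus_image` objects.
#' @param groups optional vector of group labels, one per image; with exactly
#'   two groups a two-sided Welch t-test on the percentages is reported.
#' @param threshold_frac,mode passed to [quantify_heterochromatin()].
#' @return a list of class `het_batch`: `per_image` (data.frame `group`,
#'   `het_area`, `eval_area`, `pct`), `summary` (per-group mean, sd, n), and
#'   `welch` (the `htest`, or NULL).
#' @export
batch_quantify <- function(images, groups = NULL, threshold_frac = 0.15,
                           mode = "range") {
  if (length(images) == 0L) stop_cellsig("no images supplied")
  res <- lapply(images, quantify_heterochromatin,
                threshold_frac = threshold_frac, mode = mode)
  groups <- groups %||% rep("all", length(images))
  per <- data.frame(group = as.character(groups),
                    het_area = vapply(res, `[[`, integer(1), "het_area"),
                    eval_area = vapply(res, `[[`, integer(1), "eval_area"),
                    pct = vapply(res, `[[`, numeric(1), "pct"),
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per$pct, per$group), function(p)
    data.frame(mean_pct = mean(p), sd_pct = stats::sd(p), n = length(p))))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  welch <- NULL
  if (length(unique(per$group)) == 2L) {
    sp <- split(per$pct, per$group)
    if (all(vapply(sp, length, integer(1)) >= 2L) &&
        any(vapply(sp, stats::sd, numeric(1)) > 0))
      welch <- stats::t.test(sp[[1]], sp[[2]])
  }
  structure(list(per_image = per, summary = summ, welch = welch),
            class = "het_batch")
}

#' @export
print.het_batch <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$welch))
    cat(sprintf("Welch t-test between groups: t = %.2f, p = %.3g\n",
                x$welch$statistic, x$welch$p.value))
  invisible(x)
}

#' Read a grayscale nucleus image and its masks from PNG files
#'
#' Mask PNGs are binarized at 0.5. Multi-channel images are averaged to one
#' grayscale channel.
#'
#' @param image_path grayscale PNG.
#' @param nucleus_path PNG mask of the nucleus.
#' @param nucleolus_path optional PNG mask of the nucleolus.
#' @return a `nucleus_image`.
#' @export
read_nucleus_png <- function(image_path, nucleus_path, nucleolus_path = NULL) {
  gray <- function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    a
  }
  px <- gray(image_path)
  nuc <- gray(nucleus_path) > 0.5
  nol <- if (is.null(nucleolus_path)) array(FALSE, dim(px))
         else gray(nucleolus_path) > 0.5
  nucleus_image(px, nuc, nol & nuc)
}
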