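#' Run the full morphometry pipeline over one or many images
#'
#' For each input image: grayscale conversion, optional crop, fixed-value
#' thresholding, a contrast check, Union--Find labeling, selection of the
#' largest region, contour tracing, geometry and descriptor computation, and
#' optional SI calibration. Images failing the contrast check (no foreground,
#' or implausibly much — typically transparent items or a wrong polarity)
#' are skipped and listed in the skip report rather than aborting the run;
#' unreadable files likewise. The run fails only if no image yields a row.
#'
#' @param inputs character vector of image paths, a directory containing
#'   images, or a (preferably named) list of in-memory grayscale/RGB arrays.
#' @param threshold intensity threshold (see [threshold_spec()]).
#' @param polarity `"dark"` or `"light"`.
#' @param crop optional `c(top, left, height, width)` window (0-based).
#' @param calibration optional [calibration_spec()] (or mm-per-pixel scalar)
#'   for SI output.
#' @param max_foreground contrast-check ceiling (see [contrast_report()]).
#' @param pixel_extent see [describe_region()].
#' @param out_dir optional directory; when given, `descriptors.csv` and
#'   `skipped.csv` are written there.
#' @param verbose print per-image progress to stderr.
#' @return list with `results` (descriptor data.frame, one row per measured
#'   image, first columns `image_id`, `threshold`, `polarity`) and `skipped`
#'   (data.frame `image_id`, `reason`).
#' @export
run_pipeline <- function(inputs, threshold = 127, polarity = "dark",
                         crop = NULL, calibration = NULL,
                         max_foreground = 0.5, pixel_extent = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  spec <- threshold_spec(threshold, polarity)

  if (is.character(inputs) && length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(png|jpe?g|pgm|ppm)$",
                         ignore.case = TRUE, full.names = TRUE)
  if (length(inputs) == 0L) stop("no inputs")
  ids <- if (is.list(inputs)) {
    if (!is.null(names(inputs))) names(inputs)
    else sprintf("image_%03d", seq_along(inputs))
  } else basename(inputs)

  rows <- list()
  skipped <- list()
  note <- function(id, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(image_id = id, reason = reason)
    if (verbose) message(sprintf("[skip] %s: %s", id, reason))
  }

  for (i in seq_along(inputs)) {
    id <- ids[i]
    img <- tryCatch(
      if (is.list(inputs)) inputs[[i]] else read_image(inputs[[i]]),
      error = function(e) e)
    if (inherits(img, "error")) { note(id, conditionMessage(img)); next }
    rec <- tryCatch({
      g <- to_grayscale(img)
      if (!is.null(crop)) g <- crop_image(g, crop[1], crop[2], crop[3], crop[4])
      rep_ <- contrast_report(g, spec, max_foreground)
      if (rep_$flag) stop(rep_$reason)
      mask <- threshold_mask(g, spec)
      measure_mask(mask, pixel_extent = pixel_extent)
    }, error = function(e) e)
    if (inherits(rec, "error")) { note(id, conditionMessage(rec)); next }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(image_id = id, threshold = spec$th, polarity = spec$polarity),
      rec)
    if (verbose) message(sprintf("[ok]   %s: F = %d px", id, rec$F))
  }

  if (length(rows) == 0L)
    stop("no image produced a measurable region (",
         length(skipped), " skipped)")
  results <- do.call(rbind, rows)
  if (!is.null(calibration)) {
    s <- if (inherits(calibration, "mp_calibration")) resolve_scale(calibration)
         else calibration
    results <- to_si(results, s)
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(image_id = character(0), reason = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_descriptor_csv(results, file.path(out_dir, "descriptors.csv"))
    utils::write.csv(skipped, file.path(out_dir, "skipped.csv"), row.names = FALSE)
  }
  list(results = results, skipped = skipped)
}

# comma-separated, UTF-8, '.' decimal, 6 significant digits on floats
write_descriptor_csv <- function(df, path) {
  out <- df
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive statistics of a descriptor table
#'
#' Mean / Min / Max / S.D. per numeric descriptor column, optionally grouped
#' by a tag column (e.g. a user-assigned shape class). The standard
#' deviation is the sample SD (n - 1 denominator).
#'
#' @param df descriptor data.frame (e.g. `run_pipeline(...)$results`).
#' @param by optional name of a grouping column in `df`.
#' @return data.frame with columns `group` (if `by` given), `descriptor`,
#'   `n`, `mean`, `min`, `max`, `sd`.
#' @export
summarize_descriptors <- function(df, by = NULL) {
  if (nrow(df) == 0L) stop("empty table")
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  one <- function(sub, label) {
    st <- do.call(rbind, lapply(num, function(cl) {
      x <- sub[[cl]][is.finite(sub[[cl]])]
      data.frame(descriptor = cl, n = length(x),
                 mean = mean(x), min = min(x), max = max(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0)
    }))
    if (!is.null(label)) cbind(data.frame(group = label), st) else st
  }
  if (is.null(by)) return(one(df, NULL))
  if (!by %in% names(df)) stop("grouping column not found: ", by)
  do.call(rbind, lapply(split(df, df[[by]]), function(sub)
    one(sub, sub[[by]][1])))
}
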