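#' Rating categories and their numeric values
#'
#' The four-level visual QC scale: `good` (1), `minor_error` (2; a
#' boundary misestimation restricted to one or two regions),
#' `visible_motion` (3; ringing/rippling artifact or blurring anywhere
#' in the image), `bad` (4; very poor surface reconstruction with
#' multiple errors or missing cortex). `bad` outranks `visible_motion`
#' because localized motion need not render an image unusable.
#'
#' @param label Character vector of category labels.
#' @return Integer vector of numeric ratings in 1..4.
#' @export
category_to_numeric <- function(label) {
  bad <- setdiff(unique(label), names(RATING_CATEGORIES))
  if (length(bad))
    stop("unknown rating category: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  unname(RATING_CATEGORIES[label])
}

#' Per-rater participant score
#'
#' Converts categorical ratings to their numeric values and averages
#' over images, yielding a continuous score in `[1, 4]` (1 = best,
#' 4 = worst). Equal weight per image.
#'
#' @param categories Character vector of that rater's ratings for one
#'   participant's images.
#' @return List with `score` (mean, in `[1, 4]`) and `n_images`.
#' @export
score_participant <- function(categories) {
  if (!length(categories))
    stop("no ratings supplied for participant", call. = FALSE)
  vals <- category_to_numeric(categories)
  list(score = mean(vals), n_images = length(vals))
}

#' Combine per-rater mean scores into one participant score
#'
#' Unweighted arithmetic mean over raters; a single rater's score
#' passes through unchanged.
#'
#' @param rater_scores Numeric vector of per-rater means.
#' @return Combined score in `[1, 4]`.
#' @export
combine_raters <- function(rater_scores) {
  stopifnot(length(rater_scores) >= 1L)
  mean(rater_scores)
}

#' Score all participants from ratings and a manifest
#'
#' Joins ratings to the manifest through `image_hash` to recover the
#' subject each image belongs to, averages numeric ratings over images
#' within rater, then averages per-rater means per participant.
#'
#' @param ratings One ratings table or a list of them (one per rater,
#'   or one pooled table).
#' @param manifest A `snapshot_manifest` from [anonymize_and_shuffle()].
#' @return List: `scores` (data.frame subject_id, fsqc, n_raters,
#'   n_images) and `per_rater` (data.frame subject_id, rater_id, score,
#'   n_images).
#' @export
score_participants <- function(ratings, manifest) {
  if (is.data.frame(ratings)) ratings <- list(ratings)
  all_r <- do.call(rbind, lapply(ratings, function(r)
    as.data.frame(ratings_table(as.data.frame(r)))))
  subj <- manifest$subject_id[match(all_r$image_hash,
                                    manifest$image_hash)]
  if (anyNA(subj))
    stop(sum(is.na(subj)), " rating(s) reference images absent from ",
         "the manifest", call. = FALSE)
  all_r$subject_id <- subj
  all_r$value <- category_to_numeric(all_r$category)
  per <- stats::aggregate(value ~ subject_id + rater_id, data = all_r,
                          FUN = mean)
  names(per)[names(per) == "value"] <- "score"
  ni <- stats::aggregate(value ~ subject_id + rater_id, data = all_r,
                         FUN = length)
  per$n_images <- ni$value[match(paste(per$subject_id, per$rater_id),
                                 paste(ni$subject_id, ni$rater_id))]
  comb <- stats::aggregate(score ~ subject_id, data = per, FUN = mean)
  names(comb)[names(comb) == "score"] <- "fsqc"
  nr <- stats::aggregate(rater_id ~ subject_id, data = per, FUN = length)
  comb$n_raters <- nr$rater_id[match(comb$subject_id, nr$subject_id)]
  nim <- stats::aggregate(n_images ~ subject_id, data = per, FUN = max)
  comb$n_images <- nim$n_images[match(comb$subject_id, nim$subject_id)]
  list(scores = comb, per_rater = per)
}

#' Per-image rating export for single-image exclusion criteria
#'
#' Returns the worst (maximum) numeric rating any rater gave each
#' image, so users can exclude participants on individual image
#' ratings rather than the averaged score.
#'
#' @inheritParams score_participants
#' @export
per_image_ratings <- function(ratings, manifest) {
  if (is.data.frame(ratings)) ratings <- list(ratings)
  all_r <- do.call(rbind, lapply(ratings, as.data.frame))
  all_r$value <- category_to_numeric(all_r$category)
  worst <- stats::aggregate(value ~ image_hash, data = all_r, FUN = max)
  worst$subject_id <- manifest$subject_id[match(worst$image_hash,
                                                manifest$image_hash)]
  worst$filename <- deanonymize(manifest, worst$image_hash)
  names(worst)[names(worst) == "value"] <- "worst_rating"
  worst
}

#' Summarize per-image deliberation times
#'
#' Per rater, times more than `outlier_mad` median absolute deviations
#' from that rater's median (over all of that rater's image times) are
#' removed first — these capture breaks or distraction, not
#' deliberation. When the MAD is zero (at least half the times
#' identical) the filter falls back to removing only times exceeding
#' `outlier_mad` times the median, preserving its intent without
#' dividing by zero. The median is then taken over images within
#' participant, and finally over participants within rater.
#'
#' @param ratings A ratings table (needs `deliberation_ms`).
#' @param manifest A `snapshot_manifest` mapping image hashes to
#'   subjects.
#' @param outlier_mad Outlier cut in MAD units (default 5).
#' @return List: `per_rater` (data.frame rater_id, median_s, n_removed,
#'   n_kept), `across` (median, min, max of the per-rater medians in
#'   seconds).
#' @export
deliberation_summary <- function(ratings, manifest, outlier_mad = 5) {
  r <- as.data.frame(ratings)
  r$subject_id <- manifest$subject_id[match(r$image_hash,
                                            manifest$image_hash)]
  out <- lapply(split(r, r$rater_id), function(rr) {
    t_s <- rr$deliberation_ms / 1000
    med <- stats::median(t_s)
    md <- mad_value(t_s)
    keep <- if (md > 0) abs(t_s - med) <= outlier_mad * md
            else t_s <= outlier_mad * med
    if (!any(keep))
      stop("all deliberation times removed as outliers for rater ",
           rr$rater_id[1], call. = FALSE)
    kept <- rr[keep, , drop = FALSE]
    per_part <- tapply(kept$deliberation_ms / 1000, kept$subject_id,
                       stats::median)
    data.frame(rater_id = rr$rater_id[1],
               median_s = stats::median(per_part),
               n_removed = sum(!keep), n_kept = sum(keep),
               stringsAsFactors = FALSE)
  })
  per_rater <- do.call(rbind, out)
  rownames(per_rater) <- NULL
  list(per_rater = per_rater,
       across = list(median = stats::median(per_rater$median_s),
                     min = min(per_rater$median_s),
                     max = max(per_rater$median_s)))
}

#' Run a local interactive rating session
#'
#' Presents the anonymized images in shuffle order and records one
#' categorical rating and the wall-clock deliberation time per image.
#' Keys: `1`/`g` good, `2`/`m` minor error, `3`/`v` visible motion,
#' `4`/`b` bad, `q` quit (the session is resumable: already-rated
#' images are skipped when `resume = TRUE`). A re-rating of a completed
#' image overwrites the earlier row. Missing image files are skipped
#' and logged. Deliberation is timed per final decision.
#'
#' @param manifest A `snapshot_manifest`.
#' @param rater_id Rater identifier recorded in the output.
#' @param images_dir Directory holding `<hash>.png` files.
#' @param out_csv Ratings CSV, appended to across resumed sessions.
#' @param resume Skip images already rated in `out_csv`.
#' @param input_fun Function prompting for one keystroke (injectable
#'   for scripted sessions); default reads from stdin.
#' @param display_fun Function shown each image path; default prints it.
#' @param clock Time source (seconds), injectable for tests.
#' @return The session's ratings table (all rows in `out_csv`).
#' @export
run_rating_session <- function(manifest, rater_id, images_dir, out_csv,
                               resume = TRUE,
                               input_fun = function(prompt) readline(prompt),
                               display_fun = function(path)
                                 cat("view:", path, "\n"),
                               clock = function() as.numeric(Sys.time())) {
  keymap <- c(`1` = "good", g = "good", `2` = "minor_error",
              m = "minor_error", `3` = "visible_motion",
              v = "visible_motion", `4` = "bad", b = "bad")
  existing <- if (file.exists(out_csv)) read_ratings(out_csv) else NULL
  done <- if (!is.null(existing))
    existing$image_hash[existing$rater_id == rater_id] else character()
  ord <- order(manifest$shuffle_position)
  new_rows <- list()
  for (i in ord) {
    h <- manifest$image_hash[i]
    if (resume && h %in% done) next
    img <- file.path(images_dir, paste0(h, ".png"))
    if (!file.exists(img)) {
      message("missing image, skipped: ", img)
      next
    }
    display_fun(img)
    t0 <- clock()
    repeat {
      key <- tolower(trimws(input_fun("rating [1-4/g/m/v/b, q=quit]: ")))
      if (identical(key, "q")) break
      if (key %in% names(keymap)) break
      message("unrecognized key: ", key)
    }
    if (identical(key, "q")) break
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      image_hash = h, rater_id = rater_id,
      category = unname(keymap[key]),
      deliberation_ms = round((clock() - t0) * 1000),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      stringsAsFactors = FALSE)
  }
  new_df <- if (length(new_rows)) do.call(rbind, new_rows) else NULL
  all_df <- if (is.null(existing)) new_df
            else rbind(as.data.frame(existing), new_df)
  if (is.null(all_df)) stop("no ratings recorded", call. = FALSE)
  # latest rating wins on duplicates
  key <- paste(all_df$image_hash, all_df$rater_id)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) message(sum(dup), " earlier rating(s) overwritten")
  all_df <- all_df[!dup, , drop = FALSE]
  tab <- ratings_table(all_df)
  write_ratings(tab, out_csv)
  tab
}
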