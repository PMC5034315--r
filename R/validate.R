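#' Match detected sleep episodes against ground truth
#'
#' Greedy one-to-one matching of detected episodes to ground-truth
#' episodes of the same fly by frame overlap: a pair matches when the
#' number of shared frames is at least `min_overlap` of the longer
#' episode's frame span. Used to validate the sleep pipeline on
#' synthetic stacks.
#'
#' @param detected Tibble from [sleep_episodes()].
#' @param truth Tibble of ground-truth episodes (`fly_id`,
#'   `start_frame`, `end_frame`), e.g. bound from `fly_truth$episodes`.
#' @param min_overlap Required overlap fraction.
#' @return List: `sensitivity` (matched truth / truth), `precision`
#'   (matched detected / detected), `n_truth`, `n_detected`,
#'   `n_matched`.
#' @export
match_sleep_episodes <- function(detected, truth, min_overlap = 0.5) {
  match_fly <- function(det, tru) {
    if (!nrow(det) || !nrow(tru)) return(0L)
    used <- logical(nrow(tru))
    matched <- 0L
    for (i in seq_len(nrow(det))) {
      ov <- vapply(seq_len(nrow(tru)), function(j) {
        if (used[j]) return(0)
        shared <- min(det$end_frame[i], tru$end_frame[j]) -
          max(det$start_frame[i], tru$start_frame[j]) + 1
        span <- max(det$end_frame[i] - det$start_frame[i],
                    tru$end_frame[j] - tru$start_frame[j]) + 1
        max(shared, 0) / span
      }, numeric(1))
      j <- which.max(ov)
      if (length(j) && ov[j] >= min_overlap) {
        used[j] <- TRUE
        matched <- matched + 1L
      }
    }
    matched
  }
  flies <- union(unique(detected$fly_id), unique(truth$fly_id))
  n_matched <- sum(vapply(flies, function(id)
    match_fly(detected[detected$fly_id == id, ], truth[truth$fly_id == id, ]),
    integer(1)))
  list(sensitivity = if (nrow(truth)) n_matched / nrow(truth) else NA_real_,
       precision = if (nrow(detected)) n_matched / nrow(detected) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected),
       n_matched = n_matched)
}

#' Collect ground-truth episodes of a synthetic stack
#'
#' @param stack A synthetic `frame_stack` (or a list of `fly_truth`).
#' @return Tibble: `fly_id`, `start_frame`, `end_frame`, `duration_s`.
#' @export
truth_episodes <- function(stack) {
  flies <- if (inherits(stack, "frame_stack")) stack$truth$flies else stack
  dplyr::bind_rows(lapply(flies, function(tr)
    dplyr::mutate(tr$episodes, fly_id = tr$fly_id, .before = 1)))
}
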