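#' Avoidance index from quadrant counts
#'
#' `(n_csminus - n_csplus) / (n_csminus + n_csplus)`: 1 means every fly
#' chose a CS- quadrant, 0 means the two odors were chosen equally, -1 means
#' every fly chose CS+. Flies that could not be assigned to a quadrant class
#' (e.g. on a border) are simply absent from both counts, so the total is
#' the number of classified flies.
#'
#' @param counts Either a data frame with columns `n_csplus`, `n_csminus`
#'   (one row) or a named numeric vector with those elements.
#' @return Scalar index in `[-1, 1]`.
#' @export
avoidance_index <- function(counts) {
  cc <- as.list(counts)
  np <- as.numeric(cc$n_csplus); nm <- as.numeric(cc$n_csminus)
  if (is.na(np) || is.na(nm) || np < 0 || nm < 0) stop("counts must be non-negative")
  if (np + nm == 0) stop("undefined index: zero total flies")
  (nm - np) / (nm + np)
}

#' Reciprocally balanced preference score
#'
#' Mean of the indices from two cohorts trained with swapped odor
#' identities; averaging cancels any innate preference for one odorant.
#'
#' @param index_a,index_b Indices from the two reciprocal assignments.
#' @return Scalar balanced index.
#' @export
reciprocal_balance <- function(index_a, index_b) {
  (index_a + index_b) / 2
}

#' Red-light preference index
#'
#' Per illumination configuration, `(n_light - n_dark) / total`; the values
#' from the alternating configurations (each diagonal quadrant pair lit in
#' turn) are then averaged to control for place preference. 1 means every
#' fly preferred the illuminated quadrants, 0 means indifference.
#'
#' @param counts Data frame with one row per configuration and columns
#'   `n_light`, `n_dark` (a single row is allowed).
#' @return Scalar index in `[-1, 1]`.
#' @export
light_preference_index <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("n_light", "n_dark") %in% names(counts)), nrow(counts) >= 1)
  tot <- counts$n_light + counts$n_dark
  if (any(counts$n_light < 0 | counts$n_dark < 0)) stop("counts must be non-negative")
  if (any(tot == 0)) stop("undefined index: a configuration has zero total flies")
  mean((counts$n_light - counts$n_dark) / tot)
}

#' Single-fly quadrant occupancy
#'
#' Percentage of recorded time a single fly spent in CS+ versus CS-
#' quadrants, using frame counts as the time proxy at a fixed frame rate.
#' Frames labelled anything else (e.g. a border zone) count toward total
#' time but toward neither odor, so the two percentages sum to 100 only when
#' every frame is labelled.
#'
#' @param track Character vector of per-frame quadrant labels, values
#'   `"CSplus"` / `"CSminus"` (others allowed but unclassified).
#' @return Named numeric vector `c(CSplus = , CSminus = )` in percent.
#' @export
single_fly_preference <- function(track) {
  if (length(track) == 0) stop("empty track")
  n <- length(track)
  c(CSplus = 100 * sum(track == "CSplus") / n,
    CSminus = 100 * sum(track == "CSminus") / n)
}
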