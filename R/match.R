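#' Masked template matching
#'
#' Slides the iris template over every placement that keeps it fully inside
#' the frame and scores each placement. The default score is the zero-mean
#' normalised cross-correlation computed only over pixels inside the
#' template's circular mask, which makes the score insensitive to overall
#' illumination and — because eyelid-occluded corners are excluded — robust
#' to partial lid closure. A raw product-sum score (`"ccorr"`) is available
#' for fidelity runs.
#'
#' @param frame Grayscale matrix on \[0, 255\].
#' @param tmpl An [extract_template()] result.
#' @param use_mask Restrict scoring to the circular mask. Default `TRUE`.
#' @param sim_threshold Keep placements whose similarity is at least this
#'   fraction of the per-frame maximum (when the maximum is positive).
#'   Default 0.98.
#' @param method `"ncc"` or `"ccorr"`.
#' @param peaks_only Keep only placements that are local maxima of the
#'   similarity map (3x3 neighbourhood), so a broad correlation plateau
#'   contributes one candidate rather than its whole footprint. Default
#'   `TRUE`.
#' @return Tibble of candidates sorted by similarity (descending) with
#'   columns `x`, `y` (patch top-left, 0-based) and `similarity`.
#'   Attributes: `max_similarity`, `degenerate` (`TRUE` when every placement
#'   had zero variance, e.g. a constant frame).
#' @export
match_template <- function(frame, tmpl, use_mask = TRUE,
                           sim_threshold = 0.98,
                           method = c("ncc", "ccorr"), peaks_only = TRUE) {
  method <- match.arg(method)
  res <- match_map_cpp(frame, tmpl$patch, tmpl$mask, use_mask,
                       if (method == "ccorr") 1L else 0L)
  S <- res$map
  max_sim <- max(S)
  degenerate <- res$n_degenerate == length(S)
  thr <- if (max_sim > 0) sim_threshold * max_sim else max_sim
  keep <- S >= thr
  if (peaks_only) keep <- keep & local_maxima(S)
  idx <- which(keep)
  py <- (idx - 1) %% nrow(S)
  px <- (idx - 1) %/% nrow(S)
  out <- tibble::tibble(x = px, y = py, similarity = S[idx])
  out <- dplyr::arrange(out, dplyr::desc(.data$similarity))
  attr(out, "max_similarity") <- max_sim
  attr(out, "degenerate") <- degenerate
  out
}

# TRUE where a cell is >= all its 8 neighbours (ties count as maxima, so a
# flat plateau keeps its whole crest; the similarity threshold prunes it)
local_maxima <- function(S) {
  out <- matrix(TRUE, nrow(S), ncol(S))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & (S >= shift_mat(S, dy, dx))
  }
  out
}

#' Darkest-region candidate selection
#'
#' Converts each match placement to an implied iris centre, measures the
#' mean intensity of the circular region of the iris radius at that centre,
#' and returns the darkest one — the iris is the darkest circular region in
#' a visible-light eye crop, so among near-tied correlation peaks the
#' darkest placement is the iris. Ties break on higher similarity.
#'
#' @param frame Grayscale matrix.
#' @param candidates Candidate tibble from [match_template()].
#' @param tmpl The [extract_template()] used for matching.
#' @return List with `centre` `(x, y)`, `region_mean`, `similarity`.
#' @export
select_darkest <- function(frame, candidates, tmpl) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no match candidates: frame is invalid", call. = FALSE)
  h <- nrow(frame); w <- ncol(frame)
  cx <- candidates$x + tmpl$centre_offset[1]
  cy <- candidates$y + tmpl$centre_offset[2]
  means <- vapply(seq_along(cx), function(i) {
    idx <- disc_indices(cx[i], cy[i], tmpl$iris_radius, h, w)
    mean(frame[idx])
  }, numeric(1))
  ord <- order(means, -candidates$similarity)
  i <- ord[1]
  list(centre = c(cx[i], cy[i]), region_mean = means[i],
       similarity = candidates$similarity[i])
}
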