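#' K-nearest-neighbor selection from a score map
#'
#' Walks the sorted similarity score map and keeps the first
#' `min(k, nrow(s))` entries — exactly the greedy fill-to-k rule, with ties
#' at the k-th score resolved by the map's own entity-id tie-break (never
#' expanded beyond `k`).
#'
#' @param s A `score_map` from [score_all()].
#' @param k Non-negative neighbor count.
#' @return A `neighbor_list`: the selected rows of `s`, with attributes
#'   `rule = "knn"` and `parameter = k`.
#' @export
knn_neighbors <- function(s, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != trunc(k)) {
    stop("k must be a single non-negative integer", call. = FALSE)
  }
  out <- s[seq_len(min(k, nrow(s))), ]
  attr(out, "rule") <- "knn"
  attr(out, "parameter") <- k
  class(out) <- c("neighbor_list", setdiff(class(s), "neighbor_list"))
  out
}

#' Threshold-neighbor selection from a score map
#'
#' Keeps every entry whose score is strictly greater than `t` (boundary
#' scores equal to `t` are excluded), preserving the sorted order.
#'
#' @param s A `score_map` from [score_all()].
#' @param t Similarity threshold; any real value is valid.
#' @return A `neighbor_list` with attributes `rule = "tpn"`,
#'   `parameter = t`.
#' @export
tpn_neighbors <- function(s, t) {
  if (length(t) != 1L || is.na(t)) {
    stop("t must be a single number", call. = FALSE)
  }
  out <- s[s$score > t, ]
  attr(out, "rule") <- "tpn"
  attr(out, "parameter") <- t
  class(out) <- c("neighbor_list", setdiff(class(s), "neighbor_list"))
  out
}
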