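#' Movement classes and their ternary encodings
#'
#' The controllable degrees of freedom (DoFs) are wrist flexion/extension
#' (DoF 1) and simultaneous flexion/extension of the digits (DoF 2). Each
#' DoF independently assumes one of three states \{-1, 0, +1\}, giving
#' `3^J = 9` compound movement classes for `J = 2`. Class `m = 0` is rest.
#'
#' @return A data.frame with columns `class` (integer id 0..8), `label`
#'   (description), `wrist` and `digits` (ternary encoding of each DoF).
#' @examples
#' movement_classes()
#' @export
movement_classes <- function() {
  data.frame(
    class = 0:8,
    label = c(
      "rest",
      "wrist flexion",
      "wrist extension",
      "digit flexion",
      "digit extension",
      "wrist flexion + digit flexion",
      "wrist flexion + digit extension",
      "wrist extension + digit flexion",
      "wrist extension + digit extension"
    ),
    wrist  = c(0L, -1L, 1L,  0L, 0L, -1L, -1L,  1L, 1L),
    digits = c(0L,  0L, 0L, -1L, 1L, -1L,  1L, -1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Ternary DoF encoding of a movement class
#'
#' @param m integer class id in 0..8.
#' @return Length-2 integer vector `(wrist, digits)` in \{-1, 0, 1\}.
#' @examples
#' movement_encoding(5) # c(-1, -1)
#' @export
movement_encoding <- function(m) {
  tab <- movement_classes()
  if (!all(m %in% tab$class)) {
    stop("unknown movement class id: ", paste(setdiff(m, tab$class), collapse = ", "))
  }
  idx <- match(m, tab$class)
  if (length(m) == 1L) {
    c(tab$wrist[idx], tab$digits[idx])
  } else {
    rbind(tab$wrist[idx], tab$digits[idx])
  }
}

#' Movement class id of a ternary encoding
#'
#' Inverse of [movement_encoding()]: maps per-sample ternary DoF columns to
#' class ids, as needed to derive categorical window labels for the
#' pattern-recognition benchmark.
#'
#' @param y length-2 vector or 2 x T matrix with entries in \{-1, 0, 1\}.
#' @return Integer class id(s) in 0..8.
#' @export
encoding_to_class <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) != 2L) stop("encoding must have 2 DoF rows")
  if (!all(y %in% c(-1, 0, 1))) stop("encoding entries must be ternary (-1, 0, 1)")
  tab <- movement_classes()
  key <- paste(y[1L, ], y[2L, ])
  ref <- paste(tab$wrist, tab$digits)
  tab$class[match(key, ref)]
}
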