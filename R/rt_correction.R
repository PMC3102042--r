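#' Pseudo-internal-standard anchor set
#'
#' Retention-time drift from column aging, cuts, or lot changes is corrected
#' not with an exogenous n-alkane ladder but with up to eight stable
#' endogenous metabolite peaks ("pseudo-internal standards"). Each anchor
#' pairs a compound's library retention time (`rt_old`) with its retention
#' time as observed in the current batch (`rt_new`).
#'
#' @param names Character vector of anchor compound names.
#' @param rt_old Numeric vector, library retention times in seconds.
#' @param rt_new Numeric vector, observed retention times in seconds.
#' @return An object of class `anchor_set` (a data.frame sorted by `rt_old`).
#' @export
anchor_set <- function(names, rt_old, rt_new) {
  if (length(names) != length(rt_old) || length(rt_old) != length(rt_new)) {
    stop("names, rt_old and rt_new must have the same length", call. = FALSE)
  }
  n <- length(rt_old)
  if (n < 1L || n > 8L) {
    stop(sprintf("between 1 and 8 pseudo-internal standards are supported, got %d", n),
         call. = FALSE)
  }
  if (any(rt_old < 0) || any(rt_new < 0)) {
    stop("retention times must be non-negative seconds", call. = FALSE)
  }
  ord <- order(rt_old)
  a <- data.frame(name = as.character(names)[ord],
                  rt_old = as.numeric(rt_old)[ord],
                  rt_new = as.numeric(rt_new)[ord],
                  stringsAsFactors = FALSE)
  if (n > 1L) {
    d_old <- diff(a$rt_old)
    d_new <- diff(a$rt_new)
    bad <- which(d_old <= 0 | d_new <= 0)
    if (length(bad) > 0L) {
      stop(sprintf(
        "anchors must be strictly increasing in both rt_old and rt_new; offending pair: '%s' (%.3f -> %.3f s) and '%s' (%.3f -> %.3f s)",
        a$name[bad[1]], a$rt_old[bad[1]], a$rt_new[bad[1]],
        a$name[bad[1] + 1L], a$rt_old[bad[1] + 1L], a$rt_new[bad[1] + 1L]),
        call. = FALSE)
    }
  }
  class(a) <- c("anchor_set", "data.frame")
  a
}

#' Build a retention-time correction map from anchors
#'
#' The map sends old (library) retention times to new (current batch)
#' retention times by piecewise-linear interpolation between adjacent
#' anchors. Outside the anchor range the boundary segment's affine law is
#' extended; a single anchor gives a pure time offset. The map is total and
#' strictly monotone over non-negative retention times.
#'
#' @param anchors An `anchor_set`.
#' @return An object of class `rt_map`.
#' @export
build_rt_map <- function(anchors) {
  if (!inherits(anchors, "anchor_set")) {
    stop("anchors must be an anchor_set", call. = FALSE)
  }
  structure(list(rt_old = anchors$rt_old, rt_new = anchors$rt_new,
                 rule = if (nrow(anchors) == 1L) "offset"
                        else "piecewise-linear"),
            class = "rt_map")
}

#' @export
print.rt_map <- function(x, ...) {
  cat(sprintf("<rt_map> %s over %d anchor(s), rt_old %.1f-%.1f s\n",
              x$rule, length(x$rt_old), min(x$rt_old), max(x$rt_old)))
  invisible(x)
}

#' Correct a retention time with an anchor map
#'
#' @param rt_old Numeric vector of retention times (seconds) to correct.
#' @param map An `rt_map` from [build_rt_map()].
#' @return Corrected retention times in seconds (vectorized).
#' @export
correct_rt <- function(rt_old, map) {
  stopifnot(inherits(map, "rt_map"))
  rt_old <- as.numeric(rt_old)
  if (any(rt_old < 0)) stop("retention times must be >= 0", call. = FALSE)
  xs <- map$rt_old
  ys <- map$rt_new
  n <- length(xs)
  if (n == 1L) return(rt_old + (ys - xs))
  out <- numeric(length(rt_old))
  inside <- rt_old >= xs[1] & rt_old <= xs[n]
  if (any(inside)) {
    out[inside] <- stats::approx(xs, ys, xout = rt_old[inside],
                                 method = "linear", ties = "ordered")$y
  }
  lo <- rt_old < xs[1]
  if (any(lo)) {
    slope <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[lo] <- ys[1] + slope * (rt_old[lo] - xs[1])
  }
  hi <- rt_old > xs[n]
  if (any(hi)) {
    slope <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[hi] <- ys[n] + slope * (rt_old[hi] - xs[n])
  }
  out
}

#' Update a reference library's retention times
#'
#' Applies [correct_rt()] to every entry's retention time; spectra and
#' metadata are untouched and the input library is not modified in place.
#'
#' @param library A list of `reference_entry` objects.
#' @param map An `rt_map`.
#' @return A new list of `reference_entry` objects with corrected RTs.
#' @export
update_library <- function(library, map) {
  if (length(library) == 0L) stop("library is empty", call. = FALSE)
  lapply(library, function(entry) {
    entry$rt <- correct_rt(entry$rt, map)
    entry
  })
}
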