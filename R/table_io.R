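#' Batch peak table
#'
#' A set of aligned peaks across a batch of samples, sorted by retention
#' time, with a height for every sample at every peak (no missing values).
#'
#' @param sample_names Character vector of sample names.
#' @param peaks List of `aligned_peak` objects.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(sample_names, peaks) {
  sample_names <- as.character(sample_names)
  if (length(sample_names) < 1L) stop("need at least one sample", call. = FALSE)
  for (pk in peaks) {
    stopifnot(inherits(pk, "aligned_peak"))
    if (length(pk$heights) != length(sample_names)) {
      stop(sprintf("peak '%s' has %d heights for %d samples",
                   pk$peak_id, length(pk$heights), length(sample_names)),
           call. = FALSE)
    }
  }
  if (length(peaks) > 1L) {
    rts <- vapply(peaks, function(p) p$rt, numeric(1))
    peaks <- peaks[order(rts)]
  }
  structure(list(sample_names = sample_names, peaks = peaks),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d peaks x %d samples\n",
              length(x$peaks), length(x$sample_names)))
  invisible(x)
}

#' Read an aligned-signal CSV
#'
#' The documented dialect is `rt_sec,mz,<sample_1>,...,<sample_n>`: one row
#' per aligned mass signal, retention time in seconds, integer m/z, and one
#' non-negative intensity per sample. Exports from alignment software with
#' other column names can be adapted via `col_map`.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping the dialect's
#'   `rt_sec` and `mz` onto the file's actual column names,
#'   e.g. `c(rt_sec = "RT", mz = "Mass")`.
#' @return A data.frame of parsed rows: `rt_sec`, `mz`, then one column per
#'   sample.
#' @export
read_peak_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("peak table file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  if (!all(c("rt_sec", "mz") %in% names(df))) {
    stop(sprintf(
      "unknown peak-table header: expected columns rt_sec,mz,<sample...>; got %s",
      paste(utils::head(names(df), 6), collapse = ",")), call. = FALSE)
  }
  if (ncol(df) < 3L) {
    stop("peak table has no sample columns", call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  for (col in names(df)) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf("parse error in '%s': non-numeric cell at data row %d, column '%s' (value '%s')",
                   path, bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  if (any(df$mz != round(df$mz))) {
    stop("m/z values must be integers in this dialect", call. = FALSE)
  }
  sample_cols <- setdiff(names(df), c("rt_sec", "mz"))
  if (any(as.matrix(df[sample_cols]) < 0)) {
    stop("negative intensity in peak table", call. = FALSE)
  }
  if (any(df$rt_sec < 0)) stop("negative retention time", call. = FALSE)
  df
}

#' Write an aligned-signal CSV in the documented dialect
#'
#' @param rows Data.frame as returned by [read_peak_csv()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peak_csv <- function(rows, path) {
  if (!all(c("rt_sec", "mz") %in% names(rows))) {
    stop("rows must have rt_sec and mz columns", call. = FALSE)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Group aligned mass signals into peaks
#'
#' Alignment software exports one row per mass signal; a compound's peak is
#' the cluster of signals sharing a retention time. Signals are clustered by
#' single-pass centroid linkage in RT order: a signal joins the current
#' cluster while it lies within `rt_tolerance` of the cluster's running
#' intensity-weighted RT centroid. Each cluster becomes one `aligned_peak`
#' whose spectrum holds, per member m/z, the intensity averaged across
#' samples (then normalized to base peak 100); the peak's per-sample heights
#' are the base-peak m/z intensities, and its RT is the intensity-weighted
#' mean of member RTs. Two signals with the same m/z in one cluster indicate
#' imperfect upstream deconvolution: the more intense one is kept with a
#' warning.
#'
#' @param rows Parsed signal rows from [read_peak_csv()].
#' @param rt_tolerance Clustering tolerance in seconds (default 1.5 s, three
#'   scan intervals at 20 scans/s).
#' @param mz_min,mz_max Bin range of the reconstructed spectra; out-of-range
#'   masses are dropped with a warning.
#' @return A `peak_table`.
#' @export
group_signals_into_peaks <- function(rows, rt_tolerance = 1.5,
                                     mz_min = 85L, mz_max = 500L) {
  sample_cols <- setdiff(names(rows), c("rt_sec", "mz"))
  if (length(sample_cols) == 0L) stop("no sample columns", call. = FALSE)
  out_of_range <- rows$mz < mz_min | rows$mz > mz_max
  if (any(out_of_range)) {
    warning(sprintf("dropping %d signals outside m/z %d-%d",
                    sum(out_of_range), mz_min, mz_max))
    rows <- rows[!out_of_range, , drop = FALSE]
  }
  if (nrow(rows) == 0L) return(peak_table(sample_cols, list()))
  rows <- rows[order(rows$rt_sec), , drop = FALSE]
  mean_int <- rowMeans(as.matrix(rows[sample_cols]))
  cluster_id <- integer(nrow(rows))
  current <- 1L
  centroid <- rows$rt_sec[1]
  weight <- mean_int[1]
  cluster_id[1] <- current
  for (i in seq_len(nrow(rows))[-1]) {
    if (abs(rows$rt_sec[i] - centroid) <= rt_tolerance) {
      cluster_id[i] <- current
      w_new <- weight + mean_int[i]
      if (w_new > 0) {
        centroid <- (centroid * weight + rows$rt_sec[i] * mean_int[i]) / w_new
      }
      weight <- w_new
    } else {
      current <- current + 1L
      cluster_id[i] <- current
      centroid <- rows$rt_sec[i]
      weight <- mean_int[i]
    }
  }
  n_bins <- mz_max - mz_min + 1L
  peaks <- lapply(seq_len(current), function(cl) {
    members <- which(cluster_id == cl)
    mz <- rows$mz[members]
    mi <- mean_int[members]
    if (anyDuplicated(mz)) {
      warning(sprintf("duplicate m/z within one RT cluster near %.1f s; keeping the more intense signal (possible unresolved co-elution)",
                      rows$rt_sec[members[1]]))
      keep <- unlist(lapply(split(seq_along(mz), mz),
                            function(idx) idx[which.max(mi[idx])]))
      members <- members[sort(keep)]
      mz <- rows$mz[members]
      mi <- mean_int[members]
    }
    ints <- numeric(n_bins)
    ints[mz - mz_min + 1L] <- mi
    spec <- normalize_spectrum(mass_spectrum(ints, mz_min, mz_max))
    base_member <- members[which.max(mi)]
    rt <- if (sum(mi) > 0) sum(rows$rt_sec[members] * mi) / sum(mi)
          else mean(rows$rt_sec[members])
    aligned_peak(peak_id = sprintf("P%04d", cl), rt = rt, spectrum = spec,
                 heights = as.numeric(rows[base_member, sample_cols]))
  })
  peak_table(sample_cols, peaks)
}

#' Write the organized annotation matrix
#'
#' One row per peak with its outcome (identified / annotated / unknown), the
#' matched compound name or predicted class, the match score (DOC for
#' identifications, p-value for annotations, 0 for unknowns), and every
#' sample's height. Unknown peaks are retained so the matrix covers every
#' aligned peak with no missing cells.
#'
#' @param reports Data.frame with one row per peak: `peak_id`, `rt_sec`,
#'   `status`, `label`, `score` (as produced by [run_pipeline()]).
#' @param table The `peak_table` the reports describe.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_organized_matrix <- function(reports, table, path) {
  stopifnot(inherits(table, "peak_table"))
  if (nrow(reports) != length(table$peaks)) {
    stop(sprintf("%d reports for %d peaks", nrow(reports),
                 length(table$peaks)), call. = FALSE)
  }
  heights <- do.call(rbind, lapply(table$peaks, function(p) p$heights))
  if (is.null(heights)) {
    heights <- matrix(numeric(0), nrow = 0, ncol = length(table$sample_names))
  }
  colnames(heights) <- table$sample_names
  out <- cbind(reports[c("peak_id", "rt_sec", "status", "label", "score")],
               as.data.frame(heights, check.names = FALSE))
  if (anyNA(out) || any(out == "", na.rm = TRUE)) {
    stop("organized matrix must not contain missing values", call. = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
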