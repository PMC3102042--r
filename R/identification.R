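#' Reference-library entry
#'
#' @param name Compound name.
#' @param rt Retention time in seconds.
#' @param spectrum A `mass_spectrum` of relative EI intensities.
#' @param class_label Optional chemical-class label (e.g. "sugar").
#' @param cas,kegg Optional registry identifiers.
#' @return An object of class `reference_entry`.
#' @export
reference_entry <- function(name, rt, spectrum, class_label = NA_character_,
                            cas = NA_character_, kegg = NA_character_) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!is.finite(rt) || rt < 0) stop("rt must be >= 0 seconds", call. = FALSE)
  if (max(spectrum$intensities) <= 0) {
    stop("reference spectrum must have at least one positive intensity",
         call. = FALSE)
  }
  structure(list(name = as.character(name), rt = as.numeric(rt),
                 spectrum = spectrum,
                 class_label = as.character(class_label),
                 cas = as.character(cas), kegg = as.character(kegg)),
            class = "reference_entry")
}

#' Aligned chromatographic peak
#'
#' One aligned peak across a batch of samples: a retention time, a
#' reconstructed EI spectrum, and one peak height per sample (no missing
#' values).
#'
#' @param peak_id Identifier string.
#' @param rt Retention time in seconds.
#' @param spectrum A `mass_spectrum`.
#' @param heights Numeric vector of non-negative per-sample heights.
#' @return An object of class `aligned_peak`.
#' @export
aligned_peak <- function(peak_id, rt, spectrum, heights) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  heights <- as.numeric(heights)
  if (anyNA(heights) || any(heights < 0)) {
    stop("peak heights must be non-negative with no missing values",
         call. = FALSE)
  }
  structure(list(peak_id = as.character(peak_id), rt = as.numeric(rt),
                 spectrum = spectrum, heights = heights),
            class = "aligned_peak")
}

#' Select library candidates inside a retention-time window
#'
#' Returns the library entries whose retention time lies within `c_sec`
#' seconds of the query (closed interval: a peak at 600 s with c = 2 s
#' selects exactly the 598-602 s entries), in ascending RT order.
#'
#' @param rt Query retention time in seconds.
#' @param c_sec Half-width of the search window in seconds (> 0).
#' @param library List of `reference_entry` objects (RT-corrected).
#' @return List of candidate `reference_entry` objects (possibly empty).
#' @export
candidate_window <- function(rt, c_sec, library) {
  if (!is.finite(c_sec) || c_sec <= 0) {
    stop("time width c must be > 0 seconds", call. = FALSE)
  }
  rts <- vapply(library, function(e) e$rt, numeric(1))
  keep <- which(abs(rts - rt) <= c_sec)
  library[keep[order(rts[keep])]]
}

#' Identify one peak against the reference library
#'
#' Candidates within the RT window are scored by the degree of coincidence
#' (Pearson correlation of mass-weighted spectra); the candidate with the
#' highest DOC wins if it reaches `min_doc`. Ties in DOC are broken by the
#' smaller |RT difference|, then by library order, so the result is
#' deterministic. Candidates whose weighted spectrum has zero variance are
#' treated as non-matches.
#'
#' @param peak An `aligned_peak`.
#' @param library List of `reference_entry` objects (RT-corrected).
#' @param c_sec Search window half-width in seconds.
#' @param w A `spectrum_weighting`.
#' @param min_doc Minimum DOC for a match; default 0 accepts any positive
#'   correlation winner.
#' @return A one-row data.frame: `peak_id`, `status` ("identified" or
#'   "unidentified"), `match_name`, `doc`, `delta_rt`, `candidates_considered`.
#' @export
identify_peak <- function(peak, library, c_sec, w = spectrum_weighting(),
                          min_doc = 0) {
  stopifnot(inherits(peak, "aligned_peak"))
  if (min_doc < -1 || min_doc > 1) {
    stop("min_doc must lie in [-1, 1]", call. = FALSE)
  }
  cands <- candidate_window(peak$rt, c_sec, library)
  res <- data.frame(peak_id = peak$peak_id, status = "unidentified",
                    match_name = NA_character_, doc = NA_real_,
                    delta_rt = NA_real_,
                    candidates_considered = length(cands),
                    stringsAsFactors = FALSE)
  if (length(cands) == 0L) return(res)
  u <- weight_spectrum(peak$spectrum, w)
  if (stats::var(u) == 0) return(res)
  docs <- vapply(cands, function(e) {
    v <- weight_spectrum(e$spectrum, w)
    if (stats::var(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }, numeric(1))
  if (all(is.na(docs))) return(res)
  drt <- abs(vapply(cands, function(e) e$rt, numeric(1)) - peak$rt)
  best_doc <- max(docs, na.rm = TRUE)
  if (best_doc < min_doc) return(res)
  tied <- which(!is.na(docs) & docs == best_doc)
  best <- tied[order(drt[tied])][1]
  res$status <- "identified"
  res$match_name <- cands[[best]]$name
  res$doc <- docs[best]
  res$delta_rt <- drt[best]
  res
}

#' Identify every peak of a batch
#'
#' @param peaks A `peak_table`.
#' @param library List of `reference_entry` objects (RT-corrected).
#' @param c_sec Search window half-width in seconds.
#' @param w A `spectrum_weighting`.
#' @param min_doc Minimum DOC for a match.
#' @return A data.frame with one row per peak, in peak order; a `duplicate`
#'   column flags library entries matched by more than one peak (sugars and
#'   amines legitimately give several peaks per compound, so duplicates are
#'   reported, not suppressed).
#' @export
identify_all <- function(peaks, library, c_sec, w = spectrum_weighting(),
                         min_doc = 0) {
  stopifnot(inherits(peaks, "peak_table"))
  if (length(peaks$peaks) == 0L) {
    return(data.frame(peak_id = character(), status = character(),
                      match_name = character(), doc = numeric(),
                      delta_rt = numeric(), candidates_considered = integer(),
                      duplicate = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(peaks$peaks, identify_peak, library = library, c_sec = c_sec,
                 w = w, min_doc = min_doc)
  out <- do.call(rbind, rows)
  hit <- !is.na(out$match_name)
  out$duplicate <- hit & out$match_name %in%
    names(which(table(out$match_name[hit]) > 1L))
  rownames(out) <- NULL
  out
}

#' Read a reference library CSV
#'
#' Expected header: `name,rt_sec,class,cas,kegg,i85,i86,...,i500` with
#' spectra as relative intensities over integer m/z. Blank class/cas/kegg
#' cells are tolerated.
#'
#' @param path Path to the CSV file.
#' @param mz_min,mz_max Expected m/z range of the spectral columns.
#' @return List of `reference_entry` objects.
#' @export
read_reference_library <- function(path, mz_min = 85L, mz_max = 500L) {
  if (!file.exists(path)) {
    stop(sprintf("reference library file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("name", "rt_sec", "class", "cas", "kegg")
  spec_cols <- paste0("i", seq.int(mz_min, mz_max))
  missing_cols <- setdiff(c(meta_cols, spec_cols), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "reference library dialect error: expected columns %s,i%d..i%d; missing %s",
      paste(meta_cols, collapse = ","), mz_min, mz_max,
      paste(utils::head(missing_cols, 5), collapse = ",")), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    ints <- as.numeric(df[i, spec_cols])
    reference_entry(
      name = df$name[i], rt = df$rt_sec[i],
      spectrum = mass_spectrum(ints, mz_min, mz_max),
      class_label = if (is.na(df$class[i]) || df$class[i] == "")
        NA_character_ else df$class[i],
      cas = if (is.na(df$cas[i]) || df$cas[i] == "") NA_character_ else df$cas[i],
      kegg = if (is.na(df$kegg[i]) || df$kegg[i] == "") NA_character_ else df$kegg[i])
  })
}

#' Write a reference library CSV
#'
#' @param library List of `reference_entry` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reference_library <- function(library, path) {
  stopifnot(length(library) > 0L)
  s1 <- library[[1]]$spectrum
  spec_cols <- paste0("i", mz_axis(s1))
  rows <- lapply(library, function(e) {
    v <- c(list(name = e$name, rt_sec = e$rt,
                class = ifelse(is.na(e$class_label), "", e$class_label),
                cas = ifelse(is.na(e$cas), "", e$cas),
                kegg = ifelse(is.na(e$kegg), "", e$kegg)),
           as.list(e$spectrum$intensities))
    names(v)[-(1:5)] <- spec_cols
    as.data.frame(v, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
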