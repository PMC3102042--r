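# Seeded generators for class-structured EI spectra, reference libraries and
# drifted peak tables. They emulate the structure the pipeline consumes --
# diagnostic fragment masses per chemical class, compound-specific signature
# fragments, multiplicative detector noise, linear RT drift -- not
# chromatographic peak shapes or derivatization chemistry.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Chemical-class spectrum template
#'
#' A template fixes which fragment masses characterize a class (high
#' intensity), which form its low-intensity background, and the relative
#' noise level of sampled spectra.
#'
#' @param class_name Class label.
#' @param diagnostic_masses Integer m/z values carrying the class signal.
#' @param background_masses Integer m/z values with low shared intensity.
#' @param diagnostic_intensities,background_intensities Base relative
#'   intensities for the two mass sets.
#' @param intensity_sd_rel Relative SD of multiplicative intensity noise.
#' @param mz_min,mz_max Bin range.
#' @return An object of class `class_template`.
#' @export
class_template <- function(class_name, diagnostic_masses, background_masses,
                           diagnostic_intensities = NULL,
                           background_intensities = NULL,
                           intensity_sd_rel = 0.05,
                           mz_min = 85L, mz_max = 500L) {
  all_masses <- c(diagnostic_masses, background_masses)
  if (any(all_masses < mz_min | all_masses > mz_max)) {
    stop("template masses must lie within the bin range", call. = FALSE)
  }
  if (anyDuplicated(all_masses)) {
    stop("diagnostic and background masses must be distinct", call. = FALSE)
  }
  if (intensity_sd_rel < 0) stop("intensity_sd_rel must be >= 0", call. = FALSE)
  if (is.null(diagnostic_intensities)) {
    diagnostic_intensities <- seq(100, 60, length.out = length(diagnostic_masses))
  }
  if (is.null(background_intensities)) {
    background_intensities <- rep(8, length(background_masses))
  }
  stopifnot(length(diagnostic_intensities) == length(diagnostic_masses),
            length(background_intensities) == length(background_masses))
  structure(list(class_name = class_name,
                 diagnostic_masses = as.integer(diagnostic_masses),
                 background_masses = as.integer(background_masses),
                 diagnostic_intensities = as.numeric(diagnostic_intensities),
                 background_intensities = as.numeric(background_intensities),
                 intensity_sd_rel = intensity_sd_rel,
                 mz_min = as.integer(mz_min), mz_max = as.integer(mz_max)),
            class = "class_template")
}

#' Default five-class templates
#'
#' One template per chemical class of trimethylsilylated primary
#' metabolites, with the fragment masses that discriminate each class in EI
#' spectra: sugars (m/z 89, 103, 147, 217), sugar phosphates (89, 147, 217,
#' 299), organic acids (101, 133, 147), fatty acids (117, 129, 132, 145) and
#' amines (86, 100, 174). The most class-specific fragment (e.g. m/z 299 for
#' sugar phosphates, 103 for sugars) carries the base-peak intensity;
#' fragments shared between classes (89, 147, 217) get matching moderate
#' intensities so they do not discriminate. Forty low-intensity background
#' fragments per class are drawn reproducibly from the seed, giving the
#' fragment-rich spectra typical of EI.
#'
#' @param seed Integer seed for the background-mass draw.
#' @param intensity_sd_rel Relative noise level stored in the templates.
#' @return Named list of five `class_template` objects, in the order sugar,
#'   sugar phosphate, organic acid, fatty acid, amine.
#' @export
make_default_templates <- function(seed = 1L, intensity_sd_rel = 0.05) {
  diag_sets <- list(
    "sugar" = list(mz = c(89L, 103L, 147L, 217L),
                   int = c(70, 100, 60, 60)),
    "sugar phosphate" = list(mz = c(89L, 147L, 217L, 299L),
                             int = c(70, 60, 60, 100)),
    "organic acid" = list(mz = c(101L, 133L, 147L),
                          int = c(70, 70, 100)),
    "fatty acid" = list(mz = c(117L, 129L, 132L, 145L),
                        int = c(100, 70, 70, 55)),
    "amine" = list(mz = c(86L, 100L, 174L),
                   int = c(70, 70, 100)))
  with_seed(seed, {
    templates <- lapply(names(diag_sets), function(cl) {
      dm <- diag_sets[[cl]]$mz
      pool <- setdiff(seq.int(150L, 480L, by = 3L), dm)
      bg <- sort(sample(pool, 40L))
      class_template(cl, dm, bg,
                     diagnostic_intensities = diag_sets[[cl]]$int,
                     background_intensities = stats::runif(40L, 3, 15),
                     intensity_sd_rel = intensity_sd_rel)
    })
    names(templates) <- names(diag_sets)
    templates
  })
}

# deterministic template intensity vector (no noise), not normalized
template_intensities <- function(template) {
  n_bins <- template$mz_max - template$mz_min + 1L
  ints <- numeric(n_bins)
  ints[template$diagnostic_masses - template$mz_min + 1L] <-
    template$diagnostic_intensities
  ints[template$background_masses - template$mz_min + 1L] <-
    template$background_intensities
  ints
}

#' Sample a noisy spectrum from a class template
#'
#' Applies multiplicative lognormal noise (detector-like) with relative SD
#' `intensity_sd_rel` to the template's intensities, then normalizes to base
#' peak 100. With zero noise the exact template spectrum is returned.
#'
#' @param template A `class_template`.
#' @param seed Optional integer seed.
#' @param intensity_sd_rel Override of the template's noise level.
#' @return A normalized `mass_spectrum`.
#' @export
sample_spectrum <- function(template, seed = NULL,
                            intensity_sd_rel = template$intensity_sd_rel) {
  stopifnot(inherits(template, "class_template"))
  ints <- template_intensities(template)
  with_seed(seed, {
    ints <- apply_mult_noise(ints, intensity_sd_rel)
    normalize_spectrum(mass_spectrum(ints, template$mz_min, template$mz_max))
  })
}

# per-compound variant of a class template: adds signature masses unique to
# the compound and a small rank-one modulation of the diagnostic fragments
# (emulating, e.g., varying degrees of silylation across compounds of a class)
compound_template <- function(template, signature_masses,
                              signature_intensity = 30, modulation = 0) {
  ints <- template_intensities(template)
  if (length(signature_masses) > 0L) {
    idx <- signature_masses - template$mz_min + 1L
    ints[idx] <- pmax(ints[idx], signature_intensity)
  }
  d_idx <- template$diagnostic_masses - template$mz_min + 1L
  scale <- 1 + modulation * seq(-0.15, 0.15,
                                length.out = length(d_idx))
  # the base-peak fragment is left unmodulated so the within-class structure
  # stays rank-one after base-peak normalization
  scale[which.max(template$diagnostic_intensities)] <- 1
  ints[d_idx] <- ints[d_idx] * scale
  ints
}

# multiplicative lognormal detector noise on non-zero intensities
apply_mult_noise <- function(ints, intensity_sd_rel) {
  if (intensity_sd_rel <= 0) return(ints)
  sdlog <- sqrt(log(1 + intensity_sd_rel^2))
  nz <- ints > 0
  ints[nz] <- ints[nz] *
    stats::rlnorm(sum(nz), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  ints
}

#' Generate five-class SIMCA training sets
#'
#' Builds one training matrix per class template. Each training spectrum is
#' one compound of the class: the class's diagnostic and background
#' fragments, modulated by a compound-specific latent factor (a rank-one
#' within-class structure emulating varying silylation degree), three
#' compound-specific signature fragments (distinct compounds of a class
#' share the diagnostic ions but differ elsewhere), multiplicative intensity
#' noise, and a low additive baseline floor across all bins, normalized to
#' base peak 100. Class sizes default to 12, 10, 12, 9 and 13 compounds for
#' sugar, sugar phosphate, organic acid, fatty acid and amine.
#'
#' @param templates List of `class_template` objects.
#' @param sizes Integer vector of training-set sizes, one per template.
#' @param intensity_sd_rel Relative intensity noise; the baseline floor SD is
#'   `10 * intensity_sd_rel` relative-intensity units (0.5 at the default 5%
#'   noise), so zero noise gives deterministic spectra.
#' @param seed Integer seed.
#' @return List of `simca_training_set` objects.
#' @export
make_training_sets <- function(templates = make_default_templates(),
                               sizes = c(12L, 10L, 12L, 9L, 13L),
                               intensity_sd_rel = 0.05, seed = 1L) {
  stopifnot(length(sizes) == length(templates))
  with_seed(seed, {
    mz_min <- templates[[1]]$mz_min
    mz_max <- templates[[1]]$mz_max
    n_bins <- mz_max - mz_min + 1L
    # one shared pool so signature fragments are unique across all compounds
    pool <- setdiff(seq.int(mz_min + 15L, mz_max - 5L),
                    unlist(lapply(templates, function(t)
                      c(t$diagnostic_masses, t$background_masses))))
    out <- lapply(seq_along(templates), function(ci) {
      tpl <- templates[[ci]]
      m <- sizes[ci]
      rows <- lapply(seq_len(m), function(k) {
        sig <- sample(pool, 3L)
        pool <<- setdiff(pool, sig)
        ints <- compound_template(tpl, sig, signature_intensity = 30,
                                  modulation = stats::runif(1, -1, 1))
        ints <- apply_mult_noise(ints, intensity_sd_rel)
        ints <- ints + abs(stats::rnorm(n_bins, 0, 10 * intensity_sd_rel))
        spec <- normalize_spectrum(mass_spectrum(ints, mz_min, mz_max))
        spec$intensities
      })
      training_set(tpl$class_name, do.call(rbind, rows), mz_min = mz_min)
    })
    names(out) <- vapply(out, function(t) t$class_name, character(1))
    out
  })
}

#' Generate a synthetic batch: library, drifted peak table, ground truth
#'
#' Builds a reference library of distinct compounds (each a class template
#' plus compound-specific signature fragments) on an RT grid, then simulates
#' the observed batch: every library compound elutes at
#' `alpha * rt + beta + jitter` with a noisy spectrum and lognormal
#' per-sample heights. Optionally adds class-template peaks absent from the
#' library (annotation targets) and structureless noise peaks (unknowns).
#' The first and last library compounds are designated pseudo-internal
#' standards.
#'
#' @param templates List of `class_template` objects.
#' @param library_size Number of library compounds.
#' @param n_samples Number of samples in the batch.
#' @param drift Length-2 numeric `c(alpha, beta)`: observed RT =
#'   `alpha * library RT + beta` (alpha > 0).
#' @param rt_jitter Half-width (s) of uniform RT jitter per observed peak.
#' @param intensity_sd_rel Relative spectral noise of observed peaks.
#' @param n_extra_class_peaks Peaks drawn from class templates but absent
#'   from the library.
#' @param n_noise_peaks Random unstructured peaks.
#' @param rt_start,rt_step Library RT grid (seconds).
#' @param seed Integer seed; the whole batch is a deterministic function of
#'   it.
#' @return List with `library` (entries at original grid RTs), `library_true`
#'   (same entries at drifted RTs), `signal_rows` (peak-table rows in the
#'   documented CSV dialect), `truth` (data.frame: one row per observed peak
#'   in RT order, with compound, class and kind), `anchors` (data.frame:
#'   name, rt_old, rt_true) and `sample_names`.
#' @export
make_synthetic_batch <- function(templates = make_default_templates(),
                                 library_size = 50L, n_samples = 5L,
                                 drift = c(1, 0), rt_jitter = 0,
                                 intensity_sd_rel = 0.05,
                                 n_extra_class_peaks = 0L,
                                 n_noise_peaks = 0L,
                                 rt_start = 300, rt_step = 6,
                                 seed = 1L) {
  alpha <- drift[1]
  beta <- drift[2]
  if (alpha <= 0) stop("drift slope alpha must be > 0", call. = FALSE)
  mz_min <- templates[[1]]$mz_min
  mz_max <- templates[[1]]$mz_max
  sample_names <- sprintf("S%02d", seq_len(n_samples))
  with_seed(seed, {
    mass_pool <- setdiff(seq.int(mz_min + 20L, mz_max - 5L),
                         unlist(lapply(templates, function(t)
                           c(t$diagnostic_masses, t$background_masses))))
    lib <- vector("list", library_size)
    comp_ints <- vector("list", library_size)
    for (i in seq_len(library_size)) {
      tpl <- templates[[(i - 1L) %% length(templates) + 1L]]
      sig <- sample(mass_pool, 3L)
      ints <- compound_template(tpl, sig, signature_intensity = 30,
                                modulation = stats::runif(1, -1, 1))
      comp_ints[[i]] <- ints
      lib[[i]] <- reference_entry(
        name = sprintf("compound_%03d", i),
        rt = rt_start + rt_step * (i - 1L),
        spectrum = normalize_spectrum(mass_spectrum(ints, mz_min, mz_max)),
        class_label = tpl$class_name)
    }
    obs <- list()
    add_peak <- function(rt_obs, ints, compound, class_label, kind) {
      if (kind != "noise") ints <- apply_mult_noise(ints, intensity_sd_rel)
      rel <- 100 * ints / max(ints)
      heights <- stats::rlnorm(n_samples, meanlog = log(5e4), sdlog = 0.4)
      obs[[length(obs) + 1L]] <<- list(rt = rt_obs, rel = rel,
                                       heights = heights,
                                       compound = compound,
                                       class_label = class_label, kind = kind)
    }
    for (i in seq_len(library_size)) {
      rt_obs <- alpha * lib[[i]]$rt + beta +
        if (rt_jitter > 0) stats::runif(1, -rt_jitter, rt_jitter) else 0
      add_peak(rt_obs, comp_ints[[i]], lib[[i]]$name, lib[[i]]$class_label,
               "library")
    }
    rt_end <- alpha * (rt_start + rt_step * (library_size - 1L)) + beta
    if (n_extra_class_peaks > 0L) {
      for (j in seq_len(n_extra_class_peaks)) {
        tpl <- templates[[(j - 1L) %% length(templates) + 1L]]
        sig <- sample(mass_pool, 3L)
        ints <- compound_template(tpl, sig, signature_intensity = 30,
                                  modulation = stats::runif(1, -1, 1))
        rt_obs <- rt_end + 30 + 8 * j
        add_peak(rt_obs, ints, sprintf("novel_%02d", j), tpl$class_name,
                 "annotation")
      }
    }
    if (n_noise_peaks > 0L) {
      for (j in seq_len(n_noise_peaks)) {
        masses <- sample(mass_pool, 25L)
        ints <- numeric(mz_max - mz_min + 1L)
        ints[masses - mz_min + 1L] <- stats::runif(25L, 10, 100)
        rt_obs <- rt_end + 30 + 8 * n_extra_class_peaks + 10 * j
        add_peak(rt_obs, ints, sprintf("noise_%02d", j), NA_character_,
                 "noise")
      }
    }
    rts <- vapply(obs, function(o) o$rt, numeric(1))
    obs <- obs[order(rts)]
    signal_rows <- do.call(rbind, lapply(obs, function(o) {
      nz <- which(o$rel > 0)
      block <- data.frame(rt_sec = o$rt, mz = (mz_min:mz_max)[nz])
      intensity <- outer(o$rel[nz] / 100, o$heights)
      colnames(intensity) <- sample_names
      cbind(block, as.data.frame(intensity, check.names = FALSE))
    }))
    rownames(signal_rows) <- NULL
    truth <- data.frame(
      peak_index = seq_along(obs),
      rt_obs = vapply(obs, function(o) o$rt, numeric(1)),
      compound = vapply(obs, function(o) o$compound, character(1)),
      class_label = vapply(obs, function(o) o$class_label, character(1)),
      kind = vapply(obs, function(o) o$kind, character(1)),
      stringsAsFactors = FALSE)
    anchor_idx <- c(1L, library_size)
    anchors <- data.frame(
      name = vapply(lib[anchor_idx], function(e) e$name, character(1)),
      rt_old = vapply(lib[anchor_idx], function(e) e$rt, numeric(1)),
      rt_true = alpha * vapply(lib[anchor_idx], function(e) e$rt,
                               numeric(1)) + beta,
      stringsAsFactors = FALSE)
    library_true <- lapply(lib, function(e) {
      e$rt <- alpha * e$rt + beta
      e
    })
    list(library = lib, library_true = library_true,
         signal_rows = signal_rows, truth = truth, anchors = anchors,
         sample_names = sample_names)
  })
}

#' Write training sets as a CSV
#'
#' Dialect: `name,class,i85,...,i500`, one row per training spectrum.
#'
#' @param training_sets List of `simca_training_set` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_training_sets <- function(training_sets, path) {
  stopifnot(length(training_sets) > 0L)
  rows <- do.call(rbind, lapply(training_sets, function(tr) {
    df <- as.data.frame(tr$X, check.names = FALSE)
    names(df) <- paste0("i", tr$mz_min + seq_len(ncol(tr$X)) - 1L)
    cbind(data.frame(name = tr$compound_names, class = tr$class_name,
                     stringsAsFactors = FALSE), df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read training sets written by [write_training_sets()]
#'
#' @param path CSV path.
#' @param mz_min,mz_max Expected spectral column range.
#' @return List of `simca_training_set` objects, one per class.
#' @export
read_training_sets <- function(path, mz_min = 85L, mz_max = 500L) {
  if (!file.exists(path)) {
    stop(sprintf("training-set file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  spec_cols <- paste0("i", seq.int(mz_min, mz_max))
  missing_cols <- setdiff(c("name", "class", spec_cols), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("training-set dialect error: missing columns %s",
                 paste(utils::head(missing_cols, 5), collapse = ",")),
         call. = FALSE)
  }
  lapply(split(df, df$class), function(sub) {
    training_set(sub$class[1], as.matrix(sub[spec_cols]),
                 compound_names = sub$name, mz_min = mz_min)
  })
}
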