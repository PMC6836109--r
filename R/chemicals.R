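#' Chemical objects
#'
#' A chemical object carries everything the virtual mass spectrometer needs
#' to render it in scans: a chromatographic shape (a [normalize_roi()]
#' template), a start RT, a maximum intensity, the MS1 trace definition
#' (adducts and isotopes for known chemicals with a formula; a single
#' observed m/z trace for unknown chemicals from ROIs) and a fragment
#' spectrum.
#'
#' @param formula Formula string or named count vector.
#' @param start_rt First RT (s) at which the chemical appears.
#' @param max_intensity Apex intensity of the chemical (total over traces).
#' @param chromatogram A `normalized_roi` template.
#' @param adducts Adduct table as from [default_adducts()].
#' @param isotopes Isotope proportions (numeric, sums to 1); defaults to
#'   the truncated natural-abundance approximation of the formula.
#' @param fragments Data frame with columns `mz`, `rel_intensity`.
#' @param id Optional stable identifier (used to track chemicals across
#'   replicate samples).
#' @return An object of class `known_chemical` / `unknown_chemical`
#'   (both inherit from `chemical`).
#' @export
known_chemical <- function(formula, start_rt, max_intensity, chromatogram,
                           adducts = default_adducts(),
                           isotopes = isotope_proportions(formula),
                           fragments = empty_fragments(), id = NA_integer_) {
  stopifnot(max_intensity > 0, start_rt >= 0,
            inherits(chromatogram, "normalized_roi"),
            abs(sum(adducts$proportion) - 1) < 1e-9,
            abs(sum(isotopes) - 1) < 1e-9)
  if (is.character(formula)) formula <- parse_formula(formula)
  structure(list(formula = formula,
                 mass = monoisotopic_mass(formula),
                 start_rt = start_rt, max_intensity = max_intensity,
                 chromatogram = chromatogram, adducts = adducts,
                 isotopes = isotopes, fragments = fragments, id = id),
            class = c("known_chemical", "chemical"))
}

#' @param mz Observed m/z of the single trace of an unknown chemical.
#' @rdname known_chemical
#' @export
unknown_chemical <- function(mz, start_rt, max_intensity, chromatogram,
                             fragments = empty_fragments(),
                             id = NA_integer_) {
  stopifnot(mz > 0, max_intensity > 0, start_rt >= 0,
            inherits(chromatogram, "normalized_roi"))
  structure(list(mz = mz, start_rt = start_rt,
                 max_intensity = max_intensity,
                 chromatogram = chromatogram, fragments = fragments,
                 id = id),
            class = c("unknown_chemical", "chemical"))
}

#' @rdname known_chemical
#' @export
empty_fragments <- function()
  data.frame(mz = numeric(0), rel_intensity = numeric(0))

#' @export
print.chemical <- function(x, ...) {
  if (inherits(x, "known_chemical"))
    cat("Known chemical, mass", format(x$mass), "Da,",
        nrow(x$adducts), "adduct(s) x", length(x$isotopes), "isotope(s)\n")
  else
    cat("Unknown chemical, m/z", format(x$mz), "\n")
  cat("  start RT", x$start_rt, "s, max intensity", x$max_intensity,
      ",", nrow(x$fragments), "fragment peaks\n")
  invisible(x)
}

#' MS1 traces generated by a chemical
#'
#' Expands a chemical into the individual MS1 traces it emits: one per
#' adduct x isotope combination for a known chemical (intensity split by
#' the product of proportions), a single trace for an unknown chemical.
#'
#' @param chem A chemical object.
#' @return Data frame with columns `base_mz` and `proportion`
#'   (proportions sum to 1).
#' @export
chemical_traces <- function(chem) {
  if (inherits(chem, "unknown_chemical"))
    return(data.frame(base_mz = chem$mz, proportion = 1))
  n_iso <- length(chem$isotopes)
  rows <- lapply(seq_len(nrow(chem$adducts)), function(a) {
    ad <- chem$adducts[a, ]
    data.frame(
      base_mz = adduct_mz(chem$mass, ad) +
        .neutron_shift * (seq_len(n_iso) - 1L) / ad$charge,
      proportion = ad$proportion * chem$isotopes
    )
  })
  do.call(rbind, rows)
}

#' Create chemicals by sampling formulas and spectral features
#'
#' The synthetic sample workflow: draws `n` molecular formulas from the
#' database's formula list, assigns each a start RT and maximum intensity
#' sampled jointly from the MS1 feature pool, a chromatogram template
#' chosen from `roi_pool` by intensity similarity (nearest neighbour on
#' log10 apex intensity), and a fragment spectrum via [assign_fragments()].
#'
#' @param db A `spectral_feature_db` with non-empty `formulas`.
#' @param n Number of chemicals.
#' @param adducts Adduct table applied to every chemical.
#' @param roi_pool List of `normalized_roi` templates; defaults to the
#'   database's extracted chromatograms.
#' @param fragment_method `"random"` or `"crp"` (see [assign_fragments()]).
#' @param crp A [crp_state()] shared across the sample when
#'   `fragment_method = "crp"`.
#' @return A list of `known_chemical` objects with ids `1:n`.
#' @export
sample_known_chemicals <- function(db, n, adducts = default_adducts(),
                                   roi_pool = db$chromatograms,
                                   fragment_method = c("random", "crp"),
                                   crp = NULL) {
  fragment_method <- match.arg(fragment_method)
  if (n <= 0) return(list())
  if (!length(db$formulas))
    stop("feature database holds no molecular formulas")
  if (!length(roi_pool))
    stop("no chromatogram templates available")

  pool_log_apex <- log10(vapply(roi_pool, attr, 1.0, "apex_intensity"))
  formulas <- sample(db$formulas, n, replace = TRUE)
  feats <- sample_feature(db, "ms1", n)

  lapply(seq_len(n), function(i) {
    roi_idx <- which.min(abs(pool_log_apex - log10(feats$max_intensity[i])))
    frags <- assign_fragments(db, method = fragment_method, crp = crp)
    known_chemical(formulas[i], start_rt = feats$rt[i],
                   max_intensity = feats$max_intensity[i],
                   chromatogram = roi_pool[[roi_idx]], adducts = adducts,
                   fragments = frags, id = i)
  })
}

#' Convert extracted ROIs to unknown chemicals
#'
#' The existing sample workflow: each ROI is assumed to correspond to a
#' single unknown chemical generating one MS1 trace at the ROI's mean m/z,
#' starting at the ROI's first RT, with the ROI apex as maximum intensity
#' and the normalized ROI as chromatogram.
#'
#' @param rois List of `roi` objects from [extract_rois()].
#' @param db Optional `spectral_feature_db`; when supplied, fragment
#'   spectra are assigned with [assign_fragments()].
#' @inheritParams sample_known_chemicals
#' @return A list of `unknown_chemical` objects (order preserved).
#' @export
chemicals_from_rois <- function(rois, db = NULL,
                                fragment_method = c("random", "crp"),
                                crp = NULL) {
  fragment_method <- match.arg(fragment_method)
  lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    frags <- if (!is.null(db))
      assign_fragments(db, method = fragment_method, crp = crp)
    else empty_fragments()
    unknown_chemical(mz = mean(r$mz), start_rt = r$rt[1L],
                     max_intensity = max(r$intensity),
                     chromatogram = normalize_roi(r), fragments = frags,
                     id = i)
  })
}

#' Generate replicate samples with intensity noise and dropout
#'
#' Creates related samples from a base chemical list: each sample retains
#' each chemical independently with probability `1 - dropout_prob`, and
#' retained chemicals receive independent Gaussian noise on their maximum
#' intensity (floored at 1 count to stay positive).
#'
#' @param chemicals Base list of chemical objects.
#' @param n_samples Number of replicate samples.
#' @param noise_sd Standard deviation (counts) of the intensity noise.
#' @param dropout_prob Per-sample, per-chemical exclusion probability in
#'   `[0, 1)`.
#' @return A list of `n_samples` chemical lists. Chemical identity across
#'   samples is tracked through the `id` field.
#' @export
replicate_samples <- function(chemicals, n_samples, noise_sd = 0,
                              dropout_prob = 0) {
  stopifnot(noise_sd >= 0, dropout_prob >= 0)
  if (dropout_prob >= 1) stop("dropout_prob must be < 1")
  n <- length(chemicals)
  lapply(seq_len(n_samples), function(s) {
    keep <- which(stats::runif(n) >= dropout_prob)
    noise <- stats::rnorm(length(keep), 0, noise_sd)
    out <- chemicals[keep]
    for (j in seq_along(out))
      out[[j]]$max_intensity <- max(1, out[[j]]$max_intensity + noise[j])
    out
  })
}

#' Chinese Restaurant Process state for fragment assignment
#'
#' Mutable state shared across fragmentation spectra: per-fragment-peak use
#' counts and the concentration parameter governing the rate of new peaks.
#'
#' @param concentration Positive concentration parameter (mass on drawing
#'   a previously unused fragment peak).
#' @return An environment of class `crp_state` with fields `counts` (named
#'   numeric, names are indices into the database MS2 peak pool) and
#'   `concentration`.
#' @export
crp_state <- function(concentration = 1) {
  stopifnot(concentration > 0)
  e <- new.env(parent = emptyenv())
  e$counts <- stats::setNames(numeric(0), character(0))
  e$concentration <- concentration
  class(e) <- "crp_state"
  e
}

#' Assign a fragment spectrum to a chemical
#'
#' Draws the number of fragment peaks from the database's per-scan
#' fragment-count pool, then fills the spectrum either by independent
#' uniform sampling from the MS2 peak pool (`"random"`) or by a truncated
#' Chinese Restaurant Process (`"crp"`): each draw selects a previously
#' used peak with probability proportional to its accumulated count, or a
#' new peak with probability proportional to the concentration; peaks
#' already present in the current spectrum are excluded (their probability
#' mass is redistributed proportionally), so a spectrum never contains the
#' same fragment peak twice. CRP counts in `crp` are updated in place.
#'
#' @param db A `spectral_feature_db` with non-empty `ms2_peaks` and
#'   `fragment_counts` pools.
#' @param method `"random"` or `"crp"`.
#' @param crp A [crp_state()]; required for `method = "crp"`.
#' @param n_peaks Optional fixed number of fragment peaks (otherwise
#'   sampled from the database pool).
#' @return Data frame with columns `mz` and `rel_intensity` (scaled so the
#'   most intense fragment is 1).
#' @export
assign_fragments <- function(db, method = c("random", "crp"), crp = NULL,
                             n_peaks = NULL) {
  method <- match.arg(method)
  n_pool <- nrow(db$ms2_peaks)
  if (n_pool == 0L || length(db$fragment_counts) == 0L)
    stop("feature database has no MS2 peaks or fragment counts to sample")
  if (is.null(n_peaks))
    n_peaks <- sample_feature(db, "fragment_count", 1L)
  if (n_peaks == 0L) return(empty_fragments())

  if (method == "random") {
    idx <- sample.int(n_pool, n_peaks, replace = TRUE)
  } else {
    if (is.null(crp)) stop("CRP fragment assignment requires a crp_state")
    n_peaks <- min(n_peaks, n_pool)
    idx <- integer(0)
    for (k in seq_len(n_peaks)) {
      used <- as.integer(names(crp$counts))
      avail <- setdiff(used, idx)
      w_old <- crp$counts[as.character(avail)]
      w_new <- crp$concentration
      if (sample.int(2L, 1L, prob = c(sum(w_old), w_new)) == 1L &&
          length(avail)) {
        pick <- avail[sample.int(length(avail), 1L, prob = w_old)]
      } else {
        fresh <- setdiff(seq_len(n_pool), union(used, idx))
        if (!length(fresh)) {  # pool exhausted of never-used peaks
          pick <- avail[sample.int(length(avail), 1L, prob = w_old)]
        } else {
          pick <- fresh[sample.int(length(fresh), 1L)]
        }
      }
      key <- as.character(pick)
      crp$counts[key] <- if (is.na(crp$counts[key])) 1
                         else crp$counts[key] + 1
      idx <- c(idx, pick)
    }
  }
  peaks <- db$ms2_peaks[idx, , drop = FALSE]
  data.frame(mz = peaks$mz,
             rel_intensity = peaks$intensity / max(peaks$intensity))
}
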