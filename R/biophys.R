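#' Construct a circular dichroism spectrum
#'
#' @param wavelengths wavelength grid (nm), strictly increasing.
#' @param ellipticity measured ellipticity (millidegrees) per wavelength.
#' @param concentration_uM total peptide concentration (micromolar).
#' @param n_amide_bonds number of amide bonds per peptide (10 for a capped
#'   11-mer backbone's inter-residue bonds; by convention the residue count
#'   minus one, or the value your lab uses).
#' @return object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity, concentration_uM,
                        n_amide_bonds) {
  stopifnot(length(wavelengths) == length(ellipticity),
            !is.unsorted(wavelengths, strictly = TRUE))
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 concentration_uM = concentration_uM,
                 n_amide_bonds = n_amide_bonds),
            class = "cd_spectrum")
}

#' Convert ellipticity to mean residue ellipticity
#'
#' Applies, pointwise, the conversion
#' \deqn{MRE = \frac{Ellipticity}{AmideBonds \times concentration \times
#'   10^{-7}} \times 10^{-3}}
#' with ellipticity in millidegrees and concentration in micromolar.  The
#' formula is used exactly as written, with no path-length term; the
#' resulting values are in the formula's own units (they coincide with
#' deg cm^2/dmol per residue for a 1 cm cell with concentration read as
#' molar x 10^-6).  An explicit path-length variant is available through
#' `path_length_cm`, off (1 cm) by default.
#'
#' @param spec a `cd_spectrum`.
#' @param path_length_cm optional explicit cuvette path length (cm); the
#'   default of 1 reproduces the bare formula.
#' @return a `cd_spectrum` whose `ellipticity` field holds MRE values and
#'   with `units = "MRE"`.
#' @examples
#' s <- cd_spectrum(212, 10, concentration_uM = 400, n_amide_bonds = 10)
#' mre_convert(s)$ellipticity  # 25
#' @export
mre_convert <- function(spec, path_length_cm = 1) {
  stopifnot(inherits(spec, "cd_spectrum"))
  if (spec$concentration_uM <= 0) {
    stop("concentration must be positive for MRE conversion", call. = FALSE)
  }
  if (spec$n_amide_bonds <= 0) {
    stop("amide-bond count must be positive for MRE conversion",
         call. = FALSE)
  }
  mre <- spec$ellipticity /
    (spec$n_amide_bonds * spec$concentration_uM * 1e-7 * path_length_cm) * 1e-3
  out <- spec
  out$ellipticity <- mre
  out$units <- "MRE"
  out
}

#' Beta-sheet ratio MRE212/MRE202 and state classification
#'
#' The ratio of mean residue ellipticity at 212 nm to that at 202 nm
#' separates random-coil spectra (deep minimum near 200 nm, ratio well below
#' 1) from beta-sheet spectra (minimum near 212 nm).  Classification
#' thresholds between the random-coil (RC), transition (T) and beta-sheet
#' regions are configurable; the defaults (RC below 0.6, beta above 1.0)
#' are package conventions chosen to reproduce the qualitative ordering of
#' concentration series, not published constants.
#'
#' @param spec a `cd_spectrum` of MRE values (see [mre_convert()]).
#' @param num_nm,den_nm numerator / denominator wavelengths (nm).
#' @param nearest allow nearest-neighbour wavelength lookup when the exact
#'   wavelength is absent from the grid (default TRUE).
#' @param thresholds length-2 numeric: RC/T and T/beta boundaries on the
#'   ratio scale.
#' @return list with `ratio` and `state` (`"RC"`, `"T"` or `"beta"`).
#' @export
mre_ratio <- function(spec, num_nm = 212, den_nm = 202, nearest = TRUE,
                      thresholds = c(0.6, 1.0)) {
  stopifnot(inherits(spec, "cd_spectrum"))
  pick <- function(w) {
    i <- which(spec$wavelengths == w)
    if (length(i) == 0) {
      if (!nearest) {
        stop("wavelength ", w, " nm not on the grid and nearest-neighbour ",
             "lookup is disabled", call. = FALSE)
      }
      i <- which.min(abs(spec$wavelengths - w))
    }
    spec$ellipticity[i[1]]
  }
  num <- pick(num_nm)
  den <- pick(den_nm)
  if (den == 0) {
    stop("MRE at ", den_nm, " nm is zero; ratio undefined", call. = FALSE)
  }
  ratio <- num / den
  state <- if (ratio < thresholds[1]) "RC"
           else if (ratio <= thresholds[2]) "T" else "beta"
  list(ratio = ratio, state = state)
}

#' Secondary chemical shifts relative to random coil
#'
#' The secondary chemical shift is the observed shift minus the random-coil
#' reference shift for the same residue and carbon.  Mean negative values
#' for the carbonyl carbon (around -2.7 ppm) and alpha-carbon (around
#' -0.7 ppm) indicate beta-strand conformation.  Reference shifts are
#' user-supplied (standard published random-coil tables); none are bundled.
#'
#' @param observed data.frame with columns `residue`, `carbon` (e.g.
#'   `"CO"`, `"CA"`, `"CB"`), `shift_ppm`.
#' @param reference data.frame with columns `residue`, `carbon`,
#'   `shift_ppm` of random-coil values; must cover every observed
#'   residue/carbon pair.
#' @return list with `shifts` (the observed table plus `delta_ppm`),
#'   `mean_CO`, `mean_CA` (mean secondary shifts over carbonyl and
#'   alpha-carbons; `NaN` when absent) and `classification`
#'   (`"beta-sheet-consistent"` when both means are negative,
#'   `"random coil"` when all deltas are zero, otherwise `"other"`).
#' @export
secondary_shifts <- function(observed, reference) {
  need <- c("residue", "carbon", "shift_ppm")
  stopifnot(all(need %in% names(observed)), all(need %in% names(reference)))
  key <- function(d) paste(d$residue, d$carbon)
  ref_idx <- match(key(observed), key(reference))
  if (anyNA(ref_idx)) {
    miss <- which(is.na(ref_idx))[1]
    stop("no random-coil reference for residue ", observed$residue[miss],
         " carbon ", observed$carbon[miss], call. = FALSE)
  }
  delta <- observed$shift_ppm - reference$shift_ppm[ref_idx]
  out <- observed
  out$delta_ppm <- delta
  mean_CO <- mean(delta[observed$carbon == "CO"])
  mean_CA <- mean(delta[observed$carbon == "CA"])
  classification <- if (all(delta == 0)) "random coil"
    else if (!is.nan(mean_CO) && !is.nan(mean_CA) &&
             mean_CO < 0 && mean_CA < 0) "beta-sheet-consistent"
    else "other"
  list(shifts = out, mean_CO = mean_CO, mean_CA = mean_CA,
       classification = classification)
}
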