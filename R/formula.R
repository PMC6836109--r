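## Monoisotopic atomic masses (Da) of the elements commonly seen in
## metabolite formulas; values from the CODATA/IUPAC standard tables.
.monoisotopic_masses <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.9769265325, Se = 79.9165213, B = 11.0093054, Fe = 55.9349375,
  Mg = 23.985041700, Ca = 39.96259098, Zn = 63.9291422, Cu = 62.9295975,
  Mn = 54.9380451, Co = 58.9331950, Ni = 57.9353429, As = 74.9215965,
  Li = 7.01600455, Al = 26.98153863, Cr = 51.9405075, Mo = 97.9054082,
  W = 183.9509312, D = 2.01410178
)

.proton_mass <- 1.007276467
.neutron_shift <- 1.00286864  # average mass step between isotope peaks

## relative abundance of the +1 and +2 heavy isotopes per atom, used for
## the truncated natural-abundance approximation (ratios to the light one)
.iso_plus1 <- c(C = 0.0107 / 0.9893, H = 0.000115 / 0.999885,
                N = 0.00364 / 0.99636, O = 0.00038 / 0.99757,
                S = 0.0075 / 0.9499)
.iso_plus2 <- c(O = 0.00205 / 0.99757, S = 0.0425 / 0.9499,
                Cl = 0.2424 / 0.7576, Br = 0.4931 / 0.5069)

#' Parse a molecular formula string
#'
#' @param x A formula string such as `"C6H12O6"`. Element symbols are one
#'   upper-case letter optionally followed by a lower-case letter; counts
#'   default to one.
#' @return A named integer vector of element counts.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1L]]
  toks <- regmatches(x, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A formula string or named integer vector of element
#'   counts (as from [parse_formula()]).
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L || sum(formula) == 0L)
    stop("formula contains no atoms")
  unknown <- setdiff(names(formula), names(.monoisotopic_masses))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(.monoisotopic_masses[names(formula)] * formula)
}

#' m/z of an adduct ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param adduct A single row of an adduct table (list or data frame row
#'   with `mass_shift` in Da and integer `charge`), or an element of
#'   [default_adducts()].
#' @return The ion m/z, `(mass + mass_shift) / charge`.
#' @export
adduct_mz <- function(mass, adduct) {
  z <- as.integer(adduct$charge)
  if (is.na(z) || z < 1L) stop("adduct charge must be a positive integer")
  (mass + adduct$mass_shift) / z
}

#' Default positive-mode adduct table
#'
#' @param proportions Optional named numeric vector of relative intensity
#'   proportions over the adduct names; defaults to protonation only.
#' @return A data frame with columns `name`, `mass_shift`, `charge`,
#'   `proportion` (proportions sum to one).
#' @export
default_adducts <- function(proportions = c("M+H" = 1)) {
  tab <- data.frame(
    name = c("M+H", "M+Na", "M+K", "M+NH4", "M+2H"),
    mass_shift = c(.proton_mass, 22.98922, 38.96316,
                   18.03383, 2 * .proton_mass),
    charge = c(1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  stopifnot(all(names(proportions) %in% tab$name), all(proportions >= 0),
            sum(proportions) > 0)
  tab <- tab[match(names(proportions), tab$name), , drop = FALSE]
  tab$proportion <- as.numeric(proportions) / sum(proportions)
  rownames(tab) <- NULL
  tab
}

#' Approximate natural-abundance isotope proportions
#'
#' Computes the relative abundances of the monoisotopic, +1 and +2 isotope
#' peaks of a formula from per-element heavy-isotope abundances, truncated
#' at the M+2 peak and renormalized to sum to one.
#'
#' @param formula A formula string or named count vector.
#' @return A numeric vector of length 3 (M, M+1, M+2 proportions).
#' @export
isotope_proportions <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  p1 <- sum(.iso_plus1[names(formula)] * formula, na.rm = TRUE)
  p2 <- sum(.iso_plus2[names(formula)] * formula, na.rm = TRUE) + p1^2 / 2
  v <- c(1, p1, p2)
  v / sum(v)
}
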