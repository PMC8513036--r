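#' Monoisotopic mass constants for labeled N-glycan arithmetic
#'
#' Residue (dehydrated) monoisotopic masses for the four monosaccharide
#' classes used in AGP glycan composition shorthand, together with the
#' adducts needed for negative-mode m/z arithmetic. Letters follow the
#' composition grammar: `N` = HexNAc (N-acetylglucosamine), `H` = hexose
#' (mannose/galactose), `S` = NeuAc (sialic acid), `F` = deoxyhexose
#' (fucose). Galactose (`G` on input) is counted as a hexose.
#'
#' The anthranilic-acid (AA) label increment is the net mass change of
#' reductive amination at the reducing end: + C7H7NO2 - H2O + H2 =
#' +121.052764 Da. Deprotonation uses the proton mass (charged-species
#' convention), not the hydrogen-atom mass.
#'
#' @return A named list: `residues` (named numeric vector for N/H/S/F),
#'   `water`, `proton`, `co2`, `aa_label`, and `c2h4o2` (the cross-ring
#'   remnant retained by the 0,4A2 ion), all in Da.
#' @examples
#' glyco_masses()$residues[["N"]]
#' @export
glyco_masses <- function() {
  list(
    residues = c(
      N = 203.079373, # HexNAc, C8H13NO5
      H = 162.052824, # Hex,    C6H10O5
      S = 291.095417, # NeuAc,  C11H17NO8
      F = 146.057909  # dHex,   C6H10O4
    ),
    water    = 18.010565,
    proton   = 1.007276,
    co2      = 43.989829,
    aa_label = 121.052764,  # anthranilic acid via reductive amination
    c2h4o2   = 60.021129    # 0,4A cross-ring remnant of a hexose
  )
}

#' Parse glycan composition shorthand
#'
#' Parses composition strings such as `"N4H5S2F"` into monosaccharide
#' counts. Each letter from `{N, H, S, F, G}` may appear at most once and
#' is followed by an optional positive integer (an absent digit means 1).
#' `G` (galactose) is accepted on input and folded into the hexose count;
#' canonical output strings therefore never contain `G`.
#'
#' @param text Character vector of composition strings.
#' @return A tibble with one row per input: `composition` (canonical
#'   form), `n_hexnac`, `n_hex`, `n_neuac`, `n_fuc`.
#' @examples
#' parse_composition(c("N4H5S2F", "N5H6S3F3"))
#' @seealso [format_composition()], [glycan_mass()]
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  rows <- lapply(text, parse_composition_one)
  dplyr::bind_rows(rows)
}

parse_composition_one <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    stop("empty composition string", call. = FALSE)
  }
  tokens <- stringr::str_match_all(text, "([A-Za-z])([0-9]*)")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, text)) {
    bad <- substr(text, nchar(consumed) + 1L, nchar(consumed) + 1L)
    stop(sprintf("cannot parse composition '%s': unexpected token '%s'", text, bad),
         call. = FALSE)
  }
  letters_seen <- tokens[, 2]
  unknown <- setdiff(letters_seen, c("N", "H", "S", "F", "G"))
  if (length(unknown) > 0) {
    stop(sprintf("cannot parse composition '%s': unknown residue letter '%s'",
                 text, unknown[1]), call. = FALSE)
  }
  if (anyDuplicated(letters_seen)) {
    dup <- letters_seen[duplicated(letters_seen)][1]
    stop(sprintf("cannot parse composition '%s': repeated residue letter '%s'",
                 text, dup), call. = FALSE)
  }
  counts <- ifelse(tokens[, 3] == "", 1L, suppressWarnings(as.integer(tokens[, 3])))
  if (any(is.na(counts)) || any(counts < 1L)) {
    bad <- tokens[which(is.na(counts) | counts < 1L)[1], 1]
    stop(sprintf("cannot parse composition '%s': invalid count in token '%s'",
                 text, bad), call. = FALSE)
  }
  names(counts) <- letters_seen
  get0n <- function(l) if (l %in% names(counts)) counts[[l]] else 0L
  n_hex <- get0n("H") + get0n("G") # galactose is a hexose
  out <- tibble::tibble(
    n_hexnac = get0n("N"),
    n_hex = n_hex,
    n_neuac = get0n("S"),
    n_fuc = get0n("F")
  )
  out$composition <- format_composition(out$n_hexnac, out$n_hex, out$n_neuac, out$n_fuc)
  out[, c("composition", "n_hexnac", "n_hex", "n_neuac", "n_fuc")]
}

#' Format monosaccharide counts as canonical composition shorthand
#'
#' Inverse of [parse_composition()]: letters in N, H, S, F order, zero
#' counts omitted, a count of one written without a digit (`N4H5SF`,
#' not `N4H5S1F1`).
#'
#' @param n_hexnac,n_hex,n_neuac,n_fuc Non-negative integer vectors
#'   (recycled to a common length).
#' @return Character vector of canonical composition strings.
#' @examples
#' format_composition(4, 5, 2, 1) # "N4H5S2F"
#' @export
format_composition <- function(n_hexnac, n_hex = 0L, n_neuac = 0L, n_fuc = 0L) {
  counts <- vctrs_recycle(n_hexnac, n_hex, n_neuac, n_fuc)
  if (any(unlist(counts) < 0)) stop("counts must be >= 0", call. = FALSE)
  part <- function(letter, n) {
    dplyr::case_when(n == 0 ~ "", n == 1 ~ letter, TRUE ~ paste0(letter, n))
  }
  paste0(part("N", counts[[1]]), part("H", counts[[2]]),
         part("S", counts[[3]]), part("F", counts[[4]]))
}

# base recycling helper; keeps format_composition vector-safe
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

#' Neutral monoisotopic mass of a (labeled) glycan
#'
#' Residue-sum mass: counts times residue masses, plus one water for the
#' intact (non-fragment) molecule, plus the anthranilic-acid label
#' increment when `labeled = TRUE`.
#'
#' @param composition Composition string(s) (see [parse_composition()]),
#'   or a data frame with columns `n_hexnac`, `n_hex`, `n_neuac`, `n_fuc`.
#' @param labeled Logical; reducing end carries the AA label (default TRUE).
#' @return Numeric vector of neutral masses in Da.
#' @examples
#' glycan_mass("NF", labeled = TRUE) # AA-labeled fucosylated GlcNAc, 488.2 Da
#' @export
glycan_mass <- function(composition, labeled = TRUE) {
  comp <- if (is.data.frame(composition)) composition else parse_composition(composition)
  m <- glyco_masses()
  res <- comp$n_hexnac * m$residues[["N"]] + comp$n_hex * m$residues[["H"]] +
    comp$n_neuac * m$residues[["S"]] + comp$n_fuc * m$residues[["F"]]
  res + m$water + ifelse(rep_len(labeled, nrow(comp)), m$aa_label, 0)
}

#' m/z of a deprotonated (negative-mode) ion
#'
#' `(mass - charge * proton - n_co2_losses * CO2) / charge`. Only
#' negative-mode deprotonated species are in scope; `charge` is the
#' absolute charge state.
#'
#' @param mass Neutral monoisotopic mass in Da (positive).
#' @param charge Absolute charge state, integer >= 1.
#' @param n_co2_losses Number of CO2 neutral losses (>= 0).
#' @return Numeric vector of m/z values.
#' @examples
#' mz(488.200, charge = 1) # 487.19
#' @export
mz <- function(mass, charge = 1L, n_co2_losses = 0L) {
  stopifnot(all(mass > 0), all(charge >= 1), all(n_co2_losses >= 0))
  m <- glyco_masses()
  out <- (mass - charge * m$proton - n_co2_losses * m$co2) / charge
  if (any(out <= 0)) stop("non-positive m/z: mass too small for the requested losses",
                          call. = FALSE)
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used
#' when comparing to printed instrument software output (base `round()`
#' rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Validate a composition as a plausible AGP N-glycan
#'
#' AGP is a sialoglycoprotein: every glycan observed on it carries at
#' least one sialic acid. This check is deliberately separate from
#' parsing so that fragment compositions (which may lack sialic acid)
#' remain representable.
#'
#' @param composition Composition string(s) or parsed composition tibble.
#' @return A tibble with columns `composition` and `valid_agp` (logical).
#' @export
validate_agp_composition <- function(composition) {
  comp <- if (is.data.frame(composition)) composition else parse_composition(composition)
  tibble::tibble(composition = comp$composition, valid_agp = comp$n_neuac >= 1)
}
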