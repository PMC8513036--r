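#' Enumerate Domon-Costello fragment ions of a glycan topology
#'
#' Produces B/C (non-reducing side) and Y/Z (reducing side, label and
#' water retained) ions for every glycosidic-bond cleavage combination up
#' to `max_cleavages`. Multiple simultaneous cleavages are reported for
#' the reducing-side ions (e.g. `Y3/Y4`), where the cut edges form an
#' antichain (no cut inside an already-removed branch); B/C ions come
#' from single cleavages. Subscripts count non-fucose residues from the
#' reducing end along the cleaved branch, the convention used for
#' labeled-glycan Y series. When the precursor contains sialic acid the
#' two cross-ring linkage diagnostics of [diagnostic_sialic_ions()] are
#' appended.
#'
#' @param topology A `glycan_topology` from [build_topology()].
#' @param types Ion types to enumerate, subset of `c("B","C","Y","Z")`.
#' @param max_cleavages Maximum simultaneous glycosidic cleavages (1-3).
#' @param charges Integer vector of absolute charge states.
#' @param dedupe Drop duplicate (label, m/z) rows (default TRUE);
#'   symmetric antennae otherwise yield repeated entries.
#' @return Tibble: `label`, `type`, `n_cleavages`, `composition`,
#'   `neutral_mass`, `charge`, `mz`, `diagnostic`.
#' @examples
#' topo <- build_topology(2, sialylation = "a23", core_fucose = TRUE)
#' enumerate_fragments(topo, types = "Y", max_cleavages = 2)
#' @export
enumerate_fragments <- function(topology, types = c("B", "Y", "Z"),
                                max_cleavages = 2L, charges = 1L,
                                dedupe = TRUE) {
  stopifnot(inherits(topology, "glycan_topology"))
  if (!max_cleavages %in% 1:3) {
    stop("max_cleavages must be 1, 2 or 3", call. = FALSE)
  }
  types <- match.arg(types, c("B", "C", "Y", "Z"), several.ok = TRUE)
  m <- glyco_masses()
  labeled <- isTRUE(attr(topology, "labeled"))
  res_mass <- m$residues[topology$residue]
  names(res_mass) <- topology$id

  edges <- topology$id[!is.na(topology$parent)]            # edge := child id
  subtrees <- lapply(edges, function(e) topology_subtree(topology, e))
  names(subtrees) <- edges
  subscripts <- vapply(
    edges,
    function(e) topology_depth(topology, topology$parent[topology$id == e]),
    integer(1)
  )
  names(subscripts) <- edges

  comp_string <- function(ids) {
    n <- table(factor(topology$residue[topology$id %in% ids],
                      levels = c("N", "H", "S", "F")))
    format_composition(n[["N"]], n[["H"]], n[["S"]], n[["F"]])
  }
  sum_mass <- function(ids) sum(res_mass[as.character(ids)])

  rows <- list()
  emit <- function(type, subs, ids, neutral, n_cleav) {
    lab <- paste0(type, sort(subs), collapse = "/")
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      label = lab, type = type, n_cleavages = n_cleav,
      composition = comp_string(ids), neutral_mass = neutral
    )
  }

  # reducing-side ions over antichain cut sets
  want_y <- "Y" %in% types
  want_z <- "Z" %in% types
  if (want_y || want_z) {
    cut_sets <- antichain_sets(edges, subtrees, max_cleavages)
    for (cs in cut_sets) {
      removed <- unique(unlist(subtrees[as.character(cs)]))
      kept <- setdiff(topology$id, removed)
      y_neutral <- sum_mass(kept) + m$water + if (labeled) m$aa_label else 0
      subs <- subscripts[as.character(cs)]
      if (want_y) emit("Y", subs, kept, y_neutral, length(cs))
      if (want_z) emit("Z", subs, kept, y_neutral - m$water, length(cs))
    }
  }
  # non-reducing-side ions, single cleavage
  if (any(c("B", "C") %in% types)) {
    for (e in edges) {
      ids <- subtrees[[as.character(e)]]
      depths <- vapply(ids, function(r) {
        topology_depth(topology, r) - subscripts[[as.character(e)]]
      }, integer(1))
      b_neutral <- sum_mass(ids)
      if ("B" %in% types) emit("B", max(depths), ids, b_neutral, 1L)
      if ("C" %in% types) emit("C", max(depths), ids, b_neutral + m$water, 1L)
    }
  }

  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(lapply(as.integer(charges), function(ch) {
    dplyr::mutate(out, charge = ch)
  }))
  out$mz <- mz(out$neutral_mass, out$charge)
  out$diagnostic <- NA_character_
  comp <- topology_composition(topology)
  if (comp$n_neuac >= 1) {
    diag <- diagnostic_sialic_ions()
    out <- dplyr::bind_rows(out, diag)
  }
  if (dedupe) {
    out <- dplyr::distinct(out, .data$label, .data$charge,
                           round(.data$mz, 5), .keep_all = TRUE)
    out$`round(.data$mz, 5)` <- NULL
  }
  dplyr::arrange(out, .data$mz)
}

# all antichain subsets of edges with 1..k elements (no edge lying in
# the subtree removed by another)
antichain_sets <- function(edges, subtrees, k) {
  sets <- lapply(edges, function(e) e)
  out <- sets
  for (size in seq_len(k - 1)) {
    nxt <- list()
    for (s in sets) {
      for (e in edges[edges > max(s)]) {     # canonical order avoids dupes
        ok <- !e %in% unlist(subtrees[as.character(s)]) &&
          !any(vapply(s, function(x) x %in% subtrees[[as.character(e)]],
                      logical(1)))
        if (ok) nxt[[length(nxt) + 1L]] <- c(s, e)
      }
    }
    out <- c(out, nxt)
    sets <- nxt
  }
  out
}

#' Sialic-acid linkage diagnostic ions
#'
#' The two singly charged negative-mode ions used to read sialic-acid
#' linkage from HCD spectra of labeled glycans: the 0,4A2 cross-ring ion
#' after CO2 loss (NeuAc residue plus the C2H4O2 remnant of the adjacent
#' galactose; m/z 306.12) indicates alpha-2,6 linkage, and the B2 ion
#' after CO2 loss (NeuAc + Hex; m/z 408.15) indicates alpha-2,3 linkage.
#'
#' @return Tibble of the two ions with columns as in
#'   [enumerate_fragments()] plus `diagnostic` (`"a26"` / `"a23"`).
#' @examples
#' diagnostic_sialic_ions()
#' @export
diagnostic_sialic_ions <- function() {
  m <- glyco_masses()
  a2_neutral <- m$residues[["S"]] + m$c2h4o2          # 0,4A2 neutral
  b2_neutral <- m$residues[["S"]] + m$residues[["H"]] # B2 neutral
  tibble::tibble(
    label = c("0,4A2-CO2", "B2-CO2"),
    type = c("A", "B"),
    n_cleavages = 1L,
    composition = c("S", "HS"),
    neutral_mass = c(a2_neutral, b2_neutral),
    charge = 1L,
    mz = mz(c(a2_neutral, b2_neutral), 1L, n_co2_losses = 1L),
    diagnostic = c("a26", "a23")
  )
}

#' Construct an MS/MS spectrum object
#'
#' @param mz,intensity Numeric peak vectors (same length); peaks are
#'   sorted by m/z, intensities must be non-negative.
#' @param precursor_mz Precursor m/z (NA if unknown).
#' @param charge Absolute precursor charge state.
#' @param title Source identifier.
#' @return A `glyco_spectrum`: list with `title`, `precursor_mz`,
#'   `charge`, `polarity` and a `peaks` tibble.
#' @export
spectrum <- function(mz, intensity = rep(1, length(mz)),
                     precursor_mz = NA_real_, charge = 1L, title = "") {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  structure(
    list(title = title, precursor_mz = precursor_mz, charge = as.integer(charge),
         polarity = "negative",
         peaks = tibble::tibble(mz = mz[ord], intensity = intensity[ord])),
    class = "glyco_spectrum"
  )
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("<glyco_spectrum> '%s': %d peaks, precursor %s (%d-)\n",
              x$title, nrow(x$peaks),
              ifelse(is.na(x$precursor_mz), "?", sprintf("%.4f", x$precursor_mz)),
              x$charge))
  invisible(x)
}

#' Match spectrum peaks against candidate fragment ions
#'
#' Each peak is compared to every candidate's theoretical m/z; pairs
#' within `tol_ppm` are reported. A peak matched by several candidates
#' yields one row per candidate, flagged ambiguous. The match set grows
#' monotonically with the tolerance.
#'
#' @param spec A `glyco_spectrum` or a data frame with `mz` and
#'   `intensity` columns.
#' @param candidates Tibble of fragment ions (from
#'   [enumerate_fragments()] or [diagnostic_sialic_ions()]), needing at
#'   least `label` and `mz`.
#' @param tol_ppm Matching tolerance in parts per million (> 0).
#' @return Tibble sorted by peak m/z: `peak_mz`, `intensity`, `label`,
#'   `theoretical_mz`, `ppm_error`, `ambiguous`, plus `diagnostic` and
#'   `composition` if present in `candidates`.
#' @export
match_spectrum <- function(spec, candidates, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  peaks <- if (inherits(spec, "glyco_spectrum")) spec$peaks else
    tibble::as_tibble(spec)
  empty <- tibble::tibble(peak_mz = numeric(), intensity = numeric(),
                          label = character(), theoretical_mz = numeric(),
                          ppm_error = numeric(), ambiguous = logical())
  if (nrow(peaks) == 0 || nrow(candidates) == 0) return(empty)
  keep <- intersect(c("label", "mz", "diagnostic", "composition"),
                    names(candidates))
  cand <- dplyr::rename(candidates[, keep], theoretical_mz = "mz")
  hits <- tidyr::crossing(dplyr::rename(peaks, peak_mz = "mz"), cand) |>
    dplyr::mutate(ppm_error = 1e6 * (.data$peak_mz - .data$theoretical_mz) /
                    .data$theoretical_mz) |>
    dplyr::filter(abs(.data$ppm_error) <= tol_ppm)
  if (nrow(hits) == 0) return(empty)
  hits |>
    dplyr::group_by(.data$peak_mz) |>
    dplyr::mutate(ambiguous = dplyr::n() > 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$peak_mz, .data$theoretical_mz)
}

#' Read linkage and fucose-position evidence from one MS/MS spectrum
#'
#' Applies the diagnostic rules for sialic-acid linkage and fucose
#' position to a spectrum of a glycan with known composition:
#' alpha-2,6 evidence iff the 0,4A2-CO2 ion (306.12) is matched;
#' alpha-2,3 evidence iff the B2-CO2 ion (408.15) is matched. For
#' fucosylated compositions, core-fucose evidence requires the
#' fucose-retaining Y1 ion (GlcNAc + Fuc + label), corroborated to
#' "high" confidence by the fucosylated Y2; antenna-fucose evidence
#' requires the fucose-free Y1 and Y2 together with at least one larger
#' fucose-free Y ion (antenna fucose is the labile one, preferentially
#' lost during fragmentation) and the absence of core-fucose evidence:
#' a core-fucosylated precursor can also shed its fucose by double
#' cleavage and mimic the fucose-free Y series, so the retained-fucose
#' Y1 takes precedence. Flags report evidence with supporting ions, not
#' hard verdicts.
#'
#' @param spec A `glyco_spectrum`.
#' @param composition Composition string or parsed composition row of
#'   the precursor.
#' @param tol_ppm Matching tolerance in ppm.
#' @param min_intensity Minimum peak intensity considered (absolute;
#'   default 0 = no threshold).
#' @return One-row tibble: `composition`, `a23_evidence`, `a26_evidence`,
#'   `core_fucose_evidence`, `core_fucose_confidence` (`"none"`,
#'   `"medium"`, `"high"`), `antenna_fucose_evidence`, and a list-column
#'   `supporting_ions` of matched diagnostic ions.
#' @export
assign_isomer_features <- function(spec, composition, tol_ppm = 10,
                                   min_intensity = 0) {
  stopifnot(inherits(spec, "glyco_spectrum"))
  comp <- if (is.data.frame(composition)) composition else
    parse_composition(composition)
  if (!is.na(spec$precursor_mz)) {
    m <- glyco_masses()
    obs_neutral <- spec$precursor_mz * spec$charge + spec$charge * m$proton
    theo <- glycan_mass(comp, labeled = TRUE)
    if (abs(obs_neutral - theo) / theo * 1e6 > max(tol_ppm, 20)) {
      stop(sprintf(
        "precursor m/z %.4f (z=%d) implies neutral %.4f Da; composition %s is %.4f Da",
        spec$precursor_mz, spec$charge, obs_neutral, comp$composition, theo),
        call. = FALSE)
    }
  }

  y_mass <- function(cstr) glycan_mass(cstr, labeled = TRUE)
  cand <- dplyr::bind_rows(
    diagnostic_sialic_ions(),
    tibble::tibble(
      label = c("Y1+F", "Y2+F", "Y1", "Y2", "Y4/Y4", "Y4/Y5/Y5", "Y4/Y5"),
      type = "Y", n_cleavages = NA_integer_,
      composition = c("NF", "N2F", "N", "N2", "N2H3", "N3H3", "N3H4"),
      neutral_mass = y_mass(c("NF", "N2F", "N", "N2", "N2H3", "N3H3", "N3H4")),
      charge = 1L,
      mz = mz(y_mass(c("NF", "N2F", "N", "N2", "N2H3", "N3H3", "N3H4")), 1L),
      diagnostic = NA_character_
    )
  )
  peaks <- dplyr::filter(spec$peaks, .data$intensity >= min_intensity)
  hits <- match_spectrum(spectrum(peaks$mz, peaks$intensity), cand, tol_ppm)
  got <- function(lab) lab %in% hits$label
  has_fuc <- comp$n_fuc >= 1
  core <- has_fuc && got("Y1+F")
  antenna <- has_fuc && !core && got("Y1") && got("Y2") &&
    any(c("Y4/Y4", "Y4/Y5/Y5", "Y4/Y5") %in% hits$label)
  tibble::tibble(
    composition = comp$composition,
    a23_evidence = got("B2-CO2"),
    a26_evidence = got("0,4A2-CO2"),
    core_fucose_evidence = core,
    core_fucose_confidence = if (!core) "none" else
      if (got("Y2+F")) "high" else "medium",
    antenna_fucose_evidence = antenna,
    supporting_ions = list(hits)
  )
}
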