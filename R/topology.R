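#' Build a canonical complex-type N-glycan topology
#'
#' Constructs a rooted residue tree for an anthranilic-acid-labeled
#' complex N-glycan: the chitobiose core (two GlcNAc), the trimannosyl
#' branch point, and `n_antennae` antennae of GlcNAc-Gal, optionally
#' capped by sialic acid with an alpha-2,3 or alpha-2,6 linkage tag.
#' Fucose may sit on the reducing-end GlcNAc (core) or on antenna
#' GlcNAc residues (antenna). Tri- and tetraantennary templates place
#' the extra antennae on the two branch mannoses (canonical assumption;
#' branched AGP isomer topologies are not fully resolved
#' chromatographically). An N-acetyllactosamine extension inserts an
#' extra GlcNAc-Gal unit into the first antenna.
#'
#' @param n_antennae Number of antennae (2-4).
#' @param sialylation Character vector of linkage tags, one per
#'   sialylated antenna in antenna order; each of `"a23"`, `"a26"`,
#'   `"unknown"`. Length 0 to `n_antennae`.
#' @param core_fucose Logical; fucose on the reducing-end GlcNAc.
#' @param antenna_fucose Integer; number of antennae carrying a fucose
#'   on their GlcNAc (filled in antenna order).
#' @param lacnac Number of N-acetyllactosamine (Gal-GlcNAc) extensions
#'   inserted into antenna 1 (0 or more).
#' @param labeled Logical; reducing end carries the AA label.
#' @return A `glycan_topology`: a tibble of residues with columns `id`,
#'   `parent` (NA at the root), `residue` (N/H/S/F), `antenna` (0 =
#'   core), `sia_linkage`, `fuc_position`; attribute `labeled`.
#' @examples
#' build_topology(2, sialylation = "a23", core_fucose = TRUE)
#' @export
build_topology <- function(n_antennae = 2L, sialylation = character(),
                           core_fucose = FALSE, antenna_fucose = 0L,
                           lacnac = 0L, labeled = TRUE) {
  stopifnot(n_antennae >= 2, n_antennae <= 4,
            length(sialylation) <= n_antennae,
            antenna_fucose >= 0, antenna_fucose <= n_antennae, lacnac >= 0)
  if (length(sialylation) > 0 &&
      !all(sialylation %in% c("a23", "a26", "unknown"))) {
    stop("sialylation tags must be 'a23', 'a26' or 'unknown'", call. = FALSE)
  }
  rows <- list()
  add <- function(parent, residue, antenna = 0L, sia = NA_character_,
                  fuc = NA_character_) {
    id <- length(rows) + 1L
    rows[[id]] <<- tibble::tibble(id = id, parent = parent, residue = residue,
                                  antenna = antenna, sia_linkage = sia,
                                  fuc_position = fuc)
    id
  }
  root  <- add(NA_integer_, "N")                    # reducing-end GlcNAc
  glc2  <- add(root, "N")
  man3  <- add(glc2, "H")                           # branching mannose
  man_a <- add(man3, "H")
  man_b <- add(man3, "H")
  # antenna attachment points: 2 antennae -> one per branch mannose;
  # extra antennae reuse the branch mannoses (canonical template)
  attach <- c(man_a, man_b, man_a, man_b)[seq_len(n_antennae)]
  for (k in seq_len(n_antennae)) {
    gn <- add(attach[k], "N", antenna = k)
    if (k == 1L && lacnac > 0L) {
      for (i in seq_len(lacnac)) {
        gal_x <- add(gn, "H", antenna = k)
        gn <- add(gal_x, "N", antenna = k)
      }
    }
    gal <- add(gn, "H", antenna = k)
    if (k <= length(sialylation)) {
      add(gal, "S", antenna = k, sia = sialylation[k])
    }
    if (k <= antenna_fucose) {
      add(gn, "F", antenna = k, fuc = "antenna")
    }
  }
  if (core_fucose) add(root, "F", fuc = "core")
  topo <- dplyr::bind_rows(rows)
  structure(topo, labeled = labeled,
            class = c("glycan_topology", class(topo)))
}

#' Composition of a glycan topology
#'
#' Derives the monosaccharide counts (and canonical composition string)
#' from a residue tree, the invariant linking [build_topology()] back to
#' [parse_composition()].
#'
#' @param topology A `glycan_topology`.
#' @return One-row tibble: `composition`, `n_hexnac`, `n_hex`,
#'   `n_neuac`, `n_fuc`.
#' @export
topology_composition <- function(topology) {
  stopifnot(inherits(topology, "glycan_topology"))
  n <- table(factor(topology$residue, levels = c("N", "H", "S", "F")))
  tibble::tibble(
    composition = format_composition(n[["N"]], n[["H"]], n[["S"]], n[["F"]]),
    n_hexnac = as.integer(n[["N"]]), n_hex = as.integer(n[["H"]]),
    n_neuac = as.integer(n[["S"]]), n_fuc = as.integer(n[["F"]])
  )
}

#' @export
print.glycan_topology <- function(x, ...) {
  comp <- topology_composition(x)
  cat(sprintf("<glycan_topology> %s (%d residues%s)\n", comp$composition,
              nrow(x), if (isTRUE(attr(x, "labeled"))) ", AA-labeled" else ""))
  NextMethod()
  invisible(x)
}

# ids of all residues in the subtree rooted at `id` (inclusive)
topology_subtree <- function(topology, id) {
  out <- id
  frontier <- id
  while (length(frontier) > 0) {
    kids <- topology$id[!is.na(topology$parent) & topology$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# number of non-fucose residues on the path root -> id (inclusive);
# Domon-Costello Y subscript of a cleavage below `id`
topology_depth <- function(topology, id) {
  d <- 0L
  cur <- id
  while (!is.na(cur)) {
    if (topology$residue[topology$id == cur] != "F") d <- d + 1L
    cur <- topology$parent[topology$id == cur]
  }
  d
}
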