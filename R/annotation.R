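# Base-moiety atom definitions used by the geometric annotator.
RING_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"))

EXO_ATOMS <- list(A = "N6", G = c("O6", "N2"), C = c("O2", "N4"),
                  U = c("O2", "O4"))

POLAR_ATOMS <- list(A = c("N1", "N3", "N6", "N7"),
                    G = c("N1", "N2", "N3", "O6", "N7"),
                    C = c("O2", "N3", "N4"),
                    U = c("O2", "N3", "O4"))

GLYCO_N <- c(A = "N9", G = "N9", C = "N1", U = "N1")

# Edge membership (Leontis-Westhof): Watson-Crick, Hoogsteen, Sugar.
# Lookup priority is W, H, S; atoms absent from every set default to W.
EDGE_ATOMS <- list(
  A = list(W = c("N1", "C2", "N6"), H = c("N6", "N7", "C8", "C5"),
           S = c("N3", "C2", "C4", "N9")),
  G = list(W = c("N1", "N2", "O6"), H = c("O6", "N7", "C8", "C5"),
           S = c("N3", "N2", "C4", "N9")),
  C = list(W = c("N3", "N4", "O2"), H = c("N4", "C5", "C6"),
           S = c("O2", "C2", "N1")),
  U = list(W = c("N3", "O4", "O2"), H = c("O4", "C5", "C6"),
           S = c("O2", "C2", "N1")))

# Watson-Crick / wobble donor-acceptor patterns; atom 1 belongs to the
# first base of the (alphabetically sorted) pair key.
WC_HBONDS <- list(
  "A|U" = list(c("N1", "N3"), c("N6", "O4")),
  "C|G" = list(c("N3", "N1"), c("N4", "O6"), c("O2", "N2")),
  "G|U" = list(c("N1", "O2"), c("O6", "N3")))

#' Default thresholds of the geometric interaction detector
#'
#' All distances in Angstrom, angles in degrees.  `canonical_c1_range` bounds
#' the C1'-C1' distance of a canonical pair; `hbond_max` the donor-acceptor
#' distances; `pair_plane_max` the inter-base plane angle of any pair;
#' `pair_offset_max` the out-of-plane offset below which two bases are
#' considered coplanar (pairing) rather than stacked; `stack_centroid_max`,
#' `stack_plane_max` and `stack_offset_range` define stacking.
#'
#' @return Named list of thresholds.
#' @export
annotation_params <- function() {
  list(canonical_c1_range = c(8.0, 12.0), hbond_max = 3.5,
       pair_plane_max = 65, pair_offset_max = 2.0, polar_max = 3.5,
       stack_centroid_max = 5.5, stack_plane_max = 30,
       stack_offset_range = c(2.0, 5.5))
}

# per-residue geometry: ring centroid, unit plane normal (least-squares via
# SVD), coordinates of base atoms, glycosidic N and C1'
residue_geometry <- function(model) {
  at <- model$atoms
  res <- model$residues
  rid_at <- paste(at$chain, at$number, at$icode, sep = "\r")
  out <- vector("list", nrow(res))
  skipped <- character()
  for (k in seq_len(nrow(res))) {
    base <- res$base[k]
    label <- sprintf("%s%d%s", res$chain[k], res$number[k], res$icode[k])
    if (!base %in% names(RING_ATOMS)) { skipped <- c(skipped, label); next }
    rows <- at[rid_at == paste(res$chain[k], res$number[k], res$icode[k],
                               sep = "\r"), , drop = FALSE]
    ring <- rows[rows$elety %in% RING_ATOMS[[base]], , drop = FALSE]
    gly <- rows[rows$elety == GLYCO_N[[base]], , drop = FALSE]
    c1 <- rows[rows$elety == "C1'", , drop = FALSE]
    if (nrow(ring) < 3L || nrow(gly) != 1L || nrow(c1) != 1L) {
      skipped <- c(skipped, label)
      next
    }
    xyz <- as.matrix(ring[c("x", "y", "z")])
    centroid <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2L, centroid))
    normal <- sv$v[, 3L]
    base_rows <- rows[rows$elety %in% c(RING_ATOMS[[base]],
                                        EXO_ATOMS[[base]]), , drop = FALSE]
    out[[k]] <- list(
      chain = res$chain[k], number = res$number[k], icode = res$icode[k],
      base = base, centroid = centroid, normal = normal,
      atoms = stats::setNames(
        lapply(seq_len(nrow(base_rows)),
               function(r) as.numeric(base_rows[r, c("x", "y", "z")])),
        base_rows$elety),
      gly = as.numeric(gly[1L, c("x", "y", "z")]),
      c1 = as.numeric(c1[1L, c("x", "y", "z")]))
  }
  if (length(skipped)) {
    warning(sprintf("model '%s': skipping %d residue(s) with missing or unknown base atoms: %s",
                    model$model_id, length(skipped),
                    paste(utils::head(skipped, 8L), collapse = ", ")),
            call. = FALSE)
  }
  out[!vapply(out, is.null, TRUE)]
}

plane_angle <- function(n1, n2) {
  acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
}

edge_of <- function(base, atom) {
  for (e in c("W", "H", "S")) {
    if (atom %in% EDGE_ATOMS[[base]][[e]]) return(e)
  }
  "W"
}

classify_pair <- function(gi, gj, par) {
  d <- gj$centroid - gi$centroid
  cen_dist <- sqrt(sum(d^2))
  if (cen_dist > 16) return(NULL)
  ang <- plane_angle(gi$normal, gj$normal)
  offset <- (abs(sum(d * gi$normal)) + abs(sum(d * gj$normal))) / 2

  mk <- function(kind, lw = "") {
    interaction(kind, gi$chain, gi$number, gj$chain, gj$number,
                icode_i = gi$icode, icode_j = gj$icode, lw = lw)
  }

  coplanar <- ang <= par$pair_plane_max && offset < par$pair_offset_max
  if (coplanar) {
    # canonical Watson-Crick / wobble?
    key <- paste(sort(c(gi$base, gj$base)), collapse = "|")
    bonds <- WC_HBONDS[[key]]
    if (!is.null(bonds)) {
      swap <- gi$base != sort(c(gi$base, gj$base))[1L]
      c1d <- sqrt(sum((gi$c1 - gj$c1)^2))
      if (c1d >= par$canonical_c1_range[1L] &&
          c1d <= par$canonical_c1_range[2L]) {
        ok <- TRUE
        for (b in bonds) {
          a1 <- if (swap) gj$atoms[[b[1L]]] else gi$atoms[[b[1L]]]
          a2 <- if (swap) gi$atoms[[b[2L]]] else gj$atoms[[b[2L]]]
          if (is.null(a1) || is.null(a2) ||
              sqrt(sum((a1 - a2)^2)) > par$hbond_max) { ok <- FALSE; break }
        }
        if (ok) return(mk("canonical_pair"))
      }
    }
    # non-canonical: any polar-atom contact within range
    pi_at <- gi$atoms[names(gi$atoms) %in% POLAR_ATOMS[[gi$base]]]
    pj_at <- gj$atoms[names(gj$atoms) %in% POLAR_ATOMS[[gj$base]]]
    if (length(pi_at) && length(pj_at)) {
      best <- c(Inf, NA, NA)
      for (ai in names(pi_at)) for (aj in names(pj_at)) {
        dd <- sqrt(sum((pi_at[[ai]] - pj_at[[aj]])^2))
        if (dd < best[1L]) best <- c(dd, ai, aj)
      }
      if (as.numeric(best[1L]) <= par$polar_max) {
        e1 <- edge_of(gi$base, best[2L])
        e2 <- edge_of(gj$base, best[3L])
        # cis/trans from glycosidic-bond sidedness in the mean base plane
        nm <- gi$normal + sign(sum(gi$normal * gj$normal) + 1e-12) * gj$normal
        nm <- nm / sqrt(sum(nm^2))
        axis <- gj$gly - gi$gly
        axis <- axis - sum(axis * nm) * nm
        axis <- axis / max(sqrt(sum(axis^2)), 1e-9)
        e2v <- c(nm[2L] * axis[3L] - nm[3L] * axis[2L],
                 nm[3L] * axis[1L] - nm[1L] * axis[3L],
                 nm[1L] * axis[2L] - nm[2L] * axis[1L])
        si <- sum((gi$c1 - gi$gly) * e2v)
        sj <- sum((gj$c1 - gj$gly) * e2v)
        ct <- if (si * sj > 0) "c" else "t"
        return(mk("noncanonical_pair", lw = paste0(ct, e1, e2)))
      }
    }
    return(NULL)
  }
  # stacking: face-to-face contact
  if (cen_dist <= par$stack_centroid_max && ang <= par$stack_plane_max &&
      offset >= par$stack_offset_range[1L] &&
      offset <= par$stack_offset_range[2L]) {
    return(mk("stacking"))
  }
  NULL
}

#' Annotate base pairs and stackings from 3D coordinates
#'
#' A built-in geometric detector for canonical pairs (Watson-Crick AU/GC and
#' GU wobble), non-canonical pairs (classified by Leontis-Westhof edge and
#' cis/trans orientation), and base stackings.  Canonical pairs require a
#' C1'-C1' distance within `canonical_c1_range`, every standard
#' donor-acceptor distance at most `hbond_max`, and near-coplanar bases.
#' Remaining coplanar base-base contacts with at least one polar contact
#' within `polar_max` become non-canonical pairs, with the edge taken from
#' the nearest-atom edge membership and cis/trans from glycosidic-bond
#' sidedness.  Stacking requires centroid distance at most
#' `stack_centroid_max`, plane angle at most `stack_plane_max`, and an
#' out-of-plane offset within `stack_offset_range`.  At most one pair
#' interaction is emitted per residue pair (canonical preferred).
#'
#' Residues with missing base atoms (or unmappable bases) are skipped with a
#' warning.
#'
#' @param model An `rna_model` with atom coordinates.
#' @param params Threshold list, see [annotation_params()].
#' @return An [interaction_set()] for the model.
#' @export
#' @examples
#' m <- synthetic_helix_model(c("GC", "AU"))
#' annotate_geometric(m)
annotate_geometric <- function(model, params = annotation_params()) {
  geo <- residue_geometry(model)
  found <- list()
  n <- length(geo)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      hit <- classify_pair(geo[[i]], geo[[j]], params)
      if (!is.null(hit)) found[[length(found) + 1L]] <- hit
    }
  }
  df <- if (length(found)) do.call(rbind, found) else
    data.frame(kind = character(), chain_i = character(), num_i = integer(),
               icode_i = character(), chain_j = character(),
               num_j = integer(), icode_j = character(), lw = character())
  interaction_set(df, model_id = model$model_id)
}
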