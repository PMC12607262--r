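# Idealized, planar nucleotide geometry used to build synthetic test
# structures.  Rings are regular polygons (bond length 1.39 A), exocyclic
# substituents sit on the radial bisector (bond 1.35 A), C1' extends 1.47 A
# from the glycosidic nitrogen.  The geometry is deliberately simple: it is
# not crystallographic, but it satisfies standard Watson-Crick hydrogen-bond
# distances (~2.9 A), C1'-C1' separations (~10.5-11 A), and A-form stacking
# geometry, which is what the geometric annotator measures.

deg <- function(a) a * pi / 180

# purine placed with hexagon centered at the origin, Watson-Crick edge
# facing +x, imidazole ring fused on the upper-left, glycosidic C1' below
purine_template <- function(base) {
  rr <- 1.39
  hex_ang <- c(N1 = 0, C2 = -60, N3 = -120, C4 = 180, C5 = 120, C6 = 60)
  hex <- t(vapply(hex_ang, function(a) rr * c(cos(deg(a)), sin(deg(a))),
                  numeric(2)))
  s <- 1.39
  a5 <- s / (2 * tan(deg(36)))           # pentagon apothem
  r5 <- s / (2 * sin(deg(36)))           # pentagon circumradius
  m <- (hex["C4", ] + hex["C5", ]) / 2
  pc <- m * (1 + a5 / sqrt(sum(m^2)))    # pentagon center, away from hexagon
  ang4 <- atan2(hex["C4", 2] - pc[2], hex["C4", 1] - pc[1])
  pent <- rbind(N9 = pc + r5 * c(cos(ang4 - deg(72)), sin(ang4 - deg(72))),
                C8 = pc + r5 * c(cos(ang4 - deg(144)), sin(ang4 - deg(144))),
                N7 = pc + r5 * c(cos(ang4 - deg(216)), sin(ang4 - deg(216))))
  exo <- if (base == "G") {
    rbind(O6 = hex["C6", ] * (1 + 1.35 / rr),
          N2 = hex["C2", ] * (1 + 1.35 / rr))
  } else {  # adenine
    rbind(N6 = hex["C6", ] * (1 + 1.35 / rr))
  }
  c1 <- pent["N9", ] + 1.47 * (pent["N9", ] - pc) / r5
  xy <- rbind(hex, pent, exo, `C1'` = c1)
  data.frame(elety = rownames(xy), x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

# pyrimidine placed to the right of a purine: ring centered at (pair_sep, 0)
# with N3 facing the purine N1 and the C4 substituent (O4/N4) on the +y side
pyrimidine_template <- function(base, center) {
  rr <- 1.39
  ang <- c(N3 = 180, C2 = -120, N1 = -60, C6 = 0, C5 = 60, C4 = 120)
  hex <- t(vapply(ang, function(a)
    center + rr * c(cos(deg(a)), sin(deg(a))), numeric(2)))
  out <- function(at) center + (hex[at, ] - center) * (1 + 1.35 / rr)
  exo <- if (base == "C") rbind(O2 = out("C2"), N4 = out("C4"))
         else rbind(O2 = out("C2"), O4 = out("C4"))
  c1 <- center + (hex["N1", ] - center) * (1 + 1.47 / rr)
  xy <- rbind(hex, exo, `C1'` = c1)
  data.frame(elety = rownames(xy), x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

# two paired bases in the xy-plane; b1 on the left.  Supported pair types:
# GC, CG, AU, UA, GU, UG (wobble pairs use a sheared pyrimidine placement).
pair_template <- function(b1, b2) {
  key <- paste0(b1, b2)
  flipped <- key %in% c("CG", "UA", "UG")
  if (flipped) { tmp <- b1; b1 <- b2; b2 <- tmp; key <- paste0(b1, b2) }
  if (!key %in% c("GC", "AU", "GU")) {
    stop_rnac("fixture_error", "unsupported pair type '%s'", key)
  }
  center <- if (key == "GU") c(5.28, 1.30) else c(5.68, 0)
  r1 <- purine_template(b1)
  r2 <- pyrimidine_template(b2, center)
  if (flipped) {
    # rotate the whole pair 180 degrees about the C1'-C1' midpoint so the
    # pyrimidine becomes the left-hand (strand 1) residue
    c1a <- unlist(r1[r1$elety == "C1'", c("x", "y")])
    c1b <- unlist(r2[r2$elety == "C1'", c("x", "y")])
    m <- (c1a + c1b) / 2
    rot <- function(df) { df$x <- 2 * m[1] - df$x; df$y <- 2 * m[2] - df$y; df }
    return(list(res1 = rot(r2), res2 = rot(r1)))
  }
  list(res1 = r1, res2 = r2)
}

#' Build an idealized double-helical RNA model
#'
#' Constructs a synthetic two-chain RNA 3D structure from idealized planar
#' base geometry stacked with A-form-like parameters (default rise 2.81 A,
#' twist 32.7 deg).  Chain A holds the first base of every pair, chain B the
#' second; residue `k` of chain A pairs residue `k` of chain B.  Useful as a
#' programmatic fixture for the geometric annotator: Watson-Crick pairs
#' satisfy the standard hydrogen-bond distances and consecutive residues of
#' a chain stack face-to-face.
#'
#' @param pairs Character vector of pair types, one per rung, each one of
#'   `"GC","CG","AU","UA","GU","UG"` (first letter = chain A base).
#' @param rise,twist Helical rise (Angstrom) and twist (degrees) per step.
#' @param jitter Standard deviation of Gaussian coordinate noise (Angstrom);
#'   uses the current RNG state.
#' @param model_id Model label.
#' @return An `rna_model` with chains `A` and `B`.
#' @export
#' @examples
#' m <- synthetic_helix_model(c("GC", "AU", "CG"))
#' m
synthetic_helix_model <- function(pairs, rise = 2.81, twist = 32.7,
                                  jitter = 0, model_id = "helix1") {
  stopifnot(length(pairs) >= 1L)
  rows <- list()
  for (k in seq_along(pairs)) {
    p <- strsplit(pairs[[k]], "")[[1L]]
    tpl <- pair_template(p[1L], p[2L])
    th <- deg((k - 1L) * twist)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    place <- function(df, chain, base) {
      xy <- as.matrix(df[c("x", "y")]) %*% t(rot)
      data.frame(chain = chain, number = k, icode = "", resname = base,
                 elety = df$elety, x = xy[, 1], y = xy[, 2],
                 z = (k - 1L) * rise, stringsAsFactors = FALSE)
    }
    rows[[2L * k - 1L]] <- place(tpl$res1, "A", p[1L])
    rows[[2L * k]] <- place(tpl$res2, "B", p[2L])
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$number), , drop = FALSE]
  rownames(atoms) <- NULL
  if (jitter > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(n, 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(n, 0, jitter)
  }
  atoms$base <- atoms$resname
  new_structure_model(model_id, atoms)
}
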