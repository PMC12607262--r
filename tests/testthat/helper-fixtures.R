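# shared fixtures, built in code at test time

# the three-model worked ensemble: A = {x, y}, B = {x}, C = {x, z}
xyz_ensemble <- function() {
  x <- interaction("canonical_pair", "A", 1, "A", 10)
  y <- interaction("canonical_pair", "A", 2, "A", 9)
  z <- interaction("stacking", "A", 3, "A", 4)
  cols <- c("kind", "chain_i", "num_i", "icode_i",
            "chain_j", "num_j", "icode_j", "lw")
  list(A = interaction_set(rbind(x, y)[cols], "A"),
       B = interaction_set(x[cols], "B"),
       C = interaction_set(rbind(x, z)[cols], "C"))
}

# write an idealized helix as a (possibly multi-model) PDB file
write_helix_pdb <- function(path, pairs, n_models = 1L, jitter = 0.05,
                            seed = 1L) {
  set.seed(seed)
  blocks <- vapply(seq_len(n_models), function(k) {
    m <- synthetic_helix_model(pairs, jitter = jitter)
    tmp <- tempfile(fileext = ".pdb")
    write_model_pdb(m, tmp)
    body <- paste(setdiff(readLines(tmp), "END"), collapse = "\n")
    if (n_models > 1L) sprintf("MODEL     %4d\n%s\nENDMDL", k, body)
    else body
  }, "")
  writeLines(c(blocks, "END"), path)
  path
}

# independent brute-force canonical-pair oracle: plain scalar loops over all
# residue pairs applying the documented thresholds
oracle_canonical_pairs <- function(model, par = annotation_params()) {
  geo <- rnaconsensus:::residue_geometry(model)
  bonds_tbl <- list("A|U" = list(c("N1", "N3"), c("N6", "O4")),
                    "C|G" = list(c("N3", "N1"), c("N4", "O6"),
                                 c("O2", "N2")),
                    "G|U" = list(c("N1", "O2"), c("O6", "N3")))
  found <- character()
  for (i in seq_along(geo)) for (j in seq_along(geo)) {
    if (i >= j) next
    gi <- geo[[i]]; gj <- geo[[j]]
    key <- paste(sort(c(gi$base, gj$base)), collapse = "|")
    bonds <- bonds_tbl[[key]]
    if (is.null(bonds)) next
    c1d <- sqrt(sum((gi$c1 - gj$c1)^2))
    if (c1d < par$canonical_c1_range[1] || c1d > par$canonical_c1_range[2])
      next
    ang <- acos(min(1, abs(sum(gi$normal * gj$normal)))) * 180 / pi
    if (ang > par$pair_plane_max) next
    d <- gj$centroid - gi$centroid
    off <- (abs(sum(d * gi$normal)) + abs(sum(d * gj$normal))) / 2
    if (off >= par$pair_offset_max) next
    swap <- gi$base != sort(c(gi$base, gj$base))[1]
    ok <- TRUE
    for (b in bonds) {
      a1 <- if (swap) gj$atoms[[b[1]]] else gi$atoms[[b[1]]]
      a2 <- if (swap) gi$atoms[[b[2]]] else gj$atoms[[b[2]]]
      if (is.null(a1) || is.null(a2) || sqrt(sum((a1 - a2)^2)) > par$hbond_max) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      found <- c(found, interaction("canonical_pair", gi$chain, gi$number,
                                    gj$chain, gj$number,
                                    icode_i = gi$icode,
                                    icode_j = gj$icode)$key)
    }
  }
  sort(found)
}

# independent crisp set-algebra oracle
oracle_crisp <- function(model_keys, consensus_keys) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in model_keys) {
    if (any(consensus_keys == k)) tp <- tp + 1L else fp <- fp + 1L
  }
  for (k in consensus_keys) if (!any(model_keys == k)) fn <- fn + 1L
  list(TP = tp, FP = fp, FN = fn)
}
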