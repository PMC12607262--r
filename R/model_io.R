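# Mapping of common modified nucleotide residue names to their parent base.
# Unmappable residues that still carry a C1' atom are kept with base "N" and
# excluded from interaction analysis; anything else (protein, water, ions,
# ligands) is skipped.
MODIFIED_BASE_MAP <- c(
  PSU = "U", H2U = "U", DHU = "U", "4SU" = "U", "5MU" = "U", OMU = "U",
  UR3 = "U", "70U" = "U", "5BU" = "U",
  "1MA" = "A", "2MA" = "A", MA6 = "A", A2M = "A", MIA = "A", T6A = "A",
  RIA = "A", I = "A",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", G7M = "G", OMG = "G",
  YG = "G", YYG = "G", QUO = "G",
  "5MC" = "C", OMC = "C", "4OC" = "C", CCC = "C", M4C = "C"
)

map_base <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- ifelse(resname %in% c("A", "C", "G", "U"), resname,
                unname(MODIFIED_BASE_MAP[resname]))
  out
}

residues_from_atoms <- function(atoms) {
  id <- paste(atoms$chain, atoms$number, atoms$icode, sep = "\r")
  first <- !duplicated(id)
  data.frame(chain = atoms$chain[first], number = atoms$number[first],
             icode = atoms$icode[first], base = atoms$base[first],
             resname = atoms$resname[first], stringsAsFactors = FALSE)
}

new_structure_model <- function(model_id, atoms, n_atoms_raw = nrow(atoms)) {
  residues <- residues_from_atoms(atoms)
  dup <- duplicated(paste(residues$chain, residues$number, residues$icode,
                          sep = "\r"))
  stopifnot(!any(dup))
  m <- list(model_id = model_id, atoms = atoms, residues = residues,
            n_atoms_raw = n_atoms_raw)
  class(m) <- "rna_model"
  m
}

#' @export
print.rna_model <- function(x, ...) {
  cat(sprintf("<rna_model> '%s': %d chain(s), %d residue(s), %d atom(s)\n",
              x$model_id, length(unique(x$residues$chain)),
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

# ---- format detection --------------------------------------------------

detect_format <- function(path) {
  lines <- tryCatch(readLines(path, n = 300L, warn = FALSE),
                    error = function(e) character())
  if (any(grepl("^(data_|loop_|_atom_site\\.)", lines))) return("cif")
  if (any(grepl("^(ATOM {2}|HETATM|MODEL {1,}[0-9]|HEADER|CRYST1)", lines))) {
    return("pdb")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  NA_character_
}

is_archive <- function(path) {
  magic <- tryCatch(readBin(path, "raw", n = 4L), error = function(e) raw())
  if (length(magic) >= 4L &&
      identical(magic[1:4], as.raw(c(0x50, 0x4b, 0x03, 0x04)))) return("zip")
  if (length(magic) >= 2L &&
      identical(magic[1:2], as.raw(c(0x1f, 0x8b)))) return("targz")
  ext <- tolower(path)
  if (grepl("\\.zip$", ext)) return("zip")
  if (grepl("\\.(tar\\.gz|tgz|tar)$", ext)) return("targz")
  NA_character_
}

# ---- PDB (via bio3d) ---------------------------------------------------

read_pdb_models <- function(path, stem) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      stop_rnac("parse_error", "cannot parse PDB file '%s': %s",
                path, conditionMessage(e))
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop_rnac("parse_error", "no atom records in '%s'", path)
  }
  # keep first alternate location only
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A", "1")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  n_raw <- nrow(at)
  lapply(seq_len(n_models), function(k) {
    coords <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    atoms <- data.frame(
      chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
      number = as.integer(at$resno),
      icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
      resname = trimws(as.character(at$resid)),
      elety = trimws(as.character(at$elety)),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
    atoms <- atoms[alt_ok, , drop = FALSE]
    finalize_atoms(atoms, path,
                   model_id = if (n_models > 1L) sprintf("%s#%d", stem, k)
                              else stem,
                   n_atoms_raw = n_raw)
  })
}

# ---- PDBx/mmCIF (_atom_site loop) --------------------------------------

cif_tokens <- function(line) {
  scan(text = line, what = character(), quiet = TRUE, quote = "\"'")
}

read_cif_models <- function(path, stem) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) {
    stop_rnac("parse_error", "no _atom_site loop in '%s'", path)
  }
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1L
  rows <- list()
  i <- start
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || grepl("^(#|_|loop_|data_)", l)) break
    tok <- cif_tokens(lines[i])
    if (length(tok) != length(fields)) {
      stop_rnac("parse_error",
                "'%s' line %d: %d token(s), expected %d _atom_site fields",
                path, i, length(tok), length(fields))
    }
    rows[[length(rows) + 1L]] <- tok
    i <- i + 1L
  }
  if (!length(rows)) {
    stop_rnac("parse_error", "empty _atom_site loop in '%s'", path)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(primary, fallback = NULL) {
    if (primary %in% fields) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fields) return(m[, fallback])
    rep("", nrow(m))
  }
  blank <- function(x) ifelse(x %in% c("?", "."), "", x)
  atoms_all <- data.frame(
    chain = blank(get("auth_asym_id", "label_asym_id")),
    number = as.integer(blank(get("auth_seq_id", "label_seq_id"))),
    icode = blank(get("pdbx_PDB_ins_code")),
    resname = blank(get("auth_comp_id", "label_comp_id")),
    elety = blank(get("auth_atom_id", "label_atom_id")),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    model_num = blank(get("pdbx_PDB_model_num")),
    stringsAsFactors = FALSE)
  atoms_all$model_num[atoms_all$model_num == ""] <- "1"
  model_nums <- unique(atoms_all$model_num)
  lapply(seq_along(model_nums), function(k) {
    atoms <- atoms_all[atoms_all$model_num == model_nums[k], , drop = FALSE]
    n_raw <- nrow(atoms)
    atoms$model_num <- NULL
    finalize_atoms(atoms, path,
                   model_id = if (length(model_nums) > 1L)
                                sprintf("%s#%d", stem, k) else stem,
                   n_atoms_raw = n_raw)
  })
}

# keep nucleotide residues, map modified bases, flag unknowns
finalize_atoms <- function(atoms, path, model_id, n_atoms_raw) {
  base <- map_base(atoms$resname)
  rid <- paste(atoms$chain, atoms$number, atoms$icode, sep = "\r")
  has_c1 <- rid %in% rid[atoms$elety == "C1'"]
  unknown <- is.na(base) & has_c1
  if (any(unknown)) {
    warning(sprintf(
      "%s (%s): %d residue(s) with unmappable name(s) %s kept with base 'N'",
      basename(path), model_id, length(unique(rid[unknown])),
      paste(unique(atoms$resname[unknown]), collapse = ", ")),
      call. = FALSE)
    base[unknown] <- "N"
  }
  keep <- !is.na(base)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$base <- base[keep]
  if (nrow(atoms) == 0L) {
    stop_rnac("parse_error", "no nucleotide residues in '%s' (%s)",
              path, model_id)
  }
  rownames(atoms) <- NULL
  new_structure_model(model_id, atoms, n_atoms_raw = n_atoms_raw)
}

# ---- ensemble loading --------------------------------------------------

#' Load an ensemble of RNA 3D structures
#'
#' Reads one or more PDB / PDBx-mmCIF files, directories, or ZIP / TAR.GZ
#' archives (unpacked automatically, one nesting level).  Multi-model files
#' are split into one structure per MODEL record.  Format is detected from
#' file content with the extension as fallback.
#'
#' @param paths Character vector of file, directory, or archive paths.
#' @return List of structure models (`rna_model`), with unique model ids
#'   (`stem` for single-model files, `stem#k` for MODEL record `k`; `_1`,
#'   `_2`, ... appended on clashes).
#' @export
load_ensemble <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_rnac("io_error", "no such file: %s", paste(missing, collapse = ", "))
  }
  models <- list()
  read_one <- function(path, from_archive) {
    stem <- tools::file_path_sans_ext(basename(path))
    fmt <- detect_format(path)
    if (is.na(fmt)) {
      if (from_archive) {
        warning(sprintf("skipping non-structure file '%s'", basename(path)),
                call. = FALSE)
        return(list())
      }
      stop_rnac("parse_error",
                "'%s' is neither PDB nor PDBx/mmCIF", path)
    }
    if (fmt == "pdb") read_pdb_models(path, stem) else
      read_cif_models(path, stem)
  }
  for (path in paths) {
    if (dir.exists(path)) {
      files <- list.files(path, full.names = TRUE)
      for (f in files) models <- c(models, read_one(f, from_archive = TRUE))
      next
    }
    arc <- is_archive(path)
    if (!is.na(arc)) {
      exdir <- tempfile("ensemble_")
      dir.create(exdir)
      if (arc == "zip") utils::unzip(path, exdir = exdir)
      else utils::untar(path, exdir = exdir)
      members <- list.files(exdir, full.names = TRUE, recursive = TRUE)
      for (f in members) models <- c(models, read_one(f, from_archive = TRUE))
      next
    }
    models <- c(models, read_one(path, from_archive = FALSE))
  }
  if (!length(models)) {
    stop_rnac("empty_ensemble", "no structure models found in input")
  }
  # enforce unique model ids
  ids <- vapply(models, function(m) m$model_id, "")
  if (anyDuplicated(ids)) {
    seen <- new.env(parent = emptyenv())
    for (k in seq_along(models)) {
      id <- ids[k]
      n <- (get0(id, envir = seen) %||% 0L)
      assign(id, n + 1L, envir = seen)
      if (n > 0L || sum(ids == id) > 1L) {
        models[[k]]$model_id <- sprintf("%s_%d", id, n + 1L)
      }
    }
  }
  models
}

# ---- unification -------------------------------------------------------

#' Unify chain names and residue numbering across an ensemble
#'
#' Within each model, chains are renamed `A, B, C, ...` (62-symbol alphabet:
#' uppercase, lowercase, digits) in order of first appearance, residues are
#' renumbered `1..k` per chain preserving order, and insertion codes are
#' cleared.  Coordinates are untouched.  The old-to-new identifier mapping is
#' kept in attribute `"unification_map"` of each model.  Idempotent.
#'
#' @param models List of `rna_model` objects.
#' @return List of unified `rna_model` objects.
#' @export
unify_ensemble <- function(models) {
  stopifnot(length(models) >= 1L)
  lapply(models, function(m) {
    atoms <- m$atoms
    old_chains <- unique(atoms$chain)
    alphabet <- chain_alphabet()
    if (length(old_chains) > length(alphabet)) {
      stop_rnac("limit_error",
                "model '%s' has %d chains; chain alphabet holds 62",
                m$model_id, length(old_chains))
    }
    new_chain <- stats::setNames(alphabet[seq_along(old_chains)], old_chains)
    rid <- paste(atoms$chain, atoms$number, atoms$icode, sep = "\r")
    res_first <- !duplicated(rid)
    res <- data.frame(rid = rid[res_first], chain = atoms$chain[res_first],
                      number = atoms$number[res_first],
                      icode = atoms$icode[res_first],
                      stringsAsFactors = FALSE)
    new_number <- integer(nrow(res))
    for (ch in old_chains) {
      in_ch <- res$chain == ch
      new_number[in_ch] <- seq_len(sum(in_ch))
    }
    map <- data.frame(model_id = m$model_id, old_chain = res$chain,
                      old_number = res$number, old_icode = res$icode,
                      new_chain = unname(new_chain[res$chain]),
                      new_number = new_number, stringsAsFactors = FALSE)
    idx <- match(rid, res$rid)
    atoms$chain <- map$new_chain[idx]
    atoms$number <- map$new_number[idx]
    atoms$icode <- ""
    atoms <- atoms[order(atoms$chain, atoms$number), , drop = FALSE]
    rownames(atoms) <- NULL
    out <- new_structure_model(m$model_id, atoms,
                               n_atoms_raw = m$n_atoms_raw)
    attr(out, "unification_map") <- map
    out
  })
}

# ---- consistency -------------------------------------------------------

#' Check nucleotide-composition consistency of an ensemble
#'
#' All models must have identical chain counts, per-chain lengths, and
#' per-chain base sequences (after unification).  Coordinates never
#' participate in this check.
#'
#' @param models List of unified `rna_model` objects.
#' @return A `consistency_report`: list with `consistent` (logical),
#'   `signatures` (data frame `model_id`, `signature`), and `divergent`
#'   (data frame `model_id`, `position` of the first diverging base in the
#'   concatenated sequence; `NA` position for chain-layout mismatches).
#' @export
check_consistency <- function(models) {
  stopifnot(length(models) >= 1L)
  sig_of <- function(m) {
    r <- m$residues
    chains <- unique(r$chain)
    paste(vapply(chains, function(ch)
      paste0(r$base[r$chain == ch], collapse = ""), ""), collapse = "/")
  }
  sigs <- vapply(models, sig_of, "")
  ids <- vapply(models, function(m) m$model_id, "")
  ref <- sigs[1L]
  divergent <- list()
  for (k in seq_along(sigs)[-1L]) {
    if (sigs[k] == ref) next
    a <- strsplit(gsub("/", "", ref), "")[[1L]]
    b <- strsplit(gsub("/", "", sigs[k]), "")[[1L]]
    n <- min(length(a), length(b))
    pos <- which(a[seq_len(n)] != b[seq_len(n)])[1L]
    if (is.na(pos) && length(a) != length(b)) pos <- n + 1L
    layout_a <- nchar(strsplit(ref, "/")[[1L]])
    layout_b <- nchar(strsplit(sigs[k], "/")[[1L]])
    if (length(layout_a) != length(layout_b)) pos <- NA_integer_
    divergent[[length(divergent) + 1L]] <-
      data.frame(model_id = ids[k], position = pos,
                 stringsAsFactors = FALSE)
  }
  divergent <- if (length(divergent)) do.call(rbind, divergent) else
    data.frame(model_id = character(), position = integer())
  rep <- list(consistent = nrow(divergent) == 0L,
              signatures = data.frame(model_id = ids, signature = sigs,
                                      stringsAsFactors = FALSE),
              divergent = divergent)
  class(rep) <- "consistency_report"
  rep
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %s\n",
              if (x$consistent) "consistent" else "INCONSISTENT"))
  if (!x$consistent) print.data.frame(x$divergent)
  invisible(x)
}

# ---- PDB format limits -------------------------------------------------

#' Check PDB format capacity limits
#'
#' The legacy PDB format caps a model at 99,999 atoms, 9,999 residues, and 62
#' chain identifiers.  All violations are reported, not only the first; the
#' boundaries themselves are allowed.  Atom count uses the number of atom
#' records as written in the source file when available (ions and
#' heteroatoms included).
#'
#' @param model An `rna_model`.
#' @return Character vector of violation messages; `character(0)` if ok.
#' @export
check_pdb_limits <- function(model) {
  v <- character()
  n_atoms <- model$n_atoms_raw %||% nrow(model$atoms)
  if (n_atoms > 99999L) {
    v <- c(v, sprintf("atom count %d exceeds 99,999", n_atoms))
  }
  n_res <- nrow(model$residues)
  if (n_res > 9999L) {
    v <- c(v, sprintf("residue count %d exceeds 9,999", n_res))
  }
  n_ch <- length(unique(model$residues$chain))
  if (n_ch > 62L) v <- c(v, sprintf("chain count %d exceeds 62", n_ch))
  v
}

# ---- writers -----------------------------------------------------------

#' Write a structure model as a single-model PDB file
#'
#' @param model An `rna_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  name <- ifelse(nchar(at$elety) >= 4L, substr(at$elety, 1L, 4L),
                 sprintf(" %-3s", at$elety))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(at)), name, at$resname, at$chain, at$number,
    ifelse(nzchar(at$icode), at$icode, " "), at$x, at$y, at$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the unification mapping of an ensemble as CSV
#'
#' Columns: `model_id, old_chain, old_number, old_icode, new_chain,
#' new_number`.
#'
#' @param models List of unified models (from [unify_ensemble()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unification_map <- function(models, path) {
  maps <- lapply(models, attr, "unification_map")
  if (any(vapply(maps, is.null, TRUE))) {
    stop_rnac("io_error", "models carry no unification map; run unify_ensemble first")
  }
  utils::write.csv(do.call(rbind, maps), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
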