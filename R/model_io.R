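# Coordinate-file parsing into a typed chain/residue/atom hierarchy.
#
# PDB record parsing is delegated to bio3d; this module owns the hierarchy,
# the altloc collapse rule, amino-acid classification, and the resolution
# header scan.

#' Read a coordinate file into a structure hierarchy
#'
#' Parses a PDB file into a `StructureModel`: an ordered list of chains, each
#' an ordered list of residues, each holding an atom table with B-factors,
#' occupancies, and proton numbers. Only the first MODEL block of a
#' multi-model file is used. Alternate locations are collapsed to a single
#' conformer per atom: the highest occupancy wins, ties go to file order.
#'
#' @param path path to a PDB file.
#' @param include_hydrogens logical; hydrogens are always parsed, this flag is
#'   stored on the model and controls whether downstream aggregation
#'   (B-factor and density-fit summaries) includes them. Default `FALSE`.
#' @param aa_allow extra residue names (beyond the 20 canonical codes) to be
#'   treated as amino acids, e.g. `"MSE"`.
#' @return an object of class `StructureModel` with elements `chains`
#'   (list of `Chain`), `resolution` (Angstrom, `NA` if the file has no
#'   REMARK 2 record), `source_path`, and `include_hydrogens`.
#' @export
#' @examples
#' pdb <- synthetic_model(fixture_spec(n_residues = 3))$path
#' mod <- read_model(pdb)
#' length(mod$chains[[1]]$residues)
read_model <- function(path, include_hydrogens = FALSE, aa_allow = character()) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error in coordinate file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model: no ATOM/HETATM records in ", path)

  elem <- as.character(at$elesy)
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- element_from_name(as.character(at$elety)[blank])

  atoms <- data.frame(
    name = trimws(as.character(at$elety)),
    element = toupper(trimws(elem)),
    proton = proton_number(elem),
    x = at$x, y = at$y, z = at$z,
    b = at$b,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "?", "", trimws(as.character(at$alt))),
    stringsAsFactors = FALSE
  )
  atoms$chain <- ifelse(is.na(at$chain), " ", as.character(at$chain))
  atoms$resno <- at$resno
  atoms$icode <- ifelse(is.na(at$insert) | at$insert == "?", "",
                        trimws(as.character(at$insert)))
  atoms$resid <- toupper(trimws(as.character(at$resid)))
  atoms$file_order <- seq_len(nrow(atoms))

  atoms <- collapse_altlocs(atoms)

  chains <- list()
  for (cid in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == cid, , drop = FALSE]
    key <- paste(ca$resno, ca$icode, sep = "\r")
    residues <- lapply(unique(key), function(k) {
      ra <- ca[key == k, , drop = FALSE]
      res <- list(
        seq_num = ra$resno[1],
        insertion_code = ra$icode[1],
        name = ra$resid[1],
        atoms = ra[, c("name", "element", "proton", "x", "y", "z", "b",
                       "occupancy", "altloc")]
      )
      res$is_amino_acid <- is_amino_acid(res, aa_allow = aa_allow)
      class(res) <- "Residue"
      res
    })
    ch <- list(chain_id = cid, residues = residues)
    class(ch) <- "Chain"
    chains[[length(chains) + 1L]] <- ch
  }

  model <- list(
    chains = chains,
    resolution = scan_resolution(path),
    source_path = path,
    include_hydrogens = include_hydrogens,
    aa_allow = aa_allow
  )
  class(model) <- "StructureModel"
  model
}

# Keep, per (chain, residue, atom name), the conformer with the highest
# occupancy; ties resolve to the earliest file position.
collapse_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$file_order)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$file_order), , drop = FALSE]
}

scan_resolution <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  tail_part <- sub("^.*RESOLUTION\\.?", "", rem[1])
  m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' Decide whether a residue is an analyzable amino acid
#'
#' True iff the residue name is one of the 20 canonical three-letter codes
#' (or on the caller's allow-list) and the backbone atoms N, CA, and C are all
#' present. A pure function of the residue name and atom-name set.
#'
#' @param residue a `Residue`.
#' @param aa_allow extra residue names accepted as amino acids.
#' @return logical scalar.
#' @export
is_amino_acid <- function(residue, aa_allow = character()) {
  nm <- toupper(residue$name)
  if (!(nm %in% c(.standard_aa, toupper(aa_allow)))) return(FALSE)
  all(c("N", "CA", "C") %in% residue$atoms$name)
}

# Atoms used for aggregation: hydrogens dropped unless the model asked for them.
included_atoms <- function(residue, include_hydrogens = FALSE) {
  a <- residue$atoms
  if (!include_hydrogens) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a
}

# Coordinates of a named atom within a residue, or NULL when absent.
atom_xyz <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(residue$atoms[i, c("x", "y", "z")])
}

#' @export
print.StructureModel <- function(x, ...) {
  nres <- vapply(x$chains, function(ch) length(ch$residues), integer(1))
  cat("StructureModel:", basename(x$source_path %||% "<in memory>"), "\n")
  cat("  chains:", paste(sprintf("%s (%d res)",
                                 vapply(x$chains, `[[`, "", "chain_id"), nres),
                         collapse = ", "), "\n")
  cat("  resolution:", if (is.na(x$resolution)) "unknown"
      else sprintf("%.2f A", x$resolution), "\n")
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' Non-standard residues map to `"X"`.
#' @param chain a `Chain`.
#' @return character scalar.
#' @export
chain_sequence <- function(chain) {
  paste(one_letter_code(vapply(chain$residues, `[[`, "", "name")), collapse = "")
}
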