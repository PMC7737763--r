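# Assembly of the full per-residue metrics bundle: the cascade that walks the
# chain/residue hierarchy and collects B-factor statistics, backbone and
# side-chain conformation scores, density fit, and percentiles into one
# data frame per chain (the report's unit of display).

# Standard chi torsion atom quadruples for the 20 canonical types.
.chi_atoms <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

#' Measure the chi torsions of a residue
#'
#' @param residue a `Residue`.
#' @return numeric vector of chi angles in degrees (`NA` where a defining
#'   atom is missing); zero-length for residue types without chi torsions
#'   (GLY, ALA) or non-standard residues.
#' @export
measure_chis <- function(residue) {
  quads <- .chi_atoms[[toupper(residue$name)]]
  if (is.null(quads)) return(numeric(0))
  vapply(quads, function(q) {
    pts <- lapply(q, function(a) atom_xyz(residue, a))
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
}

#' Default (synthetic) reference data bundle
#'
#' Ramachandran tables, rotamer central values, and decompressed contour
#' grids from [synthetic_rotamer_reference()]. These are demonstration
#' references with planted basins, not fitted to any structural corpus; for
#' production use load real tables via the file readers and pass them in the
#' same bundle shape.
#'
#' @param seed RNG seed forwarded to the generator.
#' @return list with `rama_tables`, `central_values`, `grids`,
#'   `rama_thresholds`.
#' @export
default_reference_data <- function(seed = 1) {
  key <- as.character(seed)
  cached <- .refdata_cache[[key]]
  if (!is.null(cached)) return(cached)
  ref <- synthetic_rotamer_reference(seed)
  out <- list(rama_tables = ref$rama_tables,
              central_values = ref$central_values,
              grids = ref$grids,
              rama_thresholds = c(favored_min = 0.02, allowed_min = 0.002))
  .refdata_cache[[key]] <- out
  out
}

.refdata_cache <- new.env(parent = emptyenv())

#' Per-residue metrics for one chain
#'
#' Runs every metric over the chain's amino-acid residues. Non-amino-acid
#' monomers are skipped (they carry no row). Missing ingredients degrade
#' gracefully: without a map the fit columns are `NA`; residue types absent
#' from the reference libraries classify `"unknown"`.
#'
#' @param chain a `Chain`.
#' @param refdata reference bundle as from [default_reference_data()].
#' @param map a `DensityMap` or `NULL`.
#' @param percentile_lib a `PercentileLibrary` or `NULL`.
#' @param resolution model resolution (Angstrom) used for percentile routing;
#'   `NA` falls back to the library's all-data entry.
#' @param include_hydrogens include hydrogens in aggregations.
#' @return data frame, one row per amino-acid residue.
#' @export
chain_metrics <- function(chain, refdata = default_reference_data(),
                          map = NULL, percentile_lib = NULL,
                          resolution = NA_real_, include_hydrogens = FALSE) {
  keep <- which(vapply(chain$residues, function(r) isTRUE(r$is_amino_acid),
                       logical(1)))
  rows <- lapply(keep, function(i) {
    res <- chain$residues[[i]]
    bf <- bfactor_summary(res, include_hydrogens)
    tor <- backbone_torsions(chain, i)

    nxt <- if (i < length(chain$residues)) chain$residues[[i + 1]]$name
           else NA_character_
    cat <- rama_category(res$name, nxt)
    rt <- refdata$rama_tables[[cat]] %||% refdata$rama_tables[["general"]]
    rp <- if (!is.null(rt)) rama_probability(tor["phi"], tor["psi"], rt)
          else NA_real_
    rc <- rama_classify(if (is.na(rp)) NA else rp, refdata$rama_thresholds)

    chis <- measure_chis(res)
    rot_score <- NA_real_
    rot_class <- "unknown"
    rot_flag <- ""
    if (length(chis) == 0L) {
      rot_flag <- "no_chi"
    } else if (anyNA(chis)) {
      rot_flag <- "incomplete"
    } else {
      cv <- refdata$central_values[[toupper(res$name)]]
      if (!is.null(cv)) {
        sc <- rotamer_score(chis, cv)
        if (inherits(sc, "chi_mismatch")) rot_flag <- "chi_mismatch"
        else rot_score <- sc
      }
      grid <- refdata$grids[[toupper(res$name)]]
      if (!is.null(grid) && length(chis) == grid$n_dims)
        rot_class <- classify_rotamer(chis, grid)
      if (is.null(cv) && is.null(grid)) rot_flag <- "no_reference"
    }

    fit <- if (!is.null(map)) residue_fit_scores(res, map, include_hydrogens)
           else list(all_atoms = NA_real_, backbone = NA_real_,
                     side_chain = NA_real_)

    data.frame(chain = chain$chain_id, seq_num = res$seq_num,
               icode = res$insertion_code, name = res$name,
               b_min = bf$minimum, b_max = bf$maximum, b_mean = bf$mean,
               b_sd = bf$sd,
               phi = unname(tor["phi"]), psi = unname(tor["psi"]),
               rama_prob = rp, rama_class = rc,
               rot_score = rot_score, rot_class = rot_class,
               rot_flag = rot_flag,
               fit_all = fit$all_atoms, fit_backbone = fit$backbone,
               fit_side = fit$side_chain,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    utils::read.csv(text = paste(
      "chain,seq_num,icode,name,b_min,b_max,b_mean,b_sd,phi,psi,rama_prob,",
      "rama_class,rot_score,rot_class,rot_flag,fit_all,fit_backbone,fit_side",
      sep = ""))
  if (!is.null(percentile_lib) && nrow(out)) {
    for (m in c("b_mean", "b_max", "fit_all", "fit_side", "rama_prob",
                "rot_score")) {
      if (!(m %in% percentile_lib$metadata$metrics)) next
      out[[paste0("pct_", m)]] <- vapply(out[[m]], function(v) {
        as.integer(display_percentile(percentile_lib, m, v, resolution))
      }, integer(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-residue metrics for a whole model
#'
#' @param model a `StructureModel`.
#' @inheritParams chain_metrics
#' @return named list of per-chain metrics data frames (chains with no
#'   amino-acid residues are dropped).
#' @export
model_metrics <- function(model, refdata = default_reference_data(),
                          map = NULL, percentile_lib = NULL) {
  out <- list()
  for (ch in model$chains) {
    df <- chain_metrics(ch, refdata = refdata, map = map,
                        percentile_lib = percentile_lib,
                        resolution = model$resolution,
                        include_hydrogens = isTRUE(model$include_hydrogens))
    if (nrow(df)) out[[ch$chain_id]] <- df
  }
  out
}
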