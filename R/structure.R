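#' Load a protein chain and its hetero ligands from a structure file
#'
#' Reads a PDB or mmCIF file through \pkg{bio3d} and keeps the protein atoms
#' of the requested chain together with all hetero (ligand) atoms in the
#' file. Alternate locations are collapsed to the highest-occupancy
#' conformer per atom; insertion codes are rejected because downstream
#' residue arithmetic assumes plain integer numbering.
#'
#' @param path a `.pdb` or `.cif` file.
#' @param chain one-letter chain identifier holding the subunit of interest.
#' @return A `structure_model`: a data frame of atoms (`chain`, `resno`,
#'   `resid`, `elety`, `x`, `y`, `z`, `elesy`, `type`) plus the source label.
#' @export
load_structure <- function(path, chain) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    pdb = bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    ent = bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    cif = bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    stop("unreadable structure format '.", ext, "' (expected .pdb or .cif)")
  )
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!chain %in% chains) {
    stop("chain '", chain, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  }
  keep <- (at$type == "ATOM" & at$chain == chain) | at$type == "HETATM"
  at <- at[keep, , drop = FALSE]
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(ins))) {
    stop("insertion codes present (e.g. residue ",
         at$resno[which(!is.na(ins) & nzchar(ins))[1]],
         "); renumber the structure before use")
  }
  at <- collapse_altloc(at)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ", path)
  }
  structure(
    list(atoms = at[, c("type", "chain", "resno", "resid", "elety",
                        "x", "y", "z", "elesy")],
         chain = chain, source = basename(path)),
    class = "structure_model"
  )
}

collapse_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(at)
  has_alt <- !is.na(alt) & nzchar(alt)
  if (!any(has_alt)) return(at)
  occ <- at$o
  if (is.null(occ) || all(is.na(occ))) occ <- rep(1, nrow(at))
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  np <- sum(x$atoms$type == "ATOM")
  nh <- sum(x$atoms$type == "HETATM")
  cat(sprintf("<structure_model> %s chain %s: %d protein atoms, %d hetero atoms\n",
              x$source, x$chain, np, nh))
  invisible(x)
}

#' Cofactor atom selector
#'
#' Cofactors are selected by their deposited hetero residue names (`FMN` for
#' flavin mononucleotide, `SF4` for a 4Fe-4S cluster), optionally restricted
#' to a chain. Selection by residue name rather than element follows the
#' convention of measuring to the nearest atom of the whole cofactor.
#'
#' @param residue_names character vector of hetero residue names.
#' @param chain optional chain restriction (`NA` = any chain).
#' @return A `ligand_selector`.
#' @export
ligand_selector <- function(residue_names, chain = NA_character_) {
  residue_names <- as.character(residue_names)
  if (length(residue_names) == 0L) stop("residue_names must be non-empty")
  structure(list(residue_names = residue_names, chain = chain),
            class = "ligand_selector")
}

# Ligand atoms matching a selector. When the file holds several copies of a
# cofactor (the intact complex carries eight FeS clusters besides N3),
# policy "nearest" keeps only the copy closest to the selected protein
# chain so a cluster from another subunit cannot shadow the local one.
select_ligand_atoms <- function(s, sel, copy_policy = c("nearest", "all")) {
  copy_policy <- match.arg(copy_policy)
  at <- s$atoms
  lig <- at[at$type == "HETATM" & at$resid %in% sel$residue_names, , drop = FALSE]
  if (!is.na(sel$chain)) lig <- lig[lig$chain == sel$chain, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop("no ligand atoms match selector (", paste(sel$residue_names, collapse = ","),
         if (!is.na(sel$chain)) paste0(", chain ", sel$chain) else "", ")")
  }
  copy <- paste(lig$chain, lig$resid, lig$resno, sep = "\r")
  if (copy_policy == "all" || length(unique(copy)) == 1L) return(lig)
  prot <- at[at$type == "ATOM" & at$chain == s$chain, , drop = FALSE]
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  dmin <- vapply(split(seq_len(nrow(lig)), copy), function(idx) {
    lxyz <- as.matrix(lig[idx, c("x", "y", "z")])
    min(vapply(seq_len(nrow(lxyz)), function(i) {
      min(sqrt(colSums((t(pxyz) - lxyz[i, ])^2)))
    }, numeric(1)))
  }, numeric(1))
  lig[copy == names(which.min(dmin)), , drop = FALSE]
}

#' Minimum distance from a residue's C-alpha to a cofactor
#'
#' Returns the minimum Euclidean center-to-center distance in Angstrom from
#' the C-alpha atom of the given residue (in the model's protein chain) to
#' any atom of the selected cofactor. Hydrogens, if deposited, participate
#' like any other cofactor atom.
#'
#' @param s a `structure_model` from [load_structure()].
#' @param residue residue number in the structure's own (mature) numbering.
#' @param sel a [ligand_selector()].
#' @param copy_policy `"nearest"` (default) keeps the cofactor copy nearest
#'   the protein chain when several are present; `"all"` uses every copy.
#' @return Distance in Angstrom (numeric scalar).
#' @export
min_distance_to_ligand <- function(s, residue, sel,
                                   copy_policy = c("nearest", "all")) {
  stopifnot(inherits(s, "structure_model"), inherits(sel, "ligand_selector"))
  at <- s$atoms
  ca <- at[at$type == "ATOM" & at$chain == s$chain &
             at$resno == residue & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop("residue ", residue, " in chain ", s$chain, " has no CA atom")
  }
  lig <- select_ligand_atoms(s, sel, copy_policy)
  dx <- lig$x - ca$x[1]; dy <- lig$y - ca$y[1]; dz <- lig$z - ca$z[1]
  min(sqrt(dx * dx + dy * dy + dz * dz))
}

#' Per-residue distance profile to the flavin and FeS cofactors
#'
#' One row per protein residue possessing a C-alpha, ordered by residue
#' number, giving the minimum C-alpha distance to each cofactor. This is the
#' all-residue profile used to place new variants relative to the FMN site
#' and cluster N3.
#'
#' @param s a `structure_model`.
#' @param sel_fmn,sel_fes [ligand_selector()]s for the flavin and the FeS
#'   cluster (defaults `FMN` and `SF4`).
#' @param copy_policy see [min_distance_to_ligand()].
#' @return A data frame with columns `residue`, `d_fmn`, `d_fes` (Angstrom,
#'   full precision).
#' @export
distance_profile <- function(s,
                             sel_fmn = ligand_selector("FMN"),
                             sel_fes = ligand_selector("SF4"),
                             copy_policy = c("nearest", "all")) {
  copy_policy <- match.arg(copy_policy)
  at <- s$atoms
  ca <- at[at$type == "ATOM" & at$chain == s$chain & at$elety == "CA", ,
           drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0L) stop("chain ", s$chain, " has no CA atoms")
  fmn <- select_ligand_atoms(s, sel_fmn, copy_policy)
  fes <- select_ligand_atoms(s, sel_fes, copy_policy)
  min_d <- function(lig, x, y, z) {
    min(sqrt((lig$x - x)^2 + (lig$y - y)^2 + (lig$z - z)^2))
  }
  data.frame(
    residue = ca$resno,
    d_fmn = vapply(seq_len(nrow(ca)), function(i)
      min_d(fmn, ca$x[i], ca$y[i], ca$z[i]), numeric(1)),
    d_fes = vapply(seq_len(nrow(ca)), function(i)
      min_d(fes, ca$x[i], ca$y[i], ca$z[i]), numeric(1))
  )
}

#' Write a distance profile as TSV
#'
#' Distances are printed to 0.1 Angstrom, the precision used in reports;
#' computations elsewhere always use full precision.
#'
#' @param profile data frame from [distance_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_profile <- function(profile, path) {
  out <- data.frame(residue = profile$residue,
                    d_fmn_A = sprintf("%.1f", profile$d_fmn),
                    d_fes_A = sprintf("%.1f", profile$d_fes))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
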