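#' Build PDB-format text for a synthetic structure
#'
#' Writes a minimal single-model PDB: one CA `ATOM` record per residue and
#' one `HETATM` record per ligand atom. Coordinates are emitted at the
#' format's 0.001 A precision, so a reload through [load_structure()]
#' reproduces them to 1e-3 A. Intended for geometry tests where cofactor
#' distances must be known by construction; it makes no attempt at
#' realistic protein geometry.
#'
#' @param residues data frame with columns `resno`, `x`, `y`, `z` and
#'   optionally `resid` (default `ALA`); one CA atom each.
#' @param ligands data frame with columns `resid` (e.g. `FMN`, `SF4`),
#'   `x`, `y`, `z` and optionally `resno`, `chain`, `elety`, `elesy`.
#' @param chain protein chain id.
#' @param altloc_duplicates if `TRUE`, each CA is written twice as altloc
#'   A (occupancy 0.6) and B (occupancy 0.4, shifted by 1 A in x), to
#'   exercise alternate-location collapsing.
#' @return Character scalar of PDB text.
#' @export
make_synthetic_structure <- function(residues, ligands, chain = "A",
                                     altloc_duplicates = FALSE) {
  stopifnot(nrow(residues) >= 1L, nrow(ligands) >= 1L)
  if (any(abs(c(residues$x, residues$y, residues$z,
                ligands$x, ligands$y, ligands$z)) >= 10000)) {
    stop("coordinates overflow the fixed-width PDB fields (|x| < 10000)")
  }
  resid <- if (is.null(residues$resid)) rep("ALA", nrow(residues)) else residues$resid
  lines <- character(0)
  serial <- 0L
  atom_line <- function(rec, serial, name, alt, resid, ch, resno, x, y, z, occ, ele) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, alt, resid, ch, resno, x, y, z, occ, 0, ele)
  }
  for (i in seq_len(nrow(residues))) {
    if (altloc_duplicates) {
      serial <- serial + 1L
      lines <- c(lines, atom_line("ATOM", serial, " CA ", "A", resid[i], chain,
                                  residues$resno[i], residues$x[i],
                                  residues$y[i], residues$z[i], 0.6, "C"))
      serial <- serial + 1L
      lines <- c(lines, atom_line("ATOM", serial, " CA ", "B", resid[i], chain,
                                  residues$resno[i], residues$x[i] + 1,
                                  residues$y[i], residues$z[i], 0.4, "C"))
    } else {
      serial <- serial + 1L
      lines <- c(lines, atom_line("ATOM", serial, " CA ", " ", resid[i], chain,
                                  residues$resno[i], residues$x[i],
                                  residues$y[i], residues$z[i], 1, "C"))
    }
  }
  lig_resno <- if (is.null(ligands$resno)) rep(900L, nrow(ligands)) else ligands$resno
  lig_chain <- if (is.null(ligands$chain)) rep(chain, nrow(ligands)) else ligands$chain
  lig_elety <- if (is.null(ligands$elety)) sprintf(" X%-2d", seq_len(nrow(ligands)) %% 100) else
    sprintf("%-4s", ligands$elety)
  lig_elesy <- if (is.null(ligands$elesy)) rep(" C", nrow(ligands)) else
    sprintf("%2s", ligands$elesy)
  for (j in seq_len(nrow(ligands))) {
    serial <- serial + 1L
    lines <- c(lines, atom_line("HETATM", serial, lig_elety[j], " ",
                                ligands$resid[j], lig_chain[j], lig_resno[j],
                                ligands$x[j], ligands$y[j], ligands$z[j], 1,
                                lig_elesy[j]))
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Write a synthetic structure to a temporary (or given) PDB file
#'
#' @inheritParams make_synthetic_structure
#' @param path output path (default: a tempfile ending in `.pdb`).
#' @return The path written.
#' @export
write_synthetic_structure <- function(residues, ligands, chain = "A",
                                      altloc_duplicates = FALSE,
                                      path = tempfile(fileext = ".pdb")) {
  cat(make_synthetic_structure(residues, ligands, chain, altloc_duplicates),
      file = path)
  path
}

#' Generate a random structure specification
#'
#' Residue CA positions and ligand atoms uniformly in a cube; used by the
#' geometry property tests to compare package distances against a
#' brute-force oracle computed directly from the spec coordinates.
#'
#' @param n_residues,n_ligand_atoms counts.
#' @param ligand_names hetero residue names to draw from.
#' @param box half-width of the coordinate cube, A.
#' @param seed RNG seed.
#' @return List with `residues` and `ligands` data frames.
#' @export
random_structure_spec <- function(n_residues = 10, n_ligand_atoms = 10,
                                  ligand_names = c("FMN", "SF4"),
                                  box = 30, seed = 1L) {
  set.seed(as.integer(seed))
  residues <- data.frame(
    resno = seq_len(n_residues),
    x = round(stats::runif(n_residues, -box, box), 3),
    y = round(stats::runif(n_residues, -box, box), 3),
    z = round(stats::runif(n_residues, -box, box), 3)
  )
  if (n_ligand_atoms < length(ligand_names)) {
    stop("need at least one ligand atom per requested ligand name")
  }
  # every requested cofactor name appears at least once
  resid <- c(ligand_names,
             sample(ligand_names, n_ligand_atoms - length(ligand_names),
                    replace = TRUE))
  ligands <- data.frame(
    resid = resid,
    x = round(stats::runif(n_ligand_atoms, -box, box), 3),
    y = round(stats::runif(n_ligand_atoms, -box, box), 3),
    z = round(stats::runif(n_ligand_atoms, -box, box), 3)
  )
  list(residues = residues, ligands = ligands)
}

#' Generate a clade-annotated MSA with prescribed conservation calls
#'
#' Builds an alignment whose per-column conservation call is guaranteed by
#' exact counting, not sampling: every member of the target clade carries
#' the reference residue, and all rows outside it carry a different
#' residue, so broader levels sit at their minimum possible fraction. The
#' construction errs out when a broader level could still exceed the
#' threshold (its cumulative size is too close to the target clade's), and
#' is deterministic for a fixed seed (the seed only chooses residue
#' letters).
#'
#' For a `"none"` column only the reference row itself carries the
#' reference residue.
#'
#' @param target_calls character vector, one call per column, each in
#'   `none`/`chordata`/`metazoa`/`eukaryota`/`all`.
#' @param n_chordata,n_metazoa,n_eukaryota,n_other rows per innermost clade
#'   label (the reference row counts toward `n_chordata`). Defaults mirror
#'   a 200-sequence alignment spread over the phylogenetic tree.
#' @param ref_id reference row id.
#' @param threshold conservation threshold the construction must respect.
#' @param seed RNG seed for residue letters.
#' @return List with `msa` (named character vector) and `clades`
#'   (`clade_table`).
#' @export
make_synthetic_msa <- function(target_calls,
                               n_chordata = 40, n_metazoa = 60,
                               n_eukaryota = 50, n_other = 50,
                               ref_id = "REF", threshold = 0.95,
                               seed = 1L) {
  stopifnot(all(target_calls %in% c("none", CLADE_LEVELS)),
            n_chordata >= 1, n_metazoa >= 0, n_eukaryota >= 0, n_other >= 0)
  set.seed(as.integer(seed))
  counts <- c(chordata = n_chordata, metazoa = n_metazoa,
              eukaryota = n_eukaryota, other = n_other)
  cum <- cumsum(counts) # cumulative sizes at each nested level
  names(cum) <- CLADE_LEVELS
  # feasibility: for target level k, broader level j holds cum[k] matches
  # out of cum[j] rows and must not exceed the threshold
  for (tc in unique(target_calls)) {
    k <- match(tc, CLADE_LEVELS)
    if (tc == "none") {
      if (1 / cum[[1]] > threshold) {
        stop("clade sizes too small for a 'none' column: need at least ",
             ceiling(1 / threshold), " chordate rows")
      }
    } else if (k < length(CLADE_LEVELS)) {
      for (j in seq(k + 1L, length(CLADE_LEVELS))) {
        if (cum[[k]] / cum[[j]] > threshold) {
          stop("cannot keep level '", CLADE_LEVELS[j], "' at or below the ",
               threshold, " threshold for target '", tc, "': need at least ",
               ceiling(cum[[k]] / threshold), " rows at that level")
        }
      }
    }
  }
  n <- sum(counts)
  ids <- c(ref_id, sprintf("seq%03d", seq_len(n - 1L)))
  labels <- rep(names(counts), counts)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ncol_ <- length(target_calls)
  mat <- matrix("", nrow = n, ncol = ncol_)
  ref_res <- character(ncol_)
  for (j in seq_len(ncol_)) {
    ref <- sample(aa20, 1)
    alt <- sample(setdiff(aa20, ref), 1)
    tc <- target_calls[j]
    k <- if (tc == "none") 0L else match(tc, CLADE_LEVELS)
    in_target <- if (k == 0L) c(TRUE, rep(FALSE, n - 1L)) else
      labels %in% names(counts)[seq_len(k)]
    mat[, j] <- ifelse(in_target, ref, alt)
    ref_res[j] <- ref
  }
  msa <- stats::setNames(apply(mat, 1, paste, collapse = ""), ids)
  list(msa = msa, clades = clade_table(stats::setNames(labels, ids)),
       ref_residues = ref_res)
}

#' The packaged variant reference table
#'
#' A machine-readable transcription of the characterization table for the
#' 19 clinically reported NDUFV1 missense variants: human variant label,
#' bovine structure residue, yeast mutation label, observed effect in the
#' yeast model, domain, C-alpha distances to the flavin and FeS cluster
#' (A), conservation call, and the published score and class.
#'
#' @return Data frame with 19 rows.
#' @export
reference_table <- function() {
  path <- system.file("extdata", "variant_reference_table.tsv",
                      package = "flavotriage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Variant labels of the packaged reference table
#'
#' @return Character vector of the 19 variant strings.
#' @export
reference_variants <- function() {
  reference_table()$variant
}

#' Human-to-yeast residue map derived from the packaged table
#'
#' Parses the human variant and yeast mutation labels of the reference
#' table into a [residue_map()] between human precursor and yeast precursor
#' numbering. Variants with no yeast counterpart (residue not conserved)
#' are simply absent from the map, so [map_position()] reports them as
#' unmapped.
#'
#' @return A `residue_map` (human-precursor -> yeast-precursor).
#' @export
table_yeast_map <- function() {
  tab <- reference_table()
  keep <- !is.na(tab$yeast_mutation)
  pos_h <- as.integer(sub("^[A-Z](\\d+)[A-Z]$", "\\1", tab$variant[keep]))
  pos_y <- as.integer(sub("^[A-Z](\\d+)[A-Z]$", "\\1", tab$yeast_mutation[keep]))
  ord <- order(pos_h)
  pos_h <- pos_h[ord]; pos_y <- pos_y[ord]
  keep2 <- !duplicated(pos_h) # R386C/R386H share a position
  residue_map(pos_h[keep2], pos_y[keep2], "human-precursor", "yeast-precursor")
}
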