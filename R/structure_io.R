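#' Read a protein-ligand complex structure
#'
#' Parses a PDB or mmCIF file into a `complex_structure`: a tidy atom table
#' split into polymer (protein) residues and heteroatom ligand candidates.
#' Nucleic-acid and other non-protein polymer residues are excluded from the
#' polymer set (they are never labelled); waters and every other HETATM
#' entity are kept as ligand candidates whose qualification is decided later
#' by [qualify_ligands()].
#'
#' Alternate locations are resolved by keeping, per atom, the conformer with
#' the highest occupancy (ties broken by alphabetical altloc, so 'A' wins).
#' Only the first model of a multi-model file is read.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` (default) or `"mmcif"`.
#' @param structure_id Identifier for the structure; defaults to the file
#'   base name.
#' @return A `complex_structure` object: a list with `structure_id`,
#'   `atoms` (tibble of all atoms with coordinates in Angstrom),
#'   `residues` (tibble of polymer residues in chain/number/insertion order)
#'   and `ligands` (tibble of heteroatom entities, one row per candidate,
#'   with `qualification` unset until [qualify_ligands()] runs).
#' @export
#' @examples
#' fx <- make_complex(fixture_spec(n_residues = 12, ligand_contacts = 5:6),
#'                    path = tempfile(fileext = ".pdb"))
#' s <- read_structure(fx$path)
#' s$residues
read_structure <- function(path, format = c("pdb", "mmcif"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path))
  }
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))

  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
    },
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )

  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste0("no atom records in '", path, "'"))
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z)) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))[1]
    abort(paste0("malformed coordinate field in '", path,
                 "' (atom record ", bad, ")"))
  }

  atoms <- tibble(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = trimws(at$elesy %|NA|% ""),
    x = at$x, y = at$y, z = at$z,
    chain = at$chain %|NA|% "",
    resnum = as.integer(at$resno),
    icode = trimws(at$insert %|NA|% ""),
    resname = toupper(trimws(at$resid)),
    occupancy = at$o %|NA|% 1,
    altloc = trimws(at$alt %|NA|% ""),
    is_hetero = at$type == "HETATM"
  )
  atoms$icode[is.na(atoms$icode)] <- ""

  # altloc resolution: highest occupancy, ties -> alphabetically first ('A')
  atoms <- atoms |>
    group_by(.data$chain, .data$resnum, .data$icode, .data$resname,
             .data$atom_name, .data$is_hetero) |>
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$serial)

  is_protein <- !atoms$is_hetero & atoms$resname %in% names(.AA3)
  atoms$entity_id <- ifelse(
    atoms$is_hetero,
    paste(atoms$chain, atoms$resnum, atoms$resname, sep = "_"),
    NA_character_
  )

  residues <- atoms[is_protein, ] |>
    distinct(.data$chain, .data$resnum, .data$icode, .data$resname) |>
    arrange(.data$chain, .data$resnum, .data$icode)
  if (nrow(residues) == 0) {
    abort(paste0("structure '", structure_id, "' has no polymer residues"))
  }

  ligands <- atoms[atoms$is_hetero, ] |>
    group_by(.data$entity_id) |>
    summarise(resname = .data$resname[1], n_atoms = n(), .groups = "drop") |>
    mutate(qualification = NA_character_)

  out <- list(
    structure_id = structure_id,
    atoms = mutate(atoms, is_protein = is_protein),
    residues = residues,
    ligands = ligands
  )
  class(out) <- "complex_structure"
  out
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", x$structure_id, "\n",
      "  polymer residues: ", nrow(x$residues),
      " (", length(unique(x$residues$chain)), " chain(s))\n",
      "  ligand candidates: ", nrow(x$ligands), "\n", sep = "")
  if (!all(is.na(x$ligands$qualification))) {
    print(table(x$ligands$qualification))
  }
  invisible(x)
}

protein_atoms <- function(s) s$atoms[s$atoms$is_protein, ]
ligand_atoms <- function(s, entity_id) {
  s$atoms[s$atoms$is_hetero & s$atoms$entity_id == entity_id, ]
}

# min distance from each protein atom set; returns the global minimum
# between two coordinate matrices
min_pair_dist <- function(a, b) {
  sqrt(min(outer_sqdist(a, b)))
}

outer_sqdist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m squared distances
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

coords <- function(df) as.matrix(df[, c("x", "y", "z")])

#' Qualify heteroatom entities as ligands
#'
#' Applies the three qualification rules to every ligand candidate of a
#' structure: a candidate is rejected if it is a water (HOH/WAT/DOD), if no
#' atom of it lies within `contact_cutoff` of any protein atom (no contact
#' with the protein surface), or if any of its atoms lies closer than
#' `covalent_cutoff` to a protein atom (covalently bound). Everything else
#' is `"qualified"`. An optional molecular-weight window can additionally
#' reject very small or very large entities by atom count proxy is not
#' attempted; instead `mw_range` filters on the summed atomic masses of the
#' entity when element symbols are available.
#'
#' @param s A `complex_structure` from [read_structure()].
#' @param contact_cutoff Maximum protein-ligand atom distance (Angstrom) for
#'   the entity to count as surface-contacting. Default 6.5.
#' @param covalent_cutoff Distance (Angstrom) below which a protein-ligand
#'   atom pair is treated as a covalent bond. Default 2.0.
#' @param mw_range Optional numeric length-2 vector; entities with estimated
#'   molecular weight outside the window are marked `"rejected_mw"`.
#'   Default `NULL` (no weight filter).
#' @return The structure with `ligands$qualification` filled in; one of
#'   `"qualified"`, `"rejected_water"`, `"rejected_no_contact"`,
#'   `"rejected_covalent"` (or `"rejected_mw"`).
#' @export
qualify_ligands <- function(s, contact_cutoff = 6.5, covalent_cutoff = 2.0,
                            mw_range = NULL) {
  stopifnot(inherits(s, "complex_structure"),
            contact_cutoff > 0, covalent_cutoff > 0)
  pa <- coords(protein_atoms(s))
  qual <- character(nrow(s$ligands))
  for (i in seq_len(nrow(s$ligands))) {
    lig <- s$ligands[i, ]
    if (lig$resname %in% .WATER_NAMES) {
      qual[i] <- "rejected_water"
      next
    }
    la <- ligand_atoms(s, lig$entity_id)
    if (!is.null(mw_range)) {
      mw <- sum(atomic_mass(la$element), na.rm = TRUE)
      if (mw < mw_range[1] || mw > mw_range[2]) {
        qual[i] <- "rejected_mw"
        next
      }
    }
    dmin <- min_pair_dist(pa, coords(la))
    qual[i] <- if (dmin < covalent_cutoff) {
      "rejected_covalent"
    } else if (dmin > contact_cutoff) {
      "rejected_no_contact"
    } else {
      "qualified"
    }
  }
  s$ligands$qualification <- qual
  s
}

atomic_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
         S = 32.06, F = 18.998, CL = 35.45, BR = 79.904, I = 126.9,
         FE = 55.845, ZN = 65.38, MG = 24.305, `NA` = 22.99, K = 39.098,
         CA = 40.078, MN = 54.938)
  out <- m[toupper(element)]
  out[is.na(out)] <- 12.011  # unknown elements counted as carbon
  unname(out)
}

#' Label binding-site residues for one qualified ligand
#'
#' A polymer residue is a binding-site residue (label 1) if at least one of
#' its atoms lies within `cutoff` Angstrom of any atom of the ligand; the
#' comparison is inclusive (a pair at exactly the cutoff counts as contact).
#' All atoms participate, hydrogens included when present.
#'
#' @param s A `complex_structure` whose ligands have been qualified.
#' @param entity_id Entity id of a qualified ligand (see `s$ligands`).
#' @param cutoff Contact distance in Angstrom; default 6.5.
#' @return A tibble of site labels, one row per polymer residue:
#'   `structure_id`, `chain`, `resnum`, `icode`, `resname`,
#'   `label` (1 = binding site, 0 = non-binding).
#' @export
extract_binding_sites <- function(s, entity_id, cutoff = 6.5) {
  stopifnot(inherits(s, "complex_structure"))
  lig <- s$ligands[s$ligands$entity_id == entity_id, ]
  if (nrow(lig) != 1) abort(paste0("unknown ligand entity '", entity_id, "'"))
  if (is.na(lig$qualification) || lig$qualification != "qualified") {
    abort(paste0("ligand '", entity_id, "' is not qualified (",
                 lig$qualification %|NA|% "unqualified",
                 "); run qualify_ligands() first"))
  }
  pa <- protein_atoms(s)
  la <- coords(ligand_atoms(s, entity_id))
  d2 <- outer_sqdist(coords(pa), la)
  atom_contact <- sqrt(apply(d2, 1, min)) <= cutoff

  pa |>
    mutate(contact = atom_contact) |>
    group_by(.data$chain, .data$resnum, .data$icode, .data$resname) |>
    summarise(label = as.integer(any(.data$contact)), .groups = "drop") |>
    arrange(.data$chain, .data$resnum, .data$icode) |>
    mutate(structure_id = s$structure_id, .before = 1)
}

#' Merge per-ligand site labels by logical OR
#'
#' A residue contacted by any of several qualified ligands of the same
#' structure is a binding-site residue.
#'
#' @param ... Site-label tibbles from [extract_binding_sites()], or a single
#'   list of them.
#' @return A single site-label tibble with the per-residue OR of the labels.
#' @export
merge_site_labels <- function(...) {
  labs <- list(...)
  if (length(labs) == 1 && is.list(labs[[1]]) && !is.data.frame(labs[[1]])) {
    labs <- labs[[1]]
  }
  stopifnot(length(labs) >= 1)
  ids <- unique(vapply(labs, function(x) x$structure_id[1], character(1)))
  if (length(ids) != 1) {
    abort(paste0("site labels come from different structures: ",
                 paste(ids, collapse = ", ")))
  }
  bind_rows(labs) |>
    group_by(.data$structure_id, .data$chain, .data$resnum, .data$icode,
             .data$resname) |>
    summarise(label = as.integer(any(.data$label == 1)), .groups = "drop") |>
    arrange(.data$chain, .data$resnum, .data$icode)
}

#' Label binding sites over all qualified ligands of a structure
#'
#' Convenience wrapper: qualifies ligands if needed, extracts per-ligand
#' labels and merges them.
#'
#' @inheritParams extract_binding_sites
#' @inheritParams qualify_ligands
#' @return Merged site-label tibble; `NULL` with a warning if the structure
#'   has no qualified ligand.
#' @export
label_binding_sites <- function(s, cutoff = 6.5, contact_cutoff = cutoff,
                                covalent_cutoff = 2.0) {
  if (all(is.na(s$ligands$qualification))) {
    s <- qualify_ligands(s, contact_cutoff = contact_cutoff,
                         covalent_cutoff = covalent_cutoff)
  }
  ok <- s$ligands$entity_id[s$ligands$qualification == "qualified"]
  if (length(ok) == 0) {
    warn(paste0("structure '", s$structure_id, "' has no qualified ligand"))
    return(NULL)
  }
  merge_site_labels(lapply(ok, function(e) {
    extract_binding_sites(s, e, cutoff = cutoff)
  }))
}

#' Write site labels as TSV
#'
#' @param labels Site-label tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
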