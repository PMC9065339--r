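#' Specification for a synthetic protein-ligand complex
#'
#' Describes a single-chain protein with a controllable backbone geometry
#' and a ligand placed so that a chosen residue set -- and only that set --
#' is within contact distance. The generator verifies the requested contact
#' set is geometrically achievable and errors otherwise.
#'
#' @param n_residues Number of residues; default 50.
#' @param geometry `"helix"` (ideal alpha-helix trace: 1.5 A rise, 100
#'   degree twist, 2.3 A C-alpha radius), `"extended"` (straight chain,
#'   3.8 A spacing) or `"random_coil"` (seeded random walk, 3.8 A steps).
#' @param ligand_contacts Integer indices (1-based) of residues the ligand
#'   must contact; may be empty.
#' @param ligand_offset Slack in Angstrom: contacted C-alphas sit at
#'   6.5 - `ligand_offset` from their ligand atom. Default 1.0.
#' @param n_ligand_atoms Ligand atom count; defaults to
#'   `max(1, length(ligand_contacts))`. Extra atoms are parked far from the
#'   protein.
#' @param seed Integer seed; default 1.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 50,
                         geometry = c("helix", "extended", "random_coil"),
                         ligand_contacts = integer(0), ligand_offset = 1.0,
                         n_ligand_atoms = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  ligand_contacts <- sort(unique(as.integer(ligand_contacts)))
  stopifnot(n_residues >= 2, ligand_offset > 0,
            all(ligand_contacts >= 1), all(ligand_contacts <= n_residues))
  structure(list(
    n_residues = as.integer(n_residues), geometry = geometry,
    ligand_contacts = ligand_contacts, ligand_offset = ligand_offset,
    n_ligand_atoms = as.integer(n_ligand_atoms %||%
                                  max(1, length(ligand_contacts))),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

backbone_coords <- function(spec) {
  n <- spec$n_residues
  i <- seq_len(n) - 1
  switch(spec$geometry,
    helix = {
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    extended = cbind(3.8 * i, 0 * i, 0 * i),
    random_coil = withr::with_seed(spec$seed, {
      # self-avoiding random walk: steps re-drawn while they land within
      # 3.5 A of an existing residue
      xyz <- matrix(0, n, 3)
      for (i in 2:n) {
        for (try in 1:100) {
          step <- stats::rnorm(3)
          cand <- xyz[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
          prev <- xyz[seq_len(i - 1), , drop = FALSE]
          if (min(sqrt(colSums((t(prev) - cand)^2))) > 3.5) break
        }
        xyz[i, ] <- cand
      }
      xyz
    })
  )
}

# residue cycle gives varied amino-acid composition, deterministic
.FIXTURE_RESNAMES <- names(.AA3)

#' Generate a synthetic protein-drug complex PDB file
#'
#' Writes a C-alpha-only protein chain plus a HETATM ligand positioned so
#' that exactly `spec$ligand_contacts` are binding-site residues at the
#' 6.5 A criterion: contacted C-alphas sit at 6.5 - `ligand_offset` A from
#' a ligand atom, every other residue is kept more than 7.0 A from all
#' ligand atoms. The ground-truth labels are returned alongside the file,
#' and the file is byte-identical for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param path Output PDB path.
#' @param structure_id Identifier written into the labels; defaults to the
#'   file base name.
#' @return List with `path`, `labels` (ground-truth site-label tibble) and
#'   `spec`.
#' @export
make_complex <- function(spec, path, structure_id = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))
  ca <- backbone_coords(spec)
  n <- spec$n_residues
  r_contact <- 6.5 - spec$ligand_offset
  stopifnot(r_contact > 0)

  lig <- matrix(numeric(0), ncol = 3)
  centroid <- colMeans(ca)
  outward <- function(idx) {
    # unit vector pointing away from the chain at residue idx
    switch(spec$geometry,
      helix = {                      # radially out from the helix axis (z)
        v <- c(ca[idx, 1:2], 0)
        v / sqrt(sum(v^2))
      },
      extended = c(0, 1, 0),         # chain runs along x
      random_coil = {
        # deterministic Fibonacci-sphere search: pick the direction whose
        # ligand position maximises clearance from the rest of the chain
        m <- 300
        i <- seq(0, m - 1)
        theta <- 2 * pi * i / ((1 + sqrt(5)) / 2)
        z <- 1 - (2 * i + 1) / m
        r <- sqrt(pmax(1 - z^2, 0))
        grid <- cbind(r * cos(theta), r * sin(theta), z)
        clear <- apply(grid, 1, function(u) {
          pos <- ca[idx, ] + r_contact * u
          min(sqrt(colSums((t(ca[-idx, , drop = FALSE]) - pos)^2)))
        })
        grid[which.max(clear), ]
      }
    )
  }
  for (idx in spec$ligand_contacts) {
    lig <- rbind(lig, ca[idx, ] + r_contact * outward(idx))
  }
  n_extra <- spec$n_ligand_atoms - nrow(lig)
  if (n_extra > 0) {
    far <- max(sqrt(rowSums(sweep(ca, 2, centroid)^2))) + 40
    extra <- cbind(centroid[1] + far + 3 * seq_len(n_extra),
                   centroid[2], centroid[3])
    lig <- rbind(lig, extra)
  }

  # feasibility: achieved contact set must equal the requested one
  if (nrow(lig) > 0) {
    d <- sqrt(outer_sqdist(ca, lig))
    dmin <- apply(d, 1, min)
    achieved <- which(dmin <= 6.5)
    non_contact <- setdiff(seq_len(n), spec$ligand_contacts)
    separated <- length(non_contact) == 0 || all(dmin[non_contact] > 7.0)
    if (!identical(achieved, spec$ligand_contacts) || !separated) {
      abort(paste0("contact set {",
                   paste(spec$ligand_contacts, collapse = ","),
                   "} is infeasible for geometry '", spec$geometry, "'"))
    }
  }

  resnames <- rep_len(.FIXTURE_RESNAMES, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("HEADER    SYNTHETIC COMPLEX %-42s", structure_id), con)
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, resnames[i], i, ca[i, 1], ca[i, 2], ca[i, 3]), con)
  }
  writeLines("TER", con)
  for (j in seq_len(nrow(lig))) {
    serial <- serial + 1L
    writeLines(sprintf(
      "HETATM%5d  C%-2d LIG L 900    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, j, lig[j, 1], lig[j, 2], lig[j, 3]), con)
  }
  writeLines("END", con)

  labels <- tibble(
    structure_id = structure_id,
    chain = "A",
    resnum = seq_len(n),
    icode = "",
    resname = resnames,
    label = as.integer(seq_len(n) %in% spec$ligand_contacts)
  )
  list(path = path, labels = labels, spec = spec)
}

#' Generate a synthetic PSI-BLAST ASCII PSSM file
#'
#' Integer log-odds drawn uniformly in \[-10, 12\], a valid header/footer,
#' parseable by [read_pssm()] and byte-identical for a fixed seed.
#'
#' @param length Sequence length (L > 0).
#' @param sequence Optional 1-letter sequence of length `length`; defaults
#'   to a seeded random sequence.
#' @param alphabet Column alphabet; default the PSI-BLAST order.
#' @param seed Integer seed.
#' @param path Output file.
#' @return List with `path` and the generated `pssm` object.
#' @export
make_pssm <- function(length, sequence = NULL, alphabet = NULL, seed = 1L,
                      path) {
  if (length <= 0) abort("PSSM length must be positive")
  alphabet <- alphabet %||% .PSSM_ALPHABET
  stopifnot(setequal(alphabet, .PSSM_ALPHABET))
  m <- withr::with_seed(seed, {
    sequence <- sequence %||%
      paste(sample(.PSSM_ALPHABET, length, replace = TRUE), collapse = "")
    scores <- matrix(sample(-10:12, length * 20, replace = TRUE),
                     nrow = length, ncol = 20,
                     dimnames = list(NULL, alphabet))
    structure(list(sequence = sequence, scores = scores,
                   column_order = alphabet), class = "pssm")
  })
  stopifnot(nchar(m$sequence) == length)
  write_pssm(m, path)
  list(path = path, pssm = m)
}

#' Generate a labelled synthetic classification set
#'
#' Emulates the class structure the feature analysis reports (binding-site
#' residues shifted upward in the informative columns): negatives are
#' N(0, `noise_sd`) in every feature column; positives are shifted by
#' `effect_size * noise_sd` in the `informative_columns` only.
#'
#' @param n_pos,n_neg Class sizes.
#' @param informative_columns Subset of [feature_columns()]; default the 7
#'   network topology columns.
#' @param effect_size Standardised mean shift (>= 0); default 3.
#' @param noise_sd Noise standard deviation; default 1.
#' @param seed Integer seed.
#' @return Feature-table tibble with residue-key plumbing columns, all 27
#'   feature columns and `label`.
#' @export
make_classification_set <- function(n_pos, n_neg,
                                    informative_columns =
                                      feature_columns("rin"),
                                    effect_size = 3, noise_sd = 1,
                                    seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, effect_size >= 0, noise_sd > 0,
            all(informative_columns %in% .FEATURE_COLS))
  n <- n_pos + n_neg
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * length(.FEATURE_COLS), sd = noise_sd),
                nrow = n, dimnames = list(NULL, .FEATURE_COLS))
    m[label == 1, informative_columns] <-
      m[label == 1, informative_columns] + effect_size * noise_sd
    m
  })
  bind_cols(
    tibble(structure_id = "synthetic", chain = "A", resnum = seq_len(n),
           icode = "", resname = rep_len(names(.AA3), n)),
    as_tibble(x),
    tibble(label = label)
  )
}
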