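#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: a header, one row per sequence
#' position carrying the position number, the query residue, 20 integer
#' log-odds scores, 20 weighted-percentage columns and two trailing
#' statistics, then footer statistics (K, lambda). Only the log-odds block
#' and the query sequence are captured; the percentage block and footer are
#' ignored.
#'
#' @param path Path to the PSSM file.
#' @return A `pssm` object: list with `sequence` (1-letter string),
#'   `scores` (L x 20 integer matrix, columns in the file's alphabet order)
#'   and `column_order` (the 20-letter alphabet).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  lines <- readLines(path, warn = FALSE)

  # the alphabet header line: 40 single letters
  hdr <- NULL
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 40 && all(nchar(f) == 1) &&
        all(f %in% c(LETTERS))) {
      hdr <- f
      hdr_i <- i
      break
    }
  }
  if (is.null(hdr)) abort(paste0("not a PSI-BLAST ASCII PSSM: '", path,
                                 "' (alphabet header line not found)"))
  alphabet <- hdr[1:20]

  seq_chars <- character(0)
  rows <- list()
  pos_expected <- 1L
  for (i in seq((hdr_i + 1), length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "") {
      if (length(rows)) break else next   # blank line ends the matrix block
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) {
      if (length(rows)) break
      abort(paste0("PSSM parse error at line ", i,
                   ": expected a position row"))
    }
    num <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (length(num) < 40 || anyNA(num[1:40])) {
      abort(paste0("PSSM parse error at line ", i, ": expected 40 numeric ",
                   "score fields, found ", sum(!is.na(num))))
    }
    seq_chars <- c(seq_chars, f[2])
    rows[[length(rows) + 1]] <- num[1:20]
    pos_expected <- pos_expected + 1L
  }
  if (length(rows) == 0) abort(paste0("empty PSSM matrix in '", path, "'"))

  scores <- do.call(rbind, rows)
  colnames(scores) <- alphabet
  out <- list(sequence = paste(seq_chars, collapse = ""),
              scores = scores, column_order = alphabet)
  class(out) <- "pssm"
  out
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> L = ", nrow(x$scores), ", alphabet ",
      paste(x$column_order, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Write a PSSM in PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_pssm()] parses back to an identical matrix
#' (round-trip property). The percentage block is filled with zeros and the
#' footer carries placeholder statistics.
#'
#' @param m A `pssm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(m, path) {
  stopifnot(inherits(m, "pssm"))
  ab <- m$column_order
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(ab, ab)), collapse = " "))
  ), con)
  seqc <- strsplit(m$sequence, "")[[1]]
  for (i in seq_len(nrow(m$scores))) {
    writeLines(paste0(
      sprintf("%5d %s ", i, seqc[i]),
      paste(sprintf("%3d", m$scores[i, ]), collapse = " "), " ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      sprintf("  %4.2f %8.2f", 0, 0)
    ), con)
  }
  writeLines(c(
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1337     0.3180",
    "Standard Gapped      0.0410     0.2670",
    "PSI Ungapped         0.1337     0.3180",
    "PSI Gapped           0.0410     0.2670"
  ), con)
  invisible(path)
}

#' Encode a PSSM as per-residue feature vectors
#'
#' One row per sequence position, 20 feature columns in the fixed
#' alphabetical order of `feature_columns("pssm")`. `"raw"` keeps the
#' log-odds values; `"sigmoid"` maps each score through 1 / (1 + exp(-P)),
#' bounding the features in (0, 1).
#'
#' @param m A `pssm` object.
#' @param scaling `"raw"` (default) or `"sigmoid"`.
#' @return A tibble with `position`, `residue` and the 20 `pssm_*` columns.
#' @export
encode_pssm <- function(m, scaling = c("raw", "sigmoid")) {
  stopifnot(inherits(m, "pssm"))
  scaling <- match.arg(scaling)
  sc <- m$scores[, sort(m$column_order), drop = FALSE]
  if (scaling == "sigmoid") sc <- 1 / (1 + exp(-sc))
  colnames(sc) <- paste0("pssm_", colnames(sc))
  bind_cols(
    tibble(position = seq_len(nrow(sc)),
           residue = strsplit(m$sequence, "")[[1]]),
    as_tibble(sc)
  )
}

#' Align a PSSM to a structure chain
#'
#' Maps PSSM rows (sequence positions) to the observed residues of one chain
#' of a structure. When the PSSM sequence and the chain's observed sequence
#' are identical the mapping is positional; otherwise a local alignment
#' (Smith-Waterman via Biostrings) matches them, and structure residues that
#' align to a PSSM position with matching residue type receive that row.
#' Fails if the aligned-region identity is below `min_identity`.
#'
#' @param m A `pssm` object.
#' @param s A `complex_structure`.
#' @param chain Chain identifier present in the structure.
#' @param min_identity Minimum fractional identity of the aligned region;
#'   default 0.95.
#' @return A tibble mapping residues to PSSM rows: `chain`, `resnum`,
#'   `icode`, `resname`, `pssm_row` (NA for unmatched residues).
#' @export
align_pssm_to_structure <- function(m, s, chain, min_identity = 0.95) {
  stopifnot(inherits(m, "pssm"), inherits(s, "complex_structure"))
  res <- s$residues[s$residues$chain == chain, ]
  if (nrow(res) == 0) {
    abort(paste0("chain '", chain, "' not found in structure '",
                 s$structure_id, "'"))
  }
  obs <- paste(aa3_to_1(res$resname), collapse = "")
  pssm_row <- rep(NA_integer_, nrow(res))

  if (identical(obs, m$sequence)) {
    pssm_row <- seq_len(nrow(res))
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(m$sequence), Biostrings::AAString(obs),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ident <- sum(pat == sub & pat != "-") / sum(pat != "-" & sub != "-")
    if (!is.finite(ident) || ident < min_identity) {
      abort(sprintf(
        "PSSM sequence does not match chain '%s' (aligned identity %.2f < %.2f)",
        chain, ifelse(is.finite(ident), ident, 0), min_identity))
    }
    p_pos <- Biostrings::start(Biostrings::pattern(al)) - 1L
    s_pos <- Biostrings::start(Biostrings::subject(al)) - 1L
    for (k in seq_along(pat)) {
      if (pat[k] != "-") p_pos <- p_pos + 1L
      if (sub[k] != "-") s_pos <- s_pos + 1L
      if (pat[k] != "-" && sub[k] != "-" && pat[k] == sub[k]) {
        pssm_row[s_pos] <- p_pos
      }
    }
  }
  bind_cols(res, tibble(pssm_row = pssm_row))
}

#' Per-residue PSSM features keyed to structure residues
#'
#' Convenience composition of [align_pssm_to_structure()] and
#' [encode_pssm()]: returns residue-keyed PSSM feature rows ready for
#' [assemble_features()]. Residues without a matched PSSM row are dropped
#' with a message.
#'
#' @inheritParams align_pssm_to_structure
#' @inheritParams encode_pssm
#' @return A tibble: `structure_id`, residue keys, 20 `pssm_*` columns.
#' @export
pssm_features_for_structure <- function(m, s, chain,
                                        scaling = c("raw", "sigmoid"),
                                        min_identity = 0.95) {
  map <- align_pssm_to_structure(m, s, chain, min_identity)
  enc <- encode_pssm(m, scaling)
  dropped <- sum(is.na(map$pssm_row))
  if (dropped > 0) {
    inform(paste0(dropped, " residue(s) of chain '", chain,
                  "' have no matching PSSM row; dropped"))
  }
  map |>
    filter(!is.na(.data$pssm_row)) |>
    mutate(structure_id = s$structure_id, .before = 1) |>
    left_join(select(enc, -"residue"),
              by = c(pssm_row = "position")) |>
    select(-"pssm_row")
}
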