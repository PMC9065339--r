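#' Assemble the labelled per-residue feature table
#'
#' Inner-joins site labels, topology features and PSSM features on the
#' residue key (`structure_id`, `chain`, `resnum`, `icode`); residues missing
#' from any selected source are dropped with a message giving the count.
#' Columns are emitted in the fixed order of [feature_columns()] (20 PSSM
#' columns then 7 network columns), restricted to the requested feature
#' groups.
#'
#' @param labels Site-label tibble(s) (from [label_binding_sites()] /
#'   [extract_binding_sites()]); a tibble or list of tibbles.
#' @param topology Topology tibble(s) from [rin_topology()]. Required when
#'   `"rin"` is among `groups`.
#' @param pssm Residue-keyed PSSM tibble(s) from
#'   [pssm_features_for_structure()]. Required when `"pssm"` is in `groups`.
#' @param groups Feature groups to include: subset of `c("pssm", "rin")`.
#' @return A feature-table tibble: residue keys, feature columns, `label`.
#' @export
assemble_features <- function(labels, topology = NULL, pssm = NULL,
                              groups = c("pssm", "rin")) {
  groups <- match.arg(groups, c("pssm", "rin"), several.ok = TRUE)
  rb <- function(x) if (is.data.frame(x)) x else bind_rows(x)
  keys <- c("structure_id", "chain", "resnum", "icode")
  out <- rb(labels)
  n0 <- nrow(out)

  if ("pssm" %in% groups) {
    stopifnot(!is.null(pssm))
    p <- rb(pssm)
    out <- inner_join(out, select(p, all_of(keys), all_of(.PSSM_COLS)),
                      by = keys)
  }
  if ("rin" %in% groups) {
    stopifnot(!is.null(topology))
    t_ <- rb(topology)
    out <- inner_join(out, select(t_, all_of(keys), all_of(.RIN_COLS)),
                      by = keys)
  }
  dropped <- n0 - nrow(out)
  if (nrow(out) == 0) abort("no residues survive the feature join")
  if (dropped > 0) {
    inform(paste0(dropped, " residue(s) missing from a feature source; dropped"))
  }
  cols <- intersect(.FEATURE_COLS, names(out))
  out |>
    arrange(.data$structure_id, .data$chain, .data$resnum, .data$icode) |>
    select(all_of(.RESIDUE_KEYS), all_of(cols), "label")
}

#' Split complexes into training and independent test sets
#'
#' Uniform random sampling without replacement, deterministic for a given
#' seed. The study design this mirrors holds out complete complexes (not
#' residues), so the split operates on structure identifiers.
#'
#' @param ids Character vector of structure identifiers.
#' @param n_test Number of complexes held out for independent testing.
#' @param seed Integer seed.
#' @return A `split_spec`: list with `train`, `test` (character vectors) and
#'   `seed`.
#' @export
split_complexes <- function(ids, n_test, seed) {
  stopifnot(n_test >= 0, n_test <= length(ids), !anyDuplicated(ids))
  test <- withr::with_seed(seed, sample(ids, n_test))
  out <- list(train = setdiff(ids, test), test = sort(test),
              seed = as.integer(seed))
  class(out) <- "split_spec"
  out
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> ", length(x$train), " train / ", length(x$test),
      " test complexes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a split specification as JSON
#' @param x A `split_spec`.
#' @param path File path.
#' @return `path` (write) or a `split_spec` (read).
#' @export
write_split <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$seed <- as.integer(x$seed)
  class(x) <- "split_spec"
  x
}

#' Random under-sampling of the majority class
#'
#' Retains every positive (binding-site) row and draws
#' `round(ratio * n_positives)` negatives uniformly without replacement;
#' the output row order is a deterministic shuffle driven by `seed`. The
#' intended use is balancing the training set only -- independent test sets
#' keep their natural class imbalance.
#'
#' @param tbl Feature-table tibble with a 0/1 `label` column.
#' @param ratio Negatives drawn per positive; default 1 (1:1 balance).
#' @param seed Integer seed.
#' @return The under-sampled tibble.
#' @export
undersample <- function(tbl, ratio = 1, seed) {
  stopifnot(ratio > 0, "label" %in% names(tbl))
  pos <- filter(tbl, .data$label == 1)
  neg <- filter(tbl, .data$label == 0)
  n_draw <- round(ratio * nrow(pos))
  if (nrow(pos) == 0) abort("no positive rows to balance against")
  if (nrow(neg) < n_draw) {
    abort(sprintf("need %d negatives for ratio %g but only %d available",
                  n_draw, ratio, nrow(neg)))
  }
  withr::with_seed(seed, {
    keep_neg <- neg[sample(nrow(neg), n_draw), ]
    out <- bind_rows(pos, keep_neg)
    out[sample(nrow(out)), ]
  })
}

#' Write a feature table as TSV
#' @param tbl Feature-table tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = c(icode = "character")))
}
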