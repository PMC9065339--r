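#' Min-max normalise features and summarise per class
#'
#' Each selected column is rescaled to \[0, 1\] by (x - min) / (max - min)
#' fitted on the pooled (both-class) values; a constant column maps to all
#' zeros with a warning. Summaries (mean, median, quartiles) are returned
#' per feature and class alongside the normalised values.
#'
#' @param tbl Labelled feature table.
#' @param columns Feature columns to normalise; default the 7 network
#'   topology columns.
#' @return A `feature_summary`: list with `values` (long tibble: `feature`,
#'   `label`, `value`) and `summary` (per feature x class statistics).
#' @export
normalize_features <- function(tbl, columns = feature_columns("rin")) {
  stopifnot(all(columns %in% names(tbl)), "label" %in% names(tbl))
  norm <- tbl
  for (cl in columns) {
    x <- tbl[[cl]]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warn(paste0("column '", cl, "' is constant; normalised to all zeros"))
      norm[[cl]] <- rep(0, length(x))
    } else {
      norm[[cl]] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  values <- norm |>
    select(all_of(c("label", columns))) |>
    tidyr::pivot_longer(all_of(columns), names_to = "feature",
                        values_to = "value") |>
    mutate(feature = factor(.data$feature, levels = columns))
  summary <- values |>
    group_by(.data$feature, .data$label) |>
    summarise(mean = mean(.data$value), median = stats::median(.data$value),
              q25 = stats::quantile(.data$value, 0.25),
              q75 = stats::quantile(.data$value, 0.75),
              min = min(.data$value), max = max(.data$value),
              n = n(), .groups = "drop")
  structure(list(values = values, summary = summary, columns = columns),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat("<feature_summary> ", length(x$columns), " features, ",
      nrow(x$values), " value rows\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare a feature's distribution between classes
#'
#' For each feature: the binding-minus-non-binding mean difference and a
#' two-sample Wilcoxon rank-sum test (normal approximation with tie
#' correction). No multiple-testing correction is applied unless
#' `p_adjust` names a method.
#'
#' @param tbl Labelled feature table (raw or normalised values).
#' @param columns Feature columns to compare; default the 7 topology
#'   columns.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Tibble: `feature`, `mean_diff` (class 1 minus class 0),
#'   `statistic` (rank-sum W), `p_value`.
#' @export
class_distribution_compare <- function(tbl,
                                       columns = feature_columns("rin"),
                                       p_adjust = "none") {
  stopifnot(all(columns %in% names(tbl)), "label" %in% names(tbl))
  out <- purrr::map_dfr(columns, function(cl) {
    x1 <- tbl[[cl]][tbl$label == 1]
    x0 <- tbl[[cl]][tbl$label == 0]
    wt <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                              correct = FALSE))
    tibble(feature = cl, mean_diff = mean(x1) - mean(x0),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}

#' Per-class frequency histogram
#'
#' Equal-width bins over the pooled range (or a supplied range); per class
#' the frequencies are normalised to sum to 1, so the two classes are
#' directly comparable regardless of class imbalance.
#'
#' @param values Numeric vector.
#' @param label 0/1 class vector, same length.
#' @param n_bins Number of bins; default 10.
#' @param range Optional length-2 numeric range; default the pooled range.
#' @return Tibble: `bin`, `lower`, `upper`, `midpoint`, `label`,
#'   `frequency`.
#' @export
frequency_histogram <- function(values, label, n_bins = 10, range = NULL) {
  stopifnot(length(values) == length(label), n_bins >= 1)
  rng <- range %||% base::range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tidyr::expand_grid(bin = seq_len(n_bins), label = sort(unique(label))) |>
    left_join(
      tibble(bin = bin, label = label) |>
        dplyr::count(.data$bin, .data$label, name = "count"),
      by = c("bin", "label")
    ) |>
    mutate(count = .data$count %|NA|% 0L) |>
    group_by(.data$label) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(lower = breaks[.data$bin], upper = breaks[.data$bin + 1],
           midpoint = (.data$lower + .data$upper) / 2) |>
    select("bin", "lower", "upper", "midpoint", "label", "frequency")
}

#' Read an amino-acid property index table
#'
#' TSV with one row per amino acid (1-letter code in the first column) and
#' one column per index (e.g. HQI1..HQI8). Each index must cover all 20
#' standard amino acids.
#'
#' @param path TSV file.
#' @return Long tibble: `aa`, `index`, `value`.
#' @export
read_aaindex <- function(path) {
  raw <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
  names(raw)[1] <- "aa"
  raw$aa <- toupper(raw$aa)
  missing_aa <- setdiff(unname(.AA3), raw$aa)
  if (length(missing_aa)) {
    abort(paste0("index table missing amino acid(s): ",
                 paste(missing_aa, collapse = ", ")))
  }
  tidyr::pivot_longer(raw, -"aa", names_to = "index", values_to = "value")
}

#' High/low property proportions at binding sites
#'
#' For each property index, a binding-site residue is HIGH when its
#' amino-acid value is at or above the unweighted mean of that index over
#' the 20 standard amino acids (ties count as HIGH), LOW otherwise.
#' Residue types absent from the index table are excluded, with the count
#' reported.
#'
#' @param labels Site-label tibble (3-letter `resname` + `label`); only
#'   label-1 residues are analysed.
#' @param aaindex Long index tibble from [read_aaindex()] (columns `aa`,
#'   `index`, `value`).
#' @return Tibble: `index`, `high_pct`, `low_pct`, `n_sites`,
#'   `n_excluded`.
#' @export
hqi_proportions <- function(labels, aaindex) {
  stopifnot(all(c("aa", "index", "value") %in% names(aaindex)))
  sites <- filter(labels, .data$label == 1)
  sites$aa <- aa3_to_1(sites$resname)
  purrr::map_dfr(unique(aaindex$index), function(ix) {
    tab <- filter(aaindex, .data$index == ix)
    threshold <- mean(tab$value[tab$aa %in% unname(.AA3)])
    v <- tab$value[match(sites$aa, tab$aa)]
    known <- !is.na(v)
    n_excl <- sum(!known)
    if (n_excl > 0) {
      inform(paste0(n_excl, " site residue(s) missing from index '", ix,
                    "'; excluded"))
    }
    high <- v[known] >= threshold
    tibble(index = ix,
           high_pct = 100 * mean(high),
           low_pct = 100 * mean(!high),
           n_sites = sum(known), n_excluded = n_excl)
  })
}

#' Amino-acid composition of binding sites per ligand group
#'
#' Counts each residue type among binding-site (label 1) residues, per
#' group of structures (e.g. organism or ligand class). With no grouping a
#' single overall group is used.
#'
#' @param labels Site-label tibble(s); tibble or list of tibbles.
#' @param grouping Optional named character vector mapping `structure_id`
#'   to a group id; unmapped structures fall in group `"all"`.
#' @return Tibble: `group`, `resname`, `count` (0 rows for groups with no
#'   sites are retained as zero counts for residue types seen in the data).
#' @export
ligand_aa_frequency <- function(labels, grouping = NULL) {
  lab <- if (is.data.frame(labels)) labels else bind_rows(labels)
  lab$group <- if (is.null(grouping)) "all" else {
    unname(grouping[lab$structure_id]) %|NA|% "all"
  }
  groups <- unique(lab$group)
  resnames <- sort(unique(lab$resname[lab$label == 1]))
  if (length(resnames) == 0) resnames <- character(0)
  counted <- lab |>
    filter(.data$label == 1) |>
    dplyr::count(.data$group, .data$resname, name = "count")
  tidyr::expand_grid(group = groups, resname = resnames) |>
    left_join(counted, by = c("group", "resname")) |>
    mutate(count = as.integer(.data$count %|NA|% 0L)) |>
    arrange(.data$group, .data$resname)
}
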