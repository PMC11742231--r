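# Response-table loading, IC50 normalization, and evaluation splits.

#' Normalize IC50 values to \[0, 1\]
#'
#' Default method rescales natural-log IC50 by per-dataset min-max, so the
#' extremes map exactly to 0 and 1; `"minmax"` skips the log (for inputs
#' already on a log or normalized scale) and `"logistic"` applies a logistic
#' squash of the standardized log values (no exact endpoint guarantee, but
#' robust to outliers).
#'
#' @param values Positive IC50 values (any positive scale for the log
#'   methods; arbitrary reals for `"minmax"`).
#' @param method `"minmax_log"` (default), `"minmax"` or `"logistic"`.
#' @return Numeric vector in \[0, 1\]. A constant (or singleton) input has no
#'   range to normalize and maps to 0.5 everywhere, with a warning.
#' @examples
#' normalize_ic50(c(1, exp(1), exp(2)))  # 0, 0.5, 1
#' @export
normalize_ic50 <- function(values, method = c("minmax_log", "minmax",
                                              "logistic")) {
  method <- match.arg(method)
  v <- as.numeric(values)
  if (!length(v)) return(numeric(0))
  if (anyNA(v)) stop("IC50 values contain NA")
  if (method != "minmax") {
    if (any(v <= 0)) stop("IC50 values must be positive for log transforms")
    v <- log(v)
  }
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    warning("degenerate range: all values equal; returning 0.5")
    return(rep(0.5, length(v)))
  }
  if (method == "logistic") {
    return(stats::plogis((v - mean(v)) / stats::sd(v)))
  }
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

read_table_auto <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
      else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE,
                                      colClasses = NA, as.is = TRUE))
}

#' Load a drug-response table
#'
#' Reads (or accepts) a table of `(drug_id, cell_id, ic50)` triples, drops
#' rows referencing drugs without a SMILES or cells without a profile
#' (mirroring the exclusion of entities lacking features during screening
#' preprocessing), keeps the first of any duplicated (drug, cell) pair, drops
#' rows with non-numeric IC50, and attaches a normalized response column
#' `y` in \[0, 1\]. Row-drop accounting is attached as attributes and always
#' satisfies kept + dropped = input.
#'
#' @param x File path (CSV/TSV) or a data frame with columns `drug_id`,
#'   `cell_id` and `ic50` (or an already-normalized `y`).
#' @param drugs Optional drug table (`drug_id`, `smiles`) used to filter
#'   unknown drugs.
#' @param cells Optional cell table (`cell_id`, ...) used to filter unknown
#'   cells.
#' @param format `"auto"`, `"csv"` or `"tsv"` (file input only).
#' @param log_input Set `TRUE` when the `ic50` column is already on the
#'   natural-log scale.
#' @param method Normalization method, see [normalize_ic50()].
#' @return A tibble `(drug_id, cell_id, raw_ic50, y)` with attributes
#'   `n_input`, `n_kept`, `n_dropped_unknown`, `n_dropped_duplicate`,
#'   `n_dropped_bad_ic50`.
#' @export
load_responses <- function(x, drugs = NULL, cells = NULL,
                           format = c("auto", "csv", "tsv"),
                           log_input = FALSE,
                           method = "minmax_log") {
  tab <- if (is.character(x)) read_table_auto(x, format) else
    tibble::as_tibble(x)
  need <- c("drug_id", "cell_id")
  if (!all(need %in% names(tab))) {
    stop("response table must have columns drug_id and cell_id")
  }
  has_y <- "y" %in% names(tab)
  if (!has_y && !"ic50" %in% names(tab)) {
    stop("response table must have an ic50 (or y) column")
  }
  n_input <- nrow(tab)
  # non-numeric ic50 rows
  n_bad <- 0L
  if (!has_y) {
    ic50 <- suppressWarnings(as.numeric(tab$ic50))
    n_bad <- sum(is.na(ic50) & !is.na(tab$ic50)) + sum(is.na(tab$ic50))
    if (n_bad > 0L) {
      warning(n_bad, " rows dropped: non-numeric or missing ic50")
      tab <- tab[!is.na(ic50), , drop = FALSE]
      ic50 <- ic50[!is.na(ic50)]
    }
    tab$ic50 <- ic50
  }
  # entities without features
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(drugs)) keep <- keep & tab$drug_id %in% drugs$drug_id
  if (!is.null(cells)) keep <- keep & tab$cell_id %in% cells$cell_id
  n_unknown <- sum(!keep)
  if (n_unknown > 0L) {
    message(n_unknown, " rows dropped: drug or cell line without features")
    tab <- tab[keep, , drop = FALSE]
  }
  # duplicate pairs: keep first
  dup <- duplicated(tab[, c("drug_id", "cell_id")])
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning(n_dup, " duplicate (drug, cell) pairs dropped (kept first)")
    tab <- tab[!dup, , drop = FALSE]
  }
  if (has_y) {
    if (any(tab$y < 0 | tab$y > 1)) stop("column y must lie in [0, 1]")
    out <- tibble::tibble(drug_id = as.character(tab$drug_id),
                          cell_id = as.character(tab$cell_id),
                          raw_ic50 = if ("raw_ic50" %in% names(tab))
                            tab$raw_ic50 else NA_real_,
                          y = tab$y)
  } else {
    vals <- tab$ic50
    y <- if (log_input) {
      normalize_ic50(exp(vals), method = method)
    } else {
      normalize_ic50(vals, method = method)
    }
    out <- tibble::tibble(drug_id = as.character(tab$drug_id),
                          cell_id = as.character(tab$cell_id),
                          raw_ic50 = if (log_input) exp(vals) else vals,
                          y = y)
  }
  structure(out, n_input = n_input, n_kept = nrow(out),
            n_dropped_unknown = n_unknown, n_dropped_duplicate = n_dup,
            n_dropped_bad_ic50 = n_bad)
}

#' Percentage of unmeasured drug-cell pairs in a screen
#'
#' Given the numbers of drugs and cell lines in a screen and the number of
#' pairs with a measured response, returns the percentage of the possible
#' drug-cell interactions that is missing.
#'
#' @param n_drugs,n_cells Entity counts after preprocessing.
#' @param n_measured Number of measured (drug, cell) pairs.
#' @return Percentage in [0, 100].
#' @examples
#' missing_pair_percentage(223, 948, 172114)  # large screens are sparse
#' @export
missing_pair_percentage <- function(n_drugs, n_cells, n_measured) {
  possible <- n_drugs * n_cells
  if (n_measured > possible) stop("more measured pairs than possible pairs")
  100 * (possible - n_measured) / possible
}

part_sizes <- function(n, ratios) {
  sizes <- floor(n * ratios)
  sizes[1L] <- sizes[1L] + (n - sum(sizes))
  sizes
}

#' Split response records for training and evaluation
#'
#' `"mixed"` shuffles the (drug, cell) pairs uniformly and cuts them
#' 80/10/10 (by default) into train/validation/test, so every drug and cell
#' line may be seen in training. `"new_cell_line"` instead shuffles and
#' partitions the cell identities, assigning every pair of a cell to that
#' cell's part -- the cold-start protocol where test cells are never seen in
#' training. With `cold_drugs = TRUE` the drug identities are partitioned as
#' well (double cold start); pairs whose drug and cell land in different
#' parts are dropped, which that variant reports via the
#' `n_dropped_cross_part` attribute.
#'
#' @param records Response tibble (e.g. from [load_responses()] or the
#'   `responses` element of a simulated dataset).
#' @param split_kind `"mixed"` or `"new_cell_line"`.
#' @param ratios Length-3 positive weights summing to 1.
#' @param seed Shuffle seed; the same seed always reproduces the same split.
#' @param cold_drugs Also hold out drugs (new-cell-line splits only).
#' @return The records with a `part` factor column
#'   (train/validation/test), class `gf_split`, attributes `split_kind` and
#'   `seed`.
#' @export
make_split <- function(records, split_kind = c("mixed", "new_cell_line"),
                       ratios = c(0.8, 0.1, 0.1), seed = 1L,
                       cold_drugs = FALSE) {
  split_kind <- match.arg(split_kind)
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  parts <- c("train", "validation", "test")
  set.seed(seed)
  dropped_cross <- 0L
  if (split_kind == "mixed") {
    sizes <- part_sizes(n, ratios)
    if (any(sizes <= 0L)) stop("too few records for a non-empty part")
    lab <- rep(parts, times = sizes)[order(sample.int(n))]
    out <- records
    out$part <- factor(lab, levels = parts)
  } else {
    assign_entities <- function(ids) {
      u <- sample(unique(ids))
      k <- length(u)
      sizes <- part_sizes(k, ratios)
      if (any(sizes <= 0L)) {
        stop("too few cell lines (or drugs) for a non-empty part")
      }
      stats::setNames(rep(parts, times = sizes), u)
    }
    cell_part <- assign_entities(records$cell_id)
    lab <- cell_part[records$cell_id]
    out <- records
    out$part <- factor(unname(lab), levels = parts)
    if (cold_drugs) {
      drug_part <- assign_entities(records$drug_id)
      agree <- unname(drug_part[records$drug_id]) == unname(lab)
      dropped_cross <- sum(!agree)
      out <- out[agree, , drop = FALSE]
    }
  }
  structure(out, class = c("gf_split", class(tibble::tibble())),
            split_kind = split_kind, seed = as.integer(seed),
            n_dropped_cross_part = dropped_cross)
}

#' Write a split manifest
#'
#' Three-column CSV (drug_id, cell_id, part) recording a split exactly.
#'
#' @param split A `gf_split`.
#' @param path Output CSV path.
#' @export
write_split <- function(split, path) {
  utils::write.csv(
    data.frame(drug_id = split$drug_id, cell_id = split$cell_id,
               part = as.character(split$part)),
    path, row.names = FALSE
  )
  invisible(path)
}
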