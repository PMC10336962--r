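#' Load the IDP radius-of-gyration benchmark table
#'
#' Reads the packaged 24-protein benchmark of experimental radii of gyration
#' and the predictions of four models (scaling law, SOP-IDP, bead-necklace,
#' Martini Stark), or a user-supplied CSV with the same column schema.
#'
#' Three cells of the printed table are dual-valued, and the loader records
#' explicit evaluation conventions for them rather than leaving the choice
#' implicit:
#' \itemize{
#'   \item alpha-synuclein lists two experimental values (40.0 and
#'     35.5 +/- 0.5 Angstrom); evaluation uses 35.5.
#'   \item Prothymosin alpha lists bead-necklace predictions at 0 and 150 mM
#'     salt (72.3 and 44.6 Angstrom); evaluation uses the 150 mM value 44.6.
#'   \item The K23 scaling-law cell prints 54.7 Angstrom, which is
#'     inconsistent with the printed +14\% deviation and the published
#'     chi-square totals; those are only reproduced by 55.9 Angstrom, the
#'     value the canonical scaling law itself predicts for N = 254.
#'     Evaluation uses the reconstructed 55.9; the printed value is retained
#'     in the \code{rg_scaling} column.
#' }
#' These conventions are the only combination consistent with the published
#' per-cell deviations and chi-square totals.
#'
#' @param path path to a benchmark CSV. `NULL` (default) loads the packaged
#'   canonical fixture. Required columns: `name`, `n_residues`, `rg_exp`, and
#'   at least one model prediction column. Optional columns: `rg_exp_err`,
#'   `rg_exp_alt`, `rg_exp_alt_err`, `rg_scaling`, `rg_scaling_alt`,
#'   `rg_sop_idp`, `rg_bead_necklace`, `rg_bead_necklace_alt`, `rg_martini`,
#'   `salt_mM`, `temperature_K`, `comment`.
#' @return a `benchmark_table`: a data frame of validated records, with an
#'   `"conventions"` attribute describing which value each dual-valued cell
#'   resolves to during evaluation.
#' @examples
#' tab <- load_benchmark()
#' nrow(tab)                 # 24
#' experimental_rg(tab)[1]   # Hst5, 13.8 Angstrom
#' @export
load_benchmark <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("table1.csv")
  if (!file.exists(path)) stop("benchmark table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  required <- c("name", "n_residues", "rg_exp")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("benchmark table is missing required column(s): ",
         paste(missing, collapse = ", "))
  model_cols <- intersect(.model_columns, names(tab))
  if (nrow(tab) > 0L && !length(model_cols))
    stop("benchmark table has no model prediction column (one of: ",
         paste(.model_columns, collapse = ", "), ")")

  if (anyDuplicated(tab$name))
    stop("duplicate protein name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  if (nrow(tab) > 0L) {
    bad_n <- !is.na(tab$n_residues) &
      (!is.finite(tab$n_residues) | tab$n_residues < 1)
    if (any(bad_n))
      stop("n_residues must be >= 1 for every record")
    rg_cols <- intersect(
      c("rg_exp", "rg_exp_alt", .model_columns,
        "rg_scaling_alt", "rg_bead_necklace_alt"),
      names(tab))
    for (col in rg_cols) {
      bad <- !is.na(tab[[col]]) & tab[[col]] <= 0
      if (any(bad))
        stop("non-positive Rg in column '", col, "' for: ",
             paste(tab$name[bad], collapse = ", "))
    }
    if ("rg_exp_err" %in% names(tab)) {
      bad <- !is.na(tab$rg_exp_err) & tab$rg_exp_err < 0
      if (any(bad)) stop("negative experimental error for: ",
                         paste(tab$name[bad], collapse = ", "))
    }
  }

  conventions <- list(
    experimental = "rg_exp_alt preferred over rg_exp where present (alpha-synuclein: 35.5)",
    bead_necklace = "rg_bead_necklace_alt preferred where present (Prothymosin alpha, 150 mM: 44.6)",
    scaling = "rg_scaling_alt preferred where present (K23: reconstructed 55.9, printed 54.7 is inconsistent with the published deviations and chi-square)"
  )
  structure(tab, class = c("benchmark_table", "data.frame"),
            conventions = conventions)
}

# canonical model identifiers -> fixture columns
.model_columns <- c(scaling = "rg_scaling", sop_idp = "rg_sop_idp",
                    bead_necklace = "rg_bead_necklace", martini = "rg_martini")

#' Benchmark model identifiers
#'
#' @return character vector of the four model identifiers used throughout the
#'   package: `"scaling"`, `"sop_idp"`, `"bead_necklace"`, `"martini"`.
#' @export
benchmark_models <- function() names(.model_columns)

#' Convention-resolved experimental and model Rg columns
#'
#' `experimental_rg()` returns the experimental radius of gyration for each
#' record, using the alternate value where the table lists two (see
#' [load_benchmark()]). `model_rg()` does the same for a model prediction
#' column.
#'
#' @param table a `benchmark_table` from [load_benchmark()]
#' @param model one of [benchmark_models()]
#' @return numeric vector, Angstrom, one value per record
#' @export
experimental_rg <- function(table) {
  e <- table$rg_exp
  if ("rg_exp_alt" %in% names(table)) {
    alt <- table$rg_exp_alt
    e[!is.na(alt)] <- alt[!is.na(alt)]
  }
  e
}

#' @rdname experimental_rg
#' @export
model_rg <- function(table, model = benchmark_models()) {
  model <- match.arg(model)
  col <- .model_columns[[model]]
  if (!col %in% names(table))
    stop("table has no '", col, "' column")
  s <- table[[col]]
  alt_col <- paste0(col, "_alt")
  if (alt_col %in% names(table)) {
    alt <- table[[alt_col]]
    s[!is.na(alt)] <- alt[!is.na(alt)]
  }
  s
}

#' Load the short-peptide extension table
#'
#' Two additional systems (the KEIF peptide and the histatin-5 dimer) with
#' experimental Rg 17.6 and 18.7 Angstrom, kept separate from the canonical
#' 24-protein benchmark.
#'
#' @return a `benchmark_table` with two records
#' @export
load_extension <- function() load_benchmark(.extdata("extension.csv"))

#' Check internal consistency of the benchmark tables
#'
#' Recomputes the signed percentage deviation of every (protein, model) cell
#' from the Rg table and compares the rounded result with the printed
#' deviation table. A consistent pair of tables produces no rows; each
#' reported row is a cell whose recomputed deviation differs from the printed
#' integer by more than `tol` percentage points.
#'
#' With the packaged fixtures and the default evaluation conventions all 96
#' cells agree. Checking the \emph{printed} K23 scaling value instead
#' (`use_conventions = FALSE` for that column) exposes the single
#' inconsistent cell of the source table.
#'
#' @param table a `benchmark_table`
#' @param deviation_table data frame of printed deviations with columns
#'   `name`, `dev_scaling`, `dev_sop_idp`, `dev_bead_necklace`,
#'   `dev_martini`; default: the packaged transcription
#' @param tol mismatch threshold in percentage points (default 1)
#' @param use_conventions resolve dual-valued cells per the table conventions
#'   (default `TRUE`); `FALSE` compares the printed primary values as-is
#' @return data frame report with one row per mismatching cell: `name`,
#'   `model`, `recomputed`, `printed`, `difference`
#' @export
validate_consistency <- function(table,
                                 deviation_table = NULL,
                                 tol = 1,
                                 use_conventions = TRUE) {
  if (is.null(deviation_table))
    deviation_table <- utils::read.csv(.extdata("table2.csv"),
                                       stringsAsFactors = FALSE)
  E <- if (use_conventions) experimental_rg(table) else table$rg_exp
  out <- list()
  for (model in benchmark_models()) {
    col <- .model_columns[[model]]
    dev_col <- paste0("dev_", model)
    if (!col %in% names(table) || !dev_col %in% names(deviation_table)) next
    S <- if (use_conventions) model_rg(table, model) else table[[col]]
    recomputed <- round(signed_pct_deviation(S, E))
    printed <- deviation_table[[dev_col]][match(table$name, deviation_table$name)]
    diff <- recomputed - printed
    bad <- which(!is.na(diff) & abs(diff) > tol)
    if (length(bad))
      out[[model]] <- data.frame(name = table$name[bad], model = model,
                                 recomputed = recomputed[bad],
                                 printed = printed[bad],
                                 difference = diff[bad],
                                 stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(name = character(), model = character(),
                      recomputed = numeric(), printed = numeric(),
                      difference = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("IDP Rg benchmark table: ", nrow(x), " system(s), models: ",
      paste(intersect(.model_columns, names(x)), collapse = ", "), "\n",
      sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
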