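# Table schemas used across the package. Comma-delimited text with
# unit-bearing column names is the interchange format throughout.
ARSBIND_SCHEMAS <- list(
  isotherm = c("label", "As_total_uM", "As_free_uM", "As_bound_uM"),
  kinetics = c("t_h", "Q_ug_per_g"),
  competition = c("As_total_uM", "R_bound_uM"),
  suspension = c("label", "mass_conc_g_per_L", "particles_per_gram"),
  loading = c("sphere_conc_uM", "protein_bound_uM"),
  interference = c("adsorbent", "metal", "Q_with", "Q_without"),
  stability = c("t_h", "bound")
)

CHARACTER_COLUMNS <- c("label", "adsorbent", "metal", "name")

# Validate presence and type of required columns; reject malformed rows
# by number so nothing is silently coerced.
require_columns <- function(data, cols, what, numeric_cols = NULL) {
  if (!is.data.frame(data)) {
    abort(sprintf("A %s must be a data frame.", what),
          class = "arsbind_parse_error")
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")),
          class = "arsbind_parse_error")
  }
  numeric_cols <- numeric_cols %||% setdiff(cols, CHARACTER_COLUMNS)
  for (col in numeric_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        abort(sprintf("%s: column `%s` has non-numeric value %s in row %d.",
                      what, col, deparse(as.character(v[bad[1]])), bad[1]),
              class = "arsbind_parse_error")
      }
      data[[col]] <- vn
    }
    if (anyNA(data[[col]])) {
      abort(sprintf("%s: column `%s` has a missing value in row %d.",
                    what, col, which(is.na(data[[col]]))[1]),
            class = "arsbind_parse_error")
    }
  }
  as_tibble(data)
}

read_arsbind_table <- function(path, schema,
                               nonnegative = setdiff(ARSBIND_SCHEMAS[[schema]],
                                                     CHARACTER_COLUMNS)) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "arsbind_parse_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  out <- require_columns(raw, ARSBIND_SCHEMAS[[schema]],
                         sprintf("%s table (%s)", schema, basename(path)))
  for (col in nonnegative) {
    bad <- which(out[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("%s table (%s): negative `%s` in row %d.",
                    schema, basename(path), col, bad[1]),
            class = "arsbind_parse_error")
    }
  }
  out
}

# '# key: value' header lines carrying table-level metadata
read_header_block <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.+?)\\s*$", hdr))
  kv <- kv[lengths(kv) == 3L]
  vals <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) m[3] else v
  })
  setNames(vals, vapply(kv, `[[`, character(1), 2))
}

#' Read experiment tables
#'
#' Comma-delimited readers for the package's table schemas, with header
#' validation, numeric coercion that names the offending cell, and
#' rejection of negative concentrations. Lines starting with `#` are
#' metadata comments; in competition tables they carry the site totals
#' (`# R_total_uM: ...`, `# P_total_uM: ...`), which are attached as
#' attributes.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble in the corresponding schema:
#'   * isotherm: `label`, `As_total_uM`, `As_free_uM`, `As_bound_uM`
#'     (mass-balance closure is checked to 1% of total);
#'   * kinetics: `t_h`, `Q_ug_per_g`;
#'   * competition: `As_total_uM`, `R_bound_uM` (+ attributes);
#'   * suspension: one [adsorbent_suspension()] row per input row;
#'   * loading: `sphere_conc_uM`, `protein_bound_uM`;
#'   * interference: `adsorbent`, `metal`, `Q_with`, `Q_without`.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_isotherm_table <- function(path) {
  out <- read_arsbind_table(path, "isotherm")
  gap <- abs(out$As_free_uM + out$As_bound_uM - out$As_total_uM)
  bad <- which(gap > 0.01 * pmax(out$As_total_uM, .Machine$double.eps))
  if (length(bad) > 0) {
    abort(sprintf("isotherm table (%s): free + bound != total in row %d.",
                  basename(path), bad[1]),
          class = "arsbind_parse_error")
  }
  out
}

#' @rdname read_tables
#' @export
read_kinetics_table <- function(path) {
  validate_kinetics_table(read_arsbind_table(path, "kinetics"))
}

#' @rdname read_tables
#' @export
read_competition_table <- function(path) {
  out <- read_arsbind_table(path, "competition")
  hdr <- read_header_block(path)
  for (key in c("R_total_uM", "P_total_uM")) {
    if (!is.null(hdr[[key]])) attr(out, key) <- hdr[[key]]
  }
  for (key in c("R_label", "P_label")) {
    if (!is.null(hdr[[key]])) attr(out, key) <- hdr[[key]]
  }
  out
}

#' @rdname read_tables
#' @export
read_suspension_table <- function(path) {
  raw <- read_arsbind_table(path, "suspension")
  purrr::map_dfr(seq_len(nrow(raw)), function(i) {
    adsorbent_suspension(raw$mass_conc_g_per_L[i], raw$particles_per_gram[i],
                         label = raw$label[i])
  })
}

#' @rdname read_tables
#' @export
read_loading_table <- function(path) {
  read_arsbind_table(path, "loading")
}

#' @rdname read_tables
#' @export
read_interference_table <- function(path) {
  read_arsbind_table(path, "interference")
}

#' Write an experiment table
#'
#' Plain CSV writer used for all package outputs; optional `header`
#' key-value pairs are written as `# key: value` comment lines so
#' table-level metadata (site totals, seeds) round-trips through
#' [read_competition_table()] and friends.
#'
#' @param data A tibble.
#' @param path Output path.
#' @param header Named list written as comment lines.
#' @return `path`, invisibly.
#' @export
write_arsbind_table <- function(data, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, format, character(1))), con)
  }
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
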