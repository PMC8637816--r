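# Panel data model and descriptive statistics.
#
# A "panel" is the tabulated outcome of an ICP-MS survey of lip cosmetics:
# one row per purchased product with its category, retail metadata and the
# measured Pb concentration in mg/kg. Non-detects (below the analytical
# detection limit) are recorded as concentration 0 with detected = FALSE and
# are INCLUDED in means and standard deviations; that convention is the only
# one consistent with survey summary tables that report a grand mean over a
# panel containing ~41% non-detects.

PANEL_CATEGORIES <- c("lipstick", "lip_gloss", "lip_balm")

PANEL_REQUIRED_COLS <- c("sample_id", "category", "brand",
                         "production_country", "color", "price_rmb",
                         "pb_mg_per_kg")

#' Construct a sample panel of Pb concentrations in lip cosmetics
#'
#' Builds the central data structure of the package: a tibble of product
#' records with measured Pb concentration (mg/kg, equivalently ug/g) and a
#' detect flag, validated against the panel invariants (unique ids,
#' non-negative concentrations, known categories, zero concentration if and
#' only if non-detect by default).
#'
#' @param sample_id character vector of unique sample labels (e.g. "LS1").
#' @param category product category; one of `"lipstick"`, `"lip_gloss"`,
#'   `"lip_balm"` (case-insensitive, spaces/hyphens tolerated).
#' @param pb_mg_per_kg non-negative Pb concentration, mg/kg.
#' @param detected logical detect flags. Defaults to `pb_mg_per_kg > 0`,
#'   the survey convention that non-detects are recorded as 0.
#' @param brand,production_country,color optional character metadata.
#' @param price_rmb optional non-negative retail price in RMB.
#' @return A `liprisk_panel`, a tibble with one row per product.
#' @export
#' @examples
#' sample_panel(c("LS1", "LG1"), c("lipstick", "lip_gloss"), c(0.138, 0))
sample_panel <- function(sample_id, category, pb_mg_per_kg,
                         detected = NULL, brand = NA_character_,
                         production_country = NA_character_,
                         color = NA_character_, price_rmb = NA_real_) {
  n <- length(sample_id)
  if (n == 0L) {
    stop_liprisk("a panel must contain at least one record",
                 "liprisk_validation_error")
  }
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    dup <- sample_id[duplicated(sample_id)][1L]
    stop_liprisk(sprintf("duplicate sample_id: '%s'", dup),
                 "liprisk_validation_error")
  }
  category <- normalize_category(category)
  pb_mg_per_kg <- as.numeric(pb_mg_per_kg)
  bad <- which(is.na(pb_mg_per_kg) | pb_mg_per_kg < 0)
  if (length(bad)) {
    stop_liprisk(
      sprintf("pb_mg_per_kg must be a non-negative number (row %d)", bad[1L]),
      "liprisk_validation_error")
  }
  if (is.null(detected)) {
    detected <- pb_mg_per_kg > 0
  }
  detected <- as.logical(detected)
  if (any(is.na(detected))) {
    stop_liprisk("detected flags must be TRUE/FALSE", "liprisk_validation_error")
  }
  if (any(!detected & pb_mg_per_kg != 0)) {
    stop_liprisk("non-detect records must carry concentration 0",
                 "liprisk_validation_error")
  }
  price_rmb <- as.numeric(price_rmb)
  if (any(!is.na(price_rmb) & price_rmb < 0)) {
    stop_liprisk("price_rmb must be non-negative", "liprisk_validation_error")
  }
  out <- tibble::tibble(
    sample_id = sample_id,
    category = category,
    brand = rep_len(as.character(brand), n),
    production_country = rep_len(as.character(production_country), n),
    color = rep_len(as.character(color), n),
    price_rmb = rep_len(price_rmb, n),
    pb_mg_per_kg = pb_mg_per_kg,
    detected = detected
  )
  class(out) <- c("liprisk_panel", class(out))
  attr(out, "unit") <- "mg/kg"
  out
}

normalize_category <- function(x) {
  key <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  key[key == "lipgloss"] <- "lip_gloss"
  key[key == "lipbalm"] <- "lip_balm"
  bad <- which(!key %in% PANEL_CATEGORIES)
  if (length(bad)) {
    stop_liprisk(
      sprintf("unknown category '%s' (row %d); expected one of %s",
              x[bad[1L]], bad[1L], paste(PANEL_CATEGORIES, collapse = ", ")),
      "liprisk_validation_error")
  }
  factor(key, levels = PANEL_CATEGORIES)
}

#' Read a concentration panel from CSV
#'
#' Expects the documented schema
#' `sample_id,category,brand,production_country,color,price_rmb,pb_mg_per_kg`
#' with an optional trailing `detected` column. When `detected` is absent,
#' rows with concentration 0 are marked non-detects.
#'
#' @param file path or connection to a UTF-8 CSV file with a header row.
#' @return A `liprisk_panel` with rows in file order.
#' @seealso [write_panel()], [sample_panel()]
#' @export
read_panel <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(PANEL_REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop_liprisk(
      sprintf("panel CSV is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "liprisk_schema_error")
  }
  sample_panel(
    sample_id = df$sample_id,
    category = df$category,
    pb_mg_per_kg = df$pb_mg_per_kg,
    detected = if ("detected" %in% names(df)) df$detected else NULL,
    brand = df$brand,
    production_country = df$production_country,
    color = df$color,
    price_rmb = df$price_rmb
  )
}

#' Write a concentration panel to CSV
#'
#' @param panel a `liprisk_panel`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_panel <- function(panel, file) {
  stopifnot(inherits(panel, "liprisk_panel"))
  df <- as.data.frame(panel)
  df$category <- as.character(df$category)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Summarise Pb concentrations by product category
#'
#' Reproduces the layout of a survey summary table: per category and for the
#' pooled panel, the record count, mean, sample standard deviation (n - 1
#' denominator), minimum, maximum and non-detect fraction. Non-detects enter
#' all statistics as 0, the convention under which the panel was tabulated.
#' An optional substitution policy replaces non-detect zeros with half a
#' user-supplied detection limit before summarising (off by default).
#'
#' @param panel a `liprisk_panel`.
#' @param substitute_half_dl optional detection limit (mg/kg); when supplied,
#'   non-detects are summarised as `substitute_half_dl / 2` instead of 0.
#' @return A tibble with one row per category plus a `"total"` row and
#'   columns `group, n, mean, sd, min, max, nondetect_fraction`. Groups of a
#'   single record report `sd = NA`.
#' @export
#' @examples
#' p <- sample_panel(c("a", "b", "c"), rep("lipstick", 3), c(0.1, 0.2, 0.3))
#' summarize_panel(p)
summarize_panel <- function(panel, substitute_half_dl = NULL) {
  stopifnot(inherits(panel, "liprisk_panel"))
  if (nrow(panel) == 0L) {
    stop_liprisk("cannot summarise an empty panel", "liprisk_validation_error")
  }
  values <- panel$pb_mg_per_kg
  if (!is.null(substitute_half_dl)) {
    assert_scalar_number(substitute_half_dl, "substitute_half_dl", 0,
                         allow_zero = FALSE)
    values[!panel$detected] <- substitute_half_dl / 2
  }
  one_group <- function(v, nd) {
    tibble::tibble(
      n = length(v),
      mean = mean(v),
      sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
      min = min(v),
      max = max(v),
      nondetect_fraction = mean(nd)
    )
  }
  groups <- levels(panel$category)
  present <- groups[groups %in% panel$category]
  rows <- lapply(present, function(g) {
    idx <- panel$category == g
    cbind(group = g, one_group(values[idx], !panel$detected[idx]))
  })
  rows <- c(rows, list(cbind(group = "total",
                             one_group(values, !panel$detected))))
  tibble::as_tibble(do.call(rbind, rows))
}

#' Flag panel records against a regulatory concentration limit
#'
#' Cosmetics regulations in China, the United States and Canada cap Pb in
#' cosmetics at 10 mg/kg; a record exceeds only if its concentration is
#' strictly greater than the limit.
#'
#' @param panel a `liprisk_panel`.
#' @param limit_mg_per_kg positive regulatory limit, mg/kg (default 10).
#' @return A list with `flags` (tibble of `sample_id, pb_mg_per_kg,
#'   exceeds`), `n_exceeding`, and `verdict` (`"compliant"` iff no record
#'   exceeds, else `"non_compliant"`).
#' @export
check_limit <- function(panel, limit_mg_per_kg = 10) {
  stopifnot(inherits(panel, "liprisk_panel"))
  assert_scalar_number(limit_mg_per_kg, "limit_mg_per_kg", 0,
                       allow_zero = FALSE)
  exceeds <- panel$pb_mg_per_kg > limit_mg_per_kg
  list(
    flags = tibble::tibble(
      sample_id = panel$sample_id,
      pb_mg_per_kg = panel$pb_mg_per_kg,
      exceeds = exceeds
    ),
    limit_mg_per_kg = limit_mg_per_kg,
    n_exceeding = sum(exceeds),
    verdict = if (any(exceeds)) "non_compliant" else "compliant"
  )
}

#' Correlate Pb concentration with category or price
#'
#' Rank (Spearman, default) or linear (Pearson) correlation between the
#' panel's Pb concentrations and either the ordinal category code or the
#' retail price. Categories are coded lipstick = 1, lip gloss = 2,
#' lip balm = 3 by default (the panel presentation order); pass
#' `category_codes` to recode.
#'
#' @param panel a `liprisk_panel` with at least 3 usable records.
#' @param x `"category"` or `"price"`.
#' @param method `"spearman"` (default; category is ordinal) or `"pearson"`.
#' @param category_codes named numeric vector mapping category to code.
#' @return A list with `estimate` (coefficient in \[-1, 1\]), `p_value`
#'   (two-sided), `method`, `x`, and `n`.
#' @export
correlate_panel <- function(panel, x = c("category", "price"),
                            method = c("spearman", "pearson"),
                            category_codes = c(lipstick = 1, lip_gloss = 2,
                                               lip_balm = 3)) {
  stopifnot(inherits(panel, "liprisk_panel"))
  x <- match.arg(x)
  method <- match.arg(method)
  xv <- switch(x,
    category = unname(category_codes[as.character(panel$category)]),
    price = panel$price_rmb
  )
  keep <- !is.na(xv)
  xv <- xv[keep]
  yv <- panel$pb_mg_per_kg[keep]
  if (length(xv) < 3L) {
    stop_liprisk("correlation needs at least 3 records with non-missing x",
                 "liprisk_validation_error")
  }
  if (length(unique(xv)) == 1L || length(unique(yv)) == 1L) {
    stop_liprisk(
      sprintf("correlation undefined: %s is constant",
              if (length(unique(xv)) == 1L) x else "Pb concentration"),
      "liprisk_degenerate_error")
  }
  ct <- suppressWarnings(
    stats::cor.test(xv, yv, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, x = x, n = length(xv))
}
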