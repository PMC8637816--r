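# Fixture builders shared across test files.

tiny_panel <- function(values, category = "lipstick") {
  sample_panel(
    sample_id = paste0("S", seq_along(values)),
    category = rep_len(category, length(values)),
    pb_mg_per_kg = values
  )
}

panel_csv_text <- function(rows, header = "sample_id,category,brand,production_country,color,price_rmb,pb_mg_per_kg") {
  paste(c(header, rows), collapse = "\n")
}

write_panel_csv <- function(rows, ...) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(panel_csv_text(rows, ...), path)
  path
}
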