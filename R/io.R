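# Delimited-table persistence for all record types. Comma-separated, UTF-8,
# dot decimal, one header row. Numbers are written with 17 significant
# digits so write -> read round-trips are exact to double precision.

.table_schemas <- list(
  thermogram = c("temperature_c", "mass_pct"),
  thermogram_resampled = c("temperature_c", "mass_pct"),
  spectrum = c("wavenumber_cm1", "transmittance_pct", "replicate_id"),
  spectrum_preprocessed = c("wavenumber_cm1", "value"),
  gcms = c("compound", "group", "proportion_pct", "detected"),
  composition = c(gcms_groups(), "htl_temperature_c")
)

.fmt_num <- function(x) sprintf("%.17g", x)

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

.read_table <- function(path, kind) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  want <- .table_schemas[[kind]]
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(want, c("compound", "group", "detected"))
  for (cn in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(vals) & nzchar(df[[cn]]))
    if (length(bad)) {
      stop("parse error in ", basename(path), ", column ", cn, ", row ",
           bad[1L], ": non-numeric cell '", df[[cn]][bad[1L]], "'", call. = FALSE)
    }
    df[[cn]] <- vals
  }
  if ("detected" %in% want) df$detected <- as.logical(df$detected)
  df
}

.record_filename <- function(record) {
  t_tag <- function(x) gsub("[^0-9A-Za-z.]", "_", format(x))
  switch(class(record)[1L],
    thermogram_raw = sprintf("tga_%s.csv", t_tag(record$htl_temperature_c)),
    thermogram_resampled = sprintf("tga_resampled_%s.csv", t_tag(record$htl_temperature_c)),
    ir_spectrum_raw = sprintf("ftir_%s_rep%d.csv", t_tag(record$htl_temperature_c),
                              record$replicate_id),
    ir_preprocessed = sprintf("ftir_preprocessed_%s.csv", t_tag(record$htl_temperature_c)),
    derivative_table = sprintf("gcms_%s.csv", t_tag(attr(record, "htl_temperature_c"))),
    composition_vector = sprintf("composition_%s.csv", t_tag(record$htl_temperature_c)),
    stop("unsupported record class: ", class(record)[1L])
  )
}

.record_kind <- function(record) {
  switch(class(record)[1L],
    thermogram_raw = "thermogram",
    thermogram_resampled = "thermogram_resampled",
    ir_spectrum_raw = "spectrum",
    ir_preprocessed = "spectrum_preprocessed",
    derivative_table = "gcms",
    composition_vector = "composition"
  )
}

.record_to_df <- function(record) {
  switch(class(record)[1L],
    thermogram_raw = data.frame(temperature_c = record$temperature_c,
                                mass_pct = record$mass_pct),
    thermogram_resampled = data.frame(
      temperature_c = seq(record$grid_start_c, record$grid_end_c),
      mass_pct = record$mass_pct),
    ir_spectrum_raw = data.frame(wavenumber_cm1 = record$wavenumber_cm1,
                                 transmittance_pct = record$transmittance_pct,
                                 replicate_id = record$replicate_id),
    ir_preprocessed = data.frame(wavenumber_cm1 = ftir_grid(),
                                 value = record$values),
    derivative_table = data.frame(compound = record$compound, group = record$group,
                                  proportion_pct = record$proportion_pct,
                                  detected = record$detected),
    composition_vector = {
      df <- as.data.frame(as.list(record$fractions))
      names(df) <- gcms_groups()
      df$htl_temperature_c <- record$htl_temperature_c
      df
    }
  )
}

.df_to_record <- function(df, kind, htl_temperature_c, replicate_id = NA_integer_) {
  switch(kind,
    thermogram = thermogram_raw(df$temperature_c, df$mass_pct, htl_temperature_c),
    thermogram_resampled = thermogram_resampled(
      df$mass_pct, grid_start_c = min(df$temperature_c),
      grid_end_c = max(df$temperature_c), htl_temperature_c = htl_temperature_c),
    spectrum = ir_spectrum_raw(df$wavenumber_cm1, df$transmittance_pct,
                               df$replicate_id[1L], htl_temperature_c),
    spectrum_preprocessed = ir_preprocessed(df$value, htl_temperature_c),
    gcms = derivative_table(df$compound, df$group, df$proportion_pct,
                            df$detected, htl_temperature_c),
    composition = {
      composition_vector(unlist(df[1L, gcms_groups()]),
                         htl_temperature_c = df$htl_temperature_c[1L])
    }
  )
}

#' Save a collection of typed records as a CSV bundle
#'
#' Writes one CSV per record under `path` along with a `manifest.json`
#' describing file, table kind and HTL temperature.
#'
#' @param records list of typed records (any mix of the package's types).
#' @param path output directory, created if absent.
#' @return Invisibly, the manifest as a data.frame.
#' @export
save_bundle <- function(records, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create directory ", path)
  entries <- lapply(records, function(r) {
    fn <- .record_filename(r)
    .write_table(.record_to_df(r), file.path(path, fn))
    t_c <- if (inherits(r, "derivative_table")) attr(r, "htl_temperature_c") else r$htl_temperature_c
    data.frame(file = fn, kind = .record_kind(r),
               htl_temperature_c = as.numeric(t_c),
               replicate_id = if (inherits(r, "ir_spectrum_raw")) r$replicate_id else NA_integer_)
  })
  manifest <- if (length(entries)) do.call(rbind, entries) else
    data.frame(file = character(), kind = character(),
               htl_temperature_c = numeric(), replicate_id = integer())
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(manifest)
}

#' Load a CSV bundle back into typed records
#'
#' @param path directory written by [save_bundle()] (or hand-assembled with a
#'   matching `manifest.json`).
#' @param kind optional table kind to restrict to, one of
#'   `"thermogram"`, `"thermogram_resampled"`, `"spectrum"`,
#'   `"spectrum_preprocessed"`, `"gcms"`, `"composition"`.
#' @return List of validated typed records, in manifest order.
#' @export
load_bundle <- function(path, kind = NULL) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("I/O error: no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (length(manifest) == 0 || nrow(manifest) == 0) return(list())
  if (!is.null(kind)) manifest <- manifest[manifest$kind %in% kind, , drop = FALSE]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    df <- .read_table(file.path(path, row$file), row$kind)
    .df_to_record(df, row$kind, row$htl_temperature_c)
  })
}
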