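# Plain-CSV readers and writers for the tables the pipeline exchanges.
# Columns are written exactly as the corresponding record fields so the
# tables round-trip losslessly.

#' Write / read a fire catalog as CSV
#' @param catalog fire catalog data.frame.
#' @param path file path.
#' @export
write_fire_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fire_catalog
#' @export
read_fire_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("road_access" %in% names(df)) df$road_access <- as.logical(df$road_access)
  df
}

#' Write / read a cost table as CSV
#' @param costs cost table.
#' @param path file path.
#' @export
write_cost_table <- function(costs, path) {
  utils::write.csv(costs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cost_table
#' @export
read_cost_table <- function(path) utils::read.csv(path,
                                                  stringsAsFactors = FALSE)

#' Write / read a burned-area series as CSV (region, year, burned_ha)
#' @param series a burned_area_series.
#' @param path file path.
#' @export
write_burned_area_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_burned_area_series
#' @export
read_burned_area_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  burned_area_series(df$region[1], df$year, df$burned_ha)
}

#' Write / read a projection-study table as CSV
#' @param studies projection-study data.frame.
#' @param path file path.
#' @export
write_projection_studies <- function(studies, path) {
  utils::write.csv(studies, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_projection_studies
#' @export
read_projection_studies <- function(path) {
  make_projection_studies(utils::read.csv(path, stringsAsFactors = FALSE))
}
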