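format_num6 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(ifelse(v > 0, "Inf", "-Inf"))
    format(signif(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
  out
}

#' Write result tables deterministically
#'
#' Writes one TSV per result table plus a JSON run manifest. Output is
#' byte-stable: rows are sorted ascending by the first column, column order
#' is preserved, floating-point values are printed at 6 significant digits,
#' and the manifest records the package version, R version, seed and a hash
#' of the configuration, so identical inputs give byte-identical files.
#'
#' @param tables Named list of data frames; list columns are dropped with a
#'   warning (they are not representable in a flat TSV).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @param config Optional configuration object; its hash is recorded.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_, config = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a fully named list.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create directory '%s'.", out_dir))
  files <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    is_list <- vapply(df, is.list, logical(1))
    if (any(is_list)) {
      warn(sprintf("Dropping list column(s) %s from '%s'.",
                   paste(names(df)[is_list], collapse = ", "), nm))
      df <- df[!is_list]
    }
    if (nrow(df) > 0) {
      df <- df[order(df[[1]], method = "radix"), , drop = FALSE]
    }
    out <- df
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], format_num6)
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    lines <- c(
      paste(names(out), collapse = "\t"),
      if (nrow(out) > 0) do.call(paste, c(unname(out), sep = "\t"))
    )
    writeLines(lines, path)
    files <- c(files, path)
  }
  manifest <- list(
    package = "kmeflow",
    package_version = as.character(utils::packageVersion("kmeflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = if (is.null(config)) NULL else rlang::hash(config),
    tables = names(tables)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, manifest_path))
}
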