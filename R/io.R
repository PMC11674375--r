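# Format round-tripping: CSV/TSV tables, group files, enzyme maps, flux
# curves, scaling factors. Dialect: comma-separated, UTF-8, header row,
# '.' decimal; gene symbols case-preserved in files, matched
# case-insensitively downstream.

#' Read a proteomics intensity table from CSV/TSV
#'
#' First column: gene symbol; header row: sample ids. A separate two-column
#' group file (`sample_id, group`) supplies the labels. Non-numeric cells are
#' a parse error naming row and column.
#'
#' @param path intensity CSV/TSV (separator auto-detected from the extension:
#'   `.tsv` -> tab, otherwise comma).
#' @param group_path two-column CSV `sample_id,group`.
#' @return a [proteomics_table()].
#' @export
read_proteomics_csv <- function(path, group_path) {
  if (!file.exists(path)) stop("proteomics table not found: ", path)
  if (!file.exists(group_path)) stop("group file not found: ", group_path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("proteomics table needs a gene column plus >= 1 sample")
  genes <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- matrix(suppressWarnings(as.numeric(mat)), nrow = nrow(mat),
                dimnames = list(NULL, colnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("parse error in '", path, "': non-numeric cell at row '",
         genes[bad[1, 1]], "' (line ", bad[1, 1] + 1L, "), column '",
         colnames(mat)[bad[1, 2]], "': \"", mat[bad[1, 1], bad[1, 2]], "\"")
  }
  if (anyNA(num)) stop("parse error in '", path, "': missing values are not supported")
  rownames(num) <- genes
  grp <- utils::read.csv(group_path, header = TRUE, colClasses = "character")
  if (ncol(grp) < 2) stop("group file must have columns sample_id, group")
  groups <- stats::setNames(grp[[2]], grp[[1]])
  proteomics_table(num, groups)
}

#' Write a proteomics table (plus group file) to CSV
#'
#' @param table a [proteomics_table()].
#' @param path intensity CSV path.
#' @param group_path group CSV path.
#' @return `path`, invisibly.
#' @export
write_proteomics_csv <- function(table, path, group_path) {
  df <- data.frame(gene = rownames(table$intensities),
                   apply(table$intensities, 2, formatC, digits = 15, format = "g"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = names(table$groups),
                              group = unname(table$groups)),
                   group_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an enzyme map from JSON
#'
#' @param path JSON document: object mapping reaction id -> array of gene
#'   symbols.
#' @return an [enzyme_map()].
#' @export
read_enzyme_map <- function(path) {
  if (!file.exists(path)) stop("enzyme map not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  enzyme_map(as.list(doc))
}

#' Write an enzyme map to JSON
#' @param map an [enzyme_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enzyme_map <- function(map, path) {
  jsonlite::write_json(lapply(unclass(map), as.list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write a flux curve to CSV
#'
#' Columns `glucose_mM, glc_flux, lac_flux, converged`, numbers at 15
#' significant digits.
#'
#' @param curve a [glucose_sweep()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  for (cn in c("glucose_mM", "glc_flux", "lac_flux")) {
    df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flux curve from CSV
#' @param path CSV written by [write_flux_curve()].
#' @return a `flux_curve` data.frame.
#' @export
read_flux_curve <- function(path) {
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = c("numeric", "numeric", "numeric", "logical"))
  structure(df, class = c("flux_curve", "data.frame"))
}

#' Write scaling factors to CSV
#'
#' Wide layout: one row per reaction, columns `reaction`, `e_mean_control`,
#' `provenance`, then one column per sample.
#'
#' @param factors a [compute_scaling_factors()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaling_factors <- function(factors, path) {
  df <- data.frame(reaction = rownames(factors$factors),
                   e_mean_control = formatC(factors$e_mean_control, digits = 15, format = "g"),
                   provenance = unname(factors$provenance),
                   apply(factors$factors, 2, formatC, digits = 15, format = "g"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read scaling factors from CSV
#'
#' @param path CSV written by [write_scaling_factors()].
#' @param groups named character vector of group labels per sample.
#' @return a `scaling_factors` object.
#' @export
read_scaling_factors <- function(path, groups) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  fixed <- c("reaction", "e_mean_control", "provenance")
  samples <- setdiff(names(df), fixed)
  fmat <- as.matrix(df[, samples, drop = FALSE])
  rownames(fmat) <- df$reaction
  structure(list(factors = fmat,
                 e_mean_control = stats::setNames(df$e_mean_control, df$reaction),
                 provenance = stats::setNames(df$provenance, df$reaction),
                 groups = groups[samples]),
            class = "scaling_factors")
}

#' Write tidy per-sample ensemble output and group summary to CSV
#'
#' `<prefix>_samples.csv`: sample, group, glucose_mM, glc_flux, lac_flux,
#' converged. `<prefix>_summary.csv`: the group mean/SD table.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, prefix) {
  tidy <- do.call(rbind, lapply(names(ensemble$curves), function(s) {
    cbind(data.frame(sample = s, group = unname(ensemble$groups[[s]])),
          as.data.frame(ensemble$curves[[s]]))
  }))
  for (cn in c("glucose_mM", "glc_flux", "lac_flux")) {
    tidy[[cn]] <- formatC(tidy[[cn]], digits = 15, format = "g")
  }
  p1 <- paste0(prefix, "_samples.csv")
  utils::write.csv(tidy, p1, row.names = FALSE, quote = FALSE)
  smry <- ensemble$summary
  for (cn in c("glucose_mM", "glc_mean", "glc_sd", "lac_mean", "lac_sd")) {
    smry[[cn]] <- formatC(smry[[cn]], digits = 15, format = "g")
  }
  p2 <- paste0(prefix, "_summary.csv")
  utils::write.csv(smry, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
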