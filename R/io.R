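#' Tabular input/output for window samples and result tables
#'
#' Window time series are serialised as tab-separated text with a
#' commented header carrying the window parameters, units and seed; a
#' campaign manifest lists the files with their window definitions.
#'
#' @name io
NULL

#' Write window samples to a tab-separated file
#'
#' @param samples an `hp_window_samples`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_window_samples <- function(samples, file) {
  hdr <- c(
    sprintf("# d0_nm: %.6g", samples$window$d0),
    sprintf("# k_kJ_mol_nm2: %.6g", samples$window$k),
    sprintf("# angle_targets_deg: %.6g %.6g",
            samples$angle_bias$targets[1], samples$angle_bias$targets[2]),
    sprintf("# angle_k_kJ_mol_deg2: %.6g", samples$angle_bias$k),
    sprintf("# stride: %d", samples$stride),
    sprintf("# seed: %d", samples$seed),
    "# units: d_nm nm; theta*_deg deg; E_* kJ/mol; U_total kJ/mol; V_nm3 nm^3")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(samples$series, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read window samples written by [write_window_samples()]
#'
#' @param file path
#' @return an `hp_window_samples`
#' @export
read_window_samples <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1]
    strsplit(sub(paste0("^# ", key, ": *"), "", ln), " +")[[1]]
  }
  series <- utils::read.table(text = lines[!grepl("^#", lines)],
                              header = TRUE, sep = "\t")
  new_window_samples(
    new_window(as.numeric(get("d0_nm")), as.numeric(get("k_kJ_mol_nm2"))),
    new_angle_bias(as.numeric(get("angle_targets_deg")),
                   as.numeric(get("angle_k_kJ_mol_deg2"))),
    series, as.integer(get("stride")), as.integer(get("seed")))
}

#' Write a campaign of window samples plus a manifest
#'
#' @param samples list of `hp_window_samples`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return path of the manifest file, invisibly
#' @export
write_campaign <- function(samples, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    fn <- sprintf("%s_%03d.tsv", prefix, i)
    write_window_samples(samples[[i]], file.path(dir, fn))
    data.frame(file = fn, d0_nm = samples[[i]]$window$d0,
               k = samples[[i]]$window$k, seed = samples[[i]]$seed,
               n_frames = nrow(samples[[i]]$series))
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a campaign directory back into window samples
#'
#' @param manifest path to the manifest written by [write_campaign()]
#' @return list of `hp_window_samples`
#' @export
read_campaign <- function(manifest) {
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t")
  lapply(file.path(dirname(manifest), tab$file), read_window_samples)
}

#' Write a PMF profile as tab-separated text
#'
#' @param pmf an `hp_pmf`
#' @param file output path
#' @export
write_pmf <- function(pmf, file) {
  hdr <- c(sprintf("# orientation: %s", pmf$orientation),
           sprintf("# reference_range_nm: %.6g %.6g",
                   pmf$reference_range[1], pmf$reference_range[2]),
           "# units: d nm; G kJ/mol; sem kJ/mol")
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(pmf$profile, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
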