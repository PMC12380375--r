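#' Read and write optical-constant spectra as delimited text
#'
#' Spectra travel as 3-column whitespace-delimited text (grid, m, kappa)
#' with `#` comment lines; the grid unit is recorded in a header comment
#' `# unit: cm-1` or `# unit: um`.
#'
#' @param path file path
#' @return [read_spectrum()]: an [optical_constants()] object
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  hdr <- readLines(path, n = 5)
  unit <- if (any(grepl("unit:\\s*um", hdr))) "um" else "cm-1"
  d <- read.table(path, comment.char = "#", col.names = c("grid", "m", "kappa"))
  optical_constants(d$grid, d$m, d$kappa, unit)
}

#' @param oc an [optical_constants()] object
#' @rdname read_spectrum
#' @export
write_spectrum <- function(oc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", oc$unit), con)
  write.table(data.frame(oc$grid, oc$m, oc$kappa), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a complex 2-D field as a two-page float TIFF
#'
#' Page 1 holds the real part, page 2 the imaginary part, both 32-bit float;
#' a JSON sidecar `<path>.json` records fov and wavelength.
#'
#' @param field a [complex_field_2d()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_field_tiff <- function(field, path) {
  s <- field$samples
  s[is.na(s)] <- 0 + 0i
  v <- c(Re(s), Im(s))
  off <- min(v)
  sc <- max(v) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF(list((Re(s) - off) / sc, (Im(s) - off) / sc), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(fov = field$fov, wavelength = field$wavelength,
                            offset = off, scale = sc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a complex 2-D field written by [write_field_tiff()]
#'
#' @param path TIFF path with its JSON sidecar
#' @return a [complex_field_2d()]
#' @export
read_field_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  re <- pages[[1]] * meta$scale + meta$offset
  im <- pages[[2]] * meta$scale + meta$offset
  complex_field_2d(matrix(complex(real = re, imaginary = im), nrow(re)),
                   meta$fov, meta$wavelength)
}

#' Write a reproducibility manifest next to generated artifacts
#'
#' Records the configuration, seed, package version and md5 checksums of the
#' written files, so any output is reproducible from configuration + seed
#' alone.
#'
#' @param dir directory containing the artifacts
#' @param config named list describing the run
#' @param seed integer seed of the run
#' @param files character vector of artifact paths
#' @return path of the manifest, invisibly
#' @export
write_manifest <- function(dir, config, seed, files) {
  manifest <- list(
    package = "chemholo",
    version = as.character(utils::packageVersion("chemholo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
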