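#' Write spectra to CSV with a sidecar metadata table
#'
#' One CSV per spectrum: first column the wavenumber (written descending,
#' instrument convention), second the intensity. A sidecar `metadata.csv`
#' maps file names to donor, age, structure, replicate and modality.
#'
#' @param spectra List of [spectrum()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sidecar metadata data frame.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    file <- sprintf("%s_%s_rep%s_%s.csv", s$donor_id, s$structure,
                    s$replicate, s$modality)
    utils::write.csv(
      data.frame(wavenumber = rev(s$wavenumber),
                 intensity = rev(s$intensity)),
      file.path(dir, file), row.names = FALSE)
    data.frame(file = file, donor_id = s$donor_id, age = s$age,
               structure = s$structure,
               replicate = as.character(s$replicate),
               modality = s$modality, stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read spectra written by [write_spectra()]
#'
#' Accepts ascending or descending wavenumber columns (normalised to
#' ascending) and joins the sidecar metadata; a spectrum file missing from
#' the sidecar is an error naming the file.
#'
#' @param dir Directory holding the CSVs and `metadata.csv`.
#' @return List of [spectrum()]s.
#' @export
read_spectra <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("missing sidecar metadata.csv in ", dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "metadata.csv")
  lapply(files, function(f) {
    row <- meta[meta$file == f, , drop = FALSE]
    if (nrow(row) == 0) stop("no metadata for spectrum file ", f)
    d <- utils::read.csv(file.path(dir, f))
    if (ncol(d) < 2 || any(!is.finite(as.matrix(d[, 1:2])))) {
      bad <- which(!stats::complete.cases(d))[1]
      stop("malformed spectrum row ", if (length(bad)) bad else "?",
           " in ", f)
    }
    spectrum(d[[1]], d[[2]], modality = row$modality[1],
             donor_id = row$donor_id[1], age = row$age[1],
             structure = row$structure[1], replicate = row$replicate[1])
  })
}

#' Read a JCAMP-DX spectrum (XYDATA dialect)
#'
#' Minimal reader for the `##XYDATA=(X++(Y..Y))` dialect: fixed-increment
#' X with one leading X value per data line, honouring `##XFACTOR`,
#' `##YFACTOR`, `##FIRSTX`, `##LASTX` and `##NPOINTS`.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @param modality Modality tag for the resulting [spectrum()].
#' @return A [spectrum()].
#' @export
read_jcampdx <- function(path, modality = c("ftir", "raman")) {
  modality <- match.arg(modality)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub(paste0("^##", name, "="), "", hit[1]))
  }
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)
  firstx <- get_field("FIRSTX")
  lastx <- get_field("LASTX")
  npts <- get_field("NPOINTS")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) == 0) stop("no ##XYDATA=(X++(Y..Y)) block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) end <- length(lines) + 1
  body <- lines[seq(start[1] + 1, end - 1)]
  ys <- unlist(lapply(body, function(ln) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    vals[-1] * yfac                       # first token is the line's X
  }))
  if (!is.na(npts) && length(ys) != npts) {
    stop("JCAMP-DX NPOINTS mismatch in ", path, ": expected ", npts,
         ", read ", length(ys))
  }
  x <- seq(firstx, lastx, length.out = length(ys)) * xfac
  spectrum(x, ys, modality = modality)
}

#' Serialise a run configuration to JSON
#'
#' A run is reproducible from its configuration plus seed alone; the JSON
#' round-trips through [read_run_config()].
#'
#' @param config A named list (cohort parameters, noise settings, model
#'   settings, seeds, ...).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
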